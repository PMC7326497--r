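protein,sequence,start,end,max_intensity,products_per_aa,mh_error_ppm,n_identifications
subunitA,GMCCPKDPQ,1,9,50070,0.356,-4.23,3
subunitA,KTGIYFKCFC,8,17,37645,0.138,-0.52,3
subunitA,WKSFQPFLSVSW,15,26,27790,0.172,4,2
subunitA,RGCGLGYCA,24,32,41522,0.25,-2.64,3
subunitA,AHHADRDARWT,31,41,55000,0.477,2.41,3
subunitA,SQWFDVMVGIEAPH,40,53,54084,0.188,4.31,3
subunitA,TGTIDMHVHV,52,61,29204,0.37,-1.61,3
subunitA,MAGDSIDIEFAGI,60,72,31714,0.344,0.4,2
subunitA,AFISCSLCELW,71,81,35891,0.441,1.87,2
subunitA,IDCQVWLMQENKAC,80,93,44150,0.202,1.87,2
subunitA,KQANFGMKWCV,92,102,50457,0.412,1.28,3
subunitA,VEHLEPENIPP,101,111,11517,0.577,3.29,2
subunitA,TIGTLVHVDIT,110,120,34314,0.407,0.77,3
subunitB,WEYKICPRDIFK,1,12,29643,0.365,-1.06,3
subunitB,ISIMQDWCWEKSFM,12,25,32246,0.416,-1.38,3
subunitB,SDQANGKAMQMWYEW,25,39,6355,0.356,-2.32,3
subunitB,DVNNVHGKGCHHD,38,50,33925,0.396,-0.2,3
subunitB,FVHMMFWLFFPNHV,50,63,13615,0.159,-1.52,3
subunitB,TVLSVAYIAEFSEPEFNY,63,80,24789,0.172,-0.02,3
subunitA,AWLKELCK,30,37,3200,0.3,1.2,3
subunitA,HNCQ,57,60,21000,0.25,0.8,3
subunitA,NMRERKPFR,64,72,15000,0.05,2.2,2
subunitA,KYPNADQMTK,85,94,18000,0.4,7.5,3
subunitA,WFVSNGG,97,103,30000,0.2,-1.4,1
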