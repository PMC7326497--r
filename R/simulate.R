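#' Reporter recruitment kinetics
#'
#' Parameters of the piecewise lag / linear / plateau progress curve used by
#' the forward model. The membrane reporter signal of a GUV of radius `R` is
#' zero before `lag_min`, rises linearly at an effective rate
#' `rate_au_per_min + curvature_coupling_b / R`, and clips at `plateau_au`.
#' The diffuse background haze saturates as
#' `baseline_max_au * (1 - exp(-t / baseline_tau_min))`; with the default
#' `baseline_tau_min` shorter than the lag, the haze rises before any membrane
#' signal, reproducing the negative corrected values seen in real lag phases.
#'
#' @param lag_min lag before product accumulation, minutes, >= 0.
#' @param rate_au_per_min curvature-independent accumulation rate, AU/min, >= 0.
#' @param plateau_au saturation level of the membrane signal, AU, > 0.
#' @param baseline_max_au asymptote of the diffuse haze, AU, >= 0.
#' @param baseline_tau_min haze time constant, minutes, > 0.
#' @param curvature_coupling_b curvature coupling, AU*um/min, >= 0; adds
#'   `b / radius_um` to the rate so smaller vesicles accumulate faster.
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(lag_min = 10, rate_au_per_min = 5, plateau_au = 600,
                           baseline_max_au = 100, baseline_tau_min = 5,
                           curvature_coupling_b = 0) {
  p <- list(lag_min = lag_min, rate_au_per_min = rate_au_per_min,
            plateau_au = plateau_au, baseline_max_au = baseline_max_au,
            baseline_tau_min = baseline_tau_min,
            curvature_coupling_b = curvature_coupling_b)
  bad <- !vapply(p, function(v) is.numeric(v) && length(v) == 1L && is.finite(v), TRUE)
  if (any(bad)) guv_stop("kinetic parameters must be finite scalars: ",
                         paste(names(p)[bad], collapse = ", "))
  if (p$lag_min < 0 || p$rate_au_per_min < 0 || p$plateau_au <= 0 ||
      p$baseline_max_au < 0 || p$curvature_coupling_b < 0) {
    guv_stop("kinetic parameter out of domain")
  }
  if (p$baseline_tau_min <= 0) guv_stop("baseline_tau_min must be > 0")
  structure(p, class = "kinetic_params")
}

#' Membrane reporter signal of one GUV
#'
#' @param t time(s) in minutes, >= 0 (vectorized).
#' @param p a [kinetic_params()] object.
#' @param radius_um GUV radius; `Inf` disables the curvature term.
#' @return Signal in AU: `0` for `t < lag`, then
#'   `min(r_eff * (t - lag), plateau)` with
#'   `r_eff = rate_au_per_min + curvature_coupling_b / radius_um`. Continuous
#'   and non-decreasing in `t`; identically zero when `r_eff == 0`.
#' @export
membrane_signal <- function(t, p, radius_um = Inf) {
  stopifnot(inherits(p, "kinetic_params"))
  if (any(t < 0)) guv_stop("t must be >= 0")
  r_eff <- p$rate_au_per_min + p$curvature_coupling_b / radius_um
  pmin(pmax(t - p$lag_min, 0) * r_eff, p$plateau_au)
}

#' Diffuse background haze
#'
#' Uniform reporter background from unbound probe and small particles,
#' saturating exponential in time: `B(t) = baseline_max * (1 - exp(-t / tau))`.
#'
#' @inheritParams membrane_signal
#' @return Haze in AU; `B(0) = 0`, non-decreasing, supremum `baseline_max_au`.
#' @export
baseline_signal <- function(t, p) {
  stopifnot(inherits(p, "kinetic_params"))
  if (any(t < 0)) guv_stop("t must be >= 0")
  p$baseline_max_au * (1 - exp(-t / p$baseline_tau_min))
}

#' Simulation scene
#'
#' Full description of one synthetic GUV movie: field geometry, vesicle
#' positions and radii, optics, kinetics, noise and time grid. When `guvs` is
#' `NULL`, vesicles are placed by seeded rejection sampling with radii drawn
#' uniformly from `radius_range_um`, wholly inside the field, and with centre
#' separations large enough that each vesicle's measurement neighbourhood
#' (1.5 x its radius) contains no foreign membrane.
#'
#' @param image_shape `(rows, cols)` in pixels.
#' @param pixel_size_um micrometres per pixel.
#' @param guvs optional data.frame with columns `center_row_um`,
#'   `center_col_um`, `radius_um`; radii must lie in \[1, 30\] um.
#' @param n_guvs number of vesicles to place when `guvs` is `NULL`.
#' @param radius_range_um sampling range for radii, within \[1, 30\] um.
#' @param membrane_thickness_um width of the rendered annulus.
#' @param psf_sigma_um Gaussian optical blur; `0` renders crisp annuli.
#' @param membrane_dye_au constant brightness of the membrane-dye channel.
#' @param kinetics a [kinetic_params()] object.
#' @param photon_gain detector counts per AU for the scaled-Poisson shot-noise
#'   model; `Inf` disables shot noise.
#' @param read_noise_sd Gaussian read noise, AU; `0` disables it.
#' @param time_grid_min strictly increasing acquisition times, minutes. A
#'   warning is issued when spacings leave the typical 2--3 min range.
#' @param seed integer seed governing placement and noise.
#' @return An object of class `simulation_scene`.
#' @export
simulation_scene <- function(image_shape = c(512, 512), pixel_size_um = 0.25,
                             guvs = NULL, n_guvs = 15,
                             radius_range_um = c(2, 5),
                             membrane_thickness_um = 0.5,
                             psf_sigma_um = 0.2, membrane_dye_au = 300,
                             kinetics = kinetic_params(),
                             photon_gain = 50, read_noise_sd = 1,
                             time_grid_min = seq(0, 60, by = 2.5),
                             seed = 1L) {
  stopifnot(inherits(kinetics, "kinetic_params"))
  if (length(time_grid_min) < 1L || any(diff(time_grid_min) <= 0)) {
    guv_stop("time_grid_min must be non-empty and strictly increasing")
  }
  dt <- diff(time_grid_min)
  if (length(dt) && (any(dt < 2) || any(dt > 3))) {
    warning("time grid spacing outside the typical 2-3 min acquisition range",
            call. = FALSE)
  }
  if (pixel_size_um <= 0 || membrane_thickness_um <= 0 || psf_sigma_um < 0 ||
      membrane_dye_au <= 0 || photon_gain <= 0 || read_noise_sd < 0) {
    guv_stop("scene parameter out of domain")
  }
  fov_um <- image_shape * pixel_size_um
  if (is.null(guvs)) {
    guvs <- withr::with_seed(as.integer(seed), {
      place_guvs(fov_um, n_guvs, radius_range_um, membrane_thickness_um)
    })
  }
  if (any(guvs$radius_um < 1 | guvs$radius_um > 30)) {
    guv_stop("GUV radii must lie in [1, 30] um")
  }
  margin <- guvs$radius_um + membrane_thickness_um / 2
  if (any(guvs$center_row_um - margin < 0 | guvs$center_col_um - margin < 0 |
          guvs$center_row_um + margin > fov_um[1] |
          guvs$center_col_um + margin > fov_um[2])) {
    guv_stop("GUV outside the field of view")
  }
  if (nrow(guvs) > 1L) {
    dd <- as.matrix(stats::dist(guvs[, c("center_row_um", "center_col_um")]))
    rr <- guvs$radius_um
    min_sep <- outer(rr, rr, function(a, b) pmax(1.5 * a + b, 1.5 * b + a))
    diag(dd) <- Inf
    if (any(dd < min_sep)) {
      guv_log("scene contains overlapping/adjacent GUVs")
    }
  }
  structure(
    list(image_shape = as.integer(image_shape), pixel_size_um = pixel_size_um,
         guvs = guvs, membrane_thickness_um = membrane_thickness_um,
         psf_sigma_um = psf_sigma_um, membrane_dye_au = membrane_dye_au,
         kinetics = kinetics, photon_gain = photon_gain,
         read_noise_sd = read_noise_sd,
         time_grid_min = as.numeric(time_grid_min), seed = as.integer(seed)),
    class = "simulation_scene"
  )
}

# rejection-sample non-interfering GUV positions (um coordinates)
place_guvs <- function(fov_um, n_guvs, radius_range_um, thickness_um,
                       max_tries = 20000L) {
  rows <- numeric(0); cols <- numeric(0); rads <- numeric(0)
  tries <- 0L
  while (length(rads) < n_guvs && tries < max_tries) {
    tries <- tries + 1L
    r <- runif(1, radius_range_um[1], radius_range_um[2])
    edge <- r + thickness_um / 2 + 1
    cy <- runif(1, edge, fov_um[1] - edge)
    cx <- runif(1, edge, fov_um[2] - edge)
    if (length(rads)) {
      d <- sqrt((rows - cy)^2 + (cols - cx)^2)
      need <- pmax(1.5 * r + rads, 1.5 * rads + r) + thickness_um + 0.5
      if (any(d < need)) next
    }
    rows <- c(rows, cy); cols <- c(cols, cx); rads <- c(rads, r)
  }
  if (length(rads) < n_guvs) {
    guv_stop("could not place ", n_guvs, " GUVs in a ",
             paste(round(fov_um, 1), collapse = " x "),
             " um field; enlarge the field or shrink radii")
  }
  data.frame(guv_id = paste0("guv", seq_len(n_guvs)),
             center_row_um = rows, center_col_um = cols, radius_um = rads,
             stringsAsFactors = FALSE)
}

# precomputed geometry shared by all frames of one scene
scene_geometry <- function(scene) {
  nr <- scene$image_shape[1]; nc <- scene$image_shape[2]
  px <- scene$pixel_size_um
  yy <- (seq_len(nr) - 0.5) * px
  xx <- (seq_len(nc) - 0.5) * px
  half <- scene$membrane_thickness_um / 2
  sigma_px <- scene$psf_sigma_um / px
  annuli <- vector("list", nrow(scene$guvs))
  blurred <- vector("list", nrow(scene$guvs))
  for (i in seq_len(nrow(scene$guvs))) {
    g <- scene$guvs[i, ]
    d <- sqrt(outer((yy - g$center_row_um)^2, (xx - g$center_col_um)^2, `+`))
    ann <- abs(d - g$radius_um) <= half
    annuli[[i]] <- ann
    blurred[[i]] <- if (sigma_px > 0) gaussian_filter(ann * 1, sigma_px) else ann * 1
  }
  dye <- if (length(blurred)) {
    Reduce(`+`, blurred) * scene$membrane_dye_au
  } else {
    matrix(0, nr, nc)
  }
  list(annuli = annuli, unit_images = blurred, dye_image = dye)
}

apply_noise <- function(img, photon_gain, read_noise_sd) {
  out <- img
  if (is.finite(photon_gain)) {
    out <- rpois(length(img), photon_gain * img) / photon_gain
  }
  if (read_noise_sd > 0) {
    out <- out + rnorm(length(img), 0, read_noise_sd)
  }
  matrix(pmax(out, 0), nrow(img), ncol(img))
}

#' Render one frame of a scene
#'
#' The membrane-dye channel shows constant-brightness annuli at each GUV
#' radius; the reporter channel shows annuli at [membrane_signal()] plus the
#' uniform [baseline_signal()] haze. Both are convolved with the Gaussian PSF
#' and then degraded with scaled-Poisson shot noise and Gaussian read noise
#' (negative pixels clipped to zero). Noise draws consume the current RNG
#' state; seed control lives in [simulate_timelapse()].
#'
#' @param scene a [simulation_scene()].
#' @param t acquisition time, minutes.
#' @param geometry internal precomputation (from repeated calls); leave `NULL`.
#' @return A list with `noisy` and `noiseless`, each a `(2, Y, X)` array with
#'   channels `membrane`, `reporter`.
#' @export
render_frame <- function(scene, t, geometry = NULL) {
  stopifnot(inherits(scene, "simulation_scene"))
  if (is.null(geometry)) geometry <- scene_geometry(scene)
  nr <- scene$image_shape[1]; nc <- scene$image_shape[2]
  rep_img <- matrix(baseline_signal(t, scene$kinetics), nr, nc)
  for (i in seq_along(geometry$unit_images)) {
    s <- membrane_signal(t, scene$kinetics, scene$guvs$radius_um[i])
    if (s > 0) rep_img <- rep_img + geometry$unit_images[[i]] * s
  }
  noiseless <- array(0, c(2L, nr, nc))
  noiseless[1, , ] <- geometry$dye_image
  noiseless[2, , ] <- rep_img
  noisy <- array(0, c(2L, nr, nc))
  noisy[1, , ] <- apply_noise(geometry$dye_image, scene$photon_gain,
                              scene$read_noise_sd)
  noisy[2, , ] <- apply_noise(rep_img, scene$photon_gain, scene$read_noise_sd)
  list(noisy = noisy, noiseless = noiseless)
}

#' Simulate a full time-lapse with ground truth
#'
#' Renders one frame per time point under the scene's seed (identical seeds
#' give bit-identical stacks) and returns the movie together with exact
#' per-GUV annulus masks, true rates and the haze profile.
#'
#' @param scene a [simulation_scene()].
#' @param keep_noiseless also return the noise-free stack (used by
#'   forward-model consistency checks).
#' @return A list with elements:
#'   * `stack`: a [image_stack()] with channels `membrane`, `reporter`;
#'   * `truth`: list with `guvs` (placement plus `true_rate_au_per_min`
#'     = `rate + b / R`), `masks` (per-GUV logical annulus, frame-invariant),
#'     `baseline` (haze value per frame) and optionally `noiseless`
#'     (a noise-free `guv_stack`).
#' @export
simulate_timelapse <- function(scene, keep_noiseless = FALSE) {
  stopifnot(inherits(scene, "simulation_scene"))
  if (length(scene$time_grid_min) < 1L) guv_stop("empty time grid")
  geometry <- scene_geometry(scene)
  nt <- length(scene$time_grid_min)
  nr <- scene$image_shape[1]; nc <- scene$image_shape[2]
  pix <- array(0, c(nt, 2L, nr, nc))
  clean <- if (keep_noiseless) array(0, c(nt, 2L, nr, nc)) else NULL
  withr::with_seed(scene$seed, {
    for (t in seq_len(nt)) {
      fr <- render_frame(scene, scene$time_grid_min[t], geometry)
      pix[t, , , ] <- fr$noisy
      if (keep_noiseless) clean[t, , , ] <- fr$noiseless
    }
  })
  channels <- c("membrane", "reporter")
  stack <- image_stack(pix, time_min = scene$time_grid_min,
                       channels = channels,
                       pixel_size_um = scene$pixel_size_um)
  truth_guvs <- scene$guvs
  truth_guvs$true_rate_au_per_min <-
    scene$kinetics$rate_au_per_min +
    scene$kinetics$curvature_coupling_b / truth_guvs$radius_um
  truth <- list(
    guvs = truth_guvs,
    masks = geometry$annuli,
    baseline = baseline_signal(scene$time_grid_min, scene$kinetics),
    scene = scene
  )
  if (keep_noiseless) {
    truth$noiseless <- image_stack(clean, time_min = scene$time_grid_min,
                                   channels = channels,
                                   pixel_size_um = scene$pixel_size_um)
  }
  guv_log("simulate_timelapse: ", nt, " frame(s), ", nrow(scene$guvs),
          " GUV(s), seed ", scene$seed)
  list(stack = stack, truth = truth)
}
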