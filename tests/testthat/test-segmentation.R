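# DoG segmentation, membrane extraction, labelling, circle fit.

test_that("DoG response cancels DC and reproduces the sampled kernel", {
  const <- matrix(9, 21, 21)
  expect_lt(max(abs(dog_response(const, 1, 3))), 1e-9)

  # unit impulse: response equals the difference of the two sampled kernels
  imp <- matrix(0, 41, 41)
  imp[21, 21] <- 1
  resp <- dog_response(imp, 1.2, 3.1)
  r <- ceiling(4 * 3.1)
  g <- function(s) {
    k1 <- exp(-(-r:r)^2 / (2 * s^2)); k1 <- k1 / sum(k1)
    outer(k1, k1)
  }
  want <- g(1.2) - g(3.1)
  expect_lt(max(abs(resp[21 + (-r:r), 21 + (-r:r)] - want)), 1e-10)

  expect_error(dog_response(imp, 1, 0.5), "sigma")
})

test_that("channel segmentation finds rings and stays empty on blanks", {
  expect_warning(m <- segment_channel(matrix(0, 32, 32)), "constant")
  expect_false(any(m))

  # noiseless single ring: recall >= 0.9 against the true annulus
  sc <- noiseless_scene(n_guvs = 1, seed = 2)
  sim <- simulate_timelapse(sc)
  mask <- segment_channel(sim$stack$pixels[1, 1, , ])
  ann <- sim$truth$masks[[1]]
  expect_gte(sum(mask & ann) / sum(ann), 0.9)

  # two rings: both annuli hit
  sc2 <- noiseless_scene(n_guvs = 2, seed = 3)
  sim2 <- simulate_timelapse(sc2)
  mask2 <- segment_channel(sim2$stack$pixels[1, 1, , ])
  for (ann in sim2$truth$masks) {
    expect_gt(sum(mask2 & ann) / sum(ann), 0.5)
  }
})

test_that("mask union is an elementwise OR", {
  a <- matrix(FALSE, 4, 4); a[1, 1] <- a[2, 2] <- TRUE
  b <- matrix(FALSE, 4, 4); b[3, 3] <- b[4, 4] <- TRUE
  expect_equal(union_masks(a, matrix(FALSE, 4, 4)), a)
  expect_equal(union_masks(a, a), a)
  expect_equal(sum(union_masks(a, b)), 4)
  expect_error(union_masks(a, matrix(FALSE, 3, 3)), "shape")
})

test_that("membrane extraction reproduces the enumeration oracle", {
  # 7x7 filled square, 1 px contour: 24-pixel border ring
  sq <- matrix(FALSE, 9, 9)
  sq[2:8, 2:8] <- TRUE
  got <- extract_membrane(sq, thickness_um = 1, pixel_size_um = 1)
  expect_equal(sum(got$membrane), 24)
  expect_equal(got$membrane, oracle_extract_membrane_k1(sq)$membrane)

  # empty input -> empty outputs
  e <- extract_membrane(matrix(FALSE, 9, 9), 1, 1)
  expect_false(any(e$membrane) || any(e$filled))

  # property: agreement with the pixel-enumeration oracle on random 9x9 masks,
  # and the contour is always inside the original segmentation and disjoint
  # from the eroded interior
  set.seed(7)
  for (i in 1:40) {
    m <- matrix(runif(81) < runif(1, 0.15, 0.6), 9, 9)
    got <- extract_membrane(m, 1, 1)
    want <- oracle_extract_membrane_k1(m)
    expect_equal(got$membrane, want$membrane)
    expect_equal(got$filled, want$filled)
    expect_true(all(got$membrane <= m))
    eroded <- oracle_erode(got$filled, matrix(1, 3, 3))
    expect_false(any(got$membrane & eroded))
  }

  expect_warning(extract_membrane(sq, thickness_um = 0.1, pixel_size_um = 1),
                 "clamped")
})

test_that("vesicle labelling filters size and circularity and fits radii", {
  # one rasterized disc of radius 10 px
  shape <- c(48, 48)
  d <- sqrt(outer((1:48 - 24)^2, (1:48 - 24)^2, `+`))
  disc <- d <= 10
  ring <- d >= 9 & d <= 10
  regions <- label_guvs(disc, ring, pixel_size_um = 1, min_radius_um = 1)
  expect_length(regions, 1)
  expect_lt(abs(regions[[1]]$radius_eq_px - 10), 0.5)

  # two disjoint discs
  disc2 <- disc | (sqrt(outer((1:48 - 10)^2, (1:48 - 38)^2, `+`)) <= 5)
  regions2 <- label_guvs(disc2, ring, pixel_size_um = 1, min_radius_um = 1)
  expect_length(regions2, 2)

  # a disc below the size threshold is discarded
  small <- sqrt(outer((1:48 - 24)^2, (1:48 - 24)^2, `+`)) <= 3
  expect_length(label_guvs(small, small, pixel_size_um = 1, min_radius_um = 5), 0)

  # 8-connectivity: two squares touching only at a corner are one component
  corner <- matrix(FALSE, 12, 12)
  corner[2:6, 2:6] <- TRUE
  corner[7:11, 7:11] <- TRUE
  lbl <- guvkin:::label_components8(corner)
  expect_equal(max(lbl), 1)
})

test_that("Kåsa circle fit is exact on circles and rejects degenerate input", {
  pts <- rbind(c(0, 1), c(1, 0), c(0, -1), c(-1, 0))
  f <- fit_circle(pts)
  expect_equal(f$center, c(0, 0), tolerance = 1e-12)
  expect_equal(f$radius_px, 1, tolerance = 1e-12)

  f2 <- fit_circle(rbind(c(0, 0), c(2, 0), c(0, 2)))
  expect_equal(f2$center, c(1, 1), tolerance = 1e-12)
  expect_equal(f2$radius_px, sqrt(2), tolerance = 1e-12)

  expect_error(fit_circle(rbind(c(0, 0), c(1, 1), c(2, 2))), "collinear")
  expect_error(fit_circle(rbind(c(0, 0), c(1, 1))), "3 points")
})

test_that("maximum projection is the elementwise max", {
  a <- matrix(c(1, 3, 5, 2), 2, 2, byrow = TRUE)
  b <- matrix(c(2, 0, 1, 9), 2, 2, byrow = TRUE)
  expect_equal(max_project(list(a)), a)
  expect_equal(max_project(list(a, b)),
               matrix(c(2, 3, 5, 9), 2, 2, byrow = TRUE))
  expect_error(max_project(list(a, matrix(0, 3, 3))), "shape")

  # projected simulated slices dominate every single slice on the annulus
  sc <- noiseless_scene(n_guvs = 1, seed = 6)
  sim <- simulate_timelapse(sc)
  slices <- lapply(1:5, function(t) sim$stack$pixels[t, 2, , ])
  proj <- max_project(slices)
  ann <- sim$truth$masks[[1]]
  for (s in slices) expect_true(all(proj[ann] >= s[ann]))
})

test_that("noiseless scenes segment to accurate membranes and radii", {
  sc <- noiseless_scene(n_guvs = 4, seed = 21)
  sim <- simulate_timelapse(sc)
  seg <- segment_stack(sim$stack)
  expect_length(seg$regions, 4)
  mt <- match_truth(seg$regions, sc$guvs, sc$pixel_size_um)
  for (j in seq_along(seg$regions)) {
    i <- mt[j, "truth_index"]
    ann <- sim$truth$masks[[i]]
    rg <- seg$regions[[j]]
    mem <- matrix(FALSE, nrow(ann), ncol(ann))
    mem[rg$membrane_idx] <- TRUE
    jac <- sum(mem & ann) / sum(mem | ann)
    expect_gte(jac, 0.6)
    expect_lt(abs(rg$radius_um - sc$guvs$radius_um[i]) / sc$guvs$radius_um[i],
              0.05)
  }
})

test_that("segmentation is deterministic and consumes no randomness", {
  sc <- noisy_scene(n_guvs = 2, seed = 31)
  sim <- simulate_timelapse(sc)
  set.seed(123)
  rng_before <- .Random.seed
  seg1 <- segment_stack(sim$stack)
  expect_identical(.Random.seed, rng_before)
  seg2 <- segment_stack(sim$stack)
  expect_identical(seg1$frame_masks, seg2$frame_masks)
  expect_identical(lapply(seg1$regions, `[[`, "membrane_idx"),
                   lapply(seg2$regions, `[[`, "membrane_idx"))
})
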