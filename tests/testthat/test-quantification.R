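# Trace measurement, baseline estimation and subtraction.

make_region <- function(label, idx, centroid = c(2, 2), radius = 2) {
  structure(list(label = label, centroid = centroid, area_px = length(idx),
                 circularity = 1, radius_eq_px = radius, radius_px = radius,
                 radius_um = radius, membrane_idx = idx),
            class = "guv_region")
}

test_that("trace values are plain means over the membrane pixels", {
  px <- array(0, c(2, 1, 2, 2))
  px[1, 1, , ] <- matrix(c(1, 3, 2, 4), 2, 2)  # column-major: [[1,2],[3,4]]
  px[2, 1, , ] <- 7
  s <- image_stack(px, time_min = c(0, 2.5), channels = "reporter",
                   pixel_size_um = 1)
  rg <- make_region(1, 1:4)
  tr <- measure_traces(s, list(rg))
  expect_equal(tr[[1]]$raw, c(2.5, 7))

  # an empty region-frame is a flagged missing value, never a silent zero
  masks <- list(matrix(TRUE, 2, 2), matrix(FALSE, 2, 2))
  tr2 <- measure_traces(s, list(make_region(1, 1:4, centroid = c(1.5, 1.5),
                                            radius = 2)), masks)
  expect_true(is.na(tr2[[1]]$raw[2]) && !is.na(tr2[[1]]$raw[1]))

  expect_error(measure_traces(s, list(make_region(1, 5L))), "out-of-bounds")
})

test_that("baseline averages the per-region temporal profiles unweighted", {
  px <- array(0, c(3, 1, 6, 6))
  px[1, 1, , ] <- 0; px[2, 1, , ] <- 0; px[3, 1, , ] <- 0
  px[, 1, 1:2, 1:2] <- c(1, 2, 3)  # region A profile 1,2,3 (recycled per px)
  px[, 1, 5:6, 5:6] <- c(3, 4, 5)  # region B profile 3,4,5
  s <- image_stack(px, time_min = c(0, 2, 4), channels = "reporter",
                   pixel_size_um = 1)
  rois <- roi_set(list(
    list(id = "a", kind = "background", shape = "polygon",
         vertices = rbind(c(0.6, 0.6), c(0.6, 2.4), c(2.4, 2.4), c(2.4, 0.6))),
    list(id = "b", kind = "background", shape = "polygon",
         vertices = rbind(c(4.6, 4.6), c(4.6, 6.4), c(6.4, 6.4), c(6.4, 4.6)))
  ), c(6, 6))
  bl <- estimate_baseline(s, rois, "reporter")
  expect_equal(bl$values, c(2, 3, 4))
  expect_equal(bl$n_regions, 2)

  # a single region: the baseline is that region's own profile
  bl1 <- estimate_baseline(s, roi_set(rois$rois[1], c(6, 6)), "reporter")
  expect_equal(bl1$values, c(1, 2, 3))

  # permutation invariance of region order
  bl_rev <- estimate_baseline(s, roi_set(rev(rois$rois), c(6, 6)), "reporter")
  expect_equal(bl_rev$values, bl$values)

  empty <- roi_set(list(), c(6, 6))
  expect_error(estimate_baseline(s, empty, "reporter"), "baseline required")
})

test_that("baseline subtraction preserves negatives and conserves raw", {
  tr <- guvkin:::new_trace("guv1", "reporter", c(0, 2, 4), c(5, 6, 7))
  bl <- structure(list(time_min = c(0, 2, 4), values = c(2, 3, 4),
                       n_regions = 1), class = "guv_baseline")
  out <- subtract_baseline(tr, bl)
  expect_equal(out$corrected, c(3, 3, 3))
  expect_equal(out$corrected + bl$values, out$raw)  # conservation

  trn <- guvkin:::new_trace("guv1", "reporter", c(0, 2, 4), c(0, 0, 0))
  blp <- structure(list(time_min = c(0, 2, 4), values = c(1, 1, 1),
                        n_regions = 1), class = "guv_baseline")
  expect_equal(subtract_baseline(trn, blp)$corrected, c(-1, -1, -1))

  bl0 <- structure(list(time_min = c(0, 2, 4), values = c(0, 0, 0),
                        n_regions = 1), class = "guv_baseline")
  expect_equal(subtract_baseline(tr, bl0)$corrected, tr$raw)

  blx <- structure(list(time_min = c(0, 1, 2), values = c(0, 0, 0),
                        n_regions = 1), class = "guv_baseline")
  expect_error(subtract_baseline(tr, blx), "time grids differ")
})

test_that("measured traces on truth masks match the analytic model", {
  sc <- noiseless_scene(n_guvs = 3, seed = 14)
  sim <- simulate_timelapse(sc)
  regions <- lapply(seq_len(3), function(i) {
    make_region(i, which(sim$truth$masks[[i]]))
  })
  traces <- measure_traces(sim$stack, regions)
  rep_traces <- Filter(function(t) t$channel == "reporter", traces)
  for (i in seq_len(3)) {
    want <- membrane_signal(sc$time_grid_min, sc$kinetics,
                            sc$guvs$radius_um[i]) +
      baseline_signal(sc$time_grid_min, sc$kinetics)
    expect_lt(max(abs(rep_traces[[i]]$raw - want) / pmax(want, 1)), 1e-6)
  }
})

test_that("with haze, corrected pre-lag traces are zero in expectation", {
  sc <- noisy_scene(n_guvs = 3, seed = 19)
  sim <- simulate_timelapse(sc)
  res <- run_guv_pipeline(sim$stack)
  rep_tr <- Filter(function(t) t$channel == "reporter", res$traces)
  pre <- which(sc$time_grid_min < sc$kinetics$lag_min)
  vals <- unlist(lapply(rep_tr, function(t) t$corrected[pre]))
  vals <- vals[is.finite(vals)]
  # band: 3 x the standard error of the pooled pre-lag mean
  expect_lt(abs(mean(vals)), 3 * sd(vals) / sqrt(length(vals)))
  # conservation on a full pipeline run
  for (tr in rep_tr) {
    expect_equal(tr$corrected + res$baseline$values, tr$raw, tolerance = 1e-9)
  }
})

test_that("background ROI placement is deterministic and avoids vesicles", {
  sc <- noisy_scene(n_guvs = 3, seed = 23)
  sim <- simulate_timelapse(sc)
  seg <- segment_stack(sim$stack)
  r1 <- auto_background_rois(seg$reference$filled)
  r2 <- auto_background_rois(seg$reference$filled)
  expect_identical(r1, r2)
  expect_length(r1$rois, 10)
  for (r in r1$rois) {
    disc <- roi_pixels(r, dim(seg$reference$filled))
    expect_false(any(disc & seg$reference$filled))
  }
})
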