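# Independent oracle implementations used to cross-check the package's
# operations. These are deliberately written with different machinery
# (explicit pixel enumeration, lm(), exhaustive loops) from the code they
# check.

# erosion by pixel enumeration: a pixel survives when every in-bounds
# neighbour covered by the structuring element is foreground
oracle_erode <- function(mask, se) {
  nr <- nrow(mask); nc <- ncol(mask)
  cy <- (nrow(se) + 1L) %/% 2L; cx <- (ncol(se) + 1L) %/% 2L
  offs <- which(se > 0, arr.ind = TRUE)
  offs[, 1] <- offs[, 1] - cy; offs[, 2] <- offs[, 2] - cx
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (!mask[i, j]) next
      ok <- TRUE
      for (k in seq_len(nrow(offs))) {
        y <- i + offs[k, 1]; x <- j + offs[k, 2]
        if (y >= 1 && y <= nr && x >= 1 && x <= nc && !mask[y, x]) {
          ok <- FALSE; break
        }
      }
      out[i, j] <- ok
    }
  }
  out
}

# hole filling by flood fill of the 4-connected background from the border
oracle_fill <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  reach <- matrix(FALSE, nr, nc)
  queue <- list()
  for (i in seq_len(nr)) for (j in c(1L, nc)) {
    if (!mask[i, j]) queue[[length(queue) + 1L]] <- c(i, j)
  }
  for (j in seq_len(nc)) for (i in c(1L, nr)) {
    if (!mask[i, j]) queue[[length(queue) + 1L]] <- c(i, j)
  }
  while (length(queue)) {
    p <- queue[[length(queue)]]
    queue[[length(queue)]] <- NULL
    i <- p[1]; j <- p[2]
    if (reach[i, j] || mask[i, j]) next
    reach[i, j] <- TRUE
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      y <- i + d[1]; x <- j + d[2]
      if (y >= 1 && y <= nr && x >= 1 && x <= nc && !reach[y, x] && !mask[y, x]) {
        queue[[length(queue) + 1L]] <- c(y, x)
      }
    }
  }
  mask | !reach
}

# full membrane extraction oracle for k = 1 (3x3 square structuring element)
oracle_extract_membrane_k1 <- function(mask) {
  filled <- oracle_fill(mask)
  se <- matrix(1, 3, 3)
  gradient <- filled & !oracle_erode(filled, se)
  list(membrane = gradient & mask, filled = filled)
}

# linear-window oracle: exhaustive enumeration using lm()
oracle_linear_window <- function(time_min, values, min_points = 4,
                                 r2_min = 0.95) {
  n <- length(values)
  best <- NULL; fallback <- NULL
  for (s in seq_len(n - min_points + 1L)) {
    for (e in seq(s + min_points - 1L, n)) {
      idx <- s:e
      ok <- is.finite(values[idx])
      if (sum(ok) < min_points) next
      fit <- lm(values[idx][ok] ~ time_min[idx][ok])
      sl <- unname(coef(fit)[2])
      r2 <- summary(fit)$r.squared
      if (!is.finite(sl)) next
      len <- e - s + 1L
      cand <- list(start = s, end = e, slope = sl, r2 = r2, len = len)
      if (len == min_points &&
          (is.null(fallback) || sl > fallback$slope + 1e-12)) fallback <- cand
      if (is.finite(r2) && r2 >= r2_min && var(values[idx][ok]) > 0) {
        if (is.null(best) || sl > best$slope + 1e-12 ||
            (abs(sl - best$slope) <= 1e-12 &&
             (len > best$len || (len == best$len && s < best$start)))) {
          best <- cand
        }
      }
    }
  }
  if (!is.null(best)) c(best, low_confidence = FALSE)
  else c(fallback, low_confidence = TRUE)
}

# match each detected region to the nearest ground-truth vesicle
match_truth <- function(regions, truth_guvs, pixel_size_um) {
  t(vapply(regions, function(rg) {
    cy <- (rg$centroid[1] - 0.5) * pixel_size_um
    cx <- (rg$centroid[2] - 0.5) * pixel_size_um
    d <- sqrt((truth_guvs$center_row_um - cy)^2 +
              (truth_guvs$center_col_um - cx)^2)
    i <- which.min(d)
    c(truth_index = i, dist_um = d[i])
  }, c(truth_index = 0, dist_um = 0)))
}
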