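# Membrane-ring segmentation: difference-of-Gaussians band-pass, threshold,
# channel union, hole filling and an internal morphological gradient of
# calibrated thickness. Everything here is deterministic (no RNG).

# mirror-padded 2-D convolution via EBImage::filter2 (FFT); the pad width
# covers the kernel support so the circular wrap never reaches real pixels
filter_mirror <- function(img, kernel) {
  pad <- (dim(kernel) - 1L) %/% 2L
  nr <- nrow(img); nc <- ncol(img)
  py <- pmin(pad[1], nr - 1L); px <- pmin(pad[2], nc - 1L)
  ridx <- c(rev(seq_len(py) + 1L), seq_len(nr), nr - seq_len(py))
  cidx <- c(rev(seq_len(px) + 1L), seq_len(nc), nc - seq_len(px))
  big <- img[ridx, cidx]
  out <- EBImage::filter2(big, kernel, boundary = "circular")
  out[py + seq_len(nr), px + seq_len(nc)]
}

gaussian_kernel_1d <- function(sigma, radius = ceiling(4 * sigma)) {
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

gaussian_kernel_2d <- function(sigma, radius = ceiling(4 * sigma)) {
  k1 <- gaussian_kernel_1d(sigma, radius)
  outer(k1, k1)
}

# isotropic Gaussian blur with mirrored boundaries (used by the simulator)
gaussian_filter <- function(img, sigma) {
  if (sigma <= 0) return(img)
  filter_mirror(img, gaussian_kernel_2d(sigma))
}

#' Difference-of-Gaussians band-pass response
#'
#' `G_sigma_small * frame - G_sigma_large * frame` with mirrored boundary
#' handling; enhances ring-like membrane structures at the scale between the
#' two sigmas and cancels exactly on constant frames.
#'
#' @param frame 2-D numeric matrix `(row, col)`.
#' @param sigma_small_px,sigma_large_px Gaussian scales in pixels,
#'   `0 < sigma_small_px < sigma_large_px`.
#' @return Real-valued matrix of the same shape (zero-mean on constants).
#' @export
dog_response <- function(frame, sigma_small_px, sigma_large_px) {
  if (!is.matrix(frame)) guv_stop("frame must be a 2-D matrix")
  if (!(sigma_small_px > 0 && sigma_small_px < sigma_large_px)) {
    guv_stop("need 0 < sigma_small_px < sigma_large_px")
  }
  r <- ceiling(4 * sigma_large_px)
  k <- gaussian_kernel_2d(sigma_small_px, r) - gaussian_kernel_2d(sigma_large_px, r)
  filter_mirror(frame, k)
}

# Otsu threshold of an arbitrary real image, computed on a 256-level
# normalization of its range
otsu_threshold <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) return(Inf)
  x01 <- (x - rng[1]) / diff(rng)
  th01 <- EBImage::otsu(x01, range = c(0, 1), levels = 256L)
  rng[1] + th01 * diff(rng)
}

#' Segment one channel of one frame
#'
#' Thresholds the difference-of-Gaussians response. The default threshold is
#' Otsu's method on the response histogram, guarded by a robust noise floor
#' (`median + noise_floor_mads` scaled MADs of the response): Otsu always
#' splits a histogram, so on a signal-free noisy frame it would return a dense
#' noise mask; the floor keeps such frames empty. A constant response yields
#' an empty mask with a warning.
#'
#' @param frame 2-D numeric matrix.
#' @param sigma_small_px,sigma_large_px DoG scales; the pipeline default is
#'   `sigma_small = 0.5 * membrane_thickness / pixel_size` and
#'   `sigma_large = 3 * sigma_small`.
#' @param threshold `"otsu"` or a fixed numeric threshold on the response.
#' @param noise_floor_mads multiple of the response MAD added to its median to
#'   form the minimum admissible threshold; `0` disables the guard.
#' @return Logical matrix: `response > threshold`.
#' @export
segment_channel <- function(frame, sigma_small_px = 1, sigma_large_px = 3,
                            threshold = "otsu", noise_floor_mads = 6) {
  resp <- dog_response(frame, sigma_small_px, sigma_large_px)
  if (diff(range(resp)) < 1e-9) {
    warning("constant DoG response; returning empty mask", call. = FALSE)
    return(matrix(FALSE, nrow(resp), ncol(resp)))
  }
  if (is.numeric(threshold)) {
    th <- threshold
  } else if (identical(threshold, "otsu")) {
    th <- otsu_threshold(resp)
    if (noise_floor_mads > 0) {
      floor_th <- median(resp) + noise_floor_mads * mad(resp)
      th <- max(th, floor_th)
    }
  } else {
    guv_stop("threshold must be \"otsu\" or a number")
  }
  resp > th
}

#' Union of two channel masks
#'
#' @param mask_a,mask_b logical matrices of equal shape.
#' @return Elementwise OR.
#' @export
union_masks <- function(mask_a, mask_b) {
  if (!all(dim(mask_a) == dim(mask_b))) guv_stop("mask shapes differ")
  mask_a | mask_b
}

# structuring elements: radius 1 is the 3x3 square; larger radii are
# EBImage disc brushes of diameter 2r+1
struct_disc <- function(radius_px) {
  EBImage::makeBrush(2L * as.integer(radius_px) + 1L, shape = "disc")
}

#' Extract the calibrated-thickness membrane band
#'
#' Reproduces the macro pipeline: optional morphological opening (smoothing),
#' hole filling of the ring interiors, an internal morphological gradient of
#' `k = round(thickness_um / pixel_size_um)` pixels (the filled region minus
#' its erosion by a disc of `k` px), and finally intersection with the
#' original segmentation so spurious interior signal is discarded.
#'
#' @param union_mask logical matrix from [union_masks()].
#' @param thickness_um calibrated contour thickness.
#' @param pixel_size_um micrometres per pixel.
#' @param smooth_radius_px radius of the opening disc; `0` (the default)
#'   skips smoothing, which would erase membrane rings thinner than about
#'   3 px (see the methods vignette).
#' @return List with `membrane` (the thick-contour band intersected with the
#'   segmentation) and `filled` (the hole-filled region), both logical.
#' @export
extract_membrane <- function(union_mask, thickness_um, pixel_size_um,
                             smooth_radius_px = 0) {
  if (thickness_um <= 0 || pixel_size_um <= 0) {
    guv_stop("thickness_um and pixel_size_um must be > 0")
  }
  m <- union_mask * 1
  if (smooth_radius_px > 0) {
    m <- EBImage::opening(m, struct_disc(smooth_radius_px))
  }
  filled <- EBImage::fillHull(m)
  k <- round(thickness_um / pixel_size_um)
  if (k < 1) {
    warning("contour thickness below one pixel; clamped to 1 px", call. = FALSE)
    k <- 1L
  }
  eroded <- EBImage::erode(filled, struct_disc(k))
  gradient <- (filled > 0) & !(eroded > 0)
  list(membrane = gradient & union_mask, filled = filled > 0)
}

# 8-connected labelling: EBImage::bwlabel is 4-connected, so labels touching
# only diagonally are merged with a union-find pass
label_components8 <- function(mask) {
  lbl <- EBImage::imageData(EBImage::bwlabel(mask * 1))
  n <- max(lbl)
  if (n <= 1) return(lbl)
  nr <- nrow(lbl); nc <- ncol(lbl)
  a1 <- lbl[-nr, -nc]; b1 <- lbl[-1, -1]     # down-right diagonal
  a2 <- lbl[-nr, -1];  b2 <- lbl[-1, -nc]    # down-left diagonal
  pairs <- rbind(cbind(as.vector(a1), as.vector(b1)),
                 cbind(as.vector(a2), as.vector(b2)))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  parent <- seq_len(n)
  if (nrow(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      ra <- pairs[r, 1]; rb <- pairs[r, 2]
      while (parent[ra] != ra) ra <- parent[ra]
      while (parent[rb] != rb) rb <- parent[rb]
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(n), function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }, 0L)
  relabel <- match(root, sort(unique(root)))
  out <- lbl
  out[lbl > 0] <- relabel[lbl[lbl > 0]]
  out
}

#' Algebraic least-squares circle fit (Kåsa)
#'
#' Fits a circle to `(row, col)` points by linear least squares; exact when
#' the points lie on a circle.
#'
#' @param points numeric matrix with columns `(row, col)`, at least 3
#'   non-collinear points.
#' @return List with `center` (`c(row, col)`) and `radius_px`.
#' @export
fit_circle <- function(points) {
  if (!is.matrix(points)) points <- as.matrix(points)
  if (nrow(points) < 3L) guv_stop("circle fit needs >= 3 points")
  y <- points[, 1]; x <- points[, 2]
  A <- cbind(2 * y, 2 * x, 1)
  rhs <- y^2 + x^2
  qrA <- qr(A)
  if (qrA$rank < 3L) guv_stop("degenerate geometry: points are collinear")
  beta <- qr.coef(qrA, rhs)
  center <- beta[1:2]
  radius <- sqrt(beta[3] + sum(center^2))
  list(center = unname(center), radius_px = unname(radius))
}

#' Label GUV regions
#'
#' Finds 8-connected components of the filled mask; computes per component the
#' centroid, the equivalent radius `sqrt(area / pi)` of the filled section,
#' the circularity `4 pi area / perimeter^2`, and the set of membrane-band
#' pixels within 1.5 x the radius of the centroid. Components smaller than
#' `min_radius_um` or less circular than `min_circularity` (e.g. touching
#' vesicles merged into one blob) are discarded and logged, mirroring manual
#' ROI curation. The reported `radius_px` / `radius_um` is the Kåsa circle fit
#' through the membrane-band pixels (the band midline, an unbiased estimate of
#' the vesicle radius); the filled-section equivalent radius, which tracks the
#' outer membrane edge, is kept as `radius_eq_px`.
#'
#' @param filled_mask,membrane_mask logical matrices from [extract_membrane()].
#' @param pixel_size_um micrometres per pixel.
#' @param min_radius_um discard components with equivalent radius below this.
#' @param min_circularity discard components below this circularity.
#' @return List of `guv_region` objects: `label`, `centroid` (row, col),
#'   `area_px`, `circularity`, `radius_eq_px`, `radius_px`, `radius_um`,
#'   `membrane_idx` (linear pixel indices of the band).
#' @export
label_guvs <- function(filled_mask, membrane_mask, pixel_size_um,
                       min_radius_um = 1, min_circularity = 0.7) {
  if (!all(dim(filled_mask) == dim(membrane_mask))) guv_stop("mask shapes differ")
  lbl <- label_components8(filled_mask)
  n <- max(lbl)
  if (n == 0) return(list())
  nr <- nrow(lbl)
  idx <- which(lbl > 0)
  labs <- lbl[idx]
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  area <- tabulate(labs, n)
  cy <- rowsum(rows, labs)[, 1] / area
  cx <- rowsum(cols, labs)[, 1] / area
  shp <- EBImage::computeFeatures.shape(lbl)
  per <- shp[, "s.perimeter"]
  circ <- ifelse(per > 0, 4 * pi * area / per^2, 0)
  r_eq <- sqrt(area / pi)
  keep <- which(r_eq * pixel_size_um >= min_radius_um & circ >= min_circularity)
  if (length(keep) < n) {
    guv_log("label_guvs: discarded ", n - length(keep),
            " component(s) failing size/circularity filters")
  }
  mem_idx_all <- which(membrane_mask)
  mem_rows <- (mem_idx_all - 1L) %% nr + 1L
  mem_cols <- (mem_idx_all - 1L) %/% nr + 1L
  out <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    d2 <- (mem_rows - cy[i])^2 + (mem_cols - cx[i])^2
    sel <- d2 <= (1.5 * r_eq[i])^2
    midx <- mem_idx_all[sel]
    radius_px <- r_eq[i]
    if (sum(sel) >= 3L) {
      fit <- tryCatch(fit_circle(cbind(mem_rows[sel], mem_cols[sel])),
                      error = function(e) NULL)
      if (!is.null(fit) && is.finite(fit$radius_px) && fit$radius_px > 0) {
        radius_px <- fit$radius_px
      }
    }
    out[[j]] <- structure(
      list(label = i, centroid = c(cy[i], cx[i]), area_px = area[i],
           circularity = unname(circ[i]), radius_eq_px = r_eq[i],
           radius_px = radius_px, radius_um = radius_px * pixel_size_um,
           membrane_idx = midx),
      class = "guv_region"
    )
  }
  out
}

#' Maximum-intensity projection
#'
#' @param zstack list of equally shaped 2-D matrices, or a 3-D array with the
#'   slice index first.
#' @return Elementwise maximum across slices.
#' @export
max_project <- function(zstack) {
  if (is.array(zstack) && length(dim(zstack)) == 3L) {
    zstack <- lapply(seq_len(dim(zstack)[1]), function(i) zstack[i, , ])
  }
  if (!length(zstack)) guv_stop("need at least one slice")
  dims <- dim(zstack[[1]])
  for (s in zstack) {
    if (!all(dim(s) == dims)) guv_stop("slice shapes differ")
  }
  Reduce(pmax, zstack)
}
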