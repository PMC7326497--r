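# Per-GUV intensity traces and haze baseline subtraction.

new_trace <- function(roi_id, channel, time_min, raw, corrected = NULL) {
  structure(list(roi_id = roi_id, channel = channel,
                 time_min = time_min, raw = raw, corrected = corrected),
            class = "guv_trace")
}

#' @export
print.guv_trace <- function(x, ...) {
  cat(sprintf("guv_trace: %s / %s, %d point(s)%s\n", x$roi_id, x$channel,
              length(x$time_min),
              if (is.null(x$corrected)) "" else " (baseline-corrected)"))
  invisible(x)
}

#' Measure per-GUV membrane intensity traces
#'
#' For each region, channel and frame, the trace value is the arithmetic mean
#' of the pixel intensities over the region's membrane pixels. With
#' `frame_masks` supplied (per-frame segmentation), a frame's pixel set is the
#' intersection of that frame's membrane mask with the region's frame-fixed
#' measurement disc (1.5 x the fitted radius around the centroid); without it,
#' the region's reference `membrane_idx` is used for every frame. A frame
#' whose pixel set is empty yields `NA` (flagged missing, never a silent 0);
#' the count of missing frames is logged.
#'
#' @param stack a [image_stack()].
#' @param regions list of `guv_region` objects from [label_guvs()].
#' @param frame_masks optional list (length `T`) of logical membrane masks.
#' @return List of [new_trace()] objects, one per region x channel.
#' @export
measure_traces <- function(stack, regions, frame_masks = NULL) {
  stopifnot(inherits(stack, "guv_stack"))
  d <- dim(stack$pixels)
  nt <- d[1]; nr <- d[3]; nc <- d[4]
  npx <- nr * nc
  if (!is.null(frame_masks) && length(frame_masks) != nt) {
    guv_stop("frame_masks must have one mask per frame")
  }
  traces <- list()
  n_missing <- 0L
  for (rg in regions) {
    if (any(rg$membrane_idx < 1L | rg$membrane_idx > npx)) {
      guv_stop("region ", rg$label, " references out-of-bounds pixels")
    }
    roi_disc_idx <- NULL
    if (!is.null(frame_masks)) {
      dy <- (seq_len(nr) - rg$centroid[1])^2
      dx <- (seq_len(nc) - rg$centroid[2])^2
      roi_disc_idx <- which(outer(dy, dx, `+`) <= (1.5 * rg$radius_px)^2)
    }
    for (ci in seq_along(stack$channels)) {
      vals <- rep(NA_real_, nt)
      for (t in seq_len(nt)) {
        idx <- if (is.null(frame_masks)) rg$membrane_idx else
          roi_disc_idx[frame_masks[[t]][roi_disc_idx]]
        if (length(idx)) {
          frame <- stack$pixels[t, ci, , , drop = TRUE]
          vals[t] <- mean(frame[idx])
        } else {
          n_missing <- n_missing + 1L
        }
      }
      traces[[length(traces) + 1L]] <-
        new_trace(paste0("guv", rg$label), stack$channels[ci],
                  stack$time_min, vals)
    }
  }
  if (n_missing > 0L) {
    guv_log("measure_traces: ", n_missing, " empty region-frame(s) -> NA")
  }
  traces
}

#' Estimate the temporal baseline from GUV-free regions
#'
#' Computes, per frame, the mean intensity within each background ROI and
#' averages the per-ROI profiles with equal weight (each region contributes
#' one profile regardless of its pixel count), matching the practice of
#' averaging the temporal profiles of ten GUV-free regions.
#'
#' @param stack a [image_stack()].
#' @param background_rois a [roi_set()]; only its `background` ROIs are used.
#' @param channel channel name or index to profile (the reporter channel).
#' @return An object of class `guv_baseline`: `time_min`, `values`,
#'   `n_regions`.
#' @export
estimate_baseline <- function(stack, background_rois, channel) {
  stopifnot(inherits(stack, "guv_stack"), inherits(background_rois, "guv_rois"))
  ci <- channel_index(stack, channel)
  rois <- Filter(function(r) r$kind == "background", background_rois$rois)
  if (!length(rois)) guv_stop("baseline required: no background ROIs")
  d <- dim(stack$pixels)
  shape <- d[3:4]
  if (!all(background_rois$image_shape == shape)) {
    guv_stop("ROI image shape does not match the stack")
  }
  profiles <- vapply(rois, function(r) {
    idx <- which(roi_pixels(r, shape))
    if (!length(idx)) guv_stop("background ROI '", r$id, "' contains no pixels")
    vapply(seq_len(d[1]), function(t) {
      mean(stack$pixels[t, ci, , , drop = TRUE][idx])
    }, 0)
  }, numeric(d[1]))
  values <- rowMeans(profiles)
  guv_log("estimate_baseline: ", length(rois), " region(s), channel ",
          stack$channels[ci])
  structure(list(time_min = stack$time_min, values = values,
                 n_regions = length(rois)),
            class = "guv_baseline")
}

#' Subtract the temporal baseline from a trace
#'
#' `corrected[i] = raw[i] - baseline[i]` at matching time points. Negative
#' corrected values are preserved: the haze rises before enzyme activity, so
#' lag-phase values are typically negative.
#'
#' @param trace a [new_trace()] object.
#' @param baseline a `guv_baseline` from [estimate_baseline()].
#' @return The trace with its `corrected` field filled in.
#' @export
subtract_baseline <- function(trace, baseline) {
  stopifnot(inherits(trace, "guv_trace"), inherits(baseline, "guv_baseline"))
  if (length(trace$time_min) != length(baseline$time_min) ||
      any(abs(trace$time_min - baseline$time_min) > 1e-9)) {
    guv_stop("trace and baseline time grids differ")
  }
  trace$corrected <- trace$raw - baseline$values
  trace
}

#' Deterministically place background ROIs away from detected vesicles
#'
#' Scans a regular grid in row-major order and keeps the first `n` disc
#' positions whose pixels stay clear of the dilated vesicle mask. Purely
#' deterministic (no RNG).
#'
#' @param filled_mask logical matrix of detected (filled) vesicles.
#' @param n number of background discs wanted.
#' @param radius_px disc radius.
#' @param margin_px exclusion margin dilated around the vesicle mask.
#' @return A [roi_set()] of `n` background discs. Errors when no position
#'   fits; warns when fewer than `n` fit.
#' @export
auto_background_rois <- function(filled_mask, n = 10, radius_px = 8,
                                 margin_px = 6) {
  excl <- EBImage::dilate(filled_mask * 1, struct_disc(margin_px)) > 0
  nr <- nrow(excl); nc <- ncol(excl)
  step <- 2 * radius_px + 2
  centres_r <- seq(radius_px + 1, nr - radius_px, by = step)
  centres_c <- seq(radius_px + 1, nc - radius_px, by = step)
  rois <- list()
  for (cr in centres_r) {
    for (cc in centres_c) {
      if (length(rois) >= n) break
      dy <- (seq_len(nr) - cr)^2
      dx <- (seq_len(nc) - cc)^2
      disc <- outer(dy, dx, `+`) <= radius_px^2
      if (!any(excl & disc)) {
        rois[[length(rois) + 1L]] <-
          list(id = paste0("bg", length(rois) + 1L), kind = "background",
               shape = "disc", center = c(cr, cc), radius = radius_px)
      }
    }
    if (length(rois) >= n) break
  }
  if (!length(rois)) guv_stop("no GUV-free area found for background ROIs")
  if (length(rois) < n) {
    warning("placed only ", length(rois), " of ", n, " background ROIs",
            call. = FALSE)
  }
  roi_set(rois, c(nr, nc))
}

#' Traces as a results table
#'
#' @param traces list of [new_trace()] objects.
#' @return data.frame with columns `roi_id`, `channel`, `time_min`, `raw`,
#'   `baseline`, `corrected` (baseline is `raw - corrected`, `NA` when the
#'   trace was not corrected).
#' @export
traces_table <- function(traces) {
  do.call(rbind, lapply(traces, function(tr) {
    corr <- if (is.null(tr$corrected)) rep(NA_real_, length(tr$raw)) else tr$corrected
    data.frame(roi_id = tr$roi_id, channel = tr$channel,
               time_min = tr$time_min, raw = tr$raw,
               baseline = tr$raw - corr, corrected = corr,
               stringsAsFactors = FALSE)
  }))
}
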