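# Membrane curvature (1/GUV radius) versus end-point reporter intensity.

#' Curvature versus intensity table
#'
#' Pairs each vesicle's curvature (`1 / radius_um`, per um, from the fitted
#' circle radius of its 2-D section) with its corrected reporter intensity at
#' the frame nearest `t_end`. Regions lacking a usable end-point value are
#' excluded and the count logged.
#'
#' @param regions list of `guv_region` objects from [label_guvs()].
#' @param traces list of corrected reporter [new_trace()] objects whose
#'   `roi_id`s follow the `guv<label>` convention.
#' @param t_end end-point time in minutes; must fall inside the acquisition
#'   range.
#' @param use_corrected use corrected values (the default) or raw.
#' @return data.frame with `roi_id`, `radius_um`, `curvature_per_um`,
#'   `intensity_au`.
#' @export
curvature_table <- function(regions, traces, t_end = 60, use_corrected = TRUE) {
  if (!length(traces)) guv_stop("no traces supplied")
  tgrid <- traces[[1]]$time_min
  if (t_end < min(tgrid) || t_end > max(tgrid)) {
    guv_stop("t_end = ", t_end, " min outside the acquisition range [",
             min(tgrid), ", ", max(tgrid), "]")
  }
  frame <- which.min(abs(tgrid - t_end))
  by_id <- setNames(traces, vapply(traces, `[[`, "", "roi_id"))
  rows <- list()
  dropped <- 0L
  for (rg in regions) {
    id <- paste0("guv", rg$label)
    tr <- by_id[[id]]
    val <- if (is.null(tr)) NA_real_ else {
      v <- if (use_corrected && !is.null(tr$corrected)) tr$corrected else tr$raw
      v[frame]
    }
    if (!is.finite(val)) {
      dropped <- dropped + 1L
      next
    }
    rows[[length(rows) + 1L]] <-
      data.frame(roi_id = id, radius_um = rg$radius_um,
                 curvature_per_um = 1 / rg$radius_um, intensity_au = val,
                 stringsAsFactors = FALSE)
  }
  if (dropped > 0L) {
    guv_log("curvature_table: excluded ", dropped,
            " region(s) without end-point data")
  }
  if (!length(rows)) return(data.frame(roi_id = character(0),
                                       radius_um = numeric(0),
                                       curvature_per_um = numeric(0),
                                       intensity_au = numeric(0)))
  do.call(rbind, rows)
}

#' Regress end-point intensity on membrane curvature
#'
#' Ordinary least squares of intensity on curvature (shared implementation
#' with [fit_line()]) with a two-sided t-test on the slope.
#'
#' @param table data.frame from [curvature_table()].
#' @param condition optional condition label carried through.
#' @return An object of class `curvature_fit`: `condition`, `n`, `slope`
#'   (AU um), `intercept` (AU), `slope_se`, `p_value`, `r_squared`.
#' @export
fit_curvature <- function(table, condition = NA_character_) {
  if (nrow(table) < 3L) guv_stop("curvature fit needs >= 3 vesicles")
  x <- table$curvature_per_um
  if (length(unique(x)) < 2L) guv_stop("degenerate curvature values")
  f <- fit_line(x, table$intensity_au)
  p <- if (is.finite(f$slope_se) && f$slope_se > 0) {
    2 * pt(-abs(f$slope / f$slope_se), df = f$n_points - 2L)
  } else if (f$slope == 0) 1 else 0
  structure(list(condition = condition, n = f$n_points, slope = f$slope,
                 intercept = f$intercept, slope_se = f$slope_se,
                 p_value = p, r_squared = f$r_squared),
            class = "curvature_fit")
}

#' @export
print.curvature_fit <- function(x, ...) {
  cat(sprintf("curvature_fit%s: n = %d, slope = %.4g AU*um (se %.3g, p = %.3g)\n",
              if (is.na(x$condition)) "" else paste0(" [", x$condition, "]"),
              x$n, x$slope, x$slope_se, x$p_value))
  invisible(x)
}
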