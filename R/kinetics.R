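# Initial-rate extraction from corrected traces, fold changes and group
# comparisons.

#' Ordinary least-squares line fit
#'
#' Closed-form simple linear regression. `NA` pairs are dropped. R-squared is
#' `1 - SSres / SStot`, defined as 1 when both sums are zero (a perfect fit to
#' constant data). The slope standard error is `NA` for a two-point fit.
#'
#' @param times numeric x values (minutes).
#' @param values numeric y values (AU).
#' @return List with `slope`, `intercept`, `r_squared`, `slope_se`,
#'   `n_points`.
#' @export
fit_line <- function(times, values) {
  if (length(times) != length(values)) guv_stop("times/values length mismatch")
  ok <- is.finite(times) & is.finite(values)
  x <- times[ok]; y <- values[ok]
  n <- length(x)
  if (n < 2L) guv_stop("need >= 2 finite points")
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) guv_stop("all time points equal")
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  ss_res <- sum(resid^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) {
    if (ss_res <= 1e-24) 1 else 0
  } else {
    1 - ss_res / ss_tot
  }
  se <- if (n > 2L) sqrt(ss_res / (n - 2L) / sxx) else NA_real_
  list(slope = slope, intercept = intercept,
       r_squared = max(min(r2, 1), 0), slope_se = se, n_points = n)
}

#' Locate the linear region of a progress curve
#'
#' Automates the manual selection of the region "after the lag phase and
#' before the plateau": among all contiguous windows of at least `min_points`
#' points whose fit reaches `r2_min`, returns the window maximizing the
#' slope; ties are broken in favour of longer windows, then earlier starts.
#' When no window qualifies, the maximum-slope window of exactly `min_points`
#' points is returned with `low_confidence = TRUE`. A constant window carries
#' no evidence of a linear increase, so qualifying windows must also have
#' positive value variance; a flat (e.g. all-zero) trace therefore always
#' falls back with `low_confidence = TRUE`.
#'
#' Windows are indexed 1-based and inclusive. `NA` values are excluded from
#' each window's fit; windows with fewer than `min_points` usable points are
#' skipped.
#'
#' @param time_min numeric time grid.
#' @param values corrected trace values (may contain `NA`).
#' @param min_points minimum window length (default 4).
#' @param r2_min minimum fit quality for a qualifying window (default 0.95).
#' @return List with `start`, `end`, `slope`, `r_squared`, `low_confidence`.
#' @export
find_linear_window <- function(time_min, values, min_points = 4, r2_min = 0.95) {
  n <- length(values)
  if (length(time_min) != n) guv_stop("time/value length mismatch")
  if (n < min_points) guv_stop("trace shorter than min_points")
  best <- NULL        # qualifying windows
  fallback <- NULL    # max-slope window of exact min_points length
  tol <- 1e-12
  for (start in seq_len(n - min_points + 1L)) {
    for (end in seq(start + min_points - 1L, n)) {
      idx <- start:end
      ok <- sum(is.finite(values[idx]) & is.finite(time_min[idx]))
      if (ok < min_points) next
      f <- tryCatch(fit_line(time_min[idx], values[idx]), error = function(e) NULL)
      if (is.null(f)) next
      len <- end - start + 1L
      cand <- list(start = start, end = end, slope = f$slope,
                   r_squared = f$r_squared, length = len)
      if (len == min_points) {
        if (is.null(fallback) || f$slope > fallback$slope + tol) fallback <- cand
      }
      vv <- values[idx]
      if (f$r_squared >= r2_min && stats::var(vv[is.finite(vv)]) > 0) {
        if (is.null(best) ||
            f$slope > best$slope + tol ||
            (abs(f$slope - best$slope) <= tol &&
             (len > best$length ||
              (len == best$length && start < best$start)))) {
          best <- cand
        }
      }
    }
  }
  if (!is.null(best)) {
    list(start = best$start, end = best$end, slope = best$slope,
         r_squared = best$r_squared, low_confidence = FALSE)
  } else if (!is.null(fallback)) {
    list(start = fallback$start, end = fallback$end, slope = fallback$slope,
         r_squared = fallback$r_squared, low_confidence = TRUE)
  } else {
    guv_stop("no usable window (too many missing values)")
  }
}

#' Initial rate of a corrected trace
#'
#' Linear regression of the corrected reporter trace over the linear window,
#' reported in AU/min. With `window = NULL` the window is located
#' automatically by [find_linear_window()]; a manual `(start, end)` index
#' pair reproduces hand-selected regions.
#'
#' @param trace a corrected [new_trace()] (or any list with `time_min` and
#'   `corrected`/`raw`).
#' @param window `NULL` or inclusive 1-based `(start, end)` indices.
#' @param min_points,r2_min forwarded to [find_linear_window()].
#' @return An object of class `initial_rate`: `roi_id`, `window`, `slope`
#'   (AU/min), `intercept`, `r_squared`, `slope_se`, `n_points`,
#'   `low_confidence`.
#' @export
initial_rate <- function(trace, window = NULL, min_points = 4, r2_min = 0.95) {
  vals <- if (!is.null(trace$corrected)) trace$corrected else trace$raw
  times <- trace$time_min
  low_conf <- FALSE
  if (is.null(window)) {
    w <- find_linear_window(times, vals, min_points = min_points, r2_min = r2_min)
    window <- c(w$start, w$end)
    low_conf <- w$low_confidence
  } else {
    window <- as.integer(window)
    if (length(window) != 2L || window[1] < 1L || window[2] > length(vals) ||
        window[1] > window[2]) {
      guv_stop("invalid window")
    }
  }
  idx <- window[1]:window[2]
  f <- fit_line(times[idx], vals[idx])
  structure(
    list(roi_id = if (!is.null(trace$roi_id)) trace$roi_id else NA_character_,
         window = window, slope = f$slope, intercept = f$intercept,
         r_squared = f$r_squared, slope_se = f$slope_se,
         n_points = f$n_points, low_confidence = low_conf),
    class = "initial_rate"
  )
}

#' Fold change between two groups of rates
#'
#' Ratio of group mean rates, `mean(rates_a) / mean(rates_b)` (vesicles are
#' the replicates).
#'
#' @param rates_a,rates_b numeric vectors of per-GUV initial rates.
#' @return The ratio. Errors with "no detectable activity in denominator"
#'   when `mean(rates_b) <= 0`.
#' @export
fold_change <- function(rates_a, rates_b) {
  if (!length(rates_a) || !length(rates_b)) guv_stop("empty rate group")
  mb <- mean(rates_b)
  if (mb <= 0) guv_stop("no detectable activity in denominator")
  mean(rates_a) / mb
}

#' Welch comparison of two rate groups
#'
#' Two-sided Welch (unequal-variance) t-test of per-GUV rates, matching the
#' pairwise significance reporting of GUV assays. With zero variance in both
#' groups the test degenerates: equal means give `t = 0`, `p = 1`; unequal
#' means give `t = +/-Inf`, `p = 0`; both are flagged `degenerate`.
#'
#' @param rates_a,rates_b numeric vectors (n >= 2 each).
#' @param labels group labels, length 2.
#' @return List with group summaries (`mean`, `sd`, `n`), `fold_change`
#'   (a over b; `NA` when the denominator mean is not positive),
#'   `t_statistic`, `df`, `p_value`, `degenerate`.
#' @export
compare_rates <- function(rates_a, rates_b, labels = c("A", "B")) {
  if (length(rates_a) < 2L || length(rates_b) < 2L) {
    guv_stop("need n >= 2 per group")
  }
  va <- stats::var(rates_a); vb <- stats::var(rates_b)
  degenerate <- va == 0 && vb == 0
  if (degenerate) {
    if (mean(rates_a) == mean(rates_b)) {
      tt <- 0; df <- length(rates_a) + length(rates_b) - 2L; p <- 1
    } else {
      tt <- sign(mean(rates_a) - mean(rates_b)) * Inf
      df <- length(rates_a) + length(rates_b) - 2L; p <- 0
    }
  } else {
    ht <- t.test(rates_a, rates_b, var.equal = FALSE)
    tt <- unname(ht$statistic); df <- unname(ht$parameter); p <- ht$p.value
  }
  fc <- if (mean(rates_b) > 0) mean(rates_a) / mean(rates_b) else NA_real_
  list(labels = labels,
       mean = c(mean(rates_a), mean(rates_b)),
       sd = c(sd(rates_a), sd(rates_b)),
       n = c(length(rates_a), length(rates_b)),
       fold_change = fc, t_statistic = tt, df = df, p_value = p,
       degenerate = degenerate)
}
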