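# End-to-end pipeline: stack -> masks -> regions -> traces -> rates.

#' Pipeline configuration
#'
#' All tunables of the segmentation/quantification/kinetics pipeline with
#' their defaults. `read_config()` overlays a YAML file on these defaults.
#'
#' @param membrane_thickness_um calibrated contour thickness (also sets the
#'   default DoG scales).
#' @param sigma_small_px,sigma_large_px DoG scales; `NULL` derives them as
#'   `0.5 * thickness / pixel_size` and three times that, per frame.
#' @param threshold `"otsu"` or a fixed response threshold.
#' @param noise_floor_mads robust noise floor for thresholding.
#' @param smooth_radius_px opening radius before hole filling (0 = off).
#' @param min_radius_um,min_circularity vesicle filters in [label_guvs()].
#' @param mask_mode `"per_frame"` (re-segment every frame, frame-fixed
#'   measurement discs) or `"reference"` (reuse the reference-frame band).
#' @param reference_frame frame used to identify vesicles (the membrane dye
#'   is constant, so the first frame suffices).
#' @param membrane_channel,reporter_channel channel names or indices.
#' @param n_background,background_radius_px background-ROI placement.
#' @param min_points,r2_min linear-window search parameters.
#' @param t_end_min end-point time for curvature analysis.
#' @return Named list.
#' @export
guv_config <- function(membrane_thickness_um = 0.5,
                       sigma_small_px = NULL, sigma_large_px = NULL,
                       threshold = "otsu", noise_floor_mads = 6,
                       smooth_radius_px = 0,
                       min_radius_um = 1, min_circularity = 0.7,
                       mask_mode = c("per_frame", "reference"),
                       reference_frame = 1L,
                       membrane_channel = "membrane",
                       reporter_channel = "reporter",
                       n_background = 10, background_radius_px = 8,
                       min_points = 4, r2_min = 0.95,
                       t_end_min = 60) {
  list(membrane_thickness_um = membrane_thickness_um,
       sigma_small_px = sigma_small_px, sigma_large_px = sigma_large_px,
       threshold = threshold, noise_floor_mads = noise_floor_mads,
       smooth_radius_px = smooth_radius_px,
       min_radius_um = min_radius_um, min_circularity = min_circularity,
       mask_mode = match.arg(mask_mode), reference_frame = reference_frame,
       membrane_channel = membrane_channel,
       reporter_channel = reporter_channel,
       n_background = n_background,
       background_radius_px = background_radius_px,
       min_points = min_points, r2_min = r2_min, t_end_min = t_end_min)
}

#' Read a YAML pipeline configuration
#'
#' Unknown keys raise an error; missing keys keep their defaults.
#'
#' @param path YAML file.
#' @return A [guv_config()] list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) guv_stop("file not found: '", path, "'")
  user <- yaml::read_yaml(path)
  base <- guv_config()
  unknown <- setdiff(names(user), names(base))
  if (length(unknown)) {
    guv_stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(guv_config, user)
}

config_sigmas <- function(config, pixel_size_um) {
  ss <- config$sigma_small_px
  if (is.null(ss)) ss <- 0.5 * config$membrane_thickness_um / pixel_size_um
  sl <- config$sigma_large_px
  if (is.null(sl)) sl <- 3 * ss
  c(ss, sl)
}

frame_union_mask <- function(stack, t, config) {
  sg <- config_sigmas(config, stack$pixel_size_um)
  masks <- lapply(stack$channels, function(ch) {
    suppressWarnings(segment_channel(stack_frame(stack, t, ch),
                                     sigma_small_px = sg[1], sigma_large_px = sg[2],
                                     threshold = config$threshold,
                                     noise_floor_mads = config$noise_floor_mads))
  })
  Reduce(union_masks, masks)
}

#' Segment a full stack
#'
#' Identifies vesicles on the reference frame (DoG segmentation of each
#' channel, channel union, hole fill, internal gradient, labelling) and
#' derives a membrane-band mask for every frame (per-frame re-segmentation by
#' default, or the reference band under `mask_mode = "reference"`).
#'
#' @param stack a [image_stack()].
#' @param config a [guv_config()] list.
#' @return List with `regions` (from [label_guvs()]), `frame_masks`
#'   (length-`T` list of logical masks) and `reference` (membrane/filled
#'   masks of the reference frame).
#' @export
segment_stack <- function(stack, config = guv_config()) {
  stopifnot(inherits(stack, "guv_stack"))
  nt <- dim(stack$pixels)[1]
  guv_log("segment_stack: ", nt, " frame(s), mode ", config$mask_mode)
  ref_union <- frame_union_mask(stack, config$reference_frame, config)
  ref <- extract_membrane(ref_union, config$membrane_thickness_um,
                          stack$pixel_size_um, config$smooth_radius_px)
  regions <- label_guvs(ref$filled, ref$membrane, stack$pixel_size_um,
                        min_radius_um = config$min_radius_um,
                        min_circularity = config$min_circularity)
  guv_log("segment_stack: ", length(regions), " vesicle(s) identified")
  frame_masks <- vector("list", nt)
  if (config$mask_mode == "reference") {
    for (t in seq_len(nt)) frame_masks[[t]] <- ref$membrane
  } else {
    for (t in seq_len(nt)) {
      um <- frame_union_mask(stack, t, config)
      frame_masks[[t]] <- extract_membrane(um, config$membrane_thickness_um,
                                           stack$pixel_size_um,
                                           config$smooth_radius_px)$membrane
    }
  }
  list(regions = regions, frame_masks = frame_masks, reference = ref)
}

#' Quantify a segmented stack
#'
#' Places background ROIs away from the detected vesicles, estimates the
#' reporter haze baseline, measures per-vesicle traces in both channels and
#' baseline-corrects the reporter traces. The membrane-dye channel is never
#' baseline-subtracted.
#'
#' @param stack a [image_stack()].
#' @param seg result of [segment_stack()].
#' @param config a [guv_config()] list.
#' @param background_rois optional [roi_set()] of manually chosen background
#'   regions; by default they are placed with [auto_background_rois()].
#' @return List with `traces` (all channels; reporter traces corrected),
#'   `baseline`, `background_rois`.
#' @export
quantify_stack <- function(stack, seg, config = guv_config(),
                           background_rois = NULL) {
  if (is.null(background_rois)) {
    background_rois <- auto_background_rois(
      seg$reference$filled, n = config$n_background,
      radius_px = config$background_radius_px)
  }
  baseline <- estimate_baseline(stack, background_rois,
                                config$reporter_channel)
  traces <- measure_traces(stack, seg$regions, seg$frame_masks)
  reporter_name <- stack$channels[channel_index(stack, config$reporter_channel)]
  traces <- lapply(traces, function(tr) {
    if (tr$channel == reporter_name) subtract_baseline(tr, baseline) else tr
  })
  list(traces = traces, baseline = baseline, background_rois = background_rois)
}

#' Initial rates for every vesicle
#'
#' @param quant result of [quantify_stack()].
#' @param config a [guv_config()] list.
#' @param reporter_channel channel whose corrected traces carry the activity.
#' @return data.frame: `roi_id`, `window_start_min`, `window_end_min`,
#'   `slope_au_per_min`, `intercept`, `r2`, `se`, `n_points`,
#'   `low_confidence`.
#' @export
guv_rates <- function(quant, config = guv_config(),
                      reporter_channel = config$reporter_channel) {
  sel <- Filter(function(tr) tr$channel == reporter_channel ||
                  identical(tr$channel, reporter_channel), quant$traces)
  if (!length(sel)) guv_stop("no reporter traces found")
  rows <- lapply(sel, function(tr) {
    ir <- initial_rate(tr, min_points = config$min_points,
                       r2_min = config$r2_min)
    data.frame(roi_id = tr$roi_id,
               window_start_min = tr$time_min[ir$window[1]],
               window_end_min = tr$time_min[ir$window[2]],
               slope_au_per_min = ir$slope, intercept = ir$intercept,
               r2 = ir$r_squared, se = ir$slope_se, n_points = ir$n_points,
               low_confidence = ir$low_confidence, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full pipeline on one movie
#'
#' Convenience wrapper: [segment_stack()], [quantify_stack()], [guv_rates()].
#'
#' @param stack a [image_stack()].
#' @param config a [guv_config()] list.
#' @return List with `regions`, `traces`, `baseline`, `rates`.
#' @export
run_guv_pipeline <- function(stack, config = guv_config()) {
  seg <- segment_stack(stack, config)
  quant <- quantify_stack(stack, seg, config)
  rates <- guv_rates(quant, config)
  list(regions = seg$regions, frame_masks = seg$frame_masks,
       traces = quant$traces, baseline = quant$baseline, rates = rates)
}

#' Recover per-GUV rates for every condition of a fixture
#'
#' Simulates each condition of a registered fixture for each seed and runs
#' the full pipeline on every movie.
#'
#' @param name fixture name for [guv_fixture()].
#' @param seeds integer vector; one simulated replicate (a "well") per seed.
#' @param profile forwarded to [guv_fixture()].
#' @param conditions optional subset of condition names to simulate.
#' @param config a [guv_config()] list.
#' @return data.frame: `condition`, `seed`, `roi_id`, `rate_au_per_min`,
#'   `low_confidence`.
#' @export
fixture_rates <- function(name, seeds = 1:3, profile = "default",
                          conditions = NULL, config = guv_config()) {
  out <- list()
  for (s in seeds) {
    scenes <- guv_fixture(name, seed = s, profile = profile)
    if (!is.null(conditions)) scenes <- scenes[conditions]
    for (cond in names(scenes)) {
      sim <- simulate_timelapse(scenes[[cond]])
      res <- run_guv_pipeline(sim$stack, config)
      if (!nrow(res$rates)) next
      out[[length(out) + 1L]] <-
        data.frame(condition = cond, seed = s, roi_id = res$rates$roi_id,
                   rate_au_per_min = res$rates$slope_au_per_min,
                   low_confidence = res$rates$low_confidence,
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Fold change between two fixture conditions, pooled over seeds
#'
#' @param rates data.frame from [fixture_rates()].
#' @param numerator,denominator condition names.
#' @return List with `fold_change`, `n` (vesicles pooled across both
#'   conditions) and the per-condition mean rates.
#' @export
pooled_fold_change <- function(rates, numerator, denominator) {
  ra <- rates$rate_au_per_min[rates$condition == numerator]
  rb <- rates$rate_au_per_min[rates$condition == denominator]
  list(fold_change = fold_change(ra, rb),
       n = length(ra) + length(rb),
       mean_rates = setNames(c(mean(ra), mean(rb)),
                             c(numerator, denominator)))
}
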