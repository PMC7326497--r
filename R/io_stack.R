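#' Multi-channel image stack
#'
#' Container for a confocal time-lapse: a 4-D intensity array indexed
#' `(time, channel, row, col)` plus acquisition metadata. Raw input
#' intensities must be non-negative and finite; time stamps are minutes since
#' enzyme addition and must be strictly increasing.
#'
#' @param pixels 4-D numeric array, dimensions `(T, C, Y, X)`.
#' @param time_min numeric vector of length `T`, strictly increasing, minutes.
#' @param channels character vector of length `C` with unique channel names.
#' @param pixel_size_um micrometres per pixel, a single positive number.
#' @return An object of class `guv_stack`: a list with elements `pixels`,
#'   `time_min`, `channels`, `pixel_size_um`.
#' @examples
#' px <- array(0, c(2, 1, 8, 8))
#' s <- image_stack(px, time_min = c(0, 2.5), channels = "membrane",
#'                  pixel_size_um = 0.25)
#' dim(s$pixels)
#' @export
image_stack <- function(pixels, time_min, channels, pixel_size_um) {
  if (!is.array(pixels) || length(dim(pixels)) != 4L) {
    guv_stop("pixels must be a 4-D array indexed (time, channel, row, col)")
  }
  d <- dim(pixels)
  if (length(time_min) != d[1]) {
    guv_stop("length(time_min) == ", length(time_min), " but T == ", d[1])
  }
  if (any(!is.finite(time_min)) || any(diff(time_min) <= 0)) {
    guv_stop("time stamps must be finite and strictly increasing")
  }
  if (length(channels) != d[2] || anyDuplicated(channels)) {
    guv_stop("channels must be ", d[2], " unique names")
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    guv_stop("pixel_size_um must be a single positive number")
  }
  if (any(!is.finite(pixels)) || any(pixels < 0)) {
    guv_stop("raw stack intensities must be finite and non-negative")
  }
  structure(
    list(pixels = pixels, time_min = as.numeric(time_min),
         channels = as.character(channels),
         pixel_size_um = as.numeric(pixel_size_um)),
    class = "guv_stack"
  )
}

#' @export
print.guv_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("guv_stack: %d frame(s) x %d channel(s) x %d x %d px\n",
              d[1], d[2], d[3], d[4]))
  cat("  channels:  ", paste(x$channels, collapse = ", "), "\n")
  cat(sprintf("  time:       %.4g .. %.4g min", x$time_min[1],
              x$time_min[length(x$time_min)]), "\n")
  cat(sprintf("  pixel size: %.4g um/px\n", x$pixel_size_um))
  invisible(x)
}

# frame accessor: 2-D matrix (row, col)
stack_frame <- function(stack, t, channel) {
  ci <- channel_index(stack, channel)
  stack$pixels[t, ci, , , drop = TRUE]
}

channel_index <- function(stack, channel) {
  if (is.character(channel)) {
    ci <- match(channel, stack$channels)
    if (is.na(ci)) guv_stop("unknown channel '", channel, "' (have: ",
                            paste(stack$channels, collapse = ", "), ")")
    ci
  } else {
    ci <- as.integer(channel)
    if (ci < 1L || ci > length(stack$channels)) guv_stop("channel index out of range")
    ci
  }
}

sidecar_path <- function(path) paste0(path, ".json")

#' Write an image stack to disk
#'
#' Writes a multi-page TIFF (pages ordered frame-major, channel-minor, i.e.
#' page `(t-1)*C + c`) together with a JSON metadata sidecar (`<path>.json`)
#' carrying channel names, time stamps, pixel size and the intensity scale.
#' Integer-valued stacks not exceeding 65535 are stored as 16-bit and round
#' trip bit-exactly; other data are stored as 32-bit float and round trip to
#' float32 precision.
#'
#' @param stack a [image_stack()] object.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @seealso [read_stack()]
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "guv_stack"))
  d <- dim(stack$pixels)
  mx <- max(stack$pixels)
  integral <- max(abs(stack$pixels - round(stack$pixels))) == 0 && mx <= 65535
  if (integral) {
    bits <- 16L
    scale <- 65535
  } else {
    bits <- 32L
    scale <- if (mx > 1) mx else 1
  }
  pages <- vector("list", d[1] * d[2])
  k <- 1L
  for (t in seq_len(d[1])) {
    for (c in seq_len(d[2])) {
      pages[[k]] <- stack$pixels[t, c, , , drop = TRUE] / scale
      k <- k + 1L
    }
  }
  ok <- tiff::writeTIFF(pages, path, bits.per.sample = bits)
  if (ok < 1) guv_stop("failed to write TIFF to '", path, "'")
  meta <- list(format = "guvkin-stack-1",
               n_frames = d[1], n_channels = d[2],
               channels = stack$channels,
               time_min = stack$time_min,
               pixel_size_um = stack$pixel_size_um,
               scale = scale, bits = bits)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  guv_log("write_stack: ", path, " [", paste(d, collapse = "x"), "], ",
          bits, "-bit, scale ", format(scale))
  invisible(path)
}

#' Read an image stack from disk
#'
#' Reads a multi-page TIFF into a `(T, C, Y, X)` [image_stack()]. When the
#' JSON sidecar written by [write_stack()] is present, all metadata come from
#' it. Without a sidecar the page layout is ambiguous, so `channels` (fixing
#' `C`), `frame_interval_min` and `pixel_size_um` must be supplied; missing
#' metadata resolved from these arguments is logged, never silently defaulted.
#'
#' @param path TIFF path.
#' @param channels optional channel names; with a sidecar they override the
#'   stored names (length must match) and without one they determine `C`.
#' @param frame_interval_min frame spacing used to build time stamps when no
#'   sidecar is present (frame 1 is t = 0).
#' @param pixel_size_um pixel size used when no sidecar is present.
#' @return A [image_stack()] object with axes normalized to `(T, C, Y, X)`.
#' @export
read_stack <- function(path, channels = NULL, frame_interval_min = NULL,
                       pixel_size_um = NULL) {
  if (!file.exists(path)) guv_stop("file not found: '", path, "'")
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, info = FALSE),
                    error = function(e) guv_stop("unreadable TIFF '", path,
                                                 "': ", conditionMessage(e)))
  if (is.matrix(pages)) pages <- list(pages)
  npage <- length(pages)
  if (npage < 1L) guv_stop("TIFF '", path, "' contains no pages")
  meta <- NULL
  if (file.exists(sidecar_path(path))) {
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  }
  if (!is.null(meta)) {
    C <- as.integer(meta$n_channels)
    T <- as.integer(meta$n_frames)
    if (T * C != npage) guv_stop("sidecar metadata inconsistent with page count")
    ch <- meta$channels
    if (!is.null(channels)) {
      if (length(channels) != C) guv_stop("channels length does not match stack")
      ch <- channels
    }
    time_min <- as.numeric(meta$time_min)
    px <- as.numeric(meta$pixel_size_um)
    scale <- as.numeric(meta$scale)
  } else {
    if (is.null(channels)) {
      guv_stop("no metadata sidecar for '", path,
               "': channel layout is ambiguous; pass channels explicitly")
    }
    C <- length(channels)
    if (npage %% C != 0L) guv_stop("page count ", npage,
                                   " is not a multiple of ", C, " channels")
    T <- npage %/% C
    ch <- channels
    if (is.null(frame_interval_min)) {
      guv_stop("no time stamps available: pass frame_interval_min")
    }
    guv_log("read_stack: no sidecar; time stamps from frame_interval_min = ",
            frame_interval_min)
    time_min <- (seq_len(T) - 1) * frame_interval_min
    if (is.null(pixel_size_um)) {
      guv_stop("no pixel size available: pass pixel_size_um")
    }
    guv_log("read_stack: no sidecar; pixel size from argument = ", pixel_size_um)
    px <- pixel_size_um
    scale <- 65535   # bare 16-bit TIFFs read as value/65535
  }
  dims <- dim(pages[[1]])
  if (length(dims) > 2L) guv_stop("multi-sample TIFF pages are not supported")
  pix <- array(0, c(T, C, dims[1], dims[2]))
  k <- 1L
  for (t in seq_len(T)) {
    for (c in seq_len(C)) {
      pg <- pages[[k]]
      if (!all(dim(pg) == dims)) guv_stop("TIFF pages differ in shape")
      pix[t, c, , ] <- pg * scale
      k <- k + 1L
    }
  }
  if (!is.null(meta) && meta$bits == 16L) pix <- round(pix)
  guv_log("read_stack: ", path, " -> (", paste(c(T, C, dims), collapse = ", "), ")")
  image_stack(pix, time_min = time_min, channels = ch, pixel_size_um = px)
}
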