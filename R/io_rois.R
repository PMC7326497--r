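#' Regions of interest
#'
#' ROIs come in two kinds: `membrane` ROIs select vesicles for measurement and
#' `background` ROIs mark GUV-free areas used for the temporal baseline. They
#' are frame-fixed (no tracking). Geometry is either a disc
#' (`centre row/col + radius`, pixels, possibly fractional) or a polygon
#' (vertex list). Pixel coordinates are 1-based `(row, col)`.
#'
#' The on-disk dialect is a plain text file, one ROI per line, `#` comments:
#' ```
#' # id  kind        shape    geometry...
#' bg1   background  disc     20.5 30.0 8
#' guv1  membrane    polygon  10 10  10 40  40 40  40 10
#' ```
#' Polygon geometry alternates row and col coordinates.
#'
#' @param rois list of ROI descriptors, each a list with `id`, `kind`
#'   (`"membrane"` or `"background"`), `shape` (`"disc"` or `"polygon"`) and
#'   either `center` + `radius` or a two-column `vertices` matrix.
#' @param image_shape `(rows, cols)` of the image the ROIs refer to.
#' @return An object of class `guv_rois`.
#' @export
roi_set <- function(rois, image_shape) {
  ids <- vapply(rois, function(r) as.character(r$id), "")
  if (anyDuplicated(ids)) {
    guv_stop("duplicate ROI id(s): ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  for (r in rois) {
    if (!r$kind %in% c("membrane", "background")) {
      guv_stop("ROI '", r$id, "': kind must be membrane or background")
    }
    if (r$shape == "disc") {
      if (r$radius <= 0) guv_stop("ROI '", r$id, "': disc radius must be > 0")
      lo <- r$center - r$radius
      hi <- r$center + r$radius
      if (any(lo < 0.5) || any(hi > image_shape + 0.5)) {
        guv_stop("ROI '", r$id, "' extends outside image bounds")
      }
    } else if (r$shape == "polygon") {
      v <- r$vertices
      if (!is.matrix(v) || ncol(v) != 2L || nrow(v) < 3L) {
        guv_stop("ROI '", r$id, "': polygon needs >= 3 (row, col) vertices")
      }
      if (any(v[, 1] < 0.5 | v[, 1] > image_shape[1] + 0.5 |
              v[, 2] < 0.5 | v[, 2] > image_shape[2] + 0.5)) {
        guv_stop("ROI '", r$id, "' has a vertex outside image bounds")
      }
    } else {
      guv_stop("ROI '", r$id, "': unknown shape '", r$shape, "'")
    }
  }
  structure(list(rois = rois, image_shape = as.integer(image_shape)),
            class = "guv_rois")
}

#' @export
print.guv_rois <- function(x, ...) {
  kinds <- vapply(x$rois, `[[`, "", "kind")
  cat(sprintf("guv_rois: %d ROI(s) (%d membrane, %d background) on %d x %d px\n",
              length(x$rois), sum(kinds == "membrane"),
              sum(kinds == "background"), x$image_shape[1], x$image_shape[2]))
  invisible(x)
}

#' Read ROIs from the guvkin text dialect
#'
#' @param path ROI file path.
#' @param image_shape `(rows, cols)`; geometry is validated against it.
#' @return A [roi_set()].
#' @export
read_rois <- function(path, image_shape) {
  if (!file.exists(path)) guv_stop("file not found: '", path, "'")
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  rois <- lapply(lines, function(ln) {
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    if (length(tok) < 4L) guv_stop("malformed ROI line: '", ln, "'")
    id <- tok[1]; kind <- tok[2]; shape <- tok[3]
    geom <- suppressWarnings(as.numeric(tok[-(1:3)]))
    if (any(is.na(geom))) guv_stop("ROI '", id, "': non-numeric geometry")
    if (shape == "disc") {
      if (length(geom) != 3L) guv_stop("ROI '", id, "': disc needs row col radius")
      list(id = id, kind = kind, shape = "disc",
           center = geom[1:2], radius = geom[3])
    } else if (shape == "polygon") {
      if (length(geom) %% 2L != 0L) {
        guv_stop("ROI '", id, "': polygon needs row/col pairs")
      }
      list(id = id, kind = kind, shape = "polygon",
           vertices = matrix(geom, ncol = 2L, byrow = TRUE))
    } else {
      guv_stop("ROI '", id, "': unknown shape '", shape, "'")
    }
  })
  guv_log("read_rois: ", path, " -> ", length(rois), " ROI(s)")
  roi_set(rois, image_shape)
}

#' Write ROIs in the guvkin text dialect
#'
#' @param rois a [roi_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rois <- function(rois, path) {
  stopifnot(inherits(rois, "guv_rois"))
  lines <- c("# guvkin ROI file: id kind shape geometry (1-based row col, px)")
  for (r in rois$rois) {
    geom <- if (r$shape == "disc") c(r$center, r$radius) else t(r$vertices)
    lines <- c(lines, paste(r$id, r$kind, r$shape,
                            paste(format(geom, trim = TRUE), collapse = " ")))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Rasterize one ROI to a logical pixel mask
#'
#' A pixel belongs to a disc ROI when its centre lies within the radius, and
#' to a polygon ROI by the even-odd (ray casting) rule applied to its centre.
#'
#' @param roi one ROI descriptor from a [roi_set()].
#' @param image_shape `(rows, cols)`.
#' @return Logical matrix of `image_shape`.
#' @export
roi_pixels <- function(roi, image_shape) {
  nr <- image_shape[1]; nc <- image_shape[2]
  if (roi$shape == "disc") {
    dy <- (seq_len(nr) - roi$center[1])^2
    dx <- (seq_len(nc) - roi$center[2])^2
    outer(dy, dx, `+`) <= roi$radius^2
  } else {
    v <- roi$vertices
    rows <- rep(seq_len(nr), times = nc)
    cols <- rep(seq_len(nc), each = nr)
    matrix(point_in_polygon(rows, cols, v), nr, nc)
  }
}

# even-odd rule; vertices (row, col), points at pixel centres
point_in_polygon <- function(py, px, v) {
  n <- nrow(v)
  inside <- logical(length(py))
  j <- n
  for (i in seq_len(n)) {
    yi <- v[i, 1]; xi <- v[i, 2]
    yj <- v[j, 1]; xj <- v[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# subset helper used by the pipeline
roi_subset <- function(rois, kind) {
  keep <- vapply(rois$rois, function(r) r$kind == kind, TRUE)
  roi_set(rois$rois[keep], rois$image_shape)
}
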