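# Hydrogen/deuterium-exchange MS peptide utility: inclusion criteria,
# sequence coverage and per-peptide uptake differences.

#' HDX peptide inclusion criteria
#'
#' Standard quality thresholds for including peptides in an HDX-MS analysis.
#' All boundaries are inclusive: a "minimum intensity of 5000" admits exactly
#' 5000 and a "maximum MH+ error of 5 ppm" admits exactly 5.
#'
#' @param min_intensity minimum peptide intensity (counts).
#' @param min_length minimum sequence length (amino acids).
#' @param min_products_per_aa minimum fragmentation products per amino acid.
#' @param max_mh_error_ppm maximum absolute MH+ mass error (ppm).
#' @param min_identifications minimum number of non-deuterated files (of
#'   three) in which the peptide was identified.
#' @return List of class `hdx_criteria`.
#' @export
hdx_criteria <- function(min_intensity = 5000, min_length = 5,
                         min_products_per_aa = 0.1, max_mh_error_ppm = 5,
                         min_identifications = 2) {
  cr <- list(min_intensity = min_intensity, min_length = min_length,
             min_products_per_aa = min_products_per_aa,
             max_mh_error_ppm = max_mh_error_ppm,
             min_identifications = min_identifications)
  if (any(unlist(cr) <= 0)) guv_stop("criteria thresholds must be positive")
  structure(cr, class = "hdx_criteria")
}

hdx_required_cols <- c("protein", "sequence", "start", "end", "max_intensity",
                       "products_per_aa", "mh_error_ppm", "n_identifications")

check_hdx_table <- function(peptides) {
  missing <- setdiff(hdx_required_cols, names(peptides))
  if (length(missing)) {
    guv_stop("peptide table lacks column(s): ", paste(missing, collapse = ", "))
  }
  bad <- peptides$start < 1 | peptides$end < peptides$start
  if (any(bad)) guv_stop("invalid residue range in row(s) ",
                         paste(which(bad), collapse = ", "))
  len <- peptides$end - peptides$start + 1
  mismatch <- nchar(peptides$sequence) != len
  if (any(mismatch)) {
    guv_stop("sequence length does not match residue range in row(s) ",
             paste(which(mismatch), collapse = ", "))
  }
  invisible(peptides)
}

#' Read a peptide table
#'
#' CSV approximating a vendor "state data" export. Required columns:
#' `protein, sequence, start, end, max_intensity, products_per_aa,
#' mh_error_ppm, n_identifications`; further columns (e.g. per-state uptake)
#' pass through untouched. `start`/`end` are 1-based inclusive residue
#' numbers.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_hdx_peptides <- function(path) {
  if (!file.exists(path)) guv_stop("file not found: '", path, "'")
  check_hdx_table(read.csv(path, stringsAsFactors = FALSE))
}

#' Filter peptides by inclusion criteria
#'
#' A peptide is kept iff it meets every criterion; each rejected peptide
#' lists all violated criteria.
#'
#' @param peptides data.frame with the columns of [read_hdx_peptides()].
#' @param criteria an [hdx_criteria()] object.
#' @return List with `kept` (data.frame) and `rejected` (data.frame with an
#'   extra `reasons` column, criteria names separated by `;`).
#' @export
filter_peptides <- function(peptides, criteria = hdx_criteria()) {
  stopifnot(inherits(criteria, "hdx_criteria"))
  check_hdx_table(peptides)
  len <- peptides$end - peptides$start + 1
  fails <- cbind(
    intensity = peptides$max_intensity < criteria$min_intensity,
    length = len < criteria$min_length,
    products_per_aa = peptides$products_per_aa < criteria$min_products_per_aa,
    mh_error = abs(peptides$mh_error_ppm) > criteria$max_mh_error_ppm,
    identifications = peptides$n_identifications < criteria$min_identifications
  )
  keep <- rowSums(fails) == 0
  rejected <- peptides[!keep, , drop = FALSE]
  if (nrow(rejected)) {
    rejected$reasons <- apply(fails[!keep, , drop = FALSE], 1, function(f) {
      paste(colnames(fails)[f], collapse = ";")
    })
  } else {
    rejected$reasons <- character(0)
  }
  guv_log("filter_peptides: kept ", sum(keep), " / ", length(keep))
  list(kept = peptides[keep, , drop = FALSE], rejected = rejected)
}

#' Sequence coverage of a protein by peptides
#'
#' Percentage of residues covered by the union of the peptides' residue
#' ranges (interval union via IRanges); invariant to peptide order and
#' duplication.
#'
#' @param peptides data.frame with `start`, `end` (1-based inclusive);
#'   optionally filter to one protein first.
#' @param protein_length protein length in residues.
#' @return Coverage percent in \[0, 100\].
#' @export
sequence_coverage <- function(peptides, protein_length) {
  if (protein_length < 1) guv_stop("protein_length must be >= 1")
  if (!nrow(peptides)) return(0)
  if (max(peptides$end) > protein_length) {
    guv_stop("peptide end ", max(peptides$end), " exceeds protein length ",
             protein_length)
  }
  covered <- sum(IRanges::width(IRanges::reduce(
    IRanges::IRanges(start = peptides$start, end = peptides$end)
  )))
  100 * covered / protein_length
}

#' Per-peptide deuterium uptake difference between two states
#'
#' For exposures shared by both states, computes `uptake(b) - uptake(a)`
#' (replicates averaged), so negative differences mean less exchange in `b`
#' (protection, e.g. by membrane binding). The summary classification is
#' `"protected"` when the difference falls below `-delta_da` at at least
#' `min_exposures` exposures, `"deprotected"` for the mirror case, otherwise
#' `"no_change"`. The numeric significance rule is a configurable stand-in;
#' community guidelines do not fix a single threshold.
#'
#' @param uptake data.frame with columns `state`, `exposure_s`, `uptake_da`
#'   for one peptide.
#' @param state_a,state_b state labels (e.g. `"apo"`, `"liposomes"`).
#' @param delta_da classification threshold in daltons (default 0.5).
#' @param min_exposures number of exposures that must exceed the threshold.
#' @return List with `delta` (data.frame `exposure_s`, `delta_da` =
#'   b minus a) and `classification`.
#' @export
uptake_difference <- function(uptake, state_a, state_b, delta_da = 0.5,
                              min_exposures = 1) {
  need <- c("state", "exposure_s", "uptake_da")
  if (!all(need %in% names(uptake))) {
    guv_stop("uptake table needs columns: ", paste(need, collapse = ", "))
  }
  mean_by <- function(st) {
    d <- uptake[uptake$state == st, , drop = FALSE]
    if (!nrow(d)) return(NULL)
    agg <- tapply(d$uptake_da, d$exposure_s, mean)
    data.frame(exposure_s = as.numeric(names(agg)), uptake_da = as.numeric(agg))
  }
  a <- mean_by(state_a); b <- mean_by(state_b)
  if (is.null(a) || is.null(b)) guv_stop("state not present in uptake table")
  shared <- intersect(a$exposure_s, b$exposure_s)
  if (!length(shared)) guv_stop("no shared exposures between states")
  shared <- sort(shared)
  dd <- b$uptake_da[match(shared, b$exposure_s)] -
    a$uptake_da[match(shared, a$exposure_s)]
  classification <- if (sum(dd < -delta_da) >= min_exposures) {
    "protected"
  } else if (sum(dd > delta_da) >= min_exposures) {
    "deprotected"
  } else {
    "no_change"
  }
  list(delta = data.frame(exposure_s = shared, delta_da = dd),
       classification = classification)
}
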