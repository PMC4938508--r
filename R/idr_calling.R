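# Binary disorder calls, IDR extraction with the 30-residue rule, IDP/FOP
# classification, and predictor-overlap (% inclusion) tables.

#' Binarize a score track into per-residue disorder calls
#'
#' A position is called disordered iff `score >= threshold` for
#' higher-is-disordered tracks, or `score < threshold` otherwise (the
#' boundary value is a disorder call only in the former convention).
#'
#' @param track A `score_track`.
#' @return Logical vector, `TRUE` = disordered.
#' @export
binarize <- function(track) {
  if (track$higher_is_disordered) track$scores >= track$threshold
  else track$scores < track$threshold
}

#' Extract IDRs from per-residue disorder calls
#'
#' An intrinsically disordered region is a maximal run of consecutive
#' disorder calls of length at least `min_len` (default 30 residues, the
#' standard long-IDR rule). Runs are maximal: the residues immediately
#' flanking each reported interval are not called disordered.
#'
#' @param calls Logical vector (`TRUE` = disordered).
#' @param min_len Minimum run length, >= 1.
#' @param protein_id,predictor Metadata carried into the output rows.
#' @return Data frame `protein_id, start, end, length, predictor`, sorted,
#'   zero rows when no run qualifies.
#' @export
call_idrs <- function(calls, min_len = 30L, protein_id = NA_character_,
                      predictor = NA_character_) {
  stopifnot(min_len >= 1L, is.logical(calls))
  r <- rle(calls)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  n <- sum(keep)
  data.frame(protein_id = rep_len(protein_id, n),
             start = starts[keep], end = ends[keep],
             length = r$lengths[keep],
             predictor = rep_len(predictor, n), stringsAsFactors = FALSE)
}

#' IDRs of a score track
#' @param track A `score_track`.
#' @param min_len Minimum IDR length (default 30).
#' @return As [call_idrs()].
#' @export
idrs_from_track <- function(track, min_len = 30L) {
  call_idrs(binarize(track), min_len, track$protein_id, track$predictor)
}

#' IDR tables for a whole proteome
#' @param tracks Named list of `score_track`.
#' @param min_len Minimum IDR length (default 30).
#' @return One combined data frame as [call_idrs()].
#' @export
idr_table <- function(tracks, min_len = 30L) {
  do.call(rbind, c(lapply(tracks, idrs_from_track, min_len = min_len),
                   make.row.names = FALSE))
}

#' Classify a protein as disorder-containing (IDP) or fully ordered (FOP)
#'
#' @param idrs IDR data frame for one protein (from one chosen track).
#' @return `"IDP"` if at least one IDR, else `"FOP"`.
#' @export
classify_idp <- function(idrs) if (nrow(idrs) > 0L) "IDP" else "FOP"

#' IDP/FOP labels for a whole proteome
#' @param idrs Combined IDR data frame.
#' @param ids Character vector of all protein ids in the dataset (proteins
#'   without IDRs must still receive an FOP label).
#' @return Named character vector of labels.
#' @export
idp_labels <- function(idrs, ids) {
  stats::setNames(ifelse(ids %in% idrs$protein_id, "IDP", "FOP"), ids)
}

#' Pairwise predictor-overlap (% inclusion) table
#'
#' For every unordered pair of predictors, reports the two dataset sizes,
#' the intersection size, and the inclusion percentage `100 * |A n B| /
#' min(|A|, |B|)` rounded half-up to two decimals. The pair orientation is
#' recorded as `"A > B"` when A's dataset is larger, `"A < B"` when
#' smaller (ties broken lexicographically, recorded as `"A < B"`). Rows
#' whose smaller set is empty carry `pct_inclusion = NA` and
#' `flagged = TRUE`; they are excluded from any downstream summary.
#'
#' @param datasets Named list mapping predictor name to a character vector
#'   (set) of IDP protein ids; at least two predictors.
#' @return Data frame with columns `predictor_a`, `predictor_b`, `pair`,
#'   `n_a`, `n_b`, `n_intersection`, `pct_inclusion`, `flagged`.
#' @export
inclusion_table <- function(datasets) {
  stopifnot(length(datasets) >= 2L, !is.null(names(datasets)))
  datasets <- lapply(datasets, unique)
  nm <- names(datasets)
  rows <- list()
  for (i in seq_len(length(nm) - 1L)) for (j in seq(i + 1L, length(nm))) {
    a <- nm[i]; b <- nm[j]
    n_a <- length(datasets[[a]]); n_b <- length(datasets[[b]])
    n_int <- length(intersect(datasets[[a]], datasets[[b]]))
    small <- min(n_a, n_b)
    pct <- if (small == 0L) NA_real_ else
      round_half_up(100 * n_int / small, 2)
    pair <- if (n_a > n_b) paste(a, ">", b) else paste(a, "<", b)
    rows[[length(rows) + 1L]] <- data.frame(
      predictor_a = a, predictor_b = b, pair = pair,
      n_a = n_a, n_b = n_b, n_intersection = n_int,
      pct_inclusion = pct, flagged = small == 0L,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Inclusion percentage from printed pair counts
#'
#' Recomputes `100 * intersection / min(n_a, n_b)` (half-up, two decimals)
#' from the sizes alone, for checking published overlap tables.
#'
#' @param n_a,n_b Dataset sizes.
#' @param n_intersection Overlap size.
#' @return Numeric percentage.
#' @export
inclusion_pct <- function(n_a, n_b, n_intersection) {
  stopifnot(all(n_intersection <= pmin(n_a, n_b)))
  round_half_up(100 * n_intersection / pmin(n_a, n_b), 2)
}
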