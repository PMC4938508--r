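# Per-residue disorder score tracks: two implemented scale-based
# predictors (charge/hydropathy FoldIndex-style score and the TOP-IDP
# propensity scale), ingestion of externally computed tracks, and the
# consensus track.

#' Construct a score track
#'
#' @param protein_id Accession.
#' @param predictor Predictor name.
#' @param scores Numeric vector, one value per residue.
#' @param threshold Decision threshold.
#' @param higher_is_disordered Logical; `TRUE` if scores at or above the
#'   threshold are calls of disorder, `FALSE` if scores *below* the
#'   threshold are.
#' @return An object of class `score_track`.
#' @export
score_track <- function(protein_id, predictor, scores, threshold,
                        higher_is_disordered) {
  stopifnot(length(scores) >= 1L, all(is.finite(scores)),
            is.finite(threshold), is.logical(higher_is_disordered))
  structure(list(protein_id = protein_id, predictor = predictor,
                 scores = as.numeric(scores), threshold = threshold,
                 higher_is_disordered = higher_is_disordered),
            class = "score_track")
}

#' @export
print.score_track <- function(x, ...) {
  cat(sprintf("<score_track> %s / %s (%d residues, threshold %g, %s)\n",
              x$protein_id, x$predictor, length(x$scores), x$threshold,
              if (x$higher_is_disordered) "higher = disordered"
              else "lower = disordered"))
  invisible(x)
}

#' FoldIndex-style charge/hydropathy disorder score
#'
#' For each residue, over the window centred there (shrunk symmetrically at
#' the termini), the mean scaled Kyte-Doolittle hydropathy \eqn{\langle H
#' \rangle} (rescaled to \[0,1\] via \eqn{(H+4.5)/9}) and the mean net
#' charge \eqn{\langle R \rangle} (fraction of K/R minus fraction of D/E)
#' give the score \deqn{2.785 \langle H \rangle - |\langle R \rangle| -
#' 1.151.} Negative scores indicate disorder (`higher_is_disordered =
#' FALSE`, threshold 0). The ambiguity code X contributes scaled
#' hydropathy 0.5 and charge 0.
#'
#' @param sequence Amino-acid string (or a `protein_record`).
#' @param window Odd window width >= 3; default 51.
#' @param protein_id Accession recorded on the track (taken from the
#'   record when one is supplied).
#' @return A `score_track`.
#' @export
foldindex_score <- function(sequence, window = 51L, protein_id = "seq") {
  if (inherits(sequence, "protein_record")) {
    protein_id <- sequence$id
    sequence <- sequence$sequence
  }
  if (!nzchar(sequence)) stop("empty sequence", call. = FALSE)
  h <- .residue_values(sequence, aa_scale("kd_scaled"), x_value = 0.5)
  q <- .residue_values(sequence, aa_scale("charge"), x_value = 0)
  s <- 2.785 * .window_mean(h, window) - abs(.window_mean(q, window)) - 1.151
  score_track(protein_id, "foldindex", s, threshold = 0,
              higher_is_disordered = FALSE)
}

#' TOP-IDP propensity disorder score
#'
#' Windowed mean of the TOP-IDP per-residue disorder propensity scale;
#' positive means disorder-prone (`higher_is_disordered = TRUE`, threshold
#' 0). X contributes scale value 0.
#'
#' @inheritParams foldindex_score
#' @param window Odd window width >= 3; default 21.
#' @return A `score_track`.
#' @export
topidp_score <- function(sequence, window = 21L, protein_id = "seq") {
  if (inherits(sequence, "protein_record")) {
    protein_id <- sequence$id
    sequence <- sequence$sequence
  }
  if (!nzchar(sequence)) stop("empty sequence", call. = FALSE)
  v <- .residue_values(sequence, aa_scale("top_idp"), x_value = 0)
  score_track(protein_id, "topidp", .window_mean(v, window), threshold = 0,
              higher_is_disordered = TRUE)
}

#' Ingest externally computed per-residue score tracks
#'
#' Reads a TSV `protein_id position score` with 1-based positions that must
#' be contiguous 1..L per protein (gaps and duplicates are hard errors).
#' When `records` is supplied, track lengths are checked against the
#' sequences.
#'
#' @param path TSV file.
#' @param predictor Name recorded on the tracks.
#' @param threshold Decision threshold of the external tool.
#' @param higher_is_disordered Orientation of the external score.
#' @param records Optional named list of `protein_record` for validation.
#' @return Named list mapping protein id to `score_track`.
#' @export
ingest_scores <- function(path, predictor, threshold, higher_is_disordered,
                          records = NULL) {
  stopifnot(file.exists(path))
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(protein_id = "character"))
  need <- c("protein_id", "position", "score")
  if (!all(need %in% names(tab)))
    stop("score table must have columns: ", paste(need, collapse = " "),
         call. = FALSE)
  out <- lapply(split(tab, tab$protein_id), function(d) {
    d <- d[order(d$position), ]
    if (!identical(as.integer(d$position), seq_len(nrow(d))))
      stop("protein ", d$protein_id[1L],
           ": positions must be contiguous 1..L without gaps or duplicates",
           call. = FALSE)
    if (!is.null(records)) {
      rec <- records[[d$protein_id[1L]]]
      if (is.null(rec))
        stop("scores refer to unknown protein id: ", d$protein_id[1L],
             call. = FALSE)
      if (nrow(d) != seq_length(rec))
        stop("protein ", d$protein_id[1L], ": score track length ", nrow(d),
             " does not match sequence length ", seq_length(rec),
             call. = FALSE)
    }
    score_track(d$protein_id[1L], predictor, d$score, threshold,
                higher_is_disordered)
  })
  out[unique(tab$protein_id)]
}

#' Write score tracks to a TSV
#' @param tracks Named list of `score_track` (or a single track).
#' @param path Output TSV `protein_id position score`.
#' @export
write_scores <- function(tracks, path) {
  if (inherits(tracks, "score_track")) tracks <- list(tracks)
  tab <- do.call(rbind, lapply(tracks, function(t)
    data.frame(protein_id = t$protein_id,
               position = seq_along(t$scores), score = t$scores)))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Normalize a track to the \[0,1\] higher-is-disordered convention
#'
#' Probability-like tracks — higher-is-disordered with a decision
#' threshold inside (0,1), the convention of the consumed external
#' predictors — are required to already lie in \[0,1\] and pass through
#' unchanged. Raw-scale tracks (any lower-is-disordered track, or a
#' higher-is-disordered scale anchored at a threshold outside (0,1), like
#' the TOP-IDP score at 0) are mapped through the logistic transform
#' \eqn{1/(1+\exp(\pm(s - t)/\tau))} with \eqn{\tau = 0.5}, signed by the
#' track orientation, which sends the decision threshold \eqn{t} to 0.5
#' and preserves the decision boundary.
#'
#' @param track A `score_track`.
#' @param tau Logistic temperature for raw-scale tracks.
#' @return A `score_track` in \[0,1\] with threshold 0.5 and
#'   `higher_is_disordered = TRUE`.
#' @export
normalize_track <- function(track, tau = 0.5) {
  if (track$higher_is_disordered && track$threshold > 0 &&
      track$threshold < 1) {
    if (any(track$scores < 0 | track$scores > 1))
      stop("protein ", track$protein_id,
           ": higher-is-disordered track must lie in [0,1] for consensus",
           call. = FALSE)
    s <- track$scores
  } else if (track$higher_is_disordered) {
    s <- 1 / (1 + exp(-(track$scores - track$threshold) / tau))
  } else {
    s <- 1 / (1 + exp((track$scores - track$threshold) / tau))
  }
  score_track(track$protein_id, paste0(track$predictor, "_norm"), s,
              threshold = 0.5, higher_is_disordered = TRUE)
}

#' Consensus of several score tracks for one protein
#'
#' Each input is first normalized (see [normalize_track()]); the consensus
#' is the per-position arithmetic mean, with threshold 0.5.
#'
#' @param tracks List of `score_track` for the same protein, equal lengths.
#' @return A `score_track` named `"consensus"`.
#' @export
consensus_track <- function(tracks) {
  stopifnot(length(tracks) >= 1L)
  lens <- vapply(tracks, function(t) length(t$scores), 1L)
  if (length(unique(lens)) != 1L)
    stop("consensus_track: input tracks have different lengths", call. = FALSE)
  norm <- lapply(tracks, normalize_track)
  m <- rowMeans(do.call(cbind, lapply(norm, `[[`, "scores")))
  score_track(tracks[[1L]]$protein_id, "consensus", m, threshold = 0.5,
              higher_is_disordered = TRUE)
}
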