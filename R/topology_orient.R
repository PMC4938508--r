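# Disorder-guided orientation of multi-pass membrane proteins: between the
# two alternating labelings compatible with a fixed TM layout, prefer the
# one that places IDRs — and, per the positive-inside rule, K/R residues
# near TM boundaries — on the cytoplasmic side.

#' Enumerate the two possible orientations over fixed TM segments
#'
#' Candidate A labels the N-terminal side Cytoplasmic and alternates
#' across each TM segment; candidate B is the complement. A TM segment
#' touching position 1 (or L) simply has no N-terminal (C-terminal) loop;
#' alternation is still defined.
#'
#' @param tm_segments Data frame with `start`, `end` (sorted, disjoint).
#' @param L Sequence length.
#' @param protein_id Accession carried on the models.
#' @return List of two `topology_model`s, named `A` and `B`.
#' @export
enumerate_orientations <- function(tm_segments, L, protein_id = "seq") {
  tm <- tm_segments[order(tm_segments$start), , drop = FALSE]
  if (nrow(tm) == 0L)
    stop("no TM segments: nothing to orient", call. = FALSE)
  stopifnot(tm$start[1L] >= 1L, tm$end[nrow(tm)] <= L,
            all(tm$start <= tm$end),
            nrow(tm) < 2L || all(tm$start[-1L] > tm$end[-nrow(tm)]))
  is_tm <- rep(FALSE, L)
  for (i in seq_len(nrow(tm))) is_tm[tm$start[i]:tm$end[i]] <- TRUE
  r <- rle(is_tm)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  # parity of a loop = number of TM segments before it
  n_tm_before <- cumsum(r$values) - ifelse(r$values, 1L, 0L)
  side_a <- ifelse(r$values, "TM",
                   ifelse(n_tm_before %% 2L == 0L, "Cytoplasmic",
                          "Extracellular"))
  segs_a <- data.frame(start = starts, end = ends, side = side_a,
                       stringsAsFactors = FALSE)
  segs_b <- segs_a
  segs_b$side <- .opposite(segs_a$side)
  list(A = structure(list(protein_id = protein_id, segments = segs_a),
                     class = "topology_model"),
       B = structure(list(protein_id = protein_id, segments = segs_b),
                     class = "topology_model"))
}

#' Score one orientation candidate
#'
#' `disorder_score` is the fraction of IDR residues lying on loops that
#' the candidate labels Cytoplasmic (TM residues excluded from the
#' denominator). `charge_score` is the fraction of K/R residues within
#' `boundary_window` residues of a TM end, on loops, that the candidate
#' places Cytoplasmic. A component with an empty denominator is
#' uninformative and contributes the neutral value 0.5. The combined score
#' is `w_d * disorder_score + w_c * charge_score`.
#'
#' @param model A candidate `topology_model` (from
#'   [enumerate_orientations()]).
#' @param sequence Amino-acid string.
#' @param idrs IDR data frame for this protein (any chosen track).
#' @param boundary_window Loop residues within this distance of a TM
#'   boundary count for the positive-inside rule (default 15).
#' @param w_d,w_c Weights of the two components (default 0.5 each).
#' @return List with `disorder_score`, `charge_score`, `combined`, and the
#'   raw counts behind each fraction.
#' @export
score_orientation <- function(model, sequence, idrs, boundary_window = 15L,
                              w_d = 0.5, w_c = 0.5) {
  stopifnot(boundary_window >= 1L)
  sides <- residue_sides(model)
  L <- length(sides)
  stopifnot(nchar(sequence) == L)

  in_idr <- rep(FALSE, L)
  idrs <- idrs[idrs$protein_id == model$protein_id | is.na(idrs$protein_id), ,
               drop = FALSE]
  for (i in seq_len(nrow(idrs))) in_idr[idrs$start[i]:idrs$end[i]] <- TRUE
  on_loop <- sides != "TM"
  idr_loop <- in_idr & on_loop
  n_idr <- sum(idr_loop)
  n_idr_cyto <- sum(idr_loop & sides == "Cytoplasmic")
  disorder_score <- if (n_idr > 0L) n_idr_cyto / n_idr else NA_real_

  # loop residues within boundary_window of a TM segment end
  seg <- model$segments[model$segments$side == "TM", , drop = FALSE]
  near <- rep(FALSE, L)
  for (i in seq_len(nrow(seg))) {
    lo <- max(1L, seg$start[i] - boundary_window)
    if (lo <= seg$start[i] - 1L) near[lo:(seg$start[i] - 1L)] <- TRUE
    hi <- min(L, seg$end[i] + boundary_window)
    if (seg$end[i] + 1L <= hi) near[(seg$end[i] + 1L):hi] <- TRUE
  }
  chars <- strsplit(sequence, "")[[1]]
  kr <- chars %in% c("K", "R") & near & on_loop
  n_kr <- sum(kr)
  n_kr_cyto <- sum(kr & sides == "Cytoplasmic")
  charge_score <- if (n_kr > 0L) n_kr_cyto / n_kr else NA_real_

  d_eff <- if (is.na(disorder_score)) 0.5 else disorder_score
  c_eff <- if (is.na(charge_score)) 0.5 else charge_score
  list(disorder_score = disorder_score, charge_score = charge_score,
       combined = w_d * d_eff + w_c * c_eff,
       n_idr_loop = n_idr, n_idr_cyto = n_idr_cyto,
       n_kr_boundary = n_kr, n_kr_cyto = n_kr_cyto)
}

#' Predict the orientation of a membrane protein from disorder placement
#'
#' Enumerates the two alternating labelings over the protein's TRANSMEM
#' segments, scores both (see [score_orientation()]), and returns the
#' higher-scoring candidate unless the margin of combined scores is below
#' `ambiguity_margin`.
#'
#' @param record A `protein_record` with TRANSMEM features attached (any
#'   TOPO_DOM annotation is ignored — orientation is predicted from
#'   scratch).
#' @param idrs IDR data frame for this protein.
#' @param boundary_window,w_d,w_c See [score_orientation()].
#' @param ambiguity_margin Verdict is `"ambiguous"` iff
#'   `|combined_A - combined_B| <` this (default 0.05).
#' @return List with `verdict` (`"A"`, `"B"` or `"ambiguous"`), `margin`
#'   (`combined_A - combined_B`), `model` (the chosen `topology_model`, or
#'   `NULL` when ambiguous), `scores` (both candidates' score lists) and
#'   `n_term_side` of the chosen candidate.
#' @export
predict_orientation <- function(record, idrs, boundary_window = 15L,
                                w_d = 0.5, w_c = 0.5,
                                ambiguity_margin = 0.05) {
  tm <- record$features[record$features$kind == "TRANSMEM", , drop = FALSE]
  cand <- enumerate_orientations(tm, seq_length(record), record$id)
  sc <- lapply(cand, score_orientation, sequence = record$sequence,
               idrs = idrs, boundary_window = boundary_window,
               w_d = w_d, w_c = w_c)
  margin <- sc$A$combined - sc$B$combined
  if (abs(margin) < ambiguity_margin) {
    verdict <- "ambiguous"; model <- NULL; n_term <- NA_character_
  } else {
    verdict <- if (margin > 0) "A" else "B"
    model <- cand[[verdict]]
    n_term <- model$segments$side[1L]
    if (n_term == "TM") n_term <- .opposite(model$segments$side[2L])
  }
  list(verdict = verdict, margin = margin, model = model, scores = sc,
       n_term_side = n_term)
}

#' Orientation verdicts for a whole proteome
#' @param records Named list of `protein_record` (TRANSMEM attached).
#' @param idrs Combined IDR data frame.
#' @param ... Passed to [predict_orientation()].
#' @return Data frame: per protein, both combined scores, margin, verdict,
#'   and the predicted side of the N-terminus.
#' @export
orientation_table <- function(records, idrs, ...) {
  rows <- lapply(records, function(r) {
    p <- predict_orientation(r, idrs[idrs$protein_id == r$id, , drop = FALSE],
                             ...)
    data.frame(protein_id = r$id,
               combined_a = p$scores$A$combined,
               combined_b = p$scores$B$combined,
               margin = p$margin, verdict = p$verdict,
               n_term_side = p$n_term_side, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
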