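# Topology models from TRANSMEM/TOPO_DOM features, side localization of
# intervals, and side/occupancy/length statistics.

SIDES <- c("Cytoplasmic", "Extracellular", "TM", "Unknown")

.opposite <- function(side) {
  ifelse(side == "Cytoplasmic", "Extracellular",
  ifelse(side == "Extracellular", "Cytoplasmic", side))
}

#' Build a per-protein topology model
#'
#' Partitions `[1, L]` into ordered Cytoplasmic / TM / Extracellular /
#' Unknown segments. TRANSMEM features become TM segments; TOPO_DOM
#' features label the loop (maximal non-TM run) containing them. Loops
#' alternate sides across each TM segment, so annotating any loop
#' determines all loops connected to it through the TM chain; loops with
#' no reachable annotation are `Unknown`. Two different labels inside one
#' loop, a TOPO_DOM overlapping a TRANSMEM, or two same-side annotations
#' across a single TM are hard errors (alternation violations).
#'
#' @param record A `protein_record` with features attached.
#' @return Object of class `topology_model`: list with `protein_id` and a
#'   `segments` data frame (`start`, `end`, `side`) covering `[1, L]`.
#' @export
build_topology <- function(record) {
  L <- seq_length(record)
  f <- record$features
  tm <- f[f$kind == "TRANSMEM", , drop = FALSE]
  td <- f[f$kind == "TOPO_DOM", , drop = FALSE]
  tm <- tm[order(tm$start), , drop = FALSE]

  # residue -> TM mask
  is_tm <- rep(FALSE, L)
  for (i in seq_len(nrow(tm))) is_tm[tm$start[i]:tm$end[i]] <- TRUE
  for (i in seq_len(nrow(td)))
    if (any(is_tm[td$start[i]:td$end[i]]))
      stop("protein ", record$id, ": TOPO_DOM [", td$start[i], ",", td$end[i],
           "] overlaps a TRANSMEM segment", call. = FALSE)

  # loops = maximal non-TM runs, in order
  r <- rle(is_tm)
  seg_end <- cumsum(r$lengths)
  seg_start <- seg_end - r$lengths + 1L
  segs <- data.frame(start = seg_start, end = seg_end,
                     side = ifelse(r$values, "TM", NA_character_),
                     stringsAsFactors = FALSE)
  loop_idx <- which(!r$values)

  # seed loop sides from TOPO_DOM annotations
  side <- rep(NA_character_, nrow(segs))
  for (i in seq_len(nrow(td))) {
    k <- which(!r$values & segs$start <= td$start[i] & segs$end >= td$end[i])
    if (length(k) != 1L)
      stop("protein ", record$id, ": TOPO_DOM [", td$start[i], ",", td$end[i],
           "] spans a TRANSMEM boundary", call. = FALSE)
    lab <- td$label[i]
    if (!is.na(side[k]) && side[k] != lab)
      stop("protein ", record$id,
           ": conflicting TOPO_DOM labels within one topological domain",
           call. = FALSE)
    side[k] <- lab
  }

  # propagate by alternation across TM segments until fixpoint
  if (length(loop_idx) > 1L) {
    repeat {
      changed <- FALSE
      for (p in seq_len(length(loop_idx) - 1L)) {
        a <- loop_idx[p]; b <- loop_idx[p + 1L]   # adjacent across one TM
        if (!is.na(side[a]) && !is.na(side[b])) {
          if (side[a] == side[b])
            stop("protein ", record$id,
                 ": same-side topological domains across a TRANSMEM segment",
                 " (alternation violation)", call. = FALSE)
        } else if (!is.na(side[a])) {
          side[b] <- .opposite(side[a]); changed <- TRUE
        } else if (!is.na(side[b])) {
          side[a] <- .opposite(side[b]); changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  side[is.na(side)] <- "Unknown"
  segs$side[is.na(segs$side)] <- side[is.na(segs$side)]
  structure(list(protein_id = record$id, segments = segs),
            class = "topology_model")
}

#' @export
print.topology_model <- function(x, ...) {
  cat(sprintf("<topology_model> %s (%d segments, %d TM)\n", x$protein_id,
              nrow(x$segments), sum(x$segments$side == "TM")))
  invisible(x)
}

#' Per-residue side vector of a topology model
#' @param model A `topology_model`.
#' @return Character vector over `[1, L]` with values in
#'   Cytoplasmic/Extracellular/TM/Unknown.
#' @export
residue_sides <- function(model) {
  s <- model$segments
  rep(s$side, s$end - s$start + 1L)
}

#' Localize an interval to a membrane side
#'
#' Counts the interval's residues overlapping Cytoplasmic vs Extracellular
#' segments (TM and Unknown residues do not vote) and assigns the strict
#' majority side; an exact tie or zero non-TM overlap is `Ambiguous`.
#' A single-residue site is a length-1 interval.
#'
#' @param model A `topology_model`.
#' @param start,end 1-based inclusive interval bounds within `[1, L]`.
#' @return List with `side` (`"Cytoplasmic"`, `"Extracellular"` or
#'   `"Ambiguous"`), `overlap_fraction` (fraction of interval residues on
#'   the assigned side; `NA` when ambiguous), `n_cyto`, `n_extra`.
#' @export
localize <- function(model, start, end = start) {
  L <- sum(model$segments$end - model$segments$start + 1L)
  stopifnot(start >= 1L, end >= start, end <= L)
  sides <- residue_sides(model)[start:end]
  n_c <- sum(sides == "Cytoplasmic")
  n_e <- sum(sides == "Extracellular")
  if (n_c == n_e)   # covers the zero-overlap case too
    return(list(side = "Ambiguous", overlap_fraction = NA_real_,
                n_cyto = n_c, n_extra = n_e))
  win <- if (n_c > n_e) "Cytoplasmic" else "Extracellular"
  list(side = win, overlap_fraction = max(n_c, n_e) / (end - start + 1L),
       n_cyto = n_c, n_extra = n_e)
}

#' Localize a table of intervals against their proteins' models
#'
#' @param models Named list of `topology_model`.
#' @param intervals Data frame with `protein_id`, `start`, `end` (an IDR,
#'   MoRF or single-site table; a missing `end` column is taken as
#'   `start`).
#' @return The input with `side`, `overlap_fraction`, `n_cyto`, `n_extra`
#'   columns appended; intervals of proteins without a model are dropped
#'   with a warning.
#' @export
localize_intervals <- function(models, intervals) {
  if (is.null(intervals$end)) intervals$end <- intervals$start
  known <- intervals$protein_id %in% names(models)
  if (any(!known)) {
    warning(sum(!known), " interval(s) dropped: no topology model",
            call. = FALSE)
    intervals <- intervals[known, , drop = FALSE]
  }
  res <- lapply(seq_len(nrow(intervals)), function(i)
    localize(models[[intervals$protein_id[i]]],
             intervals$start[i], intervals$end[i]))
  intervals$side <- vapply(res, `[[`, "", "side")
  intervals$overlap_fraction <- vapply(res, `[[`, 1, "overlap_fraction")
  intervals$n_cyto <- vapply(res, function(x) as.integer(x$n_cyto), 1L)
  intervals$n_extra <- vapply(res, function(x) as.integer(x$n_extra), 1L)
  intervals
}

#' Remove multi-pass proteins whose loops are all below the IDR length rule
#'
#' A multi-pass protein every one of whose non-TM segments is shorter than
#' `min_len` residues can never contain an IDR by definition and is
#' excluded from side analyses. Single-pass and unannotated proteins are
#' always retained.
#'
#' @param records Named list of `protein_record`.
#' @param models Named list of `topology_model` (same names).
#' @param min_len Minimum loop length (default 30).
#' @return List with `retained` (record subset) and `excluded_ids`.
#' @export
filter_undeterminable <- function(records, models, min_len = 30L) {
  excl <- vapply(names(records), function(id) {
    if (classify_pass_type(records[[id]]) != "multi-pass") return(FALSE)
    s <- models[[id]]$segments
    loops <- s[s$side != "TM", , drop = FALSE]
    nrow(loops) > 0L && all(loops$end - loops$start + 1L < min_len)
  }, TRUE)
  list(retained = records[!excl], excluded_ids = names(records)[excl])
}

#' Side percentages of localized intervals per pass type
#'
#' Percentages are computed over Cytoplasmic + Extracellular assignments
#' only; Ambiguous assignments are counted separately.
#'
#' @param assignments Output of [localize_intervals()].
#' @param pass_types Named character vector from [pass_types()].
#' @return Data frame per pass type (plus a pooled `"all"` row): counts
#'   `n_cyto`, `n_extra`, `n_ambiguous` and percentages `pct_cyto`,
#'   `pct_extra` (half-up, 1 decimal; `NA` when the two-way denominator is
#'   zero).
#' @export
side_statistics <- function(assignments, pass_types) {
  assignments$pass_type <- unname(pass_types[assignments$protein_id])
  one <- function(d, label) {
    n_c <- sum(d$side == "Cytoplasmic")
    n_e <- sum(d$side == "Extracellular")
    n_a <- sum(d$side == "Ambiguous")
    denom <- n_c + n_e
    data.frame(pass_type = label, n_cyto = n_c, n_extra = n_e,
               n_ambiguous = n_a,
               pct_cyto = if (denom) round_half_up(100 * n_c / denom, 1)
                          else NA_real_,
               pct_extra = if (denom) round_half_up(100 * n_e / denom, 1)
                           else NA_real_,
               stringsAsFactors = FALSE)
  }
  groups <- split(assignments, assignments$pass_type)
  do.call(rbind, c(unname(Map(one, groups, names(groups))),
                   list(one(assignments, "all")),
                   make.row.names = FALSE))
}

#' Per-side IDR occupancy of one protein
#'
#' Occupancy of a side is `100 * (IDR residues on that side) / (residues
#' on that side)`, pooling all of the protein's same-side segments. Sides
#' with zero residues are skipped.
#'
#' @param model A `topology_model`.
#' @param idrs IDR data frame for this protein.
#' @return Data frame `protein_id, side, n_side, n_idr, occupancy_pct`
#'   with one row per present side (Cytoplasmic/Extracellular).
#' @export
occupancy <- function(model, idrs) {
  sides <- residue_sides(model)
  in_idr <- rep(FALSE, length(sides))
  idrs <- idrs[idrs$protein_id == model$protein_id, , drop = FALSE]
  for (i in seq_len(nrow(idrs))) in_idr[idrs$start[i]:idrs$end[i]] <- TRUE
  rows <- lapply(c("Cytoplasmic", "Extracellular"), function(sd) {
    n_side <- sum(sides == sd)
    if (n_side == 0L) return(NULL)
    n_idr <- sum(in_idr & sides == sd)
    data.frame(protein_id = model$protein_id, side = sd, n_side = n_side,
               n_idr = n_idr, occupancy_pct = 100 * n_idr / n_side,
               stringsAsFactors = FALSE)
  })
  .rbind_rows(rows, data.frame(protein_id = character(), side = character(),
                               n_side = integer(), n_idr = integer(),
                               occupancy_pct = numeric()))
}

#' Occupancy distribution and summary for a proteome
#'
#' @param models Named list of `topology_model`.
#' @param idrs Combined IDR data frame.
#' @param pass_types Named pass-type vector; `NULL` pools everything.
#' @return List with `per_protein` (the full distribution, for
#'   histogramming) and `summary` (per side and pass type: n proteins,
#'   mean occupancy, standard error).
#' @export
occupancy_statistics <- function(models, idrs, pass_types = NULL) {
  per <- .rbind_rows(lapply(models, occupancy, idrs = idrs),
                     occupancy(models[[1L]], idrs[0, , drop = FALSE])[0, ])
  per$pass_type <- if (is.null(pass_types)) rep("all", nrow(per))
                   else unname(pass_types[per$protein_id])
  agg <- .rbind_rows(lapply(
    split(per, list(per$side, per$pass_type), drop = TRUE),
    function(d) data.frame(
      side = d$side[1L], pass_type = d$pass_type[1L], n = nrow(d),
      mean_occupancy = mean(d$occupancy_pct),
      se_occupancy = stats::sd(d$occupancy_pct) / sqrt(nrow(d)),
      stringsAsFactors = FALSE)),
    data.frame(side = character(), pass_type = character(), n = integer(),
               mean_occupancy = numeric(), se_occupancy = numeric()))
  list(per_protein = per, summary = agg)
}

#' Length statistics of localized IDRs per side and pass type
#'
#' @param assignments Output of [localize_intervals()] carrying a `length`
#'   column (IDR tables do); Ambiguous assignments are excluded.
#' @param pass_types Named pass-type vector.
#' @return Data frame per (side, pass type): `n`, `mean`, `median`, `q1`,
#'   `q3` of interval length. Empty cells are absent.
#' @export
length_statistics <- function(assignments, pass_types) {
  d <- assignments[assignments$side %in% c("Cytoplasmic", "Extracellular"), ,
                   drop = FALSE]
  d$pass_type <- unname(pass_types[d$protein_id])
  .rbind_rows(lapply(
    split(d, list(d$side, d$pass_type), drop = TRUE),
    function(g) data.frame(
      side = g$side[1L], pass_type = g$pass_type[1L], n = nrow(g),
      mean = mean(g$length), median = stats::median(g$length),
      q1 = unname(stats::quantile(g$length, 0.25)),
      q3 = unname(stats::quantile(g$length, 0.75)),
      stringsAsFactors = FALSE)),
    data.frame(side = character(), pass_type = character(), n = integer(),
               mean = numeric(), median = numeric(), q1 = numeric(),
               q3 = numeric()))
}
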