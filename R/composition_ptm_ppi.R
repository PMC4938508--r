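# Amino-acid composition and enrichment, PTM density and IDR
# co-localization statistics, and interaction-degree statistics.

MOD_TYPES <- c("phospho", "ubiquitin")
PHOSPHO_RESIDUES <- c("S", "T", "Y")

#' Amino-acid composition of a pooled residue set
#'
#' Percentages over the 20 standard residues; X and any other non-standard
#' letter are excluded from both numerator and denominator. Sequences are
#' pooled (composition of a concatenation), so the result for several
#' proteins is the residue-weighted composition.
#'
#' @param sequences Character vector of amino-acid strings (whole
#'   proteins, or extracted residue subsets such as IDR residues).
#' @return Named numeric vector over the 20 residues summing to 100, of
#'   class `composition_vector`.
#' @export
composition <- function(sequences) {
  chars <- unlist(strsplit(paste(sequences, collapse = ""), ""))
  chars <- chars[chars %in% AA_STANDARD]
  if (length(chars) == 0L)
    stop("no standard residues to count", call. = FALSE)
  counts <- table(factor(chars, levels = AA_STANDARD))
  structure(100 * as.numeric(counts) / length(chars),
            names = AA_STANDARD, class = "composition_vector")
}

#' Extract residue subsets inside or outside intervals
#'
#' @param records Named list of `protein_record`.
#' @param intervals Data frame `protein_id, start, end` (e.g. an IDR
#'   table).
#' @param inside `TRUE` for residues covered by intervals, `FALSE` for the
#'   complement.
#' @return Character vector of residue strings, one per protein that
#'   contributes at least one residue.
#' @export
interval_residues <- function(records, intervals, inside = TRUE) {
  out <- vapply(records, function(r) {
    L <- seq_length(r)
    cov <- rep(FALSE, L)
    iv <- intervals[intervals$protein_id == r$id, , drop = FALSE]
    for (i in seq_len(nrow(iv))) cov[iv$start[i]:iv$end[i]] <- TRUE
    keep <- if (inside) cov else !cov
    paste(strsplit(r$sequence, "")[[1]][keep], collapse = "")
  }, "")
  out[nzchar(out)]
}

#' Per-residue enrichment of a composition against a background
#'
#' The default convention reports `(subset/background - 1) * 100`, so an
#' over-represented residue has a positive enrichment (a subset at 1.66x
#' background reads +66). The alternative `"printed"` convention,
#' `100 - subset * 100 / background`, is the sign-inverted form sometimes
#' seen in figure legends. Residues with zero background are omitted and
#' listed in the `omitted` attribute rather than silently zeroed.
#'
#' @param subset,background `composition_vector`s.
#' @param convention `"ratio"` (default) or `"printed"`.
#' @return Named numeric vector of enrichment percentages (attribute
#'   `omitted` lists residues with zero background).
#' @export
enrichment <- function(subset, background,
                       convention = c("ratio", "printed")) {
  convention <- match.arg(convention)
  stopifnot(identical(names(subset), names(background)))
  zero <- names(background)[background == 0]
  keep <- setdiff(names(background), zero)
  ratio <- 100 * subset[keep] / background[keep]
  out <- if (convention == "ratio") ratio - 100 else 100 - ratio
  attr(out, "omitted") <- zero
  out
}

#' Read a PTM site table
#'
#' TSV `protein_id position residue mod_type` with `mod_type` in
#' phospho/ubiquitin. Sites are validated against the records: position in
#' range and residue letter matching the sequence are hard errors when
#' violated. Phospho sites on residues other than S/T/Y are chemically
#' implausible; with `strict = TRUE` (default) they are dropped with a
#' warning, otherwise kept with a warning.
#'
#' @param path TSV file.
#' @param records Named list of `protein_record`.
#' @param strict Drop phospho sites on non-S/T/Y residues?
#' @return Data frame of validated sites.
#' @export
read_ptm_sites <- function(path, records, strict = TRUE) {
  stopifnot(file.exists(path))
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(protein_id = "character",
                                          residue = "character",
                                          mod_type = "character"))
  need <- c("protein_id", "position", "residue", "mod_type")
  if (!all(need %in% names(tab)))
    stop("PTM table must have columns: ", paste(need, collapse = " "),
         call. = FALSE)
  if (!all(tab$mod_type %in% MOD_TYPES))
    stop("unknown mod_type; expected one of: ",
         paste(MOD_TYPES, collapse = "/"), call. = FALSE)
  unknown <- setdiff(tab$protein_id, names(records))
  if (length(unknown))
    stop("PTM sites refer to unknown protein id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  for (i in seq_len(nrow(tab))) {
    rec <- records[[tab$protein_id[i]]]
    if (tab$position[i] < 1L || tab$position[i] > seq_length(rec))
      stop("PTM site out of range: ", tab$protein_id[i], " position ",
           tab$position[i], call. = FALSE)
    actual <- substr(rec$sequence, tab$position[i], tab$position[i])
    if (actual != tab$residue[i])
      stop("PTM site residue mismatch: ", tab$protein_id[i], " position ",
           tab$position[i], " is ", actual, " not ", tab$residue[i],
           call. = FALSE)
  }
  bad <- tab$mod_type == "phospho" & !(tab$residue %in% PHOSPHO_RESIDUES)
  if (any(bad)) {
    warning(sum(bad), " phospho site(s) on non-S/T/Y residues",
            if (strict) " dropped (strict mode)" else " kept",
            call. = FALSE)
    if (strict) tab <- tab[!bad, , drop = FALSE]
  }
  tab
}

# TRUE for each site that falls inside any interval of its protein.
.sites_in_intervals <- function(sites, intervals) {
  vapply(seq_len(nrow(sites)), function(i) {
    iv <- intervals[intervals$protein_id == sites$protein_id[i], ,
                    drop = FALSE]
    any(iv$start <= sites$position[i] & sites$position[i] <= iv$end)
  }, TRUE)
}

#' PTM density and IDR co-localization statistics
#'
#' Per protein class (IDP/FOP) and modification type, reports the
#' percentage of proteins carrying at least one site, the mean number of
#' sites per protein, the mean percentage of residues modified, and the
#' fraction of sites falling inside IDRs. For phospho sites inside IDRs a
#' S/T/Y residue breakdown is included.
#'
#' @param sites Validated PTM site table ([read_ptm_sites()]).
#' @param records Named list of `protein_record`.
#' @param idrs Combined IDR data frame (defines "inside an IDR").
#' @param idp_labels Named IDP/FOP vector ([idp_labels()]); all labelled
#'   proteins enter the denominators, with zero sites where absent.
#' @return List of data frames: `by_class` (one row per class x mod type),
#'   `per_protein` (site counts, for histogramming),
#'   `sty_breakdown_in_idr` (percent S/T/Y among phospho sites inside
#'   IDRs).
#' @export
ptm_stats <- function(sites, records, idrs, idp_labels) {
  ids <- names(idp_labels)
  lens <- vapply(records[ids], seq_length, 1L)
  in_idr <- if (nrow(sites)) .sites_in_intervals(sites, idrs) else logical()

  per <- expand.grid(protein_id = ids, mod_type = MOD_TYPES,
                     stringsAsFactors = FALSE)
  key <- paste(sites$protein_id, sites$mod_type)
  cnt <- table(key)
  per$n_sites <- as.integer(cnt[paste(per$protein_id, per$mod_type)])
  per$n_sites[is.na(per$n_sites)] <- 0L
  per$class <- unname(idp_labels[per$protein_id])
  per$length <- unname(lens[per$protein_id])
  per$pct_residues_modified <- 100 * per$n_sites / per$length

  by_class <- do.call(rbind, c(lapply(
    split(per, list(per$class, per$mod_type), drop = TRUE),
    function(d) {
      cls <- d$class[1L]; mt <- d$mod_type[1L]
      sel <- sites$mod_type == mt &
        unname(idp_labels[sites$protein_id]) == cls
      n_in <- sum(in_idr[sel]); n_tot <- sum(sel)
      data.frame(
        class = cls, mod_type = mt, n_proteins = nrow(d),
        pct_with_site = 100 * mean(d$n_sites > 0),
        mean_sites_per_protein = mean(d$n_sites),
        mean_pct_residues_modified = mean(d$pct_residues_modified),
        n_sites = n_tot, n_sites_in_idr = n_in,
        pct_sites_in_idr = if (n_tot) 100 * n_in / n_tot else NA_real_,
        stringsAsFactors = FALSE)
    }), make.row.names = FALSE))

  ph_in <- sites$mod_type == "phospho" & in_idr
  sty <- if (any(ph_in)) {
    res <- factor(sites$residue[ph_in], levels = PHOSPHO_RESIDUES)
    data.frame(residue = PHOSPHO_RESIDUES,
               n = as.integer(table(res)),
               pct = 100 * as.integer(table(res)) / sum(ph_in),
               stringsAsFactors = FALSE)
  } else {
    data.frame(residue = character(), n = integer(), pct = numeric())
  }
  list(by_class = by_class, per_protein = per, sty_breakdown_in_idr = sty)
}

#' Read a bait/prey interaction edge list
#' @param path TSV `bait_id prey_id`.
#' @return Data frame of edges (ids as character).
#' @export
read_edges <- function(path) {
  stopifnot(file.exists(path))
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("bait_id", "prey_id")
  if (!all(need %in% names(tab)))
    stop("edge table must have columns: ", paste(need, collapse = " "),
         call. = FALSE)
  if (any(!nzchar(tab$bait_id)) || any(!nzchar(tab$prey_id)))
    stop("empty protein id in edge table", call. = FALSE)
  tab[, need]
}

#' Unique-partner counts from a bait/prey edge list
#'
#' The partner set of a protein p is every q != p appearing with p in an
#' edge, in either direction; duplicates and self-loops are discarded.
#'
#' @param edges Edge data frame (`bait_id`, `prey_id`).
#' @param ids Character vector of proteins to report (others' edges still
#'   contribute partners).
#' @return Named integer vector of unique-partner counts over `ids`.
#' @export
partner_counts <- function(edges, ids) {
  e <- edges[edges$bait_id != edges$prey_id, , drop = FALSE]
  a <- pmin(e$bait_id, e$prey_id)
  b <- pmax(e$bait_id, e$prey_id)
  und <- unique(data.frame(a = a, b = b, stringsAsFactors = FALSE))
  cnt <- table(factor(c(und$a, und$b), levels = ids))
  stats::setNames(as.integer(cnt), ids)
}

#' Interaction-degree statistics per protein class
#'
#' @param edges Edge data frame.
#' @param idp_labels Named IDP/FOP vector; proteins without a label are
#'   ignored (their edges still count as partners of labelled proteins).
#' @return Data frame per class: `n_proteins`, `pct_with_partner`,
#'   `mean_partners` (unique partners, direction collapsed, self-loops
#'   excluded).
#' @export
degree_stats <- function(edges, idp_labels) {
  ids <- names(idp_labels)
  deg <- partner_counts(edges, ids)
  do.call(rbind, c(lapply(split(ids, unname(idp_labels[ids])), function(g) {
    data.frame(class = unname(idp_labels[g[1L]]), n_proteins = length(g),
               pct_with_partner = 100 * mean(deg[g] > 0),
               mean_partners = mean(deg[g]), stringsAsFactors = FALSE)
  }), make.row.names = FALSE))
}
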