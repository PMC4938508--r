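# Synthetic membrane proteomes with planted ground truth: alternating
# loop/TM architecture, disordered loops with disorder-biased composition
# preferentially on the cytoplasmic side, phosphosites enriched on
# disordered proteins, and interaction degrees elevated for disordered
# proteins. Everything is deterministic given the mandatory seed.

#' Default simulator composition vectors
#'
#' Three residue compositions (disordered loops, ordered loops, TM
#' segments), shipped as a plain-text resource. The disordered vector
#' raises P/E/S/Q/D/R and lowers hydrophobic and aromatic residues
#' relative to the ordered one, with magnitudes calibrated so the
#' charge/hydropathy predictor separates planted ordered and disordered
#' segments.
#'
#' @return Named list of three probability vectors over the 20 residues.
#' @export
sim_compositions <- function() {
  path <- system.file("extdata", "sim_compositions.tsv", package = "memidr",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(setequal(tab$aa, AA_STANDARD))
  lapply(stats::setNames(c("disordered", "ordered", "tm"),
                         c("disordered", "ordered", "tm")),
         function(col) stats::setNames(tab[[col]], tab$aa))
}

#' Specification of a synthetic membrane proteome
#'
#' @param n_proteins Number of proteins.
#' @param seed Mandatory RNG seed (no wall-clock seeding).
#' @param pass_type_mix Probabilities of single- vs multi-pass
#'   architecture, named `single`/`multi`.
#' @param tm_count_range Range of TM counts for multi-pass proteins.
#' @param loop_meanlog,loop_sdlog Log-normal parameters of loop length
#'   (residues).
#' @param min_idr_len Minimum length of a planted disordered loop
#'   (default 30, the IDR rule; disordered loop lengths are drawn from the
#'   loop distribution truncated at this value).
#' @param p_disordered_loop_cyto,p_disordered_loop_extra Per-loop
#'   probability that a cytoplasmic (extracellular) loop is planted
#'   disordered.
#' @param compositions Named list `disordered`/`ordered`/`tm` of residue
#'   probability vectors; default [sim_compositions()].
#' @param tm_len_range TM segment length range (default 19..23).
#' @param ptm_rate_idp,ptm_rate_fop Expected phosphosites per 100 residues
#'   for disorder-containing and fully ordered proteins.
#' @param serine_site_fraction Fraction of phosphosites placed on serine
#'   (the rest go to T/Y).
#' @param ppi_mean_degree_idp,ppi_mean_degree_fop Mean target interaction
#'   degree per class.
#' @return Validated object of class `sim_spec`.
#' @export
sim_spec <- function(n_proteins = 500L,
                     seed,
                     pass_type_mix = c(single = 0.45, multi = 0.55),
                     tm_count_range = c(2L, 10L),
                     loop_meanlog = log(40), loop_sdlog = 0.8,
                     min_idr_len = 30L,
                     p_disordered_loop_cyto = 0.40,
                     p_disordered_loop_extra = 0.10,
                     compositions = sim_compositions(),
                     tm_len_range = c(19L, 23L),
                     ptm_rate_idp = 1.6, ptm_rate_fop = 0.8,
                     serine_site_fraction = 0.58,
                     ppi_mean_degree_idp = 9.5,
                     ppi_mean_degree_fop = 6) {
  if (missing(seed)) stop("sim_spec: an explicit seed is mandatory",
                          call. = FALSE)
  stopifnot(n_proteins >= 1L,
            setequal(names(pass_type_mix), c("single", "multi")),
            all(pass_type_mix >= 0), sum(pass_type_mix) > 0,
            tm_count_range[1L] >= 2L,
            tm_count_range[2L] >= tm_count_range[1L],
            p_disordered_loop_cyto >= 0, p_disordered_loop_cyto <= 1,
            p_disordered_loop_extra >= 0, p_disordered_loop_extra <= 1,
            min_idr_len >= 1L,
            ptm_rate_idp >= 0, ptm_rate_fop >= 0,
            serine_site_fraction >= 0, serine_site_fraction <= 1,
            ppi_mean_degree_idp >= 0, ppi_mean_degree_fop >= 0,
            setequal(names(compositions), c("disordered", "ordered", "tm")))
  for (nm in names(compositions)) {
    v <- compositions[[nm]]
    if (!setequal(names(v), AA_STANDARD) || any(v < 0) ||
        abs(sum(v) - 1) > 1e-6)
      stop("sim_spec: composition '", nm,
           "' must be a probability vector over the 20 residues",
           call. = FALSE)
  }
  # infeasible if disordered loops are requested but the loop length
  # distribution essentially never reaches the minimum IDR length
  if ((p_disordered_loop_cyto > 0 || p_disordered_loop_extra > 0) &&
      stats::plnorm(min_idr_len, loop_meanlog, loop_sdlog,
                    lower.tail = FALSE) < 1e-4)
    stop("sim_spec: loop length distribution cannot reach min_idr_len = ",
         min_idr_len, " with usable probability", call. = FALSE)
  structure(list(n_proteins = as.integer(n_proteins), seed = as.integer(seed),
                 pass_type_mix = pass_type_mix / sum(pass_type_mix),
                 tm_count_range = as.integer(tm_count_range),
                 loop_meanlog = loop_meanlog, loop_sdlog = loop_sdlog,
                 min_idr_len = as.integer(min_idr_len),
                 p_disordered_loop_cyto = p_disordered_loop_cyto,
                 p_disordered_loop_extra = p_disordered_loop_extra,
                 compositions = compositions,
                 tm_len_range = as.integer(tm_len_range),
                 ptm_rate_idp = ptm_rate_idp, ptm_rate_fop = ptm_rate_fop,
                 serine_site_fraction = serine_site_fraction,
                 ppi_mean_degree_idp = ppi_mean_degree_idp,
                 ppi_mean_degree_fop = ppi_mean_degree_fop),
            class = "sim_spec")
}

.sample_residues <- function(n, comp) {
  paste(sample(names(comp), n, replace = TRUE, prob = comp), collapse = "")
}

.loop_len <- function(spec, disordered) {
  if (!disordered) return(max(5L, round(stats::rlnorm(1L, spec$loop_meanlog,
                                                      spec$loop_sdlog))))
  for (i in 1:200) {
    l <- round(stats::rlnorm(1L, spec$loop_meanlog, spec$loop_sdlog))
    if (l >= spec$min_idr_len) return(as.integer(l))
  }
  spec$min_idr_len
}

#' Generate a synthetic membrane proteome with planted truth
#'
#' Each protein is an alternating loop/TM/loop... architecture. Loop sides
#' alternate from a random N-terminal side; each loop is independently
#' planted disordered with the side-dependent probability, in which case
#' its residues are drawn from the disordered composition (ordered loops
#' and TM segments from theirs) and its interval is recorded as truth.
#' Full TOPO_DOM/TRANSMEM annotation is attached to every record.
#'
#' @param spec A `sim_spec`.
#' @return List of class `sim_proteome`: `records` (named list of
#'   `protein_record`) and `truth` (list with `idrs` data frame including
#'   planted side, `labels` named IDP/FOP vector, `n_term_side` named
#'   vector, `spec`).
#' @export
generate_proteome <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  records <- vector("list", spec$n_proteins)
  idr_rows <- list()
  n_term <- character(spec$n_proteins)
  ids <- sprintf("SYN%05d", seq_len(spec$n_proteins))
  for (i in seq_len(spec$n_proteins)) {
    pass <- sample(c("single", "multi"), 1L, prob = spec$pass_type_mix)
    n_tm <- if (pass == "single") 1L else
      sample(seq(spec$tm_count_range[1L], spec$tm_count_range[2L]), 1L)
    first_side <- sample(c("Cytoplasmic", "Extracellular"), 1L)
    n_term[i] <- first_side
    loop_sides <- rep_len(c(first_side, .opposite(first_side)), n_tm + 1L)
    p_dis <- ifelse(loop_sides == "Cytoplasmic",
                    spec$p_disordered_loop_cyto,
                    spec$p_disordered_loop_extra)
    dis <- stats::runif(n_tm + 1L) < p_dis
    parts <- character(0); feats <- list(); pos <- 0L
    for (k in seq_len(n_tm + 1L)) {
      llen <- .loop_len(spec, dis[k])
      comp <- if (dis[k]) spec$compositions$disordered
              else spec$compositions$ordered
      parts <- c(parts, .sample_residues(llen, comp))
      feats[[length(feats) + 1L]] <- data.frame(
        kind = "TOPO_DOM", start = pos + 1L, end = pos + llen,
        label = loop_sides[k], stringsAsFactors = FALSE)
      if (dis[k])
        idr_rows[[length(idr_rows) + 1L]] <- data.frame(
          protein_id = ids[i], start = pos + 1L, end = pos + llen,
          length = llen, side = loop_sides[k], stringsAsFactors = FALSE)
      pos <- pos + llen
      if (k <= n_tm) {
        tlen <- sample(seq(spec$tm_len_range[1L], spec$tm_len_range[2L]), 1L)
        parts <- c(parts, .sample_residues(tlen, spec$compositions$tm))
        feats[[length(feats) + 1L]] <- data.frame(
          kind = "TRANSMEM", start = pos + 1L, end = pos + tlen,
          label = "", stringsAsFactors = FALSE)
        pos <- pos + tlen
      }
    }
    records[[i]] <- protein_record(ids[i], paste(parts, collapse = ""),
                                   do.call(rbind, feats))
  }
  names(records) <- ids
  idrs <- if (length(idr_rows)) do.call(rbind, idr_rows) else
    data.frame(protein_id = character(), start = integer(), end = integer(),
               length = integer(), side = character())
  labels <- stats::setNames(ifelse(ids %in% idrs$protein_id, "IDP", "FOP"),
                            ids)
  structure(list(records = records,
                 truth = list(idrs = idrs, labels = labels,
                              n_term_side = stats::setNames(n_term, ids),
                              spec = spec)),
            class = "sim_proteome")
}

#' Generate planted phosphosites for a synthetic proteome
#'
#' Per protein, a Poisson number of phosphosites at the class-dependent
#' rate (sites per 100 residues), placed without replacement on S/T/Y
#' positions with serine weighted by `serine_site_fraction`.
#'
#' @param sim A `sim_proteome`.
#' @param seed Seed for site placement (defaults to `spec seed + 1`).
#' @return PTM site data frame `protein_id, position, residue, mod_type`
#'   (all phospho).
#' @export
generate_ptm <- function(sim, seed = sim$truth$spec$seed + 1L) {
  spec <- sim$truth$spec
  set.seed(seed)
  rows <- list()
  for (id in names(sim$records)) {
    rec <- sim$records[[id]]
    rate <- if (sim$truth$labels[[id]] == "IDP") spec$ptm_rate_idp
            else spec$ptm_rate_fop
    n <- stats::rpois(1L, rate * seq_length(rec) / 100)
    if (n == 0L) next
    chars <- strsplit(rec$sequence, "")[[1]]
    s_pos <- which(chars == "S")
    ty_pos <- which(chars %in% c("T", "Y"))
    n_s <- stats::rbinom(1L, n, spec$serine_site_fraction)
    take_s <- s_pos[sample.int(length(s_pos), min(n_s, length(s_pos)))]
    take_ty <- ty_pos[sample.int(length(ty_pos),
                                 min(n - n_s, length(ty_pos)))]
    pos <- sort(c(take_s, take_ty))
    if (!length(pos)) next
    rows[[length(rows) + 1L]] <- data.frame(
      protein_id = id, position = pos, residue = chars[pos],
      mod_type = "phospho", stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(protein_id = character(), position = integer(),
                      residue = character(), mod_type = character()))
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Generate a planted interaction network for a synthetic proteome
#'
#' Degree-configured random graph: each protein draws a Poisson target
#' degree at its class mean, stubs are paired uniformly, self-loops and
#' duplicate (undirected) pairs removed, and bait/prey direction assigned
#' at random.
#'
#' @param sim A `sim_proteome` (needs at least 2 proteins).
#' @param seed Seed for graph construction (defaults to `spec seed + 2`).
#' @return Edge data frame `bait_id, prey_id`.
#' @export
generate_ppi <- function(sim, seed = sim$truth$spec$seed + 2L) {
  spec <- sim$truth$spec
  ids <- names(sim$records)
  stopifnot(length(ids) >= 2L)
  set.seed(seed)
  mean_deg <- ifelse(sim$truth$labels[ids] == "IDP",
                     spec$ppi_mean_degree_idp, spec$ppi_mean_degree_fop)
  deg <- stats::rpois(length(ids), mean_deg)
  stubs <- rep(ids, deg)
  if (length(stubs) %% 2L == 1L) stubs <- stubs[-length(stubs)]
  if (!length(stubs))
    return(data.frame(bait_id = character(), prey_id = character()))
  stubs <- sample(stubs)
  a <- stubs[seq(1L, length(stubs), by = 2L)]
  b <- stubs[seq(2L, length(stubs), by = 2L)]
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  und <- unique(data.frame(lo = pmin(a, b), hi = pmax(a, b),
                           stringsAsFactors = FALSE))
  flip <- stats::runif(nrow(und)) < 0.5
  data.frame(bait_id = ifelse(flip, und$hi, und$lo),
             prey_id = ifelse(flip, und$lo, und$hi),
             stringsAsFactors = FALSE)
}

#' Write a synthetic proteome bundle to a directory
#'
#' Emits `proteins.fasta`, `features.tsv`, `truth_idrs.tsv`,
#' `truth_labels.tsv`, and (when requested) `ptm_sites.tsv` and
#' `ppi_edges.tsv`, all in the standard I/O formats of this package.
#'
#' @param sim A `sim_proteome`.
#' @param dir Output directory (created if absent).
#' @param ptm,ppi Also generate and write PTM sites / PPI edges?
#' @return Invisibly, the vector of written paths.
#' @export
write_proteome <- function(sim, dir, ptm = TRUE, ppi = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(fasta = file.path(dir, "proteins.fasta"),
             features = file.path(dir, "features.tsv"),
             truth_idrs = file.path(dir, "truth_idrs.tsv"),
             truth_labels = file.path(dir, "truth_labels.tsv"))
  write_fasta(sim$records, paths[["fasta"]])
  write_features(sim$records, paths[["features"]])
  utils::write.table(sim$truth$idrs, paths[["truth_idrs"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(protein_id = names(sim$truth$labels),
               label = unname(sim$truth$labels),
               n_term_side = unname(sim$truth$n_term_side)),
    paths[["truth_labels"]], sep = "\t", quote = FALSE, row.names = FALSE)
  if (ptm) {
    paths[["ptm"]] <- file.path(dir, "ptm_sites.tsv")
    utils::write.table(generate_ptm(sim), paths[["ptm"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (ppi) {
    paths[["ppi"]] <- file.path(dir, "ppi_edges.tsv")
    utils::write.table(generate_ppi(sim), paths[["ppi"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}

#' Deterministic 8-TM fixture with a disordered C-terminal tail
#'
#' A synthetic multi-pass protein built from fixed sequence motifs (no
#' RNG): an ordered N-terminal tail, eight 21-residue TM segments
#' separated by short ordered loops, and a C-terminal tail carrying two
#' disordered stretches of 50 and 34 residues. With an even TM count the
#' two termini share a side, so placing the disordered tail cytoplasmic
#' also places the N-terminus cytoplasmic. Only TRANSMEM features are
#' attached; orientation is left to [predict_orientation()].
#'
#' @return List with `record` (a `protein_record`), `idrs` (the two tail
#'   IDR intervals as a data frame) and `true_n_term_side`
#'   (`"Cytoplasmic"`).
#' @export
tmem117_like_fixture <- function() {
  motif <- function(m, n) paste(rep_len(strsplit(m, "")[[1]], n),
                                collapse = "")
  tm <- function() motif("LIVFALIVFAW", 21L)
  ordered <- function(n) motif("AGSTVLEKYF", n)
  disordered <- function(n) motif("SEPQDSEGKR", n)
  parts <- c(ordered(20L))
  for (k in 1:8) {
    parts <- c(parts, tm())
    if (k < 8) parts <- c(parts, ordered(15L))
  }
  tail_start <- 20L + 8L * 21L + 7L * 15L   # 293 residues before the tail
  parts <- c(parts, ordered(5L), disordered(50L), ordered(12L),
             disordered(34L), ordered(5L))
  seqs <- paste(parts, collapse = "")
  tm_feats <- data.frame(
    kind = "TRANSMEM",
    start = 20L + (0:7) * 36L + 1L,
    end = 20L + (0:7) * 36L + 21L,
    label = "", stringsAsFactors = FALSE)
  rec <- protein_record("TMEMLIKE1", seqs, tm_feats)
  idrs <- data.frame(
    protein_id = "TMEMLIKE1",
    start = c(tail_start + 6L, tail_start + 68L),
    end = c(tail_start + 55L, tail_start + 101L),
    length = c(50L, 34L), predictor = "truth", stringsAsFactors = FALSE)
  list(record = rec, idrs = idrs, true_n_term_side = "Cytoplasmic")
}
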