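# End-to-end orchestration: predict -> IDR -> topology -> localization ->
# statistics -> orientation -> enrichment -> PTM -> PPI, with a TSV bundle,
# a hashed manifest, and a plain-text report.

#' Build and validate a pipeline run configuration
#'
#' Either `fasta` + `features` point at input files, or `spec` is a
#' [sim_spec()] and inputs are generated in memory. All stages that lack
#' their optional input (PTM sites, PPI edges) are skipped.
#'
#' @param out_dir Output directory for the TSV bundle.
#' @param fasta,features Input FASTA / feature TSV paths (ignored when
#'   `spec` is given).
#' @param spec Optional `sim_spec` for a synthetic run.
#' @param predictor `"foldindex"`, `"topidp"` or `"consensus"` (mean of
#'   the two implemented predictors).
#' @param window Sliding-window width; `NULL` uses each predictor's
#'   default.
#' @param min_len Minimum IDR length (default 30).
#' @param ptm,ppi Optional PTM site / edge TSV paths.
#' @param boundary_window,w_d,w_c,ambiguity_margin Orientation parameters.
#' @return Validated list of class `run_config`.
#' @export
run_config <- function(out_dir, fasta = NULL, features = NULL, spec = NULL,
                       predictor = c("consensus", "foldindex", "topidp"),
                       window = NULL, min_len = 30L,
                       ptm = NULL, ppi = NULL,
                       boundary_window = 15L, w_d = 0.5, w_c = 0.5,
                       ambiguity_margin = 0.05) {
  predictor <- match.arg(predictor)
  stopifnot(min_len >= 1L)
  if (is.null(spec)) {
    for (p in c(fasta, features, ptm, ppi))
      if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
    if (is.null(fasta) || is.null(features))
      stop("run_config: need either a sim_spec or fasta + features paths",
           call. = FALSE)
  } else {
    stopifnot(inherits(spec, "sim_spec"))
  }
  structure(list(out_dir = out_dir, fasta = fasta, features = features,
                 spec = spec, predictor = predictor, window = window,
                 min_len = as.integer(min_len), ptm = ptm, ppi = ppi,
                 boundary_window = boundary_window, w_d = w_d, w_c = w_c,
                 ambiguity_margin = ambiguity_margin),
            class = "run_config")
}

.predict_tracks <- function(records, predictor, window) {
  fi_w <- if (is.null(window)) 51L else window
  ti_w <- if (is.null(window)) 21L else window
  switch(predictor,
    foldindex = lapply(records, foldindex_score, window = fi_w),
    topidp    = lapply(records, topidp_score, window = ti_w),
    consensus = lapply(records, function(r)
      consensus_track(list(foldindex_score(r, fi_w), topidp_score(r, ti_w)))))
}

.write_tsv <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes every stage for which inputs are available and writes one TSV
#' per stage plus `manifest.json` (parameters, row counts, MD5 content
#' hashes) and `report.md` to `config$out_dir`. Reruns with an identical
#' configuration reproduce identical tables.
#'
#' @param config A `run_config`.
#' @return Invisibly, a list with the in-memory tables and the manifest.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  stage <- function(name) message(sprintf("[memidr] %s (%.1fs)", name,
    as.numeric(difftime(Sys.time(), t0, units = "secs"))))

  stage("load inputs")
  if (!is.null(config$spec)) {
    sim <- generate_proteome(config$spec)
    records <- sim$records
  } else {
    records <- read_fasta(config$fasta)
    records <- attach_feature_table(records, read_features(config$features))
  }
  tables <- list()

  stage("disorder prediction")
  tracks <- .predict_tracks(records, config$predictor, config$window)
  stage("IDR calling")
  idrs <- idr_table(tracks, config$min_len)
  labels <- idp_labels(idrs, names(records))
  tables$idrs <- idrs
  tables$labels <- data.frame(protein_id = names(labels),
                              label = unname(labels))

  stage("topology")
  models <- lapply(records, build_topology)
  tables$topology <- do.call(rbind, c(lapply(models, function(m)
    cbind(protein_id = m$protein_id, m$segments)), make.row.names = FALSE))
  pt <- pass_types(records)
  tables$pass_types <- pass_type_summary(records)
  kept <- filter_undeterminable(records, models, config$min_len)

  stage("localization and side statistics")
  assign_idr <- localize_intervals(models[names(kept$retained)],
                                   idrs[idrs$protein_id %in%
                                          names(kept$retained), ,
                                        drop = FALSE])
  tables$assignments <- assign_idr
  if (nrow(assign_idr)) {
    tables$side_stats <- side_statistics(assign_idr, pt)
    tables$length_stats <- length_statistics(assign_idr, pt)
  }
  occ <- occupancy_statistics(models, idrs, pt)
  tables$occupancy <- occ$per_protein
  tables$occupancy_summary <- occ$summary

  stage("predictor overlap")
  fi_ids <- names(which(vapply(records, function(r)
    nrow(idrs_from_track(foldindex_score(r), config$min_len)) > 0L, TRUE)))
  ti_ids <- names(which(vapply(records, function(r)
    nrow(idrs_from_track(topidp_score(r), config$min_len)) > 0L, TRUE)))
  tables$inclusion <- inclusion_table(list(foldindex = fi_ids,
                                           topidp = ti_ids))

  stage("orientation")
  multi <- records[pt == "multi-pass"]
  if (length(multi))
    tables$orientation <- orientation_table(
      multi, idrs, boundary_window = config$boundary_window,
      w_d = config$w_d, w_c = config$w_c,
      ambiguity_margin = config$ambiguity_margin)

  stage("composition and enrichment")
  all_comp <- composition(vapply(records, `[[`, "", "sequence"))
  idp_ids <- names(labels)[labels == "IDP"]
  if (length(idp_ids)) {
    idp_comp <- composition(vapply(records[idp_ids], `[[`, "", "sequence"))
    idr_res <- interval_residues(records, idrs)
    enr <- list(idp = enrichment(idp_comp, all_comp))
    if (length(idr_res)) enr$idr <- enrichment(composition(idr_res), all_comp)
    tables$enrichment <- data.frame(
      aa = names(enr$idp),
      idp_enrichment_pct = unname(enr$idp),
      idr_enrichment_pct = if (is.null(enr$idr)) NA_real_
                           else unname(enr$idr))
  }

  if (!is.null(config$ptm)) {
    stage("PTM statistics")
    sites <- read_ptm_sites(config$ptm, records)
    ptm <- ptm_stats(sites, records, idrs, labels)
    tables$ptm_by_class <- ptm$by_class
    tables$ptm_sty_in_idr <- ptm$sty_breakdown_in_idr
  }
  if (!is.null(config$ppi)) {
    stage("PPI statistics")
    tables$ppi <- degree_stats(read_edges(config$ppi), labels)
  }

  stage("write bundle")
  files <- character()
  for (nm in names(tables))
    files[nm] <- .write_tsv(tables[[nm]],
                            file.path(config$out_dir, paste0(nm, ".tsv")))
  manifest <- list(
    package_version = as.character(utils::packageVersion("memidr")),
    parameters = list(predictor = config$predictor, window = config$window,
                      min_len = config$min_len,
                      seed = if (is.null(config$spec)) NULL
                             else config$spec$seed),
    excluded_undeterminable = kept$excluded_ids,
    files = lapply(stats::setNames(nm = names(files)), function(nm)
      list(path = basename(files[[nm]]),
           rows = nrow(tables[[nm]]),
           md5 = unname(tools::md5sum(files[[nm]])))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  writeLines(report(tables), file.path(config$out_dir, "report.md"))
  stage("done")
  invisible(list(tables = tables, manifest = manifest))
}

.render_tsv_section <- function(tables, name, title) {
  if (is.null(tables[[name]]))
    return(c(paste("##", title), "", "_absent_", ""))
  tab <- tables[[name]]
  txt <- utils::capture.output(print(tab, row.names = FALSE, digits = 4))
  c(paste("##", title), "", "```", txt, "```", "")
}

#' Render the figure-by-figure summary report
#'
#' One section per analysis: dataset pass types, predictor overlap,
#' amino-acid enrichment, side percentages, IDR lengths and occupancy,
#' orientation verdicts, PTM and PPI statistics. Missing tables are marked
#' absent rather than failing.
#'
#' @param tables Named list of stage tables (as produced by [run_all()]).
#' @return Character vector of markdown lines.
#' @export
report <- function(tables) {
  c("# memidr analysis report", "",
    .render_tsv_section(tables, "pass_types", "Dataset pass types"),
    .render_tsv_section(tables, "inclusion", "Predictor overlap (% inclusion)"),
    .render_tsv_section(tables, "enrichment", "Amino-acid enrichment"),
    .render_tsv_section(tables, "side_stats", "IDR side percentages"),
    .render_tsv_section(tables, "length_stats", "IDR length statistics"),
    .render_tsv_section(tables, "occupancy_summary", "IDR occupancy"),
    .render_tsv_section(tables, "orientation", "Orientation verdicts"),
    .render_tsv_section(tables, "ptm_by_class", "PTM statistics"),
    .render_tsv_section(tables, "ppi", "Interaction-degree statistics"))
}
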