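#' @keywords internal
"_PACKAGE"

# Amino-acid alphabets and per-residue scales used by the disorder
# predictors. The numeric scales are shipped as a plain-text resource
# (inst/extdata/disorder_scales.tsv) so that their provenance and version
# are inspectable; they are implementation inputs, not fitted values.

AA_STANDARD <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.memidr_cache <- new.env(parent = emptyenv())

.scales_table <- function() {
  if (is.null(.memidr_cache$scales)) {
    path <- system.file("extdata", "disorder_scales.tsv", package = "memidr",
                        mustWork = TRUE)
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    stopifnot(setequal(tab$aa, AA_STANDARD))
    .memidr_cache$scales <- tab
  }
  .memidr_cache$scales
}

#' Per-residue amino-acid scales used by the implemented predictors
#'
#' @param name `"kyte_doolittle"` (raw hydropathy), `"kd_scaled"`
#'   (hydropathy rescaled to \[0,1\] via `(H + 4.5)/9`), `"top_idp"`
#'   (disorder propensity, higher = more disorder-prone), or `"charge"`
#'   (+1 for K/R, -1 for D/E, 0 otherwise).
#' @return Named numeric vector over the 20 standard residues.
#' @export
aa_scale <- function(name = c("kyte_doolittle", "kd_scaled", "top_idp",
                              "charge")) {
  name <- match.arg(name)
  tab <- .scales_table()
  v <- switch(name,
    kyte_doolittle = tab$kyte_doolittle,
    kd_scaled      = (tab$kyte_doolittle + 4.5) / 9,
    top_idp        = tab$top_idp,
    charge         = ifelse(tab$aa %in% c("K", "R"), 1,
                     ifelse(tab$aa %in% c("D", "E"), -1, 0)))
  stats::setNames(v, tab$aa)
}

# Expand a scale to a full per-residue numeric vector for a sequence,
# substituting `x_value` for the ambiguity code X (and any non-standard
# letter, which read_fasta has already warned about).
.residue_values <- function(sequence, scale, x_value) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  v <- unname(scale[chars])
  v[is.na(v)] <- x_value
  v
}
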