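# Sequence and annotation I/O: FASTA records, TRANSMEM/TOPO_DOM feature
# tables (UniProt-style 1-based inclusive coordinates), and pass-type
# classification.

FEATURE_KINDS <- c("TRANSMEM", "TOPO_DOM")
TOPO_LABELS <- c("Cytoplasmic", "Extracellular", "Lumenal")

.empty_features <- function() {
  data.frame(kind = character(), start = integer(), end = integer(),
             label = character(), stringsAsFactors = FALSE)
}

#' Construct a protein record
#'
#' A `protein_record` bundles an accession, an amino-acid sequence and a
#' (possibly empty) table of TRANSMEM / TOPO_DOM feature intervals in
#' 1-based inclusive coordinates.
#'
#' @param id Unique accession string.
#' @param sequence Amino-acid string (upper-cased; the 20 standard letters
#'   plus X; other letters trigger a warning and are ignored by
#'   composition statistics downstream).
#' @param features Data frame with columns `kind`, `start`, `end`, `label`,
#'   or `NULL` for none.
#' @return An object of class `protein_record`.
#' @export
protein_record <- function(id, sequence, features = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- toupper(as.character(sequence))
  if (nchar(sequence) < 1L)
    stop("protein ", id, ": empty sequence", call. = FALSE)
  extra <- setdiff(unique(strsplit(sequence, "")[[1]]),
                   c(AA_STANDARD, "X"))
  if (length(extra))
    warning("protein ", id, ": non-standard residue letter(s) ",
            paste(extra, collapse = ","),
            " kept in sequence but excluded from composition statistics",
            call. = FALSE)
  rec <- structure(list(id = id, sequence = sequence,
                        features = .empty_features()),
                   class = "protein_record")
  if (!is.null(features) && nrow(features)) rec <- attach_features(rec, features)
  rec
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s (%d aa, %d TRANSMEM, %d TOPO_DOM)\n",
              x$id, nchar(x$sequence),
              sum(x$features$kind == "TRANSMEM"),
              sum(x$features$kind == "TOPO_DOM")))
  invisible(x)
}

#' Sequence length of a protein record
#' @param record A `protein_record`.
#' @return Integer length.
#' @export
seq_length <- function(record) nchar(record$sequence)

#' Attach validated feature intervals to a record
#'
#' Enforces the interval contract: 1-based inclusive bounds inside the
#' sequence, labels present exactly for TOPO_DOM rows, and non-overlapping
#' TRANSMEM segments. `Lumenal` labels are collapsed to `Extracellular`
#' (side statistics are a binary cytoplasmic/extracellular split).
#'
#' @param record A `protein_record`.
#' @param features Data frame with columns `kind`, `start`, `end`, `label`.
#' @return The record with features attached (sorted by start).
#' @export
attach_features <- function(record, features) {
  f <- as.data.frame(features, stringsAsFactors = FALSE)
  if (!nrow(f)) { record$features <- .empty_features(); return(record) }
  if (is.null(f$label)) f$label <- ""
  f$label[is.na(f$label)] <- ""
  f$start <- as.integer(f$start); f$end <- as.integer(f$end)
  L <- seq_length(record)
  bad <- !(f$kind %in% FEATURE_KINDS)
  if (any(bad)) stop("protein ", record$id, ": unknown feature kind ",
                     paste(unique(f$kind[bad]), collapse = ","), call. = FALSE)
  if (any(f$start < 1L | f$start > f$end | f$end > L))
    stop("protein ", record$id,
         ": feature interval out of bounds (1-based inclusive, length ", L,
         ")", call. = FALSE)
  is_td <- f$kind == "TOPO_DOM"
  if (any(is_td & !(f$label %in% TOPO_LABELS)))
    stop("protein ", record$id, ": TOPO_DOM label must be one of ",
         paste(TOPO_LABELS, collapse = "/"), call. = FALSE)
  if (any(!is_td & nzchar(f$label)))
    stop("protein ", record$id, ": TRANSMEM feature must not carry a label",
         call. = FALSE)
  f$label[f$label == "Lumenal"] <- "Extracellular"
  tm <- f[!is_td, , drop = FALSE]
  if (nrow(tm) > 1L) {
    tm <- tm[order(tm$start), ]
    if (any(tm$start[-1L] <= tm$end[-nrow(tm)]))
      stop("protein ", record$id, ": overlapping TRANSMEM intervals",
           call. = FALSE)
  }
  record$features <- f[order(f$start, f$kind), c("kind", "start", "end", "label")]
  rownames(record$features) <- NULL
  record
}

#' Read protein sequences from a FASTA file
#'
#' The header token up to the first whitespace is the accession; sequences
#' are upper-cased. Duplicate accessions and empty sequences are hard
#' errors; letters outside the 20 standard residues plus X produce a
#' warning (the residues are kept but ignored in composition statistics).
#'
#' @param path FASTA file.
#' @return Named list of `protein_record` (features empty), input order
#'   preserved. An empty file yields an empty list.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  if (file.size(path) == 0L) return(structure(list(), names = character()))
  aas <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aas))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  seqs <- toupper(as.character(aas))
  recs <- lapply(seq_along(ids), function(i) {
    if (nchar(seqs[[i]]) == 0L)
      stop("protein ", ids[[i]], ": empty sequence", call. = FALSE)
    protein_record(ids[[i]], seqs[[i]])
  })
  stats::setNames(recs, ids)
}

#' Write protein records to FASTA
#' @param records Named list of `protein_record`.
#' @param path Output file.
#' @export
write_fasta <- function(records, path) {
  aas <- Biostrings::AAStringSet(vapply(records, `[[`, "", "sequence"))
  names(aas) <- vapply(records, `[[`, "", "id")
  Biostrings::writeXStringSet(aas, path, width = 70L)
  invisible(path)
}

#' Read a feature table (TRANSMEM / TOPO_DOM intervals)
#'
#' Expects a TSV with header `protein_id kind start end label`, coordinates
#' 1-based inclusive. Structural errors (start > end, start < 1, unknown
#' kind or label) abort with the offending line number.
#'
#' @param path TSV file.
#' @return Named list mapping protein id to a feature data frame.
#' @export
read_features <- function(path) {
  stopifnot(file.exists(path))
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(protein_id = "character",
                                          kind = "character",
                                          label = "character"))
  need <- c("protein_id", "kind", "start", "end", "label")
  if (!all(need %in% names(tab)))
    stop("feature table must have columns: ", paste(need, collapse = " "),
         call. = FALSE)
  tab$label[is.na(tab$label)] <- ""
  for (i in seq_len(nrow(tab))) {      # line i+1 in the file (header = 1)
    row <- tab[i, ]
    if (is.na(row$start) || is.na(row$end) || row$start < 1L ||
        row$start > row$end)
      stop("feature table line ", i + 1L,
           ": invalid coordinates (1-based inclusive, start <= end)",
           call. = FALSE)
    if (!row$kind %in% FEATURE_KINDS)
      stop("feature table line ", i + 1L, ": unknown kind '", row$kind, "'",
           call. = FALSE)
    if (row$kind == "TOPO_DOM" && !row$label %in% TOPO_LABELS)
      stop("feature table line ", i + 1L, ": unknown TOPO_DOM label '",
           row$label, "'", call. = FALSE)
    if (row$kind == "TRANSMEM" && nzchar(row$label))
      stop("feature table line ", i + 1L, ": TRANSMEM rows take no label",
           call. = FALSE)
  }
  split(tab[, c("kind", "start", "end", "label")], tab$protein_id)
}

#' Write feature intervals for a set of records
#' @param records Named list of `protein_record`.
#' @param path Output TSV.
#' @export
write_features <- function(records, path) {
  rows <- lapply(records, function(r) {
    if (!nrow(r$features)) return(NULL)
    cbind(protein_id = r$id, r$features)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    tab <- data.frame(protein_id = character(), kind = character(),
                      start = integer(), end = integer(),
                      label = character())
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Attach a feature table to a list of records
#' @param records Named list of `protein_record`.
#' @param features Result of [read_features()] (or an equivalent list).
#' @return Records with features attached; feature ids absent from
#'   `records` are a hard error.
#' @export
attach_feature_table <- function(records, features) {
  unknown <- setdiff(names(features), names(records))
  if (length(unknown))
    stop("features refer to unknown protein id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  for (id in names(features))
    records[[id]] <- attach_features(records[[id]], features[[id]])
  records
}

#' Classify a membrane protein by pass type
#'
#' Single-pass proteins carry exactly one TRANSMEM feature, multi-pass two
#' or more, unannotated none.
#'
#' @param record A `protein_record` with features attached.
#' @return `"single-pass"`, `"multi-pass"` or `"unannotated"`.
#' @export
classify_pass_type <- function(record) {
  n <- sum(record$features$kind == "TRANSMEM")
  if (n == 0L) "unannotated" else if (n == 1L) "single-pass" else "multi-pass"
}

#' Pass-type classification for a whole proteome
#' @param records Named list of `protein_record`.
#' @return Named character vector of pass types.
#' @export
pass_types <- function(records) {
  vapply(records, classify_pass_type, "")
}

#' Pass-type counts and percentages
#' @param records Named list of `protein_record`.
#' @return Data frame with columns `pass_type`, `n`, `pct` (percent of the
#'   dataset, to one decimal).
#' @export
pass_type_summary <- function(records) {
  pt <- factor(pass_types(records),
               levels = c("single-pass", "multi-pass", "unannotated"))
  n <- as.integer(table(pt))
  data.frame(pass_type = levels(pt), n = n,
             pct = round_half_up(100 * n / max(1L, length(pt)), 1),
             stringsAsFactors = FALSE)
}
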