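# Shared fixtures and independent brute-force oracles. The oracles are
# deliberately naive re-implementations of the contracts (loops, explicit
# enumeration) so they stay independent of the vectorized code paths they
# check.

random_sequence <- function(n, alphabet = memidr:::AA_STANDARD) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Brute-force windowed mean with symmetric shrinking at the termini.
oracle_window_mean <- function(x, window) {
  h <- (window - 1) / 2
  n <- length(x)
  sapply(seq_len(n), function(i) {
    r <- min(h, i - 1, n - i)
    mean(x[(i - r):(i + r)])
  })
}

# Brute-force FoldIndex-style score via the oracle windower.
oracle_foldindex <- function(sequence, window) {
  chars <- strsplit(sequence, "")[[1]]
  kd <- aa_scale("kd_scaled")
  ch <- aa_scale("charge")
  h <- ifelse(chars %in% names(kd), kd[chars], 0.5)
  q <- ifelse(chars %in% names(ch), ch[chars], 0)
  2.785 * oracle_window_mean(h, window) -
    abs(oracle_window_mean(q, window)) - 1.151
}

# Exhaustive enumeration of maximal TRUE runs of length >= min_len.
oracle_runs <- function(calls, min_len) {
  runs <- list()
  i <- 1L
  n <- length(calls)
  while (i <= n) {
    if (calls[i]) {
      j <- i
      while (j < n && calls[j + 1L]) j <- j + 1L
      if (j - i + 1L >= min_len)
        runs[[length(runs) + 1L]] <- c(start = i, end = j)
      i <- j + 1L
    } else i <- i + 1L
  }
  runs
}

# Naive unique-partner recount straight from the edge list.
oracle_partner_count <- function(edges, id) {
  partners <- c(edges$prey_id[edges$bait_id == id],
                edges$bait_id[edges$prey_id == id])
  length(unique(setdiff(partners, id)))
}

# A tiny annotated single-pass record: 9-residue cytoplasmic N-tail,
# TM [10,30], extracellular [31,60].
single_pass_record <- function(id = "SP1") {
  protein_record(id, strrep("A", 60), data.frame(
    kind = c("TRANSMEM", "TOPO_DOM", "TOPO_DOM"),
    start = c(10L, 1L, 31L), end = c(30L, 9L, 60L),
    label = c("", "Cytoplasmic", "Extracellular")))
}

# Overlap fraction of one truth interval by a called-IDR table.
overlap_fraction <- function(called, start, end) {
  if (!nrow(called)) return(0)
  ov <- pmax(0, pmin(called$end, end) - pmax(called$start, start) + 1)
  sum(ov) / (end - start + 1)
}
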