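test_that("foldindex evaluates the charge/hydropathy formula exactly", {
  # homopolymers: window mean of a constant is the constant
  for (w in c(3L, 21L, 51L)) {
    t_i <- foldindex_score(strrep("I", 80), w)
    expect_equal(t_i$scores, rep(2.785 * 1 - 0 - 1.151, 80))  # +1.634
    t_e <- foldindex_score(strrep("E", 80), w)
    expect_equal(t_e$scores, rep(2.785 * (1 / 9) - 1 - 1.151, 80))
    expect_true(all(t_e$scores < 0))   # poly-E disordered everywhere
    expect_false(t_e$higher_is_disordered)
    expect_identical(t_e$threshold, 0)
  }
  # X is neutral: scaled hydropathy 0.5, charge 0
  t_x <- foldindex_score(strrep("X", 20), 5)
  expect_equal(t_x$scores, rep(2.785 * 0.5 - 1.151, 20))
})

test_that("both predictors match a brute-force sliding-window oracle", {
  set.seed(101)
  scale <- aa_scale("top_idp")
  for (rep in 1:5) {
    s <- random_sequence(sample(30:120, 1))
    for (w in c(3L, 9L, 21L)) {
      expect_equal(foldindex_score(s, w)$scores, oracle_foldindex(s, w),
                   tolerance = 1e-9)
      chars <- strsplit(s, "")[[1]]
      expect_equal(topidp_score(s, w)$scores,
                   oracle_window_mean(unname(scale[chars]), w),
                   tolerance = 1e-9)
    }
  }
})

test_that("topidp homopolymers and junctions equal the scale values", {
  scale <- aa_scale("top_idp")
  expect_equal(topidp_score(strrep("P", 50), 21)$scores,
               rep(unname(scale[["P"]]), 50))
  # two long homopolymer halves: interior of each half sits at its value
  tr <- topidp_score(paste0(strrep("E", 60), strrep("I", 60)), 21)
  expect_equal(tr$scores[1:40], rep(unname(scale[["E"]]), 40))
  expect_equal(tr$scores[81:120], rep(unname(scale[["I"]]), 40))
})

test_that("foldindex is monotone under hydrophobic uncharged substitution", {
  # replacing any window residue by I (most hydrophobic, uncharged) never
  # decreases the score at the window center; exhaustive on a short seq
  set.seed(7)
  s <- random_sequence(25)
  w <- 9L
  base <- foldindex_score(s, w)$scores
  for (pos in 1:25) {
    chars <- strsplit(s, "")[[1]]
    chars[pos] <- "I"
    sub <- foldindex_score(paste(chars, collapse = ""), w)$scores
    expect_true(all(sub - base >= -1e-12))
  }
})

test_that("ingest_scores reads contiguous tracks and rejects gaps", {
  f <- withr::local_tempfile(fileext = ".tsv")
  hdr <- "protein_id\tposition\tscore"
  writeLines(c(hdr, "P1\t1\t0.2", "P1\t2\t0.9", "P1\t3\t0.4"), f)
  tr <- ingest_scores(f, "iupred", 0.5, TRUE)
  expect_length(tr$P1$scores, 3L)
  expect_equal(tr$P1$predictor, "iupred")

  writeLines(c(hdr, "P1\t1\t0.2", "P1\t3\t0.4"), f)
  expect_error(ingest_scores(f, "iupred", 0.5, TRUE), "contiguous")
  writeLines(c(hdr, "P1\t1\t0.2", "P1\t1\t0.4"), f)
  expect_error(ingest_scores(f, "iupred", 0.5, TRUE), "contiguous")

  # length checked against records when supplied
  writeLines(c(hdr, "P1\t1\t0.2", "P1\t2\t0.9"), f)
  recs <- list(P1 = protein_record("P1", "MKT"))
  expect_error(ingest_scores(f, "iupred", 0.5, TRUE, records = recs),
               "length")
})

test_that("independent predictor files yield independent tracks", {
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tposition\tscore", "P1\t1\t0.1", "P1\t2\t0.2"), f1)
  writeLines(c("protein_id\tposition\tscore", "P1\t1\t0.8", "P1\t2\t0.9"), f2)
  a <- ingest_scores(f1, "iupred", 0.5, TRUE)
  b <- ingest_scores(f2, "disopred2", 0.5, TRUE)
  expect_equal(a$P1$predictor, "iupred")
  expect_equal(b$P1$predictor, "disopred2")
  expect_false(identical(a$P1$scores, b$P1$scores))
})

test_that("consensus averages normalized tracks and stays in [0,1]", {
  t1 <- score_track("P1", "a", c(0.2, 0.4, 0.9), 0.5, TRUE)
  t2 <- score_track("P1", "b", c(0.8, 0.4, 0.1), 0.5, TRUE)
  cons <- consensus_track(list(t1, t2))
  expect_equal(cons$scores, c(0.5, 0.4, 0.5))
  expect_equal(cons$predictor, "consensus")
  expect_equal(cons$threshold, 0.5)

  # idempotence: consensus of k copies equals the track
  expect_equal(consensus_track(list(t1, t1, t1))$scores, t1$scores)
  # single lower-is-disordered input equals its normalization
  fi <- foldindex_score("MKTAYEEDDSSPPAEKR", 5)
  expect_equal(consensus_track(list(fi))$scores,
               normalize_track(fi)$scores)
  # the logistic transform preserves the decision boundary, in both
  # orientations of a raw-scale track
  expect_equal(normalize_track(score_track("P", "fi", 0, 0, FALSE))$scores,
               0.5)
  expect_equal(normalize_track(score_track("P", "ti", 0, 0, TRUE))$scores,
               0.5)
  ti <- normalize_track(topidp_score("MKEEPSDQRAAVLI", 5))
  expect_true(all(ti$scores >= 0 & ti$scores <= 1))
  expect_error(consensus_track(list(t1, score_track("P1", "c", 0.5, 0.5,
                                                    TRUE))),
               "lengths")
  expect_error(consensus_track(list(score_track("P1", "c", 1.7, 0.5, TRUE))),
               "\\[0,1\\]")
})

test_that("consensus of random track sets is bounded in [0,1]", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(20:60, 1)
    tracks <- c(
      lapply(1:2, function(i)
        score_track("P", paste0("t", i), runif(n), 0.5, TRUE)),
      list(foldindex_score(random_sequence(n), 9)))
    cons <- consensus_track(tracks)
    expect_true(all(cons$scores >= 0 & cons$scores <= 1))
    expect_length(cons$scores, n)
  }
})
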