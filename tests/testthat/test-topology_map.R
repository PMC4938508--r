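test_that("build_topology assembles annotated segments and infers by alternation", {
  m <- build_topology(single_pass_record())
  expect_equal(m$segments$side, c("Cytoplasmic", "TM", "Extracellular"))
  expect_equal(m$segments$start, c(1L, 10L, 31L))
  expect_equal(m$segments$end, c(9L, 30L, 60L))

  # only the N-tail annotated: C-side inferred by alternation
  r <- protein_record("P1", strrep("A", 60), data.frame(
    kind = c("TRANSMEM", "TOPO_DOM"), start = c(10L, 1L), end = c(30L, 9L),
    label = c("", "Cytoplasmic")))
  m2 <- build_topology(r)
  expect_equal(m2$segments$side, c("Cytoplasmic", "TM", "Extracellular"))

  # propagation crosses several TM segments
  r3 <- protein_record("P2", strrep("A", 100), data.frame(
    kind = c("TRANSMEM", "TRANSMEM", "TOPO_DOM"),
    start = c(20L, 60L, 1L), end = c(40L, 80L, 19L),
    label = c("", "", "Extracellular")))
  m3 <- build_topology(r3)
  expect_equal(m3$segments$side,
               c("Extracellular", "TM", "Cytoplasmic", "TM", "Extracellular"))
})

test_that("build_topology rejects inconsistent annotations", {
  same <- protein_record("P1", strrep("A", 60), data.frame(
    kind = c("TRANSMEM", "TOPO_DOM", "TOPO_DOM"),
    start = c(10L, 1L, 31L), end = c(30L, 9L, 60L),
    label = c("", "Cytoplasmic", "Cytoplasmic")))
  expect_error(build_topology(same), "alternation")

  overlap <- protein_record("P1", strrep("A", 60), data.frame(
    kind = c("TRANSMEM", "TOPO_DOM"), start = c(10L, 5L), end = c(30L, 15L),
    label = c("", "Cytoplasmic")))
  expect_error(build_topology(overlap), "overlaps a TRANSMEM")
})

test_that("unannotated records yield Unknown segments and total coverage", {
  r <- protein_record("P1", strrep("A", 50),
                      data.frame(kind = "TRANSMEM", start = 20L, end = 40L,
                                 label = ""))
  m <- build_topology(r)
  expect_equal(m$segments$side, c("Unknown", "TM", "Unknown"))
  expect_length(residue_sides(m), 50L)
})

test_that("model segments always partition [1, L] on generated proteomes", {
  sim <- generate_proteome(sim_spec(n_proteins = 40, seed = 17))
  for (id in names(sim$records)) {
    m <- build_topology(sim$records[[id]])
    s <- m$segments
    expect_equal(s$start[1L], 1L)
    expect_equal(s$end[nrow(s)], seq_length(sim$records[[id]]))
    if (nrow(s) > 1L) expect_equal(s$start[-1L], s$end[-nrow(s)] + 1L)
    expect_true(all(s$side %in% c("Cytoplasmic", "Extracellular", "TM")))
  }
})

test_that("localize takes the strict majority of non-TM residues", {
  m <- build_topology(single_pass_record())
  full <- localize(m, 1, 9)
  expect_equal(full$side, "Cytoplasmic")
  expect_equal(full$overlap_fraction, 1.0)

  # 25 cytoplasmic / 10 TM / 5 extracellular residues -> Cytoplasmic
  r <- protein_record("P1", strrep("A", 60), data.frame(
    kind = c("TRANSMEM", "TOPO_DOM", "TOPO_DOM"),
    start = c(26L, 1L, 36L), end = c(35L, 25L, 60L),
    label = c("", "Cytoplasmic", "Extracellular")))
  lr <- localize(build_topology(r), 1, 40)
  expect_equal(lr$side, "Cytoplasmic")
  expect_equal(lr$n_cyto, 25L)
  expect_equal(lr$n_extra, 5L)
  expect_equal(lr$overlap_fraction, 25 / 40)

  # exact tie -> Ambiguous; zero non-TM overlap -> Ambiguous
  tie <- localize(build_topology(r), 21, 40)  # 5 cyto, 10 TM, 5 extra
  expect_equal(tie$side, "Ambiguous")
  tm_only <- localize(build_topology(r), 27, 34)
  expect_equal(tm_only$side, "Ambiguous")
})

test_that("undeterminable multi-pass proteins are removed, others kept", {
  mk_multi <- function(id, loop_len) {
    L <- 2L * 21L + 3L * loop_len
    tm1 <- loop_len + 1L
    tm2 <- 2L * loop_len + 21L + 1L
    protein_record(id, strrep("A", L), data.frame(
      kind = c("TRANSMEM", "TRANSMEM"), start = c(tm1, tm2),
      end = c(tm1 + 20L, tm2 + 20L), label = ""))
  }
  short <- mk_multi("M1", 29L)
  long <- mk_multi("M2", 40L)
  sp <- protein_record("S1", strrep("A", 40),
                       data.frame(kind = "TRANSMEM", start = 11L, end = 30L,
                                  label = ""))  # 10-residue tail only
  recs <- list(M1 = short, M2 = long, S1 = sp)
  models <- lapply(recs, build_topology)
  out <- filter_undeterminable(recs, models, 30L)
  expect_equal(out$excluded_ids, "M1")
  expect_setequal(names(out$retained), c("M2", "S1"))
})

test_that("side statistics reproduce two-way percentages per pass type", {
  # 669 cytoplasmic of 826 sided multi-pass assignments -> 81%
  asg <- data.frame(protein_id = "M1",
                    side = c(rep("Cytoplasmic", 669),
                             rep("Extracellular", 157), "Ambiguous"))
  pt <- c(M1 = "multi-pass")
  s <- side_statistics(asg, pt)
  row <- s[s$pass_type == "multi-pass", ]
  expect_equal(row$pct_cyto, 81)
  expect_equal(row$n_ambiguous, 1L)
  expect_equal(row$pct_cyto + row$pct_extra, 100)

  all_c <- side_statistics(data.frame(protein_id = "M1",
                                      side = rep("Cytoplasmic", 3)), pt)
  expect_equal(all_c$pct_cyto[1L], 100)
  half <- side_statistics(data.frame(protein_id = "M1",
                                     side = c("Cytoplasmic",
                                              "Extracellular")), pt)
  expect_equal(half$pct_cyto[1L], 50)
})

test_that("occupancy is the per-side IDR residue fraction and conserves", {
  m <- build_topology(single_pass_record())  # 9 cyto, 21 TM, 30 extra
  idrs <- data.frame(protein_id = "SP1", start = 1L, end = 9L)
  occ <- occupancy(m, idrs)
  expect_equal(occ$occupancy_pct[occ$side == "Cytoplasmic"], 100)
  expect_equal(occ$occupancy_pct[occ$side == "Extracellular"], 0)

  # 61 of 100 cytoplasmic residues disordered -> 61.0
  r <- protein_record("P1", strrep("A", 140), data.frame(
    kind = c("TOPO_DOM", "TRANSMEM", "TOPO_DOM"),
    start = c(1L, 101L, 122L), end = c(100L, 121L, 140L),
    label = c("Cytoplasmic", "", "Extracellular")))
  occ2 <- occupancy(build_topology(r),
                    data.frame(protein_id = "P1", start = 20L, end = 80L))
  expect_equal(occ2$occupancy_pct[occ2$side == "Cytoplasmic"], 61)

  expect_equal(occupancy(m, idrs[0, ])$occupancy_pct, c(0, 0))

  # conservation: occupancy + outside-IDR fraction = 100 per side
  sim <- generate_proteome(sim_spec(n_proteins = 20, seed = 23))
  models <- lapply(sim$records, build_topology)
  tracks <- lapply(sim$records, foldindex_score, window = 21)
  idr_all <- idr_table(tracks)
  for (id in names(models)[1:10]) {
    o <- occupancy(models[[id]], idr_all)
    for (k in seq_len(nrow(o))) {
      outside <- 100 * (o$n_side[k] - o$n_idr[k]) / o$n_side[k]
      expect_equal(o$occupancy_pct[k] + outside, 100)
    }
  }
})

test_that("length statistics match an independent group-by recount", {
  asg <- data.frame(protein_id = "P1", side = "Cytoplasmic",
                    length = c(30L, 40L, 50L))
  ls <- length_statistics(asg, c(P1 = "single-pass"))
  expect_equal(ls$median, 40)
  one <- length_statistics(data.frame(protein_id = "P1",
                                      side = "Extracellular", length = 77L),
                           c(P1 = "single-pass"))
  expect_equal(one$median, 77)

  set.seed(31)
  asg <- data.frame(
    protein_id = sample(c("A", "B", "C"), 60, TRUE),
    side = sample(c("Cytoplasmic", "Extracellular", "Ambiguous"), 60, TRUE),
    length = sample(30:200, 60, TRUE))
  pt <- c(A = "single-pass", B = "multi-pass", C = "multi-pass")
  got <- length_statistics(asg, pt)
  for (k in seq_len(nrow(got))) {
    sub <- asg[asg$side == got$side[k] &
                 pt[asg$protein_id] == got$pass_type[k], "length"]
    expect_equal(got$n[k], length(sub))
    expect_equal(got$mean[k], mean(sub))
    expect_equal(got$median[k], median(sub))
  }
  expect_false(any(got$side == "Ambiguous"))
})
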