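test_that("composition pools residues and excludes non-standard letters", {
  v <- composition("AAAA")
  expect_equal(unname(v[["A"]]), 100)
  expect_equal(sum(v), 100)
  ac <- composition("AC")
  expect_equal(unname(ac[c("A", "C")]), c(50, 50))
  # pooling identity
  expect_equal(composition(c("AAC", "CGG")), composition("AACCGG"))
  # X excluded from numerator and denominator
  expect_equal(composition("AAXX"), composition("AA"))
  expect_error(composition("XXXX"), "no standard residues")

  set.seed(3)
  for (rep in 1:5) {
    v <- composition(random_sequence(sample(50:500, 1)))
    expect_equal(sum(v), 100, tolerance = 1e-6)
    expect_true(all(v >= 0))
  }
})

test_that("interval_residues splits inside/outside subsets", {
  recs <- list(P1 = protein_record("P1", "AAAACCCCGG"))
  iv <- data.frame(protein_id = "P1", start = 5L, end = 8L)
  expect_equal(unname(interval_residues(recs, iv, inside = TRUE)), "CCCC")
  expect_equal(unname(interval_residues(recs, iv, inside = FALSE)), "AAAAGG")
})

test_that("enrichment follows the positive-is-overrepresented convention", {
  bg <- composition(strrep("ACDE", 25))
  expect_equal(max(abs(enrichment(bg, bg))), 0)

  # subset at 1.66x background reads +66
  sub <- bg
  sub[["P"]] <- 0  # placeholder; build numerically instead
  sub <- bg * 0
  sub[c("A", "C", "D", "E")] <- c(41.5, 25, 25, 8.5)
  e <- enrichment(sub, bg)
  expect_equal(unname(e[["A"]]), 66)
  expect_equal(unname(e[["E"]]), -66)
  # absent residue in subset: -100
  expect_equal(unname(e[["C"]]), 0)
  sub2 <- bg * 0
  sub2[c("A", "C", "D")] <- c(50, 25, 25)
  expect_equal(unname(enrichment(sub2, bg)[["E"]]), -100)

  # zero-background residues are omitted and flagged, not zeroed
  om <- enrichment(sub, bg)
  expect_setequal(attr(om, "omitted"),
                  setdiff(names(bg), c("A", "C", "D", "E")))
  expect_false("P" %in% names(om))

  # the printed convention is the exact negation
  expect_equal(unname(enrichment(sub, bg, convention = "printed")),
               -unname(enrichment(sub, bg)))
})

test_that("PTM site loading validates positions, residues and chemistry", {
  recs <- list(P1 = protein_record("P1", "MSTYKAASTY"))
  f <- withr::local_tempfile(fileext = ".tsv")
  hdr <- "protein_id\tposition\tresidue\tmod_type"
  writeLines(c(hdr, "P1\t2\tS\tphospho", "P1\t5\tK\tubiquitin"), f)
  tab <- read_ptm_sites(f, recs)
  expect_equal(nrow(tab), 2L)

  writeLines(c(hdr, "P1\t2\tT\tphospho"), f)
  expect_error(read_ptm_sites(f, recs), "mismatch")
  writeLines(c(hdr, "P1\t99\tS\tphospho"), f)
  expect_error(read_ptm_sites(f, recs), "out of range")
  writeLines(c(hdr, "P1\t6\tA\tphospho"), f)
  expect_warning(strict <- read_ptm_sites(f, recs), "non-S/T/Y")
  expect_equal(nrow(strict), 0L)
  expect_warning(lax <- read_ptm_sites(f, recs, strict = FALSE), "non-S/T/Y")
  expect_equal(nrow(lax), 1L)
})

test_that("ptm_stats computes density, IDR co-localization and conservation", {
  seqs <- paste(rep("ASTYK", 20), collapse = "")  # 100 residues
  recs <- list(P1 = protein_record("P1", seqs),
               P2 = protein_record("P2", seqs))
  labels <- c(P1 = "IDP", P2 = "FOP")
  idrs <- data.frame(protein_id = "P1", start = 10L, end = 50L)
  sites <- data.frame(protein_id = "P1",
                      position = c(2L, 7L, 12L, 22L, 60L),
                      residue = "S", mod_type = "phospho")
  st <- ptm_stats(sites, recs, idrs, labels)
  idp <- st$by_class[st$by_class$class == "IDP" &
                       st$by_class$mod_type == "phospho", ]
  expect_equal(idp$mean_pct_residues_modified, 5)
  expect_equal(idp$pct_with_site, 100)
  expect_equal(idp$n_sites_in_idr + (idp$n_sites - idp$n_sites_in_idr),
               idp$n_sites)
  expect_equal(idp$pct_sites_in_idr, 40)  # positions 12 and 22 of 5
  fop <- st$by_class[st$by_class$class == "FOP" &
                       st$by_class$mod_type == "phospho", ]
  expect_equal(fop$mean_sites_per_protein, 0)
  expect_equal(fop$pct_with_site, 0)
  # S/T/Y breakdown of in-IDR phospho sites
  expect_equal(st$sty_breakdown_in_idr$pct[
    st$sty_breakdown_in_idr$residue == "S"], 100)

  # the two-site / one-IDR textbook case: 50% inside
  sites2 <- data.frame(protein_id = "P1", position = c(20L, 60L),
                       residue = c("T", "A"), mod_type = "ubiquitin")
  sites2$residue <- substring(seqs, sites2$position, sites2$position)
  st2 <- ptm_stats(sites2, recs, idrs, labels)
  ub <- st2$by_class[st2$by_class$class == "IDP" &
                       st2$by_class$mod_type == "ubiquitin", ]
  expect_equal(ub$pct_sites_in_idr, 50)

  empty <- ptm_stats(sites[0, ], recs, idrs, labels)
  expect_true(all(empty$by_class$pct_with_site == 0))
  expect_true(all(empty$by_class$mean_sites_per_protein == 0))
})

test_that("partner counts collapse direction, duplicates and self-loops", {
  e <- data.frame(bait_id = c("A", "B"), prey_id = c("B", "A"))
  expect_equal(unname(partner_counts(e, c("A", "B"))), c(1L, 1L))
  self <- data.frame(bait_id = "A", prey_id = "A")
  expect_equal(unname(partner_counts(self, "A")), 0L)

  # star graph: hub degree 5, spokes 1; matches the brute-force recount
  star <- data.frame(bait_id = "H", prey_id = paste0("S", 1:5))
  ids <- c("H", paste0("S", 1:5))
  got <- partner_counts(star, ids)
  for (id in ids) expect_equal(unname(got[id]), oracle_partner_count(star, id))

  labels <- setNames(c("IDP", rep("FOP", 5)), ids)
  ds <- degree_stats(star, labels)
  expect_equal(ds$mean_partners[ds$class == "IDP"], 5)
  expect_equal(ds$mean_partners[ds$class == "FOP"], 1)
})

test_that("degree statistics ignore edge duplication and reversal", {
  set.seed(11)
  ids <- paste0("P", 1:30)
  e <- data.frame(bait_id = sample(ids, 80, TRUE),
                  prey_id = sample(ids, 80, TRUE))
  labels <- setNames(sample(c("IDP", "FOP"), 30, TRUE), ids)
  base <- degree_stats(e, labels)
  dup <- rbind(e, e, data.frame(bait_id = e$prey_id, prey_id = e$bait_id))
  expect_equal(degree_stats(dup, labels), base)
  # recount against the naive oracle
  got <- partner_counts(e, ids)
  for (id in ids) expect_equal(unname(got[id]), oracle_partner_count(e, id))
})
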