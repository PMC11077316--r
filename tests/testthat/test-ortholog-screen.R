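# Orthogroup construction, loss filtering, confirmation screening, and the
# HRA presence/absence matrix.

mk_mbh <- function(sa, ga, sb, gb, score = 500) data.frame(
  species_a = sa, gene_a = ga, species_b = sb, gene_b = gb, score = score,
  stringsAsFactors = FALSE)

test_that("orthogroups are complete MBH cliques; open triangles are rejected", {
  wbr <- c("s1", "s2", "s3")
  closed <- list(
    "s1|s2" = mk_mbh("s1", "a", "s2", "b"),
    "s1|s3" = mk_mbh("s1", "a", "s3", "c"),
    "s2|s3" = mk_mbh("s2", "b", "s3", "c"))
  g <- build_wbr_orthogroups(closed, wbr)
  expect_equal(length(unique(g$group_id)), 1)
  expect_setequal(g$gene_id, c("a", "b", "c"))
  # drop the s2-s3 edge: a-b and a-c alone must not form a group
  open <- closed
  open[["s2|s3"]] <- mk_mbh(character(), character(), character(),
                            character(), numeric())
  expect_equal(nrow(build_wbr_orthogroups(open, wbr)), 0)
  # missing pair list errors
  expect_error(build_wbr_orthogroups(closed[1:2], wbr), "missing MBH")
  # connected-components alternative accepts the same clean clique
  g2 <- build_wbr_orthogroups(closed, wbr, grouping = "components")
  expect_setequal(g2$gene_id, c("a", "b", "c"))
})

test_that("loss filter removes any group with a sub-threshold hit", {
  groups <- data.frame(group_id = c("OG1", "OG1", "OG2", "OG2"),
                       species_id = c("s1", "s2", "s1", "s2"),
                       gene_id = c("a", "b", "c", "d"),
                       stringsAsFactors = FALSE)
  attr(groups, "anchor_species") <- "s1"
  cfg <- screen_config(wbr = c("s1", "s2"), lra = "l1")
  hit <- data.frame(query_species = "s1", query_gene = "a",
                    subject_species = "l1", subject_gene = "x",
                    score = 120, evalue = 1e-5, stringsAsFactors = FALSE)
  out <- filter_lost_in_lra(groups, hit, cfg)
  expect_setequal(unique(out$group_id), "OG2")
  expect_identical(attr(out, "removed"), "OG1")
  # a hit above the threshold does not remove
  weak <- transform(hit, evalue = 2e-4)
  out2 <- filter_lost_in_lra(groups, weak, cfg)
  expect_equal(length(unique(out2$group_id)), 2)
  # no hits at all: everything survives
  out3 <- filter_lost_in_lra(groups, list(), cfg)
  expect_equal(nrow(out3), nrow(groups))
})

test_that("confirmation screen removes at the threshold boundary and audits", {
  # calibrate K so that the known self-alignment score of 62 lands exactly at
  # E = 9e-5 (just under the 1e-4 cutoff), per the closed form E = K m n e^(-lambda S)
  seqs <- c(gA = "HEAGAWGHEE")
  lambda <- 0.267
  K <- 9e-5 * exp(lambda * 62) / (10 * 10)
  s <- scoring_scheme(K = K, lambda = lambda)
  member <- toy_proteome("s1", "WBR", seqs)
  confirm <- toy_proteome("c1", "CONFIRM", c(cX = "HEAGAWGHEE"))
  groups <- data.frame(group_id = "OG1", species_id = "s1", gene_id = "gA",
                       stringsAsFactors = FALSE)
  cfg <- screen_config(wbr = "s1", confirm = "c1")
  out <- confirm_absence(groups, list(c1 = confirm), cfg,
                         list(s1 = member), s)
  expect_equal(nrow(out), 0)
  audit <- attr(out, "audit")
  expect_equal(nrow(audit), 1)
  expect_equal(audit$evalue, 9e-5, tolerance = 1e-10)
  expect_identical(audit$subject_gene, "cX")
  # an unrelated confirmation panel keeps the group and logs nothing
  other <- toy_proteome("c1", "CONFIRM", c(cY = "PPPPPPPPPP"))
  out2 <- confirm_absence(groups, list(c1 = other), cfg, list(s1 = member), s)
  expect_equal(nrow(out2), 1)
  expect_equal(nrow(attr(out2, "audit")), 0)
  # empty panel: warning, groups pass through
  expect_warning(out3 <- confirm_absence(groups, list(), cfg,
                                         list(s1 = member), s), "empty")
  expect_equal(nrow(out3), 1)
})

test_that("HRA presence requires a mutual best hit scoring strictly over 100", {
  # self-alignments give exact raw scores: 25 alanines score 100 (4 each),
  # 24 alanines + 1 glutamate score 101
  s <- scoring_scheme()
  seq100 <- strrep("A", 25)
  seq101 <- paste0(strrep("A", 24), "E")
  anchor <- toy_proteome("w1", "WBR", c(f1 = seq101, f2 = seq100))
  hra <- toy_proteome("h1", "HRA", c(f1 = seq101, f2 = seq100))
  groups <- data.frame(group_id = c("OG1", "OG2"), species_id = "w1",
                       gene_id = c("f1", "f2"), stringsAsFactors = FALSE)
  cfg <- screen_config(wbr = "w1", hra = "h1", lra = character())
  pa <- collect_hra_orthologs(groups, anchor, list(h1 = hra), cfg, s)
  expect_identical(pa["OG1", "h1"], 1L)  # score 101 > 100: present
  expect_identical(pa["OG2", "h1"], 0L)  # score 100 is not strictly greater
  expect_identical(unname(pa[, "w1"]), c(1L, 1L))
  # species with no hit at all stays absent
  empty_hra <- toy_proteome("h1", "HRA", c(zz = strrep("P", 30)))
  pa2 <- collect_hra_orthologs(groups, anchor, list(h1 = empty_hra), cfg, s)
  expect_true(all(pa2[, "h1"] == 0L))
})

test_that("loosening the loss threshold never increases survivors", {
  sim <- small_scenario()
  red <- lapply(sim$proteomes, select_longest_isoform)
  wbr <- paste0("wbr", 1:3)
  mbh <- pairwise_mbh(red[wbr], scoring_scheme(), 1e-4)
  groups <- build_wbr_orthogroups(mbh, wbr)
  survivors <- vapply(c(1e-8, 1e-4, 1e-2), function(e) {
    cfg <- screen_config(wbr = wbr, lra = paste0("lra", 1:2),
                         evalue_max_loss = e)
    hits <- scan_panel_hits(groups, red[wbr], red[cfg$lra],
                            scoring_scheme(), e)
    length(unique(filter_lost_in_lra(groups, hits, cfg)$group_id))
  }, numeric(1))
  expect_true(all(diff(survivors) <= 0))
})

test_that("the screen recovers exactly the planted families on the fixture", {
  sim <- small_scenario()
  res <- small_screen()
  truth <- sim$truth
  # first pass: every family present in all three WBR species forms a group
  expect_equal(length(unique(res$orthogroups$group_id)),
               30 + 4 + 3) # background + planted + paralog families
  recovered <- sort(unique(res$candidates$gene_id[
    res$candidates$species_id == "wbr1"]))
  expect_identical(recovered, sort(truth$cbr_family_ids))
  # paralog families were removed by the LRA loss filter, not the clique step
  expect_true(all(truth$paralog_family_ids %in% res$orthogroups$gene_id))
  expect_false(any(truth$paralog_family_ids %in% res$candidates$gene_id))
  # presence/absence matrix: invariant plus exact HRA planting pattern
  expect_silent(validate_pa_matrix(res$pa_matrix))
  for (fam in truth$cbr_family_ids) {
    gid <- unique(res$candidates$group_id[res$candidates$gene_id == fam])
    for (hsp in paste0("hra", 1:2)) {
      expect_identical(res$pa_matrix[gid, hsp] == 1L,
                       hsp %in% truth$hra_presence[[fam]])
    }
  }
})

test_that("screen_config rejects overlapping or invalid settings", {
  expect_error(screen_config(wbr = c("a", "b"), lra = c("b")), "disjoint")
  expect_error(screen_config(wbr = character()), "at least one")
  expect_error(screen_config(wbr = "a", evalue_max_loss = -1), "positive")
  expect_error(screen_config(wbr = "a", score_min_hra = 0), "positive")
})
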