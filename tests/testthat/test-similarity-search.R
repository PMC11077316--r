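# Longest-isoform selection, Smith-Waterman scoring against independent
# oracles, E-values, all-vs-all search and mutual-best-hit calling.

test_that("longest-isoform selection keeps a maximal isoform with ties by id", {
  p <- proteome("sp1", "WBR", list(
    g1 = c(b = strrep("A", 150), c = strrep("C", 100), a = strrep("D", 150)),
    g2 = c(t1 = "MKV")))
  r <- select_longest_isoform(p)
  expect_identical(names(p$genes$g1)[match(r$genes$g1, p$genes$g1)], "a")
  expect_identical(unname(r$genes$g2), "MKV")
  expect_true(is_reduced(r))
  # empty proteome passes through; zero-isoform gene errors
  expect_length(select_longest_isoform(proteome("e", "LRA", list()))$genes, 0)
  bad <- proteome("sp2", "WBR", list(g1 = c(t1 = "MKV")))
  bad$genes$g1 <- character()
  expect_error(select_longest_isoform(bad), "zero isoforms")
})

test_that("local alignment matches the worked self-score and conventions", {
  s <- scoring_scheme()
  expect_identical(local_align_score("HEAGAWGHEE", "HEAGAWGHEE", s), 62L)
  expect_identical(local_align_score("ANYSEQ", "", s), 0L)
  expect_identical(local_align_score("", "", s), 0L)
})

test_that("kernel agrees exactly with a naive DP oracle and is symmetric", {
  s <- scoring_scheme()
  set.seed(42)
  for (i in 1:50) {
    a <- random_peptides(1, 30)
    b <- random_peptides(1, 30)
    sc <- local_align_score(a, b, s)
    expect_identical(sc, as.integer(sw_oracle(a, b, s)))
    expect_identical(sc, local_align_score(b, a, s))
  }
})

test_that("kernel agrees with an established aligner on random pairs", {
  # second, fully independent route: Biostrings local pairwiseAlignment
  s <- scoring_scheme()
  b62 <- s$matrix[1:20, 1:20]
  set.seed(7)
  for (i in 1:25) {
    a <- random_peptides(1, 40, min_len = 5)
    b <- random_peptides(1, 40, min_len = 5)
    ref <- Biostrings::pairwiseAlignment(
      a, b, type = "local", substitutionMatrix = b62,
      gapOpening = s$gap_open, gapExtension = s$gap_extend,
      scoreOnly = TRUE)
    expect_equal(local_align_score(a, b, s), max(0, ref))
  }
})

test_that("E-values follow the closed form and its scaling laws", {
  s <- scoring_scheme(K = 0.041, lambda = 0.267)
  expect_equal(estimate_evalue(0, 100, 100, s), 410)
  expect_equal(estimate_evalue(50, 100, 200, s),
               2 * estimate_evalue(50, 100, 100, s))
  expect_lt(estimate_evalue(200, 100, 100, s), 1e-4)
  ev <- estimate_evalue(0:300, 50, 1000, s)
  expect_true(all(diff(ev) < 0))
  expect_error(estimate_evalue(10, 0, 100, s), ">= 1")
})

test_that("all-vs-all reports reciprocal hits and honors the cutoff", {
  a <- toy_proteome("spA", "WBR", c(g1 = "HEAGAWGHEEHEAGAWGHEEHEAGAWGHEE"))
  b <- toy_proteome("spB", "WBR", c(h1 = "HEAGAWGHEEHEAGAWGHEEHEAGAWGHEE"))
  s <- scoring_scheme()
  hab <- all_vs_all(a, b, s, evalue_max = 1)
  hba <- all_vs_all(b, a, s, evalue_max = 1)
  expect_equal(nrow(hab), 1)
  expect_equal(nrow(hba), 1)
  expect_identical(hab$score, hba$score)
  expect_equal(nrow(all_vs_all(a, b, s, evalue_max = 0)), 0)
  multi <- proteome("spC", "WBR", list(g1 = c(t1 = "MKV", t2 = "MKVL")))
  expect_error(all_vs_all(multi, b, s), "reduced")
})

test_that("shrinking the E-value cutoff never adds hits", {
  set.seed(9)
  a <- toy_proteome("spA", "WBR", setNames(random_peptides(6, 60, 40),
                                           paste0("a", 1:6)))
  b <- toy_proteome("spB", "WBR", setNames(random_peptides(6, 60, 40),
                                           paste0("b", 1:6)))
  s <- scoring_scheme()
  cuts <- c(10, 1, 1e-2, 1e-4)
  counts <- vapply(cuts, function(e) nrow(all_vs_all(a, b, s, e)), numeric(1))
  expect_true(all(diff(counts) <= 0))
  keys <- lapply(cuts, function(e) {
    h <- all_vs_all(a, b, s, e)
    paste(h$query_gene, h$subject_gene)
  })
  for (i in 2:length(keys)) expect_true(all(keys[[i]] %in% keys[[i - 1]]))
})

test_that("mutual best hits require reciprocity and are symmetric", {
  mk <- function(qs, qg, ss, sg, sc) data.frame(
    query_species = qs, query_gene = qg, subject_species = ss,
    subject_gene = sg, score = sc, evalue = 1e-10,
    stringsAsFactors = FALSE)
  # one gene per species, hits both ways -> one pair
  ab <- mk("A", "a1", "B", "b1", 100)
  ba <- mk("B", "b1", "A", "a1", 100)
  expect_equal(nrow(mutual_best_hits(ab, ba)), 1)
  # a1's best is b1 but b1's best is a2 -> no pair for a1
  ab2 <- rbind(mk("A", "a1", "B", "b1", 100), mk("A", "a2", "B", "b1", 90))
  ba2 <- mk("B", "b1", "A", "a2", 100)
  m <- mutual_best_hits(ab2, ba2)
  expect_false("a1" %in% m$gene_a)
  # symmetry: swapping the argument order mirrors the pairs
  m1 <- mutual_best_hits(ab2, ba2)
  m2 <- mutual_best_hits(ba2, ab2)
  expect_setequal(paste(m1$gene_a, m1$gene_b), paste(m2$gene_b, m2$gene_a))
})

test_that("within the fixture, cross-species hits reflect family structure", {
  sim <- small_scenario()
  s <- scoring_scheme()
  red <- lapply(sim$proteomes[c("wbr1", "wbr2")], select_longest_isoform)
  fam <- sim$truth$cbr_family_ids[1]
  q <- proteome_sequences(red$wbr1)[fam]
  ss <- proteome_sequences(red$wbr2)
  ev <- estimate_evalue(
    regenscreen:::.sw_score_matrix_cpp(unname(q), unname(ss), s$matrix,
                                       s$gap_open, s$gap_extend)[1, ],
    nchar(q), sum(nchar(ss)), s)
  names(ev) <- names(ss)
  expect_lt(ev[[fam]], 1e-4)          # planted ortholog pair is found
  expect_equal(sum(ev <= 1e-4), 1)    # and nothing else crosses the screen
  # the diverged paralog copy still hits its WBR family member, but scores
  # below every ortholog pair (basis of the loss filter test downstream)
  pfam <- sim$truth$paralog_family_ids[1]
  lsp <- sim$truth$paralog_lra_species[[pfam]]
  lred <- select_longest_isoform(sim$proteomes[[lsp]])
  pscore <- local_align_score(proteome_sequences(red$wbr1)[[pfam]],
                              proteome_sequences(lred)[[pfam]], s)
  pev <- estimate_evalue(pscore, nchar(proteome_sequences(red$wbr1)[[pfam]]),
                         sum(nchar(proteome_sequences(lred))), s)
  expect_lt(pev, 1e-4)
  expect_lt(pscore, sim$truth$separation[["min_cbr_wbr_score"]])
})

test_that("MBH pairs on the fixture equal family co-membership", {
  sim <- small_scenario()
  red <- lapply(sim$proteomes[c("wbr1", "wbr2")], select_longest_isoform)
  mbh <- pairwise_mbh(red, scoring_scheme(), 1e-4)[["wbr1|wbr2"]]
  shared <- intersect(names(red$wbr1$genes), names(red$wbr2$genes))
  expect_setequal(mbh$gene_a, shared)
  expect_identical(mbh$gene_a, mbh$gene_b) # orthologs share family ids
})

test_that("hits survive a BLAST-tabular round trip", {
  set.seed(2)
  a <- toy_proteome("spA", "WBR", setNames(random_peptides(3, 50, 40),
                                           paste0("a", 1:3)))
  b <- toy_proteome("spB", "LRA", setNames(random_peptides(3, 50, 40),
                                           paste0("b", 1:3)))
  h <- all_vs_all(a, b, scoring_scheme(), evalue_max = 10)
  path <- tempfile(fileext = ".tsv")
  write_hits_tsv(h, path)
  h2 <- read_hits_tsv(path)
  expect_equal(h2[, c("query_gene", "subject_gene", "score")],
               h[, c("query_gene", "subject_gene", "score")],
               ignore_attr = TRUE)
  expect_equal(h2$evalue, h$evalue, tolerance = 1e-6)
})
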