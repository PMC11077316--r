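# JASPAR parsing, upstream extraction, PWM scanning, Fisher enrichment and
# the class tally.

test_that("JASPAR records parse exactly and survive a round trip", {
  pwms <- fixture_pwms()
  expect_length(pwms, 24)
  expect_identical(pwms[[1]]$matrix_id, "SYN0001.1")
  expect_identical(pwms[[1]]$tf_class, "Homeo domain factors")
  expect_true(all(vapply(pwms, function(p) ncol(p$counts) >= 5, logical(1))))
  # round trip preserves exact integer counts
  tmp <- tempfile(fileext = ".jaspar")
  write_jaspar(pwms[1:5], tmp)
  back <- read_jaspar(tmp)
  for (i in 1:5) expect_identical(back[[i]]$counts, pwms[[i]]$counts)
  # missing class annotation maps to Unclassified
  expect_identical(back[[1]]$tf_class, "Unclassified")
  # one-column record
  one <- tempfile()
  writeLines(c(">M1 ONE", "A [ 10 ]", "C [ 0 ]", "G [ 0 ]", "T [ 0 ]"), one)
  p1 <- read_jaspar(one)[[1]]
  expect_identical(dim(p1$counts), c(4L, 1L))
  # malformed inputs
  noT <- tempfile()
  writeLines(c(">M2 X", "A [ 1 2 ]", "C [ 1 2 ]", "G [ 1 2 ]"), noT)
  expect_error(read_jaspar(noT), "missing row")
  ragged <- tempfile()
  writeLines(c(">M3 X", "A [ 1 2 ]", "C [ 1 ]", "G [ 1 2 ]", "T [ 1 2 ]"),
             ragged)
  expect_error(read_jaspar(ragged), "mismatch")
})

test_that("upstream extraction respects strand, TSS exclusion and edges", {
  genome <- c(chr1 = paste(rep(c("A", "C", "G", "T"), length.out = 200),
                           collapse = ""))
  ann <- data.frame(gene_id = c("gp", "gm", "gt"),
                    contig = "chr1",
                    tss = c(101, 1, 50),
                    strand = c("+", "-", "+"),
                    stringsAsFactors = FALSE)
  up <- extract_upstream(ann, genome, 100)
  expect_identical(up[["gp"]], unname(substr(genome, 1, 100)))
  expect_identical(up[["gm"]], as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(unname(substr(genome, 2, 101))))))
  expect_identical(up[["gt"]], unname(substr(genome, 1, 49)))
  expect_identical(unname(attr(up, "truncated")), c(FALSE, FALSE, TRUE))
  bad <- data.frame(gene_id = "g", contig = "chrX", tss = 10, strand = "+")
  expect_error(extract_upstream(bad, genome, 10), "missing contig")
  expect_error(extract_upstream(ann, genome, 0), "positive")
})

test_that("PWM scanning finds consensus sites on both strands", {
  pwms <- fixture_pwms()
  hd <- pwms[[1]] # sharp width-12 homeodomain matrix
  cons <- paste(rownames(hd$counts)[apply(hd$counts, 2, which.max)],
                collapse = "")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cons)))
  params <- scan_params(score_fraction_threshold = 1)
  seq <- paste0(strrep("G", 20), cons, strrep("G", 20), rc, strrep("G", 5))
  hits <- scan_sequence(hd, seq, params)
  expect_equal(hits$position, c(20, 52))
  expect_equal(hits$strand, c(1, -1))
  # sequence shorter than the matrix: empty result
  expect_equal(nrow(scan_sequence(hd, "ACGT", params)), 0)
  # palindromic matrix: every forward hit mirrored on the reverse strand
  pal <- pwm_record("PAL", "PAL", rbind(A = c(9, 0, 0, 9), C = c(0, 9, 0, 0),
                                        G = c(0, 0, 9, 0), T = c(9, 0, 0, 9)))
  # consensus ACGT whose reverse complement is ACGT
  ph <- scan_sequence(pal, "TTACGTTT", scan_params(score_fraction_threshold = 0.99))
  expect_setequal(ph$strand, c(1, -1))
  expect_equal(ph$score[ph$strand == 1], ph$score[ph$strand == -1])
  # planted promoters at rate 1: every target has a hit at default threshold
  prom <- simulate_promoters(sprintf("g%d", 1:12), sprintf("g%d", 1:12),
                             cons, 1, 1, length = 300, seed = 21)
  hit <- vapply(prom, function(s)
    nrow(scan_sequence(hd, s, scan_params())) > 0, logical(1))
  expect_true(all(hit))
})

test_that("enrichment records match the hypergeometric oracle and edge rules", {
  pwm <- fixture_pwms()[[1]]
  genes <- c(sprintf("t%02d", 1:10), sprintf("b%03d", 1:100))
  targets <- genes[1:10]
  background <- genes[-(1:10)]
  hits <- setNames(c(rep(TRUE, 9), FALSE, rep(TRUE, 10), rep(FALSE, 90)),
                   genes)
  r <- enrichment_test(targets, background, hits, pwm, 500)
  expect_equal(r$log2_enrichment, log2(0.9 / 0.1))
  expect_equal(r$p_value, fisher_oracle(9, 10, 10, 100), tolerance = 1e-12)
  # identical proportions: p = 1, enrichment 0
  even <- setNames(c(rep(TRUE, 5), rep(FALSE, 5),
                     rep(TRUE, 50), rep(FALSE, 50)), genes)
  r2 <- enrichment_test(targets, background, even, pwm)
  expect_equal(r2$log2_enrichment, 0)
  expect_equal(r2$p_value, 1)
  # all-zero table under the continuity rule
  none <- setNames(rep(FALSE, 110), genes)
  r3 <- enrichment_test(targets, background, none, pwm)
  expect_equal(r3$log2_enrichment, 0)
  expect_equal(r3$p_value, 1)
  expect_error(enrichment_test(character(), background, hits, pwm),
               "nonempty")
  expect_error(enrichment_test(targets, c(targets[1], background), hits, pwm),
               "disjoint")
})

test_that("top-class tallies count the planted class across windows", {
  # single-class records: the class's tally equals top_k in every window
  recs <- do.call(rbind, lapply(c(100, 500), function(w)
    data.frame(matrix_id = sprintf("M%d", 1:12), tf_class = "OnlyClass",
               window_length = w, n_target_hit = 5, n_target = 10,
               n_background_hit = 5, n_background = 100,
               p_value = runif(12), log2_enrichment = 1)))
  tal <- compile_top_classes(recs, top_k = 10)
  expect_true(all(tal["OnlyClass", ] == 10))
  # fewer records than top_k warns and uses all
  expect_warning(compile_top_classes(recs[recs$window_length == 100, ][1:3, ],
                                     top_k = 10), "only")
  # planted-motif scenario: the planted class surfaces in the tally at every
  # window length (small version of the enrichment acceptance check)
  pwms <- fixture_pwms()
  params <- scan_params(window_lengths = c(100, 500))
  recs2 <- simulate_tfbs_scenario(15, 100, "TAATTAGCTAAT", 0.8, 0.1,
                                  pwms, params, seed = 33)
  tal2 <- compile_top_classes(recs2, top_k = 10)
  expect_true(all(tal2["Homeo domain factors", ] > 0))
})
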