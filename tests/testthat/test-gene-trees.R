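# Progressive alignment, corrected distances, neighbor joining, bootstrap
# supports and the monophyly test.

test_that("progressive alignment handles identity, gaps and round-trips", {
  two <- progressive_align(c(x = "MKVLHE", y = "MKVLHE"))
  expect_identical(unname(unclass(two)), c("MKVLHE", "MKVLHE"))
  gap <- progressive_align(c(x = "ACDE", y = "ACE"))
  expect_identical(unname(unclass(gap)), c("ACDE", "AC-E"))
  one <- progressive_align(c(solo = "MKV"))
  expect_identical(unname(unclass(one)), "MKV")
  # ungapping any row reproduces its input, for random inputs
  set.seed(31)
  seqs <- setNames(random_peptides(6, 40, 15), paste0("t", 1:6))
  msa <- progressive_align(seqs)
  expect_identical(gsub("-", "", unclass(msa))[names(seqs)], seqs)
  expect_length(unique(nchar(msa)), 1)
})

test_that("distances: p-distance, correction cap, symmetry, degenerate pair", {
  msa <- structure(c(a = "AAAAAAAAAA", b = "AAAAAAAAAC"), class = "regen_msa")
  expect_equal(distance_matrix(msa, correct = FALSE)["a", "b"], 0.1)
  same <- structure(c(a = "MKV", b = "MKV"), class = "regen_msa")
  expect_equal(distance_matrix(same)["a", "b"], 0)
  set.seed(5)
  seqs <- setNames(random_peptides(5, 30, 20), paste0("t", 1:5))
  d <- distance_matrix(progressive_align(seqs))
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  # zero comparable columns: cap with a warning
  disjoint <- structure(c(a = "AA--", b = "--CC"), class = "regen_msa")
  expect_warning(dd <- distance_matrix(disjoint), "comparable")
  expect_equal(dd["a", "b"], 5)
})

test_that("neighbor joining recovers the additive four-taxon case exactly", {
  d <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- neighbor_joining(d)
  expect_true(is_separated_cluster(tr, c("A", "B")))
  expect_false(is_separated_cluster(tr, c("A", "C")))
  # branch lengths: recomputed leaf-to-leaf distances reproduce the input
  expect_equal(unname(ape::cophenetic.phylo(tr)[LETTERS[1:4], LETTERS[1:4]]),
               unname(d))
  tip_edge_len <- tr$edge.length[match(1:4, tr$edge[, 2])]
  expect_equal(tip_edge_len[match(LETTERS[1:4], tr$tip.label)], c(1, 2, 3, 4))
  # three taxa: closed-form lengths
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- neighbor_joining(d3)
  expect_equal(sort(t3$edge.length), c(1, 2, 3))
  expect_error(neighbor_joining(matrix(c(0, 1, 1, 0), 2, 2)), "3 taxa")
  ns <- matrix(runif(16), 4, 4)
  expect_error(neighbor_joining(ns), "symmetric")
})

test_that("neighbor joining is consistent on random additive matrices", {
  skip_if_not_installed("phangorn")
  set.seed(17)
  for (i in 1:10) {
    n <- sample(5:8, 1)
    ref <- ape::rtree(n, br = function(k) runif(k, 0.2, 1.5))
    ref <- ape::unroot(ref)
    d <- ape::cophenetic.phylo(ref)
    d <- d[sort(rownames(d)), sort(rownames(d))]
    tr <- neighbor_joining(d)
    expect_equal(phangorn::RF.dist(tr, ref), 0)
    # and the package tree matches the reference NJ implementation
    expect_equal(phangorn::RF.dist(tr, ape::nj(as.dist(d))), 0)
  }
})

test_that("degenerate equal distances resolve deterministically", {
  d <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(d) <- 0
  t1 <- neighbor_joining(d)
  t2 <- neighbor_joining(d)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
})

test_that("bootstrap supports behave at the limits and reproduce", {
  # two well-separated clades, no homoplasy: separating edge support 100
  set.seed(3)
  c1 <- random_peptides(1, 80, 80)
  c2 <- random_peptides(1, 80, 80)
  msa <- structure(c(a1 = c1, a2 = c1, b1 = c2, b2 = c2),
                   class = "regen_msa")
  tr <- bootstrap_supports(msa, n_replicates = 100, seed = 5)
  sup <- attr(tr, "supports")
  expect_length(sup, 1) # one internal edge on an unrooted 4-taxon tree
  expect_equal(unname(sup), 100)
  # supports land on the tree's internal nodes
  expect_true(any(tr$node.label == "100"))
  # n_replicates = 1: supports are 0 or 100
  one <- bootstrap_supports(msa, n_replicates = 1, seed = 9)
  expect_true(all(attr(one, "supports") %in% c(0, 100)))
  # seed reproducibility
  r1 <- bootstrap_supports(msa, 25, seed = 11)
  r2 <- bootstrap_supports(msa, 25, seed = 11)
  expect_identical(attr(r1, "supports"), attr(r2, "supports"))
  expect_true(all(attr(r1, "supports") >= 0 & attr(r1, "supports") <= 100))
})

test_that("monophyly test validates inputs and planted paralog trees separate", {
  d <- matrix(c(0, 1, 4, 4, 1, 0, 4, 4, 4, 4, 0, 1, 4, 4, 1, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- neighbor_joining(d)
  expect_error(is_separated_cluster(tr, character()), "nonempty")
  expect_error(is_separated_cluster(tr, c("A", "B", "C", "D")), "proper")
  expect_error(is_separated_cluster(tr, "Z"), "tip labels")
  # fixture: high-regenerative members of a paralog family form their own
  # cluster against the diverged low-regenerative copy plus outgroup-ish rows
  sim <- small_scenario()
  fam <- sim$truth$paralog_family_ids[1]
  seqs <- character()
  for (p in sim$proteomes) {
    if (fam %in% names(p$genes)) {
      red <- select_longest_isoform(p)
      seqs[paste(p$species_id, fam, sep = "|")] <-
        proteome_sequences(red)[[fam]]
    }
  }
  expect_gte(length(seqs), 4)
  msa <- progressive_align(seqs)
  tr2 <- bootstrap_supports(msa, 50, seed = 2)
  wbr_taxa <- grep("^wbr", names(seqs), value = TRUE)
  expect_true(is_separated_cluster(tr2, wbr_taxa))
})

test_that("alignment writers emit valid PHYLIP and FASTA", {
  msa <- progressive_align(c(x = "ACDE", y = "ACE"))
  phy <- tempfile(fileext = ".phy")
  write_phylip(msa, phy)
  lines <- readLines(phy)
  expect_identical(lines[1], "2 4")
  expect_match(lines[2], "^x  ACDE$")
  fa <- tempfile(fileext = ".fasta")
  write_msa_fasta(msa, fa)
  back <- Biostrings::readAAStringSet(fa)
  expect_identical(as.character(back[["y"]]), "AC-E")
})
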