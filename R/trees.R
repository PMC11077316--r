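# Distance-based gene trees for ortholog/paralog adjudication: progressive
# multiple alignment, corrected pairwise distances, neighbor-joining, column
# bootstrap supports, and a monophyly test for the high-regenerative member
# set.

#' Progressive multiple alignment
#'
#' Builds a guide tree by average-linkage clustering of pairwise local
#' alignment score distances, then merges sequence profiles bottom-up with
#' global affine-gap profile-profile alignment. Deterministic for a given
#' input order.
#'
#' @param sequences Named character vector of >= 1 amino-acid sequences.
#' @param scheme A [scoring_scheme()].
#' @return An object of class `regen_msa`: named character vector of
#'   equal-length aligned rows (gap symbol `-`).
#' @export
progressive_align <- function(sequences, scheme = scoring_scheme()) {
  if (!length(sequences)) stop("no sequences to align")
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("sequences must have unique names")
  n <- length(sequences)
  if (n == 1) return(.as_msa(sequences))
  if (n == 2) {
    merged <- .align_profiles(.seq_profile(sequences[1], scheme),
                              .seq_profile(sequences[2], scheme), scheme)
    return(.as_msa(.profile_rows(merged)))
  }
  # guide distances: 1 - S(a,b) / min(S(a,a), S(b,b)), clipped at 0
  self <- vapply(sequences, function(s) local_align_score(s, s, scheme),
                 numeric(1))
  d <- matrix(0, n, n, dimnames = list(names(sequences), names(sequences)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- local_align_score(sequences[[i]], sequences[[j]], scheme)
    d[i, j] <- d[j, i] <- max(0, 1 - s / min(self[i], self[j]))
  }
  hc <- hclust(as.dist(d), method = "average")
  profiles <- lapply(seq_len(n), function(i)
    .seq_profile(sequences[i], scheme))
  merged <- vector("list", nrow(hc$merge))
  for (step in seq_len(nrow(hc$merge))) {
    pick <- function(k) if (k < 0) profiles[[-k]] else merged[[k]]
    merged[[step]] <- .align_profiles(pick(hc$merge[step, 1]),
                                      pick(hc$merge[step, 2]), scheme)
  }
  rows <- .profile_rows(merged[[length(merged)]])
  .as_msa(rows[names(sequences)])
}

.as_msa <- function(rows) {
  stopifnot(length(unique(nchar(rows))) == 1)
  structure(rows, class = "regen_msa")
}

# Character matrix of alignment rows, validating equal row lengths.
.msa_rows <- function(msa) {
  v <- unclass(msa)
  if (length(unique(nchar(v))) != 1)
    stop("alignment rows differ in length")
  rows <- do.call(rbind, strsplit(unname(v), ""))
  rownames(rows) <- names(msa)
  rows
}

#' @export
print.regen_msa <- function(x, ...) {
  cat(sprintf("<msa> %d sequences x %d columns\n", length(x), nchar(x[[1]])))
  invisible(x)
}

# A profile is a list: rows (named character vector of aligned strings) and
# freq (21 x L residue frequency matrix over ARNDCQEGHILKMFPSTWYV + X,
# gaps excluded from the numerator, denominator = number of rows).
.seq_profile <- function(seq, scheme) {
  chars <- strsplit(unname(seq), "")[[1]]
  idx <- match(chars, c(.aa_order, "X"))
  idx[is.na(idx)] <- 21L
  f <- matrix(0, 21, length(chars))
  f[cbind(idx, seq_along(chars))] <- 1
  list(rows = seq, freq = f)
}

.profile_rows <- function(p) p$rows

.align_profiles <- function(pa, pb, scheme) {
  S <- scheme$matrix[seq_len(21), seq_len(21)]
  C <- t(pa$freq) %*% S %*% pb$freq
  path <- .nw_profile_path_cpp(C, scheme$gap_open, scheme$gap_extend)
  la <- ncol(pa$freq); lb <- ncol(pb$freq)
  ia <- integer(0); ib <- integer(0) # column index or NA (gap)
  ca <- 0L; cb <- 0L
  for (code in path) {
    if (code == 3L) { ca <- ca + 1L; cb <- cb + 1L; ia <- c(ia, ca); ib <- c(ib, cb) }
    else if (code == 1L) { ca <- ca + 1L; ia <- c(ia, ca); ib <- c(ib, NA) }
    else { cb <- cb + 1L; ia <- c(ia, NA); ib <- c(ib, cb) }
  }
  splice <- function(rows, idx) {
    m <- do.call(rbind, strsplit(unname(rows), ""))
    out <- matrix("-", nrow(m), length(idx))
    out[, !is.na(idx)] <- m[, idx[!is.na(idx)], drop = FALSE]
    setNames(apply(out, 1, paste, collapse = ""), names(rows))
  }
  rows <- c(splice(pa$rows, ia), splice(pb$rows, ib))
  L <- length(ia)
  na <- length(pa$rows); nb <- length(pb$rows)
  freq <- matrix(0, 21, L)
  freq[, !is.na(ia)] <- freq[, !is.na(ia)] + pa$freq[, ia[!is.na(ia)], drop = FALSE] * na
  freq[, !is.na(ib)] <- freq[, !is.na(ib)] + pb$freq[, ib[!is.na(ib)], drop = FALSE] * nb
  list(rows = rows, freq = freq / (na + nb))
}

#' Pairwise distance matrix from an alignment
#'
#' p-distance over columns where neither row has a gap (pairwise deletion),
#' with an amino-acid Jukes-Cantor-style correction
#' `d = -(19/20) * log(1 - 20 p / 19)` capped at `cap`. Pairs with zero
#' comparable columns get the cap with a warning.
#'
#' @param msa A `regen_msa` from [progressive_align()].
#' @param correct Apply the distance correction (default `TRUE`; otherwise
#'   raw p-distances are returned).
#' @param cap Maximum distance (default 5).
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
distance_matrix <- function(msa, correct = TRUE, cap = 5) {
  rows <- .msa_rows(msa)
  n <- nrow(rows)
  d <- matrix(0, n, n, dimnames = list(names(msa), names(msa)))
  if (n < 2) return(d)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- rows[i, ] != "-" & rows[j, ] != "-"
    if (!any(ok)) {
      warning("no comparable columns between ", names(msa)[i], " and ",
              names(msa)[j], "; distance set to cap")
      d[i, j] <- d[j, i] <- cap
      next
    }
    p <- mean(rows[i, ok] != rows[j, ok])
    if (correct) {
      arg <- 1 - 20 * p / 19
      val <- if (arg <= 0) cap else min(cap, -(19 / 20) * log(arg))
    } else val <- p
    d[i, j] <- d[j, i] <- val
  }
  d
}

#' Neighbor-joining tree
#'
#' Standard Saitou-Nei neighbor joining with deterministic tie-breaking
#' (lowest index pair in the current node ordering). On an additive distance
#' matrix the generating topology and branch lengths are recovered exactly.
#' Negative branch-length estimates are clamped to zero.
#'
#' @param d Square symmetric distance matrix over >= 3 taxa with dimnames.
#' @return An unrooted `phylo` object (ape).
#' @export
neighbor_joining <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  n <- nrow(d)
  if (n < 3) stop("need at least 3 taxa")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  n_internal <- n - 2
  edge <- matrix(0L, 0, 2)
  edge_len <- numeric(0)
  # active node ids: tips 1..n, internal nodes numbered n+2, n+3, ... so the
  # final joining node can take the ape root slot n+1
  active <- seq_len(n)
  next_internal <- n + 2L
  D <- d
  while (length(active) > 3) {
    m <- length(active)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    idx <- which(Q == min(Q), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    u <- next_internal; next_internal <- next_internal + 1L
    edge <- rbind(edge, c(u, active[i]), c(u, active[j]))
    edge_len <- c(edge_len, max(0, li), max(0, lj))
    du <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]),
               c(du[keep], 0))
    active <- c(active[keep], u)
  }
  # final three nodes joined at the root (trifurcation), closed form
  a <- 1; b <- 2; c3 <- 3
  la <- (D[a, b] + D[a, c3] - D[b, c3]) / 2
  lb <- (D[a, b] + D[b, c3] - D[a, c3]) / 2
  lc <- (D[a, c3] + D[b, c3] - D[a, b]) / 2
  root <- n + 1L
  edge <- rbind(edge, c(root, active[a]), c(root, active[b]),
                c(root, active[c3]))
  edge_len <- c(edge_len, max(0, la), max(0, lb), max(0, lc))
  tr <- list(edge = edge, edge.length = edge_len, tip.label = labels,
             Nnode = n_internal)
  class(tr) <- "phylo"
  tr <- ape::reorder.phylo(tr, "cladewise")
  tr
}

# Canonical internal bipartitions of an unrooted phylo: for every internal
# edge, the sorted tip labels of the side not containing tip 1, collapsed to
# a key string.
.bipartitions <- function(tree) {
  n <- length(tree$tip.label)
  desc <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) desc[[i]] <- i
  # accumulate in postorder
  eo <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(eo))) {
    p <- eo[k, 1]; ch <- eo[k, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  keys <- character(0)
  nodes <- integer(0)
  root <- n + 1L
  for (k in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[k, 2]
    if (ch <= n || ch == root) next
    side <- sort(desc[[ch]])
    if (1L %in% side) side <- sort(setdiff(seq_len(n), side))
    if (length(side) < 2 || length(side) > n - 2) next
    keys <- c(keys, paste(tree$tip.label[side], collapse = "\r"))
    nodes <- c(nodes, ch)
  }
  list(keys = keys, nodes = nodes)
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds a tree per
#' replicate via [distance_matrix()] + [neighbor_joining()], and reports, for
#' each internal edge of the full-data tree, the percentage of replicates
#' containing the same bipartition.
#'
#' @param msa A `regen_msa`.
#' @param n_replicates Number of bootstrap replicates (default 100).
#' @param seed Integer seed.
#' @param correct,cap Passed to [distance_matrix()].
#' @return The full-data `phylo` tree with `node.label` carrying supports in
#'   `[0, 100]` (empty label on the root), plus attribute `supports` (named
#'   by bipartition key).
#' @export
bootstrap_supports <- function(msa, n_replicates = 100, seed = 1,
                               correct = TRUE, cap = 5) {
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  tree <- neighbor_joining(distance_matrix(msa, correct, cap))
  bp <- .bipartitions(tree)
  counts <- setNames(numeric(length(bp$keys)), bp$keys)
  L <- nchar(msa[[1]])
  rows <- .msa_rows(msa)
  set.seed(as.integer(seed))
  for (b in seq_len(n_replicates)) {
    cols <- sample.int(L, L, replace = TRUE)
    rep_msa <- .as_msa(setNames(apply(rows[, cols, drop = FALSE], 1, paste,
                                      collapse = ""), names(msa)))
    rep_tree <- suppressWarnings(
      neighbor_joining(distance_matrix(rep_msa, correct, cap)))
    rep_keys <- .bipartitions(rep_tree)$keys
    hit <- bp$keys %in% rep_keys
    counts[hit] <- counts[hit] + 1
  }
  supports <- 100 * counts / n_replicates
  n <- length(tree$tip.label)
  labels <- rep("", tree$Nnode)
  labels[bp$nodes - n] <- format(supports, trim = TRUE)
  tree$node.label <- labels
  attr(tree, "supports") <- supports
  tree
}

#' Does a taxon set form its own cluster in the tree?
#'
#' TRUE iff some internal edge bipartitions the leaves into exactly
#' `focal_taxa` versus the rest.
#'
#' @param tree A `phylo` object.
#' @param focal_taxa Character vector of tip labels (nonempty, proper
#'   subset).
#' @return Logical scalar.
#' @export
is_separated_cluster <- function(tree, focal_taxa) {
  tips <- tree$tip.label
  if (!length(focal_taxa) || length(focal_taxa) >= length(tips))
    stop("focal_taxa must be a nonempty proper subset of the leaves")
  if (!all(focal_taxa %in% tips)) stop("focal_taxa must be tip labels")
  if (length(focal_taxa) == 1 || length(focal_taxa) == length(tips) - 1)
    return(TRUE) # trivial splits always exist on a tree
  focal <- sort(focal_taxa)
  other <- sort(setdiff(tips, focal_taxa))
  keys <- .bipartitions(tree)$keys
  paste(focal, collapse = "\r") %in% keys ||
    paste(other, collapse = "\r") %in% keys
}

#' Write an alignment in relaxed PHYLIP format
#'
#' One-line-per-sequence relaxed PHYLIP (name, whitespace, full row), the
#' interchange format expected by external maximum-likelihood programs.
#'
#' @param msa A `regen_msa`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phylip <- function(msa, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", length(msa), nchar(msa[[1]])), con)
  writeLines(paste(names(msa), unclass(msa), sep = "  "), con)
  invisible(path)
}

#' Write an alignment as FASTA
#' @param msa A `regen_msa`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_msa_fasta <- function(msa, path) {
  x <- Biostrings::AAStringSet(unclass(msa))
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}
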