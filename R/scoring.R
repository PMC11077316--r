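# Substitution scoring and E-value calibration for the local-alignment search.

# BLOSUM62 over the 20 canonical residues, order ARNDCQEGHILKMFPSTWYV.
# A 21st row/column scores any non-canonical symbol (X etc.) at the matrix
# minimum (-4), a deliberately pessimal treatment of unknown residues.
.blosum62_values <- c(
   4,-1,-2,-2, 0,-1,-1, 0,-2,-1,-1,-1,-1,-2,-1, 1, 0,-3,-2, 0,
  -1, 5, 0,-2,-3, 1, 0,-2, 0,-3,-2, 2,-1,-3,-2,-1,-1,-3,-2,-3,
  -2, 0, 6, 1,-3, 0, 0, 0, 1,-3,-3, 0,-2,-3,-2, 1, 0,-4,-2,-3,
  -2,-2, 1, 6,-3, 0, 2,-1,-1,-3,-4,-1,-3,-3,-1, 0,-1,-4,-3,-3,
   0,-3,-3,-3, 9,-3,-4,-3,-3,-1,-1,-3,-1,-2,-3,-1,-1,-2,-2,-1,
  -1, 1, 0, 0,-3, 5, 2,-2, 0,-3,-2, 1, 0,-3,-1, 0,-1,-2,-1,-2,
  -1, 0, 0, 2,-4, 2, 5,-2, 0,-3,-3, 1,-2,-3,-1, 0,-1,-3,-2,-2,
   0,-2, 0,-1,-3,-2,-2, 6,-2,-4,-4,-2,-3,-3,-2, 0,-2,-2,-3,-3,
  -2, 0, 1,-1,-3, 0, 0,-2, 8,-3,-3,-1,-2,-1,-2,-1,-2,-2, 2,-3,
  -1,-3,-3,-3,-1,-3,-3,-4,-3, 4, 2,-3, 1, 0,-3,-2,-1,-3,-1, 3,
  -1,-2,-3,-4,-1,-2,-3,-4,-3, 2, 4,-2, 2, 0,-3,-2,-1,-2,-1, 1,
  -1, 2, 0,-1,-3, 1, 1,-2,-1,-3,-2, 5,-1,-3,-1, 0,-1,-3,-2,-2,
  -1,-1,-2,-3,-1, 0,-2,-3,-2, 1, 2,-1, 5, 0,-2,-1,-1,-1,-1, 1,
  -2,-3,-3,-3,-2,-3,-3,-3,-1, 0, 0,-3, 0, 6,-4,-2,-2, 1, 3,-1,
  -1,-2,-2,-1,-3,-1,-1,-2,-2,-3,-3,-1,-2,-4, 7,-1,-1,-4,-3,-2,
   1,-1, 1, 0,-1, 0, 0, 0,-1,-2,-2, 0,-1,-2,-1, 4, 1,-3,-2,-2,
   0,-1, 0,-1,-1,-1,-1,-2,-2,-1,-1,-1,-1,-2,-1, 1, 5,-2,-2, 0,
  -3,-3,-4,-4,-2,-2,-3,-2,-2,-3,-2,-3,-1, 1,-4,-3,-2,11, 2,-3,
  -2,-2,-2,-3,-2,-1,-2,-3, 2,-1,-1,-2,-1, 3,-3,-2,-2, 2, 7,-1,
   0,-3,-3,-3,-1,-2,-2,-3,-3, 3, 1,-2, 1,-1,-2,-2, 0,-3,-1, 4)

.aa_order <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

#' BLOSUM62 substitution matrix with a worst-case unknown-residue column
#'
#' Returns the 21 x 21 integer matrix used throughout the similarity search:
#' BLOSUM62 over the 20 canonical amino acids plus an `X` row/column fixed at
#' -4 so unknown residues can never create spurious similarity.
#'
#' @return An integer matrix with dimnames over `ARNDCQEGHILKMFPSTWYVX`.
#' @export
blosum62_matrix <- function() {
  m <- matrix(NA_integer_, 21, 21,
              dimnames = list(c(.aa_order, "X"), c(.aa_order, "X")))
  m[1:20, 1:20] <- matrix(as.integer(.blosum62_values), 20, 20, byrow = TRUE)
  m[21, ] <- -4L
  m[, 21] <- -4L
  m
}

#' Scoring scheme for the local-alignment search
#'
#' Bundles the substitution matrix, affine gap penalties and the
#' Karlin-Altschul calibration constants used to turn raw local alignment
#' scores into E-values. A gap of length L costs `gap_open + L * gap_extend`.
#' `K` and `lambda` are treated as fixed calibration constants (the screen's
#' decisions depend only on threshold ordering, not on their exact values).
#'
#' The default `K` and `lambda` were calibrated by simulation against this
#' package's own null -- gapped BLOSUM62/11/1 local alignment of
#' uniform-composition random protein sequences (see
#' [calibrate_evalue_constants()]) -- with `lambda` taken from the deep tail
#' of the fit so that E-values near decision thresholds err on the
#' conservative (larger-E) side. They differ from BLAST's database-composition
#' constants because the null composition differs.
#'
#' @param matrix Integer substitution matrix (symmetric). Defaults to
#'   [blosum62_matrix()].
#' @param gap_open Gap opening penalty (> 0).
#' @param gap_extend Gap extension penalty per residue (> 0).
#' @param K Karlin-Altschul constant (> 0).
#' @param lambda Karlin-Altschul scale in inverse score units (> 0).
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(matrix = blosum62_matrix(), gap_open = 11,
                           gap_extend = 1, K = 0.045, lambda = 0.22) {
  if (!is.matrix(matrix) || nrow(matrix) != ncol(matrix))
    stop("substitution matrix must be square")
  if (gap_open <= 0 || gap_extend <= 0) stop("gap penalties must be positive")
  if (K <= 0 || lambda <= 0) stop("K and lambda must be positive")
  structure(list(matrix = matrix, gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 K = K, lambda = lambda),
            class = "scoring_scheme")
}

#' Karlin-Altschul E-value for a local alignment score
#'
#' Computes `E = K * m * n * exp(-lambda * S)`: the expected number of chance
#' local alignments scoring at least `S` between a query of length `m` and a
#' subject database of total length `n`.
#'
#' @param score Raw local alignment score (numeric, may be vectorized).
#' @param m Query sequence length (>= 1).
#' @param n Total subject database length (>= 1); by convention the summed
#'   length of the isoform-reduced subject proteome.
#' @param scheme A [scoring_scheme()].
#' @return Numeric E-value(s).
#' @export
estimate_evalue <- function(score, m, n, scheme = scoring_scheme()) {
  if (any(m < 1) || any(n < 1)) stop("m and n must be >= 1")
  scheme$K * m * n * exp(-scheme$lambda * score)
}

# Score threshold equivalent to an E-value cutoff at given m, n.
.score_for_evalue <- function(evalue, m, n, scheme) {
  log(scheme$K * m * n / evalue) / scheme$lambda
}

#' Calibrate Karlin-Altschul constants by null simulation
#'
#' Aligns random uniform-composition sequence pairs under the scheme and fits
#' `log P(S >= s) = log K - lambda * s` to the exceedance rates per dynamic
#' programming cell over a range of score cutoffs. Useful to re-derive the
#' default `K`/`lambda` of [scoring_scheme()] or to calibrate a different
#' scoring system.
#'
#' @param scheme A [scoring_scheme()] providing matrix and gap penalties.
#' @param n_seqs Sequences per side (the fit uses `n_seqs^2` alignments per
#'   length).
#' @param lengths Sequence lengths simulated.
#' @param cutoffs Score cutoffs entering the fit.
#' @param seed Integer seed.
#' @return Named numeric vector with elements `K` and `lambda`.
#' @export
calibrate_evalue_constants <- function(scheme = scoring_scheme(),
                                       n_seqs = 60,
                                       lengths = c(250, 360, 500),
                                       cutoffs = seq(50, 75, 5), seed = 1) {
  set.seed(as.integer(seed))
  scores <- numeric(0)
  cells <- 0
  for (L in lengths) {
    q <- vapply(seq_len(n_seqs), function(i)
      paste(sample(.aa_order, L, replace = TRUE), collapse = ""),
      character(1))
    subj <- vapply(seq_len(n_seqs), function(i)
      paste(sample(.aa_order, L, replace = TRUE), collapse = ""),
      character(1))
    m <- .sw_score_matrix_cpp(q, subj, scheme$matrix, scheme$gap_open,
                              scheme$gap_extend)
    scores <- c(scores, as.vector(m))
    cells <- cells + as.numeric(n_seqs)^2 * L^2
  }
  rate <- vapply(cutoffs, function(cc) sum(scores >= cc) / cells, numeric(1))
  if (any(rate == 0))
    stop("no exceedances at the largest cutoff; lower the cutoffs")
  fit <- stats::lm(log(rate) ~ cutoffs)
  c(K = unname(exp(stats::coef(fit)[1])),
    lambda = unname(-stats::coef(fit)[2]))
}
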