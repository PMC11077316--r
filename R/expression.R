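# Amputation time-course expression: FPKM matrix I/O, normalization for
# heatmaps, rule-based phase classification of gene trajectories, and qPCR
# relative quantification.

#' Read a genes x timepoints FPKM matrix from TSV
#'
#' Expects a `gene_id` column followed by one column per timepoint with
#' header `h<hours>` (e.g. `h0`, `h24`).
#'
#' @param path TSV file path.
#' @return Numeric matrix with genes as rownames and `h<hours>` columns.
#' @export
read_fpkm <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                  check.names = FALSE)
  if (names(d)[1] != "gene_id") stop("first column must be gene_id")
  tp <- sub("^h", "", names(d)[-1])
  if (any(is.na(suppressWarnings(as.numeric(tp)))))
    stop("timepoint columns must be named h<hours>")
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$gene_id
  if (any(m < 0)) stop("FPKM values must be nonnegative")
  if (is.unsorted(as.numeric(tp), strictly = TRUE))
    stop("timepoints must be strictly increasing")
  m
}

#' Write an FPKM (or normalized) matrix as TSV
#' @param m Matrix with `h<hours>` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fpkm <- function(m, path) {
  d <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                  stringsAsFactors = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.timepoints_of <- function(m) {
  tp <- suppressWarnings(as.numeric(sub("^h", "", colnames(m))))
  if (any(is.na(tp))) stop("columns must be named h<hours>")
  tp
}

#' Normalize an FPKM matrix for heatmap display
#'
#' `log2(FPKM + 1)` followed by a per-gene z-score; genes with zero variance
#' map to all-zero rows.
#'
#' @param m Nonnegative FPKM matrix.
#' @return Normalized matrix of the same shape.
#' @export
normalize_expression <- function(m) {
  if (any(m < 0)) stop("FPKM values must be nonnegative")
  lg <- log2(m + 1)
  mu <- rowMeans(lg)
  s <- apply(lg, 1, sd)
  z <- (lg - mu) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  z
}

#' Classify one expression trajectory into a regeneration phase
#'
#' Log2 fold changes versus the 0 h baseline (with a +1 pseudocount) are
#' summarized over three windows: early `(0, early_cut]`, mid
#' `(early_cut, mid_cut]`, late `(mid_cut, end]`. The rule, applied in
#' order:
#' \enumerate{
#'   \item `wound_response` if the early window reaches `fc_threshold`
#'     (absolute log2 change);
#'   \item `late_arrested` if the mid window reaches the threshold and the
#'     late window's mean change returns within `fc_threshold / 2` of
#'     baseline;
#'   \item `proliferative` if the mid window reaches the threshold;
#'   \item `differentiation` if only the late window reaches it;
#'   \item `flat` otherwise.
#' }
#'
#' @param row Numeric vector of FPKM values.
#' @param timepoints Hours post amputation (same length as `row`, must
#'   include 0 and >= 1 timepoint per window).
#' @param early_cut End of the early window in hours (default 6).
#' @param mid_cut End of the mid window in hours (default 96, i.e. 4 d).
#' @param fc_threshold Change threshold in log2 units (default 1).
#' @return List with `phase` and `change_scores` (named log2 fold changes
#'   per timepoint).
#' @export
classify_pattern <- function(row, timepoints, early_cut = 6, mid_cut = 96,
                             fc_threshold = 1) {
  if (length(row) != length(timepoints))
    stop("row and timepoints differ in length")
  if (!0 %in% timepoints) stop("timepoints must include 0")
  early <- timepoints > 0 & timepoints <= early_cut
  mid <- timepoints > early_cut & timepoints <= mid_cut
  late <- timepoints > mid_cut
  if (!any(early) || !any(mid) || !any(late))
    stop("need at least one timepoint in each of the early/mid/late windows")
  base <- row[timepoints == 0][1]
  fc <- log2((row + 1) / (base + 1))
  phase <- if (max(abs(fc[early])) >= fc_threshold) {
    "wound_response"
  } else if (max(abs(fc[mid])) >= fc_threshold &&
             abs(mean(fc[late])) < fc_threshold / 2) {
    "late_arrested"
  } else if (max(abs(fc[mid])) >= fc_threshold) {
    "proliferative"
  } else if (max(abs(fc[late])) >= fc_threshold) {
    "differentiation"
  } else "flat"
  list(phase = phase,
       change_scores = setNames(fc, paste0("h", timepoints)))
}

#' Classify every gene of an FPKM matrix
#'
#' Replicate columns sharing a timepoint are averaged before
#' classification.
#'
#' @param m FPKM matrix with `h<hours>` columns.
#' @param ... Passed to [classify_pattern()].
#' @return Data frame with columns `gene_id` and `phase`, plus the per-gene
#'   change scores as attribute `change_scores`.
#' @export
classify_patterns <- function(m, ...) {
  tp <- .timepoints_of(m)
  if (anyDuplicated(tp)) {
    groups <- split(seq_along(tp), tp)
    m <- do.call(cbind, lapply(groups, function(ix)
      rowMeans(m[, ix, drop = FALSE])))
    colnames(m) <- paste0("h", names(groups))
    m <- m[, order(as.numeric(names(groups))), drop = FALSE]
    tp <- .timepoints_of(m)
  }
  calls <- lapply(seq_len(nrow(m)), function(i)
    classify_pattern(m[i, ], tp, ...))
  out <- data.frame(gene_id = rownames(m),
                    phase = vapply(calls, `[[`, character(1), "phase"),
                    stringsAsFactors = FALSE)
  attr(out, "change_scores") <-
    do.call(rbind, lapply(calls, `[[`, "change_scores"))
  out
}

#' qPCR relative quantification (2^-ddCt)
#'
#' Computes `ddCt = (Ct_target_treated - Ct_reference_treated) -
#' (Ct_target_control - Ct_reference_control)` and returns the fold change
#' `2^-ddCt`. Inputs are vectorized; Ct values outside the usual [1, 45]
#' cycle range trigger a warning.
#'
#' @param ct_target_treated,ct_reference_treated Ct of target and reference
#'   gene in the treated sample.
#' @param ct_target_control,ct_reference_control Ct of target and reference
#'   gene in the control sample.
#' @return Numeric fold change(s).
#' @export
delta_delta_ct <- function(ct_target_treated, ct_reference_treated,
                           ct_target_control, ct_reference_control) {
  cts <- c(ct_target_treated, ct_reference_treated,
           ct_target_control, ct_reference_control)
  if (!all(is.finite(cts))) stop("all Ct values must be finite")
  if (any(cts < 1 | cts > 45))
    warning("Ct value(s) outside the typical [1, 45] cycle range")
  ddct <- (ct_target_treated - ct_reference_treated) -
    (ct_target_control - ct_reference_control)
  2^(-ddct)
}
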