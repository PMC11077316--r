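# Promoter motif analysis: JASPAR PFM parsing, log-odds PWM scanning of
# upstream windows on both strands, gene-level Fisher-exact enrichment of
# target versus background gene sets, and compilation of top-ranked TF
# classes across window sizes.

#' Scan parameters for PWM matching
#'
#' @param pseudocount Total pseudocount added per matrix column, split by the
#'   background base frequencies (default 0.8).
#' @param background Background base frequencies (A, C, G, T); default
#'   uniform.
#' @param score_fraction_threshold A window is a hit when its log-odds score
#'   reaches this fraction of the PWM's achievable score range
#'   (min + fraction * (max - min)); default 0.85.
#' @param window_lengths Upstream window lengths in bp, strictly increasing.
#' @return An object of class `scan_params`.
#' @export
scan_params <- function(pseudocount = 0.8,
                        background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                        score_fraction_threshold = 0.85,
                        window_lengths = c(100, 500, 1000, 3000, 5000, 7500)) {
  if (length(background) != 4 || abs(sum(background) - 1) > 1e-8)
    stop("background must be 4 frequencies summing to 1")
  if (score_fraction_threshold <= 0 || score_fraction_threshold > 1)
    stop("score_fraction_threshold must lie in (0, 1]")
  if (any(window_lengths <= 0) || is.unsorted(window_lengths, strictly = TRUE))
    stop("window_lengths must be positive and strictly increasing")
  structure(list(pseudocount = pseudocount,
                 background = setNames(as.numeric(background),
                                       c("A", "C", "G", "T")),
                 score_fraction_threshold = score_fraction_threshold,
                 window_lengths = window_lengths),
            class = "scan_params")
}

#' Construct a PWM record from a count matrix
#'
#' @param matrix_id Matrix identifier (e.g. `MA0001.1`).
#' @param tf_name Transcription factor name.
#' @param counts 4 x width nonnegative count matrix, rows A, C, G, T.
#' @param tf_class TF class annotation (e.g. "Homeo domain factors");
#'   defaults to "Unclassified".
#' @return An object of class `pwm_record`.
#' @export
pwm_record <- function(matrix_id, tf_name, counts, tf_class = "Unclassified") {
  if (!is.matrix(counts) || nrow(counts) != 4)
    stop("counts must be a 4 x width matrix")
  if (ncol(counts) < 1) stop("PWM width must be >= 1")
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (any(colSums(counts) <= 0)) stop("every column needs positive total count")
  rownames(counts) <- c("A", "C", "G", "T")
  structure(list(matrix_id = matrix_id, tf_name = tf_name,
                 tf_class = tf_class, counts = counts),
            class = "pwm_record")
}

#' @export
print.pwm_record <- function(x, ...) {
  cat(sprintf("<pwm> %s %s [%s], width %d\n", x$matrix_id, x$tf_name,
              x$tf_class, ncol(x$counts)))
  invisible(x)
}

#' Read JASPAR-format PFM records
#'
#' Parses the JASPAR 2016+ text format: a `>` header line with matrix id and
#' name, followed by four bracketed count rows labeled A/C/G/T. TF classes
#' are joined from an optional sidecar TSV (`matrix_id`, `tf_class`);
#' matrices without an annotation get class "Unclassified".
#'
#' @param pfm_file Path to the JASPAR text file.
#' @param class_file Optional path to the class-annotation TSV.
#' @return List of [pwm_record()]s.
#' @export
read_jaspar <- function(pfm_file, class_file = NULL) {
  lines <- readLines(pfm_file)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no JASPAR records found in ", pfm_file)
  classes <- NULL
  if (!is.null(class_file)) {
    cd <- read.table(class_file, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    classes <- setNames(cd[[2]], cd[[1]])
  }
  ends <- c(starts[-1] - 1, length(lines))
  out <- vector("list", length(starts))
  for (r in seq_along(starts)) {
    hdr <- sub("^>\\s*", "", lines[starts[r]])
    parts <- strsplit(hdr, "\\s+")[[1]]
    matrix_id <- parts[1]
    tf_name <- if (length(parts) > 1) paste(parts[-1], collapse = " ")
               else matrix_id
    body <- lines[(starts[r] + 1):ends[r]]
    rowmap <- list()
    for (bl in body) {
      m <- regmatches(bl, regexec("^\\s*([ACGT])\\s*\\[([^]]*)\\]", bl))[[1]]
      if (length(m) != 3)
        stop("malformed count row in matrix ", matrix_id, ": ", bl)
      vals <- suppressWarnings(as.numeric(strsplit(trimws(m[3]), "\\s+")[[1]]))
      if (any(is.na(vals)))
        stop("non-numeric counts in matrix ", matrix_id)
      rowmap[[m[2]]] <- vals
    }
    missing <- setdiff(c("A", "C", "G", "T"), names(rowmap))
    if (length(missing))
      stop("matrix ", matrix_id, " is missing row(s): ",
           paste(missing, collapse = ", "))
    lens <- lengths(rowmap[c("A", "C", "G", "T")])
    if (length(unique(lens)) != 1)
      stop("row-length mismatch in matrix ", matrix_id)
    counts <- rbind(A = rowmap$A, C = rowmap$C, G = rowmap$G, T = rowmap$T)
    cls <- if (!is.null(classes) && matrix_id %in% names(classes))
      classes[[matrix_id]] else "Unclassified"
    out[[r]] <- pwm_record(matrix_id, tf_name, counts, cls)
  }
  out
}

#' Write PWM records in JASPAR text format
#'
#' @param pwms List of [pwm_record()]s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_jaspar <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(sprintf(">%s %s", p$matrix_id, p$tf_name), con)
    for (b in c("A", "C", "G", "T")) {
      writeLines(sprintf("%s [ %s ]", b,
                         paste(format(p$counts[b, ], trim = TRUE),
                               collapse = " ")), con)
    }
  }
  invisible(path)
}

# Log-odds matrix (5 x width; 5th row zeros for N) and the hit threshold
# under MATCH-style range rescaling.
.pwm_logodds <- function(pwm, params) {
  counts <- pwm$counts
  bg <- params$background
  freq <- sweep(counts + params$pseudocount * bg, 2,
                colSums(counts) + params$pseudocount, "/")
  lo <- log2(sweep(freq, 1, bg, "/"))
  smax <- sum(apply(lo, 2, max))
  smin <- sum(apply(lo, 2, min))
  thr <- smin + params$score_fraction_threshold * (smax - smin)
  list(lo = rbind(lo, N = 0), threshold = thr)
}

#' Scan one sequence with a PWM
#'
#' Log-odds scoring against the background base frequencies, on both
#' strands; a window is a hit when its score reaches the MATCH-style
#' rescaled threshold (`score_fraction_threshold` of the achievable range).
#' `N` bases contribute zero log-odds. Positions are 0-based window starts
#' on the given (forward) sequence.
#'
#' @param pwm A [pwm_record()].
#' @param seq Nucleotide sequence (single string over ACGTN).
#' @param params A [scan_params()].
#' @return Data frame with columns `position`, `strand` (1/-1), `score`;
#'   empty when the sequence is shorter than the PWM.
#' @export
scan_sequence <- function(pwm, seq, params = scan_params()) {
  lp <- .pwm_logodds(pwm, params)
  .pwm_scan_cpp(toupper(seq), lp$lo, lp$threshold)
}

# Gene-level hit indicator for a set of promoter sequences.
.genes_hit <- function(pwm, seqs, params) {
  lp <- .pwm_logodds(pwm, params)
  hit <- .pwm_any_hit_cpp(toupper(unname(seqs)), lp$lo, lp$threshold)
  setNames(hit, names(seqs))
}

#' Extract upstream regions from a genome
#'
#' Returns the `L` bases 5' of each gene's transcription start site on the
#' coding strand (reverse-complemented for minus-strand genes), excluding the
#' TSS base itself. Regions running off the contig edge are truncated and
#' flagged.
#'
#' @param annotation Data frame with columns `gene_id`, `contig`, `tss`
#'   (1-based), `strand` (`"+"`/`"-"`).
#' @param genome Named character vector (or `DNAStringSet`) of contig
#'   sequences.
#' @param L Window length in bp (> 0).
#' @return Named character vector of upstream sequences with attribute
#'   `truncated` (named logical).
#' @export
extract_upstream <- function(annotation, genome, L) {
  if (L <= 0) stop("L must be positive")
  need <- c("gene_id", "contig", "tss", "strand")
  if (!all(need %in% names(annotation)))
    stop("annotation needs columns: ", paste(need, collapse = ", "))
  if (inherits(genome, "DNAStringSet")) genome <- as.character(genome)
  n <- nrow(annotation)
  out <- character(n)
  trunc <- logical(n)
  for (i in seq_len(n)) {
    ctg <- annotation$contig[i]
    if (!ctg %in% names(genome))
      stop("gene ", annotation$gene_id[i], " is on missing contig ", ctg)
    cs <- genome[[ctg]]
    clen <- nchar(cs)
    tss <- annotation$tss[i]
    if (annotation$strand[i] == "+") {
      from <- tss - L
      to <- tss - 1
      trunc[i] <- from < 1
      from <- max(1, from)
      out[i] <- if (to < from) "" else substr(cs, from, to)
    } else {
      from <- tss + 1
      to <- tss + L
      trunc[i] <- to > clen
      to <- min(clen, to)
      s <- if (to < from) "" else substr(cs, from, to)
      out[i] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(s)))
    }
  }
  structure(setNames(out, annotation$gene_id),
            truncated = setNames(trunc, annotation$gene_id))
}

#' Gene-level enrichment of PWM hits in targets versus background
#'
#' Builds the 2x2 table of genes with/without at least one hit in the target
#' and background sets and tests it with a two-sided Fisher exact test.
#' `log2_enrichment` is the log2 ratio of hit proportions; exactly equal
#' proportions give 0, and otherwise zero hit counts are continuity-corrected
#' to 0.5 before taking the ratio.
#'
#' @param targets,background Disjoint, nonempty character vectors of gene
#'   ids.
#' @param hits_by_gene Named logical vector: does each gene have >= 1 hit?
#'   (e.g. from scanning with [scan_sequence()]).
#' @param pwm The [pwm_record()] tested (used for annotation columns).
#' @param window_length Window length annotation for the output record.
#' @return One-row data frame (an enrichment record) with columns
#'   `matrix_id`, `tf_class`, `window_length`, `n_target_hit`, `n_target`,
#'   `n_background_hit`, `n_background`, `p_value`, `log2_enrichment`.
#' @export
enrichment_test <- function(targets, background, hits_by_gene, pwm,
                            window_length = NA_real_) {
  if (!length(targets) || !length(background))
    stop("targets and background must be nonempty")
  if (length(intersect(targets, background)))
    stop("targets and background must be disjoint")
  missing <- setdiff(c(targets, background), names(hits_by_gene))
  if (length(missing))
    stop("no hit data for gene(s): ", paste(head(missing, 3), collapse = ", "))
  ht <- sum(hits_by_gene[targets])
  hb <- sum(hits_by_gene[background])
  nt <- length(targets)
  nb <- length(background)
  tab <- matrix(c(ht, nt - ht, hb, nb - hb), 2, 2)
  p <- fisher.test(tab, alternative = "two.sided")$p.value
  pt <- ht / nt
  pb <- hb / nb
  l2 <- if (pt == pb) 0 else {
    cht <- if (ht == 0) 0.5 else ht
    chb <- if (hb == 0) 0.5 else hb
    log2((cht / nt) / (chb / nb))
  }
  data.frame(matrix_id = pwm$matrix_id, tf_class = pwm$tf_class,
             window_length = window_length,
             n_target_hit = ht, n_target = nt,
             n_background_hit = hb, n_background = nb,
             p_value = p, log2_enrichment = l2,
             stringsAsFactors = FALSE)
}

#' Enrichment of a PWM panel over promoter windows
#'
#' For each window length, scans the window of each promoter nearest the TSS
#' (the last `L` bases of the upstream sequence; shorter promoters are used
#' whole) with every PWM and runs [enrichment_test()]. A Benjamini-Hochberg
#' adjusted p-value column is appended per window.
#'
#' @param promoters Named character vector of upstream sequences (3' end
#'   adjacent to the TSS).
#' @param targets Target gene ids; all other promoter owners form the
#'   background.
#' @param pwms List of [pwm_record()]s.
#' @param params A [scan_params()] (provides `window_lengths`).
#' @return Data frame of enrichment records across all windows and PWMs,
#'   with an additional `p_adjust` column.
#' @export
scan_windows <- function(promoters, targets, pwms, params = scan_params()) {
  background <- setdiff(names(promoters), targets)
  recs <- list()
  for (L in params$window_lengths) {
    win <- vapply(promoters, function(s) {
      n <- nchar(s)
      if (n <= L) s else substr(s, n - L + 1, n)
    }, character(1))
    rl <- lapply(pwms, function(p) {
      hit <- .genes_hit(p, win, params)
      enrichment_test(targets, background, hit, p, window_length = L)
    })
    d <- do.call(rbind, rl)
    d$p_adjust <- stats::p.adjust(d$p_value, method = "BH")
    recs[[as.character(L)]] <- d
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Tally TF classes of the top-ranked enrichments per window
#'
#' Per window length, selects the `top_k` records ranked by smallest p-value
#' (ties broken by largest log2 enrichment) and tallies their TF classes,
#' yielding the class x window count matrix used for the enrichment heatmap.
#'
#' @param records Enrichment records (from [scan_windows()] or row-bound
#'   [enrichment_test()] outputs).
#' @param top_k Number of top records per window (default 10). Windows with
#'   fewer records use all of them, with a warning.
#' @return Integer matrix, TF classes x window lengths.
#' @export
compile_top_classes <- function(records, top_k = 10) {
  if (!nrow(records)) stop("no enrichment records")
  windows <- sort(unique(records$window_length))
  classes <- sort(unique(records$tf_class))
  m <- matrix(0L, length(classes), length(windows),
              dimnames = list(classes, as.character(windows)))
  for (w in windows) {
    d <- records[records$window_length == w, , drop = FALSE]
    if (nrow(d) < top_k)
      warning("window ", w, ": only ", nrow(d), " records for top_k = ", top_k)
    d <- d[order(d$p_value, -d$log2_enrichment, d$matrix_id), , drop = FALSE]
    top <- head(d, top_k)
    tab <- table(top$tf_class)
    m[names(tab), as.character(w)] <- as.integer(tab)
  }
  m
}

#' Heatmap of the class x window tally
#'
#' Thin wrapper over `pheatmap` (if installed) for a quick look at the
#' compiled TF-class tallies.
#'
#' @param tally Matrix from [compile_top_classes()].
#' @param ... Passed to `pheatmap::pheatmap`.
#' @return The pheatmap object, invisibly.
#' @export
plot_class_tally <- function(tally, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE))
    stop("pheatmap not installed")
  ph <- pheatmap::pheatmap(tally, cluster_rows = FALSE, cluster_cols = FALSE,
                           ...)
  invisible(ph)
}
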