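# Self-contained BLASTP stand-in: exact Smith-Waterman local alignment with
# affine gaps, Karlin-Altschul E-values, all-vs-all search between reduced
# proteomes, and mutual-best-hit calling.

#' Smith-Waterman local alignment score
#'
#' Optimal local alignment score under the scheme's substitution matrix with
#' affine gaps (a gap of length L costs `gap_open + L * gap_extend`).
#' Symmetric in its arguments; an empty sequence scores 0 by convention.
#'
#' @param a,b Amino-acid sequences (single strings).
#' @param scheme A [scoring_scheme()].
#' @return Integer score (>= 0).
#' @export
local_align_score <- function(a, b, scheme = scoring_scheme()) {
  stopifnot(is.character(a), is.character(b), length(a) == 1, length(b) == 1)
  if (!nzchar(a) || !nzchar(b)) return(0L)
  .sw_score_pair_cpp(a, b, scheme$matrix, scheme$gap_open, scheme$gap_extend)
}

# Raw score matrix between two named sequence vectors (genes x genes).
.score_matrix <- function(qseqs, sseqs, scheme) {
  m <- .sw_score_matrix_cpp(unname(qseqs), unname(sseqs), scheme$matrix,
                            scheme$gap_open, scheme$gap_extend)
  dimnames(m) <- list(names(qseqs), names(sseqs))
  m
}

.empty_hits <- function() {
  data.frame(query_species = character(), query_gene = character(),
             subject_species = character(), subject_gene = character(),
             score = integer(), evalue = numeric(),
             stringsAsFactors = FALSE)
}

#' All-vs-all similarity search between two proteomes
#'
#' Aligns every gene of the query proteome against every gene of the subject
#' proteome and reports each cross-gene pair whose Karlin-Altschul E-value is
#' at or below `evalue_max`. The database length `n` in the E-value is the
#' summed length of the subject's reduced proteome, mirroring the BLAST
#' database-length convention. Output rows are ordered by query gene then
#' subject gene. Self-pairs are excluded when query and subject are the same
#' species.
#'
#' @param query,subject Reduced [proteome()]s (one isoform per gene).
#' @param scheme A [scoring_scheme()].
#' @param evalue_max Maximum E-value for a pair to be reported.
#' @return Data frame of similarity hits with columns `query_species`,
#'   `query_gene`, `subject_species`, `subject_gene`, `score`, `evalue`.
#' @export
all_vs_all <- function(query, subject, scheme = scoring_scheme(),
                       evalue_max = 1e-4) {
  if (!is_reduced(query) || !is_reduced(subject))
    stop("all_vs_all requires isoform-reduced proteomes")
  qs <- proteome_sequences(query)
  ss <- proteome_sequences(subject)
  if (!length(qs) || !length(ss) || evalue_max <= 0) return(.empty_hits())
  sc <- .score_matrix(qs, ss, scheme)
  n_db <- sum(nchar(ss))
  m_len <- nchar(qs)
  ev <- scheme$K * outer(m_len, rep(n_db, length(ss))) *
    exp(-scheme$lambda * sc)
  keep <- ev <= evalue_max
  if (query$species_id == subject$species_id) {
    same <- outer(names(qs), names(ss), `==`)
    keep <- keep & !same
  }
  idx <- which(keep, arr.ind = TRUE)
  if (!nrow(idx)) return(.empty_hits())
  h <- data.frame(query_species = query$species_id,
                  query_gene = names(qs)[idx[, 1]],
                  subject_species = subject$species_id,
                  subject_gene = names(ss)[idx[, 2]],
                  score = sc[idx], evalue = ev[idx],
                  stringsAsFactors = FALSE)
  h[order(h$query_gene, h$subject_gene), , drop = FALSE]
}

# Best subject per query under the deterministic tie rule:
# max score, then min E-value, then lexicographically smallest subject gene.
.best_by_query <- function(hits) {
  if (!nrow(hits)) return(hits)
  o <- order(hits$query_gene, -hits$score, hits$evalue, hits$subject_gene)
  h <- hits[o, , drop = FALSE]
  h[!duplicated(h$query_gene), , drop = FALSE]
}

#' Mutual best hits between two proteomes
#'
#' Given hit lists in both directions for a species pair, returns gene pairs
#' `(g_a, g_b)` where each is the other's best hit. "Best" means highest
#' score, with ties broken by smallest E-value and then lexicographically
#' smallest subject gene, so the result is deterministic.
#'
#' @param hits_ab Hits with species A as query, B as subject.
#' @param hits_ba Hits with species B as query, A as subject.
#' @return Data frame with columns `species_a`, `gene_a`, `species_b`,
#'   `gene_b`, `score`, sorted by `gene_a`.
#' @export
mutual_best_hits <- function(hits_ab, hits_ba) {
  empty <- data.frame(species_a = character(), gene_a = character(),
                      species_b = character(), gene_b = character(),
                      score = integer(), stringsAsFactors = FALSE)
  if (!nrow(hits_ab) || !nrow(hits_ba)) return(empty)
  ba <- .best_by_query(hits_ab)
  bb <- .best_by_query(hits_ba)
  back <- setNames(bb$subject_gene, bb$query_gene)
  keep <- !is.na(back[ba$subject_gene]) &
    back[ba$subject_gene] == ba$query_gene
  ba <- ba[keep, , drop = FALSE]
  if (!nrow(ba)) return(empty)
  out <- data.frame(species_a = ba$query_species, gene_a = ba$query_gene,
                    species_b = ba$subject_species, gene_b = ba$subject_gene,
                    score = ba$score, stringsAsFactors = FALSE)
  out <- out[order(out$gene_a), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write similarity hits as BLAST tabular (outfmt 6 style) TSV
#'
#' Columns: qseqid, sseqid, pident, length, mismatch, gapopen, qstart, qend,
#' sstart, send, evalue, bitscore. The alignment-detail columns that the
#' screen does not use are written as 0 placeholders; the bitscore column
#' carries the raw Smith-Waterman score, so real BLASTP output is drop-in
#' substitutable via [read_hits_tsv()].
#'
#' @param hits Hit data frame from [all_vs_all()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  d <- data.frame(qseqid = paste(hits$query_species, hits$query_gene, sep = "|"),
                  sseqid = paste(hits$subject_species, hits$subject_gene, sep = "|"),
                  pident = 0, length = 0, mismatch = 0, gapopen = 0,
                  qstart = 0, qend = 0, sstart = 0, send = 0,
                  evalue = hits$evalue, bitscore = hits$score)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read similarity hits from BLAST tabular (outfmt 6) TSV
#'
#' Accepts either the package's `species|gene` sequence ids or plain ids
#' (then `query_species`/`subject_species` must be supplied).
#'
#' @param path TSV path (12 columns, no header).
#' @param query_species,subject_species Species ids used when sequence ids do
#'   not embed them.
#' @return Hit data frame as produced by [all_vs_all()].
#' @export
read_hits_tsv <- function(path, query_species = NULL, subject_species = NULL) {
  d <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(d) < 12) stop("expected >= 12 tab-separated columns (outfmt 6)")
  split_id <- function(ids, species) {
    parts <- strsplit(ids, "|", fixed = TRUE)
    if (all(lengths(parts) >= 2)) {
      list(species = vapply(parts, `[`, character(1), 1),
           gene = vapply(parts, `[`, character(1), 2))
    } else {
      if (is.null(species)) stop("plain sequence ids need an explicit species")
      list(species = rep(species, length(ids)), gene = ids)
    }
  }
  q <- split_id(d[[1]], query_species)
  s <- split_id(d[[2]], subject_species)
  data.frame(query_species = q$species, query_gene = q$gene,
             subject_species = s$species, subject_gene = s$gene,
             score = d[[12]], evalue = d[[11]], stringsAsFactors = FALSE)
}
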