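# Proteome container and FASTA input/output.
#
# A proteome holds one species' protein sequences organised as
# gene -> isoforms, plus the species' regeneration-ability class
# (WBR / HRA / LRA / CONFIRM).

.reg_classes <- c("WBR", "HRA", "LRA", "CONFIRM")

#' Construct a proteome
#'
#' @param species_id Short species identifier.
#' @param reg_class One of `"WBR"`, `"HRA"`, `"LRA"`, `"CONFIRM"`.
#' @param genes Named list mapping gene id to a named character vector of
#'   amino-acid sequences (names are isoform ids).
#' @return An object of class `proteome`.
#' @export
proteome <- function(species_id, reg_class, genes) {
  reg_class <- match.arg(reg_class, .reg_classes)
  if (!is.list(genes) || (length(genes) && is.null(names(genes))))
    stop("genes must be a named list of isoform vectors")
  if (anyDuplicated(names(genes)))
    stop("gene ids must be unique within a proteome")
  p <- structure(list(species_id = species_id, reg_class = reg_class,
                      genes = genes),
                 class = "proteome")
  validate_proteome(p)
  p
}

#' @export
print.proteome <- function(x, ...) {
  n_iso <- sum(lengths(x$genes))
  cat(sprintf("<proteome> %s [%s]: %d genes, %d isoforms\n",
              x$species_id, x$reg_class, length(x$genes), n_iso))
  invisible(x)
}

#' Validate a proteome's invariants
#'
#' Sequences must be nonempty, uppercase, and drawn from the 20-letter
#' amino-acid alphabet (X tolerated); every gene needs at least one isoform.
#'
#' @param p A [proteome()].
#' @return `p`, invisibly; errors otherwise.
#' @export
validate_proteome <- function(p) {
  stopifnot(inherits(p, "proteome"))
  if (length(p$genes) == 0) return(invisible(p))
  if (any(lengths(p$genes) == 0))
    stop("gene with zero isoforms in proteome ", p$species_id)
  seqs <- unlist(p$genes, use.names = FALSE)
  if (any(!nzchar(seqs))) stop("empty sequence in proteome ", p$species_id)
  bad <- grepl("[^ARNDCQEGHILKMFPSTWYVX]", seqs)
  if (any(bad))
    stop("sequence with characters outside the amino-acid alphabet in ",
         p$species_id)
  invisible(p)
}

#' Keep only the longest isoform of each gene
#'
#' Reduces a proteome to one representative sequence per gene: a
#' maximal-length isoform, with length ties broken by the lexicographically
#' smallest isoform id. This mirrors the standard practice of using the
#' longest protein product for cross-species similarity searches.
#'
#' @param p A [proteome()].
#' @return A reduced `proteome` (one isoform per gene).
#' @export
select_longest_isoform <- function(p) {
  stopifnot(inherits(p, "proteome"))
  if (any(lengths(p$genes) == 0))
    stop("gene with zero isoforms in proteome ", p$species_id)
  p$genes <- lapply(p$genes, function(iso) {
    len <- nchar(iso)
    cand <- iso[len == max(len)]
    cand <- cand[order(names(cand))]
    cand[1]
  })
  p
}

#' Is a proteome reduced to one isoform per gene?
#' @param p A [proteome()].
#' @return Logical scalar.
#' @export
is_reduced <- function(p) {
  all(lengths(p$genes) == 1)
}

#' Flat named vector of one sequence per gene
#'
#' @param p A reduced [proteome()] (see [select_longest_isoform()]).
#' @return Named character vector, gene id -> sequence, in gene-id order.
#' @export
proteome_sequences <- function(p) {
  if (!is_reduced(p))
    stop("proteome ", p$species_id, " has genes with multiple isoforms; ",
         "call select_longest_isoform() first")
  s <- vapply(p$genes, function(iso) iso[[1]], character(1))
  s[order(names(s))]
}

#' Write a proteome as FASTA
#'
#' Headers follow the convention `>{species_id}|{gene_id}|{isoform_id}`.
#'
#' @param p A [proteome()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_proteome_fasta <- function(p, path) {
  stopifnot(inherits(p, "proteome"))
  gene_ids <- names(p$genes)
  seqs <- unlist(p$genes, use.names = FALSE)
  iso_ids <- unlist(lapply(p$genes, names), use.names = FALSE)
  hdr <- paste(p$species_id, rep(gene_ids, lengths(p$genes)), iso_ids,
               sep = "|")
  x <- Biostrings::AAStringSet(setNames(seqs, hdr))
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Read a proteome from FASTA
#'
#' Accepts either the package's `species|gene|isoform` header convention or
#' plain headers (in which case each record becomes a single-isoform gene).
#'
#' @param path FASTA file path.
#' @param species_id Species id; defaults to the one found in the headers.
#' @param reg_class Regeneration-ability class of the species.
#' @return A [proteome()].
#' @export
read_proteome_fasta <- function(path, species_id = NULL, reg_class = "WBR") {
  x <- Biostrings::readAAStringSet(path)
  hdr <- sub("\\s.*$", "", names(x))
  seqs <- as.character(x)
  parts <- strsplit(hdr, "|", fixed = TRUE)
  structured <- all(lengths(parts) == 3)
  if (structured) {
    sp <- unique(vapply(parts, `[`, character(1), 1))
    if (length(sp) != 1)
      stop("FASTA mixes species ids: ", paste(sp, collapse = ", "))
    if (is.null(species_id)) species_id <- sp
    gene <- vapply(parts, `[`, character(1), 2)
    iso <- vapply(parts, `[`, character(1), 3)
  } else {
    if (is.null(species_id))
      stop("species_id required for FASTA without species|gene|isoform headers")
    gene <- hdr
    iso <- rep("t1", length(hdr))
  }
  genes <- split(setNames(seqs, iso), gene)
  proteome(species_id, reg_class, genes)
}

#' Read a species-class table
#'
#' A TSV with columns `species_id`, `reg_class` and optionally `fasta_path`,
#' declaring the regeneration-ability class of each species in a screen.
#'
#' @param path TSV file path.
#' @return A data frame with the validated columns.
#' @export
read_species_table <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("species_id", "reg_class") %in% names(d)))
    stop("species table needs species_id and reg_class columns")
  bad <- setdiff(unique(d$reg_class), .reg_classes)
  if (length(bad))
    stop("unknown reg_class value(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(d$species_id)) stop("duplicate species ids in table")
  d
}
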