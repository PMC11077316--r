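# Synthetic species sets, promoters, and expression matrices with planted
# ground truth. The generator emulates the statistical structure the
# conservation screen assumes -- shared gene families, families private to
# high-regenerative species, diverged low-regenerative paralogs, planted
# promoter motifs and phase-structured amputation time courses -- so every
# downstream stage can be validated against known truth.

.expression_phases <- c("wound_response", "proliferative", "differentiation",
                        "late_arrested", "flat")

#' Declare one species of a synthetic scenario
#'
#' @param species_id Unique short id.
#' @param reg_class `"WBR"`, `"HRA"`, `"LRA"` or `"CONFIRM"`. CONFIRM species
#'   stand in for the second (confirmation) screening panel.
#' @param n_background_families Number of background gene families shared by
#'   all species of the scenario.
#' @param divergence Per-site substitution probability from the family
#'   ancestor sequence (>= 0).
#' @return An object of class `species_spec`.
#' @export
species_spec <- function(species_id, reg_class, n_background_families = 200,
                         divergence = 0.1) {
  reg_class <- match.arg(reg_class, .reg_classes)
  if (divergence < 0) stop("divergence must be >= 0")
  structure(list(species_id = species_id, reg_class = reg_class,
                 n_background_families = as.integer(n_background_families),
                 divergence = divergence),
            class = "species_spec")
}

#' Mutation model for sequence simulation
#'
#' Substitutions replace a residue with a uniformly chosen different symbol
#' (no rate matrix: the screen depends on score gaps, not realistic
#' evolution). Indels are single-symbol insertions/deletions.
#'
#' @param substitution_rate Default per-site substitution probability, used
#'   where a species does not supply its own divergence.
#' @param indel_rate Per-site indel probability (split evenly between
#'   insertion and deletion).
#' @param alphabet `"aa"` (20 amino acids) or `"dna"` (ACGT).
#' @return An object of class `mutation_model`.
#' @export
mutation_model <- function(substitution_rate = 0.1, indel_rate = 0.005,
                           alphabet = c("aa", "dna")) {
  alphabet <- match.arg(alphabet)
  if (substitution_rate < 0 || substitution_rate > 1 ||
      indel_rate < 0 || indel_rate > 1)
    stop("rates must lie in [0, 1]")
  structure(list(substitution_rate = substitution_rate,
                 indel_rate = indel_rate,
                 alphabet = alphabet,
                 symbols = if (alphabet == "aa") .aa_order
                           else c("A", "C", "G", "T")),
            class = "mutation_model")
}

# Mutate a character vector of residues: substitutions at sub_rate (uniform
# different symbol), then single-residue indels at indel_rate.
.mutate_seq <- function(x, sub_rate, model) {
  n <- length(x)
  syms <- model$symbols
  ns <- length(syms)
  if (sub_rate > 0) {
    hit <- which(runif(n) < sub_rate)
    if (length(hit)) {
      # uniform over the ns-1 other symbols
      cur <- match(x[hit], syms)
      shift <- sample.int(ns - 1, length(hit), replace = TRUE)
      x[hit] <- syms[((cur - 1 + shift) %% ns) + 1]
    }
  }
  if (model$indel_rate > 0 && n > 2) {
    u <- runif(n)
    del <- u < model$indel_rate / 2
    ins <- u >= model$indel_rate / 2 & u < model$indel_rate
    if (any(del) || any(ins)) {
      pieces <- x
      pieces[del] <- ""
      if (any(ins)) {
        extra <- sample(syms, sum(ins), replace = TRUE)
        pieces[ins] <- paste0(pieces[ins], extra)
      }
      y <- strsplit(paste(pieces, collapse = ""), "")[[1]]
      if (length(y) >= 2) x <- y
    }
  }
  x
}

.rand_seq <- function(len, model) {
  sample(model$symbols, len, replace = TRUE)
}

# Build 2-4 isoforms for a gene: t1 is the canonical sequence; the others are
# truncations (random terminal loss) or extensions (random C-terminal tail),
# exercising the longest-isoform selection rule.
.make_isoforms <- function(seq_chr, model) {
  k <- sample(2:4, 1)
  isos <- character(k)
  isos[1] <- paste(seq_chr, collapse = "")
  n <- length(seq_chr)
  for (i in 2:k) {
    if (runif(1) < 0.75) { # truncation
      cut <- ceiling(n * runif(1, 0.2, 0.5))
      if (runif(1) < 0.5) isos[i] <- paste(seq_chr[-seq_len(cut)], collapse = "")
      else isos[i] <- paste(seq_chr[seq_len(n - cut)], collapse = "")
    } else {              # extension
      tail_len <- sample(10:30, 1)
      isos[i] <- paste(c(seq_chr, .rand_seq(tail_len, model)), collapse = "")
    }
  }
  setNames(isos, paste0("t", seq_len(k)))
}

#' Simulate a species set with planted gene-family ground truth
#'
#' Generates one proteome per species from common family ancestors:
#' \itemize{
#'   \item background families have one ortholog in every species;
#'   \item "CBR" families (the planted candidates) have members only in WBR
#'     species and a random subset of HRA species;
#'   \item paralog families have members in all WBR species plus one strongly
#'     diverged copy in a low-regenerative (LRA) species. The LRA copy keeps
#'     a homologous domain (default up to 120 residues, mutated at
#'     `paralog_divergence_factor` times the species divergence) embedded in
#'     otherwise random sequence, so it scores well below true orthologs yet
#'     remains detectable by the loss filter and usable for gene trees.
#' }
#' A random subset of genes receives 2-4 isoforms (truncations/extensions) to
#' exercise the longest-isoform rule. Fully reproducible from `seed`.
#'
#' @param specs List of [species_spec()]s (>= 2 WBR and >= 1 LRA species).
#' @param n_cbr Number of planted candidate families.
#' @param n_paralog Number of paralog families.
#' @param model A [mutation_model()].
#' @param seed Integer seed.
#' @param len_range Family ancestor length range in residues.
#' @param cbr_hra_prob Probability that a given HRA species carries a given
#'   planted family.
#' @param isoform_prob Probability that a gene gets multiple isoforms.
#' @param paralog_domain_len Maximum length of the conserved domain retained
#'   by an LRA paralog copy.
#' @param paralog_divergence_factor Multiplier on the LRA species' divergence
#'   applied to the paralog domain (capped at 0.95).
#' @param check_separation Verify empirically that every planted family's
#'   weakest WBR-WBR score exceeds every paralog family's strongest WBR-LRA
#'   score (warns if violated).
#' @return A list with `proteomes` (named list of [proteome()]s) and `truth`
#'   (a `scenario_truth` list: family id sets, HRA presence pattern, the LRA
#'   species carrying each paralog, planted motif targets, and an expression
#'   phase per candidate gene).
#' @export
simulate_species_set <- function(specs, n_cbr, n_paralog,
                                 model = mutation_model(), seed = 1,
                                 len_range = c(120, 600),
                                 cbr_hra_prob = 0.7,
                                 isoform_prob = 0.15,
                                 paralog_domain_len = 120,
                                 paralog_divergence_factor = 3,
                                 check_separation = TRUE) {
  ids <- vapply(specs, function(s) s$species_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate species ids")
  classes <- vapply(specs, function(s) s$reg_class, character(1))
  if (sum(classes == "WBR") < 2) stop("need at least two WBR species")
  if (sum(classes == "LRA") < 1) stop("need at least one LRA species")
  if (n_cbr < 0 || n_paralog < 0) stop("family counts must be >= 0")
  n_bg <- unique(vapply(specs, function(s) s$n_background_families,
                        integer(1)))
  if (length(n_bg) != 1)
    stop("all species must share the same n_background_families")
  set.seed(as.integer(seed))

  wbr <- ids[classes == "WBR"]
  hra <- ids[classes == "HRA"]
  lra <- ids[classes == "LRA"]
  div <- setNames(vapply(specs, function(s) s$divergence, numeric(1)), ids)

  n_fam <- n_bg + n_cbr + n_paralog
  fam_ids <- sprintf("F%04d", seq_len(n_fam))
  bg_ids <- fam_ids[seq_len(n_bg)]
  cbr_ids <- if (n_cbr > 0) fam_ids[n_bg + seq_len(n_cbr)] else character()
  par_ids <- if (n_paralog > 0) fam_ids[n_bg + n_cbr + seq_len(n_paralog)]
             else character()

  genes <- setNames(vector("list", length(ids)), ids)
  for (s in ids) genes[[s]] <- list()
  hra_presence <- setNames(vector("list", n_cbr), cbr_ids)
  paralog_lra <- setNames(character(n_paralog), par_ids)

  add_gene <- function(sp, fam, seq_chr) {
    if (runif(1) < isoform_prob) {
      genes[[sp]][[fam]] <<- .make_isoforms(seq_chr, model)
    } else {
      genes[[sp]][[fam]] <<- setNames(paste(seq_chr, collapse = ""), "t1")
    }
  }

  sep_cbr <- list()   # per planted family: WBR member sequences
  sep_par <- list()   # per paralog family: WBR members + LRA copy

  for (fam in fam_ids) {
    L <- sample(seq(len_range[1], len_range[2]), 1)
    anc <- .rand_seq(L, model)
    if (fam %in% bg_ids) {
      for (sp in ids) add_gene(sp, fam, .mutate_seq(anc, div[[sp]], model))
    } else if (fam %in% cbr_ids) {
      members <- character()
      for (sp in wbr) {
        m <- .mutate_seq(anc, div[[sp]], model)
        add_gene(sp, fam, m)
        members <- c(members, paste(m, collapse = ""))
      }
      in_hra <- hra[runif(length(hra)) < cbr_hra_prob]
      hra_presence[[fam]] <- in_hra
      for (sp in in_hra) add_gene(sp, fam, .mutate_seq(anc, div[[sp]], model))
      sep_cbr[[fam]] <- members
    } else { # paralog family: WBR members + one diverged LRA copy
      members <- character()
      for (sp in wbr) {
        m <- .mutate_seq(anc, div[[sp]], model)
        add_gene(sp, fam, m)
        members <- c(members, paste(m, collapse = ""))
      }
      sp_lra <- if (length(lra) == 1) lra else sample(lra, 1)
      paralog_lra[[fam]] <- sp_lra
      dlen <- min(paralog_domain_len, L)
      dstart <- if (L > dlen) sample.int(L - dlen + 1, 1) else 1L
      dom <- anc[dstart:(dstart + dlen - 1)]
      pdiv <- min(0.95, paralog_divergence_factor * div[[sp_lra]])
      dom <- .mutate_seq(dom, pdiv, model)
      rest_n <- max(0L, L - length(dom))
      left_n <- if (rest_n > 0) sample.int(rest_n + 1L, 1) - 1L else 0L
      par_seq <- c(.rand_seq(left_n, model), dom,
                   .rand_seq(rest_n - left_n, model))
      add_gene(sp_lra, fam, par_seq)
      sep_par[[fam]] <- list(wbr = members,
                             lra = paste(par_seq, collapse = ""))
    }
  }

  proteomes <- setNames(vector("list", length(ids)), ids)
  for (i in seq_along(ids)) {
    g <- genes[[ids[i]]]
    proteomes[[ids[i]]] <- proteome(ids[i], classes[i],
                                    g[order(names(g))])
  }

  # expression phases for the planted candidate genes, cycling all phases
  phase_by_gene <- if (n_cbr > 0)
    setNames(rep_len(.expression_phases, n_cbr), cbr_ids) else
    setNames(character(), character())

  truth <- structure(list(
    background_family_ids = bg_ids,
    cbr_family_ids = cbr_ids,
    paralog_family_ids = par_ids,
    hra_presence = hra_presence,
    paralog_lra_species = paralog_lra,
    motif_target_gene_ids = cbr_ids,
    expression_phase_by_gene = phase_by_gene,
    seed = as.integer(seed)), class = "scenario_truth")

  if (check_separation && length(sep_cbr) && length(sep_par)) {
    scheme <- scoring_scheme()
    min_cbr <- min(vapply(sep_cbr, function(m) {
      best <- 0L
      for (i in seq_along(m)[-length(m)])
        for (j in (i + 1):length(m))
          best <- max(best, local_align_score(m[i], m[j], scheme))
      best
    }, numeric(1)))
    max_par <- max(vapply(sep_par, function(p) {
      max(vapply(p$wbr, function(w)
        local_align_score(w, p$lra, scheme), numeric(1)))
    }, numeric(1)))
    truth$separation <- c(min_cbr_wbr_score = min_cbr,
                          max_paralog_lra_score = max_par)
    if (min_cbr <= max_par)
      warning("paralog separation violated: weakest planted-family score (",
              min_cbr, ") <= strongest paralog score (", max_par, ")")
  }

  list(proteomes = proteomes, truth = truth)
}

#' Simulate promoter sequences with a planted motif
#'
#' Background sequence is i.i.d. uniform ACGT. With the per-gene plant
#' probability (different for target and background genes), one copy of the
#' motif consensus is inserted at a uniform position on a uniform strand
#' (forward or reverse complement).
#'
#' @param gene_ids Character vector of promoter owners.
#' @param target_ids Subset of `gene_ids` planted at `plant_rate_target`.
#' @param motif_consensus Nucleotide string to plant.
#' @param plant_rate_target,plant_rate_background Per-gene plant
#'   probabilities; the target rate must be at least the background rate.
#' @param length Promoter length in bp (>= motif length).
#' @param seed Integer seed.
#' @return Named character vector of sequences with attribute `planted`
#'   (named logical: which genes actually received the motif).
#' @export
simulate_promoters <- function(gene_ids, target_ids, motif_consensus,
                               plant_rate_target, plant_rate_background,
                               length, seed = 1) {
  if (!all(target_ids %in% gene_ids))
    stop("target_ids must be a subset of gene_ids")
  if (plant_rate_target < plant_rate_background)
    stop("plant_rate_target must be >= plant_rate_background")
  motif <- toupper(motif_consensus)
  w <- nchar(motif)
  if (length < w) stop("promoter length shorter than motif")
  if (grepl("[^ACGT]", motif)) stop("motif must be over ACGT")
  set.seed(as.integer(seed))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(motif)))
  n <- base::length(gene_ids)
  rate <- ifelse(gene_ids %in% target_ids, plant_rate_target,
                 plant_rate_background)
  seqs <- character(n)
  planted <- logical(n)
  bases <- c("A", "C", "G", "T")
  for (i in seq_len(n)) {
    s <- sample(bases, length, replace = TRUE)
    if (runif(1) < rate[i]) {
      planted[i] <- TRUE
      pos <- sample.int(length - w + 1L, 1)
      ins <- if (runif(1) < 0.5) motif else rc
      s[pos:(pos + w - 1L)] <- strsplit(ins, "")[[1]]
    }
    seqs[i] <- paste(s, collapse = "")
  }
  structure(setNames(seqs, gene_ids), planted = setNames(planted, gene_ids))
}

#' Simulate an amputation time-course FPKM matrix
#'
#' Each gene follows a phase template on a baseline of `baseline` FPKM with
#' elevated windows at `2^log2_amplitude` times baseline:
#' \itemize{
#'   \item `wound_response`: elevated from the first post-amputation
#'     timepoint (before 6 h) onward;
#'   \item `proliferative`: elevated from 24 h onward;
#'   \item `differentiation`: elevated only after 96 h (4 d);
#'   \item `late_arrested`: elevated from 24 h through 96 h, then back to
#'     baseline;
#'   \item `flat`: constant.
#' }
#' Multiplicative lognormal noise of standard deviation `noise_sd` (log2
#' units) is applied to every entry; values are strictly positive.
#'
#' @param phase_by_gene Named character vector gene -> phase label.
#' @param timepoints Hours post amputation; must include 0 and cover the
#'   early (< 6 h), mid (24 h - 4 d) and late (> 4 d) windows.
#' @param noise_sd Noise standard deviation in log2 units.
#' @param seed Integer seed.
#' @param baseline Baseline FPKM.
#' @param log2_amplitude Elevation of active windows in log2 units.
#' @return Numeric genes x timepoints matrix with columns `h<hours>`.
#' @export
simulate_expression <- function(phase_by_gene,
                                timepoints = c(0, 3, 6, 12, 24, 48, 96, 120, 168),
                                noise_sd = 0, seed = 1,
                                baseline = 10, log2_amplitude = 2) {
  bad <- setdiff(unique(phase_by_gene), .expression_phases)
  if (length(bad)) stop("unknown phase label(s): ", paste(bad, collapse = ", "))
  if (is.null(names(phase_by_gene)) || !length(phase_by_gene))
    stop("phase_by_gene must be a nonempty named vector")
  tp <- sort(unique(timepoints))
  if (!0 %in% tp) stop("timepoints must include 0")
  if (!any(tp > 0 & tp < 6) || !any(tp >= 24 & tp <= 96) || !any(tp > 96))
    stop("timepoints must span early (<6 h), mid (24-96 h) and late (>96 h) windows")
  set.seed(as.integer(seed))
  elevated <- function(phase, t) switch(phase,
    wound_response  = t > 0,
    proliferative   = t >= 24,
    differentiation = t > 96,
    late_arrested   = t >= 24 & t <= 96,
    flat            = rep(FALSE, length(t)))
  genes <- names(phase_by_gene)
  m <- matrix(0, length(genes), length(tp),
              dimnames = list(genes, paste0("h", tp)))
  for (i in seq_along(genes)) {
    tmpl <- baseline * 2^(log2_amplitude * elevated(phase_by_gene[[i]], tp))
    noise <- if (noise_sd > 0) 2^rnorm(length(tp), 0, noise_sd) else 1
    m[i, ] <- tmpl * noise
  }
  m
}

#' Write scenario truth tables as TSV
#'
#' Emits `families.tsv` (family id, role, HRA presence / LRA paralog carrier)
#' and `phases.tsv` (gene, planted expression phase) under `dir`.
#'
#' @param truth A `scenario_truth` from [simulate_species_set()].
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_truth_tsv <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fam <- rbind(
    data.frame(family_id = truth$background_family_ids, role = "background",
               detail = "", stringsAsFactors = FALSE),
    data.frame(family_id = truth$cbr_family_ids, role = "candidate",
               detail = vapply(truth$hra_presence, paste, character(1),
                               collapse = ","),
               stringsAsFactors = FALSE),
    data.frame(family_id = truth$paralog_family_ids, role = "paralog",
               detail = unname(truth$paralog_lra_species),
               stringsAsFactors = FALSE))
  p1 <- file.path(dir, "families.tsv")
  write.table(fam, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  ph <- data.frame(gene_id = names(truth$expression_phase_by_gene),
                   phase = unname(truth$expression_phase_by_gene),
                   stringsAsFactors = FALSE)
  p2 <- file.path(dir, "phases.tsv")
  write.table(ph, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2))
}
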