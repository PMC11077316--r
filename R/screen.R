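# Core inference of the screen: orthogroups conserved across all
# whole-body-regenerating (WBR) species, removal of groups with any homology
# in low-regenerative (LRA) species, confirmation against a second proteome
# panel, and collection of high-regenerative (HRA) orthologs into a
# presence/absence matrix.

#' Configuration of the conservation screen
#'
#' @param wbr,hra,lra,confirm Character vectors of species ids per
#'   regeneration-ability class (must be disjoint; `wbr` nonempty).
#' @param evalue_max_loss E-value at or below which a hit in an LRA or
#'   confirmation proteome disqualifies a group (default 1e-4).
#' @param score_min_hra Raw-score threshold for the HRA ortholog collection
#'   step; presence requires a mutual best hit with score strictly greater
#'   than this (default 100).
#' @param grouping `"clique"` (mutual-best-hit cliques across all WBR pairs,
#'   the default) or `"components"` (connected components of MBH edges, for
#'   sensitivity analysis).
#' @return An object of class `screen_config`.
#' @export
screen_config <- function(wbr, hra = character(), lra = character(),
                          confirm = character(), evalue_max_loss = 1e-4,
                          score_min_hra = 100,
                          grouping = c("clique", "components")) {
  grouping <- match.arg(grouping)
  all_ids <- c(wbr, hra, lra, confirm)
  if (anyDuplicated(all_ids))
    stop("species lists must be disjoint: ",
         paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "))
  if (!length(wbr)) stop("at least one WBR species required")
  if (evalue_max_loss <= 0) stop("evalue_max_loss must be positive")
  if (score_min_hra <= 0) stop("score_min_hra must be positive")
  structure(list(wbr = wbr, hra = hra, lra = lra, confirm = confirm,
                 evalue_max_loss = evalue_max_loss,
                 score_min_hra = score_min_hra, grouping = grouping),
            class = "screen_config")
}

.pair_key <- function(a, b) paste(sort(c(a, b)), collapse = "|")

#' Compute mutual best hits for every unordered pair of a species panel
#'
#' Convenience wrapper running [all_vs_all()] in both directions and
#' [mutual_best_hits()] for each pair.
#'
#' @param proteomes Named list of reduced [proteome()]s.
#' @param scheme A [scoring_scheme()].
#' @param evalue_max All-vs-all E-value cutoff.
#' @return Named list of MBH data frames, keyed `"spA|spB"` with the two ids
#'   sorted.
#' @export
pairwise_mbh <- function(proteomes, scheme = scoring_scheme(),
                         evalue_max = 1e-4) {
  ids <- names(proteomes)
  out <- list()
  if (length(ids) < 2) return(out)
  hits_from_scores <- function(sc, qsp, ssp, m_len, n_db, qn, sn) {
    ev <- scheme$K * (m_len %o% rep(n_db, length(sn))) *
      exp(-scheme$lambda * sc)
    idx <- which(ev <= evalue_max, arr.ind = TRUE)
    if (!nrow(idx)) return(.empty_hits())
    data.frame(query_species = qsp, query_gene = qn[idx[, 1]],
               subject_species = ssp, subject_gene = sn[idx[, 2]],
               score = sc[idx], evalue = ev[idx], stringsAsFactors = FALSE)
  }
  for (i in seq_len(length(ids) - 1)) {
    for (j in (i + 1):length(ids)) {
      a <- proteomes[[ids[i]]]
      b <- proteomes[[ids[j]]]
      qs <- proteome_sequences(a)
      ss <- proteome_sequences(b)
      # local alignment scores are symmetric: compute the matrix once and
      # derive both hit directions (database length differs per direction)
      sc <- .score_matrix(qs, ss, scheme)
      hab <- hits_from_scores(sc, a$species_id, b$species_id, nchar(qs),
                              sum(nchar(ss)), names(qs), names(ss))
      hba <- hits_from_scores(t(sc), b$species_id, a$species_id, nchar(ss),
                              sum(nchar(qs)), names(ss), names(qs))
      out[[.pair_key(ids[i], ids[j])]] <- mutual_best_hits(hab, hba)
    }
  }
  out
}

#' Build orthogroups conserved across all WBR species
#'
#' Under the default `"clique"` rule a group is emitted iff, for every pair
#' of WBR species, its two members are mutual best hits (triangle closure for
#' three species). Under `"components"` a group is a connected component of
#' the MBH graph containing at least one member per WBR species and at most
#' one per species. Each gene appears in at most one group. Group ids are
#' deterministic: groups sort by their anchor gene (the member from the first
#' WBR species).
#'
#' @param mbh Named list of MBH data frames keyed `"spA|spB"` (sorted ids),
#'   as from [pairwise_mbh()]; one entry per unordered WBR pair is required.
#' @param wbr_species Character vector of WBR species ids; the first one is
#'   the anchor species.
#' @param grouping `"clique"` or `"components"`.
#' @return Long-format data frame (`group_id`, `species_id`, `gene_id`) with
#'   attribute `anchor_species`.
#' @export
build_wbr_orthogroups <- function(mbh, wbr_species,
                                  grouping = c("clique", "components")) {
  grouping <- match.arg(grouping)
  k <- length(wbr_species)
  if (k < 2) stop("need at least two WBR species")
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (is.null(mbh[[.pair_key(wbr_species[i], wbr_species[j])]]))
      stop("missing MBH list for species pair ",
           wbr_species[i], " / ", wbr_species[j])
  }
  # partner lookup per ordered pair: partner[[sp_a]][[sp_b]][gene_a] -> gene_b
  partner <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    a <- wbr_species[i]; b <- wbr_species[j]
    m <- mbh[[.pair_key(a, b)]]
    if (!nrow(m)) {
      ga <- gb <- setNames(character(), character())
    } else if (m$species_a[1] == a) {
      ga <- setNames(m$gene_b, m$gene_a); gb <- setNames(m$gene_a, m$gene_b)
    } else {
      ga <- setNames(m$gene_a, m$gene_b); gb <- setNames(m$gene_b, m$gene_a)
    }
    partner[[a]][[b]] <- ga
    partner[[b]][[a]] <- gb
  }
  anchor_sp <- wbr_species[1]
  groups <- list()
  if (grouping == "clique") {
    anchor_genes <- sort(unique(names(partner[[anchor_sp]][[wbr_species[2]]])))
    for (g1 in anchor_genes) {
      members <- setNames(character(k), wbr_species)
      members[anchor_sp] <- g1
      ok <- TRUE
      for (s in wbr_species[-1]) {
        p <- partner[[anchor_sp]][[s]][g1]
        if (is.na(p)) { ok <- FALSE; break }
        members[s] <- p
      }
      if (!ok) next
      # clique closure: every non-anchor pair must also be MBH
      for (i in seq_len(k - 1)) {
        if (!ok) break
        for (j in (i + 1):k) {
          if (i == 1) next # anchor pairs already verified
          a <- wbr_species[i]; b <- wbr_species[j]
          p <- partner[[a]][[b]][members[a]]
          if (is.na(p) || p != members[b]) { ok <- FALSE; break }
        }
      }
      if (ok) groups[[length(groups) + 1]] <- members
    }
  } else {
    # connected components of the MBH edge set over (species, gene) nodes
    nodes <- character()
    edges_a <- character(); edges_b <- character()
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      a <- wbr_species[i]; b <- wbr_species[j]
      pa <- partner[[a]][[b]]
      if (!length(pa)) next
      na <- paste(a, names(pa), sep = "\r")
      nb <- paste(b, unname(pa), sep = "\r")
      edges_a <- c(edges_a, na); edges_b <- c(edges_b, nb)
      nodes <- c(nodes, na, nb)
    }
    nodes <- sort(unique(nodes))
    comp <- seq_along(nodes)
    names(comp) <- nodes
    find <- function(x) { while (comp[x] != x) x <- comp[x]; x }
    for (e in seq_along(edges_a)) {
      ra <- find(match(edges_a[e], nodes)); rb <- find(match(edges_b[e], nodes))
      if (ra != rb) comp[rb] <- ra
    }
    roots <- vapply(seq_along(nodes), find, integer(1))
    for (r in unique(roots)) {
      ns <- nodes[roots == r]
      parts <- strsplit(ns, "\r", fixed = TRUE)
      sp <- vapply(parts, `[`, character(1), 1)
      gene <- vapply(parts, `[`, character(1), 2)
      if (anyDuplicated(sp)) next
      if (!all(wbr_species %in% sp)) next
      groups[[length(groups) + 1]] <- setNames(gene, sp)[wbr_species]
    }
  }
  if (!length(groups)) {
    out <- data.frame(group_id = character(), species_id = character(),
                      gene_id = character(), stringsAsFactors = FALSE)
    attr(out, "anchor_species") <- anchor_sp
    return(out)
  }
  anchors <- vapply(groups, function(m) m[[anchor_sp]], character(1))
  groups <- groups[order(anchors)]
  gid <- sprintf("OG%04d", seq_along(groups))
  out <- do.call(rbind, lapply(seq_along(groups), function(i) {
    data.frame(group_id = gid[i], species_id = names(groups[[i]]),
               gene_id = unname(groups[[i]]), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "anchor_species") <- anchor_sp
  out
}

# Split a long-format orthogroup table into a named list of member vectors.
.group_members <- function(groups) {
  if (!nrow(groups)) return(list())
  split(setNames(groups$gene_id, groups$species_id), groups$group_id)
}

.subset_groups <- function(groups, keep_ids) {
  out <- groups[groups$group_id %in% keep_ids, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "anchor_species") <- attr(groups, "anchor_species")
  out
}

#' Remove orthogroups with any homology in LRA proteomes
#'
#' Any-hit semantics: a group survives iff no member has any hit with
#' E-value at or below `config$evalue_max_loss` in any LRA proteome.
#'
#' @param groups Orthogroup table from [build_wbr_orthogroups()].
#' @param hits_wbr_to_lra Hit data frame(s) (or a list of them) from querying
#'   group members against LRA proteomes, e.g. via [all_vs_all()] or
#'   [scan_panel_hits()].
#' @param config A [screen_config()].
#' @return Surviving orthogroup table (rows unchanged), with attribute
#'   `removed` listing the group ids that were filtered out.
#' @export
filter_lost_in_lra <- function(groups, hits_wbr_to_lra, config) {
  if (is.data.frame(hits_wbr_to_lra)) hits_wbr_to_lra <- list(hits_wbr_to_lra)
  hits <- do.call(rbind, hits_wbr_to_lra)
  if (is.null(hits) || !nrow(hits)) {
    attr(groups, "removed") <- character()
    return(groups)
  }
  hot <- hits[hits$evalue <= config$evalue_max_loss, , drop = FALSE]
  key_hit <- unique(paste(hot$query_species, hot$query_gene, sep = "\r"))
  key_grp <- paste(groups$species_id, groups$gene_id, sep = "\r")
  removed <- unique(groups$group_id[key_grp %in% key_hit])
  out <- .subset_groups(groups, setdiff(unique(groups$group_id), removed))
  attr(out, "removed") <- removed
  out
}

#' Scan group members against a proteome panel, stopping at the first
#' disqualifying hit
#'
#' For each orthogroup, aligns its members (in species order) against each
#' panel proteome (genes in id order) and records the first hit with
#' E-value at or below `evalue_max`. Because the loss filter uses any-hit
#' semantics, one such hit settles a group's fate, which makes this scan much
#' cheaper than a full all-vs-all while producing the same surviving set.
#'
#' @param groups Orthogroup table.
#' @param member_proteomes Named list of reduced proteomes providing the
#'   member sequences (the WBR species).
#' @param panel_proteomes Named list of reduced proteomes to scan against
#'   (LRA or confirmation species).
#' @param scheme A [scoring_scheme()].
#' @param evalue_max Disqualification threshold.
#' @return Hit data frame (one row per removed group) usable directly with
#'   [filter_lost_in_lra()].
#' @export
scan_panel_hits <- function(groups, member_proteomes, panel_proteomes,
                            scheme = scoring_scheme(), evalue_max = 1e-4) {
  members <- .group_members(groups)
  panel_seqs <- lapply(panel_proteomes, proteome_sequences)
  panel_n <- vapply(panel_seqs, function(s) sum(nchar(s)), numeric(1))
  rows <- list()
  for (gid in names(members)) {
    mem <- members[[gid]]
    found <- FALSE
    for (sp in names(mem)) {
      if (found) break
      seq <- proteome_sequences(member_proteomes[[sp]])[[mem[[sp]]]]
      m_len <- nchar(seq)
      for (psp in names(panel_seqs)) {
        thr <- .score_for_evalue(evalue_max, m_len, panel_n[[psp]], scheme)
        hit <- .sw_first_hit_cpp(seq, unname(panel_seqs[[psp]]), thr,
                                 scheme$matrix, scheme$gap_open,
                                 scheme$gap_extend)
        if (hit$index > 0) {
          sc <- hit$score
          rows[[length(rows) + 1]] <- data.frame(
            query_species = sp, query_gene = mem[[sp]],
            subject_species = psp,
            subject_gene = names(panel_seqs[[psp]])[hit$index],
            score = sc,
            evalue = estimate_evalue(sc, m_len, panel_n[[psp]], scheme),
            group_id = gid, stringsAsFactors = FALSE)
          found <- TRUE
          break
        }
      }
    }
  }
  if (!length(rows)) {
    h <- .empty_hits()
    h$group_id <- character()
    return(h)
  }
  do.call(rbind, rows)
}

#' Confirm candidate absence against a second proteome panel
#'
#' Same semantics as [filter_lost_in_lra()] but against the confirmation
#' panel (a local, reproducible stand-in for screening candidates against a
#' comprehensive sequence database). Emits a per-group audit log of any
#' removing hit as attribute `audit`.
#'
#' @param groups Orthogroup table of current survivors.
#' @param confirm_proteomes Named list of reduced confirmation proteomes.
#' @param config A [screen_config()].
#' @param member_proteomes Named list of reduced proteomes holding the group
#'   members' sequences.
#' @param scheme A [scoring_scheme()].
#' @return Surviving orthogroup table with attributes `removed` and `audit`.
#' @export
confirm_absence <- function(groups, confirm_proteomes, config,
                            member_proteomes, scheme = scoring_scheme()) {
  if (!length(confirm_proteomes)) {
    warning("empty confirmation panel; groups passed through unchanged")
    attr(groups, "removed") <- character()
    attr(groups, "audit") <- data.frame()
    return(groups)
  }
  hits <- scan_panel_hits(groups, member_proteomes, confirm_proteomes,
                          scheme, config$evalue_max_loss)
  out <- filter_lost_in_lra(groups, hits, config)
  attr(out, "audit") <- hits
  out
}

#' Collect HRA orthologs of the surviving candidates into a
#' presence/absence matrix
#'
#' For each group the anchor-species member is searched against each HRA
#' proteome. A cell is "present" (1) iff the anchor and some HRA gene are
#' mutual best hits and the raw alignment score is strictly greater than
#' `config$score_min_hra`. WBR columns are all present by construction of the
#' surviving groups; LRA and confirmation columns are all absent.
#'
#' @param groups Surviving orthogroup table (anchored in `config$wbr[1]`).
#' @param anchor_proteome Reduced proteome of the anchor species.
#' @param hra_proteomes Named list of reduced HRA proteomes.
#' @param config A [screen_config()].
#' @param scheme A [scoring_scheme()].
#' @return Binary matrix (groups x species) with attribute `reg_class`
#'   (named vector over its columns); class `presence_absence`.
#' @export
collect_hra_orthologs <- function(groups, anchor_proteome, hra_proteomes,
                                  config, scheme = scoring_scheme()) {
  anchor_sp <- config$wbr[1]
  members <- .group_members(groups)
  gids <- names(members)
  if (any(!vapply(members, function(m) anchor_sp %in% names(m), logical(1))))
    stop("a group is missing its anchor-species member")
  species <- c(config$wbr, config$hra, config$lra, config$confirm)
  cls <- setNames(rep(c("WBR", "HRA", "LRA", "CONFIRM"),
                      c(length(config$wbr), length(config$hra),
                        length(config$lra), length(config$confirm))), species)
  mat <- matrix(0L, length(gids), length(species),
                dimnames = list(gids, species))
  mat[, config$wbr] <- 1L
  anchor_seqs <- proteome_sequences(anchor_proteome)
  for (hsp in names(hra_proteomes)) {
    hseqs <- proteome_sequences(hra_proteomes[[hsp]])
    if (!length(hseqs)) next
    for (gid in gids) {
      agene <- members[[gid]][[anchor_sp]]
      aseq <- anchor_seqs[[agene]]
      fwd <- .score_matrix(setNames(aseq, agene), hseqs, scheme)
      fwd <- setNames(as.vector(fwd), colnames(fwd))
      best <- names(fwd)[order(-fwd, names(fwd))][1]
      sc <- fwd[[best]]
      if (sc <= config$score_min_hra) next
      back <- .score_matrix(setNames(hseqs[best], best), anchor_seqs, scheme)
      back <- setNames(as.vector(back), colnames(back))
      best_back <- names(back)[order(-back, names(back))][1]
      if (best_back == agene) mat[gid, hsp] <- 1L
    }
  }
  structure(mat, reg_class = cls, class = c("presence_absence", "matrix"))
}

#' Validate the presence/absence matrix invariant
#'
#' WBR columns must be all present for every row; LRA and confirmation
#' columns all absent.
#'
#' @param pa A `presence_absence` matrix from [collect_hra_orthologs()].
#' @return `pa`, invisibly; errors otherwise.
#' @export
validate_pa_matrix <- function(pa) {
  cls <- attr(pa, "reg_class")
  m <- unclass(pa)
  if (nrow(m)) {
    if (any(m[, cls == "WBR", drop = FALSE] != 1L))
      stop("presence/absence invariant violated: WBR cell absent")
    if (any(m[, cls %in% c("LRA", "CONFIRM"), drop = FALSE] != 0L))
      stop("presence/absence invariant violated: LRA/CONFIRM cell present")
  }
  invisible(pa)
}

#' Run the full conservation screen on a set of proteomes
#'
#' Convenience orchestration of the whole inference: longest-isoform
#' reduction, WBR mutual-best-hit orthogroups, loss filtering against the
#' LRA panel, confirmation against the CONFIRM panel, and HRA ortholog
#' collection.
#'
#' @param proteomes Named list of [proteome()]s (all classes).
#' @param config A [screen_config()].
#' @param scheme A [scoring_scheme()].
#' @return List with `orthogroups` (first pass), `candidates` (survivors),
#'   `pa_matrix`, `audit` (confirmation hits), `removed_lra`, and
#'   `removed_confirm`.
#' @export
run_screen <- function(proteomes, config, scheme = scoring_scheme()) {
  reduced <- lapply(proteomes, select_longest_isoform)
  wbr_prot <- reduced[config$wbr]
  mbh <- pairwise_mbh(wbr_prot, scheme, config$evalue_max_loss)
  groups <- build_wbr_orthogroups(mbh, config$wbr, config$grouping)
  lra_hits <- scan_panel_hits(groups, wbr_prot, reduced[config$lra],
                              scheme, config$evalue_max_loss)
  surv <- filter_lost_in_lra(groups, lra_hits, config)
  removed_lra <- attr(surv, "removed")
  if (length(config$confirm)) {
    surv <- confirm_absence(surv, reduced[config$confirm], config, wbr_prot,
                            scheme)
  } else {
    attr(surv, "audit") <- data.frame()
    attr(surv, "removed") <- character()
  }
  audit <- attr(surv, "audit")
  removed_confirm <- attr(surv, "removed")
  pa <- collect_hra_orthologs(surv, wbr_prot[[config$wbr[1]]],
                              reduced[config$hra], config, scheme)
  validate_pa_matrix(pa)
  list(orthogroups = groups, candidates = surv, pa_matrix = pa,
       audit = audit, removed_lra = removed_lra,
       removed_confirm = removed_confirm)
}

#' Write an orthogroup table as TSV
#' @param groups Orthogroup table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_orthogroups <- function(groups, path) {
  write.table(groups, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a presence/absence matrix as TSV (1/0 cells)
#' @param pa A `presence_absence` matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pa_matrix <- function(pa, path) {
  d <- data.frame(group_id = rownames(pa), unclass(pa),
                  check.names = FALSE, stringsAsFactors = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
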