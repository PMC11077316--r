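# Orchestration: run the synthetic scenario end to end (simulate -> screen ->
# trees -> promoter enrichment -> expression) from one config, with derived
# per-stage seeds and a provenance manifest.

.pipeline_stages <- c("simulate", "screen", "tree", "tfbs", "expr")

# Deterministic per-stage seed: global seed salted with the stage name, so
# adding or removing one stage never perturbs the seeds of its siblings.
.stage_seed <- function(seed, stage) {
  M <- 2147483563
  h <- as.numeric(seed) %% M
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% M
  as.integer(h + 1)
}

#' Default pipeline configuration
#'
#' The default synthetic scenario: 3 WBR, 5 HRA, 8 LRA and 2 confirmation
#' species; 200 background, 10 planted candidate and 10 paralog families.
#'
#' @param outdir Output directory.
#' @param seed Global seed.
#' @return A `run_config` list.
#' @export
default_config <- function(outdir = tempfile("regenscreen_run_"), seed = 7) {
  structure(list(
    seed = seed,
    outdir = outdir,
    stages = .pipeline_stages,
    scenario = list(n_wbr = 3, n_hra = 5, n_lra = 8, n_confirm = 2,
                    n_background = 200, n_cbr = 10, n_paralog = 10,
                    divergence = 0.1, indel_rate = 0.005,
                    len_range = c(120, 600)),
    screen = list(evalue_max_loss = 1e-4, score_min_hra = 100,
                  grouping = "clique"),
    tree = list(n_bootstrap = 100, n_families = 2),
    tfbs = list(motif = "TAATTAGCTAAT",
                plant_rate_target = 0.8, plant_rate_background = 0.1,
                windows = c(100, 500, 1000, 3000, 5000, 7500),
                n_background_genes = 200,
                pfm_file = system.file("extdata", "synthetic_pfms.jaspar",
                                       package = "regenscreen"),
                class_file = system.file("extdata", "synthetic_pfm_classes.tsv",
                                         package = "regenscreen")),
    expr = list(noise_sd = 0.25,
                timepoints = c(0, 3, 6, 12, 24, 48, 96, 120, 168))),
    class = "run_config")
}

#' Check a pipeline configuration, aggregating all problems
#'
#' @param config A config list (e.g. from [default_config()] or parsed
#'   YAML).
#' @return Character vector of problems; empty when the config is valid.
#' @export
check_config <- function(config) {
  errs <- character()
  add <- function(msg) errs <<- c(errs, msg)
  if (is.null(config$seed) || !is.numeric(config$seed))
    add("seed: must be a number")
  if (is.null(config$outdir)) add("outdir: missing")
  if (!is.null(config$stages)) {
    bad <- setdiff(config$stages, .pipeline_stages)
    if (length(bad)) add(paste0("stages: unknown stage(s) ",
                                paste(bad, collapse = ", ")))
  }
  sc <- config$scenario
  if (!is.null(sc)) {
    for (f in c("n_wbr", "n_hra", "n_lra", "n_confirm", "n_background",
                "n_cbr", "n_paralog")) {
      if (!is.null(sc[[f]]) && sc[[f]] < 0)
        add(paste0("scenario$", f, ": must be >= 0"))
    }
    if (!is.null(sc$n_wbr) && sc$n_wbr < 2)
      add("scenario$n_wbr: need at least two WBR species")
    if (!is.null(sc$divergence) && sc$divergence < 0)
      add("scenario$divergence: must be >= 0")
  }
  scr <- config$screen
  if (!is.null(scr)) {
    if (!is.null(scr$evalue_max_loss) && scr$evalue_max_loss <= 0)
      add("screen$evalue_max_loss: must be positive")
    if (!is.null(scr$score_min_hra) && scr$score_min_hra <= 0)
      add("screen$score_min_hra: must be positive")
    if (!is.null(scr$grouping) &&
        !scr$grouping %in% c("clique", "components"))
      add("screen$grouping: must be 'clique' or 'components'")
    lists <- scr[intersect(names(scr), c("wbr", "hra", "lra", "confirm"))]
    if (length(lists) > 1) {
      for (i in seq_len(length(lists) - 1)) for (j in (i + 1):length(lists)) {
        ov <- intersect(lists[[i]], lists[[j]])
        if (length(ov))
          add(paste0("screen: species ", paste(ov, collapse = ", "),
                     " appear in both ", names(lists)[i], " and ",
                     names(lists)[j]))
      }
    }
    for (f in c("wbr", "hra", "lra", "confirm")) {
      paths <- scr[[paste0(f, "_fasta")]]
      if (!is.null(paths)) {
        missing <- paths[!file.exists(paths)]
        if (length(missing))
          add(paste0("screen$", f, "_fasta: missing file(s) ",
                     paste(missing, collapse = ", ")))
      }
    }
  }
  tf <- config$tfbs
  if (!is.null(tf)) {
    if (!is.null(tf$windows) &&
        (any(tf$windows <= 0) || is.unsorted(tf$windows, strictly = TRUE)))
      add("tfbs$windows: must be positive and strictly increasing")
    if (!is.null(tf$plant_rate_target) && !is.null(tf$plant_rate_background) &&
        tf$plant_rate_target < tf$plant_rate_background)
      add("tfbs: plant_rate_target must be >= plant_rate_background")
    if (!is.null(tf$pfm_file) && nzchar(tf$pfm_file) &&
        !file.exists(tf$pfm_file))
      add(paste0("tfbs$pfm_file: file not found: ", tf$pfm_file))
  }
  ex <- config$expr
  if (!is.null(ex) && !is.null(ex$noise_sd) && ex$noise_sd < 0)
    add("expr$noise_sd: must be >= 0")
  errs
}

#' Validate a pipeline configuration
#'
#' Reads YAML if given a path, fills defaults for absent sections, and
#' aggregates every schema violation into a single error rather than failing
#' on the first.
#'
#' @param config A config list or path to a YAML file.
#' @return A validated `run_config` object (errors otherwise).
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  base <- default_config()
  for (f in names(config)) base[[f]] <- .merge_cfg(base[[f]], config[[f]])
  errs <- check_config(base)
  if (length(errs))
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "))
  base
}

.merge_cfg <- function(base, override) {
  if (!is.list(override) || !is.list(base)) return(override)
  for (f in names(override)) base[[f]] <- .merge_cfg(base[[f]], override[[f]])
  base
}

# Enrichment records for a planted-motif (or null) promoter scenario: for
# each window length, promoters of exactly that length are simulated with
# the motif planted at the stated rates, scanned, and tested.
#' Simulate and test a promoter-enrichment scenario
#'
#' For each window length, generates target and background promoters of that
#' length with the motif planted at the given per-gene rates, scans them
#' with the PWM panel and computes gene-level enrichment records.
#'
#' @param n_targets,n_background Numbers of target and background genes.
#' @param motif Planted motif consensus.
#' @param plant_rate_target,plant_rate_background Per-gene plant rates.
#' @param pwms List of [pwm_record()]s.
#' @param params A [scan_params()] (provides window lengths).
#' @param seed Integer seed.
#' @return Enrichment record data frame across all windows.
#' @export
simulate_tfbs_scenario <- function(n_targets, n_background, motif,
                                   plant_rate_target, plant_rate_background,
                                   pwms, params = scan_params(), seed = 1) {
  targets <- sprintf("T%03d", seq_len(n_targets))
  bg <- sprintf("B%03d", seq_len(n_background))
  recs <- list()
  for (k in seq_along(params$window_lengths)) {
    L <- params$window_lengths[k]
    prom <- simulate_promoters(c(targets, bg), targets, motif,
                               plant_rate_target, plant_rate_background,
                               length = L, seed = seed + k)
    rl <- lapply(pwms, function(p) {
      hit <- .genes_hit(p, prom, params)
      enrichment_test(targets, bg, hit, p, window_length = L)
    })
    d <- do.call(rbind, rl)
    d$p_adjust <- stats::p.adjust(d$p_value, method = "BH")
    recs[[k]] <- d
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Run the pipeline
#'
#' Executes the configured stages in order (simulate, screen, tree, tfbs,
#' expr), writing every intermediate artifact under `config$outdir` plus a
#' JSON manifest with parameters, per-stage timing, md5 checksums of all
#' written files, and summary metrics. Stages absent from `config$stages`
#' are skipped. Reruns with an identical config reproduce identical primary
#' outputs.
#'
#' @param config A `run_config`, config list, or YAML path (validated via
#'   [validate_config()]).
#' @return The manifest, invisibly (also written to
#'   `<outdir>/manifest.json`).
#' @export
run_pipeline <- function(config = default_config()) {
  config <- validate_config(config)
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = list(), files = list(),
                   parameters = config[setdiff(names(config),
                                               c("outdir"))])
  written <- character()
  note_files <- function(paths) written <<- c(written, paths)
  state <- new.env(parent = emptyenv())
  scheme <- scoring_scheme()

  run_stage <- function(name, fun) {
    if (!name %in% config$stages) return(invisible(NULL))
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    manifest$stages[[name]] <<- c(list(elapsed_s = round(
      proc.time()[["elapsed"]] - t0, 2)), res)
    invisible(NULL)
  }

  run_stage("simulate", function() {
    sc <- config$scenario
    specs <- c(
      lapply(seq_len(sc$n_wbr), function(i)
        species_spec(sprintf("wbr%d", i), "WBR", sc$n_background,
                     sc$divergence)),
      lapply(seq_len(sc$n_hra), function(i)
        species_spec(sprintf("hra%d", i), "HRA", sc$n_background,
                     sc$divergence)),
      lapply(seq_len(sc$n_lra), function(i)
        species_spec(sprintf("lra%d", i), "LRA", sc$n_background,
                     sc$divergence)),
      lapply(seq_len(sc$n_confirm), function(i)
        species_spec(sprintf("conf%d", i), "CONFIRM", sc$n_background,
                     sc$divergence)))
    sim <- simulate_species_set(
      specs, n_cbr = sc$n_cbr, n_paralog = sc$n_paralog,
      model = mutation_model(sc$divergence, sc$indel_rate),
      seed = .stage_seed(config$seed, "simulate"),
      len_range = sc$len_range)
    state$sim <- sim
    state$specs <- specs
    fasta_dir <- file.path(outdir, "proteomes")
    dir.create(fasta_dir, showWarnings = FALSE)
    for (p in sim$proteomes)
      note_files(write_proteome_fasta(
        p, file.path(fasta_dir, paste0(p$species_id, ".fasta"))))
    note_files(write_truth_tsv(sim$truth, file.path(outdir, "truth")))
    sp_tab <- data.frame(
      species_id = vapply(specs, `[[`, character(1), "species_id"),
      reg_class = vapply(specs, `[[`, character(1), "reg_class"),
      fasta_path = file.path("proteomes", paste0(
        vapply(specs, `[[`, character(1), "species_id"), ".fasta")))
    sp_path <- file.path(outdir, "species.tsv")
    write.table(sp_tab, sp_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    note_files(sp_path)
    list(n_species = length(specs),
         n_families = sc$n_background + sc$n_cbr + sc$n_paralog)
  })

  run_stage("screen", function() {
    if (is.null(state$sim)) stop("screen stage needs the simulate stage")
    sim <- state$sim
    classes <- vapply(state$specs, `[[`, character(1), "reg_class")
    ids <- vapply(state$specs, `[[`, character(1), "species_id")
    cfg <- screen_config(wbr = ids[classes == "WBR"],
                         hra = ids[classes == "HRA"],
                         lra = ids[classes == "LRA"],
                         confirm = ids[classes == "CONFIRM"],
                         evalue_max_loss = config$screen$evalue_max_loss,
                         score_min_hra = config$screen$score_min_hra,
                         grouping = config$screen$grouping)
    res <- run_screen(sim$proteomes, cfg, scheme)
    state$screen <- res
    state$screen_cfg <- cfg
    note_files(write_orthogroups(res$orthogroups,
                                 file.path(outdir, "orthogroups.tsv")))
    note_files(write_orthogroups(res$candidates,
                                 file.path(outdir, "candidates.tsv")))
    note_files(write_pa_matrix(res$pa_matrix,
                               file.path(outdir, "pa_matrix.tsv")))
    audit_path <- file.path(outdir, "confirm_audit.tsv")
    write.table(res$audit, audit_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    note_files(audit_path)
    recovered <- sort(unique(res$candidates$gene_id[
      res$candidates$species_id == cfg$wbr[1]]))
    truth_set <- sort(sim$truth$cbr_family_ids)
    tp <- length(intersect(recovered, truth_set))
    list(n_orthogroups = length(unique(res$orthogroups$group_id)),
         n_candidates = length(recovered),
         precision = if (length(recovered)) tp / length(recovered) else NA,
         recall = if (length(truth_set)) tp / length(truth_set) else NA)
  })

  run_stage("tree", function() {
    if (is.null(state$sim)) stop("tree stage needs the simulate stage")
    sim <- state$sim
    fams <- head(sim$truth$paralog_family_ids, config$tree$n_families)
    tree_dir <- file.path(outdir, "trees")
    dir.create(tree_dir, showWarnings = FALSE)
    separated <- logical(0)
    for (fam in fams) {
      seqs <- character()
      for (p in sim$proteomes) {
        if (fam %in% names(p$genes)) {
          red <- select_longest_isoform(p)
          seqs[paste(p$species_id, fam, sep = "|")] <-
            proteome_sequences(red)[[fam]]
        }
      }
      msa <- progressive_align(seqs, scheme)
      tr <- bootstrap_supports(msa, config$tree$n_bootstrap,
                               seed = .stage_seed(config$seed,
                                                  paste0("tree_", fam)))
      nwk <- file.path(tree_dir, paste0(fam, ".nwk"))
      ape::write.tree(tr, nwk)
      note_files(nwk)
      phy <- file.path(tree_dir, paste0(fam, ".phy"))
      note_files(write_phylip(msa, phy))
      wbr_taxa <- grep("^wbr", names(seqs), value = TRUE)
      separated[fam] <- is_separated_cluster(tr, wbr_taxa)
    }
    list(families = as.list(separated))
  })

  run_stage("tfbs", function() {
    tf <- config$tfbs
    pwms <- read_jaspar(tf$pfm_file, tf$class_file)
    params <- scan_params(window_lengths = tf$windows)
    n_targets <- if (!is.null(state$sim))
      max(1L, length(state$sim$truth$cbr_family_ids)) else 10L
    recs <- simulate_tfbs_scenario(
      n_targets = n_targets, n_background = tf$n_background_genes,
      motif = tf$motif, plant_rate_target = tf$plant_rate_target,
      plant_rate_background = tf$plant_rate_background,
      pwms = pwms, params = params,
      seed = .stage_seed(config$seed, "tfbs"))
    rec_path <- file.path(outdir, "tfbs_enrichment.tsv")
    write.table(recs, rec_path, sep = "\t", quote = FALSE, row.names = FALSE)
    note_files(rec_path)
    tally <- compile_top_classes(recs, top_k = 10)
    tally_path <- file.path(outdir, "tfbs_class_tally.tsv")
    write.table(data.frame(tf_class = rownames(tally), tally,
                           check.names = FALSE),
                tally_path, sep = "\t", quote = FALSE, row.names = FALSE)
    note_files(tally_path)
    hit <- which(vapply(pwms, function(p)
      grepl(tf$motif, .pwm_consensus(p), fixed = TRUE), logical(1)))
    if (length(hit)) {
      planted_class <- pwms[[hit[1]]]$tf_class
      list(planted_class = planted_class,
           planted_class_windows = sum(tally[planted_class, ] > 0),
           n_windows = ncol(tally))
    } else {
      list(planted_class = NA, n_windows = ncol(tally))
    }
  })

  run_stage("expr", function() {
    if (is.null(state$sim)) stop("expr stage needs the simulate stage")
    phases <- state$sim$truth$expression_phase_by_gene
    if (!length(phases)) return(list(skipped = "no candidate genes"))
    m <- simulate_expression(phases, config$expr$timepoints,
                             noise_sd = config$expr$noise_sd,
                             seed = .stage_seed(config$seed, "expr"))
    note_files(write_fpkm(m, file.path(outdir, "fpkm.tsv")))
    note_files(write_fpkm(round(normalize_expression(m), 6),
                          file.path(outdir, "fpkm_normalized.tsv")))
    calls <- classify_patterns(m)
    calls$truth_phase <- unname(phases[calls$gene_id])
    call_path <- file.path(outdir, "phase_calls.tsv")
    write.table(calls, call_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    note_files(call_path)
    list(phase_accuracy = mean(calls$phase == calls$truth_phase))
  })

  manifest$files <- lapply(unique(written), function(f) {
    rel <- if (startsWith(f, paste0(outdir, "/")))
      substring(f, nchar(outdir) + 2) else f
    list(path = rel, md5 = unname(tools::md5sum(f)))
  })
  json_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

# Consensus string of a PWM (most frequent base per column).
.pwm_consensus <- function(pwm) {
  paste(rownames(pwm$counts)[apply(pwm$counts, 2, which.max)], collapse = "")
}
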