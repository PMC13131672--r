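# Pipeline orchestration: one configuration drives simulate -> associate
# -> count -> activity -> motifs / spatial / haplotypes, with a run
# manifest recording parameters, seeds, and output checksums.

#' Default run configuration
#'
#' Every stage parameter sits in one place, with defaults matching the
#' assay's stated settings where one exists: the constant adapter,
#' 15-nt barcodes, minimum 10 barcodes per variant, RNA-count z cutoff 3,
#' motif p thresholds 1e-4 (variants) and 5e-4 (reference annotation),
#' gain/loss score threshold 10, 50-bp windows at q < 0.05, and both
#' adjusted-p cutoffs (0.05 headline, 0.1 alternative) exposed.
#'
#' @param ... Named overrides of any default.
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    stages = c("simulate", "associate", "count", "activity", "spatial"),
    outdir = NULL,
    seed = 1,
    sim = list(),                       # overrides for sim_config()
    adapter = mpra_adapter(),
    barcode_length = 15,
    max_mismatches = 0,
    rc_scan = TRUE,
    min_reads = 1,
    pseudocount = 1,
    min_barcodes = 10,
    z_cutoff = 3,
    p_adj_cutoff = 0.05,
    p_adj_cutoff_alt = 0.1,
    lfc_cutoff = 0.5,
    pwm_file = NULL,
    pwm_allow_list = NULL,
    p_motif_variants = 1e-4,
    p_motif_reference = 5e-4,
    score_threshold = 10,
    window = 50,
    window_step = 1,
    q_threshold = 0.05,
    haplotypes = NULL)                  # data.frame(haplotype_id, variant_ids)
  over <- list(...)
  if (length(over) == 1 && is.null(names(over)) && is.list(over[[1]])) {
    over <- over[[1]]
  }
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown run_config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' @param path YAML file of `run_config` fields.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  run_config(yaml::read_yaml(path))
}

#' Run the MPRA analysis pipeline
#'
#' Executes the enabled stages in dependency order on synthetic data
#' (`simulate` stage) and writes tab-separated outputs plus a
#' `manifest.json` with parameters, seed, and md5 checksums of every
#' output. Identical configuration and seed give identical checksums. A
#' stage whose upstream output is missing fails fast naming the stage.
#'
#' @param config A `run_config` (or list of overrides).
#' @param outdir Output directory (overrides `config$outdir`); created if
#'   needed.
#' @return Invisible list of in-memory stage results plus the manifest.
#' @export
run_pipeline <- function(config = run_config(), outdir = NULL) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  if (!is.null(outdir)) config$outdir <- outdir
  if (is.null(config$outdir)) stop("run_pipeline needs an output directory")
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages
  need <- function(stage, what) {
    if (is.null(what)) {
      stop("stage '", stage, "' requires output of a disabled stage")
    }
    what
  }
  results <- list()
  outputs <- character(0)
  emit <- function(df, name) {
    path <- file.path(config$outdir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    outputs <<- c(outputs, path)
  }

  sim <- NULL
  if ("simulate" %in% stages) {
    sim_args <- config$sim
    sim_args$seed <- config$seed
    scfg <- do.call(sim_config, sim_args)
    gen <- generate_library(scfg)
    if (!is.null(config$haplotypes)) {
      gen <- simulate_haplotype_constructs(gen, config$haplotypes, scfg)
    }
    reads <- simulate_association_reads(gen$truth, scfg, gen$library)
    counts <- simulate_counts(gen$truth, scfg)
    records <- simulate_count_records(counts, scfg)
    sim <- list(cfg = scfg, library = gen$library, truth = gen$truth,
                reads = reads, records = records)
    emit(gen$truth$assignments, "ground_truth_assignments.tsv")
    emit(data.frame(seq_id = names(gen$truth$planted_lfc),
                    planted_lfc = unname(gen$truth$planted_lfc)),
         "ground_truth_lfc.tsv")
    results$simulate <- sim
  }

  assoc <- NULL
  if ("associate" %in% stages) {
    s <- need("associate", sim)
    assoc <- build_association(
      s$reads$reads, s$library, adapter = config$adapter,
      max_mismatches = config$max_mismatches,
      barcode_length = config$barcode_length, rc_scan = config$rc_scan,
      min_reads = config$min_reads)
    emit(assoc$entries, "association.tsv")
    emit(assoc$dropped, "association_dropped.tsv")
    results$associate <- assoc
  }

  counts_tab <- NULL
  if ("count" %in% stages) {
    s <- need("count", sim)
    counts_tab <- dedup_umis(s$records)
    amap <- if (!is.null(assoc)) assoc else
      structure(list(entries = s$truth$assignments),
                class = "association_map")
    counts_tab <- attach_association(counts_tab, amap)
    emit(counts_tab, "counts.tsv")
    results$count <- counts_tab
  }

  act <- NULL
  effects <- NULL
  if ("activity" %in% stages) {
    ct <- need("activity", counts_tab)
    s <- need("activity", sim)
    act <- compute_barcode_activity(ct, pseudocount = config$pseudocount)
    pooled <- pooled_activity(act)
    filt <- filter_barcodes_and_variants(pooled, ct,
                                         min_barcodes = config$min_barcodes,
                                         z_cutoff = config$z_cutoff)
    effects <- estimate_variant_effects(filt, s$library,
                                        min_ref_barcodes =
                                          config$min_barcodes)
    qc <- qc_report(act, ct, s$library)
    calls <- call_significant(effects, p_cutoff = config$p_adj_cutoff,
                              lfc_cutoff = config$lfc_cutoff)
    emit(effects, "variant_effects.tsv")
    emit(filt$removed, "removal_log.tsv")
    emit(qc$replicate_correlations, "qc_replicate_correlations.tsv")
    results$activity <- list(effects = effects, qc = qc, calls = calls,
                             removed = filt$removed)
  }

  if ("motifs" %in% stages) {
    s <- need("motifs", sim)
    if (is.null(config$pwm_file)) stop("stage 'motifs' needs pwm_file")
    pwms <- read_pwms(config$pwm_file, allow_list = config$pwm_allow_list)
    changes <- annotate_motif_changes(s$library, pwms,
                                      score_threshold =
                                        config$score_threshold)
    emit(changes, "motif_changes.tsv")
    results$motifs <- changes
  }

  if ("spatial" %in% stages) {
    s <- need("spatial", sim)
    unif <- uniformity_tests(s$library, q_threshold = config$q_threshold)
    windows <- hotspot_scan(s$library, window = config$window,
                            step = config$window_step,
                            q_threshold = config$q_threshold)
    emit(unif, "uniformity.tsv")
    emit(windows, "windows.tsv")
    results$spatial <- list(uniformity = unif, windows = windows)
  }

  if ("haplotypes" %in% stages) {
    ef <- need("haplotypes", effects)
    if (is.null(config$haplotypes)) {
      stop("stage 'haplotypes' needs a haplotype definition table")
    }
    hap <- evaluate_haplotypes(config$haplotypes, ef)
    emit(hap, "haplotypes.tsv")
    results$haplotypes <- hap
  }

  manifest <- list(
    package = "mpravar",
    version = as.character(utils::packageVersion("mpravar")),
    seed = config$seed,
    stages = stages,
    parameters = config[setdiff(names(config),
                                c("stages", "outdir", "haplotypes"))],
    outputs = lapply(outputs, function(p) {
      list(file = basename(p), md5 = unname(tools::md5sum(p)))
    }))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  results$manifest <- manifest
  invisible(results)
}
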