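#!/usr/bin/env Rscript
# Thin command-line wrapper over mpravar::run_pipeline().
#
# Usage: Rscript scripts/run_pipeline.R --outdir <dir> [--config cfg.yaml]
#        [--seed <int>] [--stages simulate,associate,count,activity,spatial]

suppressMessages({
  library(optparse)
  library(mpravar)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL),
  make_option("--seed", type = "integer", default = NULL),
  make_option("--outdir", type = "character", default = "mpravar_run"),
  make_option("--stages", type = "character", default = NULL))))

cfg <- if (is.null(opts$config)) run_config() else
  read_run_config(opts$config)
if (!is.null(opts$seed)) cfg$seed <- opts$seed
if (!is.null(opts$stages)) {
  cfg$stages <- trimws(strsplit(opts$stages, ",")[[1]])
}

res <- run_pipeline(cfg, outdir = opts$outdir)
message("pipeline complete; outputs in ", opts$outdir)
if (!is.null(res$activity)) {
  s <- res$activity$calls$summary
  message(sprintf("tested %d variants: %d significant (p_adj<%.2g), %d past |LFC| cutoff",
                  s["n_tested"], s["n_significant"], cfg$p_adj_cutoff,
                  s["n_exceeding_lfc"]))
}
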