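#!/usr/bin/env Rscript

# Thin command-line wrapper over cistromics::run_pipeline().
#
# Usage: Rscript scripts/run_pipeline.R --config run.yaml --outdir report/
#        Rscript scripts/run_pipeline.R --simulate sim_dir --outdir report/ \
#            [--seed 1]
# With --simulate, a synthetic study is generated under the given directory
# first and the pipeline is run on it.

suppressMessages({
  library(optparse)
  library(cistromics)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL,
              help = "run configuration YAML"),
  make_option("--simulate", type = "character", default = NULL,
              help = "simulate a default synthetic study into this directory"),
  make_option("--outdir", type = "character", default = "cistromics_report"),
  make_option("--seed", type = "integer", default = 1L)
)))

if (!is.null(opts$simulate)) {
  ds <- simulate_dataset(sim_config(seed = opts$seed), opts$simulate)
  cfg <- config_from_dataset(ds, params = list(min_peaks = 100L,
                                               seed = opts$seed))
} else if (!is.null(opts$config)) {
  cfg <- load_run_config(opts$config)
} else {
  stop("provide --config or --simulate")
}

res <- run_pipeline(cfg, opts$outdir)
cat("report written to", res$outdir, "\n")
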