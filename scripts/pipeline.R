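#!/usr/bin/env Rscript

# Thin command-line wrapper over the hhequity pipeline.
#
#   Rscript scripts/pipeline.R simulate --config cfg.yaml --seed 7 --out dir/
#   Rscript scripts/pipeline.R pipeline --config cfg.yaml --seed 7 --out dir/
#
# `simulate` writes the four input CSVs, the FCT, the ground truth and a
# config echo; `pipeline` runs every analysis stage and writes per-stage
# CSVs (see ?run_pipeline). The YAML config fields are those of
# ?pipeline_config; with no --config, defaults are used.

suppressMessages({
  library(optparse)
  library(hhequity)
})

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1 || !args[1] %in% c("simulate", "pipeline")) {
  stop("usage: pipeline.R <simulate|pipeline> [--config PATH] [--seed INT] --out DIR")
}
cmd <- args[1]
opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL),
  make_option("--seed", type = "integer", default = NULL),
  make_option("--out", type = "character", default = "hhequity_out")
)), args = args[-1])

config <- if (is.null(opts$config)) {
  pipeline_config()
} else {
  read_pipeline_config(opts$config)
}
if (!is.null(opts$seed)) config$seed <- opts$seed

if (cmd == "simulate") {
  sim_args <- config$simulation
  sim_args$seed <- config$seed
  study <- simulate_study(do.call(sim_config, sim_args))
  dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
  write_tables(study, opts$out)
  write_fct(study$fct, file.path(opts$out, "fct.csv"))
  readr::write_csv(study$ground_truth$members,
                   file.path(opts$out, "ground_truth_members.csv"))
  readr::write_csv(study$ground_truth$households,
                   file.path(opts$out, "ground_truth_households.csv"))
  cat("wrote simulated study to", opts$out, "\n")
} else {
  run_pipeline(config, opts$out)
  cat("pipeline outputs written to", opts$out, "\n")
}
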