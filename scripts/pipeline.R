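#!/usr/bin/env Rscript

# Thin command-line wrapper over the package's pipeline functions.
#
#   Rscript scripts/pipeline.R simulate --config cfg.json --out sim_dir
#   Rscript scripts/pipeline.R simulate --seed 7 --out sim_dir
#   Rscript scripts/pipeline.R analyze --trials sim_dir/trials.csv \
#     [--questionnaires sim_dir/questionnaires.csv] --out results_dir

suppressPackageStartupMessages({
  library(optparse)
  library(vptbias)
})

argv <- commandArgs(trailingOnly = TRUE)
if (length(argv) < 1 || !argv[1] %in% c("simulate", "analyze")) {
  stop("usage: pipeline.R <simulate|analyze> [options]", call. = FALSE)
}
verb <- argv[1]

if (verb == "simulate") {
  opts <- parse_args(
    OptionParser(option_list = list(
      make_option("--config", type = "character", default = NULL),
      make_option("--seed", type = "integer", default = NULL),
      make_option("--out", type = "character")
    )),
    args = argv[-1]
  )
  config <- if (!is.null(opts$config)) {
    read_cohort_config(opts$config)
  } else if (!is.null(opts$seed)) {
    cohort_config(seed = opts$seed)
  } else {
    stop("simulate needs --config or --seed", call. = FALSE)
  }
  sim <- run_simulate(config, opts$out)
  cat("wrote", sim$paths$trials, "and", sim$paths$questionnaires, "\n")
} else {
  opts <- parse_args(
    OptionParser(option_list = list(
      make_option("--trials", type = "character"),
      make_option("--questionnaires", type = "character", default = NULL),
      make_option("--out", type = "character")
    )),
    args = argv[-1]
  )
  res <- run_analyze(opts$trials, opts$questionnaires, out_dir = opts$out)
  cat(
    "analysed", res$manifest$n_participants_retained, "retained of",
    res$manifest$n_participants_input, "participants; results in",
    opts$out, "\n"
  )
}
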