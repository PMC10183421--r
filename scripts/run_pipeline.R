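#!/usr/bin/env Rscript

# Thin command-line wrapper over fibsafe::run_pipeline().
#
# Usage:
#   Rscript scripts/run_pipeline.R --config cfg.yaml
#   Rscript scripts/run_pipeline.R --seed 7 --diameter 3.5 --out out_dir \
#       [--n 96] [--reference-policy mean|first|<subject_id>]

suppressPackageStartupMessages({
  library(optparse)
  library(fibsafe)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--n", type = "integer", default = 96L),
  make_option("--diameter", type = "double", default = 3.5),
  make_option("--out", type = "character", default = NULL),
  make_option("--reference-policy", dest = "reference_policy",
              type = "character", default = "mean"),
  make_option("--figures", action = "store_true", default = FALSE)
)))

cfg <- if (!is.null(opts$config)) {
  read_pipeline_config(opts$config)
} else {
  pipeline_config(
    cohort = cohort_params(n_subjects = opts$n,
                           tunnel_diameter_mm = opts$diameter),
    tunnel_diameter_mm = opts$diameter,
    reference_policy = opts$reference_policy,
    out_dir = opts$out,
    seed = opts$seed,
    write_figures = opts$figures
  )
}

print(run_pipeline(cfg))
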