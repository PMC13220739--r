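#!/usr/bin/env Rscript
# Standalone nested coverage experiment for the parametric-bootstrap
# intervals: generate -> fit -> bootstrap, repeated, against a
# micro-simulated truth. Slow at full scale (~15 min at the defaults).
# Usage: Rscript scripts/coverage_experiment.R [--reps N] [--n N] [--B N]
#        [--seed N] [--out path]

suppressMessages({
  library(optparse)
  library(adipolife)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--reps", type = "integer", default = 200L),
  make_option("--n", type = "integer", default = 5000L),
  make_option("--B", type = "integer", default = 250L),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--out", type = "character", default = "results/coverage.json")
)))

res <- coverage_experiment(n_reps = opts$reps, n = opts$n, B = opts$B,
                           seed = opts$seed)
message(sprintf("coverage %.3f (truth %.3f +/- %.3f, %d replicates)",
                res$coverage, res$truth, res$truth_se, opts$reps))
dir.create(dirname(opts$out), showWarnings = FALSE, recursive = TRUE)
jsonlite::write_json(list(coverage = res$coverage, truth = res$truth,
                          truth_se = res$truth_se, reps = opts$reps,
                          n = opts$n, B = opts$B, seed = opts$seed),
                     opts$out, auto_unbox = TRUE, digits = NA)
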