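#!/usr/bin/env Rscript
# Thin command-line wrapper over the oliguard pipeline.
#
#   Rscript scripts/run_pipeline.R simulate --n 2000 --prevalence 0.03 \
#       --seed 1 --out-dir runs/cohort
#   Rscript scripts/run_pipeline.R run-all --input-dir runs/cohort/cohort \
#       --model cnn --seed 1 --out-dir runs/report
#   Rscript scripts/run_pipeline.R run-all --n 2000 --model logistic_multi \
#       --seed 1 --out-dir runs/report      # simulate + analyse in one go

suppressMessages(library(oliguard))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1 || !args[1] %in% c("simulate", "run-all")) {
  cat("usage: run_pipeline.R {simulate|run-all} [--n N] [--prevalence P]",
      "[--input-dir DIR] [--model cnn|logistic_multi|logistic_single]",
      "[--seed S] [--out-dir DIR]\n")
  quit(status = 1)
}
cmd <- args[1]
get_arg <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}
n <- as.integer(get_arg("--n", "2000"))
prevalence <- as.numeric(get_arg("--prevalence", "0.03"))
seed <- as.integer(get_arg("--seed", "1"))
out_dir <- get_arg("--out-dir", "runs")
input_dir <- get_arg("--input-dir")
model <- get_arg("--model", "cnn")

if (cmd == "simulate") {
  cohort <- generate_cohort(cohort_config(n_patients = n,
                                          prevalence = prevalence,
                                          seed = seed))
  paths <- write_cohort_csv(cohort, out_dir)
  cat("wrote:", paste(paths, collapse = ", "), "\n")
} else {
  cfg <- pipeline_config(
    cohort_config = if (is.null(input_dir))
      cohort_config(n_patients = n, prevalence = prevalence, seed = seed),
    input_dir = input_dir, model = model, split_seed = seed, seed = seed,
    out_dir = out_dir)
  report <- run_pipeline(cfg)
  print(report)
}
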