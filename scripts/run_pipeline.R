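#!/usr/bin/env Rscript

# Thin command-line wrapper over mtpca::run_pipeline() for synthetic-mode
# end-to-end runs.
#
# Usage:
#   Rscript scripts/run_pipeline.R --seed 1 --out runs/demo
#   Rscript scripts/run_pipeline.R --config cfg.json --out runs/x --nested
#
# Options:
#   --seed N        master seed (default 1; ignored when --config is given)
#   --config FILE   synthetic configuration JSON written by write_config()
#   --out DIR       output directory for reports (required)
#   --families F,F  comma-separated subset (default: all six families)
#   --resolution N  SVM grid resolution per parameter (default 20)
#   --nested        re-run feature selection inside every LOOCV fold

suppressMessages(library(mtpca))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) {
    return(args[i + 1])
  }
  default
}
has_flag <- function(flag) flag %in% args

out <- get_arg("--out")
if (is.null(out)) stop("--out <dir> is required", call. = FALSE)

config <- if (!is.null(get_arg("--config"))) {
  read_config(get_arg("--config"))
} else {
  synthetic_config(seed = as.integer(get_arg("--seed", "1")))
}
families <- get_arg("--families")
if (!is.null(families)) families <- strsplit(families, ",")[[1]]

run <- run_pipeline(
  config,
  svm = svm_config(resolution = as.integer(get_arg("--resolution", "20"))),
  families = families,
  nested = has_flag("--nested"),
  out_dir = out
)
print(run)
cat("reports written to", out, "\n")
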