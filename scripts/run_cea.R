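#!/usr/bin/env Rscript
# Thin command-line wrapper around mtcea::run_pipeline().
#
#   Rscript scripts/run_cea.R analyze  --config cfg.yaml [--out DIR]
#   Rscript scripts/run_cea.R analyze  --fixtures [--out DIR]
#   Rscript scripts/run_cea.R analyze  --panel panel.csv [--out DIR]
#   Rscript scripts/run_cea.R simulate --seed 7 [--out DIR]
#   Rscript scripts/run_cea.R validate --panel panel.csv [--tolerance 5]
#   Rscript scripts/run_cea.R report   --out DIR   (print an existing report)
#
# Exits nonzero on any stage error.

suppressPackageStartupMessages(library(mtcea))

args <- commandArgs(trailingOnly = TRUE)
verb <- if (length(args) > 0) args[1] else "analyze"
args <- args[-1]
get_arg <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}
has_flag <- function(flag) flag %in% args

status <- tryCatch({
  out_dir <- get_arg("--out", file.path("results", paste0("cea-", verb)))
  if (verb == "report") {
    report <- file.path(out_dir, "report.md")
    if (!file.exists(report)) stop("no report at ", report)
    writeLines(readLines(report))
  } else {
    cfg_path <- get_arg("--config")
    if (!is.null(cfg_path)) {
      cfg <- read_pipeline_config(cfg_path)
      cfg$output_dir <- out_dir
    } else if (verb == "simulate") {
      seed <- as.integer(get_arg("--seed", "1"))
      cfg <- pipeline_config("simulate", sim = list(seed = seed), seed = seed,
                             output_dir = out_dir)
    } else if (!is.null(get_arg("--panel"))) {
      cfg <- pipeline_config("panel", panel_path = get_arg("--panel"),
                             seed = as.integer(get_arg("--seed", "1")),
                             output_dir = out_dir)
    } else {
      cfg <- pipeline_config("fixtures", seed = as.integer(get_arg("--seed", "1")),
                             output_dir = out_dir)
    }
    tol <- get_arg("--tolerance")
    if (!is.null(tol)) cfg$validation_tolerance_pct <- as.numeric(tol)

    res <- run_pipeline(cfg)
    writeLines(res$log)
    if (verb == "validate") {
      ok <- all(vapply(res$validation, function(v) v$valid, logical(1)))
      cat(sprintf("validation: %s (max diff %.2f points, tolerance %.1f)\n",
                  if (ok) "valid" else "INVALID",
                  max(vapply(res$validation, function(v) v$max_abs_diff,
                             numeric(1))),
                  cfg$validation_tolerance_pct))
      if (!ok) stop("model validation failed")
    }
    cat("artefacts written to ", res$output_dir, "\n", sep = "")
  }
  0L
}, error = function(e) {
  message("error: ", conditionMessage(e))
  1L
})

quit(status = status)
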