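#!/usr/bin/env Rscript
# Thin command-line wrapper around forksplice::runDemo().
#
# Usage: Rscript scripts/demo.R --out DIR [--seed N] [--config cfg.yaml]
# Exit codes: 0 success, 2 configuration error, 3 data/processing error.

suppressPackageStartupMessages(library(forksplice))

args <- commandArgs(trailingOnly = TRUE)
getArg <- function(flag, default) {
  i <- match(flag, args)
  if (is.na(i) || i == length(args)) default else args[i + 1L]
}
outDir <- getArg("--out", "forksplice_demo")
seed <- as.integer(getArg("--seed", "1"))
cfgPath <- getArg("--config", NA_character_)

status <- tryCatch({
  cfg <- if (is.na(cfgPath)) list() else forkspliceConfig(cfgPath)
  runDemo(outDir, seed = seed, config = cfg)
  cat(readLines(file.path(outDir, "report.txt")), sep = "\n")
  0L
}, error = function(e) {
  message("error: ", conditionMessage(e))
  if (grepl("config error", conditionMessage(e))) 2L else 3L
})
quit(status = status)
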