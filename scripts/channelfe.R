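#!/usr/bin/env Rscript
# Thin command-line wrapper over the channelfe entry points.
#
#   Rscript scripts/channelfe.R run [config.yaml] [--out DIR] [sec.key=val ...]
#   Rscript scripts/channelfe.R diagnose RUN_DIR [--out metrics.csv]
#   Rscript scripts/channelfe.R compare RUN_DIR... [--out table.csv]

suppressMessages(library(channelfe))

args <- commandArgs(trailingOnly = TRUE)
usage <- function() {
  cat("usage: channelfe.R run|diagnose|compare ...\n")
  quit(status = 2)
}
if (!length(args)) usage()
cmd <- args[1]; args <- args[-1]

take_opt <- function(args, flag, default) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) {
    list(value = args[i + 1], rest = args[-c(i, i + 1)])
  } else list(value = default, rest = args)
}

status <- tryCatch({
  if (cmd == "run") {
    o <- take_opt(args, "--out", "channelfe_run"); args <- o$rest
    overrides <- grep("^[a-z]+\\.", args, value = TRUE)
    cfg_path <- setdiff(args, overrides)
    cli_run(if (length(cfg_path)) cfg_path[1] else NULL, overrides, o$value)
    0
  } else if (cmd == "diagnose") {
    if (!length(args)) usage()
    o <- take_opt(args[-1], "--out", file.path(args[1], "metrics.csv"))
    cli_diagnose(args[1], o$value)
    0
  } else if (cmd == "compare") {
    o <- take_opt(args, "--out", "scenario_compare.csv"); args <- o$rest
    if (!length(args)) usage()
    cli_compare(args, o$value)
    0
  } else usage()
}, error = function(e) {
  message("error: ", conditionMessage(e))
  2
})
quit(status = status)
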