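#!/usr/bin/env Rscript
# Stage 6 — assemble the run report.
#
# Renders a single markdown report from the artifacts of stages 1-5:
# descriptives, per-country top-3 model tables, transfer RMSE summaries,
# and the all-catalog coefficient display. Sections whose artifacts are
# missing are listed as absent rather than failing the render.

suppressPackageStartupMessages(library(maternalcv))
out <- "results/run"

rep <- render_report(out)
cat("report:", rep$path, "\n")
cat("sections rendered:", paste(rep$sections, collapse = ", "), "\n")
if (length(rep$missing))
  cat("sections absent:", paste(rep$missing, collapse = ", "), "\n")
quit(status = rep$status)
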