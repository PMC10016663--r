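#!/usr/bin/env Rscript
# Builds the full 14-indicator monitoring report for the final quarter,
# applies small-cell suppression and writes CSV, JSON and markdown renderings
# under results/report/.

suppressMessages(library(prepmonitor))

store <- read_event_store("results/cohort")
cfg <- indicator_config()
quarter <- "2020Q4"
out_dir <- "results/report"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

rep <- suppress_small_cells(build_quarterly_report(store, quarter, cfg))
write_report(rep, "csv", file.path(out_dir, paste0("report_", quarter, ".csv")))
write_report(rep, "json", file.path(out_dir, paste0("report_", quarter, ".json")))
write_report(rep, "markdown", file.path(out_dir, paste0("report_", quarter, ".md")))

tidy <- report_to_tidy(rep)
cat(sprintf("%s: %d indicator blocks, %d cells, %d suppressed\n",
            quarter, length(rep$blocks), nrow(tidy), sum(tidy$suppressed)))
g <- tidy[tidy$indicator == "1" & tidy$stratum == "cis_male", ]
cat(sprintf("cisgender-male clients dispensed: %d of %d (%d%%)\n",
            g$numerator, g$denominator, g$percent))
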