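#!/usr/bin/env Rscript
# Aggregate the per-site runs: one trend row per site, the tally of the
# five Mann-Kendall trend classes, and a cross-tabulation of trend class
# against the elevation covariate, mirroring how a multi-site wetland
# survey reports its results.

suppressPackageStartupMessages(library(inundatr))

site_dirs <- list.dirs("results/sites", recursive = FALSE)
if (length(site_dirs) == 0) stop("run analysis/02_run_sites.R first")

trend <- do.call(rbind, lapply(site_dirs, function(d)
  read.csv(file.path(d, "trend.csv"))))
write.csv(trend, "results/trend_summary.csv", row.names = FALSE)

cat("Trend classification of", nrow(trend), "sites:\n")
print(table(factor(trend$trend_class,
                   levels = c("significantly_decreasing", "decreasing", "no_trend",
                              "increasing", "significantly_increasing"))))

meta <- read.csv("results/site_metadata.csv")
tab <- merge(trend[, c("site_id", "trend_class")], meta)
tab$covariate <- tab$elevation_m
ct <- covariate_crosstab(tab, bin_edges = c(0, 250, 1000, 4000, 6000))
write.csv(as.data.frame.matrix(ct), "results/trend_by_elevation.csv")

cat("\nSites per (trend class, elevation bin in metres):\n")
print(ct)
cat("\nWrote results/trend_summary.csv and results/trend_by_elevation.csv\n")
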