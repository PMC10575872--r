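#!/usr/bin/env Rscript
# Aggregate the image-based validation: per-site overall, producer's and
# user's accuracies from the 250-point error matrices, and their averages
# across sites.

suppressPackageStartupMessages(library(inundatr))

site_dirs <- list.dirs("results/sites", recursive = FALSE)
if (length(site_dirs) == 0) stop("run analysis/02_run_sites.R first")

acc <- do.call(rbind, lapply(site_dirs, function(d) {
  em <- read.csv(file.path(d, "error_matrix.csv"))
  v <- setNames(em$value, em$quantity)
  data.frame(site_id = basename(d),
             n_points = v[["n_total"]],
             overall = v[["overall_accuracy_pct"]],
             producers_dry = v[["producers_accuracy_dry_pct"]],
             producers_wet = v[["producers_accuracy_wet_pct"]],
             users_dry = v[["users_accuracy_dry_pct"]],
             users_wet = v[["users_accuracy_wet_pct"]])
}))
write.csv(acc, "results/accuracy_summary.csv", row.names = FALSE)

cat("Validation accuracy by site (percent):\n")
print(acc, row.names = FALSE, digits = 4)
cat(sprintf("\nAverage overall accuracy: %.1f%% (range %.1f-%.1f%%)\n",
            mean(acc$overall), min(acc$overall), max(acc$overall)))
cat(sprintf("Average producer's accuracy: dry %.1f%%, wet %.1f%%\n",
            mean(acc$producers_dry), mean(acc$producers_wet)))
cat(sprintf("Average user's accuracy: dry %.1f%%, wet %.1f%%\n",
            mean(acc$users_dry), mean(acc$users_wet)))
cat("\nWrote results/accuracy_summary.csv\n")
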