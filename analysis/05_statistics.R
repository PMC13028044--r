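#!/usr/bin/env Rscript
# Statistical summary of the deviation grid written by 04: the
# per-family tests (RM-ANOVA + Dunnett, paired t, Bland-Altman) are
# already in the bundle; this driver reports the significant effects and
# renders the per-family figures.

library(atcmdose)

grid_dir <- file.path("results", "grid")
stats_file <- file.path(grid_dir, "stats_summary.csv")
if (!file.exists(stats_file)) {
  stop("run analysis/04_deviation_grid.R first (missing ", stats_file, ")")
}
stats <- read.csv(stats_file)
summary_df <- read.csv(file.path(grid_dir, "summary.csv"))

sig <- stats[stats$p_adjusted < 0.05 & stats$test != "bland_altman", ]
cat(nrow(sig), "of", nrow(stats[stats$test != "bland_altman", ]),
    "family comparisons significant at adjusted p < 0.05\n")
cat("\nsignificant effects by archetype and family:\n")
print(table(sig$archetype, sig$family))

ba <- stats[stats$test == "bland_altman", ]
if (nrow(ba) > 0) {
  cat("\nBland-Altman bias (single - dual, % relative dose difference):\n")
  agg <- aggregate(statistic ~ archetype + family, data = ba, FUN = mean)
  print(agg, row.names = FALSE)
}

fig_dir <- file.path("results", "figures")
dir.create(fig_dir, recursive = TRUE, showWarnings = FALSE)
bundle <- structure(list(rel_diff = read.csv(
  file.path(grid_dir, "relative_differences.csv"))),
  class = "result_bundle")
for (arch in unique(summary_df$archetype)) {
  for (fam in intersect(unique(summary_df$family),
                        c("vertical", "lateral", "localiser",
                          "direction"))) {
    if (!any(summary_df$archetype == arch & summary_df$family == fam)) next
    f <- file.path(fig_dir, paste0(arch, "_", fam, ".png"))
    try(plot_family(bundle, arch, fam, file = f), silent = TRUE)
  }
}
cat("\nfigures under", fig_dir, "\n")
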