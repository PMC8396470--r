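#!/usr/bin/env Rscript
# Step 1 — Inheritance analysis of the dwarf mutant cross.
#
# Tests the published tall / semi-dwarf / dwarf counts of every population
# against candidate single-locus segregation ratios and records the model
# verdict, plus the dwarf / wild-type height ratio.
#
# Run from the repository root: Rscript analysis/01_segregation.R

library(dwarfmapr)
dir.create("results", showWarnings = FALSE)

counts <- study_segregation_counts()
print(counts)

obs <- lapply(seq_len(nrow(counts)), function(i)
  c(counts$tall[i], counts$semi_dwarf[i], counts$dwarf[i]))
names(obs) <- counts$population
totals <- stats::setNames(counts$n_total, counts$population)

# only segregating generations are informative for ratio tests
model <- select_inheritance_model(obs[c("F2", "B11", "B12")],
                                  totals = totals[c("F2", "B11", "B12")])
write.table(model$per_population, "results/01_segregation_tests.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

ph <- study_phenotype_summary()
dwarf_pct <- ph$height_mean_cm[ph$line == "ndf-2"] /
  ph$height_mean_cm[ph$line == "3529"] * 100

summary_lines <- c(
  sprintf("verdict: %s", model$verdict),
  sprintf("F2 chi2 (1:2:1, n = %d): %.4f", totals[["F2"]],
          chi_square_gof(obs$F2, c(1, 2, 1),
                         total = totals[["F2"]])$statistic),
  sprintf("B11 chi2 (1:1 tall:semi): %.4f",
          chi_square_gof(obs$B11, c(1, 1, 0))$statistic),
  sprintf("B12 chi2 (1:1 semi:dwarf): %.4f",
          chi_square_gof(obs$B12, c(0, 1, 1))$statistic),
  sprintf("dwarf height as %% of wild type: %.1f", dwarf_pct))
writeLines(summary_lines, "results/01_segregation_summary.txt")
cat(summary_lines, sep = "\n")
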