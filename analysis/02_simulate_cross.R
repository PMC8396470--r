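#!/usr/bin/env Rscript
# Step 2 — Synthetic study system.
#
# Simulates the biparental cross at the study-scale defaults (fixed a
# priori, seed 1): 3 x 10 Mb genome, 300 F2 plants, bulks of 30, pooled
# sequencing at ~50x. Records the F2 height-class segregation of the
# simulated population and the bulk composition.
#
# Run from the repository root: Rscript analysis/02_simulate_cross.R

library(dwarfmapr)
dir.create("results", showWarnings = FALSE)

config <- cross_config(seed = 1)
print(config)

sim <- simulate_cross(config)
bulks <- assign_bulks(sim)

classes <- classify_heights(sim$f2$height_cm)
gof <- chi_square_gof(classes, c(1, 2, 1))

geno <- table(factor(sim$f2$causal_class,
                     levels = c("hom_wt", "het", "hom_mut")))
write.table(
  data.frame(metric = c("tall", "semi_dwarf", "dwarf",
                        "hom_wt", "het", "hom_mut",
                        "chi2_1_2_1", "p_value",
                        "df_bulk_mut_allele_freq", "wt_bulk_mut_allele_freq"),
             value = c(classes, as.vector(geno),
                       gof$statistic, gof$p_value,
                       pool_alt_freq(sim, bulks$df_pool)[sim$causal_index],
                       pool_alt_freq(sim, bulks$wt_pool)[sim$causal_index])),
  "results/02_f2_summary.tsv", sep = "\t", quote = FALSE, row.names = FALSE)

write_phenotypes(sim$f2, "results/02_f2_phenotypes.tsv")

cat(sprintf("F2 height classes %d:%d:%d, chi2(1:2:1) = %.3f (p = %.3f)\n",
            classes[1], classes[2], classes[3], gof$statistic, gof$p_value))
cat(sprintf("causal mutant-allele frequency: Df-bulk %.3f, WT-bulk %.3f\n",
            pool_alt_freq(sim, bulks$df_pool)[sim$causal_index],
            pool_alt_freq(sim, bulks$wt_pool)[sim$causal_index]))
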