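#!/usr/bin/env Rscript
# Step 4 — Candidate isolation inside the mapped interval.
#
# Annotates the peak-region variants of the seed-1 scan, applies the
# functional prefilter and the four genetic-property exclusion rules, and
# writes the ranked candidate shortlist plus the per-variant exclusion
# reasons. Also demonstrates the differential-expression threshold screen
# (FDR < 0.05, |log2FC| >= 3, i.e. at least 8-fold) on a synthetic table.
#
# Run from the repository root: Rscript analysis/04_candidates.R

library(dwarfmapr)
dir.create("results", showWarnings = FALSE)

res <- run_bsa_pipeline(cross_config(seed = 1))

reasons <- res$annotated[, c("variant_id", "chrom", "pos", "region",
                             "coding_effect", "reasons", "kept")]
write.table(reasons, "results/04_filter_reasons.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(res$shortlist, "results/04_shortlist.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("peak variants: %d; kept after all filters: %d\n",
            nrow(res$annotated), sum(res$annotated$kept)))
cat("exclusion reason tally:\n")
print(sort(table(unlist(strsplit(reasons$reasons[reasons$reasons != ""],
                                 ","))), decreasing = TRUE))
cat("top-ranked candidate:\n")
print(res$shortlist[1, c("rank", "gene_id", "chrom", "pos", "coding_effect",
                         "aa_change", "degron_status", "degron_motif_alt")])

# DEG screen demonstration: the causal-gene knockdown sits well past the
# 8-fold threshold; near-threshold genes illustrate the boundary rules
deg <- data.frame(
  gene_id = c("causal_gene", "fc8_boundary", "fc7_under", "high_fdr"),
  log2fc = c(-5.2, 3.0, log2(7), -4.0),
  fdr = c(1e-6, 0.049, 1e-4, 0.05))
kept <- filter_deg(deg)
write.table(cbind(deg, kept = deg$gene_id %in% kept$gene_id),
            "results/04_deg_screen.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("DEG screen kept:", paste(kept$gene_id, collapse = ", "), "\n")
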