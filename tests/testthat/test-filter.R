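# Genotype calling, functional prefilter, genetic-property rules, shortlist
# and the DEG screen.

test_that("call_genotype applies depth and allele-fraction thresholds", {
  expect_equal(call_genotype(c(50, 20, 3, 1), c(0, 20, 2, 30)),
               c("hom_ref", "het", "missing", "hom_alt"))
  # boundary fractions are inclusive
  expect_equal(call_genotype(c(9, 1), c(1, 9)), c("hom_ref", "hom_alt"))
  expect_equal(call_genotype(11, 9), "het")  # 0.45 alt
  expect_equal(call_genotype(0, 0), "missing")
  expect_equal(call_genotype(5, 5, min_call_depth = 4), "het")
  expect_error(call_genotype(-1, 5))
})

test_that("functional_prefilter keeps functional regions, drops synonymous", {
  ann <- data.frame(
    region = c("exonic", "exonic", "intronic", "intergenic", "utr5",
               "splicing", "upstream", "downstream", "utr3"),
    coding_effect = c("missense", "synonymous", "none", "none", "none",
                      "none", "none", "none", "none"))
  expect_equal(functional_prefilter(ann),
               c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE))
  expect_error(functional_prefilter(data.frame(region = "exonic")),
               "annotated")
})

test_that("each genetic-property rule fires alone on its decoy fixture", {
  # columns: wt_parent, mut_parent, wt_bulk, df_bulk
  fx <- list(
    R1_het_in_wt       = c("het",     "hom_alt", "het",     "hom_alt"),
    R2_wt_inconsistent = c("hom_ref", "hom_alt", "hom_alt", "hom_ref"),
    R3_pools_identical = c("hom_ref", "hom_alt", "hom_ref", "hom_ref"),
    R4_het_in_mut      = c("hom_ref", "het",     "hom_ref", "hom_alt"))
  for (code in names(fx)) {
    g <- fx[[code]]
    res <- genetic_property_filter(g[1], g[2], g[3], g[4])
    expect_false(res$kept)
    expect_equal(res$reasons, code)
  }
})

test_that("the causal genotype pattern survives all rules", {
  res <- genetic_property_filter("hom_ref", "hom_alt", "hom_ref", "hom_alt")
  expect_true(res$kept)
  expect_equal(res$reasons, "")
})

test_that("missing calls and multiple violations are reported correctly", {
  expect_equal(genetic_property_filter("missing", "hom_alt", "hom_ref",
                                       "hom_alt")$reasons, "RM_missing_call")
  # all four rules fire, listed in fixed order R1 -> R4
  res <- genetic_property_filter("het", "het", "hom_alt", "hom_alt")
  expect_equal(res$reasons, paste("R1_het_in_wt", "R2_wt_inconsistent",
                                  "R3_pools_identical", "R4_het_in_mut",
                                  sep = ","))
})

test_that("wt_het_mode switches rule 1 between either and both", {
  # WT-pool het but wild-type parent homozygous
  either <- genetic_property_filter("hom_ref", "hom_alt", "het", "hom_alt")
  expect_true(grepl("R1_het_in_wt", either$reasons))
  both <- genetic_property_filter("hom_ref", "hom_alt", "het", "hom_alt",
                                  wt_het_mode = "both")
  expect_false(grepl("R1_het_in_wt", both$reasons))
  expect_equal(both$reasons, "R2_wt_inconsistent")
})

test_that("filter outcome is independent of row order", {
  set.seed(11)
  states <- c("hom_ref", "het", "hom_alt", "missing")
  g <- replicate(4, sample(states, 50, replace = TRUE), simplify = FALSE)
  res <- genetic_property_filter(g[[1]], g[[2]], g[[3]], g[[4]])
  perm <- sample(50)
  resp <- genetic_property_filter(g[[1]][perm], g[[2]][perm],
                                  g[[3]][perm], g[[4]][perm])
  expect_equal(resp$kept, res$kept[perm])
  expect_equal(resp$reasons, res$reasons[perm])
})

test_that("filter_deg enforces FDR < 0.05 (strict) and |log2FC| >= 3 (inclusive)", {
  recs <- data.frame(gene_id = c("a", "b", "c", "d", "e"),
                     log2fc = c(-3.0, 3.0, 2.9, 8, -4),
                     fdr = c(0.049, 0.05, 0.001, NA, 0.01))
  kept <- filter_deg(recs)
  expect_equal(kept$gene_id, c("a", "e"))
  expect_error(filter_deg(data.frame(gene_id = "x", log2fc = 3, fdr = 1.2)),
               "fdr")
  expect_error(filter_deg(data.frame(gene_id = "x", fc = 3)), "log2fc")
})

test_that("shortlist_candidates ranks by impact tier then linkage evidence", {
  ann <- data.frame(
    chrom = "A01", pos = c(1500, 2500, 3500, 4500),
    variant_id = paste0("v", 1:4), gene_id = paste0("g", 1:4),
    ref = "G", alt = "A",
    region = c("exonic", "exonic", "upstream", "exonic"),
    coding_effect = c("missense", "missense", "none", "missense"),
    codon_change = NA, aa_change = c("G10E", "A5V", NA, "L7P"),
    degron_status = c(NA, "altered", NA, "intact"),
    degron_motif_alt = c(NA, "EWPPV", NA, NA),
    kept = TRUE, delta = c(0.9, 0.8, 0.7, 0.95))
  peaks <- data.frame(chrom = "A01", start = 1000, end = 5000,
                      direction = "positive", peak_delta = 0.9, n_windows = 4L)
  windows <- data.frame(chrom = "A01", start = c(1000, 2000, 3000, 4000),
                        end = c(2000, 3000, 4000, 5000),
                        mean_delta = c(0.5, 0.9, 0.7, 0.6))
  sl <- shortlist_candidates(ann, peaks, windows)
  # degron-altered first, then the two plain missense by windowed delta
  expect_equal(sl$variant_id, c("v2", "v4", "v1", "v3"))
  expect_equal(sl$rank, 1:4)
  expect_equal(sl$windowed_delta, c(0.9, 0.6, 0.5, 0.7))

  # variants outside peaks or not kept are excluded
  ann2 <- ann
  ann2$kept[2] <- FALSE
  expect_false("v2" %in% shortlist_candidates(ann2, peaks, windows)$variant_id)
  far <- ann
  far$pos <- far$pos + 10000
  expect_warning(shortlist_candidates(far, peaks, windows), "no kept variants")

  expect_warning(sl0 <- shortlist_candidates(ann, peaks[0, ], windows),
                 "no peak regions")
  expect_equal(nrow(sl0), 0L)
})

test_that("unlinked decoy markers are excluded in >= 90% of cases over 20 seeds", {
  cfg <- small_config()
  set.seed(4242)
  gen <- simulate_genome(cfg)  # causal on A02; A01 markers are unlinked decoys
  decoy <- which(gen$variants$chrom == "A01")
  causal_id <- sprintf("%s_%d", gen$causal$chrom, gen$causal$pos)
  n_excluded <- 0L
  n_causal_kept <- 0L
  for (s in 1:20) {
    cfg$seed <- s
    sim <- simulate_cross(cfg, genome = gen)
    depths <- simulate_pool_experiment(sim)
    calls <- lapply(c("wt_parent", "mut_parent", "wt_bulk", "df_bulk"),
                    function(p) call_genotype(depths[[paste0(p, "_ref")]],
                                              depths[[paste0(p, "_alt")]]))
    gp <- genetic_property_filter(calls[[1]], calls[[2]], calls[[3]], calls[[4]])
    n_excluded <- n_excluded + sum(!gp$kept[decoy])
    n_causal_kept <- n_causal_kept +
      gp$kept[match(causal_id, depths$variant_id)]
  }
  expect_gte(n_excluded / (20 * length(decoy)), 0.9)
  expect_equal(n_causal_kept, 20L)
})
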