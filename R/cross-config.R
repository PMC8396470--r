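#' Configuration of a simulated biparental cross
#'
#' Builds the full parameterization of the synthetic study system: a cross
#' between two fully homozygous (doubled-haploid) parents, an F2 population
#' segregating for a single semi-dominant dwarfing locus, phenotypic bulks of
#' extreme plants, and pooled short-read sequencing of the bulks and parents.
#'
#' The phenotype model is a three-component Gaussian mixture keyed by the
#' genotype class at the causal locus. Defaults reproduce the study system:
#' wild-type homozygotes ~ N(198.7, 15.9) cm, heterozygotes ~ N(152.1, 12) cm,
#' mutant homozygotes ~ N(86.8, 4.9) cm, so the F2 height distribution is
#' trimodal and heterozygotes are intermediate (semi-dominance).
#'
#' @param n_chromosomes Number of chromosomes (named "A01", "A02", ...).
#' @param chrom_length_bp Length of each chromosome in bp.
#' @param genetic_map_cM_per_Mb Uniform recombination rate. Crossover counts
#'   per meiosis are Poisson with mean equal to the chromosome's genetic
#'   length in Morgans (Haldane model, no interference).
#' @param n_marker_snps Total number of parent-vs-parent marker SNPs,
#'   distributed evenly across chromosomes.
#' @param n_induced_mutations Total number of mutagenesis-derived variants
#'   private to the mutant parent (the planted causal SNP is one of them).
#' @param genes_per_chromosome Number of gene models simulated per chromosome.
#' @param cds_codons Coding length of each simulated gene, in codons
#'   (excluding the stop codon).
#' @param causal_chrom,causal_gene_index Chromosome and gene (index within
#'   that chromosome) carrying the planted causal SNP.
#' @param causal_codon Codon of the causal gene whose second base is mutated
#'   G>A, converting Gly (GGA) to Glu (GAA). The degron motif GWPPV is
#'   planted so that this glycine is its first residue.
#' @param f2_size Number of F2 plants.
#' @param bulk_size Number of plants per phenotypic bulk.
#' @param parent_pool_size Number of clonal individuals per parental pool.
#' @param depth_lambda Mean sequencing depth per site per pool (Poisson).
#' @param error_rate Per-read base miscall probability.
#' @param phenotype_model Named list with components `hom_wt`, `het`,
#'   `hom_mut`, each a numeric `c(mean, sd)` in cm.
#' @param seed Integer RNG seed used by [simulate_cross()].
#'
#' @return An object of class `cross_config` (a validated list).
#' @seealso [simulate_cross()], [assign_bulks()], [write_fixture_set()]
#' @export
#' @examples
#' cfg <- cross_config(f2_size = 100, n_marker_snps = 300)
#' cfg$f2_size
cross_config <- function(n_chromosomes = 3,
                         chrom_length_bp = 10e6,
                         genetic_map_cM_per_Mb = 2,
                         n_marker_snps = 3000,
                         n_induced_mutations = 60,
                         genes_per_chromosome = 20,
                         cds_codons = 300,
                         causal_chrom = "A03",
                         causal_gene_index = 10,
                         causal_codon = 84,
                         f2_size = 300,
                         bulk_size = 30,
                         parent_pool_size = 20,
                         depth_lambda = 50,
                         error_rate = 0.001,
                         phenotype_model = list(
                           hom_wt  = c(198.7, 15.9),
                           het     = c(152.1, 12.0),
                           hom_mut = c(86.8, 4.9)
                         ),
                         seed = 1L) {
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length_bp = as.numeric(chrom_length_bp),
    genetic_map_cM_per_Mb = genetic_map_cM_per_Mb,
    n_marker_snps = as.integer(n_marker_snps),
    n_induced_mutations = as.integer(n_induced_mutations),
    genes_per_chromosome = as.integer(genes_per_chromosome),
    cds_codons = as.integer(cds_codons),
    causal_chrom = causal_chrom,
    causal_gene_index = as.integer(causal_gene_index),
    causal_codon = as.integer(causal_codon),
    f2_size = as.integer(f2_size),
    bulk_size = as.integer(bulk_size),
    parent_pool_size = as.integer(parent_pool_size),
    depth_lambda = depth_lambda,
    error_rate = error_rate,
    phenotype_model = phenotype_model,
    seed = as.integer(seed)
  )
  cfg$chrom_names <- sprintf("A%02d", seq_len(cfg$n_chromosomes))
  validate_cross_config(cfg)
  class(cfg) <- "cross_config"
  cfg
}

validate_cross_config <- function(cfg) {
  stopifnot(
    cfg$n_chromosomes >= 1,
    cfg$chrom_length_bp > 0,
    cfg$genetic_map_cM_per_Mb >= 0,
    cfg$n_marker_snps >= 0,
    cfg$n_induced_mutations >= 1,
    cfg$genes_per_chromosome >= 1,
    cfg$cds_codons >= 1,
    cfg$f2_size >= 1,
    cfg$bulk_size >= 1,
    cfg$parent_pool_size >= 1,
    cfg$depth_lambda > 0
  )
  if (cfg$bulk_size > cfg$f2_size)
    stop("bulk_size must not exceed f2_size")
  if (cfg$error_rate < 0 || cfg$error_rate >= 0.5)
    stop("error_rate must lie in [0, 0.5)")
  pm <- cfg$phenotype_model
  if (!all(c("hom_wt", "het", "hom_mut") %in% names(pm)))
    stop("phenotype_model needs components hom_wt, het, hom_mut")
  if (any(vapply(pm, function(x) length(x) != 2 || any(!is.finite(x)) || x[2] <= 0,
                 logical(1))))
    stop("each phenotype_model component must be a finite c(mean, sd), sd > 0")
  if (!(pm$hom_mut[1] < pm$het[1] && pm$het[1] < pm$hom_wt[1]))
    stop("semi-dominance requires mutant mean < het mean < wild-type mean")
  if (!cfg$causal_chrom %in% cfg$chrom_names)
    stop("causal_chrom is not a simulated chromosome")
  if (cfg$causal_gene_index < 1 || cfg$causal_gene_index > cfg$genes_per_chromosome)
    stop("causal_gene_index out of range")
  if (cfg$causal_codon < 2 || cfg$causal_codon > cfg$cds_codons - 4)
    stop("causal_codon must leave room for the GWPPV motif inside the CDS")
  invisible(cfg)
}

#' @export
print.cross_config <- function(x, ...) {
  cat("Simulated cross configuration\n")
  cat(sprintf("  genome: %d chromosome(s) x %.3g Mb, %.3g cM/Mb\n",
              x$n_chromosomes, x$chrom_length_bp / 1e6, x$genetic_map_cM_per_Mb))
  cat(sprintf("  variants: %d marker SNPs + %d induced mutations (causal in gene %d on %s)\n",
              x$n_marker_snps, x$n_induced_mutations, x$causal_gene_index, x$causal_chrom))
  cat(sprintf("  F2 of %d; bulks of %d; parent pools of %d\n",
              x$f2_size, x$bulk_size, x$parent_pool_size))
  cat(sprintf("  sequencing: depth ~ Poisson(%g), error rate %g\n",
              x$depth_lambda, x$error_rate))
  invisible(x)
}
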