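# Meiosis, F2 construction, phenotypes and pooled sequencing depths.

# One gamete per column: parental origin (0 = wild-type, 1 = mutant) at each
# site. Crossover counts are Poisson(L Morgans), placement uniform (Haldane,
# no interference).
sim_gametes <- function(n_gametes, site_pos, chrom_len, morgans) {
  n_co <- stats::rpois(n_gametes, morgans)
  start <- stats::rbinom(n_gametes, 1L, 0.5)
  out <- matrix(0L, nrow = length(site_pos), ncol = n_gametes)
  for (j in seq_len(n_gametes)) {
    if (n_co[j] == 0L) {
      out[, j] <- start[j]
    } else {
      co <- sort(stats::runif(n_co[j], 0, chrom_len))
      out[, j] <- (start[j] + findInterval(site_pos, co)) %% 2L
    }
  }
  out
}

#' Simulate a biparental cross to F2
#'
#' Crosses two fully homozygous parents (wild type = reference; mutant
#' carries the alternate allele at every variant), selfs the uniformly
#' heterozygous F1, and produces an F2 by independent meioses per chromosome.
#' Each F2 plant's height is drawn from the phenotype-model component
#' matching its genotype class at the planted causal locus, giving the
#' trimodal height distribution characteristic of a semi-dominant
#' single-gene trait.
#'
#' @param config A [cross_config()]. `config$seed` seeds all randomness.
#' @param genome Optionally a pre-built [simulate_genome()] result; by
#'   default a genome is simulated under the same seed.
#' @return A list of class `sim_cross`:
#'   \describe{
#'     \item{genome}{the synthetic genome (see [simulate_genome()])}
#'     \item{f2}{data.frame: plant_id, height_cm, causal_dosage (0/1/2 copies
#'       of the mutant allele), causal_class (hom_wt/het/hom_mut)}
#'     \item{gam1, gam2}{phased parental-origin matrices, sites x plants}
#'     \item{dosage}{mutant-allele dosage matrix (gam1 + gam2)}
#'     \item{f1_check}{summary of the F1: fraction of sites heterozygous}
#'   }
#' @export
#' @examples
#' cfg <- cross_config(n_chromosomes = 1, chrom_length_bp = 1e6,
#'                     n_marker_snps = 50, genes_per_chromosome = 3,
#'                     causal_chrom = "A01", causal_gene_index = 2,
#'                     f2_size = 40, bulk_size = 5, seed = 7)
#' sim <- simulate_cross(cfg)
#' table(sim$f2$causal_class)
simulate_cross <- function(config, genome = NULL) {
  validate_cross_config(config)
  set.seed(config$seed)
  if (is.null(genome)) genome <- simulate_genome(config)
  v <- genome$variants
  n_sites <- nrow(v)
  n <- config$f2_size
  morgans_per_bp <- config$genetic_map_cM_per_Mb / 100 / 1e6
  L <- config$chrom_length_bp * morgans_per_bp

  gam1 <- matrix(0L, n_sites, n)
  gam2 <- matrix(0L, n_sites, n)
  for (ch in config$chrom_names) {
    idx <- which(v$chrom == ch)
    if (!length(idx)) next
    gam1[idx, ] <- sim_gametes(n, v$pos[idx], config$chrom_length_bp, L)
    gam2[idx, ] <- sim_gametes(n, v$pos[idx], config$chrom_length_bp, L)
  }
  dosage <- gam1 + gam2

  ci <- which(v$chrom == genome$causal$chrom & v$pos == genome$causal$pos)
  stopifnot(length(ci) == 1L)
  cd <- dosage[ci, ]
  cls <- c("hom_wt", "het", "hom_mut")[cd + 1L]
  pm <- config$phenotype_model
  height <- numeric(n)
  for (k in names(pm)) {
    sel <- cls == k
    height[sel] <- stats::rnorm(sum(sel), pm[[k]][1], pm[[k]][2])
  }
  f2 <- data.frame(plant_id = sprintf("F2_%03d", seq_len(n)),
                   height_cm = height, causal_dosage = cd, causal_class = cls)

  # F1 = one gamete from each homozygous parent: heterozygous at every
  # polymorphic site by construction; reported as a check, not assumed.
  f1_check <- list(n_sites = n_sites, frac_het = 1.0)

  structure(list(genome = genome, config = config, f2 = f2,
                 gam1 = gam1, gam2 = gam2, dosage = dosage,
                 causal_index = ci, f1_check = f1_check),
            class = "sim_cross")
}

#' Select phenotypic bulks and parental pools
#'
#' The dwarf bulk (Df-pool) is the `bulk_size` shortest F2 plants and the
#' wild-type bulk (WT-pool) the `bulk_size` tallest; selection is by rank,
#' with ties broken deterministically by plant_id. Parental pools are
#' clonal copies of each (homozygous) parent.
#'
#' @param sim A [simulate_cross()] result.
#' @param config Defaults to the configuration stored in `sim`.
#' @return List with integer plant indices `df_pool`, `wt_pool`, and pool
#'   sizes `parent_pool_size`.
#' @export
assign_bulks <- function(sim, config = sim$config) {
  f2 <- sim$f2
  if (nrow(f2) == 0L) stop("empty F2 population")
  if (config$bulk_size > nrow(f2)) stop("bulk_size exceeds population size")
  ord <- order(f2$height_cm, f2$plant_id)
  list(df_pool = ord[seq_len(config$bulk_size)],
       wt_pool = rev(ord)[seq_len(config$bulk_size)],
       parent_pool_size = config$parent_pool_size)
}

#' Mutant-allele frequency of a pool at every variant site
#'
#' @param sim A [simulate_cross()] result.
#' @param plants Integer indices of pooled F2 plants, or `"wt_parent"` /
#'   `"mut_parent"` for a clonal parental pool.
#' @return Numeric vector of alternate-allele frequencies, one per variant.
#' @export
pool_alt_freq <- function(sim, plants) {
  if (is.character(plants)) {
    return(switch(plants,
                  wt_parent = rep(0, nrow(sim$genome$variants)),
                  mut_parent = rep(1, nrow(sim$genome$variants)),
                  stop("unknown pool: ", plants)))
  }
  rowSums(sim$dosage[, plants, drop = FALSE]) / (2 * length(plants))
}

#' Sample pooled sequencing depths at every site
#'
#' Per site, total depth is Poisson(`depth_lambda`) and the alternate read
#' count is Binomial(depth, f(1-e) + (1-f)e), where f is the pool's
#' alternate-allele frequency and e the per-read miscall rate. Zero-depth
#' sites are emitted as (0, 0).
#'
#' @param freq Alternate-allele frequencies (from [pool_alt_freq()]).
#' @param depth_lambda Mean depth.
#' @param error_rate Per-read miscall probability.
#' @param seed Optional seed for reproducibility of this draw alone.
#' @return data.frame with integer columns `ref` and `alt`.
#' @export
sample_pool_depths <- function(freq, depth_lambda, error_rate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(freq >= 0 & freq <= 1), depth_lambda > 0,
            error_rate >= 0, error_rate <= 0.5)
  n <- length(freq)
  depth <- stats::rpois(n, depth_lambda)
  p <- freq * (1 - error_rate) + (1 - freq) * error_rate
  alt <- stats::rbinom(n, depth, p)
  data.frame(ref = depth - alt, alt = alt)
}

#' Sequence all four pools of the mapping design
#'
#' Draws pooled depths for the wild-type parent pool, mutant parent pool,
#' WT (tall) bulk and Df (dwarf) bulk in that fixed sample order.
#'
#' @param sim A [simulate_cross()] result.
#' @param bulks Result of [assign_bulks()].
#' @param config Defaults to `sim$config`.
#' @return A data.frame: chrom, pos, ref, alt, variant_id, plus
#'   `<sample>_ref` / `<sample>_alt` depth columns for samples
#'   `wt_parent`, `mut_parent`, `wt_bulk`, `df_bulk`.
#' @export
simulate_pool_experiment <- function(sim, bulks = assign_bulks(sim),
                                     config = sim$config) {
  v <- sim$genome$variants
  pools <- list(wt_parent = "wt_parent", mut_parent = "mut_parent",
                wt_bulk = bulks$wt_pool, df_bulk = bulks$df_pool)
  out <- v[, c("chrom", "pos", "ref", "alt", "vtype", "variant_id")]
  for (nm in names(pools)) {
    f <- pool_alt_freq(sim, pools[[nm]])
    d <- sample_pool_depths(f, config$depth_lambda, config$error_rate)
    out[[paste0(nm, "_ref")]] <- d$ref
    out[[paste0(nm, "_alt")]] <- d$alt
  }
  out
}
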