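# Causal-mutation isolation: genotype calling from pooled depths,
# functional-class prioritization, the four genetic-property exclusion
# rules, candidate shortlisting and the DEG threshold screen.

FUNCTIONAL_REGIONS <- c("upstream", "utr5", "exonic", "splicing", "utr3",
                        "downstream")

RULE_CODES <- c("R1_het_in_wt", "R2_wt_inconsistent", "R3_pools_identical",
                "R4_het_in_mut", "RM_missing_call", "F0_not_functional")

#' Call a categorical genotype from pooled allele depths
#'
#' A pool is called missing below `min_call_depth`, hom_ref when its
#' alternate-allele fraction is at most `hom_ref_max`, hom_alt at or above
#' `hom_alt_min`, and het in between. The thresholds are the module's own
#' calling convention for pooled samples; all are configurable.
#'
#' @param ref_depth,alt_depth Read counts (vectorized).
#' @param min_call_depth Minimum depth for a call (default 8).
#' @param hom_ref_max,hom_alt_min Alt-fraction cut-offs (defaults 0.1, 0.9).
#' @return Character vector in {hom_ref, het, hom_alt, missing}.
#' @export
#' @examples
#' call_genotype(c(50, 20, 3), c(0, 20, 2))
call_genotype <- function(ref_depth, alt_depth, min_call_depth = 8,
                          hom_ref_max = 0.1, hom_alt_min = 0.9) {
  stopifnot(all(ref_depth >= 0), all(alt_depth >= 0))
  depth <- ref_depth + alt_depth
  frac <- ifelse(depth > 0, alt_depth / depth, NA_real_)
  out <- rep("het", length(depth))
  out[which(frac <= hom_ref_max)] <- "hom_ref"
  out[which(frac >= hom_alt_min)] <- "hom_alt"
  out[depth < min_call_depth] <- "missing"
  out
}

#' Functional-class prioritization of annotated variants
#'
#' Keeps variants in upstream, UTR5, exonic, splicing, UTR3 or downstream
#' regions, excluding synonymous coding changes; everything else (intronic,
#' intergenic, synonymous) is dropped with reason F0_not_functional.
#'
#' @param annotated An [annotate_variants()] table.
#' @return Logical vector `keep` aligned with the rows.
#' @export
functional_prefilter <- function(annotated) {
  if (is.null(annotated$region) || is.null(annotated$coding_effect))
    stop("variants must be annotated (region, coding_effect) first")
  annotated$region %in% FUNCTIONAL_REGIONS &
    annotated$coding_effect != "synonymous"
}

#' Genetic-property exclusion rules for the four-pool design
#'
#' Applies, in fixed order, the exclusion rules that a causal mutation for
#' a recessive-by-descent (mutagenesis-derived) allele must survive:
#' \describe{
#'   \item{R1}{excluded if the wild-type parent or the WT-pool is
#'     heterozygous (`wt_het_mode = "either"`; set `"both"` to require both)}
#'   \item{R2}{excluded if the wild-type parent call differs from the
#'     WT-pool call}
#'   \item{R3}{excluded if the Df-pool call equals the WT-pool call}
#'   \item{R4}{excluded if the mutant parent is heterozygous}
#' }
#' A variant with any missing call is excluded with reason RM_missing_call.
#' All violated rules are reported; a variant is kept iff no rule fires.
#'
#' @param wt_parent,mut_parent,wt_bulk,df_bulk Genotype call vectors from
#'   [call_genotype()].
#' @param wt_het_mode How to read rule 1's "heterozygous in wild-type parent
#'   and WT-pool": `"either"` (default, stricter) or `"both"`.
#' @return data.frame: kept (logical), reasons (comma-separated rule codes,
#'   "" when kept).
#' @export
genetic_property_filter <- function(wt_parent, mut_parent, wt_bulk, df_bulk,
                                    wt_het_mode = c("either", "both")) {
  wt_het_mode <- match.arg(wt_het_mode)
  n <- length(wt_parent)
  stopifnot(length(mut_parent) == n, length(wt_bulk) == n, length(df_bulk) == n)
  miss <- wt_parent == "missing" | mut_parent == "missing" |
    wt_bulk == "missing" | df_bulk == "missing"
  r1 <- if (wt_het_mode == "either") wt_parent == "het" | wt_bulk == "het"
        else wt_parent == "het" & wt_bulk == "het"
  r2 <- wt_parent != wt_bulk
  r3 <- df_bulk == wt_bulk
  r4 <- mut_parent == "het"
  reasons <- character(n)
  for (i in seq_len(n)) {
    if (miss[i]) {
      reasons[i] <- "RM_missing_call"
    } else {
      fired <- c("R1_het_in_wt", "R2_wt_inconsistent", "R3_pools_identical",
                 "R4_het_in_mut")[c(r1[i], r2[i], r3[i], r4[i])]
      reasons[i] <- paste(fired, collapse = ",")
    }
  }
  data.frame(kept = reasons == "", reasons = reasons)
}

impact_tier <- function(coding_effect, region, degron_status) {
  ifelse(!is.na(degron_status) & degron_status == "altered", 1L,
  ifelse(coding_effect %in% c("nonsense", "frameshift"), 2L,
  ifelse(coding_effect %in% c("missense", "inframe_indel"), 3L,
  ifelse(region %in% c("splicing", "utr5", "utr3"), 4L,
  ifelse(region %in% c("upstream", "downstream"), 5L, 6L)))))
}

#' Shortlist candidate variants within peak regions
#'
#' Restricts kept variants to the called peak regions and ranks them by
#' predicted functional impact first (degron-disrupting change, then
#' nonsense/frameshift, missense/in-frame, splicing/UTR, flanking), then by
#' the largest |windowed delta| among windows covering the variant, then by
#' per-site |delta|. Variants of one gene stay adjacent in the per-gene
#' report.
#'
#' @param annotated An [annotate_variants()] table with `kept` and `delta`
#'   columns (see [run_bsa_pipeline()]).
#' @param peaks A [call_peaks()] table.
#' @param windows A [window_bands()] table (for windowed delta lookup).
#' @return data.frame of ranked candidate variants (possibly empty), with
#'   columns rank, gene_id, variant_id, chrom, pos, region, coding_effect,
#'   aa_change, degron_status, windowed_delta, delta.
#' @export
shortlist_candidates <- function(annotated, peaks, windows) {
  if (nrow(peaks) == 0L) {
    warning("no peak regions: empty candidate report")
    return(annotated[0, c("chrom", "pos")])
  }
  in_peak <- rep(FALSE, nrow(annotated))
  for (i in seq_len(nrow(peaks))) {
    in_peak <- in_peak | (annotated$chrom == peaks$chrom[i] &
                            annotated$pos >= peaks$start[i] &
                            annotated$pos <= peaks$end[i])
  }
  cand <- annotated[in_peak & annotated$kept, ]
  if (nrow(cand) == 0L) {
    warning("no kept variants inside peak regions")
    return(cand)
  }
  wd <- vapply(seq_len(nrow(cand)), function(i) {
    w <- windows[windows$chrom == cand$chrom[i] &
                   windows$start <= cand$pos[i] & windows$end > cand$pos[i], ]
    if (!nrow(w) || all(is.na(w$mean_delta))) return(NA_real_)
    max(abs(w$mean_delta), na.rm = TRUE)
  }, numeric(1))
  cand$windowed_delta <- wd
  cand$impact_tier <- impact_tier(cand$coding_effect, cand$region,
                                  cand$degron_status)
  ord <- order(cand$impact_tier, -abs(ifelse(is.na(cand$windowed_delta), 0, cand$windowed_delta)),
               -abs(ifelse(is.na(cand$delta), 0, cand$delta)),
               cand$chrom, cand$pos)
  cand <- cand[ord, ]
  cand$rank <- seq_len(nrow(cand))
  rownames(cand) <- NULL
  keep_cols <- c("rank", "gene_id", "variant_id", "chrom", "pos", "ref", "alt",
                 "region", "coding_effect", "codon_change", "aa_change",
                 "degron_status", "degron_motif_alt", "impact_tier",
                 "windowed_delta", "delta")
  cand[, intersect(keep_cols, names(cand))]
}

#' Differential-expression threshold screen
#'
#' Keeps genes with FDR strictly below `fdr_max` and |log2 fold-change| of
#' at least `min_abs_log2fc`. The default log2 threshold of 3 corresponds
#' to an 8-fold linear change.
#'
#' @param records data.frame with columns gene_id, log2fc, fdr.
#' @param fdr_max FDR cut-off, exclusive (default 0.05).
#' @param min_abs_log2fc |log2FC| cut-off, inclusive (default 3).
#' @return The kept rows of `records`.
#' @export
#' @examples
#' filter_deg(data.frame(gene_id = "g", log2fc = -3, fdr = 0.049))
filter_deg <- function(records, fdr_max = 0.05, min_abs_log2fc = 3) {
  stopifnot(all(c("gene_id", "log2fc", "fdr") %in% names(records)))
  if (any(records$fdr < 0 | records$fdr > 1, na.rm = TRUE))
    stop("fdr must lie in [0, 1]")
  records[!is.na(records$fdr) & records$fdr < fdr_max &
            abs(records$log2fc) >= min_abs_log2fc, , drop = FALSE]
}
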