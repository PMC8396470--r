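# End-to-end driver: simulate -> bulk -> sequence -> scan -> annotate ->
# filter -> shortlist. Every stage is also callable on its own.

#' Run the full bulked-segregant mapping pipeline on a simulated cross
#'
#' Simulates the cross and pooled sequencing under `config`, computes the
#' per-site delta(SNP-index) scan with Monte-Carlo null bands, calls peak
#' regions, annotates the variants inside peaks, applies the functional
#' prefilter and the four genetic-property exclusion rules, and ranks the
#' surviving candidates.
#'
#' @param config A [cross_config()]; `config$seed` drives all randomness.
#' @param window_bp,step_bp,min_sites Sliding-window parameters.
#' @param level Confidence level of the null band (default 0.95).
#' @param n_sim Monte-Carlo replicates per tabulated depth (default 10000).
#' @param min_windows,merge_gap Peak-calling parameters.
#' @param min_depth Per-bulk depth below which sites are low-confidence.
#' @return List: sim, bulks, depths, points, windows, peaks, annotated
#'   (peak variants with calls, reasons, kept), shortlist, causal
#'   (bookkeeping for the planted SNP).
#' @export
run_bsa_pipeline <- function(config = cross_config(),
                             window_bp = 1e6, step_bp = 1e5, min_sites = 5,
                             level = 0.95, n_sim = 10000,
                             min_windows = 3, merge_gap = 1, min_depth = 8) {
  sim <- simulate_cross(config)
  bulks <- assign_bulks(sim)
  depths <- simulate_pool_experiment(sim, bulks)

  points <- delta_index(depths, min_depth = min_depth)
  lens <- stats::setNames(rep(config$chrom_length_bp, config$n_chromosomes),
                          config$chrom_names)
  windows <- sliding_windows(points, window_bp, step_bp, min_sites, lens)
  windows <- window_bands(windows, bulk_size = config$bulk_size,
                          level = level, n_sim = n_sim)
  peaks <- call_peaks(windows, min_windows, merge_gap)

  in_peak <- rep(FALSE, nrow(depths))
  for (i in seq_len(nrow(peaks))) {
    in_peak <- in_peak | (depths$chrom == peaks$chrom[i] &
                            depths$pos >= peaks$start[i] &
                            depths$pos <= peaks$end[i])
  }
  pv <- depths[in_peak, ]
  annotated <- NULL
  shortlist <- pv[0, ]
  if (nrow(pv)) {
    annotated <- annotate_variants(pv, sim$genome$genes, sim$genome$features,
                                   sim$genome$seqs)
    keep_fun <- functional_prefilter(annotated)
    calls <- lapply(c("wt_parent", "mut_parent", "wt_bulk", "df_bulk"),
                    function(s) call_genotype(pv[[paste0(s, "_ref")]],
                                              pv[[paste0(s, "_alt")]],
                                              min_call_depth = min_depth))
    names(calls) <- c("wt_parent", "mut_parent", "wt_bulk", "df_bulk")
    gp <- genetic_property_filter(calls$wt_parent, calls$mut_parent,
                                  calls$wt_bulk, calls$df_bulk)
    reasons <- ifelse(keep_fun, "", "F0_not_functional")
    reasons <- ifelse(gp$reasons == "", reasons,
                      ifelse(reasons == "", gp$reasons,
                             paste(reasons, gp$reasons, sep = ",")))
    annotated$call_wt_parent <- calls$wt_parent
    annotated$call_mut_parent <- calls$mut_parent
    annotated$call_wt_bulk <- calls$wt_bulk
    annotated$call_df_bulk <- calls$df_bulk
    annotated$reasons <- reasons
    annotated$kept <- reasons == ""
    site <- match(annotated$variant_id, points$variant_id)
    annotated$delta <- points$delta[site]
    shortlist <- shortlist_candidates(annotated, peaks, windows)
  }

  list(sim = sim, bulks = bulks, depths = depths, points = points,
       windows = windows, peaks = peaks, annotated = annotated,
       shortlist = shortlist, causal = sim$genome$causal)
}

#' Plot the delta(SNP-index) scan with confidence bands
#'
#' Per-site delta as points, the sliding-window mean as a line and the 95%
#' null band as a ribbon, faceted by chromosome; called peaks shaded.
#'
#' @param points A [delta_index()] table.
#' @param windows A [window_bands()] table.
#' @param peaks Optional [call_peaks()] table.
#' @return A ggplot object.
#' @export
plot_delta_scan <- function(points, windows, peaks = NULL) {
  pts <- points[!points$low_conf & !is.na(points$delta), ]
  wctr <- windows
  wctr$mid <- (wctr$start + wctr$end) / 2
  p <- ggplot2::ggplot() +
    ggplot2::geom_point(data = pts,
                        ggplot2::aes(x = pos / 1e6, y = delta),
                        size = 0.3, alpha = 0.3, colour = "grey40") +
    ggplot2::geom_ribbon(data = wctr[!is.na(wctr$ci_low), ],
                         ggplot2::aes(x = mid / 1e6, ymin = ci_low,
                                      ymax = ci_high),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(data = wctr[!is.na(wctr$mean_delta), ],
                       ggplot2::aes(x = mid / 1e6, y = mean_delta),
                       colour = "firebrick") +
    ggplot2::facet_wrap(~chrom, ncol = 1) +
    ggplot2::labs(x = "position (Mb)", y = expression(Delta * "(SNP-index)")) +
    ggplot2::ylim(-1, 1) +
    ggplot2::theme_bw()
  if (!is.null(peaks) && nrow(peaks)) {
    p <- p + ggplot2::geom_rect(
      data = peaks,
      ggplot2::aes(xmin = start / 1e6, xmax = end / 1e6),
      ymin = -1, ymax = 1, fill = "gold", alpha = 0.15)
  }
  p
}
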