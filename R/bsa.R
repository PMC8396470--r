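# Delta(SNP-index) bulked-segregant scan: per-site indices, sliding-window
# means, Monte-Carlo 95% null bands matched to sequencing depth, and peak
# calling.

#' Per-site SNP-index from pooled allele depths
#'
#' The SNP-index is the fraction of reads carrying the alternate
#' (mutant-parent) allele: alt / (ref + alt). Undefined (NA) at zero depth.
#'
#' @param ref_depth,alt_depth Non-negative integer read counts (vectorized).
#' @return Numeric vector in \[0, 1\], NA where total depth is zero.
#' @export
#' @examples
#' snp_index(10, 30)  # 0.75
snp_index <- function(ref_depth, alt_depth) {
  stopifnot(all(ref_depth >= 0, na.rm = TRUE), all(alt_depth >= 0, na.rm = TRUE))
  tot <- ref_depth + alt_depth
  ifelse(tot == 0, NA_real_, alt_depth / tot)
}

#' Per-site delta(SNP-index) between the dwarf and wild-type bulks
#'
#' Delta is the Df-pool SNP-index minus the WT-pool SNP-index: near +1 at a
#' locus where the dwarf bulk is fixed for the mutant allele and the tall
#' bulk for the wild-type allele, and near 0 at unlinked loci. Sites where
#' either bulk is below `min_depth` are flagged low-confidence and excluded
#' from windowed means.
#'
#' @param depths Pooled-depth variant table ([simulate_pool_experiment()] or
#'   [read_pool_vcf()] output).
#' @param df_sample,wt_sample Sample names of the dwarf and tall bulks.
#' @param min_depth Minimum per-bulk depth for a confident site (default 8).
#' @return data.frame: chrom, pos, variant_id, index_df, index_wt, delta,
#'   depth_df, depth_wt, low_conf.
#' @export
delta_index <- function(depths, df_sample = "df_bulk", wt_sample = "wt_bulk",
                        min_depth = 8) {
  for (s in c(df_sample, wt_sample)) {
    if (!all(paste0(s, c("_ref", "_alt")) %in% names(depths)))
      stop("unknown sample: ", s)
  }
  d_df <- depths[[paste0(df_sample, "_ref")]] + depths[[paste0(df_sample, "_alt")]]
  d_wt <- depths[[paste0(wt_sample, "_ref")]] + depths[[paste0(wt_sample, "_alt")]]
  i_df <- snp_index(depths[[paste0(df_sample, "_ref")]],
                    depths[[paste0(df_sample, "_alt")]])
  i_wt <- snp_index(depths[[paste0(wt_sample, "_ref")]],
                    depths[[paste0(wt_sample, "_alt")]])
  data.frame(chrom = depths$chrom, pos = depths$pos,
             variant_id = if (!is.null(depths$variant_id)) depths$variant_id else
               sprintf("%s_%d", depths$chrom, depths$pos),
             index_df = i_df, index_wt = i_wt, delta = i_df - i_wt,
             depth_df = d_df, depth_wt = d_wt,
             low_conf = d_df < min_depth | d_wt < min_depth)
}

#' Sliding-window mean of delta(SNP-index)
#'
#' Tiles each chromosome with half-open windows \[start, end) of width
#' `window_bp` every `step_bp` and averages delta over confident,
#' non-missing sites. Windows with fewer than `min_sites` usable sites get
#' a missing mean and can never be called significant.
#'
#' @param points A [delta_index()] table, sorted by (chrom, pos).
#' @param window_bp,step_bp Window width and step (bp); `window_bp >=
#'   step_bp > 0`.
#' @param min_sites Minimum usable sites per window (default 5).
#' @param chrom_lengths Named vector of chromosome lengths; defaults to the
#'   last site position per chromosome.
#' @return data.frame: chrom, start, end, n_sites, mean_delta, median_depth.
#' @export
sliding_windows <- function(points, window_bp = 1e6, step_bp = 1e5,
                            min_sites = 5, chrom_lengths = NULL) {
  stopifnot(window_bp >= step_bp, step_bp > 0)
  if (any(tapply(points$pos, points$chrom, is.unsorted)))
    stop("points must be sorted by (chrom, pos)")
  use <- !points$low_conf & !is.na(points$delta)
  out <- list()
  for (ch in unique(points$chrom)) {
    len <- if (!is.null(chrom_lengths)) chrom_lengths[[ch]] else
      max(points$pos[points$chrom == ch])
    starts <- seq(0, max(0, len - window_bp), by = step_bp)
    p <- points[points$chrom == ch & use, ]
    n_sites <- integer(length(starts))
    mean_delta <- rep(NA_real_, length(starts))
    med_depth <- rep(NA_real_, length(starts))
    for (i in seq_along(starts)) {
      in_w <- p$pos >= starts[i] & p$pos < starts[i] + window_bp
      n_sites[i] <- sum(in_w)
      if (n_sites[i] >= min_sites) {
        mean_delta[i] <- mean(p$delta[in_w])
        med_depth[i] <- stats::median((p$depth_df[in_w] + p$depth_wt[in_w]) / 2)
      }
    }
    out[[ch]] <- data.frame(chrom = ch, start = starts,
                            end = starts + window_bp, n_sites = n_sites,
                            mean_delta = mean_delta, median_depth = med_depth)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Monte-Carlo null band for delta(SNP-index) at a given depth
#'
#' Simulates an unlinked marker: each bulk independently draws `bulk_size`
#' F2 plants whose genotypes are i.i.d. 1:2:1 (mutant-allele copies are
#' Binomial(2, 1/2) per plant), giving a pool allele frequency
#' count/(2 * bulk_size); each bulk then draws `depth` reads binomially at
#' that frequency. Returns the empirical (alpha/2, 1-alpha/2) quantiles of
#' the simulated delta. For a backcross design each plant carries 1 or 2
#' mutant-allele copies with equal probability.
#'
#' @param depth Read depth per bulk (>= 1).
#' @param bulk_size Plants per bulk.
#' @param level Confidence level (default 0.95).
#' @param n_sim Number of Monte-Carlo replicates (>= 1000).
#' @param seed Optional seed.
#' @param design "F2" (genotypes 1:2:1) or "BC" (backcross to the mutant
#'   parent, genotypes 1:1).
#' @return Numeric c(lo, hi).
#' @export
null_band <- function(depth, bulk_size, level = 0.95, n_sim = 10000,
                      seed = NULL, design = c("F2", "BC")) {
  design <- match.arg(design)
  stopifnot(depth >= 1, bulk_size >= 1, level > 0, level < 1, n_sim >= 1000)
  if (!is.null(seed)) set.seed(seed)
  draw_freq <- function() {
    if (design == "F2") {
      stats::rbinom(n_sim, 2L * bulk_size, 0.5) / (2 * bulk_size)
    } else {
      (bulk_size + stats::rbinom(n_sim, bulk_size, 0.5)) / (2 * bulk_size)
    }
  }
  idx <- function() stats::rbinom(n_sim, depth, draw_freq()) / depth
  delta <- idx() - idx()
  unname(stats::quantile(delta, c((1 - level) / 2, 1 - (1 - level) / 2)))
}

#' Tabulate null bands over a grid of depths
#'
#' @inheritParams null_band
#' @param depths Integer vector of depths to tabulate.
#' @return data.frame: depth, lo, hi (sorted by depth).
#' @export
null_band_table <- function(depths, bulk_size, level = 0.95, n_sim = 10000,
                            seed = NULL, design = "F2") {
  if (!is.null(seed)) set.seed(seed)
  depths <- sort(unique(as.integer(depths)))
  bands <- vapply(depths, function(d)
    null_band(d, bulk_size, level, n_sim, seed = NULL, design = design),
    numeric(2))
  data.frame(depth = depths, lo = bands[1, ], hi = bands[2, ])
}

#' Interpolate tabulated null bands at arbitrary depths
#'
#' Linear interpolation between tabulated depths; constant beyond the table
#' ends.
#'
#' @param depth Numeric vector of depths.
#' @param table A [null_band_table()].
#' @return data.frame with columns lo, hi aligned with `depth`.
#' @export
band_at_depth <- function(depth, table) {
  if (nrow(table) == 1L) {
    return(data.frame(lo = rep(table$lo, length(depth)),
                      hi = rep(table$hi, length(depth))))
  }
  data.frame(
    lo = stats::approx(table$depth, table$lo, xout = depth, rule = 2)$y,
    hi = stats::approx(table$depth, table$hi, xout = depth, rule = 2)$y)
}

#' Attach null-band bounds to sliding windows
#'
#' Bands are tabulated at the set of (rounded) window median depths and
#' evaluated per window. Windows with missing means get missing bounds.
#'
#' @param windows A [sliding_windows()] table.
#' @param bulk_size Plants per bulk.
#' @inheritParams null_band
#' @return `windows` with columns ci_low, ci_high appended.
#' @export
window_bands <- function(windows, bulk_size, level = 0.95, n_sim = 10000,
                         seed = NULL, design = "F2") {
  md <- round(windows$median_depth)
  known <- !is.na(md)
  windows$ci_low <- NA_real_
  windows$ci_high <- NA_real_
  if (any(known)) {
    tab <- null_band_table(md[known], bulk_size, level, n_sim, seed, design)
    b <- band_at_depth(md[known], tab)
    windows$ci_low[known] <- b$lo
    windows$ci_high[known] <- b$hi
  }
  windows
}

#' Call candidate peak regions from banded windows
#'
#' A window is significant when its mean delta exceeds ci_high (positive
#' direction) or falls below ci_low (negative). Runs of at least
#' `min_windows` same-direction significant windows, tolerating internal
#' gaps of up to `merge_gap` non-significant windows, are merged into peak
#' regions whose bounds are the union of member windows.
#'
#' @param windows A [window_bands()] table.
#' @param min_windows Minimum significant windows per region (default 3).
#' @param merge_gap Maximum internal gap, in windows (default 1).
#' @return data.frame: chrom, start, end, direction, peak_delta, n_windows.
#' @export
call_peaks <- function(windows, min_windows = 3, merge_gap = 1) {
  out <- list()
  for (ch in unique(windows$chrom)) {
    w <- windows[windows$chrom == ch, ]
    w <- w[order(w$start), ]
    sig <- integer(nrow(w))
    def <- !is.na(w$mean_delta) & !is.na(w$ci_low)
    sig[def & w$mean_delta > w$ci_high] <- 1L
    sig[def & w$mean_delta < w$ci_low] <- -1L
    for (dir in c(1L, -1L)) {
      hits <- which(sig == dir)
      if (!length(hits)) next
      grp <- cumsum(c(1L, diff(hits) > merge_gap + 1L))
      for (g in unique(grp)) {
        members <- hits[grp == g]
        if (length(members) < min_windows) next
        block <- w[members, ]
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, start = min(block$start), end = max(block$end),
          direction = if (dir > 0) "positive" else "negative",
          peak_delta = block$mean_delta[which.max(abs(block$mean_delta))],
          n_windows = length(members))
      }
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      direction = character(), peak_delta = numeric(),
                      n_windows = integer()))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Write peak regions as BED (0-based, half-open)
#' @param peaks A [call_peaks()] table.
#' @param path Output file.
#' @export
write_peaks_bed <- function(peaks, path) {
  bed <- data.frame(chrom = peaks$chrom, start = as.integer(peaks$start),
                    end = as.integer(peaks$end),
                    name = paste0("peak_", peaks$direction, "_", seq_len(nrow(peaks))),
                    score = round(1000 * abs(peaks$peak_delta)),
                    strand = ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Exact null distribution of delta(SNP-index) by exhaustive enumeration
#'
#' Brute-force oracle for tiny problems: enumerates all bulk allele-count
#' and read-count outcomes with their probabilities and returns the exact
#' distribution of delta, plus a quantile helper. Used to validate
#' [null_band()].
#'
#' @inheritParams null_band
#' @return List with `support`, `prob`, and `quantile(q)` (smallest support
#'   value with CDF >= q).
#' @export
enumerate_null_delta <- function(depth, bulk_size, design = c("F2", "BC")) {
  design <- match.arg(design)
  copies <- 0:(2 * bulk_size)
  p_copies <- if (design == "F2") {
    stats::dbinom(copies, 2 * bulk_size, 0.5)
  } else {
    c(rep(0, bulk_size), stats::dbinom(0:bulk_size, bulk_size, 0.5))
  }
  reads <- 0:depth
  # P(index value) for one bulk
  p_idx <- numeric(depth + 1)
  for (k in seq_along(copies)) {
    f <- copies[k] / (2 * bulk_size)
    p_idx <- p_idx + p_copies[k] * stats::dbinom(reads, depth, f)
  }
  idx <- reads / depth
  grid <- outer(idx, idx, "-")
  pr <- outer(p_idx, p_idx)
  # collapse floating-point near-duplicates (e.g. 1/3 - 1 vs -2/3)
  vals <- sort(as.vector(grid))
  support <- vals[c(TRUE, diff(vals) > 1e-9)]
  bin <- findInterval(as.vector(grid), support - 1e-9)
  prob <- vapply(seq_along(support),
                 function(i) sum(pr[bin == i]), numeric(1))
  cdf <- cumsum(prob)
  list(support = support, prob = prob,
       quantile = function(q) vapply(q, function(qq)
         support[which(cdf >= qq - 1e-12)[1]], numeric(1)))
}
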