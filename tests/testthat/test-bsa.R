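# Delta(SNP-index) scan: indices, windows, null bands, peaks.

test_that("snp_index and delta_index compute pooled allele-frequency contrasts", {
  expect_equal(snp_index(10, 30), 0.75)
  expect_equal(snp_index(30, 10), 0.25)
  expect_true(is.na(snp_index(0, 0)))
  expect_error(snp_index(-1, 5))

  depths <- data.frame(chrom = "A01", pos = c(100L, 200L, 300L),
                       variant_id = c("a", "b", "c"),
                       wt_bulk_ref = c(40L, 20L, 3L),
                       wt_bulk_alt = c(0L, 20L, 0L),
                       df_bulk_ref = c(0L, 20L, 2L),
                       df_bulk_alt = c(40L, 20L, 2L))
  d <- delta_index(depths, min_depth = 8)
  # fully contrasted site: Df fixed alt, WT fixed ref
  expect_equal(d$delta[1], 1)
  expect_equal(d$index_df[1], 1)
  expect_equal(d$index_wt[1], 0)
  # balanced site
  expect_equal(d$delta[2], 0)
  # shallow site flagged low-confidence
  expect_true(d$low_conf[3])
  expect_false(any(d$low_conf[1:2]))
  expect_error(delta_index(depths, df_sample = "nope"), "unknown sample")
})

test_that("sliding_windows averages confident sites in half-open windows", {
  pts <- data.frame(chrom = "A01",
                    pos = c(100, 200, 300, 1000, 1100, 1200),
                    delta = c(0.1, 0.2, 0.3, 0.5, 0.8, 0.9),
                    depth_df = 20, depth_wt = 20, low_conf = FALSE)
  w <- sliding_windows(pts, window_bp = 1000, step_bp = 500, min_sites = 2,
                       chrom_lengths = c(A01 = 2000))
  expect_equal(w$start, c(0, 500, 1000))
  expect_equal(w$n_sites, c(3L, 3L, 3L))  # pos 1000 excluded from [0, 1000)
  expect_equal(w$mean_delta, c(0.2, (0.5 + 0.8 + 0.9) / 3,
                               (0.5 + 0.8 + 0.9) / 3))
  expect_equal(w$median_depth, c(20, 20, 20))

  # min_sites gates the mean
  w4 <- sliding_windows(pts, 1000, 500, min_sites = 4,
                        chrom_lengths = c(A01 = 2000))
  expect_true(all(is.na(w4$mean_delta)))
  expect_equal(w4$n_sites, c(3L, 3L, 3L))

  # low-confidence sites are excluded from the mean
  pts2 <- pts
  pts2$low_conf[3] <- TRUE
  w2 <- sliding_windows(pts2, 1000, 500, min_sites = 2,
                        chrom_lengths = c(A01 = 2000))
  expect_equal(w2$mean_delta[1], 0.15)

  expect_error(sliding_windows(pts[c(2, 1, 3:6), ], 1000, 500), "sorted")
  expect_error(sliding_windows(pts, 100, 500), "window_bp")
})

test_that("null bands are symmetric around zero and narrow with depth", {
  b <- null_band(50, 30, n_sim = 20000, seed = 1)
  expect_lt(b[1], 0)
  expect_gt(b[2], 0)
  expect_lt(abs(b[1] + b[2]), 0.06)

  widths <- vapply(c(10, 50, 200), function(d) {
    bb <- null_band(d, 30, n_sim = 20000, seed = 2)
    bb[2] - bb[1]
  }, numeric(1))
  expect_true(all(diff(widths) <= 0))
  expect_lt(widths[3], widths[1])

  expect_error(null_band(0, 30), "depth")
  expect_error(null_band(50, 30, n_sim = 10), "n_sim")
})

test_that("exact enumeration matches hand-computed probabilities", {
  ex <- enumerate_null_delta(2, 2)
  expect_equal(sum(ex$prob), 1, tolerance = 1e-12)
  # P(delta = 1) = P(2 alt reads in Df) * P(0 alt in WT) = E[f^2]^2 with
  # f = Binom(4, 1/2) / 4: E[f^2] = 5/16
  expect_equal(ex$prob[which.max(ex$support)], (5 / 16)^2, tolerance = 1e-12)
  expect_equal(ex$quantile(0.975), 1)  # CDF(0.5) = 1 - (5/16)^2 < 0.975
  expect_equal(ex$quantile(0.025), -1)

  ex3 <- enumerate_null_delta(3, 2)
  expect_equal(sum(ex3$prob), 1, tolerance = 1e-12)
  # P(delta = 1) = E[f^3]^2 = (7/32)^2
  expect_equal(ex3$prob[which.max(ex3$support)], (7 / 32)^2, tolerance = 1e-12)
})

test_that("Monte-Carlo bands agree with exhaustive enumeration on tiny grids", {
  for (cfg in list(c(1, 1), c(2, 2), c(3, 2), c(4, 3))) {
    depth <- cfg[1]; bulk <- cfg[2]
    ex <- enumerate_null_delta(depth, bulk)
    mc <- null_band(depth, bulk, n_sim = 50000, seed = 4)
    exq <- ex$quantile(c(0.025, 0.975))
    # agreement within one grid step of the discrete support
    expect_lte(abs(mc[1] - exq[1]), 1 / depth + 1e-9)
    expect_lte(abs(mc[2] - exq[2]), 1 / depth + 1e-9)
  }
})

test_that("band_at_depth interpolates within the table and clamps outside", {
  tab <- data.frame(depth = c(10, 20), lo = c(-0.5, -0.3), hi = c(0.5, 0.3))
  b <- band_at_depth(c(5, 15, 30), tab)
  expect_equal(b$lo, c(-0.5, -0.4, -0.3))
  expect_equal(b$hi, c(0.5, 0.4, 0.3))
  b1 <- band_at_depth(c(1, 99), data.frame(depth = 50, lo = -0.2, hi = 0.2))
  expect_equal(b1$lo, c(-0.2, -0.2))
})

test_that("call_peaks merges significant runs and enforces min_windows", {
  mkw <- function(mean_delta) {
    n <- length(mean_delta)
    data.frame(chrom = "A01", start = seq(0, by = 100, length.out = n),
               end = seq(100, by = 100, length.out = n),
               n_sites = 10L, mean_delta = mean_delta, median_depth = 50,
               ci_low = -0.3, ci_high = 0.3)
  }
  # one positive run of 4; a negative run of 2 is below min_windows
  p1 <- call_peaks(mkw(c(0, 0.5, 0.5, 0.5, 0.5, 0, 0, -0.5, -0.5, 0)))
  expect_equal(nrow(p1), 1L)
  expect_equal(p1$direction, "positive")
  expect_equal(c(p1$start, p1$end), c(100, 500))
  expect_equal(p1$n_windows, 4L)

  # an internal gap of one window is merged at merge_gap = 1
  p2 <- call_peaks(mkw(c(0.5, 0.5, 0, 0.5, 0.5, 0.5)))
  expect_equal(nrow(p2), 1L)
  expect_equal(c(p2$start, p2$end), c(0, 600))
  expect_equal(p2$n_windows, 5L)

  # a gap of two windows splits the run
  p3 <- call_peaks(mkw(c(0.5, 0.5, 0.5, 0, 0, 0.5, 0.5, 0.5)))
  expect_equal(nrow(p3), 2L)
  # ...but is merged when merge_gap allows it
  p3b <- call_peaks(mkw(c(0.5, 0.5, 0.5, 0, 0, 0.5, 0.5, 0.5)), merge_gap = 2)
  expect_equal(nrow(p3b), 1L)

  # negative peaks are called with their own direction
  p4 <- call_peaks(mkw(c(0, -0.6, -0.6, -0.6, 0)))
  expect_equal(p4$direction, "negative")
  expect_equal(p4$peak_delta, -0.6)

  # nothing significant -> empty frame; NA windows can never be significant
  p5 <- call_peaks(mkw(c(0, 0.1, NA, -0.1, 0)))
  expect_equal(nrow(p5), 0L)
})

test_that("window_bands attaches bounds only where a mean exists", {
  w <- data.frame(chrom = "A01", start = c(0, 100), end = c(100, 200),
                  n_sites = c(10L, 1L), mean_delta = c(0.2, NA),
                  median_depth = c(50, NA))
  wb <- window_bands(w, bulk_size = 30, n_sim = 2000, seed = 1)
  expect_false(is.na(wb$ci_low[1]))
  expect_true(is.na(wb$ci_low[2]))
  expect_lt(wb$ci_low[1], 0)
  expect_gt(wb$ci_high[1], 0)
})

test_that("write_peaks_bed emits one line per peak", {
  peaks <- data.frame(chrom = "A01", start = 100, end = 500,
                      direction = "positive", peak_delta = 0.8, n_windows = 4L)
  path <- withr::local_tempfile(fileext = ".bed")
  write_peaks_bed(peaks, path)
  lines <- readLines(path)
  expect_length(lines, 1L)
  expect_equal(strsplit(lines, "\t")[[1]][1:3], c("A01", "100", "500"))
})
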