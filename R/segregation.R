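# Mendelian segregation analysis: height classification and chi-squared
# goodness-of-fit tests against candidate inheritance ratios.

#' Height classification thresholds
#'
#' Plants at or above `tall_min_cm` are tall, at or below `dwarf_max_cm`
#' dwarf, and strictly between the two semi-dwarf. The boundary values
#' themselves go to the extreme classes (tall wins at the tall threshold,
#' dwarf at the dwarf threshold), which keeps the three classes mutually
#' exclusive.
#'
#' @param dwarf_max_cm Upper height bound of the dwarf class (default 110).
#' @param tall_min_cm Lower height bound of the tall class (default 170).
#' @return A `height_class_rule` list.
#' @export
height_class_rule <- function(dwarf_max_cm = 110, tall_min_cm = 170) {
  if (!(dwarf_max_cm < tall_min_cm)) stop("dwarf_max_cm must be < tall_min_cm")
  structure(list(dwarf_max_cm = dwarf_max_cm, tall_min_cm = tall_min_cm),
            class = "height_class_rule")
}

#' Classify plant heights into tall / semi-dwarf / dwarf counts
#'
#' @param heights Numeric vector of plant heights (cm); must be finite and
#'   non-negative.
#' @param rule A [height_class_rule()].
#' @return Named integer vector c(tall, semi_dwarf, dwarf).
#' @export
#' @examples
#' classify_heights(c(200, 150, 90))
classify_heights <- function(heights, rule = height_class_rule()) {
  if (length(heights) == 0L) stop("heights must be non-empty")
  if (any(!is.finite(heights)) || any(heights < 0))
    stop("heights must be finite and non-negative")
  tall <- heights >= rule$tall_min_cm
  dwarf <- heights <= rule$dwarf_max_cm
  c(tall = sum(tall), semi_dwarf = sum(!tall & !dwarf), dwarf = sum(dwarf))
}

#' Chi-squared goodness-of-fit test against an expected segregation ratio
#'
#' Computes the uncorrected Pearson statistic sum((O-E)^2 / E) with expected
#' counts E = total * ratio / sum(ratio). Classes with expected ratio zero
#' are excluded from the statistic and from the degrees of freedom; a
#' positive observed count in such a class is a ratio violation and raises
#' an error unless `strict = FALSE`, in which case the hypothesis is
#' reported as violated with p = 0.
#'
#' `total` defaults to the classified total, but can be set to the full
#' population size when some individuals were measured yet not classified
#' (expected counts then reflect the whole population).
#'
#' @param observed Integer vector of observed class counts.
#' @param ratio Expected ratio vector aligned with `observed`, e.g.
#'   `c(1, 2, 1)`.
#' @param total Population size used for expected counts (default
#'   `sum(observed)`).
#' @param strict Error on a positive count in a zero-expected class?
#' @return A `chisq_gof` list: statistic, df, p_value, observed, expected,
#'   violated.
#' @export
#' @examples
#' chi_square_gof(c(139, 268, 159), c(1, 2, 1), total = 576)$statistic  # 3.125
chi_square_gof <- function(observed, ratio, total = sum(observed),
                           strict = TRUE) {
  if (length(observed) != length(ratio))
    stop("observed and ratio must have the same length")
  if (any(ratio < 0) || all(ratio == 0))
    stop("ratio must be non-negative with at least one positive entry")
  if (any(observed < 0)) stop("observed counts must be non-negative")
  if (total <= 0) stop("total must be positive")

  pos <- ratio > 0
  violated <- any(observed[!pos] > 0)
  if (violated && strict)
    stop("ratio violated: positive observed count in a zero-expected class")

  expected <- total * ratio / sum(ratio)
  if (violated) {
    stat <- Inf; p <- 0
  } else {
    stat <- sum((observed[pos] - expected[pos])^2 / expected[pos])
    p <- stats::pchisq(stat, df = sum(pos) - 1L, lower.tail = FALSE)
  }
  structure(list(statistic = stat, df = sum(pos) - 1L, p_value = p,
                 observed = observed, expected = expected,
                 violated = violated),
            class = "chisq_gof")
}

#' @export
print.chisq_gof <- function(x, ...) {
  cat(sprintf("chi-squared GOF: X2 = %.4g, df = %d, p = %.4g%s\n",
              x$statistic, x$df, x$p_value,
              if (x$violated) " (ratio violated)" else ""))
  invisible(x)
}

#' Candidate segregation ratios for a single-locus model
#'
#' Ratio vectors over (tall, semi-dwarf, dwarf) considered by
#' [select_inheritance_model()].
#' @export
candidate_ratios <- function() {
  list("1:0:0" = c(1, 0, 0), "0:1:0" = c(0, 1, 0), "0:0:1" = c(0, 0, 1),
       "1:2:1" = c(1, 2, 1), "1:1:0" = c(1, 1, 0), "0:1:1" = c(0, 1, 1),
       "3:0:1" = c(3, 0, 1), "1:0:3" = c(1, 0, 3))
}

#' Select the inheritance model consistent with observed segregation
#'
#' Tests each population's (tall, semi-dwarf, dwarf) counts against the
#' candidate ratio set and reports the hypotheses not rejected at `alpha`.
#' The overall verdict is "single semi-dominant gene" when the F2 is
#' consistent with 1:2:1 and any supplied backcrosses with 1:1:0 (to the
#' tall parent) or 0:1:1 (to the dwarf parent); "not segregating" when a
#' population fits a degenerate single-class ratio; otherwise
#' "inconsistent with a single semi-dominant gene".
#'
#' @param counts Named list of count vectors, e.g.
#'   `list(F2 = c(139, 268, 159), B11 = c(73, 91, 0))`.
#' @param totals Optional named vector of population sizes (defaults to the
#'   classified totals; see [chi_square_gof()]).
#' @param alpha Rejection level (default 0.05).
#' @return List with `per_population` (data.frame of all tests), `best`
#'   (named list of accepted ratio labels) and `verdict`.
#' @export
select_inheritance_model <- function(counts, totals = NULL, alpha = 0.05) {
  counts <- counts[vapply(counts, function(x) sum(x) > 0, logical(1))]
  if (length(counts) == 0L) stop("at least one non-empty population required")
  cand <- candidate_ratios()
  rows <- list()
  best <- list()
  for (popn in names(counts)) {
    obs <- counts[[popn]]
    tot <- if (!is.null(totals) && popn %in% names(totals)) totals[[popn]] else sum(obs)
    res <- lapply(cand, function(r) chi_square_gof(obs, r, total = tot,
                                                   strict = FALSE))
    p <- vapply(res, `[[`, numeric(1), "p_value")
    stat <- vapply(res, `[[`, numeric(1), "statistic")
    rows[[popn]] <- data.frame(population = popn, ratio = names(cand),
                               statistic = stat, p_value = p,
                               accepted = p > alpha, row.names = NULL)
    best[[popn]] <- names(cand)[p > alpha]
  }
  tab <- do.call(rbind, rows)

  ok <- function(popn, ratio) !popn %in% names(best) || ratio %in% best[[popn]]
  degenerate <- c("1:0:0", "0:1:0", "0:0:1")
  if (!"F2" %in% names(best)) {
    verdict <- "no F2 supplied"
  } else if (length(best$F2) > 0 && all(best$F2 %in% degenerate)) {
    verdict <- "not segregating"
  } else if ("1:2:1" %in% best$F2 && ok("B11", "1:1:0") && ok("B12", "0:1:1")) {
    verdict <- "single semi-dominant gene"
  } else {
    verdict <- "inconsistent with a single semi-dominant gene"
  }
  list(per_population = tab, best = best, verdict = verdict)
}
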