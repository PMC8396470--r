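# Allele-specific PCR (AS-PCR) marker design with the artificial-mismatch
# rule: the allele-specific primer ends exactly at the SNP (3' base = target
# allele) and carries one engineered mismatch at the third base from the 3'
# end, which sharpens discrimination between alleles.

# Destabilizing substitution map for the artificial mismatch (transversions)
MISMATCH_MAP <- c(A = "C", C = "A", G = "T", T = "G")

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Primer melting temperature by the Wallace rule
#' @param primer Primer sequence.
#' @return Tm in degrees C: 2(A+T) + 4(G+C).
#' @export
wallace_tm <- function(primer) {
  b <- strsplit(toupper(primer), NULL)[[1]]
  2 * sum(b %in% c("A", "T")) + 4 * sum(b %in% c("G", "C"))
}

has_homopolymer <- function(s, n = 6) {
  grepl(sprintf("A{%d}|C{%d}|G{%d}|T{%d}", n, n, n, n), toupper(s))
}

# Choose a primer length whose Tm falls inside the window, preferring the
# Tm closest to the window midpoint; NA length if none qualifies.
best_length <- function(make_primer, len_range, tm_window) {
  lens <- seq(len_range[1], len_range[2])
  tms <- vapply(lens, function(l) wallace_tm(make_primer(l)), numeric(1))
  ok <- tms >= tm_window[1] & tms <= tm_window[2]
  if (!any(ok)) return(NA_integer_)
  lens[ok][which.min(abs(tms[ok] - mean(tm_window)))]
}

#' Design an allele-specific PCR primer pair for a SNP
#'
#' The allele-specific (upstream) primer is taken from the template so that
#' its 3'-terminal base sits on the SNP and equals the target allele; the
#' third base from the 3' end (counting the SNP as position 1) is replaced
#' by the fixed artificial-mismatch map A<->C, G<->T. The common (reverse)
#' primer is the reverse complement of a template window placed so the
#' amplicon spans exactly `product_len_target` bp (distance between primer
#' 5' ends + 1). Primer lengths are tuned within `len_range` so each Tm
#' (Wallace rule) falls inside `tm_window`; designs over homopolymer runs
#' of 6+ or with insufficient flanking sequence are rejected.
#'
#' @param template Template (plus-strand) DNA sequence, character scalar.
#' @param snp_pos 1-based SNP position in `template`.
#' @param target_allele Base the primer should detect (e.g. the mutant
#'   allele).
#' @param product_len_target Amplicon length in bp.
#' @param primer_len Preferred allele-specific primer length (default 20).
#' @param len_range Allowed primer lengths while tuning Tm.
#' @param tm_window Acceptable Tm range in degrees C (default 55-65).
#' @param strand Design strand: `"+"` anneals the allele-specific primer on
#'   the plus strand with the amplicon extending rightward; `"-"` designs on
#'   the reverse complement (amplicon extends leftward).
#' @param mismatch_map Named substitution map for the artificial mismatch.
#' @return An `aspcr_design` list: allele_specific_primer, common_primer,
#'   mismatch_pos (= 3), product_length, snp (list), tm values.
#' @export
design_as_primer <- function(template, snp_pos, target_allele,
                             product_len_target = 798, primer_len = 20,
                             len_range = c(18, 28), tm_window = c(55, 65),
                             strand = c("+", "-"),
                             mismatch_map = MISMATCH_MAP) {
  strand <- match.arg(strand)
  template <- toupper(template)
  if (strand == "-") {
    rc <- revcomp(template)
    des <- design_as_primer(rc, nchar(template) - snp_pos + 1L,
                            comp_base(target_allele), product_len_target,
                            primer_len, len_range, tm_window, "+",
                            mismatch_map)
    des$strand <- "-"
    des$snp$pos <- snp_pos
    return(des)
  }
  n <- nchar(template)
  if (snp_pos < len_range[1])
    stop("insufficient 5' flank for the allele-specific primer")
  if (snp_pos - primer_len + product_len_target > n)
    stop("insufficient 3' flank for the requested product length")

  make_as <- function(l) {
    p <- substr(template, snp_pos - l + 1L, snp_pos)
    substr(p, l, l) <- toupper(target_allele)
    third <- substr(p, l - 2L, l - 2L)
    substr(p, l - 2L, l - 2L) <- unname(mismatch_map[third])
    p
  }
  l_as <- best_length(make_as, c(max(len_range[1], 5), min(len_range[2], snp_pos)),
                      tm_window)
  if (is.na(l_as)) l_as <- primer_len
  as_primer <- make_as(l_as)
  as_start <- snp_pos - l_as + 1L

  common_end <- as_start + product_len_target - 1L
  if (common_end > n) stop("insufficient 3' flank for the requested product length")
  make_common <- function(l) revcomp(substr(template, common_end - l + 1L, common_end))
  l_c <- best_length(make_common, len_range, tm_window)
  if (is.na(l_c)) l_c <- primer_len
  common_primer <- make_common(l_c)

  for (p in c(as_primer, common_primer)) {
    if (has_homopolymer(p))
      stop("design rejected: homopolymer run of 6+ under a primer")
  }

  structure(list(
    allele_specific_primer = as_primer,
    common_primer = common_primer,
    mismatch_pos = 3L,
    product_length = common_end - as_start + 1L,
    snp = list(pos = snp_pos, target_allele = toupper(target_allele)),
    strand = "+",
    as_primer_start = as_start,
    common_primer_end = common_end,
    tm = c(allele_specific = wallace_tm(as_primer),
           common = wallace_tm(common_primer))
  ), class = "aspcr_design")
}

#' @export
print.aspcr_design <- function(x, ...) {
  cat("AS-PCR design\n")
  cat(sprintf("  allele-specific primer (5'->3'): %s (Tm %.0f C)\n",
              x$allele_specific_primer, x$tm[["allele_specific"]]))
  cat(sprintf("  common primer (5'->3'):          %s (Tm %.0f C)\n",
              x$common_primer, x$tm[["common"]]))
  cat(sprintf("  target allele %s at template pos %d; artificial mismatch at 3'-offset %d\n",
              x$snp$target_allele, x$snp$pos, x$mismatch_pos))
  cat(sprintf("  product length: %d bp\n", x$product_length))
  invisible(x)
}

#' Predict AS-PCR products on template haplotypes
#'
#' Simulates primer annealing with a 3'-end rule: the allele-specific
#' primer amplifies a template only when its 3'-terminal base matches
#' exactly and at most `max_mismatches_3prime` of its final three bases
#' mismatch (the engineered artificial mismatch accounts for one on the
#' targeted allele; the non-target allele adds a terminal mismatch and
#' fails). The common primer must match its site perfectly. Templates too
#' short to contain the locus yield no product.
#'
#' @param design An [design_as_primer()] result (plus-strand design).
#' @param templates Named character vector / list of haplotype sequences in
#'   the same coordinates as the design template.
#' @param max_mismatches_3prime Allowed mismatches in the primer's final 3
#'   bases (default 1).
#' @return data.frame: template, product (logical), product_length.
#' @export
in_silico_pcr <- function(design, templates, max_mismatches_3prime = 1) {
  res <- lapply(names(templates), function(nm) {
    tpl <- toupper(templates[[nm]])
    ok <- FALSE
    if (design$common_primer_end <= nchar(tpl) && design$as_primer_start >= 1) {
      p <- design$allele_specific_primer
      l <- nchar(p)
      site <- substr(tpl, design$as_primer_start, design$as_primer_start + l - 1L)
      last3_p <- substr(p, l - 2L, l)
      last3_t <- substr(site, l - 2L, l)
      mm <- sum(strsplit(last3_p, NULL)[[1]] != strsplit(last3_t, NULL)[[1]])
      terminal_ok <- substr(p, l, l) == substr(site, l, l)
      common_site <- substr(tpl, design$common_primer_end - nchar(design$common_primer) + 1L,
                            design$common_primer_end)
      common_ok <- revcomp(design$common_primer) == common_site
      ok <- terminal_ok && mm <= max_mismatches_3prime && common_ok
    }
    data.frame(template = nm, product = ok,
               product_length = if (ok) design$product_length else NA_integer_)
  })
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}
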