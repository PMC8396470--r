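# Variant-effect annotation: genic context, codon-level coding consequence,
# and Aux/IAA degron (GWPPV) motif status.

REGION_LEVELS <- c("splicing", "exonic", "utr5", "utr3", "intronic",
                   "upstream", "downstream", "intergenic")

# CDS intervals of a gene in transcript (5'->3') order
cds_intervals <- function(features, gene_id) {
  cds <- features[features$gene_id == gene_id & features$type == "CDS", ]
  if (!nrow(cds)) stop("gene has no CDS: ", gene_id)
  strand <- cds$strand[1]
  cds[order(cds$start * if (strand == "+") 1 else -1), ]
}

# Spliced, strand-oriented CDS sequence (character scalar)
spliced_cds <- function(seqs, features, gene_id) {
  cds <- cds_intervals(features, gene_id)
  gen_order <- cds[order(cds$start), ]
  pieces <- as.character(Biostrings::extractAt(
    seqs[[cds$chrom[1]]], IRanges::IRanges(gen_order$start, gen_order$end)))
  s <- paste(pieces, collapse = "")
  if (cds$strand[1] == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}

# Map a genomic position to its 1-based coordinate in the spliced CDS
genomic_to_cds <- function(cds, pos) {
  widths <- cds$end - cds$start + 1L
  before <- cumsum(c(0L, widths[-length(widths)]))
  for (i in seq_len(nrow(cds))) {
    if (pos >= cds$start[i] && pos <= cds$end[i]) {
      return(before[i] + if (cds$strand[i] == "+") pos - cds$start[i] + 1L
             else cds$end[i] - pos + 1L)
    }
  }
  NA_integer_
}

comp_base <- function(b) chartr("ACGTacgt", "TGCAtgca", b)

# Translate one codon. Alternative-initiation rules (TTG/CTG -> Met) apply
# only to the first codon of a CDS, so internal codons must be translated
# with no.init.codon = TRUE.
translate_codon <- function(codon, is_first) {
  as.character(Biostrings::translate(Biostrings::DNAString(codon),
                                     no.init.codon = !is_first))
}

#' Translate a coding sequence with the standard genetic code
#' @param cds Character scalar of A/C/G/T with length divisible by 3.
#' @return Amino-acid string ("*" marks stop codons).
#' @export
translate_cds <- function(cds) {
  as.character(Biostrings::translate(Biostrings::DNAString(cds)))
}

#' Classify the genic context of variants
#'
#' Assigns each variant one region from upstream, utr5, exonic, splicing,
#' intronic, utr3, downstream, intergenic, with overlap precedence
#' splicing > exonic > UTR > intronic > upstream/downstream > intergenic.
#' "Exonic" means overlapping CDS; exonic positions within a UTR are
#' reported as utr5/utr3. Splicing covers intronic positions within
#' `splice_window` bp of an exon boundary and any variant spanning an
#' exon-intron junction. Upstream/downstream are the strand-appropriate
#' flanks within `flank_bp` of the gene.
#'
#' @param variants data.frame with chrom, pos, ref, alt.
#' @param genes,features Gene-model tables ([simulate_genome()] or
#'   [read_gene_gff3()] layout).
#' @param flank_bp Flank width defining upstream/downstream (default 2000).
#' @param splice_window Intronic bp near a junction called splicing
#'   (default 2).
#' @return data.frame: region, gene_id (NA when intergenic).
#' @export
classify_region <- function(variants, genes, features, flank_bp = 2000,
                            splice_window = 2) {
  n <- nrow(variants)
  region <- rep("intergenic", n)
  gene_id <- rep(NA_character_, n)
  known <- variants$chrom %in% unique(genes$chrom)
  if (!all(known))
    warning("variant(s) on unknown chromosome classified intergenic")

  vstart <- variants$pos
  vend <- variants$pos + pmax(nchar(variants$ref) - 1L, 0L)
  kidx <- which(known)
  gv <- GenomicRanges::GRanges(variants$chrom[kidx],
                               IRanges::IRanges(vstart[kidx], vend[kidx]))
  gg <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start - flank_bp,
                                                genes$end + flank_bp))
  hits <- GenomicRanges::findOverlaps(gv, gg, ignore.strand = TRUE)

  rank <- stats::setNames(seq_along(REGION_LEVELS), REGION_LEVELS)
  best_rank <- rep(rank[["intergenic"]], n)

  for (h in seq_along(hits)) {
    vi <- kidx[S4Vectors::queryHits(hits)[h]]
    gi <- S4Vectors::subjectHits(hits)[h]
    g <- genes[gi, ]
    f <- features[features$gene_id == g$gene_id, ]
    ex <- f[f$type == "exon", ]
    r <- classify_one(vstart[vi], vend[vi], g, ex,
                      f[f$type == "CDS", ], f[f$type == "five_prime_UTR", ],
                      f[f$type == "three_prime_UTR", ], splice_window)
    if (rank[[r]] < best_rank[vi]) {
      best_rank[vi] <- rank[[r]]
      region[vi] <- r
      gene_id[vi] <- if (r == "intergenic") NA_character_ else g$gene_id
    }
  }
  data.frame(region = region, gene_id = gene_id)
}

# Region of one variant relative to one gene (vs..ve overlaps gene +- flank)
classify_one <- function(vs, ve, gene, exons, cds, utr5, utr3, splice_window) {
  overlaps <- function(d) any(vs <= d$end & ve >= d$start)
  inside_gene <- vs <= gene$end & ve >= gene$start
  if (inside_gene) {
    in_exon <- overlaps(exons)
    # introns: gaps between consecutive exons (genomic order)
    exo <- exons[order(exons$start), ]
    in_intron <- FALSE; near_junction <- FALSE
    if (nrow(exo) > 1) {
      for (i in seq_len(nrow(exo) - 1)) {
        is_ <- exo$end[i] + 1L; ie <- exo$start[i + 1] - 1L
        if (ie < is_) next
        if (vs <= ie && ve >= is_) in_intron <- TRUE
        sw <- min(splice_window, ie - is_ + 1L)
        if ((vs <= is_ + sw - 1L && ve >= is_) || (vs <= ie && ve >= ie - sw + 1L))
          near_junction <- TRUE
      }
    }
    if (near_junction || (in_exon && in_intron)) return("splicing")
    if (overlaps(cds)) return("exonic")
    if (nrow(utr5) && overlaps(utr5)) return("utr5")
    if (nrow(utr3) && overlaps(utr3)) return("utr3")
    if (in_intron) return("intronic")
    return("exonic")  # exon but neither CDS nor UTR annotated
  }
  before <- ve < gene$start
  if (gene$strand == "+") {
    if (before) "upstream" else "downstream"
  } else {
    if (before) "downstream" else "upstream"
  }
}

#' Codon-level coding consequence of a variant
#'
#' Builds the spliced, strand-oriented CDS from the reference sequence,
#' substitutes the alternate allele, and reports the consequence. SNPs are
#' classified synonymous / missense / nonsense by translating the affected
#' codon; insertions or deletions are frameshift when the length change is
#' not a multiple of 3, in-frame otherwise. The reference allele is checked
#' against the FASTA and a mismatch is a hard error.
#'
#' @param variant One-row data.frame (chrom, pos, ref, alt).
#' @param gene_id Gene whose CDS the variant overlaps.
#' @param seqs Reference DNAStringSet.
#' @param features Feature table with CDS intervals.
#' @return List: coding_effect, codon_change, aa_change, protein_ref,
#'   protein_alt.
#' @export
coding_consequence <- function(variant, gene_id, seqs, features) {
  cds <- cds_intervals(features, gene_id)
  strand <- cds$strand[1]
  chrom <- cds$chrom[1]

  ref_at <- as.character(Biostrings::subseq(
    seqs[[chrom]], variant$pos, variant$pos + nchar(variant$ref) - 1L))
  if (ref_at != variant$ref)
    stop(sprintf("reference mismatch at %s:%d: FASTA has %s, variant claims %s",
                 chrom, variant$pos, ref_at, variant$ref))

  cds_seq <- spliced_cds(seqs, features, gene_id)
  protein_ref <- translate_cds(cds_seq)

  if (nchar(variant$ref) == 1L && nchar(variant$alt) == 1L) {
    cpos <- genomic_to_cds(cds, variant$pos)
    if (is.na(cpos)) stop("variant does not overlap the CDS of ", gene_id)
    alt_base <- if (strand == "+") variant$alt else comp_base(variant$alt)
    cds_alt <- cds_seq
    substr(cds_alt, cpos, cpos) <- alt_base
    codon_i <- (cpos - 1L) %/% 3L + 1L
    from <- substr(cds_seq, 3L * codon_i - 2L, 3L * codon_i)
    to <- substr(cds_alt, 3L * codon_i - 2L, 3L * codon_i)
    aa_from <- translate_codon(from, codon_i == 1L)
    aa_to <- translate_codon(to, codon_i == 1L)
    effect <- if (aa_from == aa_to) "synonymous"
      else if (aa_to == "*") "nonsense" else "missense"
    list(coding_effect = effect,
         codon_change = paste0(from, ">", to),
         aa_change = if (effect == "synonymous") paste0(aa_from, codon_i, aa_from)
                     else paste0(aa_from, codon_i, aa_to),
         protein_ref = protein_ref,
         protein_alt = translate_cds(cds_alt))
  } else {
    shift <- abs(nchar(variant$alt) - nchar(variant$ref))
    effect <- if (shift %% 3L != 0L) "frameshift" else "inframe_indel"
    list(coding_effect = effect, codon_change = NA_character_,
         aa_change = NA_character_, protein_ref = protein_ref,
         protein_alt = NA_character_)
  }
}

#' Status of the Aux/IAA degron motif after a mutation
#'
#' Locates the conserved domain-II degradation motif (GWPPV by default) in
#' the reference protein and reports whether the mutant protein leaves it
#' intact, alters it (returning the mutant motif, e.g. EWPPV), or whether
#' the reference lacks it.
#'
#' @param protein_ref,protein_alt Amino-acid strings.
#' @param motif Degron motif (default "GWPPV").
#' @return List: status ("intact", "altered", "absent"), motif_ref,
#'   motif_alt, position (1-based residue of the motif start, NA if absent).
#' @export
degron_check <- function(protein_ref, protein_alt, motif = "GWPPV") {
  pos <- regexpr(motif, protein_ref, fixed = TRUE)
  if (pos < 0)
    return(list(status = "absent", motif_ref = NA_character_,
                motif_alt = NA_character_, position = NA_integer_))
  alt <- if (is.na(protein_alt)) NA_character_ else
    substr(protein_alt, pos, pos + nchar(motif) - 1L)
  status <- if (is.na(alt)) "unknown"
    else if (alt == motif) "intact" else "altered"
  list(status = status, motif_ref = motif, motif_alt = alt,
       position = as.integer(pos))
}

#' Annotate a variant table against gene models and the reference
#'
#' Combines [classify_region()], [coding_consequence()] (for CDS-overlapping
#' variants) and [degron_check()] into one annotation table.
#'
#' @param variants data.frame with chrom, pos, ref, alt.
#' @param genes,features Gene models.
#' @param seqs Reference DNAStringSet.
#' @inheritParams classify_region
#' @return `variants` with region, gene_id, coding_effect, codon_change,
#'   aa_change, degron_status, degron_motif_alt appended.
#' @export
annotate_variants <- function(variants, genes, features, seqs,
                              flank_bp = 2000, splice_window = 2) {
  reg <- classify_region(variants, genes, features, flank_bp, splice_window)
  out <- cbind(variants, reg)
  out$coding_effect <- "none"
  out$codon_change <- NA_character_
  out$aa_change <- NA_character_
  out$degron_status <- NA_character_
  out$degron_motif_alt <- NA_character_
  cds_rows <- which(out$region == "exonic")
  for (i in cds_rows) {
    cds <- cds_intervals(features, out$gene_id[i])
    in_cds <- any(out$pos[i] >= cds$start & out$pos[i] <= cds$end)
    if (!in_cds) next
    cc <- coding_consequence(out[i, ], out$gene_id[i], seqs, features)
    out$coding_effect[i] <- cc$coding_effect
    out$codon_change[i] <- cc$codon_change
    out$aa_change[i] <- cc$aa_change
    dg <- degron_check(cc$protein_ref, cc$protein_alt)
    out$degron_status[i] <- dg$status
    out$degron_motif_alt[i] <- dg$motif_alt
  }
  out
}
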