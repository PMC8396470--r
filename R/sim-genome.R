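# Synthetic genome: reference sequence, gene models and segregating variants.
# The reference equals the wild-type parent; the mutant parent carries the
# alternate allele at every marker SNP and every induced mutation.

SENSE_CODONS <- setdiff(names(Biostrings::GENETIC_CODE),
                        c("TAA", "TAG", "TGA"))

DNA_RAW <- charToRaw("ACGT")

#' @keywords internal
random_dna <- function(n) {
  rawToChar(DNA_RAW[sample.int(4L, n, replace = TRUE)])
}

# Codon string for a CDS of n codons with no internal stop; the degron block
# GGA-TGG-CCG-CCA-GTG (GWPPV) is planted at `motif_codon` when not NA.
random_cds <- function(n_codons, motif_codon = NA) {
  codons <- sample(SENSE_CODONS, n_codons, replace = TRUE)
  if (!is.na(motif_codon)) {
    codons[motif_codon:(motif_codon + 4)] <- c("GGA", "TGG", "CCG", "CCA", "GTG")
  }
  codons
}

# Lay out one gene at `start` (leftmost genomic bp). Structure in transcript
# orientation: 5'UTR, exon1-CDS, intron, exon2-CDS, 3'UTR. For minus-strand
# genes the genomic layout is mirrored. Returns feature intervals plus the
# genomic sequence of the gene footprint.
build_gene <- function(gene_id, chrom, strand, start, cds_codons,
                       motif_codon = NA) {
  u5 <- 120L; intron <- 400L; u3 <- 150L
  cds_len <- 3L * cds_codons
  ex1_cds <- min(150L, 3L * (cds_codons %/% 2L))
  ex2_cds <- cds_len - ex1_cds

  codons <- random_cds(cds_codons, motif_codon)
  cds_seq <- paste(codons, collapse = "")
  tx_seq <- paste0(random_dna(u5), substr(cds_seq, 1L, ex1_cds))
  tx_seq2 <- paste0(substr(cds_seq, ex1_cds + 1L, cds_len), random_dna(u3))
  intron_seq <- random_dna(intron)

  # plus-orientation genomic blocks
  blocks <- c(u5 = u5, ex1 = ex1_cds, intron = intron, ex2 = ex2_cds, u3 = u3)
  ends <- start - 1L + cumsum(blocks)
  starts <- c(start, ends[-length(ends)] + 1L)
  names(starts) <- names(blocks)
  span <- c(start, ends[["u3"]])

  plus_seq <- paste0(tx_seq, intron_seq, tx_seq2)
  if (strand == "+") {
    gseq <- plus_seq
    iv <- list(
      exon = data.frame(start = c(starts[["u5"]], starts[["ex2"]]),
                        end = c(ends[["ex1"]], ends[["u3"]])),
      cds  = data.frame(start = c(starts[["ex1"]], starts[["ex2"]]),
                        end = c(ends[["ex1"]], ends[["ex2"]])),
      utr5 = data.frame(start = starts[["u5"]], end = ends[["u5"]]),
      utr3 = data.frame(start = starts[["u3"]], end = ends[["u3"]])
    )
  } else {
    gseq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(plus_seq)))
    # mirror intervals within the span
    flip <- function(d) {
      data.frame(start = span[2] - (d$end - span[1]),
                 end = span[2] - (d$start - span[1]))[rev(seq_len(nrow(d))), , drop = FALSE]
    }
    iv <- list(
      exon = flip(data.frame(start = c(starts[["u5"]], starts[["ex2"]]),
                             end = c(ends[["ex1"]], ends[["u3"]]))),
      cds  = flip(data.frame(start = c(starts[["ex1"]], starts[["ex2"]]),
                             end = c(ends[["ex1"]], ends[["ex2"]]))),
      utr5 = flip(data.frame(start = starts[["u5"]], end = ends[["u5"]])),
      utr3 = flip(data.frame(start = starts[["u3"]], end = ends[["u3"]]))
    )
  }
  feats <- do.call(rbind, lapply(names(iv), function(ty) {
    d <- iv[[ty]]
    data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
               type = c(exon = "exon", cds = "CDS", utr5 = "five_prime_UTR",
                        utr3 = "three_prime_UTR")[[ty]],
               start = d$start, end = d$end, row.names = NULL)
  }))
  list(gene = data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                         start = span[1], end = span[2]),
       features = feats, seq = gseq, span = span,
       ex1_cds = ex1_cds, cds_len = cds_len)
}

# Genomic position of a CDS coordinate (1-based within the spliced CDS,
# 5'->3' in transcript orientation) for a gene's CDS intervals.
cds_pos_to_genomic <- function(cds_iv, strand, cds_pos) {
  widths <- cds_iv$end - cds_iv$start + 1L
  cum <- cumsum(widths)
  i <- which(cds_pos <= cum)[1]
  if (is.na(i)) stop("cds_pos beyond CDS length")
  off <- cds_pos - c(0L, cum)[i] - 1L
  if (strand == "+") cds_iv$start[i] + off else cds_iv$end[i] - off
}

#' Simulate the reference genome, gene models and segregating variants
#'
#' Internal workhorse of [simulate_cross()], exported for direct access to
#' fixture genomes. Generates random chromosome sequences, regularly spaced
#' two-exon gene models (alternating strands), genome-wide marker SNPs,
#' induced mutations private to the mutant parent, and the planted causal
#' SNP: a G>A substitution at the second base of the GGA codon that opens the
#' causal gene's GWPPV degron motif, so its protein consequence is Gly>Glu.
#'
#' @param config A [cross_config()].
#' @return A list with elements `seqs` (DNAStringSet reference), `genes`,
#'   `features` (exon/CDS/UTR intervals), `variants` (chrom, pos, ref, alt,
#'   vtype, origin) and `causal` (locus bookkeeping).
#' @export
simulate_genome <- function(config) {
  validate_cross_config(config)
  chroms <- config$chrom_names
  len <- as.integer(config$chrom_length_bp)

  seqs <- character(length(chroms))
  names(seqs) <- chroms
  genes <- list(); feats <- list()
  causal <- NULL

  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    base_raw <- DNA_RAW[sample.int(4L, len, replace = TRUE)]
    n_genes <- config$genes_per_chromosome
    span_len <- 120L + 400L + 150L + 3L * config$cds_codons
    starts <- as.integer(round(seq(0.04 * len, 0.96 * len - span_len,
                                   length.out = n_genes)))
    for (gi in seq_len(n_genes)) {
      is_causal_gene <- (ch == config$causal_chrom && gi == config$causal_gene_index)
      strand <- if (is_causal_gene) "+" else c("+", "-")[1L + (gi %% 2L)]
      g <- build_gene(sprintf("gene_%s_%02d", ch, gi), ch, strand, starts[gi],
                      config$cds_codons,
                      motif_codon = if (is_causal_gene) config$causal_codon else NA)
      base_raw[g$span[1]:g$span[2]] <- charToRaw(g$seq)
      genes[[length(genes) + 1L]] <- g$gene
      feats[[length(feats) + 1L]] <- g$features
      if (is_causal_gene) {
        cds_iv <- g$features[g$features$type == "CDS", ]
        # order CDS intervals in transcript orientation
        cds_iv <- cds_iv[order(cds_iv$start * ifelse(strand == "+", 1, -1)), ]
        cds_pos <- 3L * (config$causal_codon - 1L) + 2L
        gpos <- cds_pos_to_genomic(cds_iv, strand, cds_pos)
        causal <- list(chrom = ch, pos = gpos, ref = "G", alt = "A",
                       gene_id = g$gene$gene_id, cds_pos = cds_pos,
                       codon = config$causal_codon)
      }
    }
    seqs[ch] <- rawToChar(base_raw)
  }
  stopifnot(!is.null(causal))

  genes <- do.call(rbind, genes)
  feats <- do.call(rbind, feats)
  seqs <- Biostrings::DNAStringSet(seqs)

  # causal ref base must be the planted G (second base of GGA on + strand)
  ref_at <- as.character(Biostrings::subseq(seqs[[causal$chrom]],
                                            causal$pos, causal$pos))
  if (ref_at != "G") stop("internal error: causal reference base is not G")

  per_chrom <- diff(round(seq(0, config$n_marker_snps, length.out = length(chroms) + 1)))
  var_list <- list()
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    n_mark <- per_chrom[ci]
    pos <- sort(sample.int(len, n_mark))
    pos <- setdiff(pos, causal$pos)
    ref <- as.character(Biostrings::extractAt(
      seqs[[ch]], IRanges::IRanges(pos, pos)))
    alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                  character(1))
    var_list[[ci]] <- data.frame(chrom = ch, pos = pos, ref = unname(ref),
                                 alt = unname(alt), vtype = "SNP",
                                 origin = "marker")
  }
  variants <- do.call(rbind, var_list)

  # induced mutations: uniform over the genome, one of them is the causal SNP
  n_ind <- config$n_induced_mutations - 1L
  ind_chrom <- sample(chroms, n_ind, replace = TRUE)
  ind_pos <- sample.int(len, n_ind)
  keep <- !(paste(ind_chrom, ind_pos) %in%
              c(paste(variants$chrom, variants$pos), paste(causal$chrom, causal$pos)))
  ind_chrom <- ind_chrom[keep]; ind_pos <- ind_pos[keep]
  ind_ref <- mapply(function(ch, p) as.character(Biostrings::subseq(seqs[[ch]], p, p)),
                    ind_chrom, ind_pos)
  ind_alt <- vapply(ind_ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                    character(1))
  induced <- data.frame(chrom = ind_chrom, pos = ind_pos, ref = unname(ind_ref),
                        alt = unname(ind_alt), vtype = "SNP", origin = "induced")
  causal_row <- data.frame(chrom = causal$chrom, pos = causal$pos,
                           ref = causal$ref, alt = causal$alt,
                           vtype = "SNP", origin = "causal")
  variants <- rbind(variants, induced, causal_row)
  variants <- variants[order(match(variants$chrom, chroms), variants$pos), ]
  rownames(variants) <- NULL
  variants$variant_id <- sprintf("%s_%d", variants$chrom, variants$pos)

  list(config = config, seqs = seqs, genes = genes, features = feats,
       variants = variants, causal = causal)
}

#' Apply one parent's alleles to the reference to obtain a haplotype sequence
#'
#' @param genome Result of [simulate_genome()] (or an element of a
#'   [simulate_cross()] result).
#' @param chrom Chromosome name.
#' @param which `"wt"` returns the reference chromosome; `"mut"` substitutes
#'   the alternate allele at every variant on that chromosome.
#' @return A character scalar DNA sequence.
#' @export
haplotype_sequence <- function(genome, chrom, which = c("wt", "mut")) {
  which <- match.arg(which)
  s <- strsplit(as.character(genome$seqs[[chrom]]), NULL)[[1]]
  if (which == "mut") {
    v <- genome$variants[genome$variants$chrom == chrom & genome$variants$vtype == "SNP", ]
    s[v$pos] <- v$alt
  }
  paste(s, collapse = "")
}
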