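# Standard-format I/O: FASTA and GFF3 via Biostrings/rtracklayer, VCF 4.2
# with per-sample AD fields, phenotype TSV.

POOL_SAMPLES <- c("wt_parent", "mut_parent", "wt_bulk", "df_bulk")

#' Write a pooled-depth variant table as VCF 4.2 with AD fields
#'
#' Sample columns appear in the fixed order wt_parent, mut_parent, wt_bulk,
#' df_bulk. Each sample's genotype field carries AD as "ref,alt".
#'
#' @param depths A [simulate_pool_experiment()] data.frame.
#' @param path Output file.
#' @param contigs Named vector of contig lengths for the header (optional).
#' @export
write_pool_vcf <- function(depths, path, contigs = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=dwarfmapr",
           '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths (ref,alt)">')
  if (!is.null(contigs)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contigs), as.integer(contigs)))
  }
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", POOL_SAMPLES), collapse = "\t"))
  gt <- sapply(POOL_SAMPLES, function(s) {
    paste0(depths[[paste0(s, "_ref")]], ",", depths[[paste0(s, "_alt")]])
  })
  body <- paste(depths$chrom, depths$pos, depths$variant_id, depths$ref,
                depths$alt, ".", "PASS", ".", "AD",
                gt[, 1], gt[, 2], gt[, 3], gt[, 4], sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a pooled-depth VCF back into the pipeline's variant table
#'
#' Parses the per-sample AD field of a multi-sample VCF (any sample names;
#' the four-pool fixture uses wt_parent, mut_parent, wt_bulk, df_bulk).
#'
#' @param path VCF file.
#' @return data.frame: chrom, pos, ref, alt, vtype, variant_id and
#'   `<sample>_ref` / `<sample>_alt` columns.
#' @export
read_pool_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  out <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                    ref = fix$REF, alt = fix$ALT,
                    vtype = ifelse(nchar(fix$REF) == 1 & nchar(fix$ALT) == 1,
                                   "SNP", "InDel"),
                    variant_id = fix$ID)
  ad <- vcfR::extract.gt(vcf, element = "AD")
  for (s in colnames(ad)) {
    parts <- strsplit(ad[, s], ",", fixed = TRUE)
    out[[paste0(s, "_ref")]] <- as.integer(vapply(parts, `[`, character(1), 1))
    out[[paste0(s, "_alt")]] <- as.integer(vapply(parts, `[`, character(1), 2))
  }
  out
}

#' Write gene models as GFF3
#'
#' Emits gene, mRNA, exon, CDS, five_prime_UTR and three_prime_UTR features
#' with Parent attributes (one mRNA per gene).
#'
#' @param genome A [simulate_genome()] result.
#' @param path Output file.
#' @export
write_gene_gff3 <- function(genome, path) {
  g <- genome$genes
  f <- genome$features
  mk <- function(chrom, start, end, strand, type, id, parent, phase = NA_integer_) {
    GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), strand = strand,
                           type = type, ID = id, Parent = parent, phase = phase)
  }
  # CDS phase in transcript order within each gene
  f$phase <- NA_integer_
  for (gid in unique(f$gene_id)) {
    i <- which(f$gene_id == gid & f$type == "CDS")
    i <- i[order(f$start[i] * ifelse(f$strand[i[1]] == "+", 1, -1))]
    w <- f$end[i] - f$start[i] + 1L
    f$phase[i] <- as.integer((3L - cumsum(c(0L, w[-length(w)])) %% 3L) %% 3L)
  }
  gr_gene <- mk(g$chrom, g$start, g$end, g$strand, "gene", g$gene_id, NA_character_)
  mrna_id <- paste0(g$gene_id, ".t1")
  gr_mrna <- mk(g$chrom, g$start, g$end, g$strand, "mRNA", mrna_id, g$gene_id)
  gr_feat <- mk(f$chrom, f$start, f$end, f$strand, f$type,
                NA_character_, paste0(f$gene_id, ".t1"), f$phase)
  gr <- c(gr_gene, gr_mrna, gr_feat)
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' @param path GFF3 file with gene/mRNA/exon/CDS/five_prime_UTR/
#'   three_prime_UTR features and Parent attributes.
#' @return A list with `genes` and `features` data.frames in the same layout
#'   as [simulate_genome()] produces.
#' @export
read_gene_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  d <- as.data.frame(gr)
  d$Parent <- vapply(d$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
                     character(1))
  genes <- d[d$type == "gene", ]
  mrna <- d[d$type == "mRNA", ]
  tx2gene <- stats::setNames(mrna$Parent, mrna$ID)
  feats <- d[d$type %in% c("exon", "CDS", "five_prime_UTR", "three_prime_UTR"), ]
  list(
    genes = data.frame(gene_id = genes$ID, chrom = as.character(genes$seqnames),
                       strand = as.character(genes$strand),
                       start = genes$start, end = genes$end),
    features = data.frame(gene_id = unname(tx2gene[feats$Parent]),
                          chrom = as.character(feats$seqnames),
                          strand = as.character(feats$strand),
                          type = as.character(feats$type),
                          start = feats$start, end = feats$end)
  )
}

#' Write per-plant phenotypes as TSV
#'
#' Columns: population, plant_id, height_cm.
#' @param f2 The `f2` data.frame of a [simulate_cross()] result.
#' @param path Output file.
#' @param population Population label (default "F2").
#' @export
write_phenotypes <- function(f2, path, population = "F2") {
  utils::write.table(
    data.frame(population = population, plant_id = f2$plant_id,
               height_cm = f2$height_cm),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype TSV (population, plant_id, height_cm)
#' @param path TSV file.
#' @return data.frame.
#' @export
read_phenotypes <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  stopifnot(all(c("population", "plant_id", "height_cm") %in% names(d)))
  d
}

#' Write the complete synthetic fixture set
#'
#' Emits reference FASTA, gene-model GFF3, the four-sample pooled-depth VCF
#' and the F2 phenotype TSV into a directory. Refuses to overwrite existing
#' files unless `overwrite = TRUE`.
#'
#' @param sim A [simulate_cross()] result.
#' @param outdir Output directory (created if needed).
#' @param depths Optional precomputed [simulate_pool_experiment()] table.
#' @param overwrite Overwrite existing files?
#' @return Invisibly, a named vector of the file paths written.
#' @export
write_fixture_set <- function(sim, outdir, depths = NULL, overwrite = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(outdir, "reference.fa"),
             gff3 = file.path(outdir, "genes.gff3"),
             vcf = file.path(outdir, "variants.vcf"),
             phenotypes = file.path(outdir, "phenotypes.tsv"))
  if (!overwrite && any(file.exists(paths))) {
    stop("fixture files already exist in ", outdir,
         " (use overwrite = TRUE to replace them)")
  }
  if (is.null(depths)) depths <- simulate_pool_experiment(sim)
  Biostrings::writeXStringSet(sim$genome$seqs, paths[["fasta"]])
  write_gene_gff3(sim$genome, paths[["gff3"]])
  contigs <- stats::setNames(Biostrings::width(sim$genome$seqs),
                             names(sim$genome$seqs))
  write_pool_vcf(depths, paths[["vcf"]], contigs = contigs)
  write_phenotypes(sim$f2, paths[["phenotypes"]])
  invisible(paths)
}
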