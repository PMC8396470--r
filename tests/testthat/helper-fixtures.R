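# Shared fast fixtures and oracle helpers. Expensive objects are built once
# per session and cached.

small_config <- function(seed = 101, ...) {
  cross_config(
    n_chromosomes = 2, chrom_length_bp = 2e6, n_marker_snps = 200,
    n_induced_mutations = 12, genes_per_chromosome = 4, cds_codons = 120,
    causal_chrom = "A02", causal_gene_index = 2, causal_codon = 40,
    f2_size = 120, bulk_size = 15, depth_lambda = 50, seed = seed, ...)
}

.fixture_env <- new.env(parent = emptyenv())

small_genome <- function() {
  if (is.null(.fixture_env$genome)) {
    set.seed(4242)
    .fixture_env$genome <- simulate_genome(small_config())
  }
  .fixture_env$genome
}

small_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    .fixture_env$sim <- simulate_cross(small_config(), genome = small_genome())
  }
  .fixture_env$sim
}

# Draw n random single-base CDS substitutions across the genome's genes.
random_cds_snp_cases <- function(genome, n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    gid <- sample(genome$genes$gene_id, 1)
    civ <- dwarfmapr:::cds_intervals(genome$features, gid)
    cds_len <- sum(civ$end - civ$start + 1L)
    cpos <- sample.int(cds_len, 1)
    gpos <- dwarfmapr:::cds_pos_to_genomic(civ, civ$strand[1], cpos)
    ref <- as.character(Biostrings::subseq(genome$seqs[[civ$chrom[1]]],
                                           gpos, gpos))
    list(gene_id = gid, cds_pos = cpos, chrom = civ$chrom[1], pos = gpos,
         ref = ref, alt = sample(setdiff(c("A", "C", "G", "T"), ref), 1),
         strand = civ$strand[1])
  })
}

# Oracle: classify a CDS SNP by mutating the full spliced CDS and diffing the
# complete translated proteins, independently of the codon arithmetic in
# coding_consequence(). Returns TRUE when coding_consequence agrees.
consequence_matches_oracle <- function(genome, case) {
  v <- data.frame(chrom = case$chrom, pos = case$pos,
                  ref = case$ref, alt = case$alt)
  cc <- coding_consequence(v, case$gene_id, genome$seqs, genome$features)
  cds <- dwarfmapr:::spliced_cds(genome$seqs, genome$features, case$gene_id)
  tx_alt <- if (case$strand == "+") case$alt else dwarfmapr:::comp_base(case$alt)
  cds_mut <- cds
  substr(cds_mut, case$cds_pos, case$cds_pos) <- tx_alt
  p_ref <- translate_cds(cds)
  p_mut <- translate_cds(cds_mut)
  if (p_ref == p_mut) {
    return(identical(cc$coding_effect, "synonymous") &&
             identical(cc$protein_alt, p_mut))
  }
  d <- which(strsplit(p_ref, NULL)[[1]] != strsplit(p_mut, NULL)[[1]])[1]
  eff <- if (substr(p_mut, d, d) == "*") "nonsense" else "missense"
  identical(cc$coding_effect, eff) &&
    identical(cc$protein_alt, p_mut) &&
    identical(cc$aa_change,
              paste0(substr(p_ref, d, d), d, substr(p_mut, d, d)))
}
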