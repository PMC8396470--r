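# Region classification, coding consequences and degron status.

# helper: genomic position of a spliced-CDS coordinate of a gene
gpos_of <- function(genome, gene_id, cds_pos) {
  civ <- dwarfmapr:::cds_intervals(genome$features, gene_id)
  dwarfmapr:::cds_pos_to_genomic(civ, civ$strand[1], cds_pos)
}

ref_at <- function(genome, chrom, pos) {
  as.character(Biostrings::subseq(genome$seqs[[chrom]], pos, pos))
}

test_that("the planted causal SNP is a degron-opening Gly>Glu missense", {
  gen <- small_genome()
  ca <- gen$causal
  v <- data.frame(chrom = ca$chrom, pos = ca$pos, ref = ca$ref, alt = ca$alt)
  ann <- annotate_variants(v, gen$genes, gen$features, gen$seqs)
  expect_equal(ann$region, "exonic")
  expect_equal(ann$gene_id, ca$gene_id)
  expect_equal(ann$coding_effect, "missense")
  expect_equal(ann$codon_change, "GGA>GAA")
  expect_equal(ann$aa_change, sprintf("G%dE", ca$codon))
  expect_equal(ann$degron_status, "altered")
  expect_equal(ann$degron_motif_alt, "EWPPV")
})

test_that("classify_region recognizes every genic context", {
  gen <- small_genome()
  g <- gen$genes[gen$genes$gene_id == gen$causal$gene_id, ]  # '+' strand
  f <- gen$features[gen$features$gene_id == g$gene_id, ]
  utr5 <- f[f$type == "five_prime_UTR", ]
  utr3 <- f[f$type == "three_prime_UTR", ]
  ex <- f[f$type == "exon", ]
  ex <- ex[order(ex$start), ]
  intron <- c(ex$end[1] + 1L, ex$start[2] - 1L)

  pos <- c(utr5$start + 5L,            # utr5
           utr3$end - 5L,              # utr3
           intron[1] + 200L,           # intron middle
           intron[1],                  # first intron base: splice donor
           intron[1] + 1L,             # second intron base: still splicing
           intron[1] + 2L,             # third base: intronic
           intron[2],                  # last intron base: splice acceptor
           g$start - 100L,             # upstream of a '+' gene
           g$end + 100L,               # downstream of a '+' gene
           10L)                        # far from all genes
  v <- data.frame(chrom = g$chrom, pos = pos, ref = "N", alt = "N")
  reg <- classify_region(v, gen$genes, gen$features)
  expect_equal(reg$region,
               c("utr5", "utr3", "intronic", "splicing", "splicing",
                 "intronic", "splicing", "upstream", "downstream",
                 "intergenic"))
  expect_true(is.na(reg$gene_id[10]))
  expect_equal(reg$gene_id[1], g$gene_id)

  # a '-' strand gene flips upstream/downstream
  gm <- gen$genes[gen$genes$strand == "-", ][1, ]
  vm <- data.frame(chrom = gm$chrom, pos = c(gm$start - 100L, gm$end + 100L),
                   ref = "N", alt = "N")
  regm <- classify_region(vm, gen$genes, gen$features)
  expect_equal(regm$region, c("downstream", "upstream"))

  # unknown chromosome warns and falls back to intergenic
  expect_warning(
    regu <- classify_region(data.frame(chrom = "chrX", pos = 100,
                                       ref = "N", alt = "N"),
                            gen$genes, gen$features),
    "unknown chromosome")
  expect_equal(regu$region, "intergenic")
})

test_that("coding_consequence classifies synonymous / missense / nonsense SNPs", {
  gen <- small_genome()
  gid <- gen$causal$gene_id
  cds <- dwarfmapr:::spliced_cds(gen$seqs, gen$features, gid)
  n_codons <- nchar(cds) / 3
  code <- Biostrings::GENETIC_CODE

  codon_at <- function(i) substr(cds, 3 * i - 2, 3 * i)
  # search the real CDS for a single-base change of each outcome class
  find_case <- function(want) {
    for (i in 2:(n_codons - 1)) {
      from <- codon_at(i)
      for (off in 1:3) {
        for (b in setdiff(c("A", "C", "G", "T"), substr(from, off, off))) {
          to <- from
          substr(to, off, off) <- b
          eff <- if (code[[to]] == code[[from]]) "synonymous"
            else if (code[[to]] == "*") "nonsense" else "missense"
          if (eff == want)
            return(list(codon = i, off = off, alt_tx = b, from = from, to = to))
        }
      }
    }
    stop("no case found")  # cannot happen in a 120-codon CDS
  }

  for (want in c("synonymous", "missense", "nonsense")) {
    cs <- find_case(want)
    cpos <- 3L * (cs$codon - 1L) + cs$off
    gp <- gpos_of(gen, gid, cpos)
    # causal gene is on '+': transcript base == genomic base
    v <- data.frame(chrom = gen$causal$chrom, pos = gp,
                    ref = ref_at(gen, gen$causal$chrom, gp), alt = cs$alt_tx)
    cc <- coding_consequence(v, gid, gen$seqs, gen$features)
    expect_equal(cc$coding_effect, want)
    expect_equal(cc$codon_change, paste0(cs$from, ">", cs$to))
    if (want == "synonymous") {
      expect_equal(cc$protein_alt, cc$protein_ref)
      aa <- code[[cs$from]]
      expect_equal(cc$aa_change, paste0(aa, cs$codon, aa))
    }
  }
})

test_that("a reference-allele mismatch is a hard error", {
  gen <- small_genome()
  ca <- gen$causal
  wrong <- setdiff(c("A", "C", "G", "T"), ca$ref)[1]
  v <- data.frame(chrom = ca$chrom, pos = ca$pos, ref = wrong, alt = "A")
  expect_error(coding_consequence(v, ca$gene_id, gen$seqs, gen$features),
               "reference mismatch")
})

test_that("indels are frameshift unless the length change is a multiple of 3", {
  gen <- small_genome()
  ca <- gen$causal
  ref2 <- as.character(Biostrings::subseq(gen$seqs[[ca$chrom]],
                                          ca$pos, ca$pos + 3L))
  # 1-bp deletion
  v1 <- data.frame(chrom = ca$chrom, pos = ca$pos,
                   ref = substr(ref2, 1, 2), alt = substr(ref2, 1, 1))
  expect_equal(coding_consequence(v1, ca$gene_id, gen$seqs,
                                  gen$features)$coding_effect, "frameshift")
  # 3-bp deletion
  v3 <- data.frame(chrom = ca$chrom, pos = ca$pos,
                   ref = ref2, alt = substr(ref2, 1, 1))
  expect_equal(coding_consequence(v3, ca$gene_id, gen$seqs,
                                  gen$features)$coding_effect, "inframe_indel")
  # 2-bp insertion
  vi <- data.frame(chrom = ca$chrom, pos = ca$pos,
                   ref = substr(ref2, 1, 1),
                   alt = paste0(substr(ref2, 1, 1), "AT"))
  expect_equal(coding_consequence(vi, ca$gene_id, gen$seqs,
                                  gen$features)$coding_effect, "frameshift")
})

test_that("degron_check reports intact / altered / absent / unknown", {
  p_ref <- "MAAGWPPVKL*"
  expect_equal(degron_check(p_ref, p_ref)$status, "intact")
  alt <- degron_check(p_ref, "MAAEWPPVKL*")
  expect_equal(alt$status, "altered")
  expect_equal(alt$motif_alt, "EWPPV")
  expect_equal(alt$position, 4L)
  expect_equal(degron_check("MAAKL*", "MAAKL*")$status, "absent")
  expect_equal(degron_check(p_ref, NA_character_)$status, "unknown")
})

test_that("consequences agree with a full-protein diff oracle, both strands", {
  gen <- small_genome()
  cases <- random_cds_snp_cases(gen, 200, seed = 314)
  expect_true(any(vapply(cases, `[[`, character(1), "strand") == "-"))
  ok <- vapply(cases, function(cs) consequence_matches_oracle(gen, cs),
               logical(1))
  expect_true(all(ok))
})

test_that("strand symmetry: mirrored genes give mirrored consequences", {
  gen <- small_genome()
  # a '-' strand gene: mutating transcript base b at spliced-CDS position k
  # must classify exactly like the same transcript-level edit
  gm <- gen$genes[gen$genes$strand == "-", ][1, ]
  cds <- dwarfmapr:::spliced_cds(gen$seqs, gen$features, gm$gene_id)
  k <- 50L
  gp <- gpos_of(gen, gm$gene_id, k)
  tx_ref <- substr(cds, k, k)
  expect_equal(dwarfmapr:::comp_base(tx_ref), ref_at(gen, gm$chrom, gp))
  tx_alt <- setdiff(c("A", "C", "G", "T"), tx_ref)[1]
  v <- data.frame(chrom = gm$chrom, pos = gp,
                  ref = ref_at(gen, gm$chrom, gp),
                  alt = dwarfmapr:::comp_base(tx_alt))
  cc <- coding_consequence(v, gm$gene_id, gen$seqs, gen$features)
  cds_mut <- cds
  substr(cds_mut, k, k) <- tx_alt
  expect_equal(cc$protein_alt, translate_cds(cds_mut))
})
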