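# CDS used across tests: ATG + AGT (Ser) + TGC (Cys) + TAA, 4 codons
BASE_CDS <- "ATGAGTTGCTAA"

test_that("transcript models extract strand-correct CDS sequence", {
  p <- toy_tx(BASE_CDS, strand = "+")
  expect_identical(p$tx$cds_seq, BASE_CDS)
  m <- toy_tx(BASE_CDS, strand = "-")
  expect_identical(m$tx$cds_seq, BASE_CDS)   # revcomp genomic, re-complemented
  expect_error(transcript_model("t", "g", "c", "*", data.frame(start = 1, end = 3),
                                data.frame(start = 1, end = 3), p$genome),
               "strand")
  expect_warning(toy_tx("ATGAGTTGCTAAG"), "not divisible by 3")
})

test_that("GFF3 models load with genes, strands and exon structure", {
  # three-exon gene plus a two-exon isoform lacking the middle exon
  dir <- withr::local_tempdir()
  seq <- paste0(strrep("A", 50), "ATGAAA", strrep("C", 10), "GGGTTT",
                strrep("C", 10), "TGCTAA", strrep("A", 50))
  fa <- file.path(dir, "g.fa")
  writeLines(c(">chrG", seq), fa)
  e1 <- c(51, 56); e2 <- c(67, 72); e3 <- c(83, 88)
  gff <- file.path(dir, "g.gff3")
  writeLines(c(
    "##gff-version 3",
    sprintf("chrG\ttest\tgene\t%d\t%d\t.\t+\t.\tID=gene1;Name=toygene", e1[1], e3[2]),
    sprintf("chrG\ttest\tmRNA\t%d\t%d\t.\t+\t.\tID=tx1;Parent=gene1", e1[1], e3[2]),
    sprintf("chrG\ttest\texon\t%d\t%d\t.\t+\t.\tParent=tx1", e1[1], e1[2]),
    sprintf("chrG\ttest\texon\t%d\t%d\t.\t+\t.\tParent=tx1", e2[1], e2[2]),
    sprintf("chrG\ttest\texon\t%d\t%d\t.\t+\t.\tParent=tx1", e3[1], e3[2]),
    sprintf("chrG\ttest\tCDS\t%d\t%d\t.\t+\t0\tParent=tx1", e1[1], e1[2]),
    sprintf("chrG\ttest\tCDS\t%d\t%d\t.\t+\t0\tParent=tx1", e2[1], e2[2]),
    sprintf("chrG\ttest\tCDS\t%d\t%d\t.\t+\t0\tParent=tx1", e3[1], e3[2]),
    sprintf("chrG\ttest\tmRNA\t%d\t%d\t.\t+\t.\tID=tx1dEx2;Parent=gene1", e1[1], e3[2]),
    sprintf("chrG\ttest\texon\t%d\t%d\t.\t+\t.\tParent=tx1dEx2", e1[1], e1[2]),
    sprintf("chrG\ttest\texon\t%d\t%d\t.\t+\t.\tParent=tx1dEx2", e3[1], e3[2]),
    sprintf("chrG\ttest\tCDS\t%d\t%d\t.\t+\t0\tParent=tx1dEx2", e1[1], e1[2]),
    sprintf("chrG\ttest\tCDS\t%d\t%d\t.\t+\t0\tParent=tx1dEx2", e3[1], e3[2])), gff)
  txs <- load_transcripts(gff, fa)
  expect_setequal(names(txs), c("tx1", "tx1dEx2"))
  expect_identical(txs$tx1$gene, "toygene")
  expect_identical(txs$tx1$cds_seq, "ATGAAAGGGTTTTGCTAA")
  # the exon-skipping isoform loads as its own, shorter model
  expect_identical(txs$tx1dEx2$cds_seq, "ATGAAATGCTAA")
  expect_equal(txs$tx1dEx2$cds_len, txs$tx1$cds_len - 6)
})

test_that("genomic-to-CDS projection handles strand, UTR, intron and intergenic", {
  # plus strand, single-exon CDS at 101..112
  p <- toy_tx(BASE_CDS, strand = "+", start = 101)$tx
  expect_equal(genomic_to_cds(p, 101)$cds_pos, 1L)
  expect_equal(genomic_to_cds(p, 112)$cds_pos, 12L)
  expect_identical(genomic_to_cds(p, 50)$region, "intergenic")

  # minus strand: CDS position 1 sits at the 3'-most genomic base
  m <- toy_tx(BASE_CDS, strand = "-", start = 101)$tx
  expect_equal(genomic_to_cds(m, 112)$cds_pos, 1L)
  expect_equal(genomic_to_cds(m, 101)$cds_pos, 12L)

  # exonic but non-coding is UTR; between exons is intron
  genome <- toy_genome(c(chrU = strrep("A", 300)))
  u <- transcript_model("txU", "gU", "chrU", "+",
                        exons = data.frame(start = c(101, 161), end = c(130, 200)),
                        cds = data.frame(start = c(111, 161), end = c(130, 182)),
                        genome = genome)
  expect_identical(genomic_to_cds(u, 105)$region, "UTR")
  expect_identical(genomic_to_cds(u, 190)$region, "UTR")
  it <- genomic_to_cds(u, 140)
  expect_identical(it$region, "intron")
  expect_equal(it$intron_dist, 10L)
  expect_identical(genomic_to_cds(u, 131)$intron_dist, 1L)
})

test_that("CDS projection round-trips on every coding base, both strands", {
  genome <- toy_genome(c(chrR = strrep("ACGT", 100)))
  for (strand in c("+", "-")) {
    tx <- transcript_model("txR", "gR", "chrR", strand,
                           exons = data.frame(start = c(21, 61, 121),
                                              end = c(50, 90, 150)),
                           cds = data.frame(start = c(31, 61, 121),
                                            end = c(50, 90, 142)),
                           genome = genome)
    for (cp in seq_len(tx$cds_len)) {
      g <- cds_to_genomic(tx, cp)
      expect_equal(genomic_to_cds(tx, g)$cds_pos, cp)
    }
    # and the reverse direction over every genomic CDS base
    gpos <- unlist(lapply(seq_len(nrow(tx$cds)), function(i)
      seq(tx$cds$start[i], tx$cds$end[i])))
    for (g in gpos)
      expect_equal(cds_to_genomic(tx, genomic_to_cds(tx, g)$cds_pos), g)
  }
})

test_that("the serine codon strand-flip contract annotates as S2R missense", {
  # minus-strand transcript; CDS position 6 (third base of the AGT serine
  # codon) lies at the 5'-most end genomically: genomic base is the
  # complement of T, i.e. A; a forward-strand A>T reads T>A on the
  # transcript and turns AGT into AGA (Ser -> Arg)
  m <- toy_tx(BASE_CDS, strand = "-", start = 101)
  gpos <- cds_to_genomic(m$tx, 6L)
  genomic_ref <- as.character(genome_seq(m$genome, "chrT", gpos, gpos))
  expect_identical(genomic_ref, "A")
  cons <- annotate_variant(list(chrom = "chrT", pos = gpos, ref = "A", alt = "T"),
                           m$tx, m$genome)
  expect_identical(cons$type, "missense")
  expect_identical(cons$impact, "MODERATE")
  expect_identical(cons$codon_change, "AGT>AGA")
  expect_identical(cons$protein_change, "S2R")
  expect_equal(cons$protein_pos, 2L)
})

test_that("synonymous and stop-gain changes classify from the codon table", {
  p <- toy_tx(BASE_CDS, strand = "+", start = 101)
  # AGT -> AGC: Ser -> Ser
  syn <- annotate_variant(list(chrom = "chrT", pos = 106, ref = "T", alt = "C"),
                          p$tx, p$genome)
  expect_identical(syn$type, "synonymous")
  expect_identical(syn$impact, "LOW")
  # TGC -> TGA: Cys -> stop
  stp <- annotate_variant(list(chrom = "chrT", pos = 109, ref = "C", alt = "A"),
                          p$tx, p$genome)
  expect_identical(stp$type, "stop_gained")
  expect_identical(stp$impact, "HIGH")
  # TAA -> CAA: stop lost
  lost <- annotate_variant(list(chrom = "chrT", pos = 110, ref = "T", alt = "C"),
                           p$tx, p$genome)
  expect_identical(lost$type, "stop_lost")
})

test_that("every single-base codon change classifies as the brute-force oracle says", {
  bases <- c("A", "C", "G", "T")
  codons <- names(CODON_AA)
  n_checked <- 0L
  for (codon in codons) {
    cds <- paste0("ATG", codon, "TAA")
    p <- toy_tx(cds, strand = "+", start = 201)
    for (off in 1:3) {
      refb <- substr(codon, off, off)
      for (altb in setdiff(bases, refb)) {
        mutated <- codon
        substr(mutated, off, off) <- altb
        aa_ref <- unname(CODON_AA[codon])
        aa_alt <- unname(CODON_AA[mutated])
        want <- if (aa_ref == aa_alt) "synonymous"
                else if (aa_alt == "*") "stop_gained"
                else if (aa_ref == "*") "stop_lost"
                else "missense"
        got <- annotate_variant(list(chrom = "chrT", pos = 203 + off,
                                     ref = refb, alt = altb), p$tx, p$genome)
        expect_identical(got$type, want)
        if (want == "missense") expect_true(aa_ref != aa_alt)
        if (want == "synonymous") expect_identical(aa_ref, aa_alt)
        n_checked <- n_checked + 1L
      }
    }
  }
  expect_equal(n_checked, 64L * 9L)
})

test_that("minus-strand annotation equals the reverse-complemented plus-strand construct", {
  withr::with_seed(41, {
    for (rep in 1:5) {
      codons <- sample(names(CODON_AA)[CODON_AA != "*"], 6, replace = TRUE)
      cds <- paste0("ATG", paste(codons, collapse = ""), "TAA")
      pl <- toy_tx(cds, strand = "+", start = 101, chrom = "chrP")
      mi <- toy_tx(cds, strand = "-", start = 101, chrom = "chrM")
      for (cp in sample(seq_len(nchar(cds)), 8)) {
        gp <- cds_to_genomic(pl$tx, cp)
        gm <- cds_to_genomic(mi$tx, cp)
        ref_p <- as.character(genome_seq(pl$genome, "chrP", gp, gp))
        ref_m <- as.character(genome_seq(mi$genome, "chrM", gm, gm))
        alt_p <- setdiff(c("A", "C", "G", "T"), ref_p)[1]
        alt_m <- unname(COMP[alt_p])
        a_p <- annotate_variant(list(chrom = "chrP", pos = gp, ref = ref_p,
                                     alt = alt_p), pl$tx, pl$genome)
        a_m <- annotate_variant(list(chrom = "chrM", pos = gm, ref = ref_m,
                                     alt = alt_m), mi$tx, mi$genome)
        expect_identical(a_m$codon_change, a_p$codon_change)
        expect_identical(a_m$protein_change, a_p$protein_change)
        expect_identical(a_m$type, a_p$type)
      }
    }
  })
})

test_that("intronic positions within 2 bp of an exon boundary are splice sites", {
  genome <- toy_genome(c(chrS = strrep("A", 400)))
  tx <- transcript_model("txS", "gS", "chrS", "+",
                         exons = data.frame(start = c(101, 201), end = c(160, 260)),
                         cds = data.frame(start = c(101, 201), end = c(160, 260)),
                         genome = genome)
  classify <- function(pos)
    annotate_variant(list(chrom = "chrS", pos = pos, ref = "A", alt = "G"),
                     tx, genome)$type
  expect_identical(classify(161), "splice_site")   # donor +1
  expect_identical(classify(162), "splice_site")   # donor +2
  expect_identical(classify(163), "intron")
  expect_identical(classify(199), "splice_site")   # acceptor -2
  expect_identical(classify(180), "intron")
  expect_identical(impact_of("splice_site"), "HIGH")
})

test_that("impact ratings follow the fixed severity table", {
  expect_identical(impact_of(c("stop_gained", "stop_lost", "splice_site")),
                   rep("HIGH", 3))
  expect_identical(impact_of("missense"), "MODERATE")
  expect_identical(impact_of("synonymous"), "LOW")
  expect_identical(impact_of(c("intron", "UTR", "intergenic")), rep("MODIFIER", 3))
  expect_error(impact_of("frameshift"), "unknown consequence type")
})

test_that("alignment-column conservation excludes gaps and flags all-gap columns", {
  aln <- Biostrings::AAStringSet(c(a = "SAK", b = "SAK", c = "SA-",
                                   d = "ST-", e = "SA-"))
  expect_equal(as.numeric(conservation_score(aln, 1)), 1.0)
  expect_equal(as.numeric(conservation_score(aln, 2)), 0.8)
  expect_identical(attr(conservation_score(aln, 2), "majority"), "A")
  # gaps excluded: column 3 has two residues, both K
  expect_equal(as.numeric(conservation_score(aln, 3)), 1.0)
  all_gap <- Biostrings::AAStringSet(c(a = "-", b = "-"))
  expect_warning(s <- conservation_score(all_gap, 1), "all-gap")
  expect_true(is.na(s))
  # ties report the lexicographically smallest majority residue
  tie <- Biostrings::AAStringSet(c(a = "T", b = "S"))
  expect_identical(attr(conservation_score(tie, 1), "majority"), "S")
})

test_that("multi-transcript annotation marks the most severe consequence per variant", {
  genome <- toy_genome(c(chrX = strrep("A", 400)))
  coding <- transcript_model("txA", "gA", "chrX", "+",
                             exons = data.frame(start = 101, end = 112),
                             cds = data.frame(start = 101, end = 112),
                             genome = genome)
  outer_tx <- transcript_model("txB", "gB", "chrX", "+",
                               exons = data.frame(start = c(50, 301), end = c(60, 320)),
                               cds = data.frame(start = c(50, 301), end = c(60, 319)),
                               genome = genome)
  tab <- make_tab("chrX", c(105, 250), ref = "A", alt = "G")
  ann <- annotate_variants(tab, list(coding, outer_tx), genome)
  first <- ann[ann$pos == 105, ]
  expect_setequal(first$tx_id, c("txA", "txB"))
  expect_true(first$is_most_severe[first$tx_id == "txA"])   # coding beats intron
  # position 250 overlaps only txB's intron
  expect_identical(ann$type[ann$pos == 250], "intron")
})
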