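# Hand-coded standard genetic code: the independent translation oracle.
CODON_AA <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

COMP <- c(A = "T", C = "G", G = "C", T = "A")

revcomp_chr <- function(s) {
  paste(rev(COMP[strsplit(s, "")[[1]]]), collapse = "")
}

# Build a small two-sample variant table from parallel vectors.
make_tab <- function(chrom, pos, ref = "A", alt = "T",
                     mut_gt = "1/1", mut_gq = 60L,
                     sib_gt = "0/1", sib_gq = 60L,
                     filter = "PASS") {
  n <- length(pos)
  variant_table(data.frame(
    chrom = rep_len(chrom, n), pos = as.integer(pos), id = rep_len(".", n),
    ref = rep_len(ref, n), alt = rep_len(alt, n), qual = rep_len(".", n),
    filter = rep_len(filter, n),
    mutant_gt = rep_len(mut_gt, n), mutant_gq = as.integer(rep_len(mut_gq, n)),
    mutant_dp = rep_len(10L, n), mutant_ad_ref = rep_len(5L, n),
    mutant_ad_alt = rep_len(5L, n),
    sibling_gt = rep_len(sib_gt, n), sibling_gq = as.integer(rep_len(sib_gq, n)),
    sibling_dp = rep_len(10L, n), sibling_ad_ref = rep_len(5L, n),
    sibling_ad_alt = rep_len(5L, n)))
}

# Random small table for brute-force QC comparisons.
random_tab <- function(n, seed) {
  withr::with_seed(seed, {
    gts <- c("0/0", "0/1", "1/1", "./.")
    make_tab(chrom = "chrA", pos = sort(sample.int(1e6, n)),
             alt = sample(c("T", "C", "C,G"), n, replace = TRUE),
             mut_gt = sample(gts, n, replace = TRUE),
             mut_gq = sample(0:60, n, replace = TRUE),
             sib_gt = sample(gts, n, replace = TRUE),
             sib_gq = sample(0:60, n, replace = TRUE),
             filter = sample(c("PASS", ".", "LowQual"), n, replace = TRUE,
                             prob = c(0.8, 0.1, 0.1)))
  })
}

# Record-by-record re-check of the hard-filter contract.
qc_oracle_keep <- function(tab, cfg) {
  vapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    if (cfg$pass_only && !r$filter %in% c("PASS", ".")) return(FALSE)
    if (cfg$biallelic_only && grepl(",", r$alt)) return(FALSE)
    if (cfg$drop_missing && (r$mutant_gt == "./." || r$sibling_gt == "./.")) return(FALSE)
    if (r$mutant_gq < cfg$min_gq || r$sibling_gq < cfg$min_gq) return(FALSE)
    TRUE
  }, logical(1))
}

# Per-point tricube weighted-least-squares fit via explicit normal equations:
# the independent oracle for the in-package smoother.
loess_oracle <- function(x, y, span = 0.3, degree = 1) {
  n <- length(x)
  k <- min(n, max(ceiling(span * n), degree + 2))
  vapply(seq_len(n), function(i) {
    d <- abs(x - x[i])
    idx <- order(d)[seq_len(k)]
    h <- max(d[idx])
    w <- if (h > 0) (1 - pmin(d[idx] / h, 1)^3)^3 else rep(1, k)
    keep <- w > 0
    X <- outer(x[idx][keep] - x[i], 0:degree, `^`)
    W <- diag(w[keep], nrow = sum(keep))
    beta <- solve(t(X) %*% W %*% X, t(X) %*% W %*% y[idx][keep])
    beta[1]
  }, numeric(1))
}

# In-memory reference genome from named sequences (supports region headers).
toy_genome <- function(...) {
  seqs <- c(...)
  load_genome(Biostrings::DNAStringSet(seqs))
}

# Single-exon transcript whose CDS sequence (transcript strand) is `cds`,
# placed so the CDS occupies [start, start + nchar - 1] on `chrom`.
toy_tx <- function(cds, strand = "+", chrom = "chrT", start = 101,
                   tx_id = "tx1", gene = "geneT", flank = 30) {
  genomic <- if (strand == "-") revcomp_chr(cds) else cds
  lo <- start - flank
  hi <- start + nchar(cds) - 1 + flank
  seq <- paste0(paste(rep("A", flank), collapse = ""), genomic,
                paste(rep("A", flank), collapse = ""))
  names(seq) <- sprintf("%s:%d-%d", chrom, lo, hi)
  genome <- toy_genome(seq)
  ex <- data.frame(start = start, end = start + nchar(cds) - 1)
  list(tx = transcript_model(tx_id, gene, chrom, strand, ex, ex, genome),
       genome = genome)
}

# Annotated consequence-style rows built directly (for cascade tests).
make_annotated <- function(chrom, pos, ref, alt, gene, type) {
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
             tx_id = paste0("tx_", gene), gene = gene, type = type,
             impact = impact_of(type),
             codon_change = NA_character_, protein_change = NA_character_,
             cds_pos = NA_integer_, protein_pos = NA_integer_)
}
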