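IMPACT_LEVELS <- c("HIGH", "MODERATE", "LOW", "MODIFIER")

#' Build a transcript model
#'
#' Holds the exon/CDS/strand structure needed to project a genomic SNV onto a
#' coding sequence.  The spliced CDS sequence is extracted from the reference
#' (minus-strand models are reverse-complemented) at construction time.  A
#' CDS whose length is not a multiple of 3 is flagged incomplete with a
#' warning and annotated only up to the last full codon.
#'
#' @param tx_id transcript identifier (unique per model set).
#' @param gene gene name.
#' @param chrom chromosome.
#' @param strand `"+"` or `"-"`.
#' @param exons,cds data.frames with columns `start`, `end` (1-based
#'   inclusive, non-overlapping).
#' @param genome a [load_genome()] reference.
#' @return object of class `transcript_model`.
#' @export
transcript_model <- function(tx_id, gene, chrom, strand, exons, cds, genome) {
  abort_if(!strand %in% c("+", "-"), sprintf("unknown strand symbol '%s'", strand))
  exons <- exons[order(exons$start), , drop = FALSE]
  cds <- cds[order(cds$start), , drop = FALSE]
  for (d in list(exons, cds)) {
    abort_if(any(d$end < d$start), "feature end before start")
    if (nrow(d) > 1)
      abort_if(any(d$start[-1] <= d$end[-nrow(d)]), "overlapping features in transcript model")
  }
  cds_len <- sum(cds$end - cds$start + 1)
  incomplete <- cds_len %% 3L != 0L
  if (incomplete)
    warning(sprintf("transcript %s: CDS length %d not divisible by 3; flagged incomplete",
                    tx_id, cds_len))
  pieces <- lapply(seq_len(nrow(cds)), function(i)
    as.character(genome_seq(genome, chrom, cds$start[i], cds$end[i])))
  cds_seq <- paste(pieces, collapse = "")
  if (strand == "-")
    cds_seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds_seq)))
  structure(list(tx_id = tx_id, gene = gene, chrom = chrom, strand = strand,
                 exons = exons, cds = cds, cds_len = cds_len,
                 cds_seq = cds_seq, incomplete = incomplete),
            class = "transcript_model")
}

#' Load transcript models from GFF3 + FASTA
#'
#' Builds one [transcript_model] per `mRNA` (or `transcript`) feature, using
#' its `exon` and `CDS` children and the gene name of its parent `gene`
#' feature.
#'
#' @param gff3 path to a GFF3 file with gene/mRNA/exon/CDS features.
#' @param fasta reference FASTA (or a [load_genome()] object); must cover
#'   every referenced CDS base.
#' @return named list of `transcript_model` objects.
#' @export
load_transcripts <- function(gff3, fasta) {
  genome <- if (inherits(fasta, "genome_ref")) fasta else load_genome(fasta)
  gr <- rtracklayer::import(gff3)
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  parents <- if ("Parent" %in% names(mc)) mc$Parent else rep(list(character(0)), length(gr))
  ids <- if ("ID" %in% names(mc)) as.character(mc$ID) else rep(NA_character_, length(gr))
  names_attr <- if ("Name" %in% names(mc)) as.character(mc$Name) else rep(NA_character_, length(gr))

  mrna_idx <- which(type %in% c("mRNA", "transcript"))
  abort_if(length(mrna_idx) == 0, "no mRNA/transcript features in GFF3")
  tx_ids <- ids[mrna_idx]
  abort_if(anyDuplicated(tx_ids[!is.na(tx_ids)]) > 0, "transcript IDs not unique")

  gene_name_of <- function(i) {
    par <- unlist(parents[[i]])
    if (length(par) > 0) {
      gi <- which(ids == par[1] & type == "gene")
      if (length(gi) > 0) {
        nm <- names_attr[gi[1]]
        if (!is.na(nm)) return(nm)
        return(ids[gi[1]])
      }
      return(par[1])
    }
    if (!is.na(names_attr[i])) names_attr[i] else ids[i]
  }

  has_parent <- function(j, id) id %in% unlist(parents[[j]])
  models <- lapply(seq_along(mrna_idx), function(k) {
    i <- mrna_idx[k]
    id <- tx_ids[k]
    kids <- which(vapply(seq_along(gr), has_parent, logical(1), id = id))
    exon_i <- kids[type[kids] == "exon"]
    cds_i <- kids[type[kids] == "CDS"]
    if (length(exon_i) == 0) exon_i <- i   # exonless model: whole transcript
    to_df <- function(j) data.frame(start = GenomicRanges::start(gr[j]),
                                    end = GenomicRanges::end(gr[j]))
    transcript_model(tx_id = id,
                     gene = gene_name_of(i),
                     chrom = as.character(GenomicRanges::seqnames(gr[i])),
                     strand = as.character(GenomicRanges::strand(gr[i])),
                     exons = to_df(exon_i),
                     cds = if (length(cds_i) > 0) to_df(cds_i) else
                       data.frame(start = integer(0), end = integer(0)),
                     genome = genome)
  })
  names(models) <- tx_ids
  models
}

#' Project a genomic position onto a transcript's CDS
#'
#' For minus-strand transcripts the CDS coordinate counts from the 3'-most
#' genomic CDS base, so position 1 is always the first base of the initiator
#' codon.  Positions inside an exon but outside the CDS are labelled `UTR`;
#' positions between exons `intron` (with the distance into the intron
#' reported for splice-site calls); positions outside the transcript span
#' `intergenic`.
#'
#' @param tx a [transcript_model].
#' @param gpos 1-based genomic position.
#' @return list: `region` (`"cds"`, `"UTR"`, `"intron"`, `"intergenic"`),
#'   `cds_pos` (1-based, `NA` unless coding), `intron_dist` (bp into the
#'   intron from the nearest exon boundary, `NA` unless intronic).
#' @export
genomic_to_cds <- function(tx, gpos) {
  abort_if(gpos < 1, "gpos must be >= 1")
  res <- list(region = "intergenic", cds_pos = NA_integer_, intron_dist = NA_integer_)
  span_lo <- min(tx$exons$start)
  span_hi <- max(tx$exons$end)
  if (gpos < span_lo || gpos > span_hi) return(res)
  cds <- tx$cds
  if (nrow(cds) > 0) {
    widths <- cds$end - cds$start + 1
    for (i in seq_len(nrow(cds))) {
      if (gpos >= cds$start[i] && gpos <= cds$end[i]) {
        if (tx$strand == "+") {
          before <- if (i > 1) sum(widths[seq_len(i - 1)]) else 0
          res$cds_pos <- as.integer(before + (gpos - cds$start[i] + 1))
        } else {
          after <- if (i < nrow(cds)) sum(widths[seq(i + 1, nrow(cds))]) else 0
          res$cds_pos <- as.integer(after + (cds$end[i] - gpos + 1))
        }
        res$region <- "cds"
        return(res)
      }
    }
  }
  in_exon <- any(gpos >= tx$exons$start & gpos <= tx$exons$end)
  if (in_exon) {
    res$region <- "UTR"
    return(res)
  }
  res$region <- "intron"
  dist_up <- gpos - tx$exons$end[tx$exons$end < gpos]
  dist_down <- tx$exons$start[tx$exons$start > gpos] - gpos
  res$intron_dist <- as.integer(min(c(dist_up, dist_down)))
  res
}

#' Inverse of [genomic_to_cds()] on coding positions
#'
#' @param tx a [transcript_model].
#' @param cds_pos 1-based CDS position.
#' @return 1-based genomic position.
#' @export
cds_to_genomic <- function(tx, cds_pos) {
  abort_if(cds_pos < 1 || cds_pos > tx$cds_len, "cds_pos outside the CDS")
  cds <- tx$cds
  widths <- cds$end - cds$start + 1
  if (tx$strand == "+") {
    cum <- cumsum(widths)
    i <- which(cds_pos <= cum)[1]
    before <- if (i > 1) cum[i - 1] else 0
    as.integer(cds$start[i] + (cds_pos - before - 1))
  } else {
    ord <- rev(seq_len(nrow(cds)))                     # 3'-most genomic first
    cum <- cumsum(widths[ord])
    j <- which(cds_pos <= cum)[1]
    i <- ord[j]
    before <- if (j > 1) cum[j - 1] else 0
    as.integer(cds$end[i] - (cds_pos - before - 1))
  }
}

#' Impact rating of a consequence type
#'
#' Fixed four-level severity scheme: `stop_gained`, `stop_lost` and
#' `splice_site` are HIGH; `missense` MODERATE; `synonymous` LOW; `intron`,
#' `UTR` and `intergenic` MODIFIER.
#'
#' @param type consequence type (vectorised).
#' @return character vector of impact ratings.
#' @export
impact_of <- function(type) {
  tbl <- c(stop_gained = "HIGH", stop_lost = "HIGH", splice_site = "HIGH",
           missense = "MODERATE", synonymous = "LOW",
           intron = "MODIFIER", UTR = "MODIFIER", intergenic = "MODIFIER")
  unknown <- setdiff(unique(type), names(tbl))
  abort_if(length(unknown) > 0,
           paste0("unknown consequence type: ", paste(unknown, collapse = ", ")))
  unname(tbl[type])
}

complement_base <- function(b) c(A = "T", C = "G", G = "C", T = "A")[b]

consequence_row <- function(v, tx_id, gene, type, codon_change = NA_character_,
                            protein_change = NA_character_,
                            cds_pos = NA_integer_, protein_pos = NA_integer_) {
  data.frame(chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
             tx_id = tx_id, gene = gene, type = type, impact = impact_of(type),
             codon_change = codon_change, protein_change = protein_change,
             cds_pos = cds_pos, protein_pos = protein_pos)
}

#' Annotate one SNV against one transcript model
#'
#' Rebuilds the codon containing the variant with the strand-adjusted
#' alternate base and translates it with the standard genetic code.  A
#' genomic change on a minus-strand transcript is complemented before codon
#' substitution, so e.g. a forward-strand A>T at the third base of a
#' (transcript-strand) AGT serine codon reads as T>A and yields AGA,
#' arginine.  Intronic positions within 2 bp of an exon boundary (canonical
#' donor/acceptor) are classified `splice_site`.
#'
#' @param v one variant: list or one-row data.frame with `chrom`, `pos`,
#'   `ref`, `alt` (biallelic SNV).
#' @param tx a [transcript_model].  A transcript on a different chromosome
#'   yields `intergenic` with respect to that transcript.
#' @param genome a [load_genome()] reference (used only for consistency
#'   checks; codons come from the transcript's cached CDS).
#' @return one-row data.frame: `chrom`, `pos`, `ref`, `alt`, `tx_id`, `gene`,
#'   `type`, `impact`, `codon_change`, `protein_change`, `cds_pos`,
#'   `protein_pos`.
#' @export
annotate_variant <- function(v, tx, genome = NULL) {
  abort_if(nchar(v$ref) != 1 || nchar(v$alt) != 1 || grepl(",", v$alt),
           "annotate_variant() handles biallelic SNVs only")
  if (v$chrom != tx$chrom)
    return(consequence_row(v, tx$tx_id, tx$gene, "intergenic"))
  loc <- genomic_to_cds(tx, v$pos)
  if (loc$region == "intron") {
    type <- if (loc$intron_dist <= 2L) "splice_site" else "intron"
    return(consequence_row(v, tx$tx_id, tx$gene, type))
  }
  if (loc$region != "cds")
    return(consequence_row(v, tx$tx_id, tx$gene, loc$region))

  cds_pos <- loc$cds_pos
  n_codons <- tx$cds_len %/% 3L
  codon_idx <- (cds_pos - 1L) %/% 3L + 1L
  if (codon_idx > n_codons) {     # incomplete terminal codon
    warning(sprintf("transcript %s: position %d falls in an incomplete terminal codon",
                    tx$tx_id, v$pos))
    return(consequence_row(v, tx$tx_id, tx$gene, "UTR",
                           cds_pos = cds_pos, protein_pos = codon_idx))
  }
  off <- cds_pos - 3L * (codon_idx - 1L)              # 1..3 within codon
  codon <- substr(tx$cds_seq, 3L * codon_idx - 2L, 3L * codon_idx)
  tx_ref <- if (tx$strand == "-") complement_base(v$ref) else v$ref
  tx_alt <- if (tx$strand == "-") complement_base(v$alt) else v$alt
  if (substr(codon, off, off) != tx_ref)
    warning(sprintf("transcript %s: reference base mismatch at %s:%d (CDS has %s, variant ref %s)",
                    tx$tx_id, v$chrom, v$pos, substr(codon, off, off), tx_ref))
  new_codon <- codon
  substr(new_codon, off, off) <- tx_alt
  aa_ref <- unname(Biostrings::GENETIC_CODE[codon])
  aa_alt <- unname(Biostrings::GENETIC_CODE[new_codon])
  type <- if (aa_ref == aa_alt) "synonymous"
          else if (aa_alt == "*") "stop_gained"
          else if (aa_ref == "*") "stop_lost"
          else "missense"
  consequence_row(v, tx$tx_id, tx$gene, type,
                  codon_change = paste0(codon, ">", new_codon),
                  protein_change = paste0(aa_ref, codon_idx, aa_alt),
                  cds_pos = cds_pos, protein_pos = codon_idx)
}

#' Annotate every variant of a table against a transcript set
#'
#' Each transcript overlapping a variant contributes one consequence row;
#' variants overlapping no transcript get a single `intergenic` row.  The
#' most severe impact per variant is marked (`is_most_severe`), mirroring
#' gene-level reporting over multiple transcripts.
#'
#' @param tab a [variant_table] (or data.frame with `chrom`, `pos`, `ref`,
#'   `alt`).
#' @param transcripts list of [transcript_model] objects.
#' @param genome a [load_genome()] reference.
#' @return data.frame of consequences (see [annotate_variant()]), plus
#'   `is_most_severe`.
#' @export
annotate_variants <- function(tab, transcripts, genome = NULL) {
  if (is.null(names(transcripts)))
    names(transcripts) <- vapply(transcripts, `[[`, character(1), "tx_id")
  spans <- lapply(transcripts, function(tx)
    list(chrom = tx$chrom, lo = min(tx$exons$start), hi = max(tx$exons$end)))
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    v <- list(chrom = as.character(tab$chrom[i]), pos = tab$pos[i],
              ref = as.character(tab$ref[i]), alt = as.character(tab$alt[i]))
    hit <- Filter(function(s) s$chrom == v$chrom && v$pos >= s$lo && v$pos <= s$hi, spans)
    if (length(hit) == 0)
      return(consequence_row(v, NA_character_, NA_character_, "intergenic"))
    do.call(rbind, lapply(transcripts[names(hit)], annotate_variant, v = v,
                          genome = genome))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  sev <- match(out$impact, IMPACT_LEVELS)
  key <- paste(out$chrom, out$pos, out$alt)
  best <- stats::ave(sev, key, FUN = min)
  out$is_most_severe <- sev == best
  out
}

#' Conservation of one alignment column
#'
#' Fraction of non-gap residues equal to the majority residue of the column.
#' Ties report the lexicographically smallest majority residue; the score is
#' unchanged.  An all-gap column is undefined (`NA`, with a warning).
#'
#' @param msa aligned protein FASTA path or [Biostrings::AAStringSet]; all
#'   sequences must have equal aligned length.
#' @param column 1-based alignment column index.
#' @return conservation fraction in `[0, 1]` with attribute `majority`
#'   (the majority residue).
#' @export
conservation_score <- function(msa, column) {
  aln <- if (inherits(msa, "AAStringSet")) msa else Biostrings::readAAStringSet(msa)
  w <- unique(Biostrings::width(aln))
  abort_if(length(w) != 1, "aligned sequences must all have the same length")
  abort_if(column < 1 || column > w, "column index outside the alignment")
  res <- vapply(seq_along(aln), function(i)
    as.character(Biostrings::subseq(aln[[i]], column, column)), character(1))
  res <- res[!res %in% c("-", ".")]
  if (length(res) == 0) {
    warning("all-gap alignment column; conservation undefined")
    return(structure(NA_real_, majority = NA_character_))
  }
  counts <- table(res)
  top <- sort(names(counts)[counts == max(counts)])[1]
  structure(as.numeric(max(counts) / length(res)), majority = top)
}
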