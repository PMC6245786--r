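#' Load a reference genome FASTA
#'
#' Sequence names are the first whitespace-delimited token of each header.
#' Headers of the form `name:start-end` (the `samtools faidx` region
#' convention) declare that the record covers only that 1-based inclusive
#' slice of the chromosome; coordinate lookups are offset accordingly, so a
#' short region extract can stand in for a long chromosome when only a locus
#' is annotated.
#'
#' @param fasta path to a (plain-text) FASTA file, or a named
#'   [Biostrings::DNAStringSet].
#' @return object of class `genome_ref`: per sequence, the `DNAString` and
#'   the 1-based genomic coordinate of its first base.
#' @export
load_genome <- function(fasta) {
  seqs <- if (inherits(fasta, "DNAStringSet")) fasta
          else Biostrings::readDNAStringSet(fasta)
  ids <- sub("\\s.*$", "", names(seqs))
  recs <- lapply(seq_along(seqs), function(i) {
    m <- regmatches(ids[i], regexec("^(.+):([0-9]+)-([0-9]+)$", ids[i]))[[1]]
    if (length(m) == 4) {
      start <- as.integer(m[3]); end <- as.integer(m[4])
      abort_if(end - start + 1L != length(seqs[[i]]),
               sprintf("region header '%s' does not match sequence length %d",
                       ids[i], length(seqs[[i]])))
      list(name = m[2], seq = seqs[[i]], offset = start)
    } else {
      list(name = ids[i], seq = seqs[[i]], offset = 1L)
    }
  })
  names(recs) <- vapply(recs, `[[`, character(1), "name")
  structure(recs, class = "genome_ref")
}

#' Extract genomic sequence from a reference
#'
#' @param genome a [load_genome()] result.
#' @param chrom chromosome name.
#' @param start,end 1-based inclusive genomic coordinates.
#' @return a [Biostrings::DNAString].
#' @export
genome_seq <- function(genome, chrom, start, end) {
  rec <- genome[[chrom]]
  abort_if(is.null(rec), sprintf("chromosome '%s' not in reference", chrom))
  lo <- start - rec$offset + 1L
  hi <- end - rec$offset + 1L
  abort_if(lo < 1L || hi > length(rec$seq),
           sprintf("%s:%d-%d outside the loaded reference slice", chrom, start, end))
  Biostrings::subseq(rec$seq, lo, hi)
}
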