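#' Pipeline configuration
#'
#' Flat, YAML-serialisable configuration covering every stage.  All
#' thresholds are echoed verbatim into the run log and the tally for
#' provenance.
#'
#' @param seed mandatory integer seed driving every random draw.
#' @param simulate generate the input tables with the built-in F2 simulator
#'   (default TRUE); otherwise `vcf` must point at a two-sample VCF.
#' @param out_dir output directory for stage-stamped artifacts.
#' @param chrom_names,chrom_lengths simulated karyotype (defaults: 25
#'   chromosomes of 50 Mb).
#' @param marker_density,cm_per_mb,causal_chrom,causal_pos,causal_ref,causal_alt
#'   simulator genome parameters (see [genome_spec()]).
#' @param n_mutants,n_siblings,depth_mutant,depth_sibling,base_error pool
#'   parameters (see [pool_spec()]).
#' @param min_gq,biallelic_only,drop_missing,pass_only QC parameters (see
#'   [qc_config()]).
#' @param window_size,step,pseudocount,span,degree,iterations,threshold_frac,min_fit_floor,informative_only
#'   mapping parameters (see [window_hom_het_ratio()], [loess_fit()],
#'   [critical_region_from_fit()]).
#' @param vcf,gff3,fasta,known_sites,msa optional input files; when
#'   `simulate` is TRUE and `gff3`/`fasta` are NULL, a synthetic annotation
#'   reference for the injected causal gene is generated in `out_dir`.
#' @param exclude_chroms chromosomes dropped from the table before mapping.
#' @param figures write the score and ratio plots (default FALSE).
#' @param write_truth write the simulator's ground-truth TSV (default FALSE).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed,
                            simulate = TRUE,
                            out_dir = tempfile("homozymap_run_"),
                            chrom_names = paste0("chr", 1:25),
                            chrom_lengths = rep(5e7, 25),
                            marker_density = 2,
                            cm_per_mb = 2,
                            causal_chrom = "chr13",
                            causal_pos = 29288858,
                            causal_ref = "A",
                            causal_alt = "T",
                            n_mutants = 40, n_siblings = 40,
                            depth_mutant = 9, depth_sibling = 8,
                            base_error = 0.01,
                            min_gq = 5, biallelic_only = TRUE,
                            drop_missing = TRUE, pass_only = TRUE,
                            window_size = 5e6, step = 5e5, pseudocount = 1,
                            span = 0.3, degree = 1, iterations = 0,
                            threshold_frac = 0.95, min_fit_floor = 1,
                            informative_only = FALSE,
                            vcf = NULL, gff3 = NULL, fasta = NULL,
                            known_sites = NULL, msa = NULL,
                            exclude_chroms = character(0),
                            figures = FALSE,
                            write_truth = FALSE) {
  abort_if(missing(seed), "pipeline_config(): `seed` is mandatory")
  cfg <- list(seed = as.integer(seed), simulate = isTRUE(simulate),
              out_dir = out_dir,
              chrom_names = as.character(chrom_names),
              chrom_lengths = as.numeric(chrom_lengths),
              marker_density = marker_density, cm_per_mb = cm_per_mb,
              causal_chrom = causal_chrom, causal_pos = as.integer(causal_pos),
              causal_ref = causal_ref, causal_alt = causal_alt,
              n_mutants = as.integer(n_mutants), n_siblings = as.integer(n_siblings),
              depth_mutant = depth_mutant, depth_sibling = depth_sibling,
              base_error = base_error,
              min_gq = as.integer(min_gq), biallelic_only = isTRUE(biallelic_only),
              drop_missing = isTRUE(drop_missing), pass_only = isTRUE(pass_only),
              window_size = window_size, step = step, pseudocount = pseudocount,
              span = span, degree = as.integer(degree),
              iterations = as.integer(iterations),
              threshold_frac = threshold_frac, min_fit_floor = min_fit_floor,
              informative_only = isTRUE(informative_only),
              vcf = vcf, gff3 = gff3, fasta = fasta,
              known_sites = known_sites, msa = msa,
              exclude_chroms = as.character(exclude_chroms),
              figures = isTRUE(figures), write_truth = isTRUE(write_truth))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write / read a pipeline configuration (YAML)
#'
#' A configuration written by [write_pipeline_config()] re-parses to an
#' identical configuration.
#'
#' @param cfg a [pipeline_config()].
#' @param path YAML file.
#' @return `path` invisibly / the re-read `pipeline_config`.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$exclude_chroms <- as.character(raw$exclude_chroms %||% character(0))
  do.call(pipeline_config, raw)
}

genome_from_config <- function(cfg) {
  genome_spec(chromosomes = data.frame(name = cfg$chrom_names,
                                       length = cfg$chrom_lengths),
              marker_density = cfg$marker_density,
              causal_site = list(chrom = cfg$causal_chrom, pos = cfg$causal_pos,
                                 ref = cfg$causal_ref, alt = cfg$causal_alt),
              cm_per_mb = cfg$cm_per_mb,
              seed = cfg$seed)
}

pools_from_config <- function(cfg) {
  pool_spec(n_mutants = cfg$n_mutants, n_siblings = cfg$n_siblings,
            depth_mutant = cfg$depth_mutant, depth_sibling = cfg$depth_sibling,
            base_error = cfg$base_error)
}

#' Generate a synthetic annotation reference for the injected causal gene
#'
#' Writes a region FASTA (`>chrom:start-end`, covering only the causal gene
#' locus) and a GFF3 with one single-exon, minus-strand gene whose CDS places
#' the causal position at the third base of codon 102, a serine (AGT) codon —
#' so the injected forward-strand change annotates as a serine-to-arginine
#' missense.  Both files are synthetic stand-ins generated in code; no real
#' transcript accession is bundled.
#'
#' @param genome a [genome_spec()].
#' @param dir output directory.
#' @return list: `fasta`, `gff3` (paths), `gene`, `tx_id`, `protein_pos`,
#'   `expected_change`.
#' @export
simulate_annotation_reference <- function(genome, dir) {
  cs <- genome$causal_site
  withr::with_seed(genome$seed, {
    n_codons <- 105L
    stops <- c("TAA", "TAG", "TGA")
    all_codons <- as.vector(outer(outer(c("A","C","G","T"), c("A","C","G","T"), paste0),
                                  c("A","C","G","T"), paste0))
    body <- sample(setdiff(all_codons, stops), n_codons - 2L, replace = TRUE)
    codons <- c("ATG", body[1:103], "TAA")
    codons[102L] <- "AGT"                    # serine; causal hits base 3
    cds <- paste(codons, collapse = "")
    g <- cs$pos
    e <- g + 305L                            # CDS position 306 maps to g (minus strand)
    s <- e - nchar(cds) + 1L
    genomic <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
    flank <- function(n) paste(sample(c("A","C","G","T"), n, replace = TRUE), collapse = "")
    lo <- s - 60L
    hi <- e + 60L
    seq_full <- paste0(flank(60L), genomic, flank(60L))
    fasta <- file.path(dir, "synthetic_causal_locus.fa")
    writeLines(c(sprintf(">%s:%d-%d synthetic causal-gene locus", cs$chrom, lo, hi),
                 seq_full), fasta)
    gff3 <- file.path(dir, "synthetic_causal_locus.gff3")
    writeLines(c("##gff-version 3",
                 sprintf("%s\thomozymap\tgene\t%d\t%d\t.\t-\t.\tID=gene:synthA;Name=synthA", cs$chrom, s, e),
                 sprintf("%s\thomozymap\tmRNA\t%d\t%d\t.\t-\t.\tID=transcript:synthA.1;Parent=gene:synthA", cs$chrom, s, e),
                 sprintf("%s\thomozymap\texon\t%d\t%d\t.\t-\t.\tParent=transcript:synthA.1", cs$chrom, s, e),
                 sprintf("%s\thomozymap\tCDS\t%d\t%d\t.\t-\t0\tParent=transcript:synthA.1", cs$chrom, s, e)),
               gff3)
    list(fasta = fasta, gff3 = gff3, gene = "synthA", tx_id = "transcript:synthA.1",
         protein_pos = 102L, expected_change = "S102R")
  })
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full mapping pipeline
#'
#' Orchestrates simulate (optional) -> QC -> chromosome selection -> windowed
#' ratio + LOESS -> critical region -> linked-variant extraction ->
#' consequence annotation -> candidate cascade, writing every stage's output
#' with a stage-stamped filename plus a run log and a machine-readable JSON
#' tally.  Deterministic given the seed: re-running the same configuration
#' produces byte-identical artifacts.  A smoothed peak below the fit floor is
#' reported as status `"no_linkage"`, distinct from errors.
#'
#' @param cfg a [pipeline_config()].
#' @return list of class `pipeline_result`: `status` (`"ok"` or
#'   `"no_linkage"`), `candidate_chromosome`, `region`, `report`, `tally`,
#'   `scores`, `windows`, `files` (named paths of all artifacts).
#' @export
run_pipeline <- function(cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  log_lines <- c("homozymap run", sprintf("seed: %d", cfg$seed),
                 sprintf("config: min_gq=%d biallelic_only=%s drop_missing=%s pass_only=%s",
                         cfg$min_gq, cfg$biallelic_only, cfg$drop_missing, cfg$pass_only),
                 sprintf("config: window=%g step=%g pseudocount=%g span=%g degree=%d iterations=%d threshold_frac=%g min_fit_floor=%g",
                         cfg$window_size, cfg$step, cfg$pseudocount, cfg$span,
                         cfg$degree, cfg$iterations, cfg$threshold_frac, cfg$min_fit_floor))
  genome <- NULL
  truth <- NULL

  if (cfg$simulate) {
    genome <- genome_from_config(cfg)
    sim <- simulate_f2_pools(genome, pools_from_config(cfg))
    tab <- sim$table
    truth <- sim$truth
    files$simulated_vcf <- file.path(cfg$out_dir, "00_simulated.vcf")
    write_vcf(tab, files$simulated_vcf, contigs = genome$chromosomes)
    if (cfg$write_truth) {
      files$truth_tsv <- file.path(cfg$out_dir, "00_truth.tsv")
      write_truth_tsv(truth, files$truth_tsv)
    }
    if (is.null(cfg$gff3) || is.null(cfg$fasta)) {
      ann_ref <- simulate_annotation_reference(genome, cfg$out_dir)
      cfg$gff3 <- ann_ref$gff3
      cfg$fasta <- ann_ref$fasta
      files$gff3 <- ann_ref$gff3
      files$fasta <- ann_ref$fasta
    }
    log_lines <- c(log_lines, sprintf("simulated %d markers, pools %d+%d",
                                      nrow(tab), cfg$n_mutants, cfg$n_siblings))
  } else {
    abort_if(is.null(cfg$vcf), "run_pipeline(): simulate is FALSE and no input VCF given")
    tab <- read_vcf(cfg$vcf)
  }

  if (length(cfg$exclude_chroms) > 0) {
    n0 <- nrow(tab)
    tab <- tab[!tab$chrom %in% cfg$exclude_chroms, , drop = FALSE]
    log_lines <- c(log_lines, sprintf("excluded chromosomes %s (%d records)",
                                      paste(cfg$exclude_chroms, collapse = ","), n0 - nrow(tab)))
  }

  qc <- apply_hard_filters(tab, qc_config(min_gq = cfg$min_gq,
                                          biallelic_only = cfg$biallelic_only,
                                          drop_missing = cfg$drop_missing,
                                          pass_only = cfg$pass_only))
  files$qc_vcf <- file.path(cfg$out_dir, "01_qc.vcf")
  write_vcf(qc$table, files$qc_vcf)
  log_lines <- c(log_lines,
                 sprintf("qc: %d in, %d out; removed: %s", qc$n_in, qc$n_out,
                         paste(sprintf("%s=%d", names(qc$removed), qc$removed), collapse = " ")))

  scores <- chromosome_homozygosity_scores(qc$table,
                                           informative_only = cfg$informative_only)
  files$scores_tsv <- file.path(cfg$out_dir, "02_scores.tsv")
  write_tsv(scores, files$scores_tsv)
  cand <- select_candidate_chromosome(scores)
  log_lines <- c(log_lines, sprintf("candidate chromosome: %s", cand))

  chrom_len <- if (!is.null(genome))
    genome$chromosomes$length[match(cand, genome$chromosomes$name)] else NULL
  windows <- window_hom_het_ratio(qc$table, cand,
                                  window_size = cfg$window_size, step = cfg$step,
                                  pseudocount = cfg$pseudocount,
                                  chrom_length = chrom_len)
  windows$fitted <- loess_fit(windows$center, windows$ratio, span = cfg$span,
                              degree = cfg$degree, iterations = cfg$iterations)
  files$windows_tsv <- file.path(cfg$out_dir, "03_windows.tsv")
  write_tsv(windows, files$windows_tsv)

  region <- critical_region_from_fit(windows, windows$fitted,
                                     threshold_frac = cfg$threshold_frac,
                                     min_fit_floor = cfg$min_fit_floor)
  tally <- list(seed = cfg$seed,
                qc = c(list(n_in = qc$n_in, n_out = qc$n_out), as.list(qc$removed)),
                candidate_chromosome = cand,
                thresholds = list(min_gq = cfg$min_gq, window_size = cfg$window_size,
                                  step = cfg$step, pseudocount = cfg$pseudocount,
                                  span = cfg$span, threshold_frac = cfg$threshold_frac,
                                  min_fit_floor = cfg$min_fit_floor))
  if (is.null(region)) {
    log_lines <- c(log_lines, "no linkage detected (smoothed peak below fit floor)")
    tally$status <- "no_linkage"
    files$tally_json <- file.path(cfg$out_dir, "07_tally.json")
    jsonlite::write_json(tally, files$tally_json, auto_unbox = TRUE, pretty = TRUE)
    files$run_log <- file.path(cfg$out_dir, "run.log")
    writeLines(log_lines, files$run_log)
    return(structure(list(status = "no_linkage", candidate_chromosome = cand,
                          region = NULL, report = NULL, tally = tally,
                          scores = scores, windows = windows, truth = truth,
                          files = files),
                     class = "pipeline_result"))
  }
  files$region_bed <- file.path(cfg$out_dir, "04_region.bed")
  write_region_bed(region, files$region_bed)
  files$region_txt <- file.path(cfg$out_dir, "04_region.txt")
  writeLines(utils::capture.output(print(region)), files$region_txt)
  log_lines <- c(log_lines, sprintf("critical region: %s:%d-%d (peak %.2f Mb)",
                                    region$chrom, region$start, region$end,
                                    region$peak_pos / 1e6))
  tally$region <- list(chrom = region$chrom, start = region$start,
                       end = region$end, peak_pos = region$peak_pos,
                       peak_value = region$peak_value)

  # Candidate extraction works on a second-stage table: structural filters
  # (biallelic, non-missing, FILTER pass) still apply, but the GQ cut does
  # not — it serves the marker-level mapping statistic, and dropping a
  # borderline-GQ record here could silently discard the causal variant.
  stage2 <- apply_hard_filters(tab, qc_config(min_gq = 0,
                                              biallelic_only = cfg$biallelic_only,
                                              drop_missing = cfg$drop_missing,
                                              pass_only = cfg$pass_only))
  linked <- extract_linked_variants(stage2$table, region)
  files$linked_vcf <- file.path(cfg$out_dir, "05_linked.vcf")
  write_vcf(linked, files$linked_vcf)
  log_lines <- c(log_lines,
                 sprintf("linked-pattern variants in region: %d (of %d region records)",
                         nrow(linked), sum(qc$table$chrom == region$chrom &
                                             qc$table$pos >= region$start &
                                             qc$table$pos <= region$end)))

  report <- NULL
  if (!is.null(cfg$gff3) && !is.null(cfg$fasta)) {
    genome_ref <- load_genome(cfg$fasta)
    transcripts <- load_transcripts(cfg$gff3, genome_ref)
    annotated <- annotate_variants(linked, transcripts, genome_ref)
    known <- if (!is.null(cfg$known_sites)) read_known_sites(cfg$known_sites)
             else known_sites()
    cascade <- candidate_cascade(annotated, known)
    conservation <- NULL
    if (!is.null(cfg$msa) && nrow(cascade$variants) > 0) {
      # alignment columns are indexed by the reference protein position
      conservation <- do.call(rbind, lapply(seq_len(nrow(cascade$variants)), function(i) {
        p <- cascade$variants$protein_pos[i]
        if (is.na(p)) return(NULL)
        data.frame(gene = cascade$variants$gene[i], protein_pos = p,
                   conservation = as.numeric(conservation_score(cfg$msa, p)))
      }))
    }
    report <- build_candidate_report(cascade, conservation = conservation,
                                     genotypes = linked)
    files$report_tsv <- file.path(cfg$out_dir, "06_candidates.tsv")
    write_candidate_report(report, files$report_tsv)
    tally$cascade <- report$tally
    log_lines <- c(log_lines,
                   sprintf("cascade: %d entering, %d after known-site filter, %d HIGH/MODERATE (%d genes)",
                           report$tally$n_entering, report$tally$n_after_known,
                           report$tally$n_after_impact, length(report$tally$genes)))
  }

  tally$status <- "ok"
  files$tally_json <- file.path(cfg$out_dir, "07_tally.json")
  jsonlite::write_json(tally, files$tally_json, auto_unbox = TRUE, pretty = TRUE)

  if (cfg$figures) {
    figs <- make_figures(scores, windows, region, cfg$out_dir)
    files <- c(files, figs)
  }
  files$run_log <- file.path(cfg$out_dir, "run.log")
  writeLines(log_lines, files$run_log)

  structure(list(status = "ok", candidate_chromosome = cand, region = region,
                 report = report, tally = tally, scores = scores,
                 windows = windows, truth = truth, files = files),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("homozymap pipeline: status %s, candidate chromosome %s\n",
              x$status, x$candidate_chromosome %||% "-"))
  if (!is.null(x$region)) print(x$region)
  if (!is.null(x$report)) print(x$report)
  invisible(x)
}
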