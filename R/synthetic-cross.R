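#' Specify a simulated genome and cross design
#'
#' Describes the genome over which an F2 incross of heterozygous carriers is
#' simulated: chromosome sizes, a regular grid of background marker SNPs that
#' segregate between the two parental strains, and one injected causal variant
#' (a recessive point mutation) that defines the mutant phenotype.
#'
#' Marker positions are laid out on a regular grid of `marker_density` markers
#' per Mb (first marker at half the inter-marker spacing); the causal site is
#' inserted as an additional marker on its chromosome.  Physical distance is
#' converted to map distance at `cm_per_mb` centimorgans per megabase, and
#' inter-marker recombination fractions follow the Haldane map function
#' (no crossover interference).
#'
#' @param chromosomes data.frame with columns `name` and `length` (bp).
#'   Default: 25 chromosomes of 50 Mb, a desk-scale genome shaped like the
#'   zebrafish karyotype.
#' @param marker_density markers per Mb (default 2).
#' @param causal_site list with `chrom`, `pos`, `ref`, `alt` for the injected
#'   recessive variant (default: chr13:29,288,858 A>T).
#' @param cm_per_mb local recombination rate, cM per Mb (default 2, a
#'   zebrafish-scale genetic map).
#' @param seed mandatory integer RNG seed; every random draw of the simulator
#'   flows from it, so a given spec reproduces byte-identical output.
#' @return object of class `genome_spec`.
#' @seealso [simulate_f2_pools()], [marker_table()]
#' @export
genome_spec <- function(chromosomes = data.frame(name = paste0("chr", 1:25),
                                                 length = 5e7),
                        marker_density = 2,
                        causal_site = list(chrom = "chr13", pos = 29288858L,
                                           ref = "A", alt = "T"),
                        cm_per_mb = 2,
                        seed) {
  abort_if(missing(seed), "genome_spec(): `seed` is mandatory (no hidden global RNG)")
  abort_if(!is_count(seed), "genome_spec(): `seed` must be a single non-negative integer")
  abort_if(!all(c("name", "length") %in% names(chromosomes)),
           "chromosomes must have columns `name` and `length`")
  abort_if(any(chromosomes$length <= 0), "all chromosome lengths must be > 0")
  abort_if(anyDuplicated(chromosomes$name) > 0, "chromosome names must be unique")
  abort_if(!causal_site$chrom %in% chromosomes$name,
           "causal_site chromosome not in the chromosome table")
  clen <- chromosomes$length[match(causal_site$chrom, chromosomes$name)]
  abort_if(causal_site$pos < 1 || causal_site$pos > clen,
           "causal_site position outside its chromosome")
  abort_if(marker_density <= 0, "marker_density must be > 0")
  abort_if(cm_per_mb < 0, "cm_per_mb must be >= 0")
  structure(list(chromosomes = data.frame(name = as.character(chromosomes$name),
                                          length = as.numeric(chromosomes$length)),
                 marker_density = marker_density,
                 causal_site = causal_site,
                 cm_per_mb = cm_per_mb,
                 seed = as.integer(seed)),
            class = "genome_spec")
}

#' Specify the phenotype-sorted pools and the sequencing model
#'
#' @param n_mutants,n_siblings embryos pooled per phenotype class (default
#'   40 + 40; a realistic clutch-scale sort).
#' @param depth_mutant,depth_sibling expected reads per site per pool
#'   (defaults 9 and 8, shallow whole-genome coverage).
#' @param base_error per-read allele miscall probability in `[0, 0.5)`
#'   (default 0.01).
#' @return object of class `pool_spec`.
#' @export
pool_spec <- function(n_mutants = 40, n_siblings = 40,
                      depth_mutant = 9, depth_sibling = 8,
                      base_error = 0.01) {
  abort_if(n_mutants < 1 || n_siblings < 1, "pool sizes must be >= 1")
  abort_if(depth_mutant <= 0 || depth_sibling <= 0, "mean depths must be > 0")
  abort_if(base_error < 0 || base_error >= 0.5, "base_error must be in [0, 0.5)")
  structure(list(n_mutants = as.integer(n_mutants),
                 n_siblings = as.integer(n_siblings),
                 depth_mutant = depth_mutant,
                 depth_sibling = depth_sibling,
                 base_error = base_error),
            class = "pool_spec")
}

#' Marker grid of a genome specification
#'
#' @param genome a [genome_spec()].
#' @return data.frame `chrom`, `pos`, `is_causal`, sorted by chromosome (spec
#'   order) with strictly increasing positions per chromosome.
#' @export
marker_table <- function(genome) {
  spacing <- 1e6 / genome$marker_density
  out <- lapply(seq_len(nrow(genome$chromosomes)), function(i) {
    nm <- genome$chromosomes$name[i]
    len <- genome$chromosomes$length[i]
    pos <- seq(from = round(spacing / 2), to = len, by = spacing)
    pos <- as.integer(round(pos))
    causal <- nm == genome$causal_site$chrom
    if (causal && !genome$causal_site$pos %in% pos)
      pos <- sort(c(pos, as.integer(genome$causal_site$pos)))
    data.frame(chrom = nm, pos = pos,
               is_causal = causal & pos == genome$causal_site$pos)
  })
  do.call(rbind, out)
}

#' Mendelian offspring genotype fractions of a one-locus cross
#'
#' Expected genotype fractions among offspring of two parents at one biallelic
#' locus with a fully penetrant recessive alternate allele.  For the standard
#' carrier incross (het x het) the homozygous-alternate fraction — the
#' expected phenotypically mutant fraction — is exactly 25%.
#'
#' @param parent1,parent2 parental genotypes, each one of `"0/0"`, `"0/1"`,
#'   `"1/1"`.
#' @return named numeric vector `c(hom_ref, het, hom_alt)` summing to 1.
#' @examples
#' expected_offspring_fractions("0/1", "0/1")  # 0.25 0.50 0.25
#' @export
expected_offspring_fractions <- function(parent1 = "0/1", parent2 = "0/1") {
  p_alt <- function(gt) switch(gt, "0/0" = 0, "0/1" = 0.5, "1/1" = 1,
                               stop("unknown parental genotype: ", gt))
  a <- p_alt(parent1); b <- p_alt(parent2)
  c(hom_ref = (1 - a) * (1 - b),
    het     = a * (1 - b) + (1 - a) * b,
    hom_alt = a * b)
}

#' Haldane map function
#'
#' Converts map distance to recombination fraction assuming crossovers form a
#' Poisson process with no interference: `r = 0.5 * (1 - exp(-2 d))`.
#'
#' @param d map distance in Morgans (vectorised, `d >= 0`).
#' @return recombination fraction(s) in `[0, 0.5)`.
#' @export
haldane_r <- function(d) {
  abort_if(any(d < 0), "haldane_r(): map distance must be >= 0")
  0.5 * (1 - exp(-2 * d))
}

#' Simulate gametes from one parental chromosome pair
#'
#' Draws gamete haplotypes from a parent whose two homologous haplotypes are
#' given row-wise.  The gamete starts on either parental haplotype with
#' probability 1/2 and switches phase between adjacent markers independently
#' with the interval's recombination fraction, so marginally each parental
#' allele is transmitted with probability 1/2.
#'
#' @param haplotypes 2 x m matrix (rows = parental haplotypes, columns =
#'   markers of one chromosome).
#' @param r recombination fractions of the m - 1 adjacent-marker intervals.
#' @param n number of gametes to draw.
#' @return n x m matrix of transmitted alleles.
#' @export
simulate_meiosis <- function(haplotypes, r, n = 1) {
  abort_if(!is.matrix(haplotypes) || nrow(haplotypes) != 2L,
           "haplotypes must be a 2 x m matrix")
  m <- ncol(haplotypes)
  abort_if(length(r) != max(m - 1L, 0L),
           "map/haplotype length mismatch: need one r per adjacent-marker interval")
  abort_if(any(r < 0 | r > 0.5), "recombination fractions must lie in [0, 0.5]")
  start <- sample.int(2L, n, replace = TRUE) - 1L   # 0 = hap 1, 1 = hap 2
  phase <- matrix(start, nrow = n, ncol = m)
  if (m > 1L) {
    switches <- matrix(stats::rbinom(n * (m - 1L), 1L, rep(r, each = n)),
                       nrow = n, ncol = m - 1L)
    acc <- start
    for (j in seq_len(m - 1L)) {
      acc <- acc + switches[, j]
      phase[, j + 1L] <- acc
    }
    phase <- phase %% 2L
  }
  gam <- matrix(haplotypes[cbind(as.vector(phase) + 1L, rep(seq_len(m), each = n))],
                nrow = n, ncol = m)
  gam
}

#' Call a pseudo-diploid genotype from pooled read counts
#'
#' Genotype likelihoods for 0/0, 0/1 and 1/1 under a binomial read model with
#' per-read alternate-allele probabilities `base_error`, `0.5` and
#' `1 - base_error`.  The call is the maximum-likelihood genotype and GQ is
#' the phred-scaled gap to the runner-up (floored, capped at 99).  Zero depth
#' yields a missing call with GQ 0.
#'
#' @param ref_count,alt_count read counts (vectorised).
#' @param base_error per-read miscall probability.
#' @return data.frame `gt`, `gq`, `depth`, `ref_count`, `alt_count`.
#' @export
call_genotype <- function(ref_count, alt_count, base_error = 0.01) {
  abort_if(any(ref_count < 0) || any(alt_count < 0), "read counts must be >= 0")
  abort_if(base_error < 0 || base_error >= 0.5, "base_error must be in [0, 0.5)")
  n <- length(ref_count)
  depth <- ref_count + alt_count
  ll <- cbind(
    `0/0` = xlogy(alt_count, base_error) + xlogy(ref_count, 1 - base_error),
    `0/1` = xlogy(depth, 0.5),
    `1/1` = xlogy(alt_count, 1 - base_error) + xlogy(ref_count, base_error)
  )
  best <- max.col(ll, ties.method = "first")
  ord <- apply(ll, 1L, function(v) sort(v, decreasing = TRUE)[1:2])
  gq <- pmin(99L, as.integer(floor(10 * (ord[1L, ] - ord[2L, ]) / log(10))))
  gt <- colnames(ll)[best]
  miss <- depth == 0L
  gt[miss] <- "./."
  gq[miss] <- 0L
  data.frame(gt = gt, gq = gq, depth = as.integer(depth),
             ref_count = as.integer(ref_count), alt_count = as.integer(alt_count))
}

# Simulate a full F2 cohort (two meioses per individual per chromosome) and
# return per-chromosome dosage matrices (individuals x markers, dosage 0/1/2
# of the carrier-strain allele).  F1 parents are heterozygous at every marker
# with the causal allele in coupling with one complete parental haplotype.
simulate_f2_cohort <- function(mk, r_by_chrom, n) {
  chroms <- unique(mk$chrom)
  out <- lapply(chroms, function(ch) {
    m <- sum(mk$chrom == ch)
    hap <- rbind(rep(1L, m), rep(0L, m))   # carrier strain = all alt
    r <- r_by_chrom[[ch]]
    simulate_meiosis(hap, r, n) + simulate_meiosis(hap, r, n)
  })
  names(out) <- chroms
  out
}

#' Simulate pool-sequenced variant tables for an F2 carrier incross
#'
#' Simulates F2 individuals from heterozygous F1 carrier parents (two
#' [simulate_meiosis()] draws per chromosome), sorts them by phenotype —
#' individuals homozygous for the causal alternate allele form the mutant
#' pool, all others the sibling pool (full penetrance, phenotype = genotype)
#' — and sequences each pool as one pseudo-diploid sample: per marker the pool
#' alternate-allele frequency is the mean individual dosage, read depth is
#' Poisson, alternate read counts are binomial with the frequency perturbed by
#' `base_error`, and one genotype per pool per marker is emitted via
#' [call_genotype()].
#'
#' @param genome a [genome_spec()].
#' @param pools a [pool_spec()].
#' @param max_batches simulated cohorts are drawn in batches of
#'   `4 * (n_mutants + n_siblings)` individuals until both pools are filled;
#'   if `max_batches` batches do not suffice an error is raised.
#' @return list of class `f2_simulation`:
#'   * `table` — two-sample [variant_table] (roles `mutant`, `sibling`);
#'   * `truth` — ground-truth record: causal site, per-marker true pool allele
#'     frequencies, and per-individual dosage matrices for both pools.
#' @export
simulate_f2_pools <- function(genome, pools = pool_spec(), max_batches = 10L) {
  withr::with_seed(genome$seed, {
    mk <- marker_table(genome)
    nmk <- nrow(mk)
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, nmk, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
    ci <- which(mk$is_causal)
    ref[ci] <- genome$causal_site$ref
    alt[ci] <- genome$causal_site$alt

    morgans_per_bp <- genome$cm_per_mb / 100 / 1e6
    r_by_chrom <- lapply(split(mk$pos, mk$chrom), function(p)
      haldane_r(diff(p) * morgans_per_bp))

    need_m <- pools$n_mutants
    need_s <- pools$n_siblings
    batch <- max(32L, 4L * (need_m + need_s))
    mut <- NULL; sib <- NULL
    for (b in seq_len(max_batches)) {
      dos <- simulate_f2_cohort(mk, r_by_chrom, batch)
      # stitch chromosomes: individuals x all markers, in marker-table order
      full <- do.call(cbind, dos[unique(mk$chrom)])
      causal_dos <- full[, ci]
      mut <- rbind(mut, full[causal_dos == 2L, , drop = FALSE])
      sib <- rbind(sib, full[causal_dos < 2L, , drop = FALSE])
      if (nrow(mut) >= need_m && nrow(sib) >= need_s) break
    }
    abort_if(nrow(mut) < need_m || nrow(sib) < need_s,
             sprintf("pool sizes unreachable after %d batches of %d individuals (got %d mutants, %d siblings)",
                     max_batches, batch, nrow(mut), nrow(sib)))
    mut <- mut[seq_len(need_m), , drop = FALSE]
    sib <- sib[seq_len(need_s), , drop = FALSE]

    freq_m <- colSums(mut) / (2 * need_m)
    freq_s <- colSums(sib) / (2 * need_s)
    e <- pools$base_error
    seq_pool <- function(freq, mean_depth) {
      dp <- stats::rpois(nmk, mean_depth)
      p_alt <- freq * (1 - e) + (1 - freq) * e
      alt_n <- stats::rbinom(nmk, dp, p_alt)
      call_genotype(dp - alt_n, alt_n, e)
    }
    cm <- seq_pool(freq_m, pools$depth_mutant)
    cs <- seq_pool(freq_s, pools$depth_sibling)

    tab <- data.frame(chrom = mk$chrom, pos = mk$pos, id = ".",
                      ref = ref, alt = alt, qual = ".", filter = "PASS",
                      mutant_gt = cm$gt, mutant_gq = cm$gq, mutant_dp = cm$depth,
                      mutant_ad_ref = cm$ref_count, mutant_ad_alt = cm$alt_count,
                      sibling_gt = cs$gt, sibling_gq = cs$gq, sibling_dp = cs$depth,
                      sibling_ad_ref = cs$ref_count, sibling_ad_alt = cs$alt_count)
    class(tab) <- c("variant_table", "data.frame")

    truth <- structure(list(
      causal = genome$causal_site,
      markers = data.frame(chrom = mk$chrom, pos = mk$pos, ref = ref, alt = alt,
                           is_causal = mk$is_causal,
                           freq_mutant = freq_m, freq_sibling = freq_s),
      mutant_dosage = t(mut),      # markers x individuals
      sibling_dosage = t(sib)),
      class = "truth_record")
    structure(list(table = tab, truth = truth, genome = genome, pools = pools),
              class = "f2_simulation")
  })
}

#' Write a ground-truth record as TSV
#'
#' Long-format table `chrom`, `pos`, `individual`, `gt` (dosage 0/1/2) for
#' every pooled individual at every marker, prefixed by the causal site.
#'
#' @param truth `truth` element of [simulate_f2_pools()] output.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#causal\t%s\t%d\t%s\t%s", truth$causal$chrom,
                     truth$causal$pos, truth$causal$ref, truth$causal$alt), con)
  writeLines("chrom\tpos\tindividual\tgt", con)
  emit <- function(dos, prefix) {
    n <- ncol(dos)
    for (i in seq_len(n)) {
      writeLines(sprintf("%s\t%d\t%s%03d\t%d", truth$markers$chrom,
                         truth$markers$pos, prefix, i, dos[, i]), con)
    }
  }
  emit(truth$mutant_dosage, "mut")
  emit(truth$sibling_dosage, "sib")
  invisible(path)
}
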