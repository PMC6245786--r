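test_that("Mendelian offspring fractions are exact for the standard crosses", {
  expect_equal(expected_offspring_fractions("0/1", "0/1"),
               c(hom_ref = 0.25, het = 0.5, hom_alt = 0.25))
  expect_equal(expected_offspring_fractions("0/0", "0/0"),
               c(hom_ref = 1, het = 0, hom_alt = 0))
  expect_equal(expected_offspring_fractions("0/1", "0/0"),
               c(hom_ref = 0.5, het = 0.5, hom_alt = 0))
  expect_error(expected_offspring_fractions("0/2", "0/1"), "unknown")
})

test_that("Haldane map function matches its closed form and limits", {
  expect_identical(haldane_r(0), 0)
  expect_equal(haldane_r(0.1), 0.5 * (1 - exp(-0.2)), tolerance = 1e-12)
  expect_equal(haldane_r(0.1), 0.090635, tolerance = 1e-5)
  expect_lt(abs(haldane_r(50) - 0.5), 1e-12)
  expect_true(all(diff(haldane_r(seq(0, 3, by = 0.01))) >= 0))
  expect_error(haldane_r(-0.01), ">= 0")
})

test_that("meiosis transmits intact haplotypes when r = 0 and mixes freely at r = 0.5", {
  hap <- rbind(c(1L, 1L, 1L, 1L), c(0L, 0L, 0L, 0L))
  withr::with_seed(1, {
    g <- simulate_meiosis(hap, r = c(0, 0, 0), n = 200)
    # every gamete equals one parental haplotype unchanged
    expect_true(all(apply(g, 1, function(x) all(x == 1L) || all(x == 0L))))

    # r = 0.5: phase-switch frequency per interval ~ Binomial(n, 0.5)
    n <- 10000
    g2 <- simulate_meiosis(rbind(rep(1L, 3), rep(0L, 3)), r = c(0.5, 0.5), n = n)
    sw <- abs(diff(t(g2)))              # 2 x n matrix of interval switches
    tol <- 3 * sqrt(0.25 / n)
    expect_true(all(abs(rowMeans(sw) - 0.5) < tol))

    # single-marker chromosome: each parental allele transmitted half the time
    g1 <- simulate_meiosis(rbind(1L, 0L), r = numeric(0), n = n)
    expect_lt(abs(mean(g1) - 0.5), tol)
  })
  expect_error(simulate_meiosis(hap, r = c(0, 0)), "mismatch")
})

test_that("genotype caller recovers hand-computed maximum-likelihood calls", {
  # (10 ref, 0 alt), e = 0.01: L(0/0) = 0.99^10 >> L(0/1) = 0.5^10 -> 0/0
  c1 <- call_genotype(10, 0, 0.01)
  expect_identical(c1$gt, "0/0")
  expect_gt(c1$gq, 5)
  # balanced counts peak at the heterozygous binomial
  expect_identical(call_genotype(5, 5, 0.01)$gt, "0/1")
  # no data -> missing with GQ 0
  c0 <- call_genotype(0, 0, 0.01)
  expect_identical(c0$gt, "./.")
  expect_identical(c0$gq, 0L)
  # GQ is the phred-scaled likelihood gap, floored and capped
  ll_gap <- 10 * (log10(0.99^10) - log10(0.5^10))
  expect_identical(c1$gq, as.integer(floor(ll_gap)))
  expect_identical(call_genotype(500, 0, 0.01)$gq, 99L)
  # error model boundary: base_error = 0 is legal
  expect_identical(call_genotype(3, 0, 0)$gt, "0/0")
})

test_that("simulated pools respect the selection rule, conservation and sort contracts", {
  g <- genome_spec(chromosomes = data.frame(name = c("chrA", "chrB"),
                                            length = c(2e7, 2e7)),
                   causal_site = list(chrom = "chrB", pos = 1.05e7,
                                      ref = "A", alt = "T"),
                   seed = 42)
  sim <- simulate_f2_pools(g, pool_spec(n_mutants = 20, n_siblings = 20))
  tab <- sim$table
  truth <- sim$truth

  ci <- which(truth$markers$is_causal)
  # every pooled mutant is homozygous alt at the causal site; no sibling is
  expect_true(all(truth$mutant_dosage[ci, ] == 2L))
  expect_true(all(truth$sibling_dosage[ci, ] < 2L))

  # read-count conservation and table sorting
  expect_true(all(tab$mutant_ad_ref + tab$mutant_ad_alt == tab$mutant_dp))
  expect_true(all(tab$sibling_ad_ref + tab$sibling_ad_alt == tab$sibling_dp))
  for (ch in unique(tab$chrom))
    expect_true(all(diff(tab$pos[tab$chrom == ch]) > 0))

  # unlinked chromosome: mutant-pool alt frequency ~ 0.5 per marker
  # (binomial over 2 * 20 chromosomes)
  un <- truth$markers$chrom == "chrA"
  tol <- 3 * sqrt(0.25 / 40)
  expect_true(mean(abs(truth$markers$freq_mutant[un] - 0.5) < tol) > 0.95)

  # at the causal marker the mutant pool call is 1/1 whenever covered
  crow <- tab[tab$chrom == "chrB" & tab$pos == 1.05e7, ]
  expect_true(crow$mutant_dp == 0 || crow$mutant_gt == "1/1")
})

test_that("pool sizes that exceed the simulated cohort are reported", {
  g <- genome_spec(chromosomes = data.frame(name = "chrA", length = 1e6),
                   marker_density = 2,
                   causal_site = list(chrom = "chrA", pos = 25e4,
                                      ref = "A", alt = "T"),
                   seed = 5)
  expect_error(simulate_f2_pools(g, pool_spec(n_mutants = 50, n_siblings = 5),
                                 max_batches = 1L),
               "unreachable")
})

test_that("homozygous-alt fraction at the causal site follows the 25% expectation", {
  n <- 2000
  withr::with_seed(99, {
    hap <- rbind(1L, 0L)
    dosage <- simulate_meiosis(hap, numeric(0), n) +
      simulate_meiosis(hap, numeric(0), n)
    frac <- mean(dosage == 2L)
  })
  expect_lt(abs(frac - 0.25), 3 * sqrt(0.25 * 0.75 / n))
})

test_that("mean mutant-pool alt frequency decays monotonically with map distance", {
  # noiseless, high-information setting: large pools, truth frequencies,
  # averaged over seeds; distances span r ~ 0 .. 0.45
  g0 <- function(seed) genome_spec(
    chromosomes = data.frame(name = "chrA", length = 4e7),
    marker_density = 0.25,                      # markers every 4 Mb
    causal_site = list(chrom = "chrA", pos = 2e6, ref = "A", alt = "T"),
    cm_per_mb = 2, seed = seed)
  freqs <- sapply(1:15, function(s) {
    sim <- simulate_f2_pools(g0(s), pool_spec(n_mutants = 150, n_siblings = 1))
    m <- sim$truth$markers
    m$freq_mutant[order(abs(m$pos - 2e6))]
  })
  avg <- rowMeans(freqs)
  se <- sqrt(avg * (1 - avg) / (15 * 300))
  # allow per-step wobble at the Monte-Carlo scale, require overall decay
  expect_true(all(diff(avg) < 3 * se[-1] + 3 * se[-length(se)]))
  expect_gt(avg[1], 0.95)
  expect_lt(avg[length(avg)], 0.65)
})

test_that("identical seed and configuration give byte-identical VCF output", {
  g <- genome_spec(chromosomes = data.frame(name = c("chrA", "chrB"),
                                            length = c(5e6, 5e6)),
                   causal_site = list(chrom = "chrB", pos = 2.5e6,
                                      ref = "A", alt = "T"),
                   seed = 7)
  p1 <- tempfile(fileext = ".vcf"); p2 <- tempfile(fileext = ".vcf")
  write_vcf(simulate_f2_pools(g)$table, p1)
  write_vcf(simulate_f2_pools(g)$table, p2)
  expect_identical(readLines(p1), readLines(p2))
  # and a different seed changes the output
  g2 <- genome_spec(chromosomes = data.frame(name = c("chrA", "chrB"),
                                             length = c(5e6, 5e6)),
                    causal_site = list(chrom = "chrB", pos = 2.5e6,
                                       ref = "A", alt = "T"),
                    seed = 8)
  p3 <- tempfile(fileext = ".vcf")
  write_vcf(simulate_f2_pools(g2)$table, p3)
  expect_false(identical(readLines(p1), readLines(p3)))
})

test_that("VCF round-trip preserves the variant table", {
  g <- genome_spec(chromosomes = data.frame(name = "chrA", length = 5e6),
                   causal_site = list(chrom = "chrA", pos = 2.5e6,
                                      ref = "A", alt = "T"),
                   seed = 11)
  tab <- simulate_f2_pools(g)$table
  p <- tempfile(fileext = ".vcf")
  write_vcf(tab, p)
  back <- read_vcf(p)
  for (col in c("chrom", "pos", "ref", "alt", "mutant_gt", "mutant_gq",
                "mutant_dp", "mutant_ad_ref", "sibling_gt", "sibling_gq",
                "sibling_ad_alt"))
    expect_equal(back[[col]], tab[[col]], ignore_attr = TRUE)
})
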