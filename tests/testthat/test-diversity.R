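one_pop <- function(calls) {
  g <- toy_geno(calls)
  list(g = g, pm = toy_popmap(g, rep("P", nrow(g$geno))))
}

test_that("site frequencies follow the dosage-count definition", {
  tp <- one_pop(matrix(c(0L, 1L, 2L), ncol = 1))
  sf <- site_frequencies(tp$g, tp$pm)
  expect_equal(sf$p, 0.5)
  expect_equal(sf$n_called, 6)
  # a population with nothing called at a site is skipped for that site
  calls <- matrix(c(NA, NA, 1L, 1L), nrow = 2, byrow = FALSE)
  g <- toy_geno(calls)
  pm <- toy_popmap(g, c("A", "A"))
  sf <- site_frequencies(g, pm)
  expect_equal(sf$pos, 200L)
})

test_that("proportion of polymorphic sites counts segregating callable sites", {
  calls <- cbind(matrix(1L, 4, 6), matrix(2L, 4, 4))  # 6 poly, 4 fixed
  tp <- one_pop(calls)
  expect_equal(unname(prop_polymorphic(tp$g, tp$pm)), 0.6)
  expect_equal(unname(prop_polymorphic(one_pop(matrix(2L, 4, 5))$g,
                                       one_pop(matrix(2L, 4, 5))$pm)), 0)
})

test_that("observed and expected heterozygosity match closed forms", {
  tp <- one_pop(matrix(c(0L, 1L, 2L), ncol = 1))
  expect_equal(unname(observed_het(tp$g, tp$pm)), 1 / 3)
  expect_equal(unname(expected_het(tp$g, tp$pm)), 0.5)
  hom <- one_pop(matrix(c(0L, 0L, 2L), ncol = 1))
  expect_equal(unname(observed_het(hom$g, hom$pm)), 0)
  # p = 0.1 with ten diploids: He = 1 - 0.01 - 0.81
  p01 <- one_pop(matrix(c(2L, rep(0L, 9)), ncol = 1))
  expect_equal(unname(expected_het(p01$g, p01$pm)), 0.18)
})

test_that("nucleotide diversity is the unbiased pairwise estimator", {
  pair <- one_pop(matrix(c(0L, 2L), ncol = 1))  # one ref, one alt... 2 diploids
  # n = 4 alleles, 2 ref 2 alt: pi = 4/ C(4,2) = 2/3
  expect_equal(unname(nucleotide_diversity(pair$g, pair$pm)), 2 * 2 / choose(4, 2))
  hap <- one_pop(matrix(1L, 1, 1))  # single het diploid: one ref one alt allele
  expect_equal(unname(nucleotide_diversity(hap$g, hap$pm)), 1)
  mono <- one_pop(matrix(0L, 5, 1))
  expect_equal(unname(nucleotide_diversity(mono$g, mono$pm)), 0)
  # p = 0.5 with 90 diploids per allele class: closed form 8100 / C(180, 2)
  calls <- matrix(c(rep(0L, 45), rep(2L, 45)), ncol = 1)
  tp <- one_pop(calls)
  expect_equal(unname(nucleotide_diversity(tp$g, tp$pm)),
               90 * 90 / choose(180, 2))
  expect_equal(round(90 * 90 / choose(180, 2), 4), 0.5028)
})

test_that("site diversity equals explicit pairwise enumeration (n <= 20)", {
  for (seed in case_seeds(6)) {
    set.seed(seed)
    n <- sample(2:10, 1)  # diploids; 4..20 alleles
    calls <- matrix(sample(0:2, n, replace = TRUE), ncol = 1)
    tp <- one_pop(calls)
    alleles <- unlist(lapply(calls[, 1], function(d) c(rep(1, d), rep(0, 2 - d))))
    expect_equal(unname(nucleotide_diversity(tp$g, tp$pm)), brute_pi(alleles))
  }
})

test_that("PIC follows the printed biallelic formula", {
  tp <- one_pop(matrix(c(0L, 1L, 2L), ncol = 1))     # p = 0.5
  expect_equal(unname(pic(tp$g, tp$pm)), 0.375)
  mono <- one_pop(matrix(2L, 4, 1))
  expect_equal(unname(pic(mono$g, mono$pm)), 0)
  p01 <- one_pop(matrix(c(2L, rep(0L, 9)), ncol = 1))  # p = 0.1
  expect_equal(unname(pic(p01$g, p01$pm)), 0.1638)
})

test_that("per-site statistics respect their ordering and symmetry invariants", {
  for (seed in case_seeds(5)) {
    set.seed(seed)
    calls <- matrix(sample(c(0:2, NA), 20 * 30, replace = TRUE,
                           prob = c(0.3, 0.3, 0.3, 0.1)), nrow = 20)
    g <- toy_geno(calls)
    pm <- toy_popmap(g, rep("P", 20))
    p <- site_frequencies(g, pm)$p
    expect_true(all(pic_vals <- 1 - p^2 - (1 - p)^2 - 2 * p^2 * (1 - p)^2 >= 0))
    he <- 1 - p^2 - (1 - p)^2
    expect_true(all(1 - p^2 - (1 - p)^2 - 2 * p^2 * (1 - p)^2 <= he + 1e-12))
    expect_true(all(he <= 0.5 + 1e-12))
    # allele-label swap: all five statistics unchanged
    g_sw <- g; g_sw$geno <- 2L - g$geno
    for (f in list(prop_polymorphic, expected_het, observed_het,
                   nucleotide_diversity, pic))
      expect_equal(f(g_sw, pm), f(g, pm))
    # sample order: unchanged
    perm <- sample(20)
    g_p <- g; g_p$geno <- g$geno[perm, ]
    pm_p <- toy_popmap(g_p, rep("P", 20))
    for (f in list(expected_het, nucleotide_diversity))
      expect_equal(unname(f(g_p, pm_p)), unname(f(g, pm)))
  }
})

test_that("stronger drift lowers within-population expected heterozygosity", {
  cfg <- sim_config(n_pops = 3, samples_per_pop = 40, n_sites = 3000,
                    chrom_length = 5e6, fst = c(0.01, 0.05, 0.25),
                    missing_rate = 0, seed = 21,
                    pop_names = c("low", "mid", "high"))
  co <- simulate_cohort(cfg)
  dt <- diversity_table(co$geno, co$popmap)
  expect_equal(dt$group[which.min(dt$He)], "high")
  expect_equal(dt$group[which.min(dt$Pi)], "high")
  expect_gt(dt$He[dt$group == "low"], dt$He[dt$group == "high"])
  # with the unbiased pairing, Pi exceeds plug-in He at every sample size
  expect_true(all(dt$Pi >= dt$He))
})

test_that("relative differences use the percent-lower convention", {
  expect_equal(relative_difference(0.2489, 0.2714), 8.29)
  expect_equal(relative_difference(0.2489, 0.2608), 4.56)
  expect_equal(relative_difference(0.2533, 0.2760), 8.22)
  expect_equal(relative_difference(0.2533, 0.2655), 4.60)
  expect_equal(relative_difference(0.5, 0.5), 0)
  expect_error(relative_difference(0.1, 0), "nonzero")
})

test_that("the comparison report reproduces a published diversity table", {
  tab <- read.delim(system.file("extdata", "sheep3_diversity_table.tsv",
                                package = "popsweep"))
  rep <- table1_report(tab)
  he <- rep$comparisons[rep$comparisons$stat == "He", ]
  expect_setequal(he$pct_lower[he$lower_group == "ZY"], c(8.29, 4.56))
  pi <- rep$comparisons[rep$comparisons$stat == "Pi", ]
  expect_setequal(pi$pct_lower[pi$lower_group == "ZY"], c(8.22, 4.60))
  ext <- rep$extremes
  expect_equal(ext$max[ext$stat == "PIC"], 0.1731)
  expect_equal(ext$max_group[ext$stat == "PIC"], "ZY")
  expect_lt(ext$max[ext$stat == "PIC"], 0.25)
  idrep <- table1_report(data.frame(group = c("a", "b"), Pn = 1, He = 0.3,
                                    Ho = 0.3, Pi = 0.3, PIC = 0.2))
  expect_true(all(idrep$comparisons$pct_lower == 0))
})
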