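test_that("EM equals direct counting when phase is unambiguous", {
  # no double heterozygotes anywhere
  g1 <- c(0L, 0L, 2L, 2L, 1L, 0L)
  g2 <- c(0L, 0L, 2L, 2L, 0L, 0L)
  h <- em_haplotype_freqs(g1, g2)
  # haplotypes countable by hand: 12 total
  expect_equal(unname(h$f),
               c(4 / 12, 1 / 12, 0 / 12, 7 / 12), tolerance = 1e-9)
  expect_true(h$converged)
})

test_that("LD coefficients match closed-form cases", {
  # perfect coupling at p = 0.5: only AB and ab haplotypes
  h <- em_haplotype_freqs(c(0L, 0L, 2L, 2L), c(0L, 0L, 2L, 2L))
  r <- r2_pair(h)
  expect_equal(unname(r["r2"]), 1)
  expect_equal(unname(r["dprime"]), 1)
  # independence: f_AB = pA * pB gives r2 = 0 and D' = 0
  r0 <- r2_pair(c(AB = 0.35 * 0.6, Ab = 0.35 * 0.4, aB = 0.65 * 0.6,
                  ab = 0.65 * 0.4))
  expect_equal(unname(r0["r2"]), 0)
  expect_equal(unname(r0["dprime"]), 0)
  # worked asymmetric case
  r1 <- r2_pair(c(AB = 0.5, Ab = 0, aB = 0.25, ab = 0.25))
  expect_equal(unname(r1["D"]), 0.125)
  expect_equal(unname(r1["r2"]), 0.125^2 / (0.5 * 0.5 * 0.75 * 0.25))
  expect_equal(unname(r1["dprime"]), 1)
  # fully monomorphic pair: undefined
  expect_true(is.na(r2_pair(c(AB = 1, Ab = 0, aB = 0, ab = 0))["r2"]))
})

test_that("EM matches a grid-search likelihood oracle to 1e-4", {
  for (seed in case_seeds(8)) {
    set.seed(seed)
    pA <- runif(1, 0.2, 0.8); pB <- runif(1, 0.2, 0.8)
    d <- runif(1, -0.5, 0.5) *
      min(pA * (1 - pB), (1 - pA) * pB, pA * pB, (1 - pA) * (1 - pB))
    f <- c(pA * pB + d, pA * (1 - pB) - d, (1 - pA) * pB - d,
           (1 - pA) * (1 - pB) + d)
    hap <- function(n) sample.int(4, n, replace = TRUE, prob = f)
    hcode <- matrix(hap(40), ncol = 2)  # 20 individuals
    gA <- rowSums(matrix(hcode %in% c(1, 2), ncol = 2))  # alt at locus 1
    gB <- rowSums(matrix(hcode %in% c(1, 3), ncol = 2))
    if (length(unique(gA)) == 1 || length(unique(gB)) == 1) next
    em <- em_haplotype_freqs(gA, gB)
    grid <- grid_hap_freqs(gA, gB)
    expect_lt(abs(unname(em$f["AB"]) - grid$fAB), 1e-4)
    expect_gte(em$loglik, grid$loglik - 1e-6)
  }
})

test_that("r2 respects its bounds and relabeling invariances", {
  for (seed in case_seeds(6)) {
    set.seed(seed)
    g1 <- sample(0:2, 40, replace = TRUE)
    g2 <- sample(0:2, 40, replace = TRUE)
    if (length(unique(g1)) == 1 || length(unique(g2)) == 1) next
    r <- r2_pair(em_haplotype_freqs(g1, g2))
    if (is.na(r["r2"])) next
    expect_gte(r[["r2"]], 0); expect_lte(r[["r2"]], 1 + 1e-9)
    expect_gte(r[["dprime"]], 0); expect_lte(r[["dprime"]], 1 + 1e-9)
    expect_lte(r[["r2"]], r[["dprime"]]^2 + 1e-9)
    # relabel alleles at locus 1: r2 unchanged
    r_sw <- r2_pair(em_haplotype_freqs(2L - g1, g2))
    expect_equal(r_sw[["r2"]], r[["r2"]], tolerance = 1e-7)
  }
})

test_that("decay curve bins qualifying pairs", {
  g <- toy_geno(rbind(c(0L, 0L), c(1L, 1L), c(2L, 2L), c(0L, 0L),
                      c(2L, 2L), c(1L, 1L)),
                pos = c(1000L, 3000L))
  pm <- toy_popmap(g, rep("P", 6))
  cv <- decay_curve(g, pm, max_dist_bp = 10000, bin_width_bp = 5000,
                    maf_min = 0)
  expect_equal(nrow(cv), 1)
  expect_equal(cv$n_pairs, 1L)
  expect_equal(cv$mean_r2, 1)
  # pairs beyond max_dist are excluded
  cv2 <- decay_curve(g, pm, max_dist_bp = 1000, bin_width_bp = 500,
                     maf_min = 0)
  expect_equal(nrow(cv2), 0)
})

test_that("unlinked sites show a flat curve near the sampling floor", {
  set.seed(31)
  n <- 60; L <- 80
  p <- runif(L, 0.2, 0.8)
  calls <- matrix(rbinom(n * L, 2, rep(p, each = n)), nrow = n)
  g <- toy_geno(calls, pos = seq_len(L) * 1000L)
  pm <- toy_popmap(g, rep("P", n))
  cv <- decay_curve(g, pm, max_dist_bp = 40000, bin_width_bp = 10000,
                    maf_min = 0.05)
  # E[r2] for independent loci is about 1/n; no trend with distance
  expect_true(all(cv$mean_r2 < 3 / n))
  expect_gt(min(cv$mean_r2), 1 / (10 * n))
  expect_lt(diff(range(cv$mean_r2)), 2 / n)
})

test_that("linked founder-mosaic data decay with distance; drift slows decay", {
  small_ne <- simulate_ld_cohort(n_samples = 60, n_sites = 150,
                                 spacing_bp = 2000, n_founders = 8,
                                 recomb_rate = 2e-5, seed = 2)
  large_ne <- simulate_ld_cohort(n_samples = 60, n_sites = 150,
                                 spacing_bp = 2000, n_founders = 60,
                                 recomb_rate = 2e-5, seed = 2)
  pm <- function(g) toy_popmap(g, rep("P", 60))
  c_small <- decay_curve(small_ne, pm(small_ne), max_dist_bp = 1e5,
                         bin_width_bp = 2e4)
  c_large <- decay_curve(large_ne, pm(large_ne), max_dist_bp = 1e5,
                         bin_width_bp = 2e4)
  # decay for the strongly linked population: strong downward trend and a
  # clear drop from the first to the last bin
  expect_lt(cor(seq_len(nrow(c_small)), c_small$mean_r2,
                method = "spearman"), -0.7)
  expect_gt(c_small$mean_r2[1], 2 * c_small$mean_r2[nrow(c_small)])
  # the high-drift (small founder pool) population sits above at all bins
  expect_true(all(c_small$mean_r2 > c_large$mean_r2))
})

test_that("EM and composite methods agree on strongly linked data", {
  g <- simulate_ld_cohort(n_samples = 50, n_sites = 40, spacing_bp = 1000,
                          n_founders = 10, recomb_rate = 1e-5, seed = 6)
  pm <- toy_popmap(g, rep("P", 50))
  em <- decay_curve(g, pm, max_dist_bp = 2e4, bin_width_bp = 2e4)
  comp <- decay_curve(g, pm, max_dist_bp = 2e4, bin_width_bp = 2e4,
                      method = "composite")
  expect_equal(em$mean_r2, comp$mean_r2, tolerance = 0.05)
})
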