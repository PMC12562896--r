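two_pop_geno <- function(calls1, calls2, pos) {
  g <- toy_geno(rbind(calls1, calls2), pos = pos)
  list(g = g, pm = toy_popmap(g, rep(c("A", "B"),
                                     c(nrow(calls1), nrow(calls2)))))
}

test_that("window tiling follows the half-open sliding convention", {
  w <- make_windows(c(chr1 = 1e5), window_size = 5e4, step = 25000)
  expect_equal(w$start, c(1, 25001, 50001, 75001))
  expect_equal(w$end, c(50001, 75001, 100001, 100001))
  # window == step tiles without overlap
  w2 <- make_windows(c(chr1 = 99000), window_size = 1e4, step = 1e4)
  expect_equal(w2$start[-1], w2$end[-nrow(w2)])
  # coverage: every base of random-length chromosomes is in some window
  for (seed in case_seeds(4)) {
    set.seed(seed)
    len <- sample(5e4:5e5, 2)
    names(len) <- c("c1", "c2")
    win <- sample(c(1e4, 3e4, 5e4), 1); stp <- win / 2
    w <- make_windows(len, win, stp)
    for (cc in names(len)) {
      wc <- w[w$chrom == cc, ]
      wc <- wc[order(wc$start), ]
      expect_equal(wc$start[1], 1)
      expect_gte(max(wc$end), len[[cc]] + 1)
      expect_true(all(wc$start[-1] <= wc$end[-nrow(wc)]))
    }
  }
})

test_that("window FST hits its analytic extremes", {
  pos <- seq(1000L, 10000L, by = 1000L)
  L <- length(pos)
  opp <- two_pop_geno(matrix(0L, 20, L), matrix(2L, 20, L), pos)
  wins <- make_windows(c(chr1 = 10000), 10000)
  expect_equal(window_fst(opp$g, opp$pm, wins, c("A", "B"))$fst, 1)

  set.seed(8)
  calls <- matrix(rbinom(40 * L, 2, 0.4), nrow = 40)
  same <- two_pop_geno(calls[1:20, ], calls[21:40, ], pos)
  f0 <- window_fst(same$g, same$pm, wins, c("A", "B"))$fst
  expect_lt(abs(f0), 0.05)

  # fewer usable SNPs than min_snps leaves the window undefined
  sparse <- two_pop_geno(matrix(c(0L, 1L), 2, 2), matrix(1L, 2, 2),
                         pos = c(100L, 200L))
  wf <- window_fst(sparse$g, sparse$pm, make_windows(c(chr1 = 300), 300),
                   c("A", "B"), min_snps = 3)
  expect_true(is.na(wf$fst))
})

test_that("windowed FST is invariant to site order and allele relabeling", {
  set.seed(12)
  pos <- sort(sample.int(5e4, 60))
  calls <- matrix(rbinom(30 * 60, 2, runif(60, 0.1, 0.9)), nrow = 30,
                  byrow = FALSE)
  tp <- two_pop_geno(calls[1:15, ], calls[16:30, ], pos)
  wins <- make_windows(c(chr1 = 5e4), 5e4)
  base <- window_fst(tp$g, tp$pm, wins, c("A", "B"))$fst
  flip <- tp$g; flip$geno <- 2L - flip$geno
  expect_equal(window_fst(flip, tp$pm, wins, c("A", "B"))$fst, base)
  expect_equal(window_fst(tp$g, tp$pm, wins, c("B", "A"))$fst, base)
})

test_that("window diversity matches the site-level closed form", {
  calls <- matrix(c(rep(0L, 45), rep(2L, 45)), ncol = 1)
  g <- toy_geno(calls, pos = 500L)
  pm <- toy_popmap(g, rep("P", 90))
  w <- window_pi(g, pm, make_windows(c(chr1 = 1000), 1000), "P",
                 min_snps = 1)
  expect_equal(w$pi, 90 * 90 / choose(180, 2))
  # per-bp mode divides by span instead
  wbp <- window_pi(g, pm, make_windows(c(chr1 = 1000), 1000), "P",
                   min_snps = 1, mode = "per_bp")
  expect_equal(wbp$pi, 90 * 90 / choose(180, 2) / 1000)
  mono <- toy_geno(matrix(0L, 10, 5), pos = c(100L, 200L, 300L, 400L, 500L))
  pm2 <- toy_popmap(mono, rep("P", 10))
  wm <- window_pi(mono, pm2, make_windows(c(chr1 = 1000), 1000), "P")
  expect_equal(wm$pi, 0)
})

test_that("top-quantile intersection selects ties and skips undefined windows", {
  stats <- data.frame(chrom = "chr1", start = seq(1, 1e6, 1e4),
                      end = seq(1, 1e6, 1e4) + 1e4)
  n <- nrow(stats)
  set.seed(3)
  stats$fst <- runif(n)
  stats$pi_ratio <- runif(n)
  all_sel <- suppressWarnings(
    top_quantile_intersection(stats, q_fst = 1, q_ratio = 1))
  expect_true(all(all_sel$selected))
  # disjoint top sets yield an empty intersection
  stats$fst <- seq_len(n)
  stats$pi_ratio <- rev(seq_len(n))
  none <- suppressWarnings(
    top_quantile_intersection(stats, q_fst = 0.1, q_ratio = 0.1))
  expect_equal(sum(none$selected), 0)
  # NA/Inf windows enter neither the quantile nor the selection
  stats$fst <- runif(n); stats$pi_ratio <- runif(n)
  stats$fst[1:5] <- NA; stats$pi_ratio[6:8] <- Inf
  sel <- suppressWarnings(top_quantile_intersection(stats, 0.2, 0.2))
  expect_true(all(!sel$selected[1:8]))
  expect_lte(sum(sel$selected), min(sum(sel$fst >= attr(sel, "thresholds")["fst"],
                                        na.rm = TRUE), n))
})

test_that("region merging equals an interval-union oracle", {
  two <- data.frame(chrom = "chr1", start = c(1, 5001), end = c(10001, 15001),
                    fst = c(0.5, 0.7), pi_ratio = c(2, 3))
  m <- merge_regions(two)
  expect_equal(nrow(m), 1)
  expect_equal(m$start, 1); expect_equal(m$end, 15001)
  expect_equal(m$peak_fst, 0.7); expect_equal(m$peak_pi_ratio, 3)
  cross <- data.frame(chrom = c("chr1", "chr2"), start = 1, end = 10001)
  expect_equal(nrow(merge_regions(cross)), 2)
  for (seed in case_seeds(5)) {
    set.seed(seed)
    n <- 40
    df <- data.frame(chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
                     start = sample.int(1e5, n))
    df$end <- df$start + sample(c(5000, 10000), n, replace = TRUE)
    gap <- sample(c(0, 1000), 1)
    expect_equal(nrow(merge_regions(df, gap)), brute_region_union(df, gap))
  }
})

test_that("gene annotation matches brute-force interval intersection", {
  gff <- tempfile(fileext = ".gff3")
  set.seed(91)
  gstart <- sort(sample.int(9e4, 10))
  gend <- gstart + sample(2000:8000, 10)
  writeLines(c("##gff-version 3",
               paste("chr1", "test", "gene", gstart, gend, ".", "+", ".",
                     sprintf("ID=g%02d", 1:10), sep = "\t")), gff)
  regions <- data.frame(chrom = "chr1",
                        start = c(gstart[3] + 100, 95000, sample.int(9e4, 4)))
  regions$end <- regions$start + 3000
  ann <- annotate_regions(regions, gff)
  for (i in seq_len(nrow(regions))) {
    hit <- which(gstart <= regions$end[i] - 1 & gend >= regions$start[i])
    expect_setequal(strsplit(ann$gene_ids[i], ",")[[1]],
                    sprintf("g%02d", hit))
  }
  expect_equal(sort(attr(ann, "genes")),
               sort(unique(unlist(strsplit(ann$gene_ids[ann$gene_ids != ""],
                                           ",")))))
  # region inside one gene reports exactly that gene
  expect_true(grepl("g03", ann$gene_ids[1]))
})

test_that("an injected sweep dominates the joint top quantiles", {
  cfg <- sim_config(n_pops = 2, samples_per_pop = 60, n_sites = 6000,
                    chrom_length = 1.2e7, fst = 0.05, seed = 55,
                    pop_names = c("ZY", "HY"),
                    sweep_specs = list(list(pop = "ZY", start = 4e6 + 1,
                                            end = 5.2e6, intensity = 0.9)))
  co <- simulate_cohort(cfg)
  scan <- sweep_scan(co$geno, co$popmap, target = "ZY", reference = "HY",
                     window_size = 1e5, step = 1e5,
                     chrom_lengths = c(chr1 = 1.2e7),
                     q_fst = 0.1, q_ratio = 0.1)
  expect_gt(nrow(scan$regions), 0)
  expect_true(any(scan$regions$start <= 5.2e6 & scan$regions$end > 4e6))
  # selected windows sit in the upper tail of both axes by construction
  thr <- scan$thresholds
  sel <- scan$windows[scan$windows$selected, ]
  expect_true(all(sel$fst >= thr["fst"]))
  expect_true(all(sel$pi_ratio >= thr["pi_ratio"]))
  expect_lte(sum(scan$windows$selected),
             min(sum(scan$windows$fst >= thr["fst"], na.rm = TRUE),
                 sum(scan$windows$pi_ratio >= thr["pi_ratio"], na.rm = TRUE)))
})
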