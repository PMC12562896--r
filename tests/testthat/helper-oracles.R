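# Shared fixtures and independent brute-force oracles.

toy_geno <- function(calls, pos = NULL, chrom = "chr1", ...) {
  calls <- as.matrix(calls)
  if (is.null(pos)) pos <- seq_len(ncol(calls)) * 100L
  sites <- data.frame(chrom = chrom, pos = pos,
                      ref = "A", alt = "G", ...)
  geno_matrix(calls, sites)
}

toy_popmap <- function(g, pops) {
  data.frame(sample = sample_ids(g), pop = pops)
}

# O(range x n) sliding scan over every possible base window
brute_cluster <- function(pos, window_bp = 5L, max_snps = 2L) {
  flag <- logical(length(pos))
  for (s in seq(min(pos), max(pos))) {
    inside <- pos >= s & pos <= s + window_bp - 1L
    if (sum(inside) > max_snps) flag[inside] <- TRUE
  }
  flag
}

# O(n * m) all-pairs proximity scan
brute_indel_near <- function(snp, indel, dist_bp = 5L) {
  vapply(seq_len(nrow(snp)), function(i) {
    same <- indel$chrom == snp$chrom[i]
    any(same & abs(indel$pos - snp$pos[i]) <= dist_bp)
  }, logical(1))
}

# average pairwise difference by explicit enumeration over allele pairs
brute_pi <- function(alleles) {
  n <- length(alleles)
  tot <- 0L; pairs <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + (alleles[i] != alleles[j])
    pairs <- pairs + 1L
  }
  tot / pairs
}

# genotype-class log-likelihood written from first principles (random union
# of gametes), independent of the package's internal EM bookkeeping
oracle_loglik <- function(g1, g2, fAB, fAb, faB, fab) {
  ll <- 0
  for (i in seq_along(g1)) {
    if (is.na(g1[i]) || is.na(g2[i])) next
    pr <- switch(paste0(g1[i], g2[i]),
                 "00" = fab^2, "01" = 2 * fab * faB, "02" = faB^2,
                 "10" = 2 * fab * fAb,
                 "11" = 2 * (fAB * fab + fAb * faB),
                 "12" = 2 * fAB * faB,
                 "20" = fAb^2, "21" = 2 * fAB * fAb, "22" = fAB^2)
    ll <- ll + log(max(pr, 1e-300))
  }
  ll
}

# grid search over the one free haplotype-frequency parameter
grid_hap_freqs <- function(g1, g2, grid_n = 4001L) {
  ok <- !is.na(g1) & !is.na(g2)
  pA <- mean(g1[ok]) / 2; pB <- mean(g2[ok]) / 2
  lo <- max(0, pA + pB - 1); hi <- min(pA, pB)
  fab_grid <- seq(lo, hi, length.out = grid_n)
  ll <- vapply(fab_grid, function(fAB)
    oracle_loglik(g1[ok], g2[ok], fAB, pA - fAB, pB - fAB,
                  1 - pA - pB + fAB), numeric(1))
  best <- fab_grid[which.max(ll)]
  list(fAB = best, fAb = pA - best, faB = pB - best,
       fab = 1 - pA - pB + best, loglik = max(ll))
}

# interval union region count on half-open intervals
brute_region_union <- function(df, gap = 0) {
  n <- 0L
  for (cc in unique(df$chrom)) {
    iv <- df[df$chrom == cc, , drop = FALSE]
    iv <- iv[order(iv$start), , drop = FALSE]
    end <- -Inf
    for (i in seq_len(nrow(iv))) {
      if (iv$start[i] - end > gap) n <- n + 1L
      end <- max(end, iv$end[i])
    }
  }
  n
}

write_toy_vcf <- function(lines, path = tempfile(fileext = ".vcf"),
                          samples = c("s1", "s2", "s3"), format = "GT") {
  hdr <- c("##fileformat=VCFv4.2",
           "##contig=<ID=chr1,length=100000>",
           "##INFO=<ID=QD,Number=1,Type=Float,Description=\"x\">",
           "##INFO=<ID=FS,Number=1,Type=Float,Description=\"x\">",
           "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"x\">",
           "##INFO=<ID=SOR,Number=1,Type=Float,Description=\"x\">",
           "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"x\">",
           "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"x\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"x\">",
           "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"x\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, lines), path)
  path
}

vcf_line <- function(pos, ref = "A", alt = "G", info = ".",
                     gts = c("0/0", "0/1", "1/1"), chrom = "chr1") {
  paste(c(chrom, pos, ".", ref, alt, ".", ".", info, "GT", gts),
        collapse = "\t")
}

# deterministic small-integer seeds for parameterized stochastic cases
case_seeds <- function(n, base = 20250) base + seq_len(n)
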