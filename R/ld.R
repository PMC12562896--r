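# EM for two-locus haplotype frequencies from unphased diploid genotypes,
# vectorized over P locus pairs. `counts` is a 9 x P matrix of genotype-class
# counts, rows ordered as class = 3*g1 + g2 + 1 for dosages (g1, g2).
# Only the double heterozygote (g1 = 1, g2 = 1) is phase-ambiguous; all other
# classes contribute fixed haplotype counts. Initialization is linkage
# equilibrium; with no double heterozygotes the first M-step already equals
# the direct count solution.
em_core <- function(counts, tol = 1e-8, max_iter = 1000L) {
  n00 <- counts[1, ]; n01 <- counts[2, ]; n02 <- counts[3, ]
  n10 <- counts[4, ]; n11 <- counts[5, ]; n12 <- counts[6, ]
  n20 <- counts[7, ]; n21 <- counts[8, ]; n22 <- counts[9, ]
  N <- colSums(counts)
  two_n <- 2 * N
  cAB <- 2 * n22 + n21 + n12
  cAb <- 2 * n20 + n21 + n10
  caB <- 2 * n02 + n01 + n12
  cab <- 2 * n00 + n01 + n10
  pA <- (cAB + cAb + n11) / two_n
  pB <- (cAB + caB + n11) / two_n
  fAB <- pA * pB; fAb <- pA * (1 - pB); faB <- (1 - pA) * pB
  fab <- (1 - pA) * (1 - pB)
  iters <- integer(ncol(counts))
  active <- two_n > 0
  for (it in seq_len(max_iter)) {
    if (!any(active)) break
    den <- fAB * fab + fAb * faB
    w <- ifelse(den > 0, fAB * fab / den, 0.5)
    nAB <- (cAB + n11 * w) / two_n
    nab <- (cab + n11 * w) / two_n
    nAb <- (cAb + n11 * (1 - w)) / two_n
    naB <- (caB + n11 * (1 - w)) / two_n
    delta <- pmax(abs(nAB - fAB), abs(nab - fab),
                  abs(nAb - fAb), abs(naB - faB))
    fAB[active] <- nAB[active]; fab[active] <- nab[active]
    fAb[active] <- nAb[active]; faB[active] <- naB[active]
    iters[active] <- it
    active <- active & (delta >= tol)
  }
  list(fAB = fAB, fAb = fAb, faB = faB, fab = fab, n = N,
       iterations = iters, converged = !active)
}

genotype_class_counts <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  cls <- 3L * g1[ok] + g2[ok] + 1L
  tabulate(cls, nbins = 9L)
}

#' EM haplotype frequencies for one locus pair
#'
#' Maximum-likelihood two-locus haplotype frequencies from unphased diploid
#' dosages, resolving the double-heterozygote phase ambiguity by EM
#' (initialized at linkage equilibrium, tolerance `1e-8`, at most 1000
#' iterations). With no double heterozygotes the estimate equals direct
#' counting. Alleles: `A`/`B` denote the alt allele at locus 1 / locus 2.
#'
#' @param g1,g2 integer dosage vectors (0/1/2, NA missing) over the same
#'   samples; pairwise-complete individuals are used.
#' @param tol,max_iter EM controls.
#' @return list with `f` (named frequencies `AB`, `Ab`, `aB`, `ab`), `D`,
#'   `n` (individuals used), `iterations`, `converged`, `loglik`.
#' @export
em_haplotype_freqs <- function(g1, g2, tol = 1e-8, max_iter = 1000L) {
  counts <- matrix(genotype_class_counts(g1, g2), ncol = 1)
  if (sum(counts) < 2) stop("need at least 2 double-called individuals")
  fit <- em_core(counts, tol, max_iter)
  f <- c(AB = fit$fAB, Ab = fit$fAb, aB = fit$faB, ab = fit$fab)
  list(f = f, D = unname(f["AB"] * f["ab"] - f["Ab"] * f["aB"]),
       n = fit$n, iterations = fit$iterations, converged = fit$converged,
       loglik = hap_loglik(counts[, 1], f))
}

# multinomial log-likelihood of the nine genotype classes given haplotype
# frequencies (random union of gametes)
hap_loglik <- function(counts9, f) {
  fAB <- f["AB"]; fAb <- f["Ab"]; faB <- f["aB"]; fab <- f["ab"]
  pr <- c(fab^2,                     # (0,0)
          2 * fab * faB,             # (0,1)
          faB^2,                     # (0,2)
          2 * fab * fAb,             # (1,0)
          2 * (fAB * fab + fAb * faB), # (1,1)
          2 * fAB * faB,             # (1,2)
          fAb^2,                     # (2,0)
          2 * fAB * fAb,             # (2,1)
          fAB^2)                     # (2,2)
  keep <- counts9 > 0
  sum(counts9[keep] * log(pmax(pr[keep], 1e-300)))
}

#' LD coefficients from haplotype frequencies
#'
#' `r2 = D^2 / (pA qA pB qB)`; `D' = D / Dmax` with
#' `Dmax = min(pA qB, qA pB)` for `D > 0` and `min(pA pB, qA qB)` for
#' `D < 0`; `D = 0` gives `D' = 0`.
#'
#' @param h result of [em_haplotype_freqs()], or a named frequency vector
#'   with elements `AB`, `Ab`, `aB`, `ab`.
#' @return named numeric vector `c(r2, dprime, D)`; `NA` when either locus
#'   is monomorphic.
#' @export
r2_pair <- function(h) {
  f <- if (is.list(h)) h$f else h
  pA <- unname(f["AB"] + f["Ab"]); pB <- unname(f["AB"] + f["aB"])
  D <- unname(f["AB"] * f["ab"] - f["Ab"] * f["aB"])
  den <- pA * (1 - pA) * pB * (1 - pB)
  if (den <= 0) return(c(r2 = NA_real_, dprime = NA_real_, D = D))
  dmax <- if (D > 0) min(pA * (1 - pB), (1 - pA) * pB)
          else if (D < 0) min(pA * pB, (1 - pA) * (1 - pB))
          else NA_real_
  dprime <- if (D == 0) 0 else abs(D) / dmax
  c(r2 = D^2 / den, dprime = dprime, D = D)
}

# class-count matrix (9 x P) for a list of locus pairs via indicator algebra
pair_class_counts <- function(G, jj, kk) {
  ind <- lapply(0:2, function(d) {
    m <- G == d
    m[is.na(m)] <- FALSE
    m
  })
  counts <- matrix(0, nrow = 9, ncol = length(jj))
  for (a in 0:2) for (b in 0:2) {
    counts[3L * a + b + 1L, ] <-
      colSums(ind[[a + 1]][, jj, drop = FALSE] *
              ind[[b + 1]][, kk, drop = FALSE])
  }
  counts
}

#' Distance-binned LD decay per population
#'
#' Scores every same-chromosome locus pair within `max_dist_bp` with `r2`
#' (EM haplotype frequencies by default, or the composite dosage
#' correlation), restricted to sites with within-population MAF at least
#' `maf_min`, then averages `r2` in distance bins.
#'
#' @param x a [geno_matrix()].
#' @param popmap population map; LD is computed within populations only.
#' @param max_dist_bp maximum pair distance (default 300 kb).
#' @param bin_width_bp distance bin width (default 1 kb).
#' @param maf_min within-population MAF floor for sites entering pairs.
#' @param method `"em"` (EM haplotype r2) or `"composite"` (squared dosage
#'   correlation).
#' @param keep_pairs also return the per-pair table.
#' @return data.frame with `pop`, `bin_start`, `bin_end`, `mean_r2`,
#'   `n_pairs` (empty bins omitted); with `keep_pairs`, the per-pair
#'   data.frame is attached as attribute `pairs`.
#' @export
decay_curve <- function(x, popmap, max_dist_bp = 300000, bin_width_bp = 1000,
                        maf_min = 0.05, method = c("em", "composite"),
                        keep_pairs = FALSE) {
  method <- match.arg(method)
  idx <- split_pops(x, popmap)
  out <- list(); pair_out <- list()
  for (pp in names(idx)) {
    G <- x$geno[idx[[pp]], , drop = FALSE]
    pc <- pop_counts(G)
    usable <- which(pc$n_all >= 4 &
                    pmin(pc$p, 1 - pc$p) >= maf_min &
                    pc$p > 0 & pc$p < 1)
    if (length(usable) < 2) next
    pos <- x$sites$pos[usable]
    chrom <- x$sites$chrom[usable]
    jj <- integer(0); kk <- integer(0)
    for (cc in unique(chrom)) {
      ci <- which(chrom == cc)
      cpos <- pos[ci]
      hi <- findInterval(cpos + max_dist_bp, cpos)
      for (a in seq_along(ci)) {
        if (hi[a] > a) {
          jj <- c(jj, rep(ci[a], hi[a] - a))
          kk <- c(kk, ci[(a + 1):hi[a]])
        }
      }
    }
    if (!length(jj)) next
    dist <- pos[kk] - pos[jj]
    r2 <- pair_r2(G[, usable, drop = FALSE], jj, kk, method)
    keep <- !is.na(r2)
    df <- data.frame(pop = pp, dist = dist[keep], r2 = r2[keep])
    if (keep_pairs) pair_out[[pp]] <- df
    if (!nrow(df)) next
    bin <- floor(df$dist / bin_width_bp)
    agg <- stats::aggregate(df$r2, by = list(bin = bin),
                            FUN = function(v) c(mean(v), length(v)))
    out[[pp]] <- data.frame(pop = pp,
                            bin_start = agg$bin * bin_width_bp,
                            bin_end = (agg$bin + 1) * bin_width_bp,
                            mean_r2 = agg$x[, 1],
                            n_pairs = as.integer(agg$x[, 2]))
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(pop = character(), bin_start = numeric(),
               bin_end = numeric(), mean_r2 = numeric(),
               n_pairs = integer())
  rownames(res) <- NULL
  if (keep_pairs) attr(res, "pairs") <- do.call(rbind, pair_out)
  res
}

# r2 for a list of pairs, chunked to bound memory
pair_r2 <- function(G, jj, kk, method, chunk = 20000L) {
  P <- length(jj)
  r2 <- numeric(P)
  for (s in seq(1L, P, by = chunk)) {
    e <- min(s + chunk - 1L, P)
    j <- jj[s:e]; k <- kk[s:e]
    if (method == "composite") {
      r2[s:e] <- composite_r2(G, j, k)
    } else {
      counts <- pair_class_counts(G, j, k)
      fit <- em_core(counts)
      f <- rbind(AB = fit$fAB, Ab = fit$fAb, aB = fit$faB, ab = fit$fab)
      pA <- f["AB", ] + f["Ab", ]; pB <- f["AB", ] + f["aB", ]
      D <- f["AB", ] * f["ab", ] - f["Ab", ] * f["aB", ]
      den <- pA * (1 - pA) * pB * (1 - pB)
      r2[s:e] <- ifelse(den > 0, D^2 / den, NA_real_)
    }
  }
  r2
}

composite_r2 <- function(G, jj, kk) {
  vapply(seq_along(jj), function(i) {
    r <- suppressWarnings(
      stats::cor(G[, jj[i]], G[, kk[i]], use = "pairwise.complete.obs"))
    r^2
  }, numeric(1))
}
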