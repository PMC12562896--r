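# per-population allele-count summaries; the workhorse behind every
# diversity statistic. Returns, for one population's sample rows:
#   n_ind  diploids called per site
#   n_all  called allele count (2 * n_ind)
#   c_alt  alt-allele count
#   p      alt-allele frequency (NA where nothing called)
#   h_obs  fraction of called diploids that are heterozygous
pop_counts <- function(geno_rows) {
  n_ind <- colSums(!is.na(geno_rows))
  c_alt <- colSums(geno_rows, na.rm = TRUE)
  n_all <- 2 * n_ind
  p <- ifelse(n_all > 0, c_alt / n_all, NA_real_)
  h_obs <- ifelse(n_ind > 0, colSums(geno_rows == 1, na.rm = TRUE) / n_ind,
                  NA_real_)
  list(n_ind = n_ind, n_all = n_all, c_alt = c_alt, p = p, h_obs = h_obs)
}

split_pops <- function(x, popmap) {
  popmap <- check_popmap(x, popmap)
  split(seq_len(n_samples(x)), popmap$pop)
}

#' Per-site allele frequencies by population
#'
#' @param x a [geno_matrix()].
#' @param popmap population map data.frame (`sample`, `pop`).
#' @return data.frame with `pop`, `chrom`, `pos`, `n_called` (alleles),
#'   `p` (alt frequency) and `maf`; sites with no called genotype in a
#'   population are omitted for that population.
#' @export
site_frequencies <- function(x, popmap) {
  idx <- split_pops(x, popmap)
  out <- lapply(names(idx), function(pp) {
    pc <- pop_counts(x$geno[idx[[pp]], , drop = FALSE])
    keep <- pc$n_all > 0
    data.frame(pop = pp, chrom = x$sites$chrom[keep], pos = x$sites$pos[keep],
               n_called = pc$n_all[keep], p = pc$p[keep],
               maf = pmin(pc$p[keep], 1 - pc$p[keep]))
  })
  do.call(rbind, out)
}

#' Proportion of polymorphic sites per population
#'
#' A site counts as polymorphic within a population when its within-
#' population minor allele frequency exceeds `maf_min` (default 0: any
#' segregating site), out of all sites with at least one called genotype.
#'
#' @inheritParams site_frequencies
#' @param maf_min polymorphism MAF floor.
#' @return named numeric vector, one value per population.
#' @export
prop_polymorphic <- function(x, popmap, maf_min = 0) {
  idx <- split_pops(x, popmap)
  vapply(idx, function(rows) {
    pc <- pop_counts(x$geno[rows, , drop = FALSE])
    callable <- pc$n_all > 0
    if (!any(callable)) return(NA_real_)
    maf <- pmin(pc$p[callable], 1 - pc$p[callable])
    sum(maf > maf_min) / sum(callable)
  }, numeric(1))
}

#' Observed heterozygosity per population
#'
#' Per site, the fraction of called diploids that are heterozygous;
#' averaged over callable sites.
#'
#' @inheritParams site_frequencies
#' @return named numeric vector.
#' @export
observed_het <- function(x, popmap) {
  idx <- split_pops(x, popmap)
  vapply(idx, function(rows) {
    pc <- pop_counts(x$geno[rows, , drop = FALSE])
    mean(pc$h_obs[pc$n_ind > 0])
  }, numeric(1))
}

#' Expected heterozygosity per population
#'
#' Per site, the Nei plug-in estimator `1 - p^2 - q^2`; averaged over
#' callable sites. No small-sample correction is applied (see
#' [nucleotide_diversity()] for the unbiased pairwise form).
#'
#' @inheritParams site_frequencies
#' @return named numeric vector.
#' @export
expected_het <- function(x, popmap) {
  idx <- split_pops(x, popmap)
  vapply(idx, function(rows) {
    pc <- pop_counts(x$geno[rows, , drop = FALSE])
    keep <- pc$n_all > 0
    mean(het_exp_site(pc$p[keep]))
  }, numeric(1))
}

het_exp_site <- function(p) 1 - p^2 - (1 - p)^2

# unbiased per-site pairwise nucleotide diversity from allele counts
pi_site <- function(c_alt, n_all) {
  c_ref <- n_all - c_alt
  ifelse(n_all >= 2, c_ref * c_alt / choose(n_all, 2), NA_real_)
}

#' Nucleotide diversity per population
#'
#' Per site, the unbiased average pairwise difference
#' `c_ref * c_alt / choose(n, 2)` over the `n` called alleles (the estimator
#' used by per-site VCF diversity tools); averaged over sites with at least
#' two called alleles. Division is by the number of SNP sites, not genome
#' length, so values are on the per-variant-site scale.
#'
#' @inheritParams site_frequencies
#' @return named numeric vector.
#' @export
nucleotide_diversity <- function(x, popmap) {
  idx <- split_pops(x, popmap)
  vapply(idx, function(rows) {
    pc <- pop_counts(x$geno[rows, , drop = FALSE])
    v <- pi_site(pc$c_alt, pc$n_all)
    mean(v, na.rm = TRUE)
  }, numeric(1))
}

pic_site <- function(p) {
  q <- 1 - p
  1 - (p^2 + q^2) - 2 * p^2 * q^2
}

#' Polymorphism information content per population
#'
#' Per biallelic site, `PIC = 1 - (p^2 + q^2) - 2 p^2 q^2` (the classic
#' marker-informativeness index, the biallelic reduction of
#' `1 - sum p_i^2 - sum_i sum_j 2 p_i^2 p_j^2`); averaged over callable
#' sites.
#'
#' @inheritParams site_frequencies
#' @return named numeric vector.
#' @export
pic <- function(x, popmap) {
  idx <- split_pops(x, popmap)
  vapply(idx, function(rows) {
    pc <- pop_counts(x$geno[rows, , drop = FALSE])
    keep <- pc$n_all > 0
    mean(pic_site(pc$p[keep]))
  }, numeric(1))
}

#' Per-population diversity table
#'
#' One row per population with the five summary statistics `Pn`, `He`,
#' `Ho`, `Pi`, `PIC`, each averaged over the retained sites. A global site
#' call-rate floor is applied first so every statistic is computed on the
#' same site set.
#'
#' @inheritParams site_frequencies
#' @param maf_min polymorphism floor passed to [prop_polymorphic()].
#' @param callrate_min minimum overall fraction of called genotypes a site
#'   needs to enter the statistics (0 disables).
#' @return data.frame with columns `group`, `Pn`, `He`, `Ho`, `Pi`, `PIC`;
#'   the number of sites used is attached as attribute `n_sites_used`.
#' @export
diversity_table <- function(x, popmap, maf_min = 0, callrate_min = 0.8) {
  if (callrate_min > 0 && n_sites(x) > 0) {
    cr <- colMeans(!is.na(x$geno))
    x <- subset_sites(x, cr >= callrate_min)
  }
  tab <- data.frame(group = sort(unique(popmap$pop)))
  tab$Pn <- prop_polymorphic(x, popmap, maf_min)[tab$group]
  tab$He <- expected_het(x, popmap)[tab$group]
  tab$Ho <- observed_het(x, popmap)[tab$group]
  tab$Pi <- nucleotide_diversity(x, popmap)[tab$group]
  tab$PIC <- pic(x, popmap)[tab$group]
  attr(tab, "n_sites_used") <- n_sites(x)
  tab
}

#' Relative difference between two statistics, in percent
#'
#' `100 * (b - a) / b`, rounded to two decimals -- the "`a` is X% lower
#' than `b`" convention used when comparing per-population diversity values.
#'
#' @param a,b numeric statistics; `b` must be nonzero.
#' @return percentage, rounded to 2 decimals.
#' @export
relative_difference <- function(a, b) {
  if (any(b == 0)) stop("reference value must be nonzero")
  round(100 * (b - a) / b, 2)
}

#' Pairwise comparison report for a diversity table
#'
#' For every unordered pair of populations and each of `He` and `Pi`,
#' reports how much lower the smaller value is than the larger one
#' (via [relative_difference()]), plus the per-column extremes.
#'
#' @param tab a [diversity_table()] result (or any data.frame with columns
#'   `group`, `Pn`, `He`, `Ho`, `Pi`, `PIC`).
#' @param stats columns to compare.
#' @return list with `comparisons` (data.frame: `stat`, `lower_group`,
#'   `higher_group`, `lower`, `higher`, `pct_lower`) and `extremes`
#'   (data.frame: `stat`, `min_group`, `min`, `max_group`, `max`).
#' @export
table1_report <- function(tab, stats = c("He", "Pi")) {
  stopifnot(nrow(tab) >= 2)
  cmp <- list()
  for (st in stats) {
    v <- tab[[st]]
    for (i in seq_len(nrow(tab) - 1)) for (j in (i + 1):nrow(tab)) {
      lo <- if (v[i] <= v[j]) i else j
      hi <- if (v[i] <= v[j]) j else i
      cmp[[length(cmp) + 1]] <- data.frame(
        stat = st, lower_group = tab$group[lo], higher_group = tab$group[hi],
        lower = v[lo], higher = v[hi],
        pct_lower = relative_difference(v[lo], v[hi]))
    }
  }
  all_stats <- intersect(c("Pn", "He", "Ho", "Pi", "PIC"), names(tab))
  ext <- do.call(rbind, lapply(all_stats, function(st) {
    v <- tab[[st]]
    data.frame(stat = st, min_group = tab$group[which.min(v)], min = min(v),
               max_group = tab$group[which.max(v)], max = max(v))
  }))
  list(comparisons = do.call(rbind, cmp), extremes = ext)
}
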