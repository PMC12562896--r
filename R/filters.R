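#' Hard-filter thresholds for SNP site removal
#'
#' The standard GATK-style post-calling thresholds: a site is removed when
#' any *present* metric violates its bound (strict inequalities; a metric
#' exactly at its threshold passes, and an absent metric never triggers
#' removal).
#'
#' @return named list of thresholds.
#' @export
hard_filter_defaults <- function() {
  list(min_qd = 2.0, max_fs = 60.0, min_mq = 40.0, max_sor = 3.0,
       min_mqranksum = -12.5, min_readposranksum = -8.0)
}

filter_report <- function(stage, sites_in, sites_out, removed_by_rule = list(),
                          masked_genotypes = 0L) {
  structure(list(stage = stage, sites_in = sites_in, sites_out = sites_out,
                 removed = sites_in - sites_out,
                 removed_by_rule = removed_by_rule,
                 masked_genotypes = masked_genotypes),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("[%s] %d sites in, %d removed, %d out\n", x$stage,
              x$sites_in, x$removed, x$sites_out))
  for (nm in names(x$removed_by_rule))
    cat(sprintf("    %-16s %d\n", nm, x$removed_by_rule[[nm]]))
  if (x$masked_genotypes > 0)
    cat(sprintf("    genotypes masked: %d\n", x$masked_genotypes))
  invisible(x)
}

#' Remove sites violating INFO hard-filter thresholds
#'
#' @param x a [geno_matrix()] whose site table carries the INFO metric
#'   columns (any subset of QD, FS, MQ, SOR, MQRankSum, ReadPosRankSum).
#' @param thresholds as [hard_filter_defaults()].
#' @return list with `geno` (filtered matrix) and `report`
#'   (a `filter_report`; per-metric tallies count every violation, so a site
#'   failing two rules appears in both tallies).
#' @export
hard_filter <- function(x, thresholds = hard_filter_defaults()) {
  s <- x$sites
  gv <- function(k) if (k %in% names(s)) s[[k]] else rep(NA_real_, nrow(s))
  viol <- list(
    QD = !is.na(gv("QD")) & gv("QD") < thresholds$min_qd,
    FS = !is.na(gv("FS")) & gv("FS") > thresholds$max_fs,
    MQ = !is.na(gv("MQ")) & gv("MQ") < thresholds$min_mq,
    SOR = !is.na(gv("SOR")) & gv("SOR") > thresholds$max_sor,
    MQRankSum = !is.na(gv("MQRankSum")) &
      gv("MQRankSum") < thresholds$min_mqranksum,
    ReadPosRankSum = !is.na(gv("ReadPosRankSum")) &
      gv("ReadPosRankSum") < thresholds$min_readposranksum)
  any_viol <- Reduce(`|`, viol)
  out <- subset_sites(x, !any_viol)
  list(geno = out,
       report = filter_report("hard_filter", n_sites(x), n_sites(out),
                              lapply(viol, sum)))
}

# TRUE for every SNP that lies in some window of `window_bp` consecutive
# bases holding more than `max_snps` SNPs; positions must be sorted
cluster_flags <- function(pos, window_bp, max_snps) {
  L <- length(pos)
  flag <- logical(L)
  if (L <= max_snps) return(flag)
  k <- max_snps  # a violating window holds >= max_snps + 1 SNPs
  span_ok <- pos[(1 + k):L] - pos[1:(L - k)] <= window_bp - 1L
  for (i in which(span_ok)) flag[i:(i + k)] <- TRUE
  flag
}

#' Remove SNP clusters
#'
#' A SNP is removed when it belongs to any window of `window_bp` consecutive
#' bases (endpoints inclusive) containing more than `max_snps` SNPs -- the
#' "no more than 2 SNPs within 5 bp" rule at the defaults.
#'
#' @param x a [geno_matrix()] (sites sorted by position).
#' @param window_bp window span in bases.
#' @param max_snps maximum SNPs tolerated per window.
#' @return list with `geno` and `report`.
#' @export
cluster_filter <- function(x, window_bp = 5L, max_snps = 2L) {
  s <- x$sites
  drop <- logical(nrow(s))
  for (cc in unique(s$chrom)) {
    i <- which(s$chrom == cc)
    drop[i] <- cluster_flags(s$pos[i], window_bp, max_snps)
  }
  out <- subset_sites(x, !drop)
  list(geno = out,
       report = filter_report("cluster_filter", n_sites(x), n_sites(out),
                              list(snp_cluster = sum(drop))))
}

#' Remove SNPs near indels
#'
#' A SNP is removed when any indel on the same chromosome lies within
#' `dist_bp` of it (inclusive).
#'
#' @param x a [geno_matrix()]; the indel side list from [read_vcf()] is used
#'   unless `indel_positions` is supplied.
#' @param indel_positions optional data.frame with `chrom`, `pos`.
#' @param dist_bp proximity threshold in bases.
#' @return list with `geno` and `report`.
#' @export
indel_proximity_filter <- function(x, indel_positions = NULL, dist_bp = 5L) {
  if (is.null(indel_positions)) indel_positions <- x$indels
  s <- x$sites
  drop <- logical(nrow(s))
  for (cc in unique(indel_positions$chrom)) {
    ip <- sort(indel_positions$pos[indel_positions$chrom == cc])
    if (!length(ip)) next
    i <- which(s$chrom == cc)
    if (!length(i)) next
    # nearest indel via binary search on the sorted indel positions
    j <- findInterval(s$pos[i], ip)
    d_lo <- ifelse(j >= 1, s$pos[i] - ip[pmax(j, 1L)], Inf)
    d_hi <- ifelse(j < length(ip), ip[pmin(j + 1L, length(ip))] - s$pos[i],
                   Inf)
    drop[i] <- pmin(d_lo, d_hi) <= dist_bp
  }
  out <- subset_sites(x, !drop)
  list(geno = out,
       report = filter_report("indel_proximity_filter", n_sites(x),
                              n_sites(out),
                              list(indel_proximity = sum(drop))))
}

#' Mask low-quality genotype calls
#'
#' Genotype calls with GQ below `min_gq` (strict) are set to missing; sites
#' are never removed by this rule, matching the convention of marking the
#' sample's call rather than dropping the locus.
#'
#' @param x a [geno_matrix()] carrying per-call GQ.
#' @param min_gq threshold.
#' @return list with `geno` and `report` (masked-call count).
#' @export
gq_mask <- function(x, min_gq = 20.0) {
  if (is.null(x$gq)) {
    warning("no GQ values present; gq_mask is a no-op")
    return(list(geno = x,
                report = filter_report("gq_mask", n_sites(x), n_sites(x))))
  }
  low <- !is.na(x$gq) & x$gq < min_gq & !is.na(x$geno)
  x$geno[low] <- NA_integer_
  list(geno = x,
       report = filter_report("gq_mask", n_sites(x), n_sites(x),
                              masked_genotypes = sum(low)))
}

#' Apply the full post-calling filter cascade
#'
#' Fixed order: hard INFO filter, SNP-cluster filter, indel-proximity
#' filter, then per-genotype GQ masking.
#'
#' @param x a [geno_matrix()].
#' @param thresholds hard-filter thresholds.
#' @param cluster_window,cluster_max cluster-rule parameters.
#' @param indel_dist indel-proximity distance (bp).
#' @param min_gq GQ masking threshold (`NULL` skips masking).
#' @return list with `geno` (filtered matrix) and `reports` (list of
#'   per-stage `filter_report`s; their site counts chain).
#' @export
filter_variants <- function(x, thresholds = hard_filter_defaults(),
                            cluster_window = 5L, cluster_max = 2L,
                            indel_dist = 5L, min_gq = 20.0) {
  r1 <- hard_filter(x, thresholds)
  r2 <- cluster_filter(r1$geno, cluster_window, cluster_max)
  r3 <- indel_proximity_filter(r2$geno, dist_bp = indel_dist)
  reports <- list(hard = r1$report, cluster = r2$report, indel = r3$report)
  g <- r3$geno
  if (!is.null(min_gq) && !is.null(g$gq)) {
    r4 <- gq_mask(g, min_gq)
    g <- r4$geno
    reports$gq <- r4$report
  }
  list(geno = g, reports = reports)
}

#' Serialize filter reports as JSON
#' @param reports list of `filter_report`s (as from [filter_variants()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(reports, path) {
  jsonlite::write_json(lapply(reports, unclass), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
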