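#' Tile chromosomes with sliding windows
#'
#' Half-open windows `[start, end)` starting at 1 and advancing by `step`;
#' the final windows are truncated at the chromosome end. Every base of
#' every chromosome is covered by at least one window.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param window_size window span in bp.
#' @param step stride in bp (`step <= window_size`).
#' @return data.frame with `chrom`, `start`, `end`.
#' @export
make_windows <- function(chrom_lengths, window_size = 100000,
                         step = window_size) {
  stopifnot(window_size >= step, step > 0)
  out <- lapply(names(chrom_lengths), function(cc) {
    len <- chrom_lengths[[cc]]
    starts <- seq(1, len, by = step)
    data.frame(chrom = cc, start = starts,
               end = pmin(starts + window_size, len + 1))
  })
  do.call(rbind, out)
}

# Weir & Cockerham (1984) per-site variance components a, b, c for two
# populations from dosage rows. Sites need at least one called diploid in
# each population and nbar > 1.
wc_site_components <- function(G1, G2) {
  s1 <- pop_counts(G1); s2 <- pop_counts(G2)
  n1 <- s1$n_ind; n2 <- s2$n_ind
  p1 <- s1$p; p2 <- s2$p
  h1 <- s1$h_obs; h2 <- s2$h_obs
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2v <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2v - (pbar * (1 - pbar) - s2v * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2v * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  bad <- n1 == 0 | n2 == 0 | nbar <= 1 | is.na(pbar)
  a[bad] <- NA_real_; b[bad] <- NA_real_; cc[bad] <- NA_real_
  # monomorphic across both populations: no allelic variance to partition
  mono <- !bad & (pbar == 0 | pbar == 1)
  a[mono] <- NA_real_; b[mono] <- NA_real_; cc[mono] <- NA_real_
  list(a = a, b = b, c = cc)
}

# sum per-site values over each window via cumulative sums on sorted sites
window_sums <- function(sites, windows, values) {
  v <- ifelse(is.na(values), 0, values)
  used <- !is.na(values)
  out_sum <- numeric(nrow(windows)); out_n <- integer(nrow(windows))
  for (cc in unique(windows$chrom)) {
    si <- which(sites$chrom == cc)
    wi <- which(windows$chrom == cc)
    if (!length(si)) next
    pos <- sites$pos[si]
    cs <- c(0, cumsum(v[si]))
    cn <- c(0, cumsum(as.integer(used[si])))
    lo <- findInterval(windows$start[wi] - 0.5, pos)   # sites with pos < start
    hi <- findInterval(windows$end[wi] - 0.5, pos)     # sites with pos < end
    out_sum[wi] <- cs[hi + 1] - cs[lo + 1]
    out_n[wi] <- cn[hi + 1] - cn[lo + 1]
  }
  list(sum = out_sum, n = out_n)
}

#' Sliding-window Weir-Cockerham FST between two populations
#'
#' Per-site 1984 variance components `a`, `b`, `c`; each window reports the
#' ratio-of-sums estimate `sum(a) / sum(a + b + c)` over its usable sites.
#' Windows with fewer than `min_snps` usable sites are `NA`.
#'
#' @param x a [geno_matrix()].
#' @param popmap population map.
#' @param windows window table from [make_windows()].
#' @param pops character vector of exactly two population labels.
#' @param min_snps minimum usable SNPs per window.
#' @return the `windows` data.frame with `n_snps` and `fst` columns added.
#' @export
window_fst <- function(x, popmap, windows, pops, min_snps = 3L) {
  stopifnot(length(pops) == 2)
  idx <- split_pops(x, popmap)
  if (!all(pops %in% names(idx)))
    stop("populations not in map: ", paste(setdiff(pops, names(idx)),
                                           collapse = ", "))
  comp <- wc_site_components(x$geno[idx[[pops[1]]], , drop = FALSE],
                             x$geno[idx[[pops[2]]], , drop = FALSE])
  num <- window_sums(x$sites, windows, comp$a)
  den <- window_sums(x$sites, windows, comp$a + comp$b + comp$c)
  windows$n_snps <- den$n
  windows$fst <- ifelse(den$n >= min_snps & den$sum != 0,
                        num$sum / den$sum, NA_real_)
  windows
}

#' Sliding-window nucleotide diversity for one population
#'
#' Sum of per-site unbiased pairwise diversity over the window's SNPs,
#' divided by the SNP count (`mode = "per_snp"`) or the window span in bp
#' (`mode = "per_bp"`).
#'
#' @inheritParams window_fst
#' @param pop population label.
#' @param mode denominator convention.
#' @return the `windows` data.frame with `n_snps` and `pi` columns added.
#' @export
window_pi <- function(x, popmap, windows, pop, min_snps = 3L,
                      mode = c("per_snp", "per_bp")) {
  mode <- match.arg(mode)
  idx <- split_pops(x, popmap)
  pc <- pop_counts(x$geno[idx[[pop]], , drop = FALSE])
  v <- pi_site(pc$c_alt, pc$n_all)
  ws <- window_sums(x$sites, windows, v)
  windows$n_snps <- ws$n
  den <- if (mode == "per_snp") ws$n else (windows$end - windows$start)
  windows$pi <- ifelse(ws$n >= min_snps, ws$sum / den, NA_real_)
  windows
}

#' Select windows in the joint top quantiles of FST and the pi ratio
#'
#' Empirical upper quantiles are computed over windows with defined values
#' only; a window is selected when it reaches both the `1 - q_fst` FST
#' quantile and the `1 - q_ratio` pi-ratio quantile (ties included).
#' Windows whose target-population diversity is exactly zero have an
#' undefined ratio; they are excluded from ranking and selection and
#' flagged in `fixed_target` instead.
#'
#' @param stats window-statistics data.frame with `fst` and `pi_ratio`
#'   columns (as built by [sweep_scan()]).
#' @param q_fst,q_ratio upper-tail fractions.
#' @return `stats` with logical column `selected` added; the thresholds are
#'   attached as attribute `thresholds`.
#' @export
top_quantile_intersection <- function(stats, q_fst = 1e-4, q_ratio = q_fst) {
  ok_f <- !is.na(stats$fst)
  ok_r <- !is.na(stats$pi_ratio) & is.finite(stats$pi_ratio)
  if (sum(ok_f) < 1 / q_fst || sum(ok_r) < 1 / q_ratio)
    warning("fewer windows than 1/q; top-quantile selection is coarse")
  thr_f <- stats::quantile(stats$fst[ok_f], 1 - q_fst, names = FALSE)
  thr_r <- stats::quantile(stats$pi_ratio[ok_r], 1 - q_ratio, names = FALSE)
  stats$selected <- ok_f & ok_r & stats$fst >= thr_f & stats$pi_ratio >= thr_r
  attr(stats, "thresholds") <- c(fst = thr_f, pi_ratio = thr_r)
  stats
}

#' Merge selected windows into candidate sweep regions
#'
#' Overlapping or near-adjacent selected windows on the same chromosome
#' (gap between half-open intervals at most `gap_tolerance` bp) merge into
#' one region carrying the peak statistics of its members.
#'
#' @param selected data.frame of selected windows (`chrom`, `start`, `end`,
#'   optionally `fst`, `pi_ratio`).
#' @param gap_tolerance maximum gap in bp (0 merges touching windows).
#' @return data.frame with `chrom`, `start`, `end`, `n_windows`,
#'   `peak_fst`, `peak_pi_ratio`.
#' @export
na_max <- function(a, b) {
  v <- c(a, b)
  if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
}

merge_regions <- function(selected, gap_tolerance = 0) {
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_windows = integer(),
                      peak_fst = numeric(), peak_pi_ratio = numeric())
  if (!nrow(selected)) return(empty)
  sel <- selected[order(selected$chrom, selected$start), , drop = FALSE]
  has_fst <- "fst" %in% names(sel)
  has_ratio <- "pi_ratio" %in% names(sel)
  regions <- list()
  cur <- NULL
  flush <- function(cur) data.frame(
    chrom = cur$chrom, start = cur$start, end = cur$end,
    n_windows = cur$n, peak_fst = cur$fst, peak_pi_ratio = cur$ratio)
  for (i in seq_len(nrow(sel))) {
    w <- sel[i, ]
    wf <- if (has_fst) w$fst else NA_real_
    wr <- if (has_ratio) w$pi_ratio else NA_real_
    if (!is.null(cur) && w$chrom == cur$chrom &&
        w$start - cur$end <= gap_tolerance) {
      cur$end <- max(cur$end, w$end)
      cur$n <- cur$n + 1L
      cur$fst <- na_max(cur$fst, wf)
      cur$ratio <- na_max(cur$ratio, wr)
    } else {
      if (!is.null(cur)) regions[[length(regions) + 1]] <- flush(cur)
      cur <- list(chrom = w$chrom, start = w$start, end = w$end, n = 1L,
                  fst = wf, ratio = wr)
    }
  }
  regions[[length(regions) + 1]] <- flush(cur)
  out <- do.call(rbind, regions)
  rownames(out) <- NULL
  out
}

#' Full FST x pi-ratio selective-sweep scan
#'
#' Computes windowed Weir-Cockerham FST between target and reference
#' populations, windowed nucleotide diversity in each, the diversity ratio
#' (default orientation `pi_ref / pi_target`, so high values mean diversity
#' loss in the target), selects windows in the joint top quantiles, and
#' merges them into candidate regions.
#'
#' @inheritParams window_fst
#' @param target,reference population labels; the target is the population
#'   screened for sweeps.
#' @param window_size,step window tiling in bp (used when `windows` is NULL).
#' @param chrom_lengths named lengths; defaults to max position per
#'   chromosome.
#' @param windows optional precomputed window table.
#' @param q_fst,q_ratio upper-tail fractions for selection.
#' @param gap_tolerance region-merge gap (bp).
#' @param orientation `"ref_over_target"` or `"target_over_ref"`.
#' @param pi_mode denominator convention for window diversity.
#' @return object of class `sweep_scan`: list with `windows` (per-window
#'   stats incl. `pi_target`, `pi_ref`, `pi_ratio`, `log2_ratio`,
#'   `selected`, `fixed_target`), `regions`, `fixed_regions` (regions from
#'   zero-target-diversity windows passing the FST threshold, reported
#'   separately), `thresholds`, and `params`.
#' @export
sweep_scan <- function(x, popmap, target, reference, window_size = 100000,
                       step = window_size, chrom_lengths = NULL,
                       windows = NULL, q_fst = 1e-4, q_ratio = q_fst,
                       min_snps = 3L, gap_tolerance = 0,
                       orientation = c("ref_over_target", "target_over_ref"),
                       pi_mode = c("per_snp", "per_bp")) {
  orientation <- match.arg(orientation)
  pi_mode <- match.arg(pi_mode)
  if (is.null(windows)) {
    if (is.null(chrom_lengths)) {
      chrom_lengths <- tapply(x$sites$pos, x$sites$chrom, max)
      chrom_lengths <- stats::setNames(as.numeric(chrom_lengths),
                                       names(chrom_lengths))
    }
    windows <- make_windows(chrom_lengths, window_size, step)
  }
  wf <- window_fst(x, popmap, windows, c(target, reference), min_snps)
  wt <- window_pi(x, popmap, windows, target, min_snps, pi_mode)
  wr <- window_pi(x, popmap, windows, reference, min_snps, pi_mode)
  stats <- windows
  stats$n_snps <- wf$n_snps
  stats$fst <- wf$fst
  stats$pi_target <- wt$pi
  stats$pi_ref <- wr$pi
  num <- if (orientation == "ref_over_target") stats$pi_ref else stats$pi_target
  den <- if (orientation == "ref_over_target") stats$pi_target else stats$pi_ref
  stats$pi_ratio <- ifelse(!is.na(den) & den > 0 & !is.na(num),
                           num / den, NA_real_)
  stats$fixed_target <- !is.na(den) & den == 0 & !is.na(num) & num > 0
  stats$log2_ratio <- log2(stats$pi_ratio)
  stats <- top_quantile_intersection(stats, q_fst, q_ratio)
  thr <- attr(stats, "thresholds")
  fixed_sel <- stats$fixed_target & !is.na(stats$fst) & stats$fst >= thr["fst"]
  structure(list(
    windows = stats,
    regions = merge_regions(stats[stats$selected, , drop = FALSE],
                            gap_tolerance),
    fixed_regions = merge_regions(stats[fixed_sel, , drop = FALSE],
                                  gap_tolerance),
    thresholds = thr,
    params = list(target = target, reference = reference,
                  window_size = window_size, step = step, q_fst = q_fst,
                  q_ratio = q_ratio, min_snps = min_snps,
                  gap_tolerance = gap_tolerance, orientation = orientation,
                  pi_mode = pi_mode)),
    class = "sweep_scan")
}

#' @export
print.sweep_scan <- function(x, ...) {
  cat("sweep_scan:", nrow(x$windows), "windows,",
      sum(x$windows$selected, na.rm = TRUE), "selected,",
      nrow(x$regions), "regions\n")
  cat("  thresholds: fst >=", format(x$thresholds["fst"], digits = 4),
      ", pi_ratio >=", format(x$thresholds["pi_ratio"], digits = 4), "\n")
  invisible(x)
}

#' Annotate regions with overlapping genes from a GFF3 file
#'
#' Genes whose interval intersects a region (1-based inclusive coordinates
#' on both sides) are listed on it; the global deduplicated gene set is
#' attached as an attribute.
#'
#' @param regions data.frame with `chrom`, `start`, `end` (half-open window
#'   coordinates; the inclusive end is `end - 1`).
#' @param gff path to a GFF3 file, or a `GRanges` of gene features.
#' @param feature_type GFF3 type to use (default `"gene"`).
#' @return `regions` with a `gene_ids` column (comma-separated, "" when
#'   none) and `n_genes`; the unique gene vector is attribute `genes`.
#' @export
annotate_regions <- function(regions, gff, feature_type = "gene") {
  if (is.character(gff)) {
    gr <- rtracklayer::import(gff)
  } else gr <- gff
  gr <- gr[as.character(gr$type) %in% feature_type]
  ids <- gene_ids_of(gr)
  if (!nrow(regions)) {
    regions$gene_ids <- character(0)
    regions$n_genes <- integer(0)
    attr(regions, "genes") <- character(0)
    return(regions)
  }
  q <- GenomicRanges::GRanges(
    regions$chrom,
    IRanges::IRanges(start = regions$start, end = regions$end - 1))
  hits <- GenomicRanges::findOverlaps(q, gr)
  gene_ids <- character(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    g <- unique(ids[S4Vectors::subjectHits(hits)[
      S4Vectors::queryHits(hits) == i]])
    gene_ids[i] <- paste(g, collapse = ",")
  }
  regions$gene_ids <- gene_ids
  regions$n_genes <- vapply(strsplit(gene_ids, ","), function(v)
    sum(nzchar(v)), integer(1))
  attr(regions, "genes") <-
    unique(ids[S4Vectors::subjectHits(hits)])
  regions
}

gene_ids_of <- function(gr) {
  md <- S4Vectors::mcols(gr)
  for (col in c("gene_id", "ID", "Name")) {
    if (col %in% names(md)) {
      v <- as.character(md[[col]])
      if (any(!is.na(v))) return(v)
    }
  }
  paste0("gene", seq_along(gr))
}

#' Write regions as BED
#'
#' BED is 0-based half-open; the half-open 1-based region `[start, end)`
#' maps to BED `start - 1`, `end - 1`.
#'
#' @param regions region data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  bed <- data.frame(chrom = regions$chrom,
                    start = as.integer(regions$start) - 1L,
                    end = as.integer(regions$end) - 1L,
                    name = sprintf("region_%d", seq_len(max(nrow(regions), 0))))
  if (!nrow(regions)) bed <- bed[0, ]
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
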