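#' Simulation configuration for a structured cohort
#'
#' Describes a star-shaped divergence of `n_pops` populations from a common
#' ancestral gene pool under the Balding-Nichols model: each site has an
#' ancestral alt-allele frequency `p ~ Beta(a, b)` (resampled until the minor
#' allele frequency reaches `maf_min`, emulating SNP-panel ascertainment),
#' and population `k` draws its own frequency from
#' `Beta(p (1 - F_k) / F_k, (1 - p) (1 - F_k) / F_k)`, so that the expected
#' differentiation between populations with divergence `F` equals `F` in the
#' Weir-Cockerham sense. Selective sweeps are injected as localized pushes of
#' the target population's frequencies toward fixation; a configurable
#' fraction of sites carries "artifact" INFO annotations that violate the
#' standard hard-filter thresholds.
#'
#' @param n_pops number of populations (>= 2).
#' @param samples_per_pop diploid samples per population (default 90, the
#'   cohort size per breed the pipeline is dimensioned for).
#' @param n_sites number of biallelic SNP sites.
#' @param chrom_length chromosome length in bp.
#' @param fst per-population divergence parameter F in [0, 1); recycled to
#'   `n_pops`.
#' @param ancestral_beta shape parameters (a, b) of the ancestral frequency
#'   Beta distribution.
#' @param maf_min ascertainment floor on the ancestral minor allele
#'   frequency (0 disables it).
#' @param missing_rate per-call missingness probability.
#' @param sweep_specs list of sweeps, each a list with elements `pop`
#'   (target population label), `start`, `end` (bp, inclusive interval) and
#'   `intensity` in (0, 1].
#' @param artifact_rate fraction of sites whose INFO values are drawn from
#'   the artifact component of `info_model`.
#' @param low_gq_rate per-call probability of a genotype quality below 20.
#' @param info_model as returned by [default_info_model()].
#' @param pop_names population labels (default pop1..popK).
#' @param chrom chromosome name.
#' @param seed integer seed; every randomized step derives from it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_pops = 3, samples_per_pop = 90, n_sites = 10000,
                       chrom_length = 1e7, fst = 0.05,
                       ancestral_beta = c(1, 1), maf_min = 0.05,
                       missing_rate = 0.02, sweep_specs = list(),
                       artifact_rate = 0, low_gq_rate = 0.02,
                       info_model = default_info_model(),
                       pop_names = paste0("pop", seq_len(n_pops)),
                       chrom = "chr1", seed = 1L) {
  stopifnot(n_pops >= 2, samples_per_pop >= 1, n_sites >= 1,
            chrom_length >= 1, length(ancestral_beta) == 2,
            all(ancestral_beta > 0))
  fst <- rep_len(fst, n_pops)
  if (any(fst < 0) || any(fst >= 1)) stop("fst must lie in [0, 1)")
  for (pr in c(missing_rate, artifact_rate, low_gq_rate, maf_min))
    if (pr < 0 || pr >= 1) stop("rates must lie in [0, 1)")
  if (length(pop_names) != n_pops) stop("need one name per population")
  iv <- lapply(sweep_specs, function(s) {
    stopifnot(all(c("pop", "start", "end", "intensity") %in% names(s)))
    if (!s$pop %in% pop_names) stop("sweep target '", s$pop, "' unknown")
    if (s$start < 1 || s$end > chrom_length || s$start > s$end)
      stop("sweep interval outside [1, chrom_length]")
    if (s$intensity <= 0 || s$intensity > 1)
      stop("sweep intensity must lie in (0, 1]")
    c(s$start, s$end)
  })
  if (length(iv) > 1) {
    m <- do.call(rbind, iv)
    m <- m[order(m[, 1]), , drop = FALSE]
    if (any(m[-1, 1] <= m[-nrow(m), 2])) stop("sweep intervals overlap")
  }
  structure(list(n_pops = n_pops, samples_per_pop = samples_per_pop,
                 n_sites = n_sites, chrom_length = chrom_length, fst = fst,
                 ancestral_beta = ancestral_beta, maf_min = maf_min,
                 missing_rate = missing_rate, sweep_specs = sweep_specs,
                 artifact_rate = artifact_rate, low_gq_rate = low_gq_rate,
                 info_model = info_model, pop_names = pop_names,
                 chrom = chrom, seed = as.integer(seed)),
            class = "sim_config")
}

#' Default INFO-field model for simulated sites
#'
#' Two labelled components. "Clean" sites draw every metric from a range that
#' strictly passes the standard GATK-style hard filter; "artifact" sites pick
#' one metric at random and draw it from beyond its threshold, so a hard
#' filter at the standard thresholds removes exactly the artifact set.
#'
#' @return list with `clean` and `artifact` range tables (min, max per metric).
#' @export
default_info_model <- function() {
  list(
    clean = list(QD = c(10, 35), FS = c(0, 20), MQ = c(50, 60),
                 SOR = c(0.5, 2.5), MQRankSum = c(-4, 4),
                 ReadPosRankSum = c(-4, 4)),
    artifact = list(QD = c(0, 1.99), FS = c(60.01, 200), MQ = c(20, 39.99),
                    SOR = c(3.01, 9), MQRankSum = c(-20, -12.51),
                    ReadPosRankSum = c(-15, -8.01))
  )
}

info_metrics <- c("QD", "FS", "MQ", "SOR", "MQRankSum", "ReadPosRankSum")

#' Draw per-site ancestral and population allele frequencies
#'
#' Balding-Nichols draws at every site for every population; `F = 0` is the
#' degenerate copy case (`p_k = p` exactly, no Beta draw). Sweep flags are
#' initialized to `FALSE`; [inject_sweep()] sets them.
#'
#' @param config a [sim_config()].
#' @return a `truth_table` data.frame: `chrom`, `pos`, `p_anc`, one `p_<pop>`
#'   column per population, one `sweep_<pop>` flag per population, `fst_used`,
#'   and `artifact`.
#' @export
draw_site_frequencies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$n_sites
  pos <- sort(sample.int(config$chrom_length, L, replace = FALSE))
  a <- config$ancestral_beta[1]; b <- config$ancestral_beta[2]
  p <- stats::rbeta(L, a, b)
  if (config$maf_min > 0) {
    for (it in 1:200) {
      bad <- pmin(p, 1 - p) < config$maf_min
      if (!any(bad)) break
      p[bad] <- stats::rbeta(sum(bad), a, b)
    }
    # clip stragglers rather than loop forever on extreme Beta shapes
    p <- pmin(pmax(p, config$maf_min), 1 - config$maf_min)
  }
  tt <- data.frame(chrom = config$chrom, pos = pos, p_anc = p)
  for (k in seq_len(config$n_pops)) {
    Fk <- config$fst[k]
    if (Fk == 0) {
      pk <- p
    } else {
      scale <- (1 - Fk) / Fk
      pk <- stats::rbeta(L, p * scale, (1 - p) * scale)
      # Beta draws can return exact 0/1 at tiny shapes; keep them (fixation
      # through drift is legitimate), but guard NaN from degenerate shapes
      pk[p == 0] <- 0; pk[p == 1] <- 1
    }
    tt[[paste0("p_", config$pop_names[k])]] <- pk
  }
  for (nm in config$pop_names) tt[[paste0("sweep_", nm)]] <- FALSE
  tt$fst_used <- rep(config$fst[1], L)  # per-site F of pop 1 for reference
  tt$artifact <- stats::runif(L) < config$artifact_rate
  class(tt) <- c("truth_table", "data.frame")
  tt
}

#' Inject a selective sweep into a truth table
#'
#' Inside the interval, the target population's allele frequencies are pushed
#' toward the nearest fixation boundary by the sweep intensity `s`:
#' `p' = p (1 - s)` for `p < 0.5` and `p' = p + s (1 - p)` otherwise. The
#' transform is monotone in `s`, the identity at `s = 0`, and full fixation
#' at `s = 1`; expected heterozygosity inside the interval drops in the
#' target population only.
#'
#' @param truth a `truth_table` from [draw_site_frequencies()].
#' @param spec a single sweep spec (list with `pop`, `start`, `end`,
#'   `intensity`).
#' @return the modified truth table.
#' @export
inject_sweep <- function(truth, spec) {
  col <- paste0("p_", spec$pop)
  if (!col %in% names(truth)) stop("unknown sweep target '", spec$pop, "'")
  inside <- truth$pos >= spec$start & truth$pos <= spec$end
  p <- truth[[col]][inside]
  s <- spec$intensity
  truth[[col]][inside] <- ifelse(p < 0.5, p * (1 - s), p + s * (1 - p))
  truth[[paste0("sweep_", spec$pop)]][inside] <- TRUE
  truth
}

#' Sample diploid genotypes from a truth table
#'
#' Each genotype is an independent `Binomial(2, p_k)` draw (Hardy-Weinberg
#' within populations), masked to missing at `missing_rate`. Per-call GQ and
#' per-site INFO values are drawn from the configured models.
#'
#' @param truth a `truth_table`.
#' @param config the [sim_config()] the truth table came from.
#' @return list with `geno` (a [geno_matrix()] carrying INFO columns and GQ)
#'   and `popmap` (sample-to-population data.frame).
#' @export
sample_genotypes <- function(truth, config) {
  set.seed(config$seed + 1L)
  L <- nrow(truth)
  n <- config$samples_per_pop
  K <- config$n_pops
  geno <- matrix(NA_integer_, nrow = n * K, ncol = L)
  samples <- character(n * K)
  for (k in seq_len(K)) {
    pk <- truth[[paste0("p_", config$pop_names[k])]]
    rows <- (k - 1L) * n + seq_len(n)
    geno[rows, ] <- matrix(stats::rbinom(n * L, 2L, rep(pk, each = n)),
                           nrow = n)
    samples[rows] <- sprintf("%s_%03d", config$pop_names[k], seq_len(n))
  }
  if (config$missing_rate > 0)
    geno[stats::runif(length(geno)) < config$missing_rate] <- NA_integer_
  rownames(geno) <- samples
  gq <- matrix(round(stats::runif(length(geno), 30, 99)), nrow = nrow(geno))
  low <- stats::runif(length(geno)) < config$low_gq_rate
  gq[low] <- round(stats::runif(sum(low), 2, 19))
  rownames(gq) <- samples

  info <- draw_info_fields(truth$artifact, config$info_model)
  alleles <- sample_alleles(L)
  sites <- data.frame(chrom = truth$chrom, pos = truth$pos,
                      ref = alleles$ref, alt = alleles$alt, info)
  list(geno = geno_matrix(geno, sites, gq = gq),
       popmap = data.frame(sample = samples,
                           pop = rep(config$pop_names, each = n)))
}

draw_info_fields <- function(artifact, model) {
  L <- length(artifact)
  out <- as.data.frame(lapply(info_metrics, function(m) {
    rg <- model$clean[[m]]
    stats::runif(L, rg[1], rg[2])
  }))
  names(out) <- info_metrics
  idx <- which(artifact)
  if (length(idx)) {
    which_metric <- sample(info_metrics, length(idx), replace = TRUE)
    for (m in info_metrics) {
      j <- idx[which_metric == m]
      rg <- model$artifact[[m]]
      out[[m]][j] <- stats::runif(length(j), rg[1], rg[2])
    }
  }
  round(out, 3)
}

sample_alleles <- function(L) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, L, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  list(ref = ref, alt = unname(alt))
}

#' Simulate a full cohort
#'
#' Runs [draw_site_frequencies()], applies every configured sweep with
#' [inject_sweep()], and samples genotypes. Deterministic given
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with `truth`, `geno` (a [geno_matrix()]), and `popmap`.
#' @export
simulate_cohort <- function(config) {
  truth <- draw_site_frequencies(config)
  for (s in config$sweep_specs) truth <- inject_sweep(truth, s)
  gm <- sample_genotypes(truth, config)
  list(truth = truth, geno = gm$geno, popmap = gm$popmap, config = config)
}

#' Write a truth table as TSV
#' @param truth a `truth_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Simulate linked genotypes with a founder-haplotype mosaic
#'
#' Generates one population whose haplotypes are mosaics of `n_founders`
#' founder haplotypes with per-base switch probability `recomb_rate`.
#' Linkage disequilibrium between nearby sites decays with distance at a
#' rate governed by `recomb_rate`, and its overall level by `n_founders`
#' (few founders = strong drift = high r2 that decays slowly) -- the knob
#' used to emulate fast- versus slow-decaying populations.
#'
#' @param n_samples diploid samples.
#' @param n_sites number of sites.
#' @param spacing_bp fixed distance between adjacent sites.
#' @param n_founders founder haplotype pool size (effective-size proxy).
#' @param recomb_rate per-bp probability of switching founder.
#' @param maf_min founder allele-frequency floor.
#' @param chrom chromosome name.
#' @param seed integer seed.
#' @return a [geno_matrix()] (no INFO/GQ annotations).
#' @export
simulate_ld_cohort <- function(n_samples = 60, n_sites = 200,
                               spacing_bp = 1000, n_founders = 20,
                               recomb_rate = 1e-5, maf_min = 0.1,
                               chrom = "chr1", seed = 1L) {
  set.seed(seed)
  pos <- seq_len(n_sites) * spacing_bp
  p <- stats::runif(n_sites, maf_min, 1 - maf_min)
  founders <- matrix(stats::rbinom(n_founders * n_sites, 1L,
                                   rep(p, each = n_founders)),
                     nrow = n_founders)
  p_switch <- 1 - (1 - recomb_rate)^spacing_bp
  hap <- matrix(0L, nrow = 2L * n_samples, ncol = n_sites)
  for (h in seq_len(2L * n_samples)) {
    f <- sample.int(n_founders, 1L)
    sw <- stats::runif(n_sites) < p_switch
    for (j in seq_len(n_sites)) {
      if (sw[j]) f <- sample.int(n_founders, 1L)
      hap[h, j] <- founders[f, j]
    }
  }
  geno <- hap[seq(1, 2 * n_samples, by = 2), ] +
    hap[seq(2, 2 * n_samples, by = 2), ]
  rownames(geno) <- sprintf("S%03d", seq_len(n_samples))
  sites <- data.frame(chrom = chrom, pos = pos,
                      ref = "A", alt = "G")
  geno_matrix(geno, sites)
}
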