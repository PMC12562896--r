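#' Default pipeline configuration
#'
#' Returns the full parameter set of [run_pipeline()] with its documented
#' defaults: hard-filter thresholds at the standard GATK-style values,
#' cluster rule "no more than 2 SNPs within 5 bp", indel proximity 5 bp,
#' GQ mask at 20; diversity on sites with call rate >= 0.8; LD decay to
#' 300 kb in 1 kb bins with MAF floor 0.05; 100 kb sweep windows with a
#' literal top-0.01% joint quantile.
#'
#' @return named list of parameters.
#' @export
pipeline_defaults <- function() {
  list(
    vcf = NULL, popmap = NULL, gff = NULL, chrom_lengths = NULL,
    out_dir = "popsweep_out", seed = 1L,
    filter = list(min_qd = 2.0, max_fs = 60.0, min_mq = 40.0, max_sor = 3.0,
                  min_mqranksum = -12.5, min_readposranksum = -8.0,
                  cluster_window = 5L, cluster_max = 2L, indel_dist = 5L,
                  min_gq = 20.0),
    diversity = list(maf_min = 0, callrate_min = 0.8),
    ld = list(max_dist_bp = 300000, bin_width_bp = 1000, maf_min = 0.05,
              method = "em"),
    structure = list(n_components = 10L, patterson = TRUE,
                     max_missing = 0.2, tree_on = "pop-means"),
    sweep = list(target = NULL, reference = NULL, window_size = 100000,
                 step = 100000, q_fst = 1e-4, q_ratio = 1e-4, min_snps = 3L,
                 gap_tolerance = 0, orientation = "ref_over_target",
                 pi_mode = "per_snp"),
    run = list(ld = TRUE, structure = TRUE, sweep = TRUE)
  )
}

# merge a user config (list or YAML path) over the defaults, rejecting
# unknown keys so typos cannot silently fall back to defaults
merge_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- pipeline_defaults()
  merge1 <- function(def, usr, path) {
    unknown <- setdiff(names(usr), names(def))
    if (length(unknown))
      stop("unknown config key(s): ",
           paste(paste0(path, unknown), collapse = ", "))
    for (k in names(usr)) {
      def[[k]] <- if (is.list(def[[k]]) && is.list(usr[[k]]))
        merge1(def[[k]], usr[[k]], paste0(path, k, ".")) else usr[[k]]
    }
    def
  }
  merge1(defaults, config, "")
}

read_chrom_lengths <- function(path) {
  cl <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "length"))
  stats::setNames(as.numeric(cl$length), as.character(cl$chrom))
}

#' Run the full analysis pipeline
#'
#' Reads a VCF and population map, applies the filter cascade, and produces
#' the diversity table with its comparison report, LD decay curves, PCA /
#' IBS / NJ structure outputs, and the FST x pi-ratio sweep scan with
#' region merging and (when a GFF3 is configured) gene annotation. Every
#' artifact is written under `out_dir` together with a run manifest
#' (version, configuration echo, input checksums, per-stage record counts).
#'
#' @param config a named list overriding [pipeline_defaults()], or the path
#'   to a YAML file of such overrides. `vcf` and `popmap` are required;
#'   `sweep$target` / `sweep$reference` default to the first two
#'   populations of the map.
#' @return the output directory path, invisibly; the manifest is also
#'   returned as attribute `manifest`.
#' @export
run_pipeline <- function(config) {
  cfg <- merge_config(if (is.list(config)) config else config)
  if (is.null(cfg$vcf) || is.null(cfg$popmap))
    stop("[config] 'vcf' and 'popmap' are required")
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  manifest <- list(tool = "popsweep",
                   version = as.character(utils::packageVersion("popsweep")),
                   config = cfg,
                   inputs = as.list(tools::md5sum(
                     stats::na.omit(c(cfg$vcf, cfg$popmap, cfg$gff)))),
                   stages = list())

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE))
  }

  popmap <- stage("read", read_popmap(cfg$popmap))
  g0 <- stage("read", read_vcf(cfg$vcf, popmap))
  manifest$stages$read <- attr(g0, "read_report")

  fl <- cfg$filter
  fr <- stage("filter", filter_variants(
    g0, thresholds = fl[c("min_qd", "max_fs", "min_mq", "max_sor",
                          "min_mqranksum", "min_readposranksum")],
    cluster_window = fl$cluster_window, cluster_max = fl$cluster_max,
    indel_dist = fl$indel_dist, min_gq = fl$min_gq))
  g <- fr$geno
  write_filter_report(fr$reports, file.path(out, "filter_report.json"))
  manifest$stages$filter <- list(sites_in = n_sites(g0),
                                 sites_out = n_sites(g))

  dt <- stage("diversity", diversity_table(
    g, popmap, maf_min = cfg$diversity$maf_min,
    callrate_min = cfg$diversity$callrate_min))
  utils::write.table(dt, file.path(out, "diversity_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  rep1 <- table1_report(dt)
  utils::write.table(rep1$comparisons,
                     file.path(out, "diversity_comparisons.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(table = dt, comparisons = rep1$comparisons,
                            extremes = rep1$extremes),
                       file.path(out, "diversity.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest$stages$diversity <- list(populations = nrow(dt),
                                    sites_used = attr(dt, "n_sites_used"))

  if (isTRUE(cfg$run$ld)) {
    ld <- stage("ld", decay_curve(
      g, popmap, max_dist_bp = cfg$ld$max_dist_bp,
      bin_width_bp = cfg$ld$bin_width_bp, maf_min = cfg$ld$maf_min,
      method = cfg$ld$method))
    utils::write.table(ld, file.path(out, "ld_decay.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    manifest$stages$ld <- list(bins = nrow(ld),
                               pairs = sum(ld$n_pairs))
  }

  if (isTRUE(cfg$run$structure)) {
    pc <- stage("structure", pca_genotypes(
      g, n_components = cfg$structure$n_components,
      patterson = cfg$structure$patterson,
      max_missing = cfg$structure$max_missing))
    utils::write.table(
      data.frame(sample = rownames(pc$scores),
                 pop = popmap$pop[match(rownames(pc$scores), popmap$sample)],
                 pc$scores),
      file.path(out, "pca_scores.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.table(
      data.frame(component = seq_along(pc$variance_explained),
                 variance_explained = pc$variance_explained),
      file.path(out, "pca_variance.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    d <- stage("structure", ibs_distance(g))
    utils::write.table(round(d, 6), file.path(out, "ibs_matrix.tsv"),
                       sep = "\t", quote = FALSE)
    dtree <- if (identical(cfg$structure$tree_on, "samples")) d
             else pop_mean_distance(d, popmap)
    if (nrow(dtree) >= 3) {
      tr <- stage("structure", nj_tree(dtree))
      write_newick(tr, file.path(out, "nj_tree.nwk"))
    }
    manifest$stages$structure <- list(pca_sites = pc$n_sites_used,
                                      samples = nrow(pc$scores))
  }

  if (isTRUE(cfg$run$sweep)) {
    sw <- cfg$sweep
    pops <- sort(unique(popmap$pop))
    target <- if (is.null(sw$target)) pops[1] else sw$target
    reference <- if (is.null(sw$reference)) pops[2] else sw$reference
    chrl <- if (!is.null(cfg$chrom_lengths))
      read_chrom_lengths(cfg$chrom_lengths) else NULL
    scan <- stage("sweep", sweep_scan(
      g, popmap, target = target, reference = reference,
      window_size = sw$window_size, step = sw$step, chrom_lengths = chrl,
      q_fst = sw$q_fst, q_ratio = sw$q_ratio, min_snps = sw$min_snps,
      gap_tolerance = sw$gap_tolerance, orientation = sw$orientation,
      pi_mode = sw$pi_mode))
    utils::write.table(scan$windows, file.path(out, "sweep_windows.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    regions <- scan$regions
    if (!is.null(cfg$gff))
      regions <- stage("sweep", annotate_regions(regions, cfg$gff))
    utils::write.table(regions, file.path(out, "sweep_regions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_regions_bed(regions, file.path(out, "sweep_regions.bed"))
    manifest$stages$sweep <- list(
      windows = nrow(scan$windows),
      selected = sum(scan$windows$selected, na.rm = TRUE),
      regions = nrow(regions),
      genes = if (!is.null(attr(regions, "genes")))
        length(attr(regions, "genes")) else NA)
  }

  manifest$wall_stamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  res <- out
  attr(res, "manifest") <- manifest
  invisible(res)
}
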