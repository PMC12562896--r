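#' Read a multi-sample VCF into a genotype matrix
#'
#' Loads biallelic SNP records as alt-allele dosages. Multiallelic records
#' and non-SNP records are excluded from the matrix; records carrying an
#' allele longer than one base are retained in the indel side list so the
#' indel-proximity filter can use them. Half-calls and `./.` are missing.
#'
#' @param path path to a VCF 4.x file (plain or bgzipped).
#' @param popmap optional population map data.frame (or path to one); when
#'   given, every VCF sample must appear in it and vice versa.
#' @return a [geno_matrix()] with INFO metric columns (`QD`, `FS`, `MQ`,
#'   `SOR`, `MQRankSum`, `ReadPosRankSum`; NA where absent), per-call GQ when
#'   present, and the indel side list. The exclusion tally is attached as
#'   attribute `read_report`.
#' @export
read_vcf <- function(path, popmap = NULL) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  n_rec <- nrow(fix)
  if (n_rec == 0) {
    n_samp <- max(ncol(vcf@gt) - 1L, 0L)
    gm <- geno_matrix(matrix(integer(), nrow = n_samp, ncol = 0),
                      data.frame(chrom = character(), pos = integer(),
                                 ref = character(), alt = character()))
    attr(gm, "read_report") <- list(records = 0, snps = 0, multiallelic = 0,
                                    indel_records = 0)
    return(gm)
  }
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  alt[is.na(alt)] <- "."
  multi <- grepl(",", alt, fixed = TRUE)
  alt_split <- strsplit(alt, ",", fixed = TRUE)
  has_indel_allele <- nchar(ref) > 1L |
    vapply(alt_split, function(a) any(nchar(a) > 1L), TRUE)
  snp <- !multi & nchar(ref) == 1L & nchar(alt) == 1L &
    alt %in% c("A", "C", "G", "T")
  indels <- data.frame(chrom = fix[has_indel_allele, "CHROM"],
                       pos = as.integer(fix[has_indel_allele, "POS"]))

  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1)
  gt <- gt[snp, , drop = FALSE]
  a1 <- substr(gt, 1, 1); a2 <- substr(gt, 3, 3)
  dos <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  ok <- (a1 == "0" | a1 == "1") & (a2 == "0" | a2 == "1")
  ok[is.na(ok)] <- FALSE
  dos[ok] <- (a1[ok] == "1") + (a2[ok] == "1")
  dimnames(dos) <- dimnames(gt)

  info <- as.data.frame(lapply(info_metrics, function(k)
    suppressWarnings(vcfR::extract.info(vcf, element = k,
                                        as.numeric = TRUE))[snp]))
  names(info) <- info_metrics

  gq <- NULL
  fmt <- vcf@gt[, 1]
  if (any(grepl("(^|:)GQ(:|$)", fmt))) {
    gq <- suppressWarnings(
      vcfR::extract.gt(vcf, element = "GQ", as.numeric = TRUE))
    if (is.null(dim(gq))) gq <- matrix(gq, nrow = 1)
    gq <- t(gq[snp, , drop = FALSE])
  }

  sites <- data.frame(chrom = fix[snp, "CHROM"],
                      pos = as.integer(fix[snp, "POS"]),
                      ref = ref[snp], alt = alt[snp], info)
  gm <- geno_matrix(t(dos), sites, gq = gq, indels = indels)
  if (!is.null(popmap)) {
    if (is.character(popmap)) popmap <- read_popmap(popmap)
    check_popmap(gm, popmap)
  }
  attr(gm, "read_report") <- list(records = n_rec, snps = sum(snp),
                                  multiallelic = sum(multi),
                                  indel_records = nrow(indels))
  gm
}

#' Write a genotype matrix as a VCF 4.2 text file
#'
#' Emits GT:GQ per sample (GQ omitted when the matrix has none) and the six
#' hard-filter INFO keys for every site where they are non-missing. Reading
#' the file back with [read_vcf()] reproduces the dosage matrix exactly.
#'
#' @param x a [geno_matrix()].
#' @param path output path.
#' @param chrom_lengths optional named vector of contig lengths for the
#'   header; defaults to the maximum position seen per chromosome.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path, chrom_lengths = NULL) {
  stopifnot(inherits(x, "geno_matrix"))
  sites <- x$sites
  chroms <- unique(sites$chrom)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(chroms, function(cc)
      if (any(sites$chrom == cc)) max(sites$pos[sites$chrom == cc]) else 1L,
      numeric(1))
  }
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(chrom_lengths),
                   as.integer(chrom_lengths)),
           sprintf(paste0("##INFO=<ID=%s,Number=1,Type=Float,",
                          "Description=\"Variant quality metric\">"),
                   info_metrics),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  has_gq <- !is.null(x$gq)
  if (has_gq)
    hdr <- c(hdr, paste0("##FORMAT=<ID=GQ,Number=1,Type=Integer,",
                         "Description=\"Genotype Quality\">"))
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", sample_ids(x)),
                      collapse = "\t"))
  L <- n_sites(x)
  info_str <- rep(".", L)
  if (L > 0) {
    have <- intersect(info_metrics, names(sites))
    if (length(have)) {
      parts <- vapply(have, function(k) {
        v <- sites[[k]]
        ifelse(is.na(v), NA_character_, sprintf("%s=%.6g", k, v))
      }, character(L))
      if (L == 1) parts <- matrix(parts, nrow = 1)
      info_str <- apply(parts, 1, function(r)
        if (all(is.na(r))) "." else paste(r[!is.na(r)], collapse = ";"))
    }
  }
  gt_codes <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = nrow(x$geno), ncol = L)
  nn <- !is.na(x$geno)
  gt[nn] <- gt_codes[x$geno[nn] + 1L]
  if (has_gq) {
    gqs <- matrix(".", nrow = nrow(x$geno), ncol = L)
    gg <- !is.na(x$gq)
    gqs[gg] <- formatC(x$gq[gg], format = "g")
    gt[] <- paste(gt, gqs, sep = ":")
  }
  body <- if (L > 0) {
    fields <- apply(gt, 2, paste, collapse = "\t")
    paste(sites$chrom, sites$pos, ".", sites$ref, sites$alt, ".", ".",
          info_str, if (has_gq) "GT:GQ" else "GT", fields, sep = "\t")
  } else character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a simulated cohort to disk
#'
#' Convenience wrapper producing `<prefix>.vcf`, `<prefix>.popmap.tsv` and
#' `<prefix>.truth.tsv` from a [simulate_cohort()] result.
#'
#' @param cohort result of [simulate_cohort()].
#' @param prefix output path prefix.
#' @return named character vector of the paths written.
#' @export
write_simulated_vcf <- function(cohort, prefix) {
  paths <- c(vcf = paste0(prefix, ".vcf"),
             popmap = paste0(prefix, ".popmap.tsv"),
             truth = paste0(prefix, ".truth.tsv"))
  write_vcf(cohort$geno, paths["vcf"],
            chrom_lengths = stats::setNames(cohort$config$chrom_length,
                                            cohort$config$chrom))
  write_popmap(cohort$popmap, paths["popmap"])
  write_truth_table(cohort$truth, paths["truth"])
  paths
}
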