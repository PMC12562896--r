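#' Genotype matrix container
#'
#' Holds diploid biallelic genotypes as alt-allele dosages (0/1/2, `NA` =
#' missing) for S samples by L sites, together with per-site metadata
#' (coordinates, alleles, INFO filter metrics), optional per-call genotype
#' qualities, and a side list of indel positions used by the indel-proximity
#' filter.
#'
#' @param geno integer matrix, samples x sites, values in \{0,1,2,NA\}.
#' @param sites data.frame with at least `chrom`, `pos`, `ref`, `alt`;
#'   optionally the INFO metric columns `QD`, `FS`, `MQ`, `SOR`, `MQRankSum`,
#'   `ReadPosRankSum` (NA where absent).
#' @param gq optional numeric matrix of per-call genotype qualities, same
#'   dimensions as `geno`.
#' @param indels optional data.frame with `chrom`, `pos` of indel records
#'   seen alongside the SNPs.
#' @return an object of class `geno_matrix`.
#' @export
geno_matrix <- function(geno, sites, gq = NULL, indels = NULL) {
  geno <- as.matrix(geno)
  stopifnot(is.data.frame(sites), all(c("chrom", "pos") %in% names(sites)))
  if (ncol(geno) != nrow(sites))
    stop("geno has ", ncol(geno), " sites but site table has ", nrow(sites))
  bad <- geno[!is.na(geno)]
  if (length(bad) && !all(bad %in% 0:2))
    stop("non-missing dosages must be 0, 1 or 2")
  if (!is.null(gq)) {
    gq <- as.matrix(gq)
    stopifnot(all(dim(gq) == dim(geno)))
  }
  if (is.null(indels)) indels <- data.frame(chrom = character(), pos = integer())
  if (is.null(rownames(geno))) rownames(geno) <- paste0("S", seq_len(nrow(geno)))
  ord <- order(sites$chrom, sites$pos)
  if (is.unsorted(ord)) {
    sites <- sites[ord, , drop = FALSE]
    geno <- geno[, ord, drop = FALSE]
    if (!is.null(gq)) gq <- gq[, ord, drop = FALSE]
  }
  rownames(sites) <- NULL
  structure(list(geno = geno, sites = sites, gq = gq, indels = indels),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix: ", nrow(x$geno), " samples x ", ncol(x$geno), " sites\n",
      sep = "")
  cat("  chromosomes: ", paste(unique(x$sites$chrom), collapse = ", "), "\n",
      sep = "")
  cat("  missing calls: ",
      format(mean(is.na(x$geno)), digits = 3), "\n", sep = "")
  if (!is.null(x$gq)) cat("  per-call GQ present\n")
  if (nrow(x$indels)) cat("  indel side list: ", nrow(x$indels), " records\n",
                          sep = "")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$geno)

#' Number of samples / sites
#' @param x a `geno_matrix`
#' @return integer count
#' @export
n_samples <- function(x) nrow(x$geno)

#' @rdname n_samples
#' @export
n_sites <- function(x) ncol(x$geno)

#' Sample identifiers of a genotype matrix
#' @param x a `geno_matrix`
#' @return character vector
#' @export
sample_ids <- function(x) rownames(x$geno)

# keep a subset of sites, preserving all parallel slots
subset_sites <- function(x, keep) {
  x$geno <- x$geno[, keep, drop = FALSE]
  x$sites <- x$sites[keep, , drop = FALSE]
  rownames(x$sites) <- NULL
  if (!is.null(x$gq)) x$gq <- x$gq[, keep, drop = FALSE]
  x
}

#' Read a sample-to-population map
#'
#' Two-column TSV (`sample_id<TAB>pop_label`), no header required; a header
#' line starting with `sample` is tolerated and skipped.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `sample`, `pop`.
#' @export
read_popmap <- function(path) {
  pm <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("sample", "pop"),
                          colClasses = "character")
  if (nrow(pm) && tolower(pm$sample[1]) %in% c("sample", "sample_id"))
    pm <- pm[-1, , drop = FALSE]
  if (anyDuplicated(pm$sample))
    stop("duplicate sample ids in population map")
  rownames(pm) <- NULL
  pm
}

#' Write a sample-to-population map
#' @param popmap data.frame with columns `sample`, `pop`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_popmap <- function(popmap, path) {
  utils::write.table(popmap[, c("sample", "pop")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# validate popmap against a geno_matrix; returns popmap reordered to samples
check_popmap <- function(x, popmap) {
  ids <- sample_ids(x)
  if (!all(ids %in% popmap$sample))
    stop("samples absent from population map: ",
         paste(utils::head(setdiff(ids, popmap$sample), 5), collapse = ", "))
  extra <- setdiff(popmap$sample, ids)
  if (length(extra))
    stop("population map lists samples not in the data: ",
         paste(utils::head(extra, 5), collapse = ", "))
  popmap[match(ids, popmap$sample), , drop = FALSE]
}
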