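#' Genotype principal component analysis
#'
#' Drops monomorphic and high-missingness sites, mean-imputes remaining
#' missing dosages per site, centers each site at twice its allele
#' frequency and (optionally, default) applies Patterson scaling by
#' `sqrt(2 p (1 - p))`, then eigendecomposes the sample covariance.
#'
#' @param x a [geno_matrix()].
#' @param n_components number of components to return scores for.
#' @param patterson apply the drift-variance scaling.
#' @param max_missing per-site missingness cap.
#' @return object of class `geno_pca`: list with `scores`
#'   (samples x components), `variance_explained` (fraction of total
#'   variance per retained component, non-increasing), `n_sites_used`.
#' @export
pca_genotypes <- function(x, n_components = 10L, patterson = TRUE,
                          max_missing = 0.2) {
  G <- x$geno
  miss <- colMeans(is.na(G))
  p <- colMeans(G, na.rm = TRUE) / 2
  keep <- !is.na(p) & p > 0 & p < 1 & miss <= max_missing
  G <- G[, keep, drop = FALSE]
  p <- p[keep]
  M <- sweep(G, 2, 2 * p)
  M[is.na(M)] <- 0  # missing dosage = column mean, i.e. 0 after centering
  if (patterson) M <- sweep(M, 2, sqrt(2 * p * (1 - p)), "/")
  sv <- svd(M, nu = min(n_components, dim(M)), nv = 0)
  ev <- sv$d^2
  k <- min(n_components, length(ev), ncol(sv$u))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], nrow = k)
  dimnames(scores) <- list(sample_ids(x), paste0("PC", seq_len(k)))
  structure(list(scores = scores,
                 variance_explained = ev[seq_len(k)] / sum(ev),
                 n_sites_used = sum(keep)),
            class = "geno_pca")
}

#' @export
print.geno_pca <- function(x, ...) {
  cat("geno_pca:", nrow(x$scores), "samples,", x$n_sites_used,
      "sites used\n")
  ve <- round(100 * x$variance_explained, 2)
  cat("  variance explained (%):", paste(utils::head(ve, 5), collapse = ", "),
      "\n")
  invisible(x)
}

#' Identity-by-state genetic distance matrix
#'
#' `d(i, j) = 1 - (sum of per-site shared alleles) / (2 * n_complete)` over
#' sites called in both samples; per-site sharing is `2 - |dosage_i -
#' dosage_j|`. Identical samples are at distance 0, opposite homozygotes at
#' every site at distance 1.
#'
#' @param x a [geno_matrix()].
#' @return symmetric numeric matrix with zero diagonal and sample-id
#'   dimnames.
#' @export
ibs_distance <- function(x) {
  G <- x$geno
  ind <- lapply(0:2, function(d) {
    m <- (G == d)
    m[is.na(m)] <- FALSE
    storage.mode(m) <- "numeric"
    m
  })
  M <- !is.na(G); storage.mode(M) <- "numeric"
  n_complete <- tcrossprod(M)
  absdiff <- tcrossprod(ind[[1]], ind[[2]]) + tcrossprod(ind[[2]], ind[[1]]) +
    tcrossprod(ind[[2]], ind[[3]]) + tcrossprod(ind[[3]], ind[[2]]) +
    2 * (tcrossprod(ind[[1]], ind[[3]]) + tcrossprod(ind[[3]], ind[[1]]))
  d <- ifelse(n_complete > 0, absdiff / (2 * n_complete), NA_real_)
  diag(d) <- 0
  dimnames(d) <- list(sample_ids(x), sample_ids(x))
  d
}

#' Average a sample distance matrix to population means
#'
#' Off-diagonal entries are the mean pairwise distance between (or within)
#' populations; the diagonal is set to zero so the result can seed a
#' population-level tree.
#'
#' @param d sample distance matrix.
#' @param popmap population map covering the matrix's samples.
#' @return pop x pop numeric matrix.
#' @export
pop_mean_distance <- function(d, popmap) {
  pops <- sort(unique(popmap$pop))
  pm <- popmap$pop[match(rownames(d), popmap$sample)]
  out <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)) for (j in seq_along(pops)) {
    if (i == j) next
    out[i, j] <- mean(d[pm == pops[i], pm == pops[j]])
  }
  out
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic Saitou-Nei agglomeration (via \pkg{ape}). Negative branch
#' lengths, which NJ can produce on noisy non-additive matrices, are
#' clamped to zero in the returned tree with the count recorded in the
#' `negative_branches` attribute.
#'
#' @param d symmetric distance matrix with dimnames.
#' @return an \pkg{ape} `phylo` object.
#' @export
nj_tree <- function(d) {
  stopifnot(nrow(d) >= 3)
  tr <- ape::nj(stats::as.dist(d))
  neg <- sum(tr$edge.length < 0)
  if (neg) tr$edge.length <- pmax(tr$edge.length, 0)
  attr(tr, "negative_branches") <- neg
  tr
}

#' Write a tree in Newick format
#' @param tree a `phylo` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
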