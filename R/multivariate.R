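## Ordination of codon-usage profiles: average-linkage (UPGMA) clustering
## with a similarity-scaled dendrogram, and correlation-matrix PCA with
## factor score coefficients.

#' Average-linkage hierarchical clustering of a feature matrix
#'
#' UPGMA over Euclidean distances; merge heights are also expressed as
#' similarities 100 * (1 - d / d_max) so the dendrogram can be read on a
#' similarity scale. The tree is serialised to Newick with branch lengths
#' derived from the merge heights.
#'
#' @param m numeric matrix, rows = entities (>= 2), columns = features; all
#'   values finite; rownames label the leaves.
#' @return list of class `scub_cluster`: `hclust`, `merge_heights`,
#'   `similarity`, `newick`.
#' @export
hierarchical_cluster <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2) stop("hierarchical_cluster: need at least 2 rows")
  if (any(!is.finite(m))) stop("hierarchical_cluster: non-finite values")
  if (is.null(rownames(m))) rownames(m) <- paste0("e", seq_len(nrow(m)))
  d <- stats::dist(m, method = "euclidean")
  hc <- stats::hclust(d, method = "average")
  d_max <- max(d)
  sim <- if (d_max > 0) 100 * (1 - hc$height / d_max) else rep(100, length(hc$height))
  newick <- ape::write.tree(ape::as.phylo(hc))
  structure(list(hclust = hc, merge_heights = hc$height,
                 similarity = sim, newick = newick),
            class = "scub_cluster")
}

#' @export
print.scub_cluster <- function(x, ...) {
  cat("<scub_cluster> ", length(x$hclust$labels), " leaves; merges at h = ",
      paste(signif(x$merge_heights, 4), collapse = ", "), "\n", sep = "")
  cat(x$newick, "\n")
  invisible(x)
}

#' Principal component analysis of a codon-usage feature matrix
#'
#' Eigendecomposition of the correlation matrix (default) or covariance
#' matrix. Reports eigenvalues, variance proportions, loadings, factor score
#' coefficients (eigenvector columns scaled by 1/sqrt(eigenvalue), the
#' standard weights mapping standardised features to unit-variance factor
#' scores) and entity scores on the leading components. Sign convention:
#' within each component the largest-magnitude loading is positive, so
#' results are comparable across linear-algebra backends.
#'
#' @param m numeric matrix, rows = entities (>= 2), columns = features (>= 2).
#' @param standardize use the correlation matrix (default TRUE); a constant
#'   column is an error when TRUE.
#' @param n_components number of leading components to report scores and
#'   coefficients for (default 3; truncated to components with positive
#'   eigenvalue).
#' @return list of class `scub_pca`: `eigenvalues`, `proportions`,
#'   `loadings`, `coefficients`, `scores`, `n_components`.
#' @export
pca_ordination <- function(m, standardize = TRUE, n_components = 3) {
  X <- as.matrix(m)
  if (nrow(X) < 2 || ncol(X) < 2) stop("pca_ordination: need >= 2 rows and columns")
  if (any(!is.finite(X))) stop("pca_ordination: non-finite values")
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  sds <- apply(X, 2, stats::sd)
  if (standardize && any(sds == 0)) {
    stop("pca_ordination: constant column(s) with standardize = TRUE: ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  }
  Z <- scale(X, center = TRUE, scale = standardize)
  C <- if (standardize) stats::cor(X) else stats::cov(X)
  e <- eigen(C, symmetric = TRUE)
  lambda <- pmax(e$values, 0)
  V <- e$vectors
  loadings <- V %*% diag(sqrt(lambda), nrow = length(lambda))
  # deterministic signs: largest |loading| positive per component
  for (k in seq_along(lambda)) {
    if (lambda[k] == 0) next
    j <- which.max(abs(loadings[, k]))
    if (loadings[j, k] < 0) {
      V[, k] <- -V[, k]
      loadings[, k] <- -loadings[, k]
    }
  }
  tol <- max(lambda) * 1e-10
  kmax <- min(n_components, sum(lambda > tol))
  ks <- seq_len(kmax)
  coef <- sweep(V[, ks, drop = FALSE], 2, sqrt(lambda[ks]), "/")
  scores <- Z %*% V[, ks, drop = FALSE]
  pcn <- paste0("PC", ks)
  dimnames(coef) <- list(colnames(X), pcn)
  dimnames(scores) <- list(rownames(X), pcn)
  dimnames(loadings) <- list(colnames(X), paste0("PC", seq_along(lambda)))
  structure(list(eigenvalues = lambda,
                 proportions = lambda / sum(lambda),
                 loadings = loadings,
                 coefficients = coef,
                 scores = scores,
                 n_components = kmax,
                 standardize = standardize),
            class = "scub_pca")
}

#' @export
print.scub_pca <- function(x, ...) {
  cat("<scub_pca> ", length(x$eigenvalues), " components; proportions: ",
      paste(signif(x$proportions[seq_len(min(3, length(x$proportions)))], 3),
            collapse = ", "), " ...\n", sep = "")
  invisible(x)
}

#' Assemble the species x 59-SC feature matrix for ordination
#'
#' @param tables named list of `codon_counts` (one per entity).
#' @param feature `"frequency"` (SC frequencies over the SC total) or
#'   `"rscu"`.
#' @return numeric matrix, rows = entities, columns = the 59 SCs in canonical
#'   order.
#' @export
sc_feature_matrix <- function(tables, feature = c("frequency", "rscu")) {
  feature <- match.arg(feature)
  rows <- lapply(tables, function(t) {
    switch(feature,
      frequency = codon_frequencies(t, "sc59"),
      rscu = rscu(t)
    )
  })
  m <- do.call(rbind, rows)
  rownames(m) <- names(tables)
  m[, SC_CODONS, drop = FALSE]
}
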