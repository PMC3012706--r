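#' Library-level principal component analysis
#'
#' PCA over the expression matrix with the study's conventions:
#' transcripts expressed (assigned count >= 1, equivalently RPKM > 0) in
#' fewer than `min_libraries` libraries are filtered out; each surviving
#' transcript's RPKM profile is standardized to zero mean and unit
#' variance across libraries; the eigen-decomposition is taken on the
#' library x library covariance of the standardized matrix (equivalent
#' to the transcript-variable formulation since standardization makes
#' covariance equal correlation, and far cheaper when transcripts vastly
#' outnumber libraries). Libraries receive component scores and
#' transcripts loadings. The sign of each component is fixed so that its
#' largest-magnitude transcript loading is positive.
#'
#' @param expr RPKM matrix, transcripts/units x libraries.
#' @param min_libraries Minimum number of libraries a transcript must be
#'   expressed in to enter the PCA (default 6 of the 12-library design).
#' @return List of class `"library_pca"`: `variance_fraction` (per
#'   component, sums to 1), `scores` (libraries x components),
#'   `loadings` (transcripts x components), `n_retained` (transcripts
#'   surviving the filters) and `sdev`.
#' @export
pca_libraries <- function(expr, min_libraries = 6) {
  if (ncol(expr) < 2) stop("need at least two libraries")
  keep <- rowSums(expr > 0) >= min_libraries
  x <- expr[keep, , drop = FALSE]
  # zero-variance transcripts cannot be standardized
  v <- apply(x, 1, stats::var)
  x <- x[v > 0, , drop = FALSE]
  if (nrow(x) < 2) stop("degenerate input: fewer than two transcripts survive filtering")
  z <- t(scale(t(x)))  # per-transcript zero mean, unit variance
  cov_ll <- crossprod(z) / (nrow(z) - 1)
  eig <- eigen(cov_ll, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  scores <- eig$vectors
  loadings <- z %*% scores
  # sign convention: largest-magnitude loading positive per component
  for (j in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  pcs <- paste0("PC", seq_along(ev))
  dimnames(scores) <- list(colnames(expr), pcs)
  dimnames(loadings) <- list(rownames(z), pcs)
  structure(list(variance_fraction = stats::setNames(ev / sum(ev), pcs),
                 scores = scores, loadings = loadings,
                 n_retained = nrow(z), sdev = sqrt(ev)),
            class = "library_pca")
}

#' @export
print.library_pca <- function(x, ...) {
  cat("Library PCA:", x$n_retained, "transcripts,",
      nrow(x$scores), "libraries\n")
  vf <- round(100 * x$variance_fraction[seq_len(min(4, length(x$variance_fraction)))], 1)
  cat("Variance explained (%):", paste(names(vf), vf, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write PCA results (scores, loadings, scree) as TSV files
#' @param pca A `"library_pca"` object.
#' @param dir Output directory.
#' @export
write_pca_tsv <- function(pca, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_matrix(pca$scores, file.path(dir, "pca_scores.tsv"))
  write_tsv_matrix(pca$loadings, file.path(dir, "pca_loadings.tsv"))
  utils::write.table(
    data.frame(component = names(pca$variance_fraction),
               variance_fraction = pca$variance_fraction),
    file.path(dir, "pca_scree.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
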