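#' TMM normalization and adjusted RPKM
#'
#' Between-library comparisons are distorted when a few very abundant
#' transcripts dominate one library's sequencing real estate (composition
#' bias). The trimmed mean of M-values (TMM; Robinson & Oshlack 2010)
#' estimates a relative-abundance scaling factor f per library against a
#' reference library. The effective library size is then
#' N_eff = N * sqrt(f), and RPKM values are computed against N_eff:
#' RPKM = count / ((length/1000) * (N_eff/1e6)). Cluster units are
#' expanded to member transcripts, each member inheriting the cluster's
#' count but normalized by its own length.
#'
#' @name normexpr
#' @keywords internal
NULL

#' TMM normalization factor of one library against a reference
#'
#' Direct implementation of the published weighted TMM estimator: units
#' with a zero count in either library are excluded; for the rest
#' M = log2((y_k/N_k)/(y_r/N_r)) and A = mean log2 relative abundance;
#' the M values are doubly trimmed (a fraction `logratio_trim` off each
#' tail of M and `abundance_trim` off each tail of A) and averaged with
#' inverse asymptotic-variance (delta-method) weights; the factor is
#' 2^weighted-mean. A library identical (or proportional) to the
#' reference gets f = 1.
#'
#' @param lib,ref Count vectors over the same counting units.
#' @param logratio_trim,abundance_trim Trim fractions per tail (defaults
#'   0.30 and 0.05, the published defaults).
#' @return Positive scalar normalization factor.
#' @export
tmm_factor <- function(lib, ref, logratio_trim = 0.30, abundance_trim = 0.05) {
  stopifnot(length(lib) == length(ref))
  lib <- as.numeric(lib); ref <- as.numeric(ref)
  Nk <- sum(lib); Nr <- sum(ref)
  if (Nk <= 0 || Nr <= 0) stop("library totals must be positive")
  keep <- lib > 0 & ref > 0
  yk <- lib[keep]; yr <- ref[keep]
  if (length(yk) == 0) stop("degenerate input: no units expressed in both libraries")
  M <- log2((yk / Nk) / (yr / Nr))
  A <- 0.5 * log2((yk / Nk) * (yr / Nr))
  w <- 1 / ((Nk - yk) / (Nk * yk) + (Nr - yr) / (Nr * yr))
  # all-M-equal shortcut (e.g. proportional libraries): factor is exact
  if (max(abs(M - M[1])) < 1e-10) return(2^M[1])
  # trim by value quantiles, bounds inclusive: robust to the massive M
  # ties that discrete counts produce (rank-based trimming can then
  # exclude everything), identical to rank trimming on continuous data
  qM <- stats::quantile(M, c(logratio_trim, 1 - logratio_trim), names = FALSE)
  qA <- stats::quantile(A, c(abundance_trim, 1 - abundance_trim), names = FALSE)
  keep2 <- M >= qM[1] & M <= qM[2] & A >= qA[1] & A <= qA[2]
  if (!any(keep2)) stop("degenerate input: no units survive trimming")
  f <- 2^(sum(w[keep2] * M[keep2]) / sum(w[keep2]))
  if (!is.finite(f) || f <= 0) stop("degenerate TMM factor")
  f
}

#' TMM factors for a whole count matrix
#'
#' Computes each library's factor against the chosen reference column and
#' renormalizes the factors so their log-mean is zero across libraries
#' (the published convention), recording both raw and renormalized values.
#'
#' @param counts Counting-unit x library matrix.
#' @param ref Reference library (column name or index); the study design
#'   here uses the solitary egg library as reference.
#' @param renormalize Rescale factors to log-mean zero (default TRUE).
#' @param ... Passed to [tmm_factor()].
#' @return data.frame with columns `library`, `N` (total assigned reads),
#'   `f` (normalization factor) and `N_eff` (effective size, see
#'   [effective_size()]); the reference row has raw factor 1.
#' @export
tmm_normalize <- function(counts, ref = 1, renormalize = TRUE, ...) {
  if (is.character(ref)) ref <- match(ref, colnames(counts))
  stopifnot(!is.na(ref), ref >= 1, ref <= ncol(counts))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref) 1 else tmm_factor(counts[, j], counts[, ref], ...)
  }, numeric(1))
  if (renormalize) f <- f / exp(mean(log(f)))
  N <- colSums(counts)
  data.frame(library = colnames(counts), N = N, f = f,
             N_eff = effective_size(N, f), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Effective library size
#'
#' N_eff = N * sqrt(f): the original library size scaled by the square
#' root of the TMM normalization factor.
#' @param N Original library size (assigned reads).
#' @param f TMM normalization factor.
#' @return Effective library size (vectorised).
#' @export
effective_size <- function(N, f) {
  if (any(N <= 0) || any(f <= 0)) stop("N and f must be positive")
  N * sqrt(f)
}

#' Adjusted RPKM matrix
#'
#' RPKM(t, lib) = count / ((length_t / 1000) * (N_eff_lib / 1e6)). When a
#' catalog is supplied, cluster units are expanded to their member
#' transcripts: each member inherits the unit's count and is normalized
#' by its own length.
#'
#' @param counts Counting-unit x library matrix (from [assign_reads()] or
#'   [simulate_counts()]).
#' @param lengths Named vector of transcript lengths in bp.
#' @param norm Normalization table from [tmm_normalize()]; pass `NULL` to
#'   use raw library sizes (f = 1).
#' @param clusters Optional cluster map; when given, rows are member
#'   transcripts rather than counting units.
#' @return Numeric matrix of RPKM values; zero exactly where the count is
#'   zero.
#' @export
rpkm_matrix <- function(counts, lengths, norm = NULL, clusters = NULL) {
  if (!is.null(clusters)) {
    lookup <- .cluster_lookup(clusters)
    members <- as.character(clusters$transcript)
    counts <- counts[lookup[members], , drop = FALSE]
    rownames(counts) <- members
  }
  if (is.null(norm)) {
    n_eff <- colSums(counts)
  } else {
    n_eff <- stats::setNames(norm$N_eff, norm$library)[colnames(counts)]
  }
  if (any(is.na(n_eff)) || any(n_eff <= 0)) stop("invalid effective sizes")
  len <- lengths[rownames(counts)]
  if (any(is.na(len))) stop("missing length for some counting units")
  if (any(len <= 0)) stop("lengths must be positive")
  rpkm <- sweep(counts / (len / 1000), 2, n_eff / 1e6, "/")
  storage.mode(rpkm) <- "double"
  rpkm
}

#' Write a normalization table or expression matrix as TSV
#' @param x data.frame or matrix with row names as the first column.
#' @param path Output TSV path.
#' @export
write_tsv_matrix <- function(x, path) {
  if (is.matrix(x)) x <- data.frame(id = rownames(x), x, check.names = FALSE)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
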