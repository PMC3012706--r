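#' Term enrichment against a whole-transcriptome background
#'
#' GOstat-style enrichment of a gene list: for each term, a 2x2 table of
#' list vs background-minus-list against in-term vs not-in-term is
#' tested. The p-value is approximated by the Pearson chi-square test
#' (1 df, no continuity correction); when any expected cell count falls
#' below 5 the two-sided Fisher exact test (point-mass method) is used
#' instead. Raw p-values are reported — the study convention flags terms
#' at p < 0.01 without cross-term correction; Benjamini-Hochberg
#' adjustment is available as an explicit option.
#'
#' @name enrich
#' @keywords internal
NULL

#' Test one 2x2 enrichment table
#'
#' Cells: `a` = list members annotated with the term, `b` = list members
#' without it, `c` = background-only genes with the term, `d` =
#' background-only genes without it.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return List with `p` (two-sided p-value), `test` ("chisq" or
#'   "fisher") and `min_expected` (smallest expected cell count).
#' @export
enrich_test <- function(a, b, c, d) {
  tab <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  if (any(tab < 0)) stop("cell counts must be non-negative")
  n <- sum(tab)
  if (n == 0) stop("undefined test: all-zero table")
  expected <- outer(rowSums(tab), colSums(tab)) / n
  if (min(expected) < 5) {
    p <- stats::fisher.test(tab)$p.value
    test <- "fisher"
  } else {
    p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
    if (is.nan(p)) p <- 1  # zero-variance margin: no contrast
    test <- "chisq"
  }
  list(p = min(p, 1), test = test, min_expected = min(expected))
}

#' Scan all terms for enrichment in a gene list
#'
#' @param gene_list Character vector of gene/unit ids (must be a subset
#'   of `background`).
#' @param annotation data.frame with columns `gene` and `term` (one pair
#'   per line; GO- or KEGG-style ids treated as opaque strings).
#' @param background Character vector: the whole transcriptome set.
#' @param alpha Reporting threshold on the raw p-value (default 0.01).
#' @param adjust If TRUE, add a Benjamini-Hochberg `q` column (the
#'   `enriched` flag still uses the raw p, as in the study convention).
#' @return data.frame, one row per term with at least one background
#'   member: counts `a`,`b`,`c`,`d`, `expected` (expected a under
#'   independence), `test`, `p`, `direction` ("over"/"under") and
#'   `enriched` (p < alpha and over-represented).
#' @export
enrich_scan <- function(gene_list, annotation, background, alpha = 0.01,
                        adjust = FALSE) {
  gene_list <- unique(as.character(gene_list))
  background <- unique(as.character(background))
  if (!all(gene_list %in% background))
    stop("gene list contains ids absent from the background")
  ann <- annotation[as.character(annotation$gene) %in% background, , drop = FALSE]
  terms <- split(as.character(ann$gene), as.character(ann$term))
  n_list <- length(gene_list)
  n_bg_only <- length(background) - n_list
  rows <- lapply(names(terms), function(tm) {
    members <- unique(terms[[tm]])
    a <- sum(members %in% gene_list)
    b <- n_list - a
    c_ <- length(members) - a
    d <- n_bg_only - c_
    res <- enrich_test(a, b, c_, d)
    expected_a <- n_list * length(members) / (n_list + n_bg_only)
    data.frame(term = tm, a = a, b = b, c = c_, d = d,
               expected = expected_a, test = res$test, p = res$p,
               direction = if (a >= expected_a) "over" else "under",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(term = character(0), a = integer(0), b = integer(0),
                      c = integer(0), d = integer(0), expected = numeric(0),
                      test = character(0), p = numeric(0),
                      direction = character(0), stringsAsFactors = FALSE)
  if (adjust) out$q <- bh_fdr(out$p)
  out$enriched <- out$p < alpha & out$direction == "over"
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a gene-term annotation map (TSV: gene_id, term_id per line)
#' @param path TSV path (header optional).
#' @return data.frame with columns `gene` and `term`.
#' @export
read_annotation_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  header <- grepl("gene", first, fixed = TRUE)
  d <- utils::read.table(path, sep = "\t", header = header,
                         stringsAsFactors = FALSE)
  stats::setNames(d[, 1:2], c("gene", "term"))
}
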