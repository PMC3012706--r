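#' Assembly quality metrics
#'
#' Length statistics (bins, mean/median, N50), reference-coverage
#' evaluation against an independent sequence set (e.g. Sanger ESTs or
#' full-length cDNAs), and chimera flagging from protein-hit tables.
#'
#' @name asmqc
#' @keywords internal
NULL

#' Length statistics of an assembly
#'
#' N50 is the length of the sequence at which the descending cumulative
#' length first reaches at least half the total. Bins follow the
#' assembly report convention of mutually exclusive rows 100-500,
#' 500-1000, 1000-2000 and >= 2000 bp (half-open on the right); the
#' assembler's minimum reported length is 100 bp, and any shorter input
#' is counted in the first bin so the bins always sum to the total.
#'
#' @param lengths Vector of sequence lengths in bp (all >= 1).
#' @return List of class `"assembly_stats"`: `n`, `total`, `mean`,
#'   `median`, `min`, `max`, `n50` and `bins` (named counts).
#' @export
length_stats <- function(lengths) {
  if (length(lengths) == 0) stop("empty length list")
  if (any(lengths < 1)) stop("lengths must be >= 1")
  sorted <- sort(lengths, decreasing = TRUE)
  n50 <- sorted[which(cumsum(sorted) >= sum(sorted) / 2)[1]]
  bins <- c("100-500" = sum(lengths < 500),
            "500-1000" = sum(lengths >= 500 & lengths < 1000),
            "1000-2000" = sum(lengths >= 1000 & lengths < 2000),
            ">=2000" = sum(lengths >= 2000))
  structure(list(n = length(lengths), total = sum(lengths),
                 mean = mean(lengths), median = stats::median(lengths),
                 min = min(lengths), max = max(lengths),
                 n50 = n50, bins = bins),
            class = "assembly_stats")
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat(sprintf("%d sequences, %.0f bp total; mean %.1f, median %.1f, N50 %d\n",
              x$n, x$total, x$mean, x$median, x$n50))
  print(x$bins)
  invisible(x)
}

#' Coverage evaluation against reference sequences
#'
#' Per reference: the fraction of bases covered at depth >= `min_depth`
#' by the supplied alignment intervals, a qualifying flag
#' (covered fraction strictly greater than `min_cov`), and a pooled
#' mismatch rate = total mismatches within covered regions / total
#' covered bases (covered = depth >= 1; the depth threshold applies to
#' the qualifying fraction only). Intervals are 1-based inclusive.
#'
#' @param intervals data.frame with columns `ref`, `start`, `end` and
#'   optionally `mismatches` (per-alignment mismatch count).
#' @param ref_lengths Named vector of reference lengths in bp.
#' @param min_depth Depth threshold for the coverage fraction
#'   (default 2, "at least 2X").
#' @param min_cov Strict qualifying threshold on the covered fraction
#'   (default 0.9).
#' @return List of class `"coverage_report"`: `per_ref` (data.frame with
#'   `ref`, `covered_fraction`, `qualifies`), `mismatch_rate` and the
#'   thresholds used.
#' @export
coverage_eval <- function(intervals, ref_lengths, min_depth = 2,
                          min_cov = 0.9) {
  stopifnot(all(c("ref", "start", "end") %in% names(intervals)))
  refs <- names(ref_lengths)
  if (!all(as.character(intervals$ref) %in% refs))
    stop("intervals reference unknown sequences")
  if (any(intervals$start < 1) ||
      any(intervals$end > ref_lengths[as.character(intervals$ref)]))
    stop("interval out of reference bounds")
  mm <- if ("mismatches" %in% names(intervals)) intervals$mismatches else
    rep(0, nrow(intervals))
  covered_fraction <- stats::setNames(numeric(length(refs)), refs)
  total_covered <- 0; total_mm <- 0
  by_ref <- split(seq_len(nrow(intervals)), as.character(intervals$ref))
  for (r in refs) {
    idx <- by_ref[[r]]
    if (is.null(idx)) next
    ir <- IRanges::IRanges(start = intervals$start[idx],
                           end = intervals$end[idx])
    depth <- IRanges::coverage(ir, width = ref_lengths[[r]])
    covered_fraction[r] <- sum(depth >= min_depth) / ref_lengths[[r]]
    total_covered <- total_covered + sum(depth >= 1)
    total_mm <- total_mm + sum(mm[idx])
  }
  mismatch_rate <- if (total_covered > 0) total_mm / total_covered else NA_real_
  structure(list(
    per_ref = data.frame(ref = refs,
                         covered_fraction = unname(covered_fraction),
                         qualifies = unname(covered_fraction > min_cov),
                         row.names = NULL, stringsAsFactors = FALSE),
    mismatch_rate = mismatch_rate,
    min_depth = min_depth, min_cov = min_cov),
    class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("%d references; %d qualify (> %.0f%% covered at >= %dX); mismatch rate %.5f\n",
              nrow(x$per_ref), sum(x$per_ref$qualifies), 100 * x$min_cov,
              x$min_depth, x$mismatch_rate))
  invisible(x)
}

#' Flag candidate chimeric sequences from protein hits
#'
#' A sequence is flagged when at least two distinct subject proteins
#' each pass all three thresholds (identity > 0.3, e-value < 1e-10,
#' score > 200); no positional condition is imposed on the query.
#'
#' @param hits data.frame with columns `query`, `subject`, `identity`
#'   (fraction), `evalue`, `score`.
#' @param min_identity,max_evalue,min_score Strict thresholds.
#' @return Character vector of flagged query ids (possibly empty).
#' @export
chimera_flags <- function(hits, min_identity = 0.3, max_evalue = 1e-10,
                          min_score = 200) {
  if (is.null(hits) || nrow(hits) == 0) return(character(0))
  ok <- hits$identity > min_identity & hits$evalue < max_evalue &
    hits$score > min_score
  h <- hits[ok, , drop = FALSE]
  if (nrow(h) == 0) return(character(0))
  n_subj <- tapply(as.character(h$subject), as.character(h$query),
                   function(s) length(unique(s)))
  sort(names(n_subj)[n_subj >= 2])
}

#' Read alignment intervals for coverage evaluation (TSV: ref, start,
#' end, mismatches)
#' @param path TSV path (header optional).
#' @return data.frame with columns ref, start, end, mismatches.
#' @export
read_intervals_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  header <- grepl("ref", first, fixed = TRUE)
  d <- utils::read.table(path, sep = "\t", header = header,
                         stringsAsFactors = FALSE)
  stats::setNames(d[, 1:4], c("ref", "start", "end", "mismatches"))
}
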