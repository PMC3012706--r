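#' Sequence clustering from pairwise similarity matches
#'
#' A de novo transcriptome carries unresolved isoforms and recent paralogs as
#' separate contigs. Before quantification these are grouped into sequence
#' clusters by a self-to-self similarity search: two transcripts are linked
#' when their match overlaps most of the shorter sequence at high identity,
#' and clusters are the connected components of that link graph ("overlap to
#' any sequence" = single linkage). Two threshold presets are used:
#' gene-set deduplication (overlap ratio > 0.60, identity > 0.96) and
#' expression clustering (overlap ratio > 0.80, identity > 0.96). The
#' longest member represents a cluster; its id is used as the cluster id.
#'
#' @name seqcluster
#' @keywords internal
NULL

#' Overlap ratio of a pairwise match
#'
#' Ratio of the aligned overlap length to the length of the shorter of the
#' two sequences, so a short isoform fully contained in a longer one scores
#' near 1. Set `denominator = "longer"` for the stricter alternative.
#'
#' @param overlap Aligned overlap length in bp (vectorised).
#' @param len_query,len_subject Lengths of the two sequences in bp.
#' @param denominator `"shorter"` (default) or `"longer"`.
#' @return Numeric vector of overlap ratios in \[0, 1\].
#' @examples
#' overlap_ratio(300, 500, 800) # 0.6
#' @export
overlap_ratio <- function(overlap, len_query, len_subject,
                          denominator = c("shorter", "longer")) {
  denominator <- match.arg(denominator)
  if (any(len_query <= 0) || any(len_subject <= 0))
    stop("sequence lengths must be positive")
  if (any(overlap < 0))
    stop("overlap length must be non-negative")
  denom <- if (denominator == "shorter") pmin(len_query, len_subject)
           else pmax(len_query, len_subject)
  if (any(overlap > pmin(len_query, len_subject)))
    stop("inconsistent match record: overlap exceeds the shorter sequence")
  overlap / denom
}

#' Build sequence clusters from match records
#'
#' Edges are matches whose overlap ratio and identity both strictly exceed
#' their thresholds; clusters are connected components of the resulting
#' graph; every transcript without a qualifying match is a singleton. The
#' representative of a cluster is its longest member (ties broken by the
#' lexicographically smallest id) and doubles as the cluster id.
#'
#' @param matches A data.frame with columns `query`, `subject`,
#'   `overlap` (bp) and `identity` (fraction), as read by
#'   [read_match_tsv()] or [read_blast_tab()]. May have zero rows.
#' @param catalog A transcript catalog: data.frame with columns
#'   `transcript` and `length` (bp).
#' @param min_overlap,min_identity Strict lower thresholds; the presets are
#'   `cluster_presets$dedup` (0.60, 0.96) and
#'   `cluster_presets$expression` (0.80, 0.96, the default).
#' @param denominator Passed to [overlap_ratio()].
#' @return A cluster map: data.frame with columns `transcript`,
#'   `cluster` (the representative's id) and `representative` (logical).
#' @export
build_clusters <- function(matches, catalog,
                           min_overlap = 0.80, min_identity = 0.96,
                           denominator = "shorter") {
  stopifnot(is.data.frame(catalog), all(c("transcript", "length") %in% names(catalog)))
  if (min_overlap <= 0 || min_overlap > 1 || min_identity <= 0 || min_identity > 1)
    stop("thresholds must lie in (0, 1]")
  ids <- as.character(catalog$transcript)
  if (anyDuplicated(ids)) stop("duplicate transcript ids in catalog")
  len <- stats::setNames(as.numeric(catalog$length), ids)

  edges <- matrix(character(0), ncol = 2)
  if (!is.null(matches) && nrow(matches) > 0) {
    q <- as.character(matches$query)
    s <- as.character(matches$subject)
    unknown <- setdiff(c(q, s), ids)
    if (length(unknown) > 0)
      stop("match records reference transcripts absent from catalog: ",
           paste(utils::head(unknown, 5), collapse = ", "))
    self <- q == s
    q <- q[!self]; s <- s[!self]
    ov <- as.numeric(matches$overlap)[!self]
    idt <- as.numeric(matches$identity)[!self]
    if (length(q) > 0) {
      # any single record passing both thresholds links the pair;
      # asymmetric duplicates (A-B / B-A) then collapse to one edge
      ratio <- overlap_ratio(ov, len[q], len[s], denominator = denominator)
      keep <- ratio > min_overlap & idt > min_identity
      q <- q[keep]; s <- s[keep]
      key <- ifelse(q < s, paste(q, s, sep = "\r"), paste(s, q, sep = "\r"))
      first <- !duplicated(key)
      edges <- cbind(q[first], s[first])
    }
  }

  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2]),
    directed = FALSE, vertices = data.frame(name = ids))
  comp <- igraph::components(g)$membership[ids]

  # representative: longest member, ties to smallest id
  ord <- order(comp, -len[ids], ids)
  first <- !duplicated(comp[ord])
  rep_of <- stats::setNames(ids[ord][first], comp[ord][first])
  cluster <- unname(rep_of[as.character(comp)])
  data.frame(transcript = ids, cluster = cluster,
             representative = ids == cluster, stringsAsFactors = FALSE)
}

#' Threshold presets for clustering
#'
#' `dedup` collapses alternative-splicing/redundancy for gene-set building;
#' `expression` is the stricter preset used before read counting.
#' @export
cluster_presets <- list(
  dedup = list(min_overlap = 0.60, min_identity = 0.96),
  expression = list(min_overlap = 0.80, min_identity = 0.96)
)

#' Read a minimal 4-column match table (query, subject, overlap_bp, identity)
#' @param path TSV path, with or without a header line.
#' @return data.frame with columns query, subject, overlap, identity.
#' @export
read_match_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  header <- grepl("query", first, fixed = TRUE)
  d <- utils::read.table(path, sep = "\t", header = header,
                         stringsAsFactors = FALSE)
  names(d) <- c("query", "subject", "overlap", "identity")
  d$overlap <- as.numeric(d$overlap)
  d$identity <- as.numeric(d$identity)
  d
}

#' Read BLAST tabular output (outfmt 6) as match records
#'
#' Uses qseqid, sseqid, pident (percent, converted to a fraction) and
#' length (alignment length, used as the overlap in bp).
#' @param path Path to a BLAST `-outfmt 6` file.
#' @return data.frame with columns query, subject, overlap, identity.
#' @export
read_blast_tab <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  data.frame(query = as.character(d[[1]]), subject = as.character(d[[2]]),
             overlap = as.numeric(d[[4]]), identity = as.numeric(d[[3]]) / 100,
             stringsAsFactors = FALSE)
}

#' Write / read a cluster map as 3-column TSV
#' @param clusters Cluster map from [build_clusters()].
#' @param path Output TSV path.
#' @export
write_cluster_map <- function(clusters, path) {
  utils::write.table(clusters, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_cluster_map
#' @export
read_cluster_map <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  d$representative <- as.logical(d$representative)
  d
}

# internal: transcript -> cluster-id lookup vector
.cluster_lookup <- function(clusters) {
  stats::setNames(as.character(clusters$cluster),
                  as.character(clusters$transcript))
}

# internal: all-singleton cluster map for a catalog
singleton_clusters <- function(catalog) {
  ids <- as.character(catalog$transcript)
  data.frame(transcript = ids, cluster = ids, representative = TRUE,
             stringsAsFactors = FALSE)
}
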