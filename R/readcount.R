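#' Cluster-aware read counting
#'
#' Without a reference genome, multi-mapping reads cannot be resolved by
#' position, and discarding them under-counts genes assembled as several
#' isoform/paralog contigs. The counting rule used here: a read whose hits
#' all fall inside one sequence cluster is counted once for that cluster
#' unit (a singleton transcript is its own unit); a read whose hits span
#' two or more units is discarded. Each read contributes at most one count
#' and the per-library total mapped reads N counts assigned reads only.
#'
#' Alignments are held in long ("one row per hit") form: a data.frame with
#' columns `read`, `library`, `lane`, `transcript` and, when available for
#' QC reuse, `mismatches`, `start`, `end`.
#'
#' @name readcount
#' @keywords internal
NULL

#' Assign reads to counting units
#'
#' @param alignments Long-form alignment records (see [readcount]); every
#'   read must have at least one hit row.
#' @param clusters Cluster map from [build_clusters()]; every hit
#'   transcript must appear in it. With an all-singleton map this reduces
#'   to classical uniquely-mapped-read counting.
#' @return A list with `counts` (integer matrix, counting units x
#'   libraries, covering every unit in `clusters`), `N` (named vector of
#'   assigned reads per library) and `discarded` (reads dropped per
#'   library because their hits spanned more than one unit).
#' @export
assign_reads <- function(alignments, clusters) {
  al <- data.table::as.data.table(alignments)
  stopifnot(all(c("read", "library", "transcript") %in% names(al)))
  lookup <- .cluster_lookup(clusters)
  units <- sort(unique(as.character(clusters$cluster)))
  libs <- sort(unique(as.character(al$library)))
  counts <- matrix(0L, nrow = length(units), ncol = length(libs),
                   dimnames = list(units, libs))
  if (nrow(al) == 0)
    return(list(counts = counts,
                N = stats::setNames(integer(length(libs)), libs),
                discarded = stats::setNames(integer(length(libs)), libs)))
  unknown <- !(as.character(al$transcript) %in% names(lookup))
  if (any(unknown))
    stop("alignment hits reference transcripts absent from the cluster map: ",
         paste(utils::head(unique(al$transcript[unknown]), 5), collapse = ", "))
  al[, unit := lookup[as.character(transcript)]]
  per_read <- al[, .(n_units = data.table::uniqueN(unit), unit = unit[1L]),
                 by = .(library, read)]
  kept <- per_read[n_units == 1L]
  tab <- kept[, .N, by = .(unit, library)]
  counts[cbind(match(tab$unit, units), match(as.character(tab$library), libs))] <-
    as.integer(tab$N)
  disc <- per_read[, .(d = sum(n_units > 1L)), by = library]
  discarded <- stats::setNames(integer(length(libs)), libs)
  discarded[as.character(disc$library)] <- as.integer(disc$d)
  list(counts = counts, N = colSums(counts), discarded = discarded)
}

#' Lane-detection counts per unit
#'
#' For each counting unit and library, the number of sequencing lanes in
#' which at least one read was assigned to the unit (same assignment rule
#' as [assign_reads()]). Used to summarise how reproducibly a transcript
#' is detected across lanes (detected in all / some / one).
#'
#' @inheritParams assign_reads
#' @return data.frame with columns `unit`, `library`, `lanes_detected`;
#'   units with zero assigned reads report 0 for every library present.
#' @export
detection_by_lanes <- function(alignments, clusters) {
  al <- data.table::as.data.table(alignments)
  units <- sort(unique(as.character(clusters$cluster)))
  if (nrow(al) == 0)
    return(data.frame(unit = character(0), library = character(0),
                      lanes_detected = integer(0)))
  stopifnot("lane" %in% names(al))
  lookup <- .cluster_lookup(clusters)
  al[, unit := lookup[as.character(transcript)]]
  per_read <- al[, .(n_units = data.table::uniqueN(unit), unit = unit[1L],
                     lane = lane[1L]), by = .(library, read)]
  kept <- per_read[n_units == 1L]
  det <- kept[, .(lanes_detected = data.table::uniqueN(lane)),
              by = .(unit, library)]
  libs <- sort(unique(as.character(al$library)))
  full <- data.table::CJ(unit = units, library = libs)
  out <- merge(full, det, by = c("unit", "library"), all.x = TRUE)
  out[is.na(lanes_detected), lanes_detected := 0L]
  as.data.frame(out)
}

#' Summarise lane-detection counts
#'
#' @param detection Output of [detection_by_lanes()].
#' @param n_lanes Total number of lanes per library.
#' @return data.frame per library with counts of units detected in all
#'   lanes, in more than one but not all (`some`), in exactly one, and in
#'   none.
#' @export
lane_detection_summary <- function(detection, n_lanes) {
  split_det <- split(detection$lanes_detected, detection$library)
  out <- lapply(split_det, function(d) {
    data.frame(all = sum(d == n_lanes & n_lanes > 0),
               some = sum(d > 1 & d < n_lanes),
               one = sum(d == 1), none = sum(d == 0))
  })
  cbind(library = names(out), do.call(rbind, out), row.names = NULL)
}

#' Down-sample a deep paired-end library to one lane
#'
#' Deep paired-end libraries are reduced for cross-library comparisons by
#' keeping a single randomly selected lane (reads treated as single-end).
#'
#' @param alignments Long-form alignment records.
#' @param libraries Library ids to down-sample; others pass through.
#' @param seed Integer seed controlling the lane choice.
#' @return Filtered alignment records.
#' @export
downsample_to_lane <- function(alignments, libraries, seed = 1L) {
  al <- data.table::as.data.table(alignments)
  set.seed(seed)
  keep <- rep(TRUE, nrow(al))
  for (lib in libraries) {
    lanes <- sort(unique(al$lane[al$library == lib]))
    chosen <- lanes[sample.int(length(lanes), 1L)]
    keep <- keep & (al$library != lib | al$lane == chosen)
  }
  as.data.frame(al[keep])
}

#' Write / read a count table as TSV with per-library totals
#'
#' The header carries one `#total_mapped <library> <N>` comment line per
#' library so that N (assigned reads) survives the round trip even if the
#' matrix is later subset.
#' @param assigned Output of [assign_reads()], or a bare counts matrix.
#' @param path TSV path.
#' @export
write_count_table <- function(assigned, path) {
  if (is.matrix(assigned)) assigned <- list(counts = assigned, N = colSums(assigned))
  con <- file(path, "w")
  on.exit(close(con))
  for (lib in colnames(assigned$counts))
    writeLines(sprintf("#total_mapped\t%s\t%d", lib,
                       as.integer(assigned$N[[lib]])), con)
  utils::write.table(data.frame(unit = rownames(assigned$counts),
                                assigned$counts, check.names = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#total_mapped", lines, value = TRUE)
  body <- utils::read.table(text = lines[!startsWith(lines, "#")],
                            sep = "\t", header = TRUE, check.names = FALSE,
                            stringsAsFactors = FALSE)
  counts <- as.matrix(body[, -1, drop = FALSE])
  rownames(counts) <- as.character(body[[1]])
  storage.mode(counts) <- "integer"
  N <- colSums(counts)
  if (length(hdr) > 0) {
    parts <- do.call(rbind, strsplit(hdr, "\t", fixed = TRUE))
    N[parts[, 2]] <- as.numeric(parts[, 3])
  }
  list(counts = counts, N = N)
}

#' Read alignments from the tabular dialect
#'
#' One line per read: `read_id TAB library TAB lane TAB hit1,hit2,...`,
#' expanded to the long one-row-per-hit form used throughout.
#' @param path TSV path (header optional).
#' @return Long-form alignment data.frame.
#' @export
read_alignments_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  header <- grepl("read", first, fixed = TRUE)
  d <- utils::read.table(path, sep = "\t", header = header,
                         stringsAsFactors = FALSE,
                         col.names = c("read", "library", "lane", "hits"))
  hits <- strsplit(as.character(d$hits), ",", fixed = TRUE)
  n <- lengths(hits)
  if (any(n == 0)) stop("alignment record with no hits")
  data.frame(read = rep(as.character(d$read), n),
             library = rep(as.character(d$library), n),
             lane = rep(as.character(d$lane), n),
             transcript = unlist(hits), stringsAsFactors = FALSE)
}

#' @rdname read_alignments_tsv
#' @param alignments Long-form alignment records.
#' @export
write_alignments_tsv <- function(alignments, path) {
  al <- data.table::as.data.table(alignments)
  rec <- al[, .(lane = lane[1L], hits = paste(transcript, collapse = ",")),
            by = .(read, library)]
  utils::write.table(rec[, .(read, library, lane, hits)], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read alignments from a SAM file
#'
#' Mapped records only; multi-hit reads must be reported as one line per
#' hit (secondary alignments included). Library and lane are taken from
#' the read-group tag `RG:Z:library.lane` when present, else from
#' `library`/`lane` arguments.
#' @param path Uncompressed SAM path.
#' @param library,lane Fallback identifiers when no RG tag is present.
#' @return Long-form alignment data.frame (with `mismatches` from `NM:i:`
#'   tags and `start`/`end` from POS and the read span when available).
#' @export
read_alignments_sam <- function(path, library = "lib1", lane = "1") {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0)
    return(data.frame(read = character(0), library = character(0),
                      lane = character(0), transcript = character(0)))
  f <- strsplit(lines, "\t", fixed = TRUE)
  flag <- vapply(f, function(x) as.integer(x[2]), integer(1))
  rname <- vapply(f, function(x) x[3], character(1))
  mapped <- bitwAnd(flag, 4L) == 0L & rname != "*"
  f <- f[mapped]
  grab_tag <- function(x, tag) {
    hit <- grep(paste0("^", tag, ":"), x[-(1:11)], value = TRUE)
    if (length(hit) == 0) NA_character_ else sub(paste0(tag, ":[AifZ]:"), "", hit[1])
  }
  rg <- vapply(f, grab_tag, character(1), tag = "RG")
  nm <- suppressWarnings(as.integer(vapply(f, grab_tag, character(1), tag = "NM")))
  pos <- vapply(f, function(x) as.integer(x[4]), integer(1))
  seqlen <- vapply(f, function(x) nchar(x[10]), integer(1))
  lib <- ifelse(is.na(rg), library, sub("\\..*$", "", rg))
  ln <- ifelse(is.na(rg) | !grepl(".", rg, fixed = TRUE), lane,
               sub("^[^.]*\\.", "", rg))
  data.frame(read = vapply(f, `[`, character(1), 1),
             library = lib, lane = ln,
             transcript = vapply(f, `[`, character(1), 3),
             mismatches = nm, start = pos, end = pos + seqlen - 1L,
             stringsAsFactors = FALSE)
}
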