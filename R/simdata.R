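#' Synthetic data with known ground truth
#'
#' Generates every input the pipeline consumes — transcript catalogs
#' with isoform/paralog clusters, pairwise similarity matches,
#' per-library counts with planted phase and stage effects, read
#' alignments with controllable multi-mapping, and term annotations with
#' a planted enriched term — under a fixed seed, so that every
#' downstream stage can be validated against the generating truth.
#'
#' The default experimental design mirrors the 2-phase x 6-stage study
#' layout: twelve libraries (gregarious and solitary at egg, 1st+2nd,
#' 3rd, 4th, 5th instar and adult), with the two 4th-instar libraries
#' (G4, S4) sequenced 20x deeper than the rest and split over four
#' lanes.
#'
#' @name simdata
#' @keywords internal
NULL

#' The default 12-library experimental design
#'
#' @param deep_factor Relative sequencing depth of the two deep
#'   4th-instar libraries (default 20).
#' @param deep_lanes,shallow_lanes Number of lanes per library.
#' @return data.frame with columns `library`, `phase` ("G"/"S"),
#'   `stage`, `size_factor` and `lanes`.
#' @export
default_design <- function(deep_factor = 20, deep_lanes = 4, shallow_lanes = 1) {
  stages <- c("egg", "N12", "N3", "N4", "N5", "adult")
  d <- expand.grid(phase = c("G", "S"), stage = stages,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d$library <- paste(d$phase, d$stage, sep = "-")
  d$size_factor <- ifelse(d$stage == "N4", deep_factor, 1)
  d$lanes <- ifelse(d$stage == "N4", deep_lanes, shallow_lanes)
  d[, c("library", "phase", "stage", "size_factor", "lanes")]
}

#' Generate a transcript catalog with planted sequence clusters
#'
#' Singletons plus `n_clusters` clusters whose members are linked by
#' match records that pass the expression-clustering thresholds
#' (overlap ratio > 0.8 of the shorter sequence, identity > 0.96), so
#' that [build_clusters()] with default thresholds reconstructs the
#' emitted cluster map exactly.
#'
#' @param n_singletons,n_clusters Non-negative counts.
#' @param cluster_size_sampler Function(n) returning n integer cluster
#'   sizes >= 2 (default: uniform on 2..4).
#' @param length_sampler Function(n) returning n transcript lengths in
#'   bp, floored at 100 (default: log-normal around ~800 bp).
#' @param seed Integer seed; identical seeds give identical output.
#' @return List with `catalog` (data.frame transcript, length),
#'   `clusters` (cluster map as from [build_clusters()]) and `matches`
#'   (match records reconstructing the clusters).
#' @export
make_catalog <- function(n_singletons = 1600, n_clusters = 100,
                         cluster_size_sampler = function(n) sample(2:4, n, replace = TRUE),
                         length_sampler = function(n) pmax(100L, as.integer(round(stats::rlnorm(n, log(800), 0.6)))),
                         seed = 1L) {
  if (n_singletons < 0 || n_clusters < 0)
    stop("invalid parameter: counts must be non-negative")
  set.seed(seed)
  sizes <- if (n_clusters > 0) cluster_size_sampler(n_clusters) else integer(0)
  if (any(sizes < 2)) stop("invalid parameter: cluster sizes must be >= 2")
  n <- n_singletons + sum(sizes)
  if (n == 0) stop("empty catalog requested")
  ids <- sprintf("T%05d", seq_len(n))
  lengths <- length_sampler(n)
  if (any(lengths < 100)) stop("invalid parameter: lengths must be >= 100 bp")
  catalog <- data.frame(transcript = ids, length = as.numeric(lengths),
                        stringsAsFactors = FALSE)
  member_of <- c(rep(NA_integer_, n_singletons), rep(seq_along(sizes), sizes))
  matches <- NULL
  if (n_clusters > 0) {
    # chain each cluster's members; every edge passes both thresholds
    q <- s <- character(0)
    for (cl in seq_along(sizes)) {
      m <- ids[which(member_of == cl)]
      q <- c(q, m[-length(m)]); s <- c(s, m[-1])
    }
    lmin <- pmin(catalog$length[match(q, ids)], catalog$length[match(s, ids)])
    frac <- stats::runif(length(q), 0.85, 0.99)
    matches <- data.frame(query = q, subject = s,
                          overlap = floor(frac * lmin),
                          identity = round(stats::runif(length(q), 0.965, 0.995), 4),
                          stringsAsFactors = FALSE)
  } else {
    matches <- data.frame(query = character(0), subject = character(0),
                          overlap = numeric(0), identity = numeric(0))
  }
  # truth cluster map with the same representative rule as build_clusters
  cluster <- ids
  for (cl in seq_along(sizes)) {
    m <- which(member_of == cl)
    rep_id <- ids[m][order(-lengths[m], ids[m])][1]
    cluster[m] <- rep_id
  }
  clusters <- data.frame(transcript = ids, cluster = cluster,
                         representative = ids == cluster,
                         stringsAsFactors = FALSE)
  list(catalog = catalog, clusters = clusters, matches = matches)
}

#' Simulate per-library counts with planted effects
#'
#' Counts are drawn negative-binomially (variance mu + phi * mu^2;
#' phi = 0 gives Poisson, `noiseless = TRUE` gives rounded means) around
#' mean = relative abundance x planted fold x library size. Planted
#' effects, recorded in the returned truth object:
#'
#' * phase DE: a fraction of units up-regulated `de_fold`-fold in one
#'   phase; under the `"increasing"` stage profile the fold grows
#'   geometrically from 1 at egg to the full fold at adult (phase
#'   divergence grows with development), under `"constant"` it applies
#'   to every stage;
#' * stage effects: a fraction `frac_stage` of units carry per-stage
#'   log-normal multipliers (sd `stage_sd`) shared by both phases, the
#'   developmental signal that dominates library-level PCA;
#' * phase-specific markers: expressed in one phase, zero mean in the
#'   other;
#' * stable-difference markers: constant `marker_ratio`-fold offset
#'   between phases at every stage;
#' * composition bias: a few very-high-abundance units assigned to one
#'   phase, the canonical stressor for TMM normalization.
#'
#' Planted marker units draw their relative abundance from the upper
#' half of the abundance distribution (a marker below the detection
#' limit would be undefined), and marker/composition units carry no
#' stage effect (the screens define markers as development-stable).
#'
#' @param catalog Catalog (or `make_catalog()` output); with `clusters`
#'   supplied, counting units are the clusters.
#' @param design Library design as from [default_design()].
#' @param base_size Expected mapped reads of a depth-factor-1 library.
#' @param frac_de Fraction of units with planted phase DE.
#' @param de_fold Planted fold (> 1).
#' @param stage_profile `"increasing"` (default) or `"constant"`.
#' @param frac_stage Fraction of units with per-stage multipliers.
#' @param stage_sd Log-scale sd of the stage multipliers.
#' @param n_specific_markers,n_stable_markers,marker_ratio Planted
#'   marker counts and the stable-marker fold.
#' @param n_composition,composition_fold,composition_phase Composition
#'   bias block.
#' @param dispersion NB dispersion phi (>= 0).
#' @param noiseless If TRUE, counts are the rounded means (for
#'   screen-recovery checks free of sampling noise).
#' @param clusters Optional cluster map.
#' @param seed Integer seed.
#' @return List with `counts` (unit x library integer matrix), `truth`
#'   (planted effects, unit means, library scalings) and `design`.
#' @export
simulate_counts <- function(catalog, design = default_design(),
                            base_size = 80000, frac_de = 0.1, de_fold = 2,
                            stage_profile = c("increasing", "constant"),
                            frac_stage = 0.3, stage_sd = 1,
                            n_specific_markers = 0, n_stable_markers = 0,
                            marker_ratio = 3,
                            n_composition = 0, composition_fold = 50,
                            composition_phase = "G",
                            dispersion = 0.05, noiseless = FALSE,
                            clusters = NULL, seed = 1L) {
  stage_profile <- match.arg(stage_profile)
  if (is.list(catalog) && !is.data.frame(catalog)) {
    if (is.null(clusters)) clusters <- catalog$clusters
    catalog <- catalog$catalog
  }
  if (is.null(catalog) || nrow(catalog) == 0) stop("invalid input: empty catalog")
  if (nrow(design) < 2) stop("design needs at least two libraries")
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (frac_de > 0 && de_fold <= 1) stop("planted folds must be > 1")
  set.seed(seed)
  units <- if (is.null(clusters)) as.character(catalog$transcript)
           else sort(unique(as.character(clusters$cluster)))
  nu <- length(units)
  libs <- as.character(design$library)
  stages <- unique(as.character(design$stage))
  stage_idx <- stats::setNames(seq_along(stages), stages)
  phases <- sort(unique(as.character(design$phase)))

  abund_raw <- stats::rlnorm(nu, meanlog = 0, sdlog = 1)

  # disjoint planted blocks
  n_de <- round(frac_de * nu)
  need <- n_de + n_specific_markers + n_stable_markers + n_composition
  if (need > nu) stop("more planted units than catalog units")
  picks <- sample(units, need)
  de_units <- picks[seq_len(n_de)]
  spec_units <- picks[n_de + seq_len(n_specific_markers)]
  stab_units <- picks[n_de + n_specific_markers + seq_len(n_stable_markers)]
  comp_units <- picks[n_de + n_specific_markers + n_stable_markers +
                        seq_len(n_composition)]
  de_dir <- sample(phases, n_de, replace = TRUE)
  spec_dir <- sample(phases, n_specific_markers, replace = TRUE)
  stab_dir <- sample(phases, n_stable_markers, replace = TRUE)

  # markers must sit above the detection limit to be meaningful
  marker_units <- c(spec_units, stab_units)
  abund_raw[match(marker_units, units)] <-
    pmax(abund_raw[match(marker_units, units)], 1)
  abund <- abund_raw / sum(abund_raw)

  # shared-between-phase stage multipliers for a random subset of units
  # (markers and composition units stay development-stable)
  stage_pool <- setdiff(units, c(marker_units, comp_units))
  n_stage <- min(round(frac_stage * nu), length(stage_pool))
  stage_units <- sample(stage_pool, n_stage)
  stage_mult <- matrix(1, nrow = nu, ncol = length(stages),
                       dimnames = list(units, stages))
  if (n_stage > 0 && stage_sd > 0)
    stage_mult[stage_units, ] <- exp(matrix(
      stats::rnorm(n_stage * length(stages), 0, stage_sd),
      nrow = n_stage))

  fold <- matrix(1, nrow = nu, ncol = nrow(design),
                 dimnames = list(units, libs))
  for (j in seq_len(nrow(design))) {
    ph <- design$phase[j]; st <- design$stage[j]
    f_st <- if (stage_profile == "constant" || length(stages) == 1) de_fold
            else de_fold^((stage_idx[[st]] - 1) / (length(stages) - 1))
    fold[de_units[de_dir == ph], j] <- f_st
    fold[spec_units[spec_dir != ph], j] <- 0
    fold[stab_units[stab_dir == ph], j] <- marker_ratio
    if (ph == composition_phase)
      fold[comp_units, j] <- composition_fold
    fold[, j] <- fold[, j] * stage_mult[, st]
  }
  lib_size <- base_size * design$size_factor
  mu <- abund * fold %*% diag(lib_size, nrow = length(lib_size))
  dimnames(mu) <- list(units, libs)
  counts <- if (noiseless) round(mu)
            else if (dispersion == 0) matrix(stats::rpois(length(mu), mu), nrow = nu)
            else matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion), nrow = nu)
  dimnames(counts) <- list(units, libs)
  storage.mode(counts) <- "integer"

  truth <- list(
    de = data.frame(unit = de_units, direction = de_dir,
                    fold = rep(de_fold, n_de), stringsAsFactors = FALSE),
    markers = rbind(
      data.frame(unit = spec_units,
                 class = rep("phase-specific", length(spec_units)),
                 direction = spec_dir,
                 ratio = rep(NA_real_, length(spec_units)),
                 stringsAsFactors = FALSE),
      data.frame(unit = stab_units,
                 class = rep("stable-difference", length(stab_units)),
                 direction = stab_dir,
                 ratio = rep(marker_ratio, length(stab_units)),
                 stringsAsFactors = FALSE)),
    composition = comp_units,
    stage_units = stage_units,
    library_scaling = stats::setNames(design$size_factor, libs),
    mean_matrix = mu)
  list(counts = counts, truth = truth, design = design)
}

#' Simulate read alignments from a count table
#'
#' Emits one read per count, hitting a member of its generating unit;
#' with probability `intra_cluster_multimap_rate` a read from a
#' multi-member cluster gains a second hit on another member of the same
#' cluster, and with probability `cross_cluster_noise_rate` a read gains
#' a spurious hit outside its unit. Lanes are assigned uniformly
#' according to the design. With both rates zero, [assign_reads()] on
#' the output reproduces the generating counts exactly.
#'
#' @param catalog Catalog or `make_catalog()` output.
#' @param counts Unit x library count matrix from [simulate_counts()].
#' @param design Library design (for lane counts); default
#'   [default_design()].
#' @param intra_cluster_multimap_rate,cross_cluster_noise_rate
#'   Probabilities in \[0, 1\].
#' @param clusters Cluster map (defaults to the catalog's).
#' @param seed Integer seed.
#' @return Long-form alignment data.frame (`read`, `library`, `lane`,
#'   `transcript`).
#' @export
simulate_alignments <- function(catalog, counts, design = default_design(),
                                intra_cluster_multimap_rate = 0,
                                cross_cluster_noise_rate = 0,
                                clusters = NULL, seed = 1L) {
  if (is.list(catalog) && !is.data.frame(catalog)) {
    if (is.null(clusters)) clusters <- catalog$clusters
    catalog <- catalog$catalog
  }
  if (is.null(clusters)) clusters <- singleton_clusters(catalog)
  r1 <- intra_cluster_multimap_rate; r2 <- cross_cluster_noise_rate
  if (r1 < 0 || r1 > 1 || r2 < 0 || r2 > 1) stop("rates must lie in [0, 1]")
  if (!all(rownames(counts) %in% clusters$cluster))
    stop("counts reference units unknown to the cluster map")
  if (r2 > 0 && length(unique(clusters$cluster)) < 2)
    stop("cross-cluster noise requires at least two counting units")
  set.seed(seed)
  members <- split(as.character(clusters$transcript),
                   as.character(clusters$cluster))
  lanes <- stats::setNames(design$lanes, design$library)
  all_tx <- as.character(clusters$transcript)
  tx_unit <- .cluster_lookup(clusters)
  # flat member table for vectorised member picking
  member_vec <- unlist(members, use.names = FALSE)
  member_n <- lengths(members)
  member_off <- c(0L, cumsum(member_n))[seq_along(members)]
  names(member_n) <- names(member_off) <- names(members)
  out <- vector("list", ncol(counts))
  for (j in seq_len(ncol(counts))) {
    lib <- colnames(counts)[j]
    k <- counts[, j]
    total <- sum(k)
    if (total == 0) {
      out[[j]] <- data.table::data.table(read = character(0),
                                         library = character(0),
                                         lane = character(0),
                                         transcript = character(0))
      next
    }
    unit <- rep(rownames(counts), k)
    msize <- member_n[unit]
    off <- member_off[unit]
    pick <- floor(stats::runif(total) * msize)        # 0-based member index
    primary <- member_vec[off + pick + 1L]
    read <- sprintf("%s:r%07d", lib, seq_len(total))
    lane <- as.character(sample.int(lanes[[lib]], total, replace = TRUE))
    rows <- data.table::data.table(read = read, library = lib, lane = lane,
                                   transcript = primary, unit = unit)
    # intra-cluster multimap: one extra member hit (index offset skips the
    # primary member)
    multi <- msize >= 2 & stats::runif(total) < r1
    if (any(multi)) {
      shift <- floor(stats::runif(sum(multi)) * (msize[multi] - 1)) + 1L
      pick2 <- (pick[multi] + shift) %% msize[multi]
      extra <- member_vec[off[multi] + pick2 + 1L]
      rows <- rbind(rows, data.table::data.table(
        read = read[multi], library = lib, lane = lane[multi],
        transcript = extra, unit = unit[multi]))
    }
    # cross-cluster noise: one spurious hit outside the unit (uniform draw
    # with rejection of in-unit transcripts)
    noisy <- stats::runif(total) < r2
    if (any(noisy)) {
      n_noisy <- sum(noisy)
      spurious <- all_tx[sample.int(length(all_tx), n_noisy, replace = TRUE)]
      bad <- tx_unit[spurious] == unit[noisy]
      while (any(bad)) {
        spurious[bad] <- all_tx[sample.int(length(all_tx), sum(bad),
                                           replace = TRUE)]
        bad <- tx_unit[spurious] == unit[noisy]
      }
      rows <- rbind(rows, data.table::data.table(
        read = read[noisy], library = lib, lane = lane[noisy],
        transcript = spurious, unit = unit[noisy]))
    }
    out[[j]] <- rows[, c("read", "library", "lane", "transcript")]
  }
  as.data.frame(data.table::rbindlist(out))
}

#' Simulate a term-annotation map with one planted enriched term
#'
#' Every term samples its members uniformly from the catalog units
#' except the planted term, whose sampling weights up-weight the planted
#' differentially expressed units by `factor`, making the term
#' over-represented in DE gene lists by that factor (factor 1 = null).
#'
#' @param units Character vector of annotatable unit ids (or a catalog /
#'   `make_catalog()` output).
#' @param de_ids Units carrying planted DE (from `truth$de$unit`).
#' @param n_terms Number of terms (>= 1), ids "TERM001", ...
#' @param term_size_sampler Function(n) giving term sizes (default:
#'   uniform 10..60, capped at the catalog size).
#' @param planted_term List with `id` (default "TERM_planted"), `factor`
#'   (enrichment weight, >= 1) and `size`.
#' @param seed Integer seed.
#' @return data.frame annotation map with columns `gene`, `term`.
#' @export
simulate_annotation <- function(units, de_ids = character(0), n_terms = 50,
                                term_size_sampler = function(n) sample(10:60, n, replace = TRUE),
                                planted_term = list(id = "TERM_planted", factor = 4, size = 50),
                                seed = 1L) {
  if (is.list(units) && !is.data.frame(units)) units <- units$catalog
  if (is.data.frame(units)) units <- as.character(units$transcript)
  if (n_terms < 1) stop("invalid parameter: n_terms must be >= 1")
  if (planted_term$factor < 1)
    stop("invalid parameter: enrichment factor must be >= 1")
  if (!all(de_ids %in% units)) stop("de_ids must be catalog units")
  set.seed(seed)
  sizes <- pmin(term_size_sampler(n_terms), length(units))
  rows <- lapply(seq_len(n_terms), function(i) {
    data.frame(gene = sample(units, sizes[i]),
               term = sprintf("TERM%03d", i), stringsAsFactors = FALSE)
  })
  w <- ifelse(units %in% de_ids, planted_term$factor, 1)
  planted_size <- min(planted_term$size, length(units))
  rows[[n_terms + 1]] <- data.frame(
    gene = sample(units, planted_size, prob = w),
    term = planted_term$id, stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a catalog as a lengths TSV (and FASTA when sequences are given)
#' @param catalog Catalog data.frame (optionally with a `sequence`
#'   column).
#' @param path Base path; writes `<path>.lengths.tsv` and, with
#'   sequences, `<path>.fasta` via Biostrings.
#' @export
write_catalog <- function(catalog, path) {
  utils::write.table(catalog[, c("transcript", "length")],
                     paste0(path, ".lengths.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if ("sequence" %in% names(catalog)) {
    if (!requireNamespace("Biostrings", quietly = TRUE))
      stop("Biostrings is required to write FASTA")
    seqs <- Biostrings::DNAStringSet(stats::setNames(catalog$sequence,
                                                     catalog$transcript))
    Biostrings::writeXStringSet(seqs, paste0(path, ".fasta"))
  }
  invisible(path)
}
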