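#' End-to-end expression-profiling pipeline
#'
#' Wires the stages into the study workflow: similarity clustering ->
#' cluster-aware read counting -> TMM normalization and adjusted RPKM ->
#' per-stage phase differential expression -> marker screens, term
#' enrichment of the deep-pair DETs, library PCA and assembly QC. A
#' companion generator, [simulate_inputs()], produces every input with
#' known ground truth so the full pipeline runs with zero external
#' files. Every stage writes TSV outputs into the run directory together
#' with a run log recording sizes, thresholds and discarded-record
#' counts; outputs are deterministic for a fixed seed.
#'
#' @name pipeline
#' @keywords internal
NULL

#' Default pipeline configuration
#'
#' All thresholds default to the study's printed values: expression
#' clustering at overlap ratio > 0.8 and identity > 0.96; DE calls at
#' FDR < 0.01 and fold change > 2 (FDR < 1e-5 for the deep pair);
#' marker screens at CV < 0.3, ratio > 1.5, t-test p < 0.05;
#' enrichment reported at p < 0.01; PCA filter at six libraries.
#'
#' @param ... Overrides for individual fields.
#' @return Named list of configuration values.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    min_overlap = 0.80, min_identity = 0.96,
    fdr_cutoff = 0.01, fc_cutoff = 2, deep_fdr_cutoff = 1e-5,
    cv_max = 0.3, ratio_min = 1.5, marker_alpha = 0.05, cv_mode = "both",
    enrich_alpha = 0.01, pca_min_libraries = 6,
    reference_library = "S-egg", deep_stage = "N4",
    seed = 1L)
  over <- list(...)
  stopifnot(all(names(over) %in% names(cfg)))
  cfg[names(over)] <- over
  cfg
}

#' Generate a complete synthetic input bundle
#'
#' Runs the generator chain (catalog -> counts -> alignments ->
#' annotation) under one seed, at the default study conditions: ~2,000
#' counting units (1,600 singletons + 100 clusters), the 12-library
#' 2-phase x 6-stage design with the 4th-instar pair 20x deeper, phase
#' DE growing with development, planted phase markers, composition
#' bias, and a planted enriched term.
#'
#' @param n_singletons,n_clusters Catalog composition.
#' @param base_size Expected mapped reads of a shallow library.
#' @param frac_de,de_fold Planted phase-DE block.
#' @param n_specific_markers,n_stable_markers,marker_ratio Marker block.
#' @param n_composition Composition-bias block.
#' @param dispersion NB dispersion phi.
#' @param intra_rate,cross_rate Multi-mapping rates for alignments.
#' @param seed Integer seed driving every stage.
#' @return List with `catalog`, `clusters`, `matches`, `counts`,
#'   `truth`, `design`, `alignments`, `annotation`.
#' @export
simulate_inputs <- function(n_singletons = 1600, n_clusters = 100,
                            base_size = 80000, frac_de = 0.1, de_fold = 4,
                            n_specific_markers = 50, n_stable_markers = 50,
                            marker_ratio = 3, n_composition = 10,
                            dispersion = 0.05,
                            intra_rate = 0.3, cross_rate = 0.02,
                            seed = 1L) {
  cat_bundle <- make_catalog(n_singletons, n_clusters, seed = seed)
  design <- default_design()
  sim <- simulate_counts(cat_bundle, design = design, base_size = base_size,
                         frac_de = frac_de, de_fold = de_fold,
                         n_specific_markers = n_specific_markers,
                         n_stable_markers = n_stable_markers,
                         marker_ratio = marker_ratio,
                         n_composition = n_composition,
                         dispersion = dispersion, seed = seed + 1L)
  al <- simulate_alignments(cat_bundle, sim$counts, design = design,
                            intra_cluster_multimap_rate = intra_rate,
                            cross_cluster_noise_rate = cross_rate,
                            seed = seed + 2L)
  ann <- simulate_annotation(rownames(sim$counts),
                             de_ids = sim$truth$de$unit,
                             seed = seed + 3L)
  list(catalog = cat_bundle$catalog, clusters = cat_bundle$clusters,
       matches = cat_bundle$matches, counts = sim$counts,
       truth = sim$truth, design = design, alignments = al,
       annotation = ann)
}

#' Run the full pipeline on an input bundle
#'
#' @param inputs Bundle as from [simulate_inputs()] (or assembled from
#'   files with the reader functions: `catalog`, `matches`, `design`,
#'   `alignments`, `annotation`).
#' @param config Configuration from [pipeline_config()].
#' @param out_dir Optional directory; when given, every stage output is
#'   written as TSV plus a `run_log.tsv` with stage-level numbers.
#' @return List with `clusters`, `assigned` (counts, N, discarded),
#'   `norm`, `rpkm`, `de_by_stage` (per-stage phase comparisons at the
#'   series N_min), `de_deep` (deep pair at its stricter FDR),
#'   `markers`, `enrichment` (deep-pair up-DETs vs background), `pca`,
#'   `asm_stats` and `log`.
#' @export
run_pipeline <- function(inputs, config = pipeline_config(),
                         out_dir = NULL) {
  log <- list()
  note <- function(stage, ...) {
    log[[length(log) + 1]] <<- data.frame(stage = stage,
                                          message = sprintf(...),
                                          stringsAsFactors = FALSE)
  }
  for (field in c("catalog", "matches", "design", "alignments"))
    if (is.null(inputs[[field]]))
      stop("stage-dependency error: missing input '", field, "'")
  design <- inputs$design

  clusters <- build_clusters(inputs$matches, inputs$catalog,
                             min_overlap = config$min_overlap,
                             min_identity = config$min_identity)
  note("cluster", "%d transcripts -> %d units",
       nrow(clusters), length(unique(clusters$cluster)))

  assigned <- assign_reads(inputs$alignments, clusters)
  note("count", "assigned %d reads, discarded %d multi-unit reads",
       sum(assigned$N), sum(assigned$discarded))

  norm <- tmm_normalize(assigned$counts, ref = config$reference_library)
  unit_len <- stats::setNames(inputs$catalog$length,
                              inputs$catalog$transcript)[rownames(assigned$counts)]
  rpkm <- rpkm_matrix(assigned$counts, unit_len, norm)
  note("normalize", "TMM factors in [%.3f, %.3f], reference %s",
       min(norm$f), max(norm$f), config$reference_library)

  stages <- unique(as.character(design$stage))
  phases <- sort(unique(as.character(design$phase)))
  series_min <- min(assigned$N)
  de_by_stage <- lapply(stages, function(st) {
    libs <- design$library[design$stage == st]
    a <- design$library[design$stage == st & design$phase == phases[1]]
    b <- design$library[design$stage == st & design$phase == phases[2]]
    call_dets(assigned$counts, unit_len, norm, a, b,
              fdr_cutoff = config$fdr_cutoff, fc_cutoff = config$fc_cutoff,
              N_min = series_min)
  })
  names(de_by_stage) <- stages
  n_dets <- vapply(de_by_stage, function(d) sum(d$call != "ns"), integer(1))
  note("detest", "per-stage DETs at FDR<%g, fc>%g: %s", config$fdr_cutoff,
       config$fc_cutoff, paste(stages, n_dets, sep = "=", collapse = ", "))

  deep <- config$deep_stage
  a <- design$library[design$stage == deep & design$phase == phases[1]]
  b <- design$library[design$stage == deep & design$phase == phases[2]]
  de_deep <- call_dets(assigned$counts, unit_len, norm, a, b,
                       fdr_cutoff = config$deep_fdr_cutoff,
                       fc_cutoff = config$fc_cutoff)
  note("detest-deep", "deep pair %s vs %s: %d up, %d down (FDR<%g)",
       a, b, sum(de_deep$call == "up"), sum(de_deep$call == "down"),
       config$deep_fdr_cutoff)

  mk <- screen_markers(assigned$counts, rpkm, design,
                       cv_max = config$cv_max, ratio_min = config$ratio_min,
                       alpha = config$marker_alpha, cv_mode = config$cv_mode)
  note("markers", "%d phase-specific, %d stable-difference, %d overlap",
       nrow(mk$specific), nrow(mk$stable), length(mk$overlap))

  enrichment <- NULL
  if (!is.null(inputs$annotation)) {
    # up- and down-regulated deep-pair DETs tested as separate lists
    scans <- lapply(c(up = "up", down = "down"), function(side) {
      ids <- de_deep$unit[de_deep$call == side]
      if (length(ids) == 0) return(NULL)
      cbind(gene_list = side,
            enrich_scan(ids, inputs$annotation,
                        background = rownames(assigned$counts),
                        alpha = config$enrich_alpha))
    })
    enrichment <- do.call(rbind, scans)
    rownames(enrichment) <- NULL
    note("enrich", "%d term tests, %d enriched at p<%g",
         NROW(enrichment), sum(enrichment$enriched), config$enrich_alpha)
  }

  pca <- pca_libraries(rpkm, min_libraries = config$pca_min_libraries)
  note("pca", "%d transcripts retained; PC1 %.1f%%, PC2 %.1f%%",
       pca$n_retained, 100 * pca$variance_fraction[1],
       100 * pca$variance_fraction[2])

  asm_stats <- length_stats(inputs$catalog$length)
  note("asmqc", "N50 %d bp over %d sequences", asm_stats$n50, asm_stats$n)

  log <- do.call(rbind, log)
  result <- list(clusters = clusters, assigned = assigned, norm = norm,
                 rpkm = rpkm, de_by_stage = de_by_stage, de_deep = de_deep,
                 markers = mk, enrichment = enrichment, pca = pca,
                 asm_stats = asm_stats, log = log)
  if (!is.null(out_dir)) .write_bundle(result, inputs, config, out_dir)
  result
}

.write_bundle <- function(result, inputs, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, name) utils::write.table(
    x, file.path(out_dir, name), sep = "\t", quote = FALSE, row.names = FALSE)
  write_cluster_map(result$clusters, file.path(out_dir, "clusters.tsv"))
  write_count_table(result$assigned, file.path(out_dir, "counts.tsv"))
  w(result$norm, "normalization.tsv")
  write_tsv_matrix(round(result$rpkm, 4), file.path(out_dir, "rpkm.tsv"))
  for (st in names(result$de_by_stage))
    w(result$de_by_stage[[st]], sprintf("de_%s.tsv", st))
  w(result$de_deep, "de_deep.tsv")
  w(result$markers$specific, "markers_specific.tsv")
  w(result$markers$stable, "markers_stable.tsv")
  if (!is.null(result$enrichment)) w(result$enrichment, "enrichment.tsv")
  write_pca_tsv(result$pca, out_dir)
  w(data.frame(metric = c("n", "total", "mean", "median", "min", "max", "n50"),
               value = unlist(result$asm_stats[c("n", "total", "mean",
                                                 "median", "min", "max",
                                                 "n50")])),
    "assembly_stats.tsv")
  w(result$log, "run_log.tsv")
  cfg <- data.frame(key = names(config),
                    value = vapply(config, function(v) paste(format(v), collapse = ","),
                                   character(1)))
  w(cfg, "config.tsv")
  invisible(out_dir)
}
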