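test_that("make_catalog honours requested composition", {
  b <- make_catalog(3, 0, seed = 1)
  expect_equal(nrow(b$catalog), 3)
  expect_equal(length(unique(b$clusters$cluster)), 3)
  expect_equal(nrow(b$matches), 0)

  b2 <- make_catalog(0, 1, cluster_size_sampler = function(n) rep(3L, n),
                     seed = 7)
  expect_equal(nrow(b2$catalog), 3)
  expect_equal(length(unique(b2$clusters$cluster)), 1)
  expect_gte(nrow(b2$matches), 2)
  comp <- uf_components(b2$catalog$transcript,
                        as.matrix(b2$matches[, c("query", "subject")]))
  expect_equal(length(unique(comp)), 1)

  expect_error(make_catalog(-1, 0), "non-negative")
})

test_that("identical seeds give identical generator output", {
  a <- make_catalog(50, 10, seed = 42)
  b <- make_catalog(50, 10, seed = 42)
  expect_identical(a, b)
  s1 <- simulate_counts(a, design = pair_design(), frac_de = 0, seed = 42)
  s2 <- simulate_counts(b, design = pair_design(), frac_de = 0, seed = 42)
  expect_identical(s1$counts, s2$counts)
  al1 <- simulate_alignments(a, s1$counts, design = pair_design(),
                             intra_cluster_multimap_rate = 0.5,
                             cross_cluster_noise_rate = 0.1, seed = 42)
  al2 <- simulate_alignments(b, s2$counts, design = pair_design(),
                             intra_cluster_multimap_rate = 0.5,
                             cross_cluster_noise_rate = 0.1, seed = 42)
  expect_identical(al1, al2)
  an1 <- simulate_annotation(a, seed = 42)
  an2 <- simulate_annotation(b, seed = 42)
  expect_identical(an1, an2)
})

test_that("emitted match records reconstruct the emitted cluster map exactly", {
  b <- make_catalog(100, 30, seed = 5)
  cm <- build_clusters(b$matches, b$catalog)
  expect_identical(cm[order(cm$transcript), ],
                   b$clusters[order(b$clusters$transcript), ])
})

test_that("null configuration gives Poisson-like equal means across libraries", {
  cat0 <- flat_catalog(200)
  sim <- simulate_counts(cat0, design = pair_design(), frac_de = 0,
                         frac_stage = 0, dispersion = 0, base_size = 50000,
                         seed = 3)
  m <- sim$truth$mean_matrix
  expect_equal(m[, 1], m[, 2])
  # realised counts scatter around the configured means
  expect_lt(abs(mean(sim$counts[, 1]) / mean(m[, 1]) - 1), 0.05)
})

test_that("a planted phase fold is recovered in the empirical mean ratio", {
  cat0 <- flat_catalog(20)
  tot_g <- 0; tot_s <- 0
  de_unit <- NULL
  for (rep in 1:200) {
    sim <- simulate_counts(cat0, design = pair_design(), frac_de = 0.05,
                           de_fold = 2, stage_profile = "constant",
                           frac_stage = 0, dispersion = 0,
                           base_size = 20000, seed = rep)
    u <- sim$truth$de$unit[1]
    g_lib <- paste0(sim$truth$de$direction[1], "-x")
    s_lib <- setdiff(colnames(sim$counts), g_lib)
    tot_g <- tot_g + sim$counts[u, g_lib]
    tot_s <- tot_s + sim$counts[u, s_lib]
  }
  expect_lt(abs(tot_g / tot_s - 2), 0.15)
})

test_that("recorded library sizes equal count-table column sums", {
  sim <- simulate_counts(flat_catalog(100), design = default_design(),
                         seed = 9, base_size = 5000)
  expect_equal(unname(colSums(sim$counts) > 0), rep(TRUE, 12))
  expect_true(all(sim$counts >= 0))
  expect_type(sim$counts[1, 1], "integer")
  expect_error(simulate_counts(flat_catalog(0)), "empty")
  expect_error(simulate_counts(flat_catalog(10), dispersion = -1), ">= 0")
})

test_that("zero-rate alignments round-trip the generating counts exactly", {
  b <- make_catalog(40, 10, seed = 2)
  sim <- simulate_counts(b, design = pair_design(), base_size = 5000, seed = 2)
  al <- simulate_alignments(b, sim$counts, design = pair_design(), seed = 2)
  got <- assign_reads(al, b$clusters)
  expect_equal(got$counts[rownames(sim$counts), colnames(sim$counts)],
               sim$counts)
  expect_equal(sum(got$discarded), 0)
})

test_that("full intra-cluster multimapping doubles hits within 2-member clusters", {
  b <- make_catalog(0, 1, cluster_size_sampler = function(n) rep(2L, n),
                    seed = 3)
  sim <- simulate_counts(b, design = pair_design(), base_size = 500, seed = 3)
  al <- simulate_alignments(b, sim$counts, design = pair_design(),
                            intra_cluster_multimap_rate = 1, seed = 3)
  hits_per_read <- table(al$read)
  expect_true(all(hits_per_read == 2))
  # both hits stay inside the cluster: counts still recovered exactly
  got <- assign_reads(al, b$clusters)
  expect_equal(got$counts[rownames(sim$counts), colnames(sim$counts),
                          drop = FALSE],
               sim$counts)
})

test_that("cross-cluster noise hits are discarded from unique counting", {
  b <- make_catalog(30, 5, seed = 4)
  sim <- simulate_counts(b, design = pair_design(), base_size = 2000, seed = 4)
  al <- simulate_alignments(b, sim$counts, design = pair_design(),
                            cross_cluster_noise_rate = 1, seed = 4)
  got <- assign_reads(al, b$clusters)
  n_generated <- sum(sim$counts)
  expect_equal(sum(got$discarded), n_generated)
  expect_equal(sum(got$counts), 0)
  expect_error(
    simulate_alignments(b, matrix(1, 1, 2, dimnames = list("ZZZ", c("G-x", "S-x"))),
                        design = pair_design()),
    "unknown")
})

test_that("annotation maps are referentially intact with a valid planted term", {
  b <- make_catalog(200, 0, seed = 6)
  de <- b$catalog$transcript[1:20]
  ann <- simulate_annotation(b, de_ids = de, n_terms = 10, seed = 6)
  expect_true(all(ann$gene %in% b$catalog$transcript))
  expect_true("TERM_planted" %in% ann$term)
  expect_error(simulate_annotation(b, de, planted_term =
    list(id = "T", factor = 0.5, size = 20)), "factor")
  # null factor: planted-term DE fraction matches background in expectation
  fr <- replicate(50, {
    a <- simulate_annotation(b, de_ids = de, n_terms = 1,
                             planted_term = list(id = "P", factor = 1, size = 50),
                             seed = sample.int(1e6, 1))
    mean(a$gene[a$term == "P"] %in% de)
  })
  expect_lt(abs(mean(fr) - 0.1), 0.03)
})
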