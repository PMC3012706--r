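test_that("overlap ratio uses the shorter sequence as denominator", {
  expect_equal(overlap_ratio(500, 500, 500), 1.0)
  expect_equal(overlap_ratio(300, 500, 800), 0.6)
  expect_equal(overlap_ratio(0, 500, 800), 0.0)
  expect_equal(overlap_ratio(300, 500, 800, denominator = "longer"), 0.375)
  expect_error(overlap_ratio(600, 500, 800), "exceeds")
  expect_error(overlap_ratio(100, 0, 800), "positive")
})

test_that("clusters are single-linkage components with longest-member representatives", {
  catalog <- data.frame(transcript = c("A", "B", "C", "D"),
                        length = c(900, 1200, 700, 500))
  matches <- data.frame(query = c("A", "B"), subject = c("B", "C"),
                        overlap = c(800, 600), identity = c(0.99, 0.98))
  cm <- build_clusters(matches, catalog)
  expect_equal(sort(unique(cm$cluster)), c("B", "D"))
  expect_equal(cm$cluster[cm$transcript %in% c("A", "B", "C")],
               rep("B", 3))
  expect_true(cm$representative[cm$transcript == "B"])
  expect_equal(cm$cluster[cm$transcript == "D"], "D")
})

test_that("no qualifying matches leaves every transcript a singleton", {
  catalog <- data.frame(transcript = c("A", "B"), length = c(500, 500))
  cm <- build_clusters(NULL, catalog)
  expect_equal(cm$cluster, c("A", "B"))
  expect_true(all(cm$representative))
})

test_that("thresholds are strict: identity 0.95 creates no edge at cutoff 0.96", {
  catalog <- data.frame(transcript = c("A", "B"), length = c(500, 500))
  m1 <- data.frame(query = "A", subject = "B", overlap = 500, identity = 0.95)
  expect_equal(length(unique(build_clusters(m1, catalog)$cluster)), 2)
  # exactly at the overlap threshold also fails (strict '>')
  m2 <- data.frame(query = "A", subject = "B", overlap = 400, identity = 0.99)
  expect_equal(length(unique(build_clusters(m2, catalog)$cluster)), 2)
  m3 <- data.frame(query = "A", subject = "B", overlap = 401, identity = 0.99)
  expect_equal(length(unique(build_clusters(m3, catalog)$cluster)), 1)
})

test_that("any single qualifying record links a pair; duplicates collapse", {
  catalog <- data.frame(transcript = c("A", "B"), length = c(500, 500))
  m <- data.frame(query = c("A", "B"), subject = c("B", "A"),
                  overlap = c(100, 450), identity = c(0.99, 0.99))
  cm <- build_clusters(m, catalog)
  expect_equal(length(unique(cm$cluster)), 1)
  # neither record qualifying -> no edge, even jointly
  m2 <- data.frame(query = c("A", "B"), subject = c("B", "A"),
                   overlap = c(450, 100), identity = c(0.95, 0.99))
  expect_equal(length(unique(build_clusters(m2, catalog)$cluster)), 2)
})

test_that("matches referencing unknown transcripts are rejected", {
  catalog <- data.frame(transcript = "A", length = 500)
  m <- data.frame(query = "A", subject = "Z", overlap = 400, identity = 0.99)
  expect_error(build_clusters(m, catalog), "absent")
})

test_that("cluster assignment equals a union-find oracle on random graphs", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 200
    catalog <- data.frame(transcript = sprintf("N%03d", 1:n),
                          length = sample(100:2000, n, replace = TRUE))
    n_edges <- 150
    q <- sample(catalog$transcript, n_edges, replace = TRUE)
    s <- sample(catalog$transcript, n_edges, replace = TRUE)
    keep <- q != s
    q <- q[keep]; s <- s[keep]
    lmin <- pmin(catalog$length[match(q, catalog$transcript)],
                 catalog$length[match(s, catalog$transcript)])
    matches <- data.frame(query = q, subject = s,
                          overlap = round(runif(length(q), 0.5, 1) * lmin),
                          identity = runif(length(q), 0.9, 1))
    ratio <- matches$overlap / lmin
    pass <- ratio > 0.8 & matches$identity > 0.96
    cm <- build_clusters(matches, catalog)
    comp <- uf_components(catalog$transcript,
                          as.matrix(matches[pass, c("query", "subject")]))
    # same partition: cluster labels induce identical groupings
    expect_equal(length(unique(cm$cluster)), length(unique(comp)))
    expect_true(all(tapply(comp, cm$cluster[match(names(comp), cm$transcript)],
                           function(x) length(unique(x))) == 1))
  }
})

test_that("raising either threshold never merges clusters", {
  set.seed(42)
  n <- 80
  catalog <- data.frame(transcript = sprintf("N%03d", 1:n),
                        length = sample(200:2000, n, replace = TRUE))
  q <- sample(catalog$transcript, 60, replace = TRUE)
  s <- sample(catalog$transcript, 60, replace = TRUE)
  keep <- q != s; q <- q[keep]; s <- s[keep]
  lmin <- pmin(catalog$length[match(q, catalog$transcript)],
               catalog$length[match(s, catalog$transcript)])
  matches <- data.frame(query = q, subject = s,
                        overlap = round(runif(length(q), 0.4, 1) * lmin),
                        identity = runif(length(q), 0.9, 1))
  n_clusters <- function(ov, id)
    length(unique(build_clusters(matches, catalog, ov, id)$cluster))
  for (ov in c(0.5, 0.6, 0.8)) {
    expect_lte(n_clusters(ov, 0.92), n_clusters(ov, 0.96))
    expect_lte(n_clusters(ov, 0.96), n_clusters(ov, 0.99))
  }
  for (id in c(0.92, 0.96))
    expect_lte(n_clusters(0.6, id), n_clusters(0.8, id))
})

test_that("partition property holds and the TSV round trip preserves the map", {
  bundle <- make_catalog(20, 5, seed = 11)
  cm <- build_clusters(bundle$matches, bundle$catalog)
  expect_setequal(cm$transcript, bundle$catalog$transcript)
  expect_equal(anyDuplicated(cm$transcript), 0)
  path <- tempfile(fileext = ".tsv")
  write_cluster_map(cm, path)
  expect_equal(read_cluster_map(path), cm)
})

test_that("match tables read from BLAST outfmt-6 and the 4-column dialect", {
  p1 <- tempfile()
  writeLines(c("A\tB\t98.5\t300\t4\t0\t1\t300\t1\t300\t1e-50\t500"), p1)
  b <- read_blast_tab(p1)
  expect_equal(b$identity, 0.985)
  expect_equal(b$overlap, 300)
  p2 <- tempfile()
  writeLines(c("query\tsubject\toverlap\tidentity", "A\tB\t300\t0.98"), p2)
  m <- read_match_tsv(p2)
  expect_equal(m$overlap, 300)
  expect_equal(m$identity, 0.98)
})
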