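make_clusters <- function() {
  # T1 singleton; T2, T3 form cluster (T2 longer -> representative)
  data.frame(transcript = c("T1", "T2", "T3"),
             cluster = c("T1", "T2", "T2"),
             representative = c(TRUE, TRUE, FALSE),
             stringsAsFactors = FALSE)
}

al_row <- function(read, hits, library = "L1", lane = "1") {
  data.frame(read = read, library = library, lane = lane,
             transcript = hits, stringsAsFactors = FALSE)
}

test_that("the cluster-adjusted unique-mapping rule counts and discards correctly", {
  cl <- make_clusters()
  al <- rbind(al_row("r1", "T1"),          # unique singleton hit
              al_row("r2", c("T2", "T3")), # multiread within one cluster
              al_row("r3", c("T1", "T2")), # spans two units -> discarded
              al_row("r4", "T3"))          # single hit inside cluster
  got <- assign_reads(al, cl)
  expect_equal(got$counts["T1", "L1"], 1L)
  expect_equal(got$counts["T2", "L1"], 2L)
  expect_equal(unname(got$N["L1"]), 3)
  expect_equal(unname(got$discarded["L1"]), 1L)
})

test_that("assigned plus discarded reads equal the input total per library", {
  b <- make_catalog(50, 10, seed = 8)
  sim <- simulate_counts(b, design = pair_design(), base_size = 3000, seed = 8)
  al <- simulate_alignments(b, sim$counts, design = pair_design(),
                            intra_cluster_multimap_rate = 0.4,
                            cross_cluster_noise_rate = 0.3, seed = 8)
  got <- assign_reads(al, b$clusters)
  n_reads <- tapply(al$read, al$library, function(r) length(unique(r)))
  for (lib in names(n_reads))
    expect_equal(unname(got$N[lib] + got$discarded[lib]),
                 unname(n_reads[lib]))
})

test_that("with all-singleton clusters counting reduces to unique mapping", {
  cl <- data.frame(transcript = c("T1", "T2"), cluster = c("T1", "T2"),
                   representative = TRUE)
  al <- rbind(al_row("r1", "T1"), al_row("r2", c("T1", "T2")),
              al_row("r3", "T2"), al_row("r4", "T2"))
  got <- assign_reads(al, cl)
  expect_equal(got$counts[, "L1"], c(T1 = 1L, T2 = 2L))
  expect_equal(unname(got$discarded["L1"]), 1L)
})

test_that("counting is independent of record order", {
  cl <- make_clusters()
  al <- rbind(al_row("r1", "T1"), al_row("r2", c("T2", "T3")),
              al_row("r3", c("T1", "T2")), al_row("r4", "T3"))
  set.seed(1)
  for (i in 1:3) {
    got <- assign_reads(al[sample.int(nrow(al)), ], cl)
    expect_equal(got$counts["T2", "L1"], 2L)
    expect_equal(unname(got$N["L1"]), 3)
  }
})

test_that("unknown hit transcripts raise a consistency error", {
  expect_error(assign_reads(al_row("r1", "TX"), make_clusters()), "absent")
})

test_that("lane detection counts lanes with at least one assigned read", {
  cl <- make_clusters()
  al <- rbind(al_row("r1", "T1", lane = "1"),
              al_row("r2", "T1", lane = "2"),
              al_row("r3", "T1", lane = "2"),
              al_row("r4", "T2", lane = "3"))
  det <- detection_by_lanes(al, cl)
  expect_equal(det$lanes_detected[det$unit == "T1"], 2L)
  expect_equal(det$lanes_detected[det$unit == "T2"], 1L)
  expect_equal(nrow(detection_by_lanes(al[0, ], cl)), 0)
  summ <- lane_detection_summary(det, n_lanes = 4)
  expect_equal(summ$one, 1)
  expect_equal(summ$some, 1)
})

test_that("units expressed in exactly 2 of 4 lanes give a pure histogram at 2", {
  set.seed(5)
  n <- 100
  cl <- data.frame(transcript = sprintf("U%03d", 1:n),
                   cluster = sprintf("U%03d", 1:n), representative = TRUE)
  rows <- lapply(1:n, function(i) {
    lanes <- sample(1:4, 2)
    al_row(sprintf("U%03d_r%d", i, 1:2), rep(cl$transcript[i], 2),
           lane = as.character(lanes))
  })
  det <- detection_by_lanes(do.call(rbind, rows), cl)
  expect_true(all(det$lanes_detected == 2L))
  summ <- lane_detection_summary(det, n_lanes = 4)
  expect_equal(summ$some, 100)
  expect_equal(summ$all + summ$one + summ$none, 0)
})

test_that("deep-library down-sampling keeps exactly one lane", {
  al <- rbind(al_row("r1", "T1", library = "D", lane = "1"),
              al_row("r2", "T1", library = "D", lane = "2"),
              al_row("r3", "T1", library = "S", lane = "1"))
  kept <- downsample_to_lane(al, "D", seed = 4)
  expect_equal(length(unique(kept$lane[kept$library == "D"])), 1)
  expect_equal(sum(kept$library == "S"), 1)
  expect_identical(downsample_to_lane(al, "D", seed = 4),
                   downsample_to_lane(al, "D", seed = 4))
})

test_that("count tables and alignment tables survive their TSV round trips", {
  cl <- make_clusters()
  al <- rbind(al_row("r1", "T1"), al_row("r2", c("T2", "T3")),
              al_row("r4", "T3"))
  got <- assign_reads(al, cl)
  p <- tempfile(fileext = ".tsv")
  write_count_table(got, p)
  back <- read_count_table(p)
  expect_equal(back$counts, got$counts)
  expect_equal(back$N[colnames(got$counts)], got$N)

  pa <- tempfile(fileext = ".tsv")
  write_alignments_tsv(al, pa)
  back_al <- read_alignments_tsv(pa)
  key <- function(d) d[order(d$read, d$transcript),
                       c("read", "library", "lane", "transcript")]
  expect_equal(key(back_al), key(al), ignore_attr = TRUE)
})

test_that("SAM records parse into long-form alignments", {
  sam <- c("@HD\tVN:1.6",
           "@SQ\tSN:T1\tLN:1000",
           "r1\t0\tT1\t101\t60\t35M\t*\t0\t0\tACGTACGTACGTACGTACGTACGTACGTACGTACG\t*\tNM:i:1\tRG:Z:G-egg.2",
           "r2\t4\t*\t0\t0\t*\t*\t0\t0\tACGT\t*",
           "r3\t256\tT1\t201\t0\t35M\t*\t0\t0\tACGTACGTACGTACGTACGTACGTACGTACGTACG\t*\tNM:i:0")
  p <- tempfile(fileext = ".sam")
  writeLines(sam, p)
  al <- read_alignments_sam(p, library = "fallback", lane = "9")
  expect_equal(nrow(al), 2)  # unmapped r2 dropped
  expect_equal(al$library[al$read == "r1"], "G-egg")
  expect_equal(al$lane[al$read == "r1"], "2")
  expect_equal(al$mismatches[al$read == "r1"], 1L)
  expect_equal(al$start[al$read == "r1"], 101L)
  expect_equal(al$end[al$read == "r1"], 135L)
  expect_equal(al$library[al$read == "r3"], "fallback")
})
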