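mk_lib <- function(reads, total = 1e6, tissue = "t", rep = 1,
                   id = sprintf("%s_rep%d", tissue, rep)) {
  reads$length <- reads$end - reads$start
  if (is.null(reads$count)) reads$count <- 1L
  if (is.null(reads$strand)) reads$strand <- "+"
  if (is.null(reads$five_prime)) reads$five_prime <- "U"
  list(library_id = id, tissue = tissue, replicate = rep,
       total_mapped_reads = total, reads = reads)
}

test_that("rpm_normalize follows its definition and rejects bad totals", {
  expect_equal(rpm_normalize(2, 1e6), 2.0)
  expect_equal(rpm_normalize(0, 123), 0.0)
  expect_equal(rpm_normalize(5, 2e6), 2.5)
  expect_error(rpm_normalize(1, 0), "library_total")
})

test_that("cluster discovery merges by gap and applies the 2-RPM floor", {
  lib <- mk_lib(data.frame(scaffold = "S", start = c(100L, 150L),
                           end = c(123L, 173L)))
  cl <- discover_clusters(lib, min_rpm = 0)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$start, 100L)
  expect_equal(cl$end, 173L)

  # 1 read in a 1e6-read library = 1 RPM -> dropped; 2 reads -> kept
  one <- mk_lib(data.frame(scaffold = "S", start = 500L, end = 524L))
  expect_equal(nrow(discover_clusters(one)), 0L)
  two <- mk_lib(data.frame(scaffold = "S", start = c(500L, 510L),
                           end = c(524L, 534L)))
  expect_equal(nrow(discover_clusters(two)), 1L)

  # gap 76 splits at pad 75
  far <- mk_lib(data.frame(scaffold = "S",
                           start = c(100L, 100L, 199L, 199L),
                           end = c(123L, 123L, 223L, 223L)))
  expect_equal(nrow(discover_clusters(far, min_rpm = 0)), 2L)
  near <- mk_lib(data.frame(scaffold = "S",
                            start = c(100L, 100L, 198L, 198L),
                            end = c(123L, 123L, 222L, 222L)))
  expect_equal(nrow(discover_clusters(near, min_rpm = 0)), 1L)
})

test_that("cluster discovery agrees with the pairwise gap-graph oracle", {
  withr::local_seed(11)
  for (case in 1:8) {
    n <- sample(20:200, 1)
    reads <- data.frame(
      scaffold = sample(c("A", "B"), n, replace = TRUE),
      start = sample.int(5000, n, replace = TRUE))
    reads$end <- reads$start + sample(20:24, n, replace = TRUE)
    reads$count <- sample(1:5, n, replace = TRUE)
    lib <- mk_lib(reads, total = 1e6)
    got <- discover_clusters(lib, min_rpm = 3, island_pad = 75)
    exp <- oracle_clusters(lib$reads, 1e6, 3, 75)
    expect_equal(got$start, exp$start)
    expect_equal(got$end, exp$end)
    expect_equal(got$reads, exp$reads)
  }
})

test_that("consensus keeps >=3-library intervals, pads 25-nt gaps, rescues at 0.5 RPM", {
  clus <- function(start, end, rpm = 5) {
    data.frame(scaffold = "S", start = start, end = end,
               reads = 100, rpm = rpm, stringsAsFactors = FALSE)
  }
  tmap <- c(l1 = "t", l2 = "t", l3 = "t")
  # 3 of 3 replicates -> retained
  cl3 <- list(l1 = clus(100, 200), l2 = clus(100, 200), l3 = clus(100, 200))
  expect_equal(nrow(consensus_loci(cl3, tmap)), 1L)
  # 2 of 3 -> dropped
  cl2 <- list(l1 = clus(100, 200), l2 = clus(100, 200),
              l3 = clus(5000, 5100))
  expect_equal(nrow(suppressWarnings(consensus_loci(cl2, tmap))), 0L)

  # 25-nt gap merged, 26-nt gap kept separate
  g25 <- list(l1 = clus(c(100, 225), c(200, 300)),
              l2 = clus(c(100, 225), c(200, 300)),
              l3 = clus(c(100, 225), c(200, 300)))
  expect_equal(nrow(consensus_loci(g25, tmap)), 1L)
  g26 <- list(l1 = clus(c(100, 226), c(200, 300)),
              l2 = clus(c(100, 226), c(200, 300)),
              l3 = clus(c(100, 226), c(200, 300)))
  expect_equal(nrow(consensus_loci(g26, tmap)), 2L)

  # tissue-max RPM 0.4 removed, 0.5 retained
  lo <- list(l1 = clus(100, 200, rpm = 0.4), l2 = clus(100, 200, rpm = 0.4),
             l3 = clus(100, 200, rpm = 0.4))
  expect_equal(nrow(consensus_loci(lo, tmap)), 0L)
  hi <- list(l1 = clus(100, 200, rpm = 0.5), l2 = clus(100, 200, rpm = 0.4),
             l3 = clus(100, 200, rpm = 0.4))
  expect_equal(nrow(consensus_loci(hi, tmap)), 1L)

  # a tissue with fewer libraries than min_libraries warns and yields nothing
  expect_warning(consensus_loci(list(l1 = clus(1, 50)), c(l1 = "t")),
                 "min_libraries")
})

test_that("consensus matches the per-base vote oracle on small instances", {
  withr::local_seed(23)
  L <- 50000
  for (case in 1:5) {
    cfg <- sim_config(seed = 100 + case, genome = c(S = L),
                      n_planted_loci = 12, srna_noise_reads = 100)
    libs <- gen_srna_libraries(gen_annotation(cfg), cfg)$libraries
    clusters <- lapply(libs, discover_clusters)
    tmap <- vapply(libs, function(l) l$tissue, character(1))
    names(tmap) <- names(clusters) <- vapply(libs, function(l) l$library_id, character(1))
    got <- consensus_loci(clusters, tmap)
    exp <- oracle_consensus(clusters, tmap, L, "S")
    if (is.null(exp)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(got$start, exp$start)
      expect_equal(got$end, exp$end)
      expect_equal(got$tissues, exp$tissues)
    }
  }
})

test_that("consensus loci never overlap and are monotone in thresholds", {
  cfg <- sim_config(seed = 17, n_planted_loci = 80)
  libs <- gen_srna_libraries(gen_annotation(cfg), cfg)$libraries
  clusters <- lapply(libs, discover_clusters)
  tmap <- vapply(libs, function(l) l$tissue, character(1))
  names(tmap) <- names(clusters) <- vapply(libs, function(l) l$library_id, character(1))
  loci <- consensus_loci(clusters, tmap)
  for (s in unique(loci$scaffold)) {
    d <- loci[loci$scaffold == s, ]
    if (nrow(d) > 1) expect_true(all(d$start[-1] > d$end[-nrow(d)]))
  }
  expect_lte(sum(loci$end - loci$start), sum(cfg$genome))

  stricter_libs <- suppressWarnings(consensus_loci(clusters, tmap, min_libraries = 4))
  expect_lte(nrow(stricter_libs), nrow(loci))
  stricter_rpm <- consensus_loci(clusters, tmap, min_rpm_rescue = 5)
  expect_lte(nrow(stricter_rpm), nrow(loci))
})

test_that("locus classification follows the 80% dominance rule and definitions", {
  rd <- function(len, count, start = seq_along(len) * 30L, fp = "U") {
    data.frame(start = start, end = start + len, length = len,
               strand = "+", count = count, five_prime = fp)
  }
  expect_equal(classify_locus(rd(c(24, 24, 24, 24, 24, 24, 24, 24, 24, 21),
                                 rep(1L, 10)))$size_class, "23-24")
  expect_equal(classify_locus(rd(rep(21, 5), rep(1L, 5)))$size_class, "20-22")
  expect_equal(classify_locus(rd(c(24, 24, 21, 21), rep(1L, 4)))$size_class, "mixed")
  # 10 copies of one identical read -> complexity 0.1
  one <- data.frame(start = 100L, end = 124L, length = 24L, strand = "+",
                    count = 10L, five_prime = "U")
  cl <- classify_locus(one)
  expect_equal(cl$complexity, 0.1)
  expect_equal(sum(cl$five_prime_freq), 1, tolerance = 1e-9)
  expect_equal(unname(cl$five_prime_freq["U"]), 1)
  expect_error(classify_locus(one[0, ]), "zero reads")
})

test_that("phase score: degenerate perfect phasing and small-n reason code", {
  perfect <- data.frame(start = 1000L + 24L * (0:49), length = 24L, count = 1L)
  ph <- phase_score(perfect, register = 24)
  expect_equal(ph$score, 1)
  expect_true(ph$phased)
  few <- data.frame(start = c(0L, 24L), length = 24L, count = c(1L, 1L))
  ph2 <- phase_score(few, register = 24)
  expect_false(ph2$phased)
  expect_equal(ph2$reason, "too_few_reads")
})

test_that("phasing type-I error is controlled and power is high", {
  withr::local_seed(31)
  # type I: uniform 5' offsets
  n_sim <- 10000
  false_pos <- 0
  for (i in seq_len(n_sim)) {
    n <- 30
    rd <- data.frame(start = sample.int(24 * 20, n, replace = TRUE),
                     length = 24L, count = 1L)
    if (phase_score(rd, register = 24, origin = 0)$phased) {
      false_pos <- false_pos + 1
    }
  }
  expect_lte(false_pos / n_sim, 0.07)

  # power: planted register multiples with 10% off-register noise
  detected <- 0
  n_pow <- 400
  for (i in seq_len(n_pow)) {
    n <- 30
    on_grid <- runif(n) >= 0.1
    start <- ifelse(on_grid, 24 * sample.int(15, n, replace = TRUE),
                    sample.int(24 * 15, n, replace = TRUE))
    rd <- data.frame(start = as.integer(start), length = 24L, count = 1L)
    if (phase_score(rd, register = 24, origin = 0)$phased) detected <- detected + 1
  }
  expect_gte(detected / n_pow, 0.95)
})

test_that("tissue partition is a conservation-respecting Venn tabulation", {
  loci <- data.frame(
    scaffold = "S", start = 1:6 * 100L, end = 1:6 * 100L + 50L,
    tissues = c("root,rosette,pollen,inflorescence",
                "root,rosette,pollen,inflorescence",
                "root,rosette,pollen,inflorescence",
                "root", "pollen", "root,rosette"),
    stringsAsFactors = FALSE)
  tp <- tissue_partition(loci)
  expect_equal(tp$shared_all, 3L)
  expect_equal(unname(tp$private["root"]), 1L)
  expect_equal(unname(tp$private["pollen"]), 1L)
  expect_equal(sum(unlist(tp$by_subset)), nrow(loci))
})

test_that("tissue-private planted loci surface only in their tissue", {
  cfg <- sim_config(seed = 19)
  libs <- gen_srna_libraries(gen_annotation(cfg), cfg)
  loci <- srna_pipeline(libs$libraries)
  tr <- libs$truth
  priv <- tr[!grepl(",", tr$tissues) & tr$abundance_rpm > 15, ]
  hits <- 0; clean <- 0
  for (i in seq_len(nrow(priv))) {
    ov <- loci$scaffold == priv$scaffold[i] &
      loci$start < priv$end[i] & loci$end > priv$start[i]
    if (!any(ov)) next
    hits <- hits + 1
    tis <- unique(unlist(strsplit(loci$tissues[ov], ",")))
    if (identical(tis, priv$tissues[i])) clean <- clean + 1
  }
  expect_gt(hits, 0)
  expect_equal(clean, hits)
})
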