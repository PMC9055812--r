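test_that("density tracks count by midpoint and conserve totals", {
  feats <- data.frame(
    scaffold = "S",
    start = c(0L, 100L, 200L, 999900L, 1500000L),
    end = c(50L, 150L, 250L, 1000100L, 1500050L),
    type = c("gene", "gene", "gene", "gene", "TE:Gypsy"))
  tr <- density_tracks(feats, c(S = 2.5e6), window = 1e6)
  expect_equal(nrow(tr), 3L)
  # feature straddling the 1-Mbp boundary has midpoint 1000000 -> window 2
  expect_equal(tr$gene, c(3L, 1L, 0L))
  expect_equal(tr[["TE:Gypsy"]], c(0L, 1L, 0L))
  expect_equal(sum(tr$gene) + sum(tr[["TE:Gypsy"]]), nrow(feats))
  # last window truncated
  expect_equal(tr$window_end[3], 2.5e6)
})

test_that("gene density partition thresholds strictly above the mean", {
  gp <- gene_density_partition(c(10, 20, 60))
  expect_equal(as.character(gp$labels), c("depleted", "depleted", "enriched"))
  expect_equal(gp$mean, 30)
  allsame <- gene_density_partition(c(5, 5, 5))
  expect_true(all(allsame$labels == "depleted"))
  counts <- c(2, 8, 14, 54, 60, 7)
  gp2 <- gene_density_partition(counts)
  expect_gte(mean(counts[gp2$labels == "enriched"]), gp2$mean)
  expect_equal(gp2$median, median(counts))
})

test_that("intersect_fraction applies precedence and conserves mass", {
  ann <- data.frame(
    scaffold = "S",
    start = c(100L, 100L, 150L, 300L, 400L),
    end = c(200L, 140L, 200L, 350L, 500L),
    type = c("gene", "exon", "intron", "TE:Helitron", "exon"))
  loci <- data.frame(
    scaffold = "S",
    start = c(160L, 320L, 420L, 900L),
    end = c(180L, 340L, 430L, 950L))
  res <- intersect_fraction(loci, ann)
  expect_equal(res$class, c("intron", "TE", "exon", "intergenic"))
  expect_equal(sum(res$fractions), 1, tolerance = 1e-12)

  # overlapping exon and TE -> exon wins by precedence
  ann2 <- data.frame(scaffold = "S", start = c(100L, 100L),
                     end = c(200L, 200L), type = c("exon", "TE:Gypsy"))
  both <- intersect_fraction(data.frame(scaffold = "S", start = 150L, end = 160L), ann2)
  expect_equal(both$class, "exon")
  # permuting precedence flips only this tie case
  flipped <- intersect_fraction(data.frame(scaffold = "S", start = 150L, end = 160L),
                                ann2, precedence = c("TE", "exon", "intron", "intergenic"))
  expect_equal(flipped$class, "TE")
})

test_that("distance_to_nearest matches the quadratic oracle and thresholds", {
  tgt <- data.frame(scaffold = "S", start = c(1000L, 5000L), end = c(2000L, 6000L))
  loci <- data.frame(scaffold = "S",
                     start = c(1500L, 3400L, 7600L, 2000L),
                     end = c(1600L, 3500L, 7700L, 2100L))
  res <- distance_to_nearest(loci, tgt)
  expect_equal(res$distance, c(0, 1400, 1600, 0))
  expect_equal(res$fraction_within, 0.75)
  expect_error(distance_to_nearest(loci, tgt[0, ]), "empty target")

  withr::local_seed(5)
  for (case in 1:4) {
    loci2 <- data.frame(scaffold = sample(c("A", "B"), 300, replace = TRUE),
                        start = sample.int(100000, 300))
    loci2$end <- loci2$start + sample(50:500, 300, replace = TRUE)
    tgt2 <- data.frame(scaffold = sample(c("A", "B"), 200, replace = TRUE),
                       start = sample.int(100000, 200))
    tgt2$end <- tgt2$start + sample(50:2000, 200, replace = TRUE)
    got <- distance_to_nearest(loci2, tgt2)$distance
    expect_equal(got, oracle_nearest(loci2, tgt2))
  }
})

test_that("TE containment requires full span inside one TE", {
  tes <- data.frame(scaffold = "S", start = c(50L, 400L), end = c(300L, 600L),
                    type = c("TE:Gypsy", "TE:MuLE"))
  genes <- data.frame(scaffold = "S",
                      start = c(100L, 250L, 450L), end = c(200L, 350L, 550L),
                      id = c("g_in", "g_straddle", "g_mule"))
  res <- te_contained_genes(genes, tes)
  expect_setequal(res$contained, c("g_in", "g_mule"))
  expect_equal(res$mule_intersecting, "g_mule")
  # sharing the TE start but extending past its end is not containment
  edge <- data.frame(scaffold = "S", start = 50L, end = 350L, id = "g_edge")
  expect_length(te_contained_genes(edge, tes)$contained, 0)
})

test_that("ancestral block painting: runs, dissent and the exhaustive oracle", {
  go <- function(n) data.frame(scaffold = "S", gene_index = seq_len(n))
  seg6 <- assign_ancestral_blocks(go(6), rep("A", 6))
  expect_equal(nrow(seg6), 1L)
  expect_equal(seg6$block, "A")
  expect_equal(c(seg6$from_index, seg6$to_index), c(1L, 6L))

  expect_equal(nrow(assign_ancestral_blocks(go(3), rep("B", 3))), 0L)

  lab10 <- c("A", "A", "A", "A", "B", "A", "A", "A", "A", "A")
  seg10 <- assign_ancestral_blocks(go(10), lab10)
  expect_equal(nrow(seg10), 1L)
  expect_equal(seg10$block, "A")
  expect_equal(seg10$n_labelled, 10L)

  # unlabelled genes do not break runs
  labNA <- c("A", "A", NA, "A", NA, "A", "A")
  segNA <- assign_ancestral_blocks(go(7), labNA)
  expect_equal(nrow(segNA), 1L)
  expect_equal(segNA$n_labelled, 5L)

  withr::local_seed(13)
  for (case in 1:6) {
    n <- sample(10:18, 1)
    lab <- sample(c("A", "B", "C", NA), n, replace = TRUE,
                  prob = c(0.4, 0.3, 0.1, 0.2))
    got <- assign_ancestral_blocks(go(n), lab)
    best <- oracle_blocks(lab)
    expect_equal(sum(got$n_labelled), best)
  }
})
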