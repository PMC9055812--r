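test_that("generators are deterministic per seed and respect the config", {
  cfg1 <- sim_config(seed = 42)
  cfg2 <- sim_config(seed = 42)
  expect_identical(gen_annotation(cfg1), gen_annotation(cfg2))
  expect_identical(gen_srna_libraries(gen_annotation(cfg1), cfg1),
                   gen_srna_libraries(gen_annotation(cfg2), cfg2))
  expect_identical(gen_expression_counts(cfg1), gen_expression_counts(cfg2))
  expect_identical(gen_contigs_kmers_genotypes(cfg1),
                   gen_contigs_kmers_genotypes(cfg2))
  # different seed changes output
  cfg3 <- sim_config(seed = 43)
  expect_false(identical(gen_annotation(cfg1), gen_annotation(cfg3)))
})

test_that("zero-length scaffolds and out-of-bounds planted loci are rejected", {
  expect_error(sim_config(genome = c(S1 = 0)), "zero-length")
  bad <- plant_srna_loci(sim_config(seed = 1), n = 5)
  bad$end[1] <- 3e6
  expect_error(sim_config(seed = 1, planted_srna_loci = bad), "outside scaffold")
})

test_that("annotation geometry: no TE records without TEs, clean nesting", {
  cfg <- sim_config(seed = 7, annotation_params = list(n_tes = 0, n_te_contained = 0))
  ann <- gen_annotation(cfg)$annotation
  expect_true(all(ann$type %in% c("gene", "exon", "intron")))

  cfg2 <- sim_config(seed = 7)
  res <- gen_annotation(cfg2)
  ann2 <- res$annotation
  # exons/introns nested in their parent gene
  sub <- ann2[ann2$type %in% c("exon", "intron"), ]
  genes <- ann2[ann2$type == "gene", ]
  g <- genes[match(sub$parent, genes$id), ]
  expect_true(all(sub$start >= g$start & sub$end <= g$end))
  # genes other than the planted TE-contained ones do not overlap each other
  plain <- genes[!genes$id %in% res$truth$te_contained_genes, ]
  for (s in unique(plain$scaffold)) {
    d <- plain[plain$scaffold == s, ]
    d <- d[order(d$start), ]
    if (nrow(d) > 1) expect_true(all(d$start[-1] >= d$end[-nrow(d)]))
  }
})

test_that("planted TE-contained genes are recovered exactly downstream", {
  cfg <- sim_config(seed = 3, annotation_params = list(n_te_contained = 5))
  res <- gen_annotation(cfg)
  ann <- res$annotation
  genes <- ann[ann$type == "gene", ]
  tes <- ann[startsWith(ann$type, "TE:"), ]
  got <- te_contained_genes(genes, tes)
  expect_identical(got$contained, res$truth$te_contained_genes)
  expect_length(got$contained, 5L)
})

test_that("hairpin fixture structures are balanced dot-bracket", {
  hp <- gen_hairpin_set(sim_config(seed = 1))
  for (cand in hp$candidates) {
    ch <- strsplit(cand$structure, "")[[1]]
    expect_equal(sum(ch == "("), sum(ch == ")"))
    expect_equal(nchar(cand$sequence), nchar(cand$structure))
    expect_true(all(cand$reads$start >= 0 & cand$reads$end <= nchar(cand$sequence)))
  }
  expect_true("pass_all" %in% names(hp$candidates))
  expect_gte(sum(!hp$expected$expected_pass), 7)
})

test_that("methylation calls respect genome bounds and planted ordering", {
  cfg <- sim_config(seed = 5, methylation_params = list(n_sites = 30000))
  ann <- gen_annotation(cfg)
  met <- gen_methylation_calls(ann, cfg)
  expect_true(all(met$position >= 1 &
                    met$position <= cfg$genome[met$scaffold]))
  expect_true(all(met$methylated <= met$total))
  lev <- global_context_levels(filter_coverage(met)$calls)
  expect_true(lev$weighted_level[1] > lev$weighted_level[2])
  expect_true(lev$weighted_level[2] > lev$weighted_level[3])
  expect_true(lev$site_fraction[1] > lev$site_fraction[2])
  expect_true(lev$site_fraction[2] > lev$site_fraction[3])
})

test_that("generated files round-trip through the package readers", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(seed = 9, n_planted_loci = 20,
                    methylation_params = list(n_sites = 2000))
  ann <- gen_annotation(cfg)

  p <- file.path(dir, "ann.gff3")
  write_annotation_gff3(ann$annotation, p)
  back <- read_annotation_gff3(p)
  ord <- function(d) { d <- d[order(d$scaffold, d$start, d$end, d$type, d$id), ]
                       rownames(d) <- NULL; d }
  expect_equal(ord(back), ord(ann$annotation))

  libs <- gen_srna_libraries(ann, cfg)$libraries
  write_srna_libraries(libs[1:2], file.path(dir, "srna"))
  libs2 <- read_srna_libraries(file.path(dir, "srna"))
  expect_equal(libs2[[1]]$reads, libs[[1]]$reads)
  expect_equal(libs2[[2]]$total_mapped_reads, libs[[2]]$total_mapped_reads)

  met <- gen_methylation_calls(ann, cfg)
  write_methylation(met, file.path(dir, "met.tsv"))
  expect_equal(read_methylation(file.path(dir, "met.tsv")), met)

  ex <- gen_expression_counts(cfg)
  write_counts(ex$counts, file.path(dir, "counts.tsv"))
  expect_equal(read_counts(file.path(dir, "counts.tsv")), ex$counts)

  hp <- gen_hairpin_set(cfg)
  write_hairpins(hp$candidates, file.path(dir, "hp"))
  hp2 <- read_hairpins(file.path(dir, "hp"))
  expect_equal(hp2$pass_all$structure, hp$candidates$pass_all$structure)
  expect_equal(hp2$pass_all$sequence, hp$candidates$pass_all$sequence)
  expect_equal(hp2$fail_bulge$mature, hp$candidates$fail_bulge$mature)

  qc <- gen_contigs_kmers_genotypes(cfg)
  write_genotypes(qc$genotypes, file.path(dir, "geno.tsv"))
  g2 <- read_genotypes(file.path(dir, "geno.tsv"))
  expect_equal(unname(g2$dosage), unname(qc$genotypes$dosage))
  expect_equal(g2$markers$position, qc$genotypes$markers$position)
})
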