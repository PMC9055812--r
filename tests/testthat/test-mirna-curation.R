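test_that("parse_structure pairs, loops, errors and render round-trip", {
  pt <- parse_structure("((((....))))")
  expect_equal(sum(!is.na(pt$partner)) / 2, 4)
  expect_equal(pt$n_terminal_loops, 1L)
  expect_equal(pt$partner[1], 11L)  # 0-based partner of position 0

  pt2 <- parse_structure("((..))((..))")
  expect_equal(pt2$n_terminal_loops, 2L)

  expect_error(parse_structure("((("), "unbalanced")
  expect_error(parse_structure("())"), "unbalanced")
  expect_error(parse_structure("(x)"), "invalid structure character")

  for (s in c("((((....))))", "((..))((..))", "..(((...)))..", "....")) {
    expect_equal(render_structure(parse_structure(s)), s)
  }
})

test_that("duplex extraction classifies oppositions and overhangs", {
  # perfect 30-bp stem, 22-nt mature on the 5' arm
  struct <- paste0(strrep("(", 30), strrep(".", 8), strrep(")", 30))
  cand <- list(id = "x", sequence = strrep("A", 68), structure = struct,
               mature = c(2L, 24L), reads = NULL)
  d <- extract_duplex(cand)
  expect_true(d$single_stem)
  expect_equal(d$mismatches, 0L)
  expect_equal(d$bulge_nts, 0L)
  expect_equal(d$internal_loops, 0L)
  expect_equal(d$overhang_mature_3p, 2L)
  expect_equal(d$overhang_star_3p, 2L)
  # star: partner(b-3)=partner(21)=46 .. partner(a)+3=65+3: [46, 68)
  expect_equal(d$star$start, 46L)
  expect_equal(d$star$end, 68L)

  # one 1:1 opposition inside the duplex -> 1 mismatch
  s5 <- rep("(", 30); s5[11] <- "."
  s3 <- rep(")", 30); s3[30 - 10] <- "."
  struct_mm <- paste0(paste(s5, collapse = ""), strrep(".", 8),
                      paste(s3, collapse = ""))
  d2 <- extract_duplex(list(id = "y", sequence = strrep("A", 68),
                            structure = struct_mm, mature = c(2L, 24L)))
  expect_equal(d2$mismatches, 1L)
  expect_equal(d2$bulge_nts, 0L)

  # two unpaired on the mature strand opposite zero -> asymmetric bulge of 2
  s5 <- rep("(", 30); s5[11:12] <- "."
  struct_bu <- paste0(paste(s5, collapse = ""), strrep(".", 8), strrep(")", 28))
  d3 <- extract_duplex(list(id = "z", sequence = strrep("A", 66),
                            structure = struct_bu, mature = c(2L, 24L)))
  expect_equal(d3$bulge_nts, 2L)
  expect_equal(d3$mismatches, 0L)

  # mature spanning the loop: single_stem fails without an exception
  d4 <- extract_duplex(list(id = "w", sequence = strrep("A", 68),
                            structure = struct, mature = c(25L, 45L)))
  expect_false(d4$single_stem)
})

test_that("single-fault fixtures fail exactly their designed criterion", {
  hp <- gen_hairpin_set(sim_config(seed = 1))
  verdicts <- curate_hairpins(hp$candidates)
  crits <- c("hairpin_length", "single_stem", "duplex_read_fraction",
             "mature_length", "mismatch_count", "asymmetric_bulge_count",
             "internal_loops", "three_prime_overhang")
  m <- merge(verdicts, hp$expected, by = "id")
  for (i in seq_len(nrow(m))) {
    fails <- crits[!unlist(m[i, crits])]
    if (m$expected_pass[i]) {
      expect_true(m$pass[i], label = m$id[i])
      expect_length(fails, 0)
    } else {
      expect_false(m$pass[i], label = m$id[i])
      expect_identical(fails, m$fail_criterion[i])
    }
  }
})

test_that("boundary cases: 300 vs 301 nt and 0.74 vs 0.75 duplex fraction", {
  mk_perfect <- function(arm, loop, dup, other) {
    struct <- paste0(strrep("(", arm), strrep(".", loop), strrep(")", arm))
    L <- 2 * arm + loop
    list(id = "b", sequence = paste(rep("A", L), collapse = ""),
         structure = struct, mature = c(10L, 32L),
         reads = data.frame(start = c(10L, floor(L / 2) - 11L),
                            end = c(32L, floor(L / 2) + 11L),
                            count = c(dup, other)))
  }
  v300 <- evaluate_candidate(mk_perfect(146, 8, 80, 5))   # 300 nt
  expect_true(v300$criteria$hairpin_length)
  v301 <- evaluate_candidate(mk_perfect(146, 9, 80, 5))   # 301 nt
  expect_false(v301$criteria$hairpin_length)
  expect_true(v301$criteria$mismatch_count)

  v74 <- evaluate_candidate(mk_perfect(60, 8, 74, 26))
  expect_equal(v74$measures$duplex_read_fraction, 0.74)
  expect_false(v74$criteria$duplex_read_fraction)
  v75 <- evaluate_candidate(mk_perfect(60, 8, 75, 25))
  expect_equal(v75$measures$duplex_read_fraction, 0.75)
  expect_true(v75$criteria$duplex_read_fraction)
})

test_that("verdicts are invariant to read order and count scaling; no reads fail", {
  hp <- gen_hairpin_set(sim_config(seed = 2))
  cand <- hp$candidates$pass_all
  v0 <- evaluate_candidate(cand)
  cand_rev <- cand
  cand_rev$reads <- cand$reads[rev(seq_len(nrow(cand$reads))), ]
  expect_equal(evaluate_candidate(cand_rev)$criteria, v0$criteria)
  cand_scaled <- cand
  cand_scaled$reads$count <- cand$reads$count * 7L
  expect_equal(evaluate_candidate(cand_scaled)$measures$duplex_read_fraction,
               v0$measures$duplex_read_fraction)

  cand_nr <- cand
  cand_nr$reads <- cand$reads[0, ]
  vnr <- evaluate_candidate(cand_nr)
  expect_false(vnr$criteria$duplex_read_fraction)
  expect_equal(vnr$measures$duplex_fraction_reason, "no_reads")

  # mature defaults to the most abundant read when not proposed
  cand_auto <- cand
  cand_auto$mature <- NULL
  expect_true(evaluate_candidate(cand_auto)$pass)
})
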