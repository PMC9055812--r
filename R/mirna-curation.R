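#' Parse a dot-bracket secondary structure
#'
#' @param structure Dot-bracket string using only `.`, `(` and `)`.
#' @return List with `partner` (0-based integer vector, `NA` where
#'   unpaired), `n_terminal_loops` (number of hairpin loops, i.e. base
#'   pairs enclosing no further pairs) and `structure` (the input).
#'   Unbalanced structures raise an error naming the first offending
#'   0-based index.
#' @export
parse_structure <- function(structure) {
  ch <- strsplit(structure, "", fixed = TRUE)[[1]]
  bad <- which(!ch %in% c(".", "(", ")"))
  if (length(bad)) {
    stop(sprintf("invalid structure character '%s' at index %d", ch[bad[1]], bad[1] - 1L))
  }
  n <- length(ch)
  partner <- rep(NA_integer_, n)
  stack <- integer(0)
  n_loops <- 0L
  pairs_since_open <- logical(0)  # per stack level: any pair closed inside?
  for (i in seq_len(n)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
      pairs_since_open <- c(pairs_since_open, FALSE)
    } else if (ch[i] == ")") {
      if (!length(stack)) {
        stop(sprintf("unbalanced structure: unmatched ')' at index %d", i - 1L))
      }
      j <- stack[length(stack)]
      if (!pairs_since_open[length(pairs_since_open)]) n_loops <- n_loops + 1L
      stack <- stack[-length(stack)]
      pairs_since_open <- pairs_since_open[-length(pairs_since_open)]
      if (length(pairs_since_open)) pairs_since_open[length(pairs_since_open)] <- TRUE
      partner[i] <- j - 1L
      partner[j] <- i - 1L
    }
  }
  if (length(stack)) {
    stop(sprintf("unbalanced structure: unmatched '(' at index %d", stack[1] - 1L))
  }
  list(partner = partner, n_terminal_loops = n_loops, structure = structure)
}

#' Render a pair table back to dot-bracket
#'
#' Inverse of [parse_structure()] for nested structures.
#' @param pair_table Output of [parse_structure()].
#' @return Dot-bracket string.
#' @export
render_structure <- function(pair_table) {
  p <- pair_table$partner
  out <- rep(".", length(p))
  idx <- which(!is.na(p))
  out[idx] <- ifelse(p[idx] > idx - 1L, "(", ")")
  paste(out, collapse = "")
}

# Estimated partner of position x (0-based) using the nearest paired
# position within [lo, hi): along one stem arm the partner index is a
# decreasing function of position, so unpaired positions are extrapolated
# from the nearest paired neighbour.
.partner_est <- function(pt, x, lo, hi) {
  p <- pt$partner
  if (!is.na(p[x + 1L])) return(p[x + 1L])
  cand <- (lo:(hi - 1L))[!is.na(p[(lo:(hi - 1L)) + 1L])]
  if (!length(cand)) return(NA_integer_)
  xp <- cand[which.min(abs(cand - x))]
  p[xp + 1L] - (x - xp)
}

#' Infer the miRNA* interval
#'
#' Star interval by the miRNA/miRNA* duplex convention: the positions
#' pairing with the mature plus a 2-nt 3' offset on the star strand. The
#' same expression serves both stem arms because partner index decreases
#' along an arm. Coordinates are 0-based half-open in the hairpin.
#'
#' @param pair_table Output of [parse_structure()].
#' @param mature `c(start, end)` of the mature arm.
#' @return List with `start` and `end` (possibly extending past the
#'   hairpin terminus; callers clamp and judge the overhang criterion).
#' @export
infer_star <- function(pair_table, mature) {
  a <- mature[1]; b <- mature[2]
  s_lo <- .partner_est(pair_table, b - 3L, a, b)
  s_hi_anchor <- .partner_est(pair_table, a, a, b)
  if (is.na(s_lo) || is.na(s_hi_anchor)) {
    return(list(start = NA_integer_, end = NA_integer_))
  }
  list(start = s_lo, end = s_hi_anchor + 3L)
}

#' Extract and align the miRNA/miRNA* duplex
#'
#' Walks the pairing between the mature arm and its inferred star,
#' classifying each opposition: stacked pair, mismatch (1 unpaired
#' nucleotide on each strand), asymmetric bulge (unpaired nucleotides on
#' exactly one strand) or internal loop (>= 2 unpaired on both strands).
#' Also measures both duplex 3' overhangs: the number of 3'-terminal bases
#' of each strand not paired into the other strand's interval.
#'
#' @param candidate Hairpin candidate (fields `structure`, `mature`).
#' @param pair_table Optional pre-parsed structure.
#' @return List: `star` interval, `mismatches`, `bulge_nts`,
#'   `internal_loops`, `overhang_mature_3p`, `overhang_star_3p`,
#'   `single_stem` flag. When the mature spans the terminal loop the
#'   `single_stem` flag is `FALSE` and duplex measures are `NA` (no error
#'   is thrown).
#' @export
extract_duplex <- function(candidate, pair_table = NULL) {
  if (is.null(pair_table)) pair_table <- parse_structure(candidate$structure)
  p <- pair_table$partner
  L <- length(p)
  a <- candidate$mature[1]; b <- candidate$mature[2]
  stopifnot(a >= 0, b > a, b <= L)
  mat_idx <- a:(b - 1L)
  paired <- mat_idx[!is.na(p[mat_idx + 1L])]

  bad <- list(star = list(start = NA_integer_, end = NA_integer_),
              mismatches = NA_integer_, bulge_nts = NA_integer_,
              internal_loops = NA_integer_,
              overhang_mature_3p = NA_integer_, overhang_star_3p = NA_integer_,
              single_stem = FALSE)
  if (!length(paired)) return(bad)
  # mature folding back on itself (spans the terminal loop) is not a stem arm
  if (any(p[paired + 1L] %in% mat_idx)) return(bad)

  star <- infer_star(pair_table, candidate$mature)
  s_lo <- max(0L, star$start); s_hi <- min(L, star$end)
  if (is.na(star$start) || s_hi <= s_lo) return(bad)

  # single stem: exactly one terminal loop across the mature--star span
  span <- range(c(a, b - 1L, s_lo, s_hi - 1L))
  n_loops <- .count_terminal_loops(p, span[1], span[2])
  single_stem <- identical(n_loops, 1L)

  # opposition walk between consecutive paired mature positions
  mism <- 0L; bulge <- 0L; iloop <- 0L
  if (length(paired) > 1) {
    for (k in seq_len(length(paired) - 1L)) {
      u <- paired[k + 1L] - paired[k] - 1L
      v <- p[paired[k] + 1L] - p[paired[k + 1L] + 1L] - 1L
      if (u == 0L && v == 0L) next
      if (u >= 2L && v >= 2L) iloop <- iloop + 1L
      else { mism <- mism + min(u, v); bulge <- bulge + abs(u - v) }
    }
  }

  in_star <- function(x) x >= star$start & x < star$end
  in_mat <- function(x) x >= a & x < b
  m_in <- paired[in_star(p[paired + 1L])]
  o_m3 <- if (length(m_in)) (b - 1L) - max(m_in) else NA_integer_
  star_idx <- s_lo:(s_hi - 1L)
  sp <- star_idx[!is.na(p[star_idx + 1L])]
  s_in <- sp[in_mat(p[sp + 1L])]
  o_s3 <- if (length(s_in)) (star$end - 1L) - max(s_in) else NA_integer_

  list(star = star, mismatches = mism, bulge_nts = bulge,
       internal_loops = iloop, overhang_mature_3p = o_m3,
       overhang_star_3p = o_s3, single_stem = single_stem)
}

# terminal loops whose closing pair lies within [lo, hi] (0-based)
.count_terminal_loops <- function(partner, lo, hi) {
  n <- 0L
  idx <- which(!is.na(partner)) - 1L
  opens <- idx[partner[idx + 1L] > idx]
  for (i in opens) {
    j <- partner[i + 1L]
    if (i < lo || j > hi) next
    inner <- if (j - i > 1L) (i + 1L):(j - 1L) else integer(0)
    if (!length(inner) || all(is.na(partner[inner + 1L]))) n <- n + 1L
  }
  n
}

#' Evaluate a MIRNA hairpin candidate
#'
#' Applies the structural and read-based curation rules for plant MIRNA
#' annotation: hairpin length at most 300 nt; a single stem across the
#' mature--star span; at least 75% of copy-weighted hairpin reads belonging
#' to the miRNA/miRNA* duplex (interval membership with +/- `read_slack`
#' nt end slack); mature length 20-24 nt; at most 5 mismatched bases and
#' at most 3 nucleotides in asymmetric bulges; no internal loops; and
#' 2-nt 3' overhangs on both duplex ends. Criteria that require a
#' well-formed duplex are reported as `NA` measures (and not failed) when
#' the stem itself is invalid; the overall verdict then fails through
#' `single_stem`.
#'
#' @param candidate List with `id`, `sequence`, `structure`, `mature`
#'   (`c(start, end)`, 0-based half-open; `NULL` to use the most abundant
#'   read), `reads` (data frame `start`, `end`, `count` in hairpin
#'   coordinates).
#' @param max_hairpin_length,min_duplex_fraction,mature_length_range
#'   Curation thresholds.
#' @param max_mismatches,max_bulge_nts,required_overhang Duplex thresholds.
#' @param read_slack Positional slack (nt) for duplex read membership.
#' @param both_overhangs Require the 2-nt overhang on both duplex ends
#'   (set `FALSE` to tolerate a hairpin-terminus truncation on one end).
#' @return A `curation_verdict` list: `pass`, per-criterion logical
#'   `criteria`, and `measures`.
#' @export
evaluate_candidate <- function(candidate,
                               max_hairpin_length = 300L,
                               min_duplex_fraction = 0.75,
                               mature_length_range = c(20L, 24L),
                               max_mismatches = 5L,
                               max_bulge_nts = 3L,
                               required_overhang = 2L,
                               read_slack = 2L,
                               both_overhangs = TRUE) {
  stopifnot(nchar(candidate$sequence) == nchar(candidate$structure))
  pt <- parse_structure(candidate$structure)
  L <- nchar(candidate$structure)

  reads <- candidate$reads
  if (is.null(candidate$mature)) {
    if (is.null(reads) || !nrow(reads)) {
      stop("candidate has neither a proposed mature interval nor reads")
    }
    top <- reads[which.max(reads$count), ]
    candidate$mature <- c(top$start, top$end)
  }
  a <- candidate$mature[1]; b <- candidate$mature[2]
  mature_len <- b - a

  dup <- extract_duplex(candidate, pt)

  crit <- list()
  meas <- list(hairpin_length = L, mature_length = mature_len,
               mismatches = dup$mismatches, bulge_nts = dup$bulge_nts,
               internal_loops = dup$internal_loops,
               overhang_mature_3p = dup$overhang_mature_3p,
               overhang_star_3p = dup$overhang_star_3p,
               duplex_read_fraction = NA_real_,
               star_start = dup$star$start, star_end = dup$star$end,
               duplex_fraction_reason = NA_character_)

  crit$hairpin_length <- L <= max_hairpin_length
  crit$single_stem <- isTRUE(dup$single_stem)
  crit$mature_length <- mature_len >= mature_length_range[1] &&
    mature_len <= mature_length_range[2]

  # duplex read fraction (copy-weighted, +/- slack interval membership)
  if (is.null(reads) || !nrow(reads)) {
    crit$duplex_read_fraction <- FALSE
    meas$duplex_fraction_reason <- "no_reads"
  } else if (!crit$single_stem || is.na(dup$star$start)) {
    crit$duplex_read_fraction <- TRUE   # undefined without a duplex; fails via single_stem
    meas$duplex_fraction_reason <- "no_duplex"
  } else {
    s0 <- max(0L, dup$star$start); s1 <- min(L, dup$star$end)
    in_int <- function(rs, re, lo, hi) rs >= lo - read_slack & re <= hi + read_slack
    dupread <- in_int(reads$start, reads$end, a, b) |
      in_int(reads$start, reads$end, s0, s1)
    frac <- sum(reads$count[dupread]) / sum(reads$count)
    meas$duplex_read_fraction <- frac
    crit$duplex_read_fraction <- frac >= min_duplex_fraction
  }

  na_pass <- function(x) is.na(x) || x   # duplex-less candidates fail via single_stem
  crit$mismatch_count <- na_pass(dup$mismatches <= max_mismatches)
  crit$asymmetric_bulge_count <- na_pass(dup$bulge_nts <= max_bulge_nts)
  crit$internal_loops <- na_pass(dup$internal_loops == 0L)
  o_ok <- c(dup$overhang_mature_3p == required_overhang,
            dup$overhang_star_3p == required_overhang)
  crit$three_prime_overhang <- if (both_overhangs) {
    all(vapply(o_ok, na_pass, logical(1)))
  } else {
    any(vapply(o_ok, na_pass, logical(1)))
  }

  crit <- lapply(crit, isTRUE)
  structure(list(id = candidate$id, pass = all(unlist(crit)),
                 criteria = crit, measures = meas),
            class = "curation_verdict")
}

#' Evaluate a set of hairpin candidates
#'
#' @param candidates List of candidates (see [evaluate_candidate()]).
#' @param ... Thresholds passed to [evaluate_candidate()].
#' @return Data frame with one row per candidate: `id`, `pass`, one
#'   logical column per criterion and the measured values.
#' @export
curate_hairpins <- function(candidates, ...) {
  rows <- lapply(candidates, function(cand) {
    v <- evaluate_candidate(cand, ...)
    data.frame(id = v$id, pass = v$pass,
               as.data.frame(v$criteria),
               duplex_read_fraction_value = v$measures$duplex_read_fraction,
               mismatches = v$measures$mismatches,
               bulge_nts = v$measures$bulge_nts,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
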