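#' Generate multi-tissue replicate sRNA libraries
#'
#' Emits one library per (tissue, replicate): planted loci produce reads at
#' their configured RPM in the tissues they are expressed in, with read
#' lengths matching their size class (phased loci emit register-length
#' reads whose 5' ends sit at exact register multiples apart from a 10%
#' off-register noise fraction), plus scattered background singleton reads
#' below the cluster detection floor. Read rows carry copy counts;
#' `total_mapped_reads` is the configured library total (the RPM
#' denominator), of which the listed reads are the locus-associated and
#' background fraction.
#'
#' @param annotation Output of [gen_annotation()] (accepted for interface
#'   symmetry; read placement depends only on the planted loci).
#' @param config A [sim_config()] object.
#' @param off_register_fraction Fraction of a phased locus's reads placed
#'   off the register grid.
#' @return List with `libraries` (list of sRNA library objects: fields
#'   `library_id`, `tissue`, `replicate`, `total_mapped_reads`, `reads`)
#'   and `truth` (the planted locus table).
#' @export
gen_srna_libraries <- function(annotation, config, off_register_fraction = 0.1) {
  stopifnot(inherits(config, "sim_config"))
  planted <- config$planted_srna_loci
  validate_planted_loci(planted, config$genome)
  total <- config$srna_library_size

  with_stream(config$seed, 2L, {
    libs <- list()
    for (t in config$tissues) {
      expressed <- planted[vapply(strsplit(planted$tissues, ","),
                                  function(x) t %in% x, logical(1)), ]
      for (r in seq_len(config$n_replicates_per_tissue)) {
        lib_id <- sprintf("%s_rep%d", t, r)
        reads <- .emit_locus_reads(expressed, total, off_register_fraction)
        noise <- .emit_noise_reads(config$genome, config$srna_noise_reads)
        rd <- rbind(reads, noise)
        rd <- rd[order(rd$scaffold, rd$start, rd$end, rd$strand), ]
        # aggregate identical alignments into copy counts
        key <- paste(rd$scaffold, rd$start, rd$end, rd$strand, rd$five_prime)
        agg <- rowsum(rd$count, key, reorder = FALSE)
        first <- !duplicated(key)
        rd <- rd[first, ]
        rd$count <- as.integer(agg[match(key[first], rownames(agg)), 1])
        rownames(rd) <- NULL
        libs[[lib_id]] <- list(
          library_id = lib_id, tissue = t, replicate = r,
          total_mapped_reads = total, reads = rd
        )
      }
    }
    list(libraries = libs, truth = planted)
  })
}

.emit_locus_reads <- function(loci, total, off_register_fraction) {
  out <- vector("list", nrow(loci))
  for (i in seq_len(nrow(loci))) {
    lo <- loci[i, ]
    n <- stats::rpois(1, lo$abundance_rpm * total / 1e6)
    if (n == 0) { out[[i]] <- NULL; next }
    if (lo$phased) {
      len <- rep(lo$register, n)
      n_phase <- max(0L, ceiling(lo$end - lo$start) %/% lo$register)
      on_grid <- stats::runif(n) >= off_register_fraction
      k <- sample.int(max(1L, n_phase), n, replace = TRUE) - 1L
      start <- ifelse(on_grid,
                      lo$start + k * lo$register,
                      lo$start + floor(stats::runif(n, 0, max(1, lo$end - lo$start - len))))
    } else if (lo$size_class == "23-24") {
      len <- sample(c(23L, 24L), n, replace = TRUE, prob = c(0.3, 0.7))
      start <- lo$start + floor(stats::runif(n, 0, pmax(1, lo$end - lo$start - len)))
    } else {
      len <- sample(c(20L, 21L, 22L), n, replace = TRUE, prob = c(0.15, 0.6, 0.25))
      start <- lo$start + floor(stats::runif(n, 0, pmax(1, lo$end - lo$start - len)))
    }
    five <- ifelse(stats::runif(n) < lo$five_prime_u, "U",
                   sample(c("A", "C", "G"), n, replace = TRUE))
    out[[i]] <- data.frame(
      scaffold = lo$scaffold, start = as.integer(start),
      end = as.integer(start + len), length = as.integer(len),
      strand = ifelse(lo$phased, "+",
                      sample(c("+", "-"), n, replace = TRUE, prob = c(0.7, 0.3))),
      count = 1L, five_prime = five, stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(scaffold = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      strand = character(0), count = integer(0),
                      five_prime = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

.emit_noise_reads <- function(genome, n) {
  if (n == 0) {
    return(data.frame(scaffold = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      strand = character(0), count = integer(0),
                      five_prime = character(0), stringsAsFactors = FALSE))
  }
  scaf <- sample(names(genome), n, replace = TRUE, prob = genome / sum(genome))
  len <- sample(20:24, n, replace = TRUE)
  start <- floor(stats::runif(n, 0, genome[scaf] - len))
  data.frame(scaffold = scaf, start = as.integer(start),
             end = as.integer(start + len), length = as.integer(len),
             strand = sample(c("+", "-"), n, replace = TRUE),
             count = 1L,
             five_prime = sample(c("A", "C", "G", "U"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

#' Generate MIRNA hairpin curation fixtures
#'
#' Engineers a set of hairpin candidates: one passing every curation rule
#' and, for each rule, one candidate failing exactly that rule (hairpin
#' length, duplex-read fraction, mature length, mismatch count,
#' asymmetric-bulge nucleotides, 3' overhang, single-stem structure, plus
#' an internal-loop case). Structures are valid dot-bracket strings; reads
#' are given in hairpin coordinates with copy counts.
#'
#' @param config A [sim_config()] object (used for the RNG stream seeding
#'   the random sequence content; geometry is deterministic).
#' @return List with `candidates` (list of hairpin candidate objects:
#'   `id`, `sequence`, `structure`, `mature` c(start, end) 0-based
#'   half-open, `reads` data frame start/end/count) and
#'   `expected` (data frame: id, expected_pass, fail_criterion).
#' @export
gen_hairpin_set <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_stream(config$seed, 3L, {
    cands <- list()
    expected <- list()
    add <- function(cand, pass, fail = NA_character_) {
      cands[[cand$id]] <<- cand
      expected[[cand$id]] <<- data.frame(id = cand$id, expected_pass = pass,
                                         fail_criterion = fail,
                                         stringsAsFactors = FALSE)
    }

    add(.hp_perfect("pass_all", arm = 60, loop = 8, mature = c(10L, 32L)),
        TRUE)
    add(.hp_perfect("fail_length", arm = 146, loop = 9, mature = c(10L, 32L)),
        FALSE, "hairpin_length")
    add(.hp_perfect("fail_duplex_fraction", arm = 60, loop = 8,
                    mature = c(10L, 32L), duplex_reads = 74L, other_reads = 26L),
        FALSE, "duplex_read_fraction")
    add(.hp_perfect("fail_mature_length", arm = 60, loop = 8,
                    mature = c(10L, 29L)),
        FALSE, "mature_length")
    add(.hp_dotted("fail_mismatch", arm = 60, loop = 8, mature = c(10L, 32L),
                   dots5 = c(12L, 15L, 18L, 21L, 24L, 27L), mirror = TRUE),
        FALSE, "mismatch_count")
    add(.hp_dotted("fail_bulge", arm = 62, loop = 8, mature = c(10L, 32L),
                   dots5 = c(14L, 15L, 22L, 23L), mirror = FALSE),
        FALSE, "asymmetric_bulge_count")
    add(.hp_dotted("fail_internal_loop", arm = 60, loop = 8,
                   mature = c(10L, 32L), dots5 = c(16L, 17L), mirror = TRUE),
        FALSE, "internal_loops")
    add(.hp_dotted("fail_overhang", arm = 60, loop = 8, mature = c(10L, 32L),
                   dots5 = c(28L, 29L), mirror = FALSE),
        FALSE, "three_prime_overhang")
    add(.hp_loop_spanning("fail_single_stem", arm = 60, loop = 8,
                          mature = c(50L, 72L)),
        FALSE, "single_stem")

    list(candidates = cands, expected = do.call(rbind, unname(expected)))
  })
}

.rna_letters <- function(n) paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                                  collapse = "")

# perfectly paired stem: arm x '(' + loop x '.' + arm x ')'
.hp_perfect <- function(id, arm, loop, mature, duplex_reads = 80L,
                        other_reads = 5L) {
  struct <- paste0(strrep("(", arm), strrep(".", loop), strrep(")", arm))
  L <- nchar(struct)
  .hp_assemble(id, struct, L, mature, duplex_reads, other_reads)
}

# stem with unpaired positions: dots5 on the 5' arm; if mirror, also the
# opposing 3'-arm positions (1:1 or n:n oppositions), else mature-side-only
# bulges
.hp_dotted <- function(id, arm, loop, mature, dots5, mirror) {
  n5 <- arm
  n3 <- if (mirror) arm else arm - length(dots5)
  arm5 <- rep("(", n5); arm5[dots5 + 1L] <- "."
  struct5 <- paste(arm5, collapse = "")
  if (mirror) {
    L <- n5 + loop + n3
    # mirror positions in the full string are L-1-dots5; offset into 3' arm
    arm3 <- rep(")", n3)
    arm3[(L - 1L - dots5) - (n5 + loop) + 1L] <- "."
    struct3 <- paste(arm3, collapse = "")
  } else {
    struct3 <- strrep(")", n3)
  }
  struct <- paste0(struct5, strrep(".", loop), struct3)
  .hp_assemble(id, struct, nchar(struct), mature, 80L, 5L)
}

# mature interval spanning the terminal loop (single-stem violation)
.hp_loop_spanning <- function(id, arm, loop, mature) {
  struct <- paste0(strrep("(", arm), strrep(".", loop), strrep(")", arm))
  L <- nchar(struct)
  reads <- data.frame(start = c(mature[1], 2L), end = c(mature[2], 24L),
                      count = c(90L, 10L))
  list(id = id, sequence = .rna_letters(L), structure = struct,
       mature = mature, reads = reads)
}

.hp_assemble <- function(id, struct, L, mature, duplex_reads, other_reads) {
  # reads: the mature stack plus an off-duplex read over the loop; the
  # star is inferred during curation and need not be sequenced, and the
  # two read classes make the duplex fraction exact for boundary fixtures
  loop_mid <- floor(L / 2)
  reads <- data.frame(
    start = c(mature[1], loop_mid - 11L),
    end = c(mature[2], loop_mid + 11L),
    count = c(as.integer(duplex_reads), as.integer(other_reads)))
  list(id = id, sequence = .rna_letters(L), structure = struct,
       mature = mature, reads = reads)
}
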