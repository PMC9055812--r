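#' Simulation configuration
#'
#' Builds the single configuration object consumed by all synthetic-data
#' generators. Every generator draws from its own RNG stream derived from
#' `seed`, so the same config always yields byte-identical output and the
#' generators do not perturb each other.
#'
#' The defaults describe the study conditions the downstream pipelines are
#' exercised under: a 2-scaffold x 2-Mbp genome with gene density high at
#' the scaffold ends and TE density high at the centre (telomere /
#' pericentromere geometry), four tissues with three replicate sRNA
#' libraries each, and 200 planted sRNA loci.
#'
#' @param seed Integer seed; fully determines all generator output.
#' @param genome Named numeric vector of scaffold lengths (bp).
#' @param n_tissues,n_replicates_per_tissue sRNA library design.
#' @param tissues Tissue labels; defaults to the first `n_tissues` of
#'   rosette, root, inflorescence, pollen (extended generically if more).
#' @param planted_srna_loci Data frame of planted loci as returned by
#'   [plant_srna_loci()], or `NULL` to plant `n_planted_loci` defaults.
#' @param n_planted_loci Number of default planted loci when
#'   `planted_srna_loci` is `NULL`.
#' @param srna_library_size Total mapped 20-24-nt reads per library (the
#'   RPM denominator); listed reads are the locus-associated and background
#'   fraction of this total.
#' @param srna_noise_reads Scattered background singleton reads per
#'   library. At the default library size a singleton island is 1 RPM,
#'   below the 2-RPM cluster floor.
#' @param annotation_params List: `n_genes`, `n_tes`, `n_te_contained`
#'   (genes planted fully inside TE bodies), `te_superfamily_probs`.
#' @param methylation_params List of per-context mean levels (`cg`, `chg`,
#'   `chh`, each in `[0,1]`) for `te`, `gene` and `background` compartments,
#'   plus `mean_depth` and `n_sites`.
#' @param expression_params List: `n_genes`, `tissues`, `n_replicates`,
#'   `library_size`, `dispersion`, `n_single_tissue`, `n_uniform`,
#'   `low_coverage_tissues` (library size divided by
#'   `low_coverage_factor`).
#' @param contig_params List: `true_genome_size`, `duplicated_fraction`,
#'   `n_contigs`, `depth_single`, `depth_duplicated`, `depth_cv`.
#' @param kmer_params List: `peak_depth`, `genome_size`, `error_kmers`.
#' @param ld_params List: `decay_scale` (bp), `n_samples`, `n_markers`,
#'   `region_length`.
#'
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L,
                       genome = c(Scaffold_1 = 2e6, Scaffold_2 = 2e6),
                       n_tissues = 4L,
                       n_replicates_per_tissue = 3L,
                       tissues = NULL,
                       planted_srna_loci = NULL,
                       n_planted_loci = 200L,
                       srna_library_size = 1e6,
                       srna_noise_reads = 2000L,
                       annotation_params = list(),
                       methylation_params = list(),
                       expression_params = list(),
                       contig_params = list(),
                       kmer_params = list(),
                       ld_params = list()) {
  if (is.null(names(genome)) || any(!nzchar(names(genome)))) {
    stop("`genome` must be a named vector of scaffold lengths")
  }
  if (any(genome <= 0)) stop("zero-length scaffold rejected: all scaffold lengths must be > 0")
  n_tissues <- as.integer(n_tissues)
  if (is.null(tissues)) {
    base <- c("rosette", "root", "inflorescence", "pollen")
    tissues <- if (n_tissues <= length(base)) base[seq_len(n_tissues)] else
      c(base, paste0("tissue_", seq_len(n_tissues - length(base))))
  }
  stopifnot(length(tissues) == n_tissues, n_replicates_per_tissue >= 1)

  ap <- utils::modifyList(list(
    n_genes = 400L, n_tes = 700L, n_te_contained = 5L,
    te_superfamily_probs = c(Gypsy = 0.50, Copia = 0.15, LINE = 0.08,
                             Helitron = 0.08, MuLE = 0.09, other = 0.10)
  ), annotation_params)
  mp <- utils::modifyList(list(
    te = c(cg = 0.90, chg = 0.60, chh = 0.35),
    gene = c(cg = 0.04, chg = 0.03, chh = 0.02),
    background = c(cg = 0.40, chg = 0.20, chh = 0.08),
    mean_depth = 8, n_sites = 150000L
  ), methylation_params)
  ep <- utils::modifyList(list(
    n_genes = 1500L,
    tissues = c("shoot", "root", "rosette_leaf", "cauline_leaf",
                "inflorescence", "open_flower", "young_green_silique",
                "seed_pod", "green_seed", "mature_seed", "old_green_silique"),
    n_replicates = 3L, library_size = 2e6, dispersion = 0.05,
    n_single_tissue = 100L, n_uniform = 100L,
    low_coverage_tissues = c("mature_seed", "old_green_silique"),
    low_coverage_factor = 20
  ), expression_params)
  cp <- utils::modifyList(list(
    true_genome_size = 5e6, duplicated_fraction = 0.30, n_contigs = 150L,
    depth_single = 30, depth_duplicated = 15, depth_cv = 0.08
  ), contig_params)
  kp <- utils::modifyList(list(
    peak_depth = 30L, genome_size = 5e6, error_kmers = 2e6
  ), kmer_params)
  lp <- utils::modifyList(list(
    decay_scale = 2000, n_samples = 40L, n_markers = 2000L,
    region_length = 2e6
  ), ld_params)
  if (cp$duplicated_fraction < 0 || cp$duplicated_fraction >= 1) {
    stop("contig_params$duplicated_fraction must be in [0, 1)")
  }
  for (comp in c("te", "gene", "background")) {
    if (any(mp[[comp]] < 0 | mp[[comp]] > 1)) {
      stop("methylation context means must lie in [0, 1]")
    }
  }

  cfg <- structure(list(
    seed = as.integer(seed), genome = genome,
    n_tissues = n_tissues, tissues = tissues,
    n_replicates_per_tissue = as.integer(n_replicates_per_tissue),
    srna_library_size = srna_library_size,
    srna_noise_reads = as.integer(srna_noise_reads),
    annotation_params = ap, methylation_params = mp,
    expression_params = ep, contig_params = cp,
    kmer_params = kp, ld_params = lp
  ), class = "sim_config")

  cfg$planted_srna_loci <- if (is.null(planted_srna_loci)) {
    plant_srna_loci(cfg, n = n_planted_loci)
  } else {
    validate_planted_loci(planted_srna_loci, genome)
    planted_srna_loci
  }
  cfg
}

validate_planted_loci <- function(loci, genome) {
  .stopifnot_cols(loci, c("locus_id", "scaffold", "start", "end", "size_class",
                          "phased", "register", "tissues", "abundance_rpm",
                          "five_prime_u"), "planted locus table")
  if (any(loci$end <= loci$start)) stop("planted locus with end <= start")
  if (any(loci$abundance_rpm <= 0)) stop("planted locus abundance must be > 0")
  if (any(!loci$register %in% c(21L, 24L))) stop("phasing register must be 21 or 24")
  if (any(!loci$scaffold %in% names(genome))) {
    stop("planted locus outside scaffold bounds: unknown scaffold")
  }
  bad <- loci$end > genome[loci$scaffold] | loci$start < 0
  if (any(bad)) stop("planted locus outside scaffold bounds")
  invisible(TRUE)
}

#' Plant a default set of sRNA loci
#'
#' Draws `n` non-overlapping planted loci over the configured genome:
#' roughly 90% heterochromatic 23-24-nt loci and 10% 20-22-nt loci, a
#' phased subset (register 24 dominant, a few register 21), tissue
#' expression patterns ranging from all-tissue to tissue-private, and
#' log-uniform abundance between 8 and 50 RPM. A strong 5'-U bias is
#' planted for the 20-22-nt class.
#'
#' @param config A [sim_config()] object (only `seed`, `genome` and
#'   `tissues` are used).
#' @param n Number of loci.
#' @return Data frame with one row per planted locus (0-based half-open
#'   coordinates) and a `tissues` column of comma-separated labels.
#' @export
plant_srna_loci <- function(config, n = 200L) {
  empty <- data.frame(locus_id = character(0), scaffold = character(0),
                      start = integer(0), end = integer(0),
                      size_class = character(0), phased = logical(0),
                      register = integer(0), tissues = character(0),
                      abundance_rpm = numeric(0), five_prime_u = numeric(0),
                      stringsAsFactors = FALSE)
  if (n <= 0) return(empty)
  with_stream(config$seed, 11L, {
    genome <- config$genome
    tissues <- config$tissues
    n <- as.integer(n)
    scaf <- sample(names(genome), n, replace = TRUE,
                   prob = genome / sum(genome))
    len <- sample(100:300, n, replace = TRUE)
    start <- floor(runif(n, 0, genome[scaf] - len - 1))
    # resolve overlaps per scaffold by nudging onto a sorted grid
    ord <- order(scaf, start)
    scaf <- scaf[ord]; len <- len[ord]; start <- start[ord]
    for (s in names(genome)) {
      i <- which(scaf == s)
      if (length(i) < 2) next
      for (k in seq(2, length(i))) {
        lo <- start[i[k - 1]] + len[i[k - 1]] + 200
        if (start[i[k]] < lo) start[i[k]] <- lo
      }
      keep_ok <- start[i] + len[i] <= genome[s]
      # drop any pushed off the end by marking zero-length (filtered below)
      len[i][!keep_ok] <- 0L
    }
    keep <- len > 0
    scaf <- scaf[keep]; start <- start[keep]; len <- len[keep]
    n <- length(scaf)

    size_class <- sample(c("23-24", "20-22"), n, replace = TRUE,
                         prob = c(0.9, 0.1))
    phased <- rep(FALSE, n)
    phased[sample.int(n, max(1L, round(0.1 * n)))] <- TRUE
    register <- ifelse(size_class == "23-24", 24L, 21L)
    # tissue patterns: all tissues, private, or a random pair
    pattern <- sample(c("all", "private", "pair"), n, replace = TRUE,
                      prob = c(0.4, 0.3, 0.3))
    tiss <- vapply(seq_len(n), function(i) {
      switch(pattern[i],
        all = paste(tissues, collapse = ","),
        private = sample(tissues, 1),
        pair = paste(sort(sample(tissues, min(2L, length(tissues)))),
                     collapse = ","))
    }, character(1))
    abundance <- exp(runif(n, log(8), log(50)))
    five_prime_u <- ifelse(size_class == "20-22", 0.85, 0.45)
    data.frame(
      locus_id = sprintf("planted_%04d", seq_len(n)),
      scaffold = scaf, start = as.integer(start),
      end = as.integer(start + len),
      size_class = size_class, phased = phased, register = register,
      tissues = tiss, abundance_rpm = abundance,
      five_prime_u = five_prime_u,
      row.names = NULL, stringsAsFactors = FALSE
    )
  })
}
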