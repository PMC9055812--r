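#' Generate contig table, k-mer histogram and genotype matrix
#'
#' Three assembly-QC / population-genetic inputs with recorded truth:
#'
#' * a contig depth table drawn from a two-mode mixture (a duplicated
#'   fraction at roughly half depth), with BUSCO labels such that some
#'   single-status BUSCOs sit on low-depth contigs (the hard case for the
#'   purge walk);
#' * a k-mer histogram with an error spike at multiplicity 1 and a main
#'   Poisson-shaped peak at the configured depth plus a smaller
#'   two-copy shoulder;
#' * a genotype dosage matrix whose pairwise correlation decays
#'   exponentially with distance at the configured scale (binary Markov
#'   haplotypes at allele frequency 1/2, two haplotypes per sample).
#'
#' @param config A [sim_config()] object (see `contig_params`,
#'   `kmer_params`, `ld_params`).
#' @return List: `contigs` (data frame with truth column `duplicated`),
#'   `kmers` (data frame multiplicity/count), `genotypes` (list `markers`,
#'   `dosage`), `truth` (list: `duplicated_contigs`, `kmer_genome_size`,
#'   `ld_decay_scale`).
#' @export
gen_contigs_kmers_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cp <- config$contig_params
  kp <- config$kmer_params
  lp <- config$ld_params
  with_stream(config$seed, 6L, {
    ## contigs ---------------------------------------------------------
    n <- cp$n_contigs
    dup <- stats::runif(n) < cp$duplicated_fraction
    # lengths sum roughly to true size + duplicated excess
    len <- as.integer(stats::rlnorm(n, log(cp$true_genome_size / n), 0.5))
    depth_mean <- ifelse(dup, cp$depth_duplicated, cp$depth_single)
    depth <- stats::rnorm(n, depth_mean, depth_mean * cp$depth_cv)
    busco_single <- rep(FALSE, n)
    # unique BUSCOs live on non-duplicated contigs, including some whose
    # depth falls on the low side of the single-copy mode
    singles <- which(!dup)
    busco_single[sample(singles, max(1L, round(0.3 * length(singles))))] <- TRUE
    # a few genuinely single-copy contigs with low coverage: they sit in
    # the purge walk's removal zone and must be skipped, not removed
    low_cov <- sample(which(busco_single), min(3L, sum(busco_single)))
    depth[low_cov] <- stats::rnorm(length(low_cov), cp$depth_duplicated,
                                   cp$depth_duplicated * cp$depth_cv)
    contigs <- data.frame(
      contig = sprintf("tig%04d", seq_len(n)),
      length = len, depth = depth, busco_single = busco_single,
      duplicated = dup, stringsAsFactors = FALSE)

    ## k-mer histogram -------------------------------------------------
    peak <- kp$peak_depth
    mult <- 1:(4 * peak)
    main <- stats::dpois(mult, peak) * kp$genome_size * 0.8
    two_copy <- stats::dpois(mult, 2 * peak) * kp$genome_size * 0.1
    err <- kp$error_kmers * exp(-(mult - 1))
    kmers <- data.frame(multiplicity = mult,
                        count = round(err + main + two_copy))

    ## genotypes -------------------------------------------------------
    m <- lp$n_markers
    ns <- lp$n_samples
    pos <- sort(sample.int(lp$region_length, m))
    markers <- data.frame(scaffold = "Scaffold_1", position = pos,
                          stringsAsFactors = FALSE)
    gap <- diff(pos)
    keep_p <- (1 + exp(-gap / lp$decay_scale)) / 2  # per-step copy prob
    hap <- function() {
      h <- matrix(0L, nrow = m, ncol = ns)
      h[1, ] <- stats::rbinom(ns, 1, 0.5)
      for (k in 2:m) {
        same <- stats::runif(ns) < keep_p[k - 1]
        h[k, ] <- ifelse(same, h[k - 1, ], 1L - h[k - 1, ])
      }
      h
    }
    dosage <- hap() + hap()
    colnames(dosage) <- sprintf("acc%02d", seq_len(ns))

    list(contigs = contigs, kmers = kmers,
         genotypes = list(markers = markers, dosage = dosage),
         truth = list(duplicated_contigs = contigs$contig[dup],
                      kmer_genome_size = kp$genome_size,
                      ld_decay_scale = lp$decay_scale))
  })
}
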