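#' k-mer genome-size estimation
#'
#' Separates the sequencing-error spike from the main coverage peak at the
#' first local minimum of the histogram (or an explicit cutoff), takes the
#' peak as the multiplicity with maximal count above that valley, and
#' estimates genome size as total retained k-mers divided by the peak
#' depth. The single-copy fraction is the retained k-mer mass with
#' multiplicity within `[peak/2, 3*peak/2]`.
#'
#' @param histogram Data frame (`multiplicity`, `count`).
#' @param error_cutoff Multiplicities strictly below this are discarded as
#'   sequencing errors; `NULL` finds the first local minimum
#'   automatically.
#' @return List: `genome_size` (bp, floored), `peak_depth`,
#'   `total_kmers` (retained), `single_copy_fraction`, `error_cutoff`.
#' @export
kmer_genome_size <- function(histogram, error_cutoff = NULL) {
  h <- histogram[order(histogram$multiplicity), , drop = FALSE]
  if (anyDuplicated(h$multiplicity)) stop("duplicate multiplicities in histogram")
  m <- h$multiplicity; cnt <- as.numeric(h$count)
  if (is.null(error_cutoff)) {
    # first local minimum of counts along multiplicity
    valley <- NA_integer_
    for (i in seq(2, length(cnt) - 1)) {
      if (cnt[i] <= cnt[i - 1] && cnt[i] < cnt[i + 1]) { valley <- i; break }
    }
    if (is.na(valley)) {
      stop("no interior error/coverage valley found; supply error_cutoff")
    }
    error_cutoff <- m[valley]
  }
  keep <- m >= error_cutoff
  if (!any(keep) || all(cnt[keep] == 0)) stop("no retained k-mer mass above cutoff")
  peak <- m[keep][which.max(cnt[keep])]
  total <- sum(m[keep] * cnt[keep])
  sc <- m >= peak / 2 & m <= 3 * peak / 2 & keep
  list(genome_size = floor(total / peak), peak_depth = peak,
       total_kmers = total,
       single_copy_fraction = sum(m[sc] * cnt[sc]) / total,
       error_cutoff = error_cutoff)
}

#' Contig read-depth modes
#'
#' Length-weighted kernel density of per-contig mean depth; reports local
#' maxima and, when bimodal, the contig-length fraction below the
#' inter-mode valley (the putatively duplicated mass at ~half depth).
#'
#' @param table Contig data frame (`contig`, `length`, `depth`).
#' @param bw Kernel bandwidth passed to [stats::density()]; the default
#'   widens the unweighted normal-reference bandwidth slightly, since
#'   [stats::density()] ignores weights when choosing an automatic
#'   bandwidth.
#' @param min_separation Minimum depth separation between reported modes
#'   (local maxima closer than this to a taller mode are smoothing
#'   artefacts and are dropped); defaults to a tenth of the depth range.
#' @return List: `modes` (depth locations of local maxima, tallest
#'   first), `duplicated_mass` (length fraction below the valley; 0 when
#'   unimodal), `valley` (`NA` when unimodal).
#' @export
depth_modes <- function(table, bw = NULL, min_separation = NULL) {
  stopifnot(nrow(table) >= 10)
  w <- table$length / sum(table$length)
  if (is.null(bw)) bw <- 1.5 * stats::bw.nrd0(table$depth)
  if (is.null(min_separation)) min_separation <- diff(range(table$depth)) / 10
  dens <- stats::density(table$depth, weights = w, bw = bw)
  y <- dens$y; x <- dens$x
  i <- which(diff(sign(diff(y))) == -2) + 1L
  if (!length(i)) i <- which.max(y)
  # keep modes in height order, dropping any within min_separation of a
  # taller, already-kept mode
  i <- i[order(y[i], decreasing = TRUE)]
  kept <- integer(0)
  for (k in i) {
    if (!length(kept) || all(abs(x[k] - x[kept]) >= min_separation)) {
      kept <- c(kept, k)
    }
  }
  modes <- x[kept]
  if (length(modes) >= 2) {
    # the valley must be genuinely lower than the smaller of the two top
    # modes, otherwise the split is a smoothing ripple and the
    # distribution is effectively unimodal
    rng <- sort(modes[1:2])
    between <- x > rng[1] & x < rng[2]
    valley <- x[between][which.min(y[between])]
    y_valley <- min(y[between])
    y_low_mode <- min(y[kept[1]], y[kept[2]])
    if (y_valley < 0.5 * y_low_mode) {
      return(list(modes = modes,
                  duplicated_mass = sum(w[table$depth < valley]),
                  valley = valley))
    }
  }
  list(modes = modes[1], duplicated_mass = 0, valley = NA_real_)
}

#' Greedy duplicate-contig purge with BUSCO protection
#'
#' Contigs are walked in ascending read-depth order (ties broken by
#' descending length, then id) and consecutively removed until the
#' retained assembly length falls within `tolerance` of the target genome
#' size. A contig carrying a non-duplicated ("single") BUSCO gene is never
#' removed: the walk skips it and discards the next unprotected contig
#' with lowest depth instead. If the protected length alone exceeds the
#' budget the walk stops with a warning, returning all protected contigs
#' plus the minimal unprotected tail.
#'
#' @param table Contig data frame (`contig`, `length`, `depth`,
#'   `busco_single` logical: carries at least one single-status BUSCO).
#' @param target_size Estimated genome size (bp).
#' @param tolerance Retained length budget is `target_size * (1 +
#'   tolerance)`.
#' @return List: `kept`, `removed` (contig ids), `report` (retained and
#'   removed length, budget, `protected_overflow` flag).
#' @export
purge_duplicates <- function(table, target_size, tolerance = 0.02) {
  stopifnot(target_size > 0)
  budget <- target_size * (1 + tolerance)
  ord <- order(table$depth, -table$length, table$contig)
  t2 <- table[ord, , drop = FALSE]
  retained <- sum(t2$length)
  removed <- logical(nrow(t2))
  for (i in seq_len(nrow(t2))) {
    if (retained <= budget) break
    if (isTRUE(t2$busco_single[i])) next
    removed[i] <- TRUE
    retained <- retained - t2$length[i]
  }
  overflow <- retained > budget
  if (overflow) {
    warning("protected (single-BUSCO) length alone exceeds the size budget")
  }
  list(kept = sort(t2$contig[!removed]), removed = sort(t2$contig[removed]),
       report = list(retained_length = retained,
                     removed_length = sum(t2$length[removed]),
                     budget = budget, protected_overflow = overflow))
}
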