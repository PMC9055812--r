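#' Reads-per-million normalization
#'
#' @param count Read count (>= 0).
#' @param library_total Total mapped reads in the library (> 0).
#' @return `count * 1e6 / library_total`.
#' @export
rpm_normalize <- function(count, library_total) {
  if (any(library_total <= 0)) stop("library_total must be > 0")
  if (any(count < 0)) stop("count must be >= 0")
  count * 1e6 / library_total
}

#' De-novo sRNA cluster discovery in one library
#'
#' Merges reads whose gaps are at most `island_pad` nt into islands and
#' keeps islands whose copy-weighted abundance reaches `min_rpm` reads per
#' million mapped reads. Coordinates are 0-based half-open.
#'
#' @param library sRNA library object (fields `reads`,
#'   `total_mapped_reads`; see [gen_srna_libraries()]).
#' @param min_rpm Minimum island expression (RPM).
#' @param island_pad Maximum gap (nt) merged within an island.
#' @return Data frame of non-overlapping, sorted clusters: `scaffold`,
#'   `start`, `end`, `reads` (copy-weighted), `rpm`.
#' @export
discover_clusters <- function(library, min_rpm = 2.0, island_pad = 75L) {
  rd <- library$reads
  total <- library$total_mapped_reads
  if (is.null(rd) || !nrow(rd)) {
    return(data.frame(scaffold = character(0), start = integer(0),
                      end = integer(0), reads = integer(0), rpm = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out <- lapply(split(rd, rd$scaffold), function(d) {
    ir <- .ir(d$start, d$end)
    isl <- IRanges::reduce(ir, min.gapwidth = island_pad + 1L)
    hit <- IRanges::findOverlaps(ir, isl)
    cnt <- rowsum(d$count[S4Vectors::queryHits(hit)],
                  S4Vectors::subjectHits(hit))
    n <- integer(length(isl))
    n[as.integer(rownames(cnt))] <- as.integer(cnt[, 1])
    df <- .from_ir(isl)
    data.frame(scaffold = d$scaffold[1], start = df$start, end = df$end,
               reads = n, rpm = rpm_normalize(n, total),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[out$rpm >= min_rpm, , drop = FALSE]
  out <- out[order(out$scaffold, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Multi-library, multi-tissue consensus sRNA loci
#'
#' Per tissue, a per-base multi-intersection keeps intervals covered by
#' clusters from at least `min_libraries` of that tissue's libraries;
#' surviving per-tissue loci separated by gaps of at most `merge_gap` nt
#' are padded together; per-tissue loci whose maximum expression across
#' that tissue's libraries stays below `min_rpm_rescue` RPM are removed.
#' A final cross-tissue merge unions overlapping per-tissue loci and
#' records every contributing tissue.
#'
#' @param clusters_by_library Named list (library id -> cluster data frame
#'   from [discover_clusters()]).
#' @param tissue_map Named character vector: library id -> tissue label.
#' @param min_libraries Minimum supporting libraries within a tissue.
#' @param merge_gap Maximum per-tissue gap (nt) padded together.
#' @param min_rpm_rescue Per-tissue expression floor (max RPM over the
#'   tissue's libraries).
#' @return Data frame of consensus loci: `scaffold`, `start`, `end`,
#'   `tissues` (comma-separated), `tissue_max_rpm` (comma-separated,
#'   aligned with `tissues`), `max_rpm`.
#' @export
consensus_loci <- function(clusters_by_library, tissue_map,
                           min_libraries = 3L, merge_gap = 25L,
                           min_rpm_rescue = 0.5) {
  stopifnot(all(names(clusters_by_library) %in% names(tissue_map)))
  tissues <- unique(unname(tissue_map[names(clusters_by_library)]))
  per_tissue <- list()

  for (t in tissues) {
    lib_ids <- names(clusters_by_library)[tissue_map[names(clusters_by_library)] == t]
    if (length(lib_ids) < min_libraries) {
      warning(sprintf("tissue '%s' has %d libraries (< min_libraries = %d); no loci",
                      t, length(lib_ids), min_libraries))
      next
    }
    scafs <- unique(unlist(lapply(clusters_by_library[lib_ids],
                                  function(d) d$scaffold)))
    rows <- list()
    for (s in scafs) {
      covs <- lapply(lib_ids, function(id) {
        d <- clusters_by_library[[id]]
        d <- d[d$scaffold == s, , drop = FALSE]
        IRanges::coverage(.ir(d$start, d$end))
      })
      len <- max(vapply(covs, length, integer(1)))
      total_cov <- Reduce(`+`, lapply(covs, function(x) {
        if (length(x) < len) c(x, S4Vectors::Rle(0L, len - length(x))) else x
      }))
      hi <- IRanges::slice(total_cov, lower = min_libraries, rangesOnly = TRUE)
      if (!length(hi)) next
      merged <- IRanges::reduce(hi, min.gapwidth = merge_gap + 1L)
      df <- .from_ir(merged)
      # per-library expression of each locus: summed RPM of overlapping clusters
      rpm_mat <- vapply(lib_ids, function(id) {
        d <- clusters_by_library[[id]]
        d <- d[d$scaffold == s, , drop = FALSE]
        if (!nrow(d)) return(numeric(length(merged)))
        hit <- IRanges::findOverlaps(.ir(d$start, d$end), merged)
        out <- numeric(length(merged))
        if (length(hit)) {
          agg <- rowsum(d$rpm[S4Vectors::queryHits(hit)], S4Vectors::subjectHits(hit))
          out[as.integer(rownames(agg))] <- agg[, 1]
        }
        out
      }, numeric(length(merged)))
      rpm_mat <- matrix(rpm_mat, nrow = length(merged))
      max_rpm <- apply(rpm_mat, 1, max)
      keep <- max_rpm >= min_rpm_rescue
      if (!any(keep)) next
      rows[[s]] <- data.frame(scaffold = s, start = df$start[keep],
                              end = df$end[keep], tissue = t,
                              rpm = max_rpm[keep], stringsAsFactors = FALSE)
    }
    if (length(rows)) per_tissue[[t]] <- do.call(rbind, rows)
  }

  if (!length(per_tissue)) {
    return(data.frame(scaffold = character(0), start = integer(0),
                      end = integer(0), tissues = character(0),
                      tissue_max_rpm = character(0), max_rpm = numeric(0),
                      stringsAsFactors = FALSE))
  }
  all_t <- do.call(rbind, unname(per_tissue))

  out <- lapply(split(all_t, all_t$scaffold), function(d) {
    merged <- IRanges::reduce(.ir(d$start, d$end))
    hit <- IRanges::findOverlaps(.ir(d$start, d$end), merged)
    df <- .from_ir(merged)
    tis <- character(length(merged)); trpm <- character(length(merged))
    mx <- numeric(length(merged))
    for (i in seq_along(merged)) {
      q <- S4Vectors::queryHits(hit)[S4Vectors::subjectHits(hit) == i]
      ord <- order(d$tissue[q])
      # one value per tissue: max rpm of that tissue's contributing loci
      agg <- vapply(split(d$rpm[q], d$tissue[q]), max, numeric(1))
      tis[i] <- paste(names(agg), collapse = ",")
      trpm[i] <- paste(sprintf("%.4g", unname(agg)), collapse = ",")
      mx[i] <- max(agg)
    }
    data.frame(scaffold = d$scaffold[1], start = df$start, end = df$end,
               tissues = tis, tissue_max_rpm = trpm, max_rpm = mx,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$scaffold, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify a locus by read size class, complexity and 5' nucleotide
#'
#' Size class is 23-24 when at least `dominance` of the copy-weighted read
#' mass has length 23-24, 20-22 when at least `dominance` has length
#' 20-22, and mixed otherwise. Complexity is the number of distinct
#' (start, length, strand) read positions divided by the total read
#' copies. The 5' nucleotide frequencies are copy-weighted.
#'
#' @param reads Data frame of locus reads (`start`, `end`, `length`,
#'   `strand`, `count`, `five_prime`).
#' @param dominance Size-class dominance threshold.
#' @return List: `size_class`, `complexity`, `five_prime_freq` (named
#'   A/C/G/U vector summing to 1).
#' @export
classify_locus <- function(reads, dominance = 0.8) {
  if (is.null(reads) || !nrow(reads)) stop("classify_locus: zero reads")
  w <- reads$count
  mass <- sum(w)
  m2324 <- sum(w[reads$length >= 23 & reads$length <= 24]) / mass
  m2022 <- sum(w[reads$length >= 20 & reads$length <= 22]) / mass
  size_class <- if (m2324 >= dominance) "23-24" else
    if (m2022 >= dominance) "20-22" else "mixed"
  distinct <- nrow(unique(reads[, c("start", "length", "strand")]))
  complexity <- distinct / mass
  fp <- vapply(c(A = "A", C = "C", G = "G", U = "U"),
               function(nt) sum(w[reads$five_prime == nt]), numeric(1))
  fp <- fp / mass
  list(size_class = size_class, complexity = complexity, five_prime_freq = fp)
}

#' Phasing score for a locus
#'
#' Tests whether register-length read 5' ends accumulate in one phase of
#' the register. The score is the largest fraction of 5' ends falling in a
#' single register offset; its p-value is the binomial tail of the best
#' offset under a uniform-offset null, Bonferroni-corrected by the
#' register. A locus is called phased when the corrected p-value is below
#' `alpha` and the score reaches `min_score`.
#'
#' @param reads Locus read data frame (`start`, `length`, `count`).
#' @param register Phase length (21 or 24).
#' @param min_reads Minimum copy-weighted register-length reads; below it
#'   the locus is reported unphased with a reason code, not an error.
#' @param alpha,min_score Call thresholds.
#' @param origin Phase origin (defaults to the leftmost register-length
#'   read 5' end).
#' @return List: `score`, `p_value`, `phased`, `n_reads`, `reason`.
#' @export
phase_score <- function(reads, register = 24L, min_reads = 10L,
                        alpha = 0.05, min_score = 0.5, origin = NULL) {
  stopifnot(register %in% c(21L, 24L))
  rd <- reads[reads$length == register, , drop = FALSE]
  n <- if (nrow(rd)) sum(rd$count) else 0L
  if (n < min_reads) {
    return(list(score = NA_real_, p_value = NA_real_, phased = FALSE,
                n_reads = n, reason = "too_few_reads"))
  }
  if (is.null(origin)) origin <- min(rd$start)
  off <- (rd$start - origin) %% register
  tab <- rowsum(rd$count, off)
  best <- max(tab[, 1])
  score <- best / n
  p <- stats::pbinom(best - 1, n, 1 / register, lower.tail = FALSE)
  p <- min(1, p * register)
  list(score = score, p_value = p, phased = (p < alpha && score >= min_score),
       n_reads = n, reason = NA_character_)
}

#' Tabulate locus sharing across tissues
#'
#' @param loci Consensus locus data frame (column `tissues`,
#'   comma-separated labels).
#' @return List: `by_subset` (counts per tissue subset, names are sorted
#'   comma-joined labels), `private` (per-tissue private counts),
#'   `shared_all` (count present in every tissue), `n_tissues`, `total`.
#' @export
tissue_partition <- function(loci) {
  sets <- strsplit(loci$tissues, ",", fixed = TRUE)
  keys <- vapply(sets, function(x) paste(sort(x), collapse = ","), character(1))
  by_subset <- table(keys)
  all_tissues <- sort(unique(unlist(sets)))
  private <- vapply(all_tissues, function(t) sum(keys == t), integer(1))
  shared_all <- sum(keys == paste(all_tissues, collapse = ","))
  list(by_subset = as.list(by_subset), private = private,
       shared_all = shared_all, n_tissues = length(all_tissues),
       total = nrow(loci))
}

#' Annotate consensus loci with read-derived metrics
#'
#' Pools reads from all libraries over each consensus locus and attaches
#' size class, complexity, 5' nucleotide frequencies and the phasing
#' result for the register matching the locus size class (24 for 23-24
#' and mixed loci, 21 for 20-22 loci).
#'
#' @param loci Consensus loci ([consensus_loci()]).
#' @param libraries List of sRNA library objects.
#' @param ... Passed to [phase_score()].
#' @return `loci` with columns `size_class`, `complexity`, `fp_A`, `fp_C`,
#'   `fp_G`, `fp_U`, `phase_register`, `phase_score`, `phase_p`, `phased`.
#' @export
annotate_loci <- function(loci, libraries, ...) {
  if (!nrow(loci)) return(loci)
  pooled <- do.call(rbind, lapply(libraries, function(l) l$reads))
  res <- vector("list", nrow(loci))
  for (i in seq_len(nrow(loci))) {
    sel <- pooled$scaffold == loci$scaffold[i] &
      pooled$start < loci$end[i] & pooled$end > loci$start[i]
    rd <- pooled[sel, , drop = FALSE]
    if (!nrow(rd)) {
      res[[i]] <- data.frame(size_class = NA_character_, complexity = NA_real_,
                             fp_A = NA_real_, fp_C = NA_real_, fp_G = NA_real_,
                             fp_U = NA_real_, phase_register = NA_integer_,
                             phase_score = NA_real_, phase_p = NA_real_,
                             phased = FALSE)
      next
    }
    cl <- classify_locus(rd)
    reg <- if (cl$size_class == "20-22") 21L else 24L
    ph <- phase_score(rd, register = reg, ...)
    res[[i]] <- data.frame(size_class = cl$size_class,
                           complexity = cl$complexity,
                           fp_A = cl$five_prime_freq[["A"]],
                           fp_C = cl$five_prime_freq[["C"]],
                           fp_G = cl$five_prime_freq[["G"]],
                           fp_U = cl$five_prime_freq[["U"]],
                           phase_register = reg,
                           phase_score = ph$score, phase_p = ph$p_value,
                           phased = ph$phased)
  }
  cbind(loci, do.call(rbind, res))
}

#' Run the full consensus pipeline on a set of libraries
#'
#' Convenience wrapper: per-library cluster discovery followed by the
#' multi-tissue consensus.
#'
#' @param libraries List of sRNA library objects.
#' @param min_rpm,island_pad Per-library discovery thresholds.
#' @param ... Passed to [consensus_loci()].
#' @return Consensus locus data frame.
#' @export
srna_pipeline <- function(libraries, min_rpm = 2.0, island_pad = 75L, ...) {
  clusters <- lapply(libraries, discover_clusters,
                     min_rpm = min_rpm, island_pad = island_pad)
  tissue_map <- vapply(libraries, function(l) l$tissue, character(1))
  names(tissue_map) <- names(clusters) <- vapply(libraries, function(l) l$library_id,
                                                character(1))
  consensus_loci(clusters, tissue_map, ...)
}
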