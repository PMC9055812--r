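#' Per-window feature density tracks
#'
#' Tiling windows per scaffold (last window truncated); each feature is
#' counted once, in the window containing its midpoint.
#'
#' @param features Data frame (`scaffold`, `start`, `end`, `type`;
#'   0-based half-open).
#' @param genome Named vector of scaffold lengths.
#' @param window Window size (bp).
#' @return Data frame: `scaffold`, `window_start`, `window_end`, one count
#'   column per feature type.
#' @export
density_tracks <- function(features, genome, window = 1e6) {
  stopifnot(window > 0)
  types <- sort(unique(features$type))
  rows <- lapply(names(genome), function(s) {
    L <- genome[[s]]
    n_win <- max(1L, ceiling(L / window))
    ws <- (seq_len(n_win) - 1) * window
    d <- features[features$scaffold == s, , drop = FALSE]
    mid <- (d$start + d$end) / 2
    idx <- pmin(floor(mid / window) + 1L, n_win)
    counts <- sapply(types, function(ty) {
      tabulate(idx[d$type == ty], nbins = n_win)
    })
    counts <- matrix(counts, nrow = n_win, dimnames = list(NULL, types))
    data.frame(scaffold = s, window_start = ws,
               window_end = pmin(ws + window, L), counts,
               check.names = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Partition windows into gene-enriched and gene-depleted
#'
#' The threshold is the mean of the per-window gene counts: windows
#' strictly above the mean are labelled enriched, all others depleted.
#' The median is reported alongside.
#'
#' @param gene_counts Numeric vector of per-window gene counts.
#' @return List: `labels` (factor enriched/depleted), `mean`, `median`.
#' @export
gene_density_partition <- function(gene_counts) {
  stopifnot(length(gene_counts) >= 1)
  m <- mean(gene_counts)
  labels <- factor(ifelse(gene_counts > m, "enriched", "depleted"),
                   levels = c("enriched", "depleted"))
  list(labels = labels, mean = m, median = stats::median(gene_counts))
}

#' Assign loci to annotation classes by overlap precedence
#'
#' Each locus receives the first class in `precedence` that it overlaps by
#' at least one bp; loci overlapping nothing are intergenic.
#'
#' @param loci,annotation Data frames with `scaffold`, `start`, `end`
#'   (annotation also `type`; TE superfamilies collapse onto `"TE"`).
#' @param precedence Class order.
#' @return List: `class` (per-locus), `fractions` (per-class fractions
#'   over loci, summing to 1).
#' @export
intersect_fraction <- function(loci, annotation,
                               precedence = c("exon", "intron", "TE", "intergenic")) {
  cls <- rep("intergenic", nrow(loci))
  type <- ifelse(startsWith(annotation$type, "TE:"), "TE", annotation$type)
  for (s in unique(loci$scaffold)) {
    li <- which(loci$scaffold == s)
    ai <- which(annotation$scaffold == s)
    if (!length(li) || !length(ai)) next
    lr <- .ir(loci$start[li], loci$end[li])
    for (p in setdiff(precedence, "intergenic")) {
      sel <- ai[type[ai] == p]
      if (!length(sel)) next
      ov <- IRanges::overlapsAny(lr, .ir(annotation$start[sel], annotation$end[sel]))
      assign_now <- ov & cls[li] == "intergenic"
      # precedence: only fill loci not yet claimed by an earlier class
      cls[li][assign_now] <- p
    }
  }
  fr <- vapply(precedence, function(p) mean(cls == p), numeric(1))
  list(class = cls, fractions = fr)
}

#' Distance from each locus to the nearest target feature
#'
#' Distance is 0 for overlapping (or book-ended) intervals, otherwise the
#' gap in bp to the nearest target on the same scaffold; loci on
#' target-free scaffolds get `NA`.
#'
#' @param loci,targets Data frames with `scaffold`, `start`, `end`.
#' @param threshold Report the fraction of loci within this distance (bp).
#' @return List: `distance` (per locus), `fraction_within` (over loci with
#'   a defined distance), `n_missing`.
#' @export
distance_to_nearest <- function(loci, targets, threshold = 1500) {
  if (!nrow(targets)) stop("empty target set")
  d <- rep(NA_real_, nrow(loci))
  for (s in unique(loci$scaffold)) {
    li <- which(loci$scaffold == s)
    ti <- which(targets$scaffold == s)
    if (!length(ti)) next
    lr <- .ir(loci$start[li], loci$end[li])
    tr <- .ir(targets$start[ti], targets$end[ti])
    nt <- IRanges::distanceToNearest(lr, tr)
    d[li[S4Vectors::queryHits(nt)]] <- S4Vectors::mcols(nt)$distance
  }
  ok <- !is.na(d)
  list(distance = d,
       fraction_within = if (any(ok)) mean(d[ok] <= threshold) else NA_real_,
       n_missing = sum(!ok))
}

#' Genes contained fully within TE bodies
#'
#' A gene counts as TE-contained when its full span lies within a single
#' TE interval. The MuLE subset flags contained genes whose containing (or
#' any overlapping) TE belongs to the MuLE superfamily.
#'
#' @param genes Data frame (`scaffold`, `start`, `end`, `id`).
#' @param tes Data frame (`scaffold`, `start`, `end`, `type` like
#'   `"TE:Gypsy"` or a `superfamily` column).
#' @return List: `contained` (gene ids), `mule_intersecting` (subset).
#' @export
te_contained_genes <- function(genes, tes) {
  fam <- if ("superfamily" %in% names(tes)) tes$superfamily else
    sub("^TE:", "", tes$type)
  contained <- character(0); mule <- character(0)
  for (s in unique(genes$scaffold)) {
    gi <- which(genes$scaffold == s)
    ti <- which(tes$scaffold == s)
    if (!length(gi) || !length(ti)) next
    gr <- .ir(genes$start[gi], genes$end[gi])
    tr <- .ir(tes$start[ti], tes$end[ti])
    hit <- IRanges::findOverlaps(gr, tr, type = "within")
    inside <- unique(S4Vectors::queryHits(hit))
    contained <- c(contained, genes$id[gi[inside]])
    if (length(inside)) {
      any_hit <- IRanges::findOverlaps(gr[inside], tr)
      is_mule <- fam[ti[S4Vectors::subjectHits(any_hit)]] == "MuLE"
      mule_q <- unique(S4Vectors::queryHits(any_hit)[is_mule])
      mule <- c(mule, genes$id[gi[inside[mule_q]]])
    }
  }
  list(contained = sort(unique(contained)),
       mule_intersecting = sort(unique(mule)))
}

# A segment [i..j] in gene-index space is admissible when it carries at
# least min_run labelled genes and its majority label reaches
# 1 - max_dissent of the labelled genes.
.seg_ok <- function(lab_counts_prefix, i, j, min_run, max_dissent) {
  cnt <- lab_counts_prefix[j + 1L, ] - lab_counts_prefix[i, ]
  tot <- sum(cnt)
  if (tot < min_run) return(NULL)
  mx <- max(cnt)
  if (mx / tot < 1 - max_dissent) return(NULL)
  list(total = tot, label = colnames(lab_counts_prefix)[which.max(cnt)])
}

#' Paint ancestral karyotype blocks along a gene order
#'
#' Segments each scaffold's gene order into ancestral-karyotype blocks
#' from per-gene ortholog block labels: admissible segments carry at least
#' `min_run` labelled genes with a majority label of frequency at least
#' `1 - max_dissent`; unlabelled genes never break a run. Among all
#' admissible segmentations the one covering the most labelled genes is
#' chosen (dynamic programme, exact); segment ends are trimmed to labelled
#' genes.
#'
#' @param gene_order Data frame: `scaffold`, `gene_index` (position order
#'   within scaffold), optional `id`.
#' @param labels Character vector of block labels (A-X), `NA` where the
#'   gene has no ortholog label.
#' @param min_run Minimum labelled genes per segment.
#' @param max_dissent Maximum dissenting labelled-gene fraction.
#' @return Data frame of segments: `scaffold`, `from_index`, `to_index`
#'   (inclusive gene indices), `block`, `n_labelled`, `n_majority`.
#' @export
assign_ancestral_blocks <- function(gene_order, labels, min_run = 5L,
                                    max_dissent = 0.2) {
  stopifnot(nrow(gene_order) == length(labels))
  out <- list()
  for (s in unique(gene_order$scaffold)) {
    sel <- gene_order$scaffold == s
    ord <- order(gene_order$gene_index[sel])
    idx <- gene_order$gene_index[sel][ord]
    lab <- labels[sel][ord]
    n <- length(lab)
    lvls <- sort(unique(lab[!is.na(lab)]))
    if (!length(lvls)) next
    onehot <- vapply(lvls, function(l) cumsum(!is.na(lab) & lab == l),
                     numeric(n))
    prefix <- rbind(0, matrix(onehot, nrow = n, dimnames = list(NULL, lvls)))

    # dp over positions: best labelled coverage using genes 1..j
    dp <- numeric(n + 1L)
    choice <- vector("list", n + 1L)
    for (j in seq_len(n)) {
      dp[j + 1L] <- dp[j]
      choice[j + 1L] <- list(NULL)  # [[<- NULL would delete the element
      for (i in seq_len(j)) {
        ok <- .seg_ok(prefix, i, j, min_run, max_dissent)
        if (is.null(ok)) next
        cand <- dp[i] + ok$total
        if (cand > dp[j + 1L]) {
          dp[j + 1L] <- cand
          choice[[j + 1L]] <- list(from = i, label = ok$label, total = ok$total)
        }
      }
    }
    # backtrack
    j <- n
    segs <- list()
    while (j >= 1L) {
      ch <- choice[[j + 1L]]
      if (is.null(ch)) { j <- j - 1L; next }
      i <- ch$from
      lab_pos <- which(!is.na(lab))
      from <- min(lab_pos[lab_pos >= i]); to <- max(lab_pos[lab_pos <= j])
      cnt <- prefix[j + 1L, ] - prefix[i, ]
      segs[[length(segs) + 1L]] <- data.frame(
        scaffold = s, from_index = idx[from], to_index = idx[to],
        block = ch$label, n_labelled = sum(cnt), n_majority = max(cnt),
        stringsAsFactors = FALSE)
      j <- i - 1L
    }
    if (length(segs)) out[[s]] <- do.call(rbind, rev(segs))
  }
  if (!length(out)) {
    return(data.frame(scaffold = character(0), from_index = integer(0),
                      to_index = integer(0), block = character(0),
                      n_labelled = integer(0), n_majority = integer(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, unname(out))
  rownames(res) <- NULL
  res
}
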