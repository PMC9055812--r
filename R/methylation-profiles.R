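#' Coverage-filter methylation calls
#'
#' @param calls Data frame (`scaffold`, `position` 1-based, `strand`,
#'   `context` in CG/CHG/CHH, `methylated`, `total`).
#' @param min_depth Minimum total reads per cytosine.
#' @return List: `calls` (filtered), `report` (per-context kept/removed).
#' @export
filter_coverage <- function(calls, min_depth = 3L) {
  keep <- calls$total >= min_depth
  ctx <- factor(calls$context, levels = c("CG", "CHG", "CHH"))
  report <- data.frame(
    context = levels(ctx),
    input = as.integer(table(ctx)),
    kept = as.integer(table(ctx[keep])),
    stringsAsFactors = FALSE)
  report$removed <- report$input - report$kept
  list(calls = calls[keep, , drop = FALSE], report = report)
}

#' Global per-context methylation levels
#'
#' Two measures per context: the coverage-weighted level (sum of
#' methylated reads over sum of total reads) and the fraction of sites
#' called methylated (per-site level at least `site_call_threshold`).
#' Contexts with no sites yield `NA`, not zero.
#'
#' @param calls Coverage-filtered methylation calls.
#' @param site_call_threshold Per-site methylated/total ratio calling a
#'   cytosine methylated.
#' @return Data frame: `context`, `weighted_level`, `site_fraction`,
#'   `n_sites`.
#' @export
global_context_levels <- function(calls, site_call_threshold = 0.5) {
  out <- lapply(c("CG", "CHG", "CHH"), function(cx) {
    d <- calls[calls$context == cx, , drop = FALSE]
    if (!nrow(d)) {
      return(data.frame(context = cx, weighted_level = NA_real_,
                        site_fraction = NA_real_, n_sites = 0L))
    }
    data.frame(context = cx,
               weighted_level = sum(d$methylated) / sum(d$total),
               site_fraction = mean(d$methylated / d$total >= site_call_threshold),
               n_sites = nrow(d))
  })
  do.call(rbind, out)
}

#' Per-window per-context weighted methylation levels
#'
#' @param calls Coverage-filtered methylation calls.
#' @param genome Named vector of scaffold lengths.
#' @param window Window size (bp).
#' @return Data frame: `scaffold`, `window_start`, `window_end`, `CG`,
#'   `CHG`, `CHH` (weighted level; `NA` where a context has no site).
#' @export
window_levels <- function(calls, genome, window = 200000) {
  stopifnot(window > 0)
  rows <- lapply(names(genome), function(s) {
    L <- genome[[s]]
    n_win <- max(1L, ceiling(L / window))
    d <- calls[calls$scaffold == s, , drop = FALSE]
    idx <- pmin(floor((d$position - 1) / window) + 1L, n_win)
    lev <- sapply(c("CG", "CHG", "CHH"), function(cx) {
      sel <- d$context == cx
      me <- tabulate_sum(idx[sel], d$methylated[sel], n_win)
      to <- tabulate_sum(idx[sel], d$total[sel], n_win)
      ifelse(to > 0, me / to, NA_real_)
    })
    ws <- (seq_len(n_win) - 1) * window
    data.frame(scaffold = s, window_start = ws, window_end = pmin(ws + window, L),
               matrix(lev, nrow = n_win, dimnames = list(NULL, c("CG", "CHG", "CHH"))),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

tabulate_sum <- function(idx, w, nbins) {
  out <- numeric(nbins)
  if (length(idx)) {
    agg <- rowsum(as.numeric(w), idx)
    out[as.integer(rownames(agg))] <- agg[, 1]
  }
  out
}

#' Feature metaprofile of methylation
#'
#' Averages methylation over a set of stranded features in fixed `bin`-bp
#' flank bins (`flank/bin` bins on each side) and `body_bins` proportional
#' body bins. Minus-strand features are reversed so the position axis is
#' always 5' to 3'; per-bin levels are coverage-weighted over all
#' features' cytosines. Features shorter than `body_bins` bp still
#' contribute through proportional assignment (a note is attached).
#'
#' @param calls Coverage-filtered methylation calls.
#' @param features Data frame (`scaffold`, `start`, `end`, `strand`;
#'   0-based half-open).
#' @param flank Flank size (bp); must be divisible by `bin`.
#' @param bin Flank bin width (bp).
#' @param body_bins Number of proportional body bins.
#' @return Data frame: `bin` (1..2*flank/bin+body_bins), `region`
#'   (upstream/body/downstream), `CG`, `CHG`, `CHH`. Attribute
#'   `n_short_features` counts features shorter than `body_bins` bp.
#' @export
metaprofile <- function(calls, features, flank = 2000L, bin = 25L,
                        body_bins = 40L) {
  stopifnot(flank %% bin == 0, nrow(features) >= 1)
  n_flank <- flank %/% bin
  n_bins <- 2L * n_flank + body_bins
  me <- matrix(0, nrow = n_bins, ncol = 3,
               dimnames = list(NULL, c("CG", "CHG", "CHH")))
  to <- me
  n_short <- 0L

  for (s in unique(features$scaffold)) {
    fi <- which(features$scaffold == s)
    d <- calls[calls$scaffold == s, , drop = FALSE]
    if (!nrow(d)) next
    pos0 <- d$position - 1L  # 0-based
    ext <- .ir(features$start[fi] - flank, features$end[fi] + flank)
    sites <- IRanges::IRanges(pos0 + 1L, width = 1L)
    hit <- IRanges::findOverlaps(sites, ext)
    if (!length(hit)) next
    q <- S4Vectors::queryHits(hit); f <- fi[S4Vectors::subjectHits(hit)]
    p <- pos0[q]
    fs <- features$start[f]; fe <- features$end[f]
    neg <- features$strand[f] == "-"
    blen <- fe - fs
    n_short <- n_short + length(unique(f[blen < body_bins]))

    # signed position relative to the feature in 5'->3' orientation
    upstream <- ifelse(neg, p >= fe, p < fs)
    downstream <- ifelse(neg, p < fs, p >= fe)
    bin_idx <- integer(length(p))
    # upstream flank: distance from feature 5' end, bins n_flank..1 outward
    du <- ifelse(neg, p - fe, fs - 1L - p)          # 0-based distance into flank
    bin_idx[upstream] <- n_flank - (du[upstream] %/% bin)
    # body: proportional position
    rel <- ifelse(neg, (fe - 1L - p) / blen, (p - fs) / blen)
    inb <- !upstream & !downstream
    bin_idx[inb] <- n_flank + pmin(body_bins, floor(rel[inb] * body_bins) + 1L)
    # downstream flank
    dd <- ifelse(neg, fs - 1L - p, p - fe)
    bin_idx[downstream] <- n_flank + body_bins + (dd[downstream] %/% bin) + 1L

    ok <- bin_idx >= 1L & bin_idx <= n_bins
    cx <- d$context[q]
    for (ctx in c("CG", "CHG", "CHH")) {
      sel <- ok & cx == ctx
      me[, ctx] <- me[, ctx] + tabulate_sum(bin_idx[sel], d$methylated[q][sel], n_bins)
      to[, ctx] <- to[, ctx] + tabulate_sum(bin_idx[sel], d$total[q][sel], n_bins)
    }
  }
  lev <- ifelse(to > 0, me / to, NA_real_)
  out <- data.frame(bin = seq_len(n_bins),
                    region = rep(c("upstream", "body", "downstream"),
                                 c(n_flank, body_bins, n_flank)),
                    lev, stringsAsFactors = FALSE)
  attr(out, "n_short_features") <- n_short
  out
}
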