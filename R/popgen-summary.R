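#' Variant-class summary under a QD filter
#'
#' Removes records whose quality-by-depth (QD) score falls below `min_qd`
#' (records without a QD value are kept), then tabulates counts and
#' percentages per variant class and, over exonic records, per effect
#' label. Percentages are `100 * count / total` rounded half-even to one
#' decimal.
#'
#' @param table Variant data frame (`class` in SNP/insertion/deletion;
#'   optional `qd`, `effect`, `exonic`). An optional `n` column gives a
#'   multiplicity per row, so tallied variant tables (one row per class
#'   with its count) are summarized without materializing every record.
#' @param min_qd QD threshold (applied only where `qd` is present).
#' @return List: `summary` (data frame class/count/percent), `total`,
#'   `effects` (effect counts over exonic records, or `NULL`).
#' @export
variant_class_summary <- function(table, min_qd = 2000) {
  if ("qd" %in% names(table)) {
    keep <- is.na(table$qd) | table$qd >= min_qd
    table <- table[keep, , drop = FALSE]
  }
  n <- if ("n" %in% names(table)) as.numeric(table$n) else rep(1, nrow(table))
  if (!nrow(table) || sum(n) == 0) stop("no variants left after QD filter")
  classes <- c("SNP", "insertion", "deletion")
  cnt <- vapply(classes, function(cl) sum(n[table$class == cl]), numeric(1))
  other <- sum(n) - sum(cnt)
  if (other > 0) cnt <- c(cnt, other = other)
  total <- sum(n)
  summary <- data.frame(class = names(cnt), count = as.numeric(cnt),
                        percent = round(100 * as.numeric(cnt) / total, 1),
                        stringsAsFactors = FALSE)
  effects <- NULL
  if (all(c("effect", "exonic") %in% names(table))) {
    ex <- table$exonic %in% TRUE
    if (any(ex)) {
      effects <- tapply(n[ex], table$effect[ex], sum)
      effects <- effects[!is.na(effects)]
    }
  }
  list(summary = summary, total = total, effects = effects)
}

#' Sliding-window pairwise r-squared
#'
#' For every marker pair on the same scaffold whose index separation is at
#' most `window_markers`, the squared Pearson correlation of genotype
#' dosages over pairwise-complete samples. Monomorphic markers and pairs
#' with fewer than two complete samples are skipped.
#'
#' @param geno List with `markers` (data frame `scaffold`, `position`,
#'   strictly increasing per scaffold) and `dosage` (markers x samples
#'   matrix of 0/1/2, `NA` allowed).
#' @param window_markers Sliding-window size in markers.
#' @return Data frame: `distance` (bp), `r2`.
#' @export
pairwise_r2 <- function(geno, window_markers = 40L) {
  mk <- geno$markers
  X <- geno$dosage
  stopifnot(nrow(mk) == nrow(X), nrow(mk) >= 2)
  res <- list()
  for (s in unique(mk$scaffold)) {
    idx <- which(mk$scaffold == s)
    if (any(diff(mk$position[idx]) <= 0)) {
      stop("marker positions must be strictly increasing per scaffold")
    }
    n <- length(idx)
    Xs <- X[idx, , drop = FALSE]
    if (!anyNA(Xs)) {
      # complete-data fast path: per-offset vectorized correlations
      ns <- ncol(Xs)
      sx <- rowSums(Xs); sxx <- rowSums(Xs^2)
      vx <- ns * sxx - sx^2
      for (d in seq_len(min(window_markers, n - 1L))) {
        a <- seq_len(n - d); b <- a + d
        sxy <- rowSums(Xs[a, , drop = FALSE] * Xs[b, , drop = FALSE])
        den <- vx[a] * vx[b]
        ok <- den > 0
        r2 <- (ns * sxy[ok] - sx[a][ok] * sx[b][ok])^2 / den[ok]
        res[[length(res) + 1L]] <- data.frame(
          distance = (mk$position[idx[b]] - mk$position[idx[a]])[ok], r2 = r2)
      }
    } else {
      for (a in seq_len(n - 1L)) {
        for (b in seq(a + 1L, min(n, a + window_markers))) {
          xi <- Xs[a, ]; xj <- Xs[b, ]
          ok <- !is.na(xi) & !is.na(xj)
          if (sum(ok) < 2) next
          if (stats::var(xi[ok]) == 0 || stats::var(xj[ok]) == 0) next
          r <- stats::cor(xi[ok], xj[ok])
          res[[length(res) + 1L]] <- data.frame(
            distance = mk$position[idx[b]] - mk$position[idx[a]], r2 = r * r)
        }
      }
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Recover an exponential LD decay scale from genotype data
#'
#' Convenience recovery route for planted exponential decay: computes
#' sliding-window pairwise r-squared, restricts to the decay region
#' (`max_distance`), finds the LOESS crossing of `threshold`, and inverts
#' the dosage-correlation model `E[r2] = rho^2 + (1 - rho^2)/n` with
#' `rho = exp(-d / scale)`, which corrects for the finite-sample
#' r-squared baseline.
#'
#' @param geno Genotype list (see [pairwise_r2()]).
#' @param threshold,loess_span Passed to [ld_decay_distance()].
#' @param window_markers Passed to [pairwise_r2()].
#' @param max_distance Fit region (bp); pairs further apart carry only
#'   baseline information and are excluded from the curve fit.
#' @return List: `scale` (recovered bp), `crossing`, `pairs_used`.
#' @export
ld_recover_scale <- function(geno, threshold = 0.2, loess_span = 0.3,
                             window_markers = 40L, max_distance = 15000) {
  pr <- pairwise_r2(geno, window_markers = window_markers)
  prf <- pr[pr$distance <= max_distance, , drop = FALSE]
  ld <- ld_decay_distance(prf, threshold = threshold, loess_span = loess_span)
  n <- ncol(geno$dosage)
  rho2 <- (threshold - 1 / n) / (1 - 1 / n)
  scale <- if (is.na(ld$crossing) || rho2 <= 0) NA_real_ else
    -2 * ld$crossing / log(rho2)
  list(scale = scale, crossing = ld$crossing, pairs_used = nrow(prf))
}

#' LD decay curve and threshold-crossing distance
#'
#' Fits a locally weighted (LOESS) regression of r-squared on physical
#' distance, evaluates it on a fixed grid, and reports the smallest
#' distance at which the fitted curve first reaches the threshold
#' (linear interpolation between grid points). If the curve never crosses
#' the threshold the crossing is `NA` and the curve minimum is reported.
#'
#' @param pairs Data frame (`distance`, `r2`), e.g. from [pairwise_r2()].
#' @param threshold r-squared decay threshold.
#' @param loess_span LOESS span.
#' @param grid_n Grid resolution.
#' @return List: `curve` (data frame distance/r2), `crossing` (bp or
#'   `NA`), `reached` flag, `minimum` (curve minimum).
#' @export
ld_decay_distance <- function(pairs, threshold = 0.2, loess_span = 0.3,
                              grid_n = 400L) {
  stopifnot(nrow(pairs) >= 10)
  fit <- stats::loess(r2 ~ distance, data = pairs, span = loess_span,
                      degree = 2, family = "gaussian")
  grid <- seq(min(pairs$distance), max(pairs$distance), length.out = grid_n)
  yhat <- stats::predict(fit, newdata = data.frame(distance = grid))
  ok <- !is.na(yhat)
  grid <- grid[ok]; yhat <- yhat[ok]
  curve <- data.frame(distance = grid, r2 = yhat)
  below <- which(yhat <= threshold)
  if (!length(below)) {
    return(list(curve = curve, crossing = NA_real_, reached = FALSE,
                minimum = min(yhat)))
  }
  i <- below[1]
  crossing <- if (i == 1L) grid[1] else {
    # linear interpolation between the bracketing grid points
    grid[i - 1L] + (grid[i] - grid[i - 1L]) *
      (yhat[i - 1L] - threshold) / (yhat[i - 1L] - yhat[i])
  }
  list(curve = curve, crossing = crossing, reached = TRUE, minimum = min(yhat))
}
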