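#' TMM normalization
#'
#' Per-sample scaling factors from the trimmed mean of M-values (log-ratio
#' trim 30%, absolute-intensity trim 5%, reference sample chosen by upper
#' quartile closest to the mean upper quartile, factors scaled to
#' geometric mean 1), computed with edgeR. Factors are computed from
#' relative library sizes at a canonical one-million-read scale, so they
#' — and hence the normalized matrix — are exactly invariant under a
#' global library-size rescaling. The normalized value is
#' `count / (library size x factor) x mean library size`.
#'
#' @param counts Integer matrix, genes x samples.
#' @param lib_sizes Library sizes; defaults to column sums.
#' @return List: `factors` (per sample), `normalized` (matrix),
#'   `lib_sizes`.
#' @export
tmm_normalize <- function(counts, lib_sizes = NULL) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("TMM needs at least 2 samples")
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  if (any(lib_sizes <= 0)) stop("all-zero sample: library size must be > 0")
  # rounding removes float jitter, so rescaled inputs give identical factors
  lib_canonical <- round(lib_sizes / mean(lib_sizes) * 1e6)
  f <- edgeR::calcNormFactors(counts, lib.size = lib_canonical, method = "TMM")
  eff <- lib_sizes * f
  normalized <- sweep(counts, 2, eff, "/") * mean(lib_sizes)
  list(factors = f, normalized = normalized, lib_sizes = lib_sizes)
}

#' Tau tissue-specificity index
#'
#' Drops excluded samples, averages normalized expression per tissue,
#' applies a `log2(x + 1)` transform, scales each gene by its maximum
#' tissue value and computes `tau = sum(1 - x_hat) / (n - 1)` over the
#' `n` tissues. Genes with zero maximum expression (or an undefined
#' tissue mean) get `NA` ("ignored due to missing data").
#'
#' @param normalized Genes x samples matrix of normalized counts.
#' @param tissue_map Named character vector: sample -> tissue.
#' @param excluded_samples Sample names dropped before averaging (e.g.
#'   low-coverage groups).
#' @param log_transform Apply `log2(x + 1)` before tau (default TRUE).
#' @return List: `tau` (per gene), `tissue_means` (genes x tissues matrix
#'   of transformed per-tissue means), `tissues`.
#' @export
tau_specificity <- function(normalized, tissue_map, excluded_samples = character(0),
                            log_transform = TRUE) {
  keep <- setdiff(colnames(normalized), excluded_samples)
  normalized <- normalized[, keep, drop = FALSE]
  tissue <- tissue_map[keep]
  tissues <- unique(unname(tissue))
  if (length(tissues) < 2) stop("tau needs at least 2 tissues after exclusion")
  means <- vapply(tissues, function(t) {
    rowMeans(normalized[, tissue == t, drop = FALSE])
  }, numeric(nrow(normalized)))
  means <- matrix(means, nrow = nrow(normalized),
                  dimnames = list(rownames(normalized), tissues))
  x <- if (log_transform) log2(means + 1) else means
  mx <- apply(x, 1, max)
  bad <- mx <= 0 | !is.finite(mx) | apply(x, 1, function(r) any(!is.finite(r)))
  tau <- rowSums(1 - x / mx) / (ncol(x) - 1)
  tau[bad] <- NA_real_
  list(tau = tau, tissue_means = x, tissues = tissues)
}

#' Specificity classes and per-tissue top genes
#'
#' Classes: low `[0, 0.2)`, intermediate `[0.2, 0.8)`, high `[0.8, 1.0]`
#' (missing tau kept separate). Per tissue, among high-specificity genes
#' the `k` with the highest expression in that tissue are reported with
#' their expression relative (log2) to the per-gene mean across tissues.
#'
#' @param tau_result Output of [tau_specificity()].
#' @param k Top genes per tissue.
#' @return List: `class` (per-gene factor), `class_counts`, `top`
#'   (data frame: tissue, gene, tau, expression, relative_log2).
#' @export
atlas_summary <- function(tau_result, k = 30L) {
  tau <- tau_result$tau
  cls <- cut(tau, breaks = c(-Inf, 0.2, 0.8, Inf), right = FALSE,
             labels = c("low", "intermediate", "high"))
  cls <- factor(ifelse(is.na(tau), "missing", as.character(cls)),
                levels = c("low", "intermediate", "high", "missing"))
  x <- tau_result$tissue_means
  rel <- x - rowMeans(x)
  rows <- list()
  for (t in colnames(x)) {
    hi <- which(!is.na(tau) & tau >= 0.8)
    if (!length(hi)) next
    ord <- hi[order(x[hi, t], decreasing = TRUE)]
    sel <- utils::head(ord, k)
    rows[[t]] <- data.frame(
      tissue = t,
      gene = if (!is.null(rownames(x))) rownames(x)[sel] else as.character(sel),
      tau = tau[sel], expression = x[sel, t], relative_log2 = rel[sel, t],
      stringsAsFactors = FALSE)
  }
  top <- if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE))) else
    data.frame(tissue = character(0), gene = character(0), tau = numeric(0),
               expression = numeric(0), relative_log2 = numeric(0))
  list(class = cls, class_counts = table(cls), top = top)
}
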