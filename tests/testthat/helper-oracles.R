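# Independent brute-force oracles. These deliberately avoid the package's
# interval machinery: clusters via the pairwise gap graph, consensus via a
# per-base vote, distances and containment via quadratic scans, purge and
# block painting via exhaustive enumeration.

# union of reads over the pairwise gap graph (gap <= pad connects)
oracle_clusters <- function(reads, total, min_rpm, pad) {
  out <- list()
  for (s in unique(reads$scaffold)) {
    d <- reads[reads$scaffold == s, ]
    d <- d[order(d$start, d$end), ]
    n <- nrow(d)
    comp <- seq_len(n)
    find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      gap <- max(d$start[j], d$start[i]) - min(d$end[j], d$end[i])
      if (gap <= pad) {
        ri <- find(i); rj <- find(j)
        comp[max(ri, rj)] <- min(ri, rj)
      }
    }
    roots <- vapply(seq_len(n), find, integer(1))
    for (r in unique(roots)) {
      m <- roots == r
      cnt <- sum(d$count[m])
      rpm <- cnt * 1e6 / total
      if (rpm >= min_rpm) {
        out[[length(out) + 1]] <- data.frame(
          scaffold = s, start = min(d$start[m]), end = max(d$end[m]),
          reads = cnt, rpm = rpm, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(NULL)
  res <- do.call(rbind, out)
  res[order(res$scaffold, res$start), ]
}

# per-base vote consensus on a single scaffold of length L
oracle_consensus <- function(clusters_by_library, tissue_map, L, scaffold,
                             min_libraries = 3, merge_gap = 25,
                             min_rpm_rescue = 0.5) {
  tissues <- unique(unname(tissue_map))
  per_tissue <- list()
  for (t in tissues) {
    libs <- names(tissue_map)[tissue_map == t]
    vote <- integer(L)
    for (id in libs) {
      d <- clusters_by_library[[id]]
      d <- d[d$scaffold == scaffold, , drop = FALSE]
      covered <- logical(L)
      for (k in seq_len(nrow(d))) {
        covered[(d$start[k] + 1):d$end[k]] <- TRUE
      }
      vote <- vote + covered
    }
    keep <- vote >= min_libraries
    if (!any(keep)) next
    # contiguous runs
    r <- rle(keep)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    iv <- data.frame(start = starts[r$values] - 1, end = ends[r$values])
    # pad together gaps <= merge_gap
    merged <- iv[1, , drop = FALSE]
    for (k in seq_len(nrow(iv))[-1]) {
      if (iv$start[k] - merged$end[nrow(merged)] <= merge_gap) {
        merged$end[nrow(merged)] <- iv$end[k]
      } else merged <- rbind(merged, iv[k, ])
    }
    # rescue filter: max over libraries of summed overlapping-cluster RPM
    ok <- logical(nrow(merged))
    for (k in seq_len(nrow(merged))) {
      mx <- 0
      for (id in libs) {
        d <- clusters_by_library[[id]]
        d <- d[d$scaffold == scaffold, , drop = FALSE]
        ov <- d$start < merged$end[k] & d$end > merged$start[k]
        if (any(ov)) mx <- max(mx, sum(d$rpm[ov]))
      }
      ok[k] <- mx >= min_rpm_rescue
    }
    if (any(ok)) {
      per_tissue[[t]] <- cbind(merged[ok, , drop = FALSE], tissue = t)
    }
  }
  if (!length(per_tissue)) return(NULL)
  all_t <- do.call(rbind, per_tissue)
  # final cross-tissue union (overlapping or book-ended)
  covered <- logical(L)
  for (k in seq_len(nrow(all_t))) covered[(all_t$start[k] + 1):all_t$end[k]] <- TRUE
  r <- rle(covered)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  iv <- data.frame(start = starts[r$values] - 1, end = ends[r$values])
  iv$tissues <- vapply(seq_len(nrow(iv)), function(k) {
    contrib <- all_t$tissue[all_t$start < iv$end[k] & all_t$end > iv$start[k]]
    paste(sort(unique(contrib)), collapse = ",")
  }, character(1))
  iv
}

# quadratic nearest-distance scan (0-based half-open, gap in bp)
oracle_nearest <- function(loci, targets) {
  vapply(seq_len(nrow(loci)), function(i) {
    ti <- targets[targets$scaffold == loci$scaffold[i], , drop = FALSE]
    if (!nrow(ti)) return(NA_real_)
    min(vapply(seq_len(nrow(ti)), function(j) {
      if (loci$start[i] < ti$end[j] && loci$end[i] > ti$start[j]) return(0)
      max(ti$start[j] - loci$end[i], loci$start[i] - ti$end[j])
    }, numeric(1)))
  }, numeric(1))
}

# exhaustive purge: repeatedly remove the lowest-depth unprotected contig
# (ties: longest, then id) until within budget; implemented as an
# independent simulation over explicit candidate sets
oracle_purge <- function(table, target, tolerance = 0.02) {
  budget <- target * (1 + tolerance)
  remaining <- table
  removed <- character(0)
  while (sum(remaining$length) > budget) {
    cand <- remaining[!remaining$busco_single, , drop = FALSE]
    if (!nrow(cand)) break
    cand <- cand[order(cand$depth, -cand$length, cand$contig), , drop = FALSE]
    pick <- cand$contig[1]
    removed <- c(removed, pick)
    remaining <- remaining[remaining$contig != pick, , drop = FALSE]
  }
  sort(removed)
}

# exhaustive block segmentation maximizing labelled-gene coverage
oracle_blocks <- function(labels, min_run = 5, max_dissent = 0.2) {
  n <- length(labels)
  seg_ok <- function(i, j) {
    lab <- labels[i:j]
    lab <- lab[!is.na(lab)]
    if (length(lab) < min_run) return(NULL)
    tab <- table(lab)
    if (max(tab) / length(lab) < 1 - max_dissent) return(NULL)
    length(lab)
  }
  best <- 0
  # enumerate all sets of disjoint intervals via recursion
  recurse <- function(pos, acc) {
    if (pos > n) { best <<- max(best, acc); return(invisible()) }
    recurse(pos + 1, acc)  # skip gene at pos
    for (j in pos:n) {
      v <- seg_ok(pos, j)
      if (!is.null(v)) recurse(j + 1, acc + v)
    }
  }
  recurse(1, 0)
  best
}

# hand-computed TMM factor (trimmed, precision-weighted mean of M-values)
oracle_tmm_factor <- function(obs, ref, lib_obs, lib_ref,
                              logratio_trim = 0.3, sum_trim = 0.05) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  m <- log2((obs / lib_obs) / (ref / lib_ref))
  a <- (log2(obs / lib_obs) + log2(ref / lib_ref)) / 2
  v <- (lib_obs - obs) / (lib_obs * obs) + (lib_ref - ref) / (lib_ref * ref)
  fin <- is.finite(m) & is.finite(a)
  m <- m[fin]; a <- a[fin]; v <- v[fin]
  n <- length(m)
  lo_m <- floor(n * logratio_trim) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * sum_trim) + 1; hi_a <- n + 1 - lo_a
  keep <- rank(m) >= lo_m & rank(m) <= hi_m & rank(a) >= lo_a & rank(a) <= hi_a
  2^(sum(m[keep] / v[keep]) / sum(1 / v[keep]))
}
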