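#' Generate a synthetic genome annotation
#'
#' Places non-overlapping genes (with exon/intron substructure) and TEs on
#' the configured scaffolds. Gene placement weight is highest towards the
#' scaffold ends and lowest at the centre; TE weight is the complement, so
#' the geometry mimics gene-dense telomeres and a TE-dense pericentromere.
#' TEs are labelled by superfamily with the configured relative abundance,
#' and a configured number of extra genes are planted fully inside TE
#' bodies (recorded in the returned truth table).
#'
#' @param config A [sim_config()] object.
#' @return A list with `annotation` (data frame: scaffold, start, end
#'   0-based half-open, strand, type, id, parent) and `truth` (list with
#'   `te_contained_genes`, the ids of genes planted inside TE bodies).
#' @export
gen_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ap <- config$annotation_params
  with_stream(config$seed, 1L, {
    genome <- config$genome
    rows <- list()
    te_contained_ids <- character(0)
    gene_counter <- 0L
    te_counter <- 0L

    for (s in names(genome)) {
      L <- genome[[s]]
      # density weights on a 50-kb grid: genes at ends, TEs at centre
      grid <- seq(0, L, by = 5e4)
      mid_dist <- abs((grid[-length(grid)] + 2.5e4) - L / 2) / (L / 2)
      w_gene <- 0.2 + mid_dist^2 * 4
      w_te <- 0.2 + (1 - mid_dist)^2 * 4

      n_genes <- max(1L, round(ap$n_genes * L / sum(genome)))
      n_tes <- round(ap$n_tes * L / sum(genome))

      place <- function(n, w, min_len, max_len) {
        if (n == 0) return(data.frame(start = integer(0), end = integer(0)))
        cell <- sample.int(length(w), n, replace = TRUE, prob = w)
        pos <- (cell - 1) * 5e4 + floor(runif(n, 0, 5e4))
        len <- sample(min_len:max_len, n, replace = TRUE)
        end <- pmin(pos + len, L)
        keep <- end > pos
        df <- data.frame(start = as.integer(pos[keep]), end = as.integer(end[keep]))
        df <- df[order(df$start), , drop = FALSE]
        # drop overlaps greedily
        if (nrow(df) > 1) {
          ok <- rep(TRUE, nrow(df))
          last_end <- df$end[1]
          for (i in seq(2, nrow(df))) {
            if (df$start[i] < last_end) ok[i] <- FALSE else last_end <- df$end[i]
          }
          df <- df[ok, , drop = FALSE]
        }
        df
      }

      genes <- place(n_genes, w_gene, 800L, 5000L)
      tes <- place(n_tes, w_te, 300L, 8000L)
      # remove TEs overlapping genes so base annotation is clean
      if (nrow(tes) && nrow(genes)) {
        ov <- IRanges::overlapsAny(.ir(tes$start, tes$end), .ir(genes$start, genes$end))
        tes <- tes[!ov, , drop = FALSE]
      }

      if (nrow(genes)) {
        ids <- sprintf("gene_%05d", gene_counter + seq_len(nrow(genes)))
        gene_counter <- gene_counter + nrow(genes)
        strand <- sample(c("+", "-"), nrow(genes), replace = TRUE)
        rows[[length(rows) + 1L]] <- data.frame(
          scaffold = s, start = genes$start, end = genes$end, strand = strand,
          type = "gene", id = ids, parent = NA_character_,
          stringsAsFactors = FALSE)
        rows[[length(rows) + 1L]] <- .gene_substructure(s, genes, strand, ids)
      }

      if (nrow(tes)) {
        fam <- sample(names(ap$te_superfamily_probs), nrow(tes), replace = TRUE,
                      prob = ap$te_superfamily_probs)
        ids <- sprintf("te_%05d", te_counter + seq_len(nrow(tes)))
        te_counter <- te_counter + nrow(tes)
        rows[[length(rows) + 1L]] <- data.frame(
          scaffold = s, start = tes$start, end = tes$end,
          strand = sample(c("+", "-"), nrow(tes), replace = TRUE),
          type = paste0("TE:", fam), id = ids, parent = NA_character_,
          stringsAsFactors = FALSE)
      }
    }
    ann <- do.call(rbind, rows)

    # plant genes fully inside TE bodies (the downstream recovery target)
    n_contained <- ap$n_te_contained
    if (n_contained > 0) {
      tes_all <- ann[startsWith(ann$type, "TE:"), ]
      host <- tes_all[tes_all$end - tes_all$start >= 1500, ]
      if (nrow(host) < n_contained) {
        stop("not enough long TEs to host te-contained genes; raise n_tes")
      }
      pick <- host[sample.int(nrow(host), n_contained), ]
      glen <- pmin(800L, as.integer((pick$end - pick$start) * 0.5))
      gstart <- pick$start + as.integer((pick$end - pick$start - glen) / 2)
      ids <- sprintf("gene_te_%03d", seq_len(n_contained))
      te_contained_ids <- ids
      strand <- sample(c("+", "-"), n_contained, replace = TRUE)
      extra <- data.frame(
        scaffold = pick$scaffold, start = gstart, end = gstart + glen,
        strand = strand, type = "gene", id = ids, parent = NA_character_,
        stringsAsFactors = FALSE)
      sub <- .gene_substructure(NULL, data.frame(start = gstart, end = gstart + glen),
                                strand, ids, scaffold = pick$scaffold)
      ann <- rbind(ann, extra, sub)
    }

    ann <- ann[order(ann$scaffold, ann$start, ann$end, ann$type, ann$id), ]
    rownames(ann) <- NULL
    list(annotation = ann, truth = list(te_contained_genes = sort(te_contained_ids)))
  })
}

# exon/intron substructure: 1-4 exons, introns between them
.gene_substructure <- function(s, genes, strand, ids, scaffold = NULL) {
  out <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g0 <- genes$start[i]; g1 <- genes$end[i]
    len <- g1 - g0
    n_ex <- sample(1:4, 1)
    if (n_ex == 1 || len < 400) {
      ex <- data.frame(start = g0, end = g1)
    } else {
      cuts <- sort(sample(seq(g0 + 50, g1 - 50, by = 10), 2 * (n_ex - 1)))
      b <- c(g0, cuts, g1)
      ex <- data.frame(start = b[seq(1, length(b), by = 2)],
                       end = b[seq(2, length(b), by = 2)])
    }
    scf <- if (is.null(scaffold)) s else scaffold[i]
    exons <- data.frame(scaffold = scf, start = as.integer(ex$start),
                        end = as.integer(ex$end), strand = strand[i],
                        type = "exon",
                        id = sprintf("%s.exon%d", ids[i], seq_len(nrow(ex))),
                        parent = ids[i], stringsAsFactors = FALSE)
    if (nrow(ex) > 1) {
      introns <- data.frame(scaffold = scf,
                            start = as.integer(ex$end[-nrow(ex)]),
                            end = as.integer(ex$start[-1]), strand = strand[i],
                            type = "intron",
                            id = sprintf("%s.intron%d", ids[i], seq_len(nrow(ex) - 1)),
                            parent = ids[i], stringsAsFactors = FALSE)
      out[[i]] <- rbind(exons, introns)
    } else out[[i]] <- exons
  }
  do.call(rbind, out)
}
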