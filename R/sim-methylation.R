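#' Generate per-cytosine methylation calls
#'
#' Scatters cytosine sites over the genome and draws methylated read
#' counts binomially at compartment-dependent means: TE bodies
#' hypermethylated, gene bodies essentially unmethylated (no gene-body
#' methylation, as in species that lost gbM), intergenic background in
#' between, and CG > CHG > CHH within every compartment. Read depths are
#' Poisson with some sites below 3x, so the coverage filter has work to
#' do.
#'
#' @param annotation Output of [gen_annotation()] (or a compatible
#'   annotation data frame in `$annotation`).
#' @param config A [sim_config()] object.
#' @return Data frame of calls: `scaffold`, `position` (1-based),
#'   `strand`, `context`, `methylated`, `total`.
#' @export
gen_methylation_calls <- function(annotation, config) {
  stopifnot(inherits(config, "sim_config"))
  ann <- if (is.data.frame(annotation)) annotation else annotation$annotation
  mp <- config$methylation_params
  with_stream(config$seed, 4L, {
    genome <- config$genome
    n <- mp$n_sites
    scaf <- sample(names(genome), n, replace = TRUE, prob = genome / sum(genome))
    pos0 <- floor(stats::runif(n, 0, genome[scaf]))
    context <- sample(c("CG", "CHG", "CHH"), n, replace = TRUE,
                      prob = c(0.25, 0.25, 0.5))
    strand <- sample(c("+", "-"), n, replace = TRUE)

    compartment <- rep("background", n)
    genes <- ann[ann$type == "gene", ]
    tes <- ann[startsWith(ann$type, "TE:"), ]
    for (s in names(genome)) {
      si <- which(scaf == s)
      if (!length(si)) next
      sites <- IRanges::IRanges(pos0[si] + 1L, width = 1L)
      gi <- genes[genes$scaffold == s, ]
      ti <- tes[tes$scaffold == s, ]
      in_te <- if (nrow(ti)) IRanges::overlapsAny(sites, .ir(ti$start, ti$end)) else FALSE
      in_gene <- if (nrow(gi)) IRanges::overlapsAny(sites, .ir(gi$start, gi$end)) else FALSE
      compartment[si][in_te] <- "te"
      compartment[si][in_gene & !in_te] <- "gene"
    }

    ctx_key <- c(CG = "cg", CHG = "chg", CHH = "chh")
    p <- mapply(function(comp, cx) mp[[comp]][[ctx_key[[cx]]]],
                compartment, context)
    total <- stats::rpois(n, mp$mean_depth)
    methylated <- stats::rbinom(n, total, p)
    out <- data.frame(scaffold = scaf, position = as.integer(pos0 + 1L),
                      strand = strand, context = context,
                      methylated = methylated, total = total,
                      compartment = compartment, stringsAsFactors = FALSE)
    out <- out[order(out$scaffold, out$position), ]
    rownames(out) <- NULL
    out
  })
}
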