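# Plain-text readers and writers for the formats the generators emit.
# Coordinates are BED-native (0-based half-open) in all TSV dialects;
# GFF3 is converted on I/O; methylation positions are 1-based.

#' Write / read a genome annotation as GFF3
#'
#' @param annotation Annotation data frame (see [gen_annotation()]).
#' @param path File path.
#' @return `read_annotation_gff3` returns the annotation data frame.
#' @export
write_annotation_gff3 <- function(annotation, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$scaffold,
    ranges = IRanges::IRanges(annotation$start + 1L, annotation$end),
    strand = annotation$strand)
  gr$type <- annotation$type
  gr$ID <- annotation$id
  gr$Parent <- annotation$parent
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_annotation_gff3
#' @export
read_annotation_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  parent <- as.character(gr$Parent)
  parent[!nzchar(parent)] <- NA_character_
  out <- data.frame(
    scaffold = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    id = as.character(gr$ID),
    parent = parent,
    stringsAsFactors = FALSE)
  out[order(out$scaffold, out$start, out$end, out$type, out$id), ]
}

#' Write / read sRNA reads (BED-like TSV)
#'
#' Columns: scaffold, start, end, length, strand, count, five_prime,
#' library_id; one header line. A library set round-trips through a
#' manifest of per-library totals.
#'
#' @param libraries List of sRNA library objects.
#' @param dir Output directory (one `reads_<library>.tsv` per library plus
#'   `manifest.tsv`).
#' @return `read_srna_libraries` returns the list of library objects.
#' @export
write_srna_libraries <- function(libraries, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest <- data.frame(
    library_id = vapply(libraries, `[[`, character(1), "library_id"),
    tissue = vapply(libraries, `[[`, character(1), "tissue"),
    replicate = vapply(libraries, function(l) as.integer(l$replicate), integer(1)),
    total_mapped_reads = vapply(libraries, function(l) as.numeric(l$total_mapped_reads),
                                numeric(1)),
    stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (l in libraries) {
    utils::write.table(l$reads, file.path(dir, sprintf("reads_%s.tsv", l$library_id)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_srna_libraries
#' @export
read_srna_libraries <- function(dir) {
  manifest <- utils::read.table(file.path(dir, "manifest.tsv"), sep = "\t",
                                header = TRUE, stringsAsFactors = FALSE)
  libs <- lapply(seq_len(nrow(manifest)), function(i) {
    reads <- utils::read.table(
      file.path(dir, sprintf("reads_%s.tsv", manifest$library_id[i])),
      sep = "\t", header = TRUE, stringsAsFactors = FALSE)
    list(library_id = manifest$library_id[i], tissue = manifest$tissue[i],
         replicate = manifest$replicate[i],
         total_mapped_reads = manifest$total_mapped_reads[i], reads = reads)
  })
  names(libs) <- manifest$library_id
  libs
}

#' Write / read methylation calls (TSV)
#'
#' MethylDackel-adjacent dialect: scaffold, 1-based position, strand,
#' context, methylated count, total count (plus any extra columns).
#'
#' @param calls Methylation call data frame.
#' @param path File path.
#' @export
write_methylation <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_methylation
#' @export
read_methylation <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write / read a counts matrix (TSV, genes in rows)
#'
#' @param counts Integer matrix with row and column names.
#' @param path File path.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Write / read hairpin candidates (FASTA + structure/read TSVs)
#'
#' Sequences go to `<stem>.fa`, structures and mature intervals to
#' `<stem>.str.tsv`, read stacks to `<stem>.reads.tsv`.
#'
#' @param candidates List of hairpin candidates ([gen_hairpin_set()]).
#' @param stem Path stem.
#' @export
write_hairpins <- function(candidates, stem) {
  seqs <- Biostrings::RNAStringSet(vapply(candidates, `[[`, character(1), "sequence"))
  names(seqs) <- vapply(candidates, `[[`, character(1), "id")
  Biostrings::writeXStringSet(seqs, paste0(stem, ".fa"))
  str_df <- data.frame(
    id = names(seqs),
    structure = vapply(candidates, `[[`, character(1), "structure"),
    mature_start = vapply(candidates, function(x) x$mature[1], integer(1)),
    mature_end = vapply(candidates, function(x) x$mature[2], integer(1)),
    stringsAsFactors = FALSE)
  utils::write.table(str_df, paste0(stem, ".str.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  reads <- do.call(rbind, lapply(candidates, function(x) {
    cbind(id = x$id, x$reads)
  }))
  utils::write.table(reads, paste0(stem, ".reads.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(stem)
}

#' @rdname write_hairpins
#' @export
read_hairpins <- function(stem) {
  seqs <- Biostrings::readRNAStringSet(paste0(stem, ".fa"))
  str_df <- utils::read.table(paste0(stem, ".str.tsv"), sep = "\t",
                              header = TRUE, stringsAsFactors = FALSE)
  reads <- utils::read.table(paste0(stem, ".reads.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(str_df)), function(i) {
    id <- str_df$id[i]
    list(id = id, sequence = as.character(seqs[[id]]),
         structure = str_df$structure[i],
         mature = c(str_df$mature_start[i], str_df$mature_end[i]),
         reads = reads[reads$id == id, c("start", "end", "count"),
                       drop = FALSE])
  })
  names(out) <- str_df$id
  out
}

#' Write / read simple TSV tables (contigs, k-mer histograms, variants)
#'
#' @param table Data frame.
#' @param path File path.
#' @export
write_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write / read a genotype dosage matrix (TSV)
#'
#' Columns: scaffold, position, then one dosage column per sample.
#'
#' @param genotypes List with `markers` and `dosage`.
#' @param path File path.
#' @export
write_genotypes <- function(genotypes, path) {
  df <- cbind(genotypes$markers, as.data.frame(genotypes$dosage))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  dosage <- as.matrix(df[, -(1:2), drop = FALSE])
  storage.mode(dosage) <- "integer"
  list(markers = df[, 1:2], dosage = dosage)
}

#' Convert SAM alignments to the sRNA read table
#'
#' Minimal converter for headered SAM text: primary alignments only,
#' optional MAPQ filter, read length taken from the sequence, 5'
#' nucleotide strand-aware (reverse-complemented for minus-strand
#' alignments, reported in the RNA alphabet).
#'
#' @param path SAM file path.
#' @param min_mapq Minimum MAPQ.
#' @return sRNA read data frame (count 1 per alignment row).
#' @export
sam_to_srna_reads <- function(path, min_mapq = 0L) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines)) {
    return(data.frame(scaffold = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      strand = character(0), count = integer(0),
                      five_prime = character(0), stringsAsFactors = FALSE))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  flag <- vapply(f, function(x) as.integer(x[2]), integer(1))
  mapq <- vapply(f, function(x) as.integer(x[5]), integer(1))
  keep <- bitwAnd(flag, 0x900) == 0 & bitwAnd(flag, 0x4) == 0 & mapq >= min_mapq
  f <- f[keep]; flag <- flag[keep]
  seq <- vapply(f, `[[`, character(1), 10)
  len <- nchar(seq)
  start <- vapply(f, function(x) as.integer(x[4]), integer(1)) - 1L
  minus <- bitwAnd(flag, 0x10) != 0
  five <- ifelse(minus,
                 chartr("ACGT", "UGCA", substr(seq, len, len)),
                 chartr("T", "U", substr(seq, 1, 1)))
  data.frame(scaffold = vapply(f, `[[`, character(1), 3),
             start = start, end = start + len, length = len,
             strand = ifelse(minus, "-", "+"), count = 1L,
             five_prime = five, stringsAsFactors = FALSE)
}
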