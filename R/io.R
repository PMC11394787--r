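#' Write an annotation tibble as GTF
#'
#' Emits transcript and exon features (1-based inclusive coordinates) with
#' `gene_id`, `transcript_id` and `biotype` attributes via rtracklayer.
#'
#' @param annotation Annotation tibble with an `exons` list-column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(annotation, path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("rtracklayer is required for GTF output")
  }
  rows <- purrr::map_dfr(seq_len(nrow(annotation)), function(i) {
    a <- annotation[i, ]
    ex <- a$exons[[1]]
    bind_rows(
      tibble(type = "transcript", start = a$start, end = a$end),
      tibble(type = "exon", start = ex$start, end = ex$end)
    ) %>%
      mutate(chrom = a$chrom, strand = a$strand, gene_id = a$gene_id,
             transcript_id = a$transcript_id, biotype = a$biotype)
  })
  gr <- GenomicRanges::GRanges(
    seqnames = rows$chrom,
    ranges = IRanges::IRanges(rows$start, rows$end),
    strand = rows$strand
  )
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = "lncprog", type = rows$type, gene_id = rows$gene_id,
    transcript_id = rows$transcript_id, biotype = rows$biotype
  )
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read a GTF into the package's annotation tibble
#'
#' Reconstructs one row per transcript with an `exons` list-column,
#' `n_exons`, `spliced_length` and (when present) `biotype`.
#'
#' @param path GTF file with exon features carrying `gene_id` and
#'   `transcript_id` attributes.
#' @return Annotation tibble.
#' @export
read_gtf <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("rtracklayer is required for GTF input")
  }
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as_tibble(as.data.frame(gr))
  ex <- filter(df, .data$type == "exon")
  if (!"biotype" %in% names(ex)) ex$biotype <- NA_character_
  ex %>%
    group_by(.data$transcript_id) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    summarise(
      gene_id = .data$gene_id[1],
      chrom = as.character(.data$seqnames[1]),
      strand = as.character(.data$strand[1]),
      n_exons = n(),
      spliced_length = sum(.data$end - .data$start + 1),
      biotype = .data$biotype[1],
      exons = {
        es <- as.numeric(.data$start)
        ee <- as.numeric(.data$end)
        list(tibble(start = es, end = ee))
      },
      # assigned last: these names shadow the exon-level columns above
      start = min(.data$start), end = max(.data$end),
      .groups = "drop"
    ) %>%
    select("transcript_id", "gene_id", "chrom", "start", "end", "strand",
           "n_exons", "spliced_length", "biotype", "exons")
}

#' Write spliced transcript sequences as FASTA
#'
#' @param sequences Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("Biostrings is required for FASTA output")
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

#' Read transcript sequences from FASTA
#'
#' @param path FASTA file.
#' @return Named character vector.
#' @export
read_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("Biostrings is required for FASTA input")
  }
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Read a counts TSV (transcript_id + one column per sample)
#' @param path TSV path.
#' @return Counts tibble.
#' @export
read_counts <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE) %>%
    rename(transcript_id = 1)
}

#' Read the sample-label sidecar TSV (columns sample_id, group)
#' @param path TSV path.
#' @return Samples tibble.
#' @export
read_samples <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("sample_id", "group") %in% names(tb))) {
    abort_schema("sample table needs columns `sample_id` and `group`")
  }
  tb
}
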