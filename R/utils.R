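#' Convert a counts tibble to a numeric matrix
#'
#' Throughout the package expression data travel as a tibble whose first
#' column (`transcript_id`) identifies the transcript and whose remaining
#' columns are samples. This helper converts to the row-named numeric matrix
#' used internally.
#'
#' @param counts A tibble with a `transcript_id` column and one numeric
#'   column per sample.
#' @return A numeric matrix, transcripts in rows, samples in columns.
#' @export
counts_matrix <- function(counts) {
  stopifnot(is.data.frame(counts), "transcript_id" %in% names(counts))
  ids <- as.character(counts$transcript_id)
  m <- as.matrix(counts[setdiff(names(counts), "transcript_id")])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Convert an expression matrix back to the package's tibble layout
#'
#' @param m Numeric matrix with transcript row names and sample column names.
#' @return Tibble with `transcript_id` first.
#' @export
counts_tibble <- function(m) {
  dplyr::bind_cols(tibble(transcript_id = rownames(m)), as_tibble(m))
}

# Benjamini-Hochberg step-up; NA-safe thin wrapper kept in one place so the
# adjustment convention is uniform across contrasts.
bh_adjust <- function(p) {
  p.adjust(p, method = "BH")
}

# group labels: named vector sample_id -> group from a samples tibble
sample_groups <- function(samples) {
  stopifnot(is.data.frame(samples), all(c("sample_id", "group") %in% names(samples)))
  setNames(as.character(samples$group), as.character(samples$sample_id))
}

abort_arg <- function(msg) abort(msg, class = "lncprog_argument_error")
abort_schema <- function(msg) abort(msg, class = "lncprog_schema_error")
abort_sizing <- function(msg) abort(msg, class = "lncprog_sizing_error")

# Derive a reproducible 32-bit sub-seed from a master seed and a stage tag.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 1103L + h) %% 2147483647)
}
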