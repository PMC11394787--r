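#' Screen transcripts for lncRNA candidacy
#'
#' Basic screen applied before coding-potential assessment: a candidate must
#' have spliced length strictly greater than 200 nt and at least two exons.
#'
#' @param records Annotation tibble with columns `spliced_length` and
#'   `n_exons` (as produced by [generate_annotation()] or [read_gtf()]).
#' @return The retained rows, same columns; possibly empty.
#' @export
filter_candidates <- function(records) {
  stopifnot(all(c("spliced_length", "n_exons") %in% names(records)))
  filter(records, .data$spliced_length > 200, .data$n_exons >= 2)
}

.coding_tools <- c("cpc", "cnci", "cpat", "plek", "cppred")

#' Five-tool consensus noncoding call
#'
#' A transcript is accepted as noncoding only if all five coding-potential
#' tools (CPC, CNCI, CPAT, PLEK, CPPred) call it noncoding.
#'
#' @param calls Tibble with `transcript_id` and one column per tool holding
#'   `"coding"` or `"noncoding"`.
#' @return Tibble `transcript_id`, `noncoding` (logical).
#' @export
consensus_noncoding <- function(calls) {
  if (!is.data.frame(calls) || !"transcript_id" %in% names(calls)) {
    abort_schema("`calls` must be a data frame with a `transcript_id` column")
  }
  tools_present <- setdiff(names(calls), "transcript_id")
  if (!setequal(tools_present, .coding_tools)) {
    abort_schema(paste0(
      "verdict table must have exactly the five tool columns ",
      paste(.coding_tools, collapse = ", ")))
  }
  vals <- as.matrix(calls[.coding_tools])
  if (!all(vals %in% c("coding", "noncoding"))) {
    abort_schema("verdicts must be 'coding' or 'noncoding'")
  }
  tibble(transcript_id = calls$transcript_id,
         noncoding = rowSums(vals == "noncoding") == length(.coding_tools))
}

# span-to-span distance (0 on overlap, Inf across chromosomes)
.span_distance <- function(chrom1, s1, e1, chrom2, s2, e2) {
  ifelse(chrom1 != chrom2, Inf, pmax(0, pmax(s1, s2) - pmin(e1, e2)))
}

# is every exon of `rec` inside one intron of one same-strand reference
# isoform? (the strict reading of "contained entirely in an intron")
.in_intron_of <- function(rec, ref_row) {
  if (rec$chrom != ref_row$chrom || rec$strand != ref_row$strand) return(FALSE)
  ex <- ref_row$exons[[1]]
  if (nrow(ex) < 2) return(FALSE)
  introns <- tibble(start = head(ex$end, -1) + 1, end = tail(ex$start, -1) - 1)
  any(vapply(seq_len(nrow(introns)), function(i) {
    rec$start >= introns$start[i] && rec$end <= introns$end[i]
  }, logical(1)))
}

# does `rec` contain a reference transcript wholly within one of its introns?
.contains_in_intron <- function(rec, ref_row) {
  if (rec$chrom != ref_row$chrom || rec$strand != ref_row$strand) return(FALSE)
  ex <- rec$exons[[1]]
  if (nrow(ex) < 2) return(FALSE)
  introns <- tibble(start = head(ex$end, -1) + 1, end = tail(ex$start, -1) - 1)
  any(introns$start <= ref_row$start & ref_row$end <= introns$end)
}

# >= 1 bp exon-exon overlap between rec and ref_row
.exon_overlap <- function(rec, ref_row) {
  if (rec$chrom != ref_row$chrom) return(FALSE)
  a <- rec$exons[[1]]
  b <- ref_row$exons[[1]]
  for (i in seq_len(nrow(a))) {
    if (any(a$start[i] <= b$end & b$start <= a$end[i])) return(TRUE)
  }
  FALSE
}

# exact same exon chain on the same strand/chrom as some reference isoform
.is_known <- function(rec, ref_row) {
  if (rec$chrom != ref_row$chrom || rec$strand != ref_row$strand) return(FALSE)
  a <- rec$exons[[1]]
  b <- ref_row$exons[[1]]
  nrow(a) == nrow(b) && all(a$start == b$start) && all(a$end == b$end)
}

#' Classify novel transcripts against a reference annotation
#'
#' Assigns each record one of the class codes `known`, `i` (wholly inside an
#' intron of a same-strand reference isoform), `y` (a reference transcript
#' wholly inside one of the record's introns), `p` (within 2 kb of a
#' reference span), or `u` (intergenic), with precedence
#' known > i > y > p > u, and a positional type: `intronic` (the code-i
#' geometry), else `antisense` (>= 1 bp exonic overlap with an
#' opposite-strand reference), else `intergenic`.
#'
#' An empty reference classifies everything `u`/`intergenic`.
#'
#' @param records,reference Annotation tibbles with `exons` list-columns.
#' @return Tibble `transcript_id`, `class_code`, `positional_type`,
#'   `matched_reference` (first reference id supporting the code, or NA).
#' @export
classify_vs_reference <- function(records, reference) {
  stopifnot("exons" %in% names(records))
  out <- purrr::map_dfr(seq_len(nrow(records)), function(i) {
    rec <- records[i, ]
    code <- "u"
    match_id <- NA_character_
    if (nrow(reference) > 0) {
      near <- reference[reference$chrom == rec$chrom &
                          .span_distance(reference$chrom, reference$start,
                                         reference$end, rec$chrom, rec$start,
                                         rec$end) <= 2000, , drop = FALSE]
      near <- arrange(near, .data$transcript_id)
      pick <- function(pred) {
        for (j in seq_len(nrow(near))) {
          if (pred(rec, near[j, ])) return(near$transcript_id[j])
        }
        NA_character_
      }
      checks <- list(known = .is_known, i = .in_intron_of,
                     y = .contains_in_intron)
      for (code_k in names(checks)) {
        m <- pick(checks[[code_k]])
        if (!is.na(m)) {
          code <- code_k
          match_id <- m
          break
        }
      }
      if (code == "u" && nrow(near) > 0) {
        code <- "p"
        match_id <- near$transcript_id[1]
      }
    }
    ptype <- if (code == "i") "intronic" else {
      anti <- nrow(reference) > 0 && any(vapply(seq_len(nrow(reference)), function(j) {
        reference$strand[j] != rec$strand && .exon_overlap(rec, reference[j, ])
      }, logical(1)))
      if (anti) "antisense" else "intergenic"
    }
    tibble(transcript_id = rec$transcript_id, class_code = code,
           positional_type = ptype, matched_reference = match_id)
  })
  out
}
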