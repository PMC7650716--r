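#' Trim the 3' adapter from read sequences
#'
#' Locates the leftmost occurrence of an adapter prefix with at least
#' `min_overlap` nt of overlap, allowing one mismatch for overlaps of
#' `mm_min_overlap` nt or more and none for shorter overlaps, and returns
#' the insert upstream of it. Reads without a detectable adapter are
#' returned unchanged with `found = FALSE`; they may be full-length
#' inserts and are not discarded here.
#'
#' @param sequence Character vector of read sequences.
#' @param adapter3 3' adapter sequence (at least 7 nt).
#' @param min_overlap Minimum adapter prefix overlap (default 7).
#' @param mm_min_overlap Minimum overlap for which one mismatch is
#'   tolerated (default 10).
#' @return data.frame with columns `insert` and `found`.
#' @export
#' @examples
#' trim_adapter("ACGTACGTACGTACGTACGTTGGAATTCTCGGGTGCCAAGG",
#'              "TGGAATTCTCGGGTGCCAAGG")
trim_adapter <- function(sequence, adapter3,
                         min_overlap = 7L, mm_min_overlap = 10L) {
  if (nchar(adapter3) < 7L) stop("adapter must be at least 7 nt")
  pos <- cpp_adapter_pos(sequence, adapter3, min_overlap, mm_min_overlap)
  found <- pos > 0L
  insert <- sequence
  insert[found] <- substr(sequence[found], 1L, pos[found] - 1L)
  data.frame(insert = insert, found = found, stringsAsFactors = FALSE)
}

#' Mean-quality filter
#'
#' A read passes when the mean PHRED score over its (trimmed) insert is at
#' least `min_mean_q`; the boundary is inclusive. Empty inserts fail.
#'
#' @param quality PHRED+33 quality strings.
#' @param insert_len Length of the insert the quality applies to
#'   (defaults to the full string).
#' @param min_mean_q Minimum mean PHRED score (default 20).
#' @return Logical vector.
#' @export
quality_pass <- function(quality, insert_len = nchar(quality), min_mean_q = 20) {
  mq <- cpp_mean_qual(quality, as.integer(insert_len))
  !is.nan(mq) & mq >= min_mean_q
}

#' Small RNA length filter
#'
#' Keeps sequences of 18 to 35 nt inclusive, the standard small RNA
#' window spanning the 21-24 nt functional classes.
#'
#' @param sequence Character vector (or integer lengths).
#' @param min_len,max_len Inclusive bounds (defaults 18 and 35).
#' @return Logical vector.
#' @export
length_filter <- function(sequence, min_len = 18L, max_len = 35L) {
  len <- if (is.character(sequence)) nchar(sequence) else sequence
  len >= min_len & len <= max_len
}

#' Collapse sequences to unique tags with counts
#'
#' @param sequences Character vector of clean insert sequences.
#' @return data.frame with `sequence`, `count`, ordered by decreasing
#'   count then sequence.
#' @export
collapse_tags <- function(sequences) {
  if (!length(sequences)) {
    return(data.frame(sequence = character(), count = integer(),
                      stringsAsFactors = FALSE))
  }
  tab <- table(sequences)
  out <- data.frame(sequence = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out[order(-out$count, out$sequence), , drop = FALSE] |>
    (\(d) { rownames(d) <- NULL; d })()
}

#' Clean one library and collapse it to unique tags
#'
#' Applies, in order: 3' adapter trimming, removal of adapter-only reads
#' (empty insert), mean-quality filtering over the insert, and the
#' 18-35 nt length filter, then collapses surviving inserts to unique
#' tags with counts. The stats ledger balances exactly:
#' `raw = clean + discarded_adapter + discarded_quality + discarded_length`.
#'
#' @param records data.frame from [read_fastq()].
#' @param adapter3 3' adapter sequence.
#' @param min_mean_q Mean PHRED threshold (default 20).
#' @param min_len,max_len Length bounds (defaults 18, 35).
#' @param library Library label stored in the stats.
#' @param strict_adapter Discard reads without a detectable adapter
#'   (default FALSE: such reads are kept if they pass the other filters).
#' @return list with `tags` (sequence/count data.frame) and `stats`
#'   (one-row data.frame plus a `length_histogram` attribute).
#' @export
preprocess_library <- function(records, adapter3, min_mean_q = 20,
                               min_len = 18L, max_len = 35L,
                               library = "library", strict_adapter = FALSE) {
  raw <- nrow(records)
  tr <- trim_adapter(records$sequence, adapter3)
  empty <- nchar(tr$insert) == 0L
  no_adapter <- !tr$found & strict_adapter
  drop_adapter <- empty | no_adapter

  qok <- quality_pass(records$quality, nchar(tr$insert), min_mean_q)
  drop_quality <- !drop_adapter & !qok

  lok <- length_filter(tr$insert, min_len, max_len)
  drop_length <- !drop_adapter & !drop_quality & !lok

  keep <- !(drop_adapter | drop_quality | drop_length)
  inserts <- tr$insert[keep]
  hist <- table(factor(nchar(inserts), levels = min_len:max_len))
  stats <- data.frame(library = library, raw = raw,
                      clean = sum(keep),
                      discarded_adapter = sum(drop_adapter),
                      discarded_quality = sum(drop_quality),
                      discarded_length = sum(drop_length),
                      stringsAsFactors = FALSE)
  attr(stats, "length_histogram") <- setNames(as.integer(hist), names(hist))
  list(tags = collapse_tags(inserts), stats = stats)
}

#' Merge per-library tag tables into a count matrix
#'
#' @param tag_tables Named list of `tags` data.frames (one per library).
#' @return data.frame with `sequence` plus one integer count column per
#'   library; absent tags count 0.
#' @export
merge_tag_counts <- function(tag_tables) {
  stopifnot(length(tag_tables) > 0, !is.null(names(tag_tables)))
  seqs <- sort(unique(unlist(lapply(tag_tables, `[[`, "sequence"))))
  out <- data.frame(sequence = seqs, stringsAsFactors = FALSE)
  for (lib in names(tag_tables)) {
    tt <- tag_tables[[lib]]
    cnt <- integer(length(seqs))
    cnt[match(tt$sequence, seqs)] <- tt$count
    out[[lib]] <- cnt
  }
  out
}
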