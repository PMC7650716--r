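#' Map tags to a reference by exact match
#'
#' Reports every exact occurrence of each tag on both strands of the
#' reference contigs. Minus-strand hits are positions whose reverse
#' complement equals the tag. Tags containing non-ACGT characters cannot
#' match and get no hits.
#'
#' @param sequences Character vector of tag sequences.
#' @param reference Named `DNAStringSet` (or named character vector) of
#'   reference contigs.
#' @return data.frame with `sequence`, `contig`, `start` (0-based),
#'   `end` (exclusive), `strand`.
#' @export
map_tags <- function(sequences, reference) {
  if (!methods::is(reference, "DNAStringSet")) {
    reference <- Biostrings::DNAStringSet(unlist(reference))
  }
  seqs <- unique(sequences)
  seqs <- seqs[grepl("^[ACGT]+$", seqs)]
  empty <- data.frame(sequence = character(), contig = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE)
  if (!length(seqs)) return(empty)
  res <- list()
  widths <- nchar(seqs)
  for (w in sort(unique(widths))) {
    sw <- seqs[widths == w]
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(setNames(sw, sw)))
    for (cn in names(reference)) {
      subj <- reference[[cn]]
      L <- length(subj)
      if (w > L) next
      for (strand in c("+", "-")) {
        s2 <- if (strand == "+") subj else Biostrings::reverseComplement(subj)
        mi <- Biostrings::matchPDict(pd, s2)
        nhit <- S4Vectors::elementNROWS(mi)
        if (!sum(nhit)) next
        u <- unlist(mi)   # IRanges, names = pattern (tag) sequences
        st <- IRanges::start(u); en <- IRanges::end(u)
        if (strand == "-") {
          st2 <- L - en + 1L; en <- L - IRanges::start(u) + 1L; st <- st2
        }
        res[[length(res) + 1L]] <- data.frame(
          sequence = names(u), contig = cn, start = st - 1L, end = en,
          strand = strand, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  out <- out[order(out$sequence, out$contig, out$start, out$strand), ]
  rownames(out) <- NULL
  out
}

#' @rdname map_tags
#' @param tag A single tag sequence.
#' @export
map_perfect <- function(tag, reference) {
  stopifnot(length(tag) == 1L)
  map_tags(tag, reference)[, -1L]
}

#' Category precedence used by the classifier
#' @return Character vector, highest priority first.
#' @export
category_precedence <- function() {
  c("miRNA", "mt", "cp", "rRNA", "tRNA", "snRNA", "snoRNA", "lncRNA",
    "mRNA", "repeats")
}

#' Classify tags into non-coding RNA categories
#'
#' A tag matches a category when any of its exact hits overlaps an
#' annotation interval of that category by at least half the tag length
#' (strand-agnostic). Conflicts are resolved by a fixed precedence
#' ([category_precedence()]): miRNA first, then organelles, then the
#' structural RNA classes, then repeats. Tags with a catalog miRNA
#' assignment are `miRNA` regardless of genomic overlaps. Tags matching
#' nothing are `unclassified`. The result is a strict partition, so
#' category counts are disjoint.
#'
#' @param sequences Character vector of tag sequences.
#' @param hits data.frame from [map_tags()] (may cover several contigs).
#' @param annotation Annotation data.frame (see [read_annotation()]).
#' @param mirna_tags Optional character vector of tag sequences already
#'   assigned to a catalog miRNA.
#' @return Character vector of categories, parallel to `sequences`.
#' @export
classify_tags <- function(sequences, hits, annotation, mirna_tags = NULL) {
  cats <- setNames(rep("unclassified", length(sequences)), NULL)
  prec <- category_precedence()
  if (nrow(hits) && nrow(annotation)) {
    hg <- GenomicRanges::GRanges(hits$contig,
                                 IRanges::IRanges(hits$start + 1L, hits$end))
    ag <- GenomicRanges::GRanges(annotation$contig,
                                 IRanges::IRanges(annotation$start + 1L,
                                                  annotation$end))
    ov <- GenomicRanges::findOverlaps(hg, ag, ignore.strand = TRUE)
    if (length(ov)) {
      qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
      w <- IRanges::width(IRanges::pintersect(IRanges::ranges(hg)[qh],
                                              IRanges::ranges(ag)[sh]))
      tag_len <- nchar(hits$sequence[qh])
      keep <- w >= tag_len / 2
      if (any(keep)) {
        df <- data.frame(sequence = hits$sequence[qh][keep],
                         category = annotation$category[sh][keep],
                         stringsAsFactors = FALSE)
        rank <- match(df$category, prec)
        best <- tapply(rank, df$sequence, min)
        i <- match(sequences, names(best))
        cats[!is.na(i)] <- prec[best[i[!is.na(i)]]]
      }
    }
  }
  if (!is.null(mirna_tags)) cats[sequences %in% mirna_tags] <- "miRNA"
  cats
}

#' @rdname classify_tags
#' @param tag A single tag sequence.
#' @param is_mirna Whether the tag has a catalog miRNA assignment.
#' @export
classify_tag <- function(tag, hits, annotation, is_mirna = FALSE) {
  classify_tags(tag, hits, annotation,
                mirna_tags = if (is_mirna) tag else NULL)
}

#' Annotate tags against a mature miRNA catalog
#'
#' Considers every ungapped placement of each tag against each mature
#' with 5'/3' end offsets between -2 and 2 and an overlap of at least the
#' mature length minus 2. Internal mismatches are Hamming distance over
#' the overlap; overhang bases beyond the mature ends are validated
#' against the precursor flanks when a precursor is available, and count
#' as mismatches otherwise. The best hit minimizes
#' (mismatches, |off5| + |off3|, name) deterministically.
#'
#' @param sequences Character vector of tag sequences.
#' @param catalog Catalog data.frame (see [read_catalog()]).
#' @param max_mm Maximum mismatches, 0 for exact-and-variant-only search
#'   or 2 to tolerate polymorphisms (default 2).
#' @param max_off Maximum absolute end offset (default 2).
#' @return data.frame with `sequence`, `mirna_name`, `family`,
#'   `mismatches`, `off5`, `off3`; NA columns where no placement
#'   satisfies the bounds.
#' @export
annotate_tags <- function(sequences, catalog, max_mm = 2L, max_off = 2L) {
  stopifnot(max_mm >= 0L)
  ord <- order(catalog$name)
  cat_s <- catalog[ord, , drop = FALSE]
  fl <- catalog_flanks(cat_s, width = max_off)
  hit <- cpp_match_mirna(sequences, cat_s$mature, fl$flank5, fl$flank3,
                         as.integer(max_mm), as.integer(max_off))
  idx <- hit$idx
  data.frame(sequence = sequences,
             mirna_name = ifelse(idx > 0L, cat_s$name[pmax(idx, 1L)], NA),
             family = ifelse(idx > 0L, cat_s$family[pmax(idx, 1L)], NA),
             mismatches = hit$mismatches,
             off5 = hit$off5, off3 = hit$off3,
             stringsAsFactors = FALSE)
}

#' @rdname annotate_tags
#' @param tag A single tag sequence.
#' @return For `match_mirna`: a one-row data.frame, or NULL when there
#'   is no admissible placement.
#' @export
match_mirna <- function(tag, catalog, max_mm = 2L, max_off = 2L) {
  stopifnot(length(tag) == 1L)
  out <- annotate_tags(tag, catalog, max_mm, max_off)
  if (is.na(out$mirna_name)) NULL else out
}

#' Per-category read counts and percentages
#'
#' Percentages are 100 * reads / clean, rounded half-up to 2 decimals.
#'
#' @param counts Named numeric vector of per-category read counts.
#' @param clean Total clean reads (> 0).
#' @return data.frame with `category`, `reads`, `pct`.
#' @export
summarize_counts <- function(counts, clean) {
  if (clean <= 0) stop("clean read total must be positive")
  data.frame(category = names(counts), reads = as.numeric(counts),
             pct = round_half_up(100 * as.numeric(counts) / clean, 2L),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Library summary across non-coding RNA categories
#'
#' The per-library analog of a sequencing summary table: raw and clean
#' totals, genome-mapped reads, and read counts plus percentages of
#' clean for every category, with catalog miRNA reads split into the
#' study species (`self_prefix`) and other plants.
#'
#' @param tags data.frame `sequence`, `count` for one library.
#' @param categories Character vector of categories per tag (parallel to
#'   `tags$sequence`), from [classify_tags()].
#' @param genome_mapped Logical vector: tag has at least one exact hit on
#'   the reference.
#' @param stats One-row stats data.frame from [preprocess_library()].
#' @param mirna_names Optional per-tag catalog names (to split
#'   self-species from other-plant miRNAs).
#' @param self_prefix Species prefix of the study organism in catalog
#'   names (default `"zma"`).
#' @return data.frame with `category`, `reads`, `pct` (library metadata
#'   in attributes `library`, `raw`, `clean`).
#' @export
summarize_library <- function(tags, categories, genome_mapped, stats,
                              mirna_names = NULL, self_prefix = "zma") {
  clean <- stats$clean
  if (clean <= 0) stop("clean read total is zero; percentages undefined")
  cnt <- function(sel) sum(tags$count[sel])
  is_mir <- categories == "miRNA"
  if (is.null(mirna_names)) mirna_names <- rep(NA_character_, nrow(tags))
  self_mir <- is_mir & startsWith(ifelse(is.na(mirna_names), "", mirna_names),
                                  self_prefix)
  counts <- c("genome-mapped" = cnt(genome_mapped),
              mt = cnt(categories == "mt"),
              cp = cnt(categories == "cp"),
              mRNA = cnt(categories == "mRNA"),
              rRNA = cnt(categories == "rRNA"),
              tRNA = cnt(categories == "tRNA"),
              snRNA = cnt(categories == "snRNA"),
              snoRNA = cnt(categories == "snoRNA"),
              lncRNA = cnt(categories == "lncRNA"),
              repeats = cnt(categories == "repeats"),
              miRNA = cnt(self_mir),
              "other-miRNA" = cnt(is_mir & !self_mir))
  out <- summarize_counts(counts, clean)
  attr(out, "library") <- stats$library
  attr(out, "raw") <- stats$raw
  attr(out, "clean") <- clean
  out
}

#' Detect organelle-derived small RNA hotspots
#'
#' Exact-maps tags to the organelle contigs, merges overlapping hit
#' intervals into maximal regions, and reports regions whose summed tag
#' TPM reaches `min_total_tpm`, sorted by total TPM descending. Strand is
#' ignored in reporting: a hotspot is a genomic interval.
#'
#' @param tags data.frame `sequence`, `count` for one library.
#' @param organelles Named `DNAStringSet`/character vector of organelle
#'   contigs.
#' @param clean_total Clean read total of the library (TPM denominator).
#' @param min_total_tpm Minimum summed TPM for a reported region.
#' @return data.frame with `contig`, `start`, `end`, `span_nt`,
#'   `total_tpm`, `n_tags`.
#' @export
organelle_hotspots <- function(tags, organelles, clean_total,
                               min_total_tpm = 1) {
  hits <- map_tags(tags$sequence, organelles)
  empty <- data.frame(contig = character(), start = integer(),
                      end = integer(), span_nt = integer(),
                      total_tpm = numeric(), n_tags = integer(),
                      stringsAsFactors = FALSE)
  if (!nrow(hits)) return(empty)
  tag_tpm <- setNames(tpm(tags$count, clean_total), tags$sequence)
  hg <- GenomicRanges::GRanges(hits$contig,
                               IRanges::IRanges(hits$start + 1L, hits$end))
  merged <- GenomicRanges::reduce(hg, ignore.strand = TRUE)
  ov <- GenomicRanges::findOverlaps(hg, merged, ignore.strand = TRUE)
  region <- S4Vectors::subjectHits(ov)
  rows <- lapply(seq_along(merged), function(i) {
    tag_seqs <- unique(hits$sequence[S4Vectors::queryHits(ov)[region == i]])
    data.frame(contig = as.character(GenomicRanges::seqnames(merged))[i],
               start = GenomicRanges::start(merged)[i] - 1L,
               end = GenomicRanges::end(merged)[i],
               span_nt = GenomicRanges::width(merged)[i],
               total_tpm = sum(tag_tpm[tag_seqs]),
               n_tags = length(tag_seqs), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$total_tpm >= min_total_tpm, , drop = FALSE]
  out <- out[order(-out$total_tpm, out$contig, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
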