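#' Read a FASTQ file of small RNA reads
#'
#' Parses plain 4-line FASTQ (PHRED+33). `U`/`u` in the sequence line is
#' normalized to `T` and sequences are upper-cased, so RNA-space input is
#' accepted transparently. Malformed records raise an error naming the
#' offending line.
#'
#' @param path Path to an uncompressed or gzip-compressed FASTQ file.
#' @return A data.frame with columns `id`, `sequence`, `quality`.
#' @export
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1", "ACGU", "+", "IIII"), fq)
#' read_fastq(fq)$sequence  # "ACGT"
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  lines <- readLines(path)
  n <- length(lines)
  if (n == 0L) {
    return(data.frame(id = character(), sequence = character(),
                      quality = character(), stringsAsFactors = FALSE))
  }
  if (n %% 4L != 0L) {
    stop("truncated FASTQ record starting at line ", 4L * (n %/% 4L) + 1L,
         " in ", path)
  }
  hdr <- lines[seq(1L, n, by = 4L)]
  seqs <- lines[seq(2L, n, by = 4L)]
  plus <- lines[seq(3L, n, by = 4L)]
  qual <- lines[seq(4L, n, by = 4L)]
  bad <- which(substr(hdr, 1L, 1L) != "@")
  if (length(bad)) {
    stop("FASTQ header does not start with '@' at line ", 4L * (bad[1L] - 1L) + 1L)
  }
  bad <- which(substr(plus, 1L, 1L) != "+")
  if (length(bad)) {
    stop("FASTQ separator line is not '+' at line ", 4L * (bad[1L] - 1L) + 3L)
  }
  bad <- which(nchar(seqs) != nchar(qual))
  if (length(bad)) {
    stop("sequence/quality length mismatch at line ", 4L * (bad[1L] - 1L) + 2L)
  }
  if (any(nchar(seqs) == 0L)) {
    bad <- which(nchar(seqs) == 0L)[1L]
    stop("empty sequence at line ", 4L * (bad - 1L) + 2L)
  }
  data.frame(id = sub("^@", "", sub("\\s.*$", "", hdr)),
             sequence = normalize_seq(seqs),
             quality = qual, stringsAsFactors = FALSE)
}

#' Write reads as FASTQ
#'
#' @param reads data.frame with `id`, `sequence`, `quality` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "sequence", "quality") %in% names(reads)))
  if (any(nchar(reads$sequence) != nchar(reads$quality))) {
    stop("sequence/quality length mismatch")
  }
  out <- character(4L * nrow(reads))
  out[seq(1L, length(out), by = 4L)] <- paste0("@", reads$id)
  out[seq(2L, length(out), by = 4L)] <- reads$sequence
  out[seq(3L, length(out), by = 4L)] <- "+"
  out[seq(4L, length(out), by = 4L)] <- reads$quality
  writeLines(out, path)
  invisible(path)
}

normalize_seq <- function(x) chartr("uU", "tT", x) |> toupper()

#' Derive the miRNA family label from a catalog name
#'
#' Strips the species prefix up to the first `miR` token and drops the
#' trailing variant letters/arm suffix after the family number, so
#' `zma-miR156k` and `miR167cdeg` both reduce to their family
#' (`miR156`, `miR167`).
#'
#' @param name Character vector of miRNA identifiers.
#' @return Character vector of family labels.
#' @export
infer_family <- function(name) {
  fam <- regmatches(name, regexpr("miR[0-9]+", name))
  if (length(fam) != length(name)) {
    missing <- name[!grepl("miR[0-9]+", name)]
    stop("cannot infer miRNA family from name(s): ",
         paste(missing, collapse = ", "))
  }
  fam
}

#' Read a mature miRNA catalog
#'
#' Loads mature sequences from FASTA plus an optional metadata table with
#' columns `name` and any of `family`, `precursor`. When no metadata is
#' given the family is inferred from the entry name (see [infer_family()]).
#' Sequences are normalized to DNA alphabet (U to T).
#'
#' @param fasta_path FASTA of mature sequences, names are catalog names.
#' @param meta_path Optional TSV mapping `name` to `family`/`precursor`.
#' @return data.frame with columns `name`, `family`, `mature`, `precursor`
#'   (NA when unknown).
#' @export
read_catalog <- function(fasta_path, meta_path = NULL) {
  set <- Biostrings::readBStringSet(fasta_path)
  cat <- data.frame(name = names(set),
                    mature = normalize_seq(as.character(set)),
                    stringsAsFactors = FALSE)
  cat$family <- NA_character_
  cat$precursor <- NA_character_
  if (!is.null(meta_path)) {
    meta <- read.delim(meta_path, stringsAsFactors = FALSE)
    stopifnot("name" %in% names(meta))
    i <- match(cat$name, meta$name)
    if ("family" %in% names(meta)) cat$family <- meta$family[i]
    if ("precursor" %in% names(meta)) {
      cat$precursor <- normalize_seq(meta$precursor[i])
    }
  }
  missing_fam <- is.na(cat$family) | cat$family == ""
  cat$family[missing_fam] <- infer_family(cat$name[missing_fam])
  rownames(cat) <- NULL
  validate_catalog(cat)
}

#' Validate a catalog data.frame
#'
#' Checks name uniqueness, mature length bounds (18-26 nt), and that each
#' precursor, when present, contains its mature sequence.
#'
#' @param cat data.frame with `name`, `family`, `mature`, `precursor`.
#' @return `cat`, invisibly usable (returned after validation).
#' @export
validate_catalog <- function(cat) {
  stopifnot(all(c("name", "family", "mature", "precursor") %in% names(cat)))
  dup <- cat$name[duplicated(cat$name)]
  if (length(dup)) stop("duplicate catalog names: ", paste(unique(dup), collapse = ", "))
  len <- nchar(cat$mature)
  if (any(len < 18L | len > 26L)) {
    stop("mature sequence length outside [18, 26] for: ",
         paste(cat$name[len < 18L | len > 26L], collapse = ", "))
  }
  has_pre <- !is.na(cat$precursor)
  if (any(has_pre)) {
    inside <- mapply(grepl, cat$mature[has_pre], cat$precursor[has_pre],
                     MoreArgs = list(fixed = TRUE))
    if (!all(inside)) {
      stop("mature sequence not found in its precursor for: ",
           paste(cat$name[has_pre][!inside], collapse = ", "))
    }
  }
  cat
}

#' Precursor flanks around each mature sequence
#'
#' For every catalog entry with a precursor, extracts up to `width` bases
#' immediately 5' and 3' of the first occurrence of the mature within the
#' precursor. Entries without a precursor get empty flanks; overhanging
#' isomiR bases then cannot be validated and count as mismatches.
#'
#' @param cat Catalog data.frame.
#' @param width Maximum flank width (default 2, the positional-variant bound).
#' @return data.frame with `name`, `flank5`, `flank3`.
#' @export
catalog_flanks <- function(cat, width = 2L) {
  f5 <- f3 <- character(nrow(cat))
  for (i in seq_len(nrow(cat))) {
    pre <- cat$precursor[i]
    if (is.na(pre)) next
    pos <- regexpr(cat$mature[i], pre, fixed = TRUE)
    if (pos < 0L) next
    end <- pos + nchar(cat$mature[i]) - 1L
    f5[i] <- substr(pre, max(1L, pos - width), pos - 1L)
    f3[i] <- substr(pre, end + 1L, min(nchar(pre), end + width))
  }
  data.frame(name = cat$name, flank5 = f5, flank3 = f3,
             stringsAsFactors = FALSE)
}

#' Read a BED-like annotation table
#'
#' Six tab-separated columns without header: contig, start (0-based),
#' end (exclusive), name, category, strand. Categories follow the
#' non-coding RNA classes used in library summaries.
#'
#' @param path Path to the annotation file.
#' @return data.frame with typed columns.
#' @export
read_annotation <- function(path) {
  ann <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("contig", "start", "end", "name",
                                  "category", "strand"))
  validate_annotation(ann)
}

#' @rdname read_annotation
#' @param ann data.frame with annotation columns.
#' @export
validate_annotation <- function(ann) {
  stopifnot(all(c("contig", "start", "end", "category", "strand") %in% names(ann)))
  if (any(ann$start < 0L) || any(ann$start >= ann$end)) {
    stop("annotation intervals must satisfy 0 <= start < end")
  }
  bad <- setdiff(unique(ann$category), annotation_categories())
  if (length(bad)) stop("unknown annotation categories: ", paste(bad, collapse = ", "))
  if (!all(ann$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  ann
}

#' Annotation categories recognized by the classifier
#' @return Character vector of category labels.
#' @export
annotation_categories <- function() {
  c("mt", "cp", "mRNA", "rRNA", "tRNA", "snRNA", "snoRNA", "lncRNA",
    "repeats", "miRNA")
}

#' Write an annotation table in the 6-column BED-like layout
#' @param ann Annotation data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  write.table(ann[, c("contig", "start", "end", "name", "category", "strand")],
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Round half away from zero
#'
#' Fixed-precision rounding used for reported percentages and fold
#' changes, where the conventional half-up rule is expected
#' (e.g. -4.385 renders as -4.39), unlike IEEE round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Write a tab-separated results table
#'
#' UTF-8 TSV with a header line. Floating point columns are rendered with
#' two decimals (half-away-from-zero), matching the precision used for
#' percentages and fold-change values in the study tables.
#'
#' @param rows data.frame to write.
#' @param path Output path.
#' @param float_digits Decimals for non-integer numeric columns.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path, float_digits = 2L) {
  out <- as.data.frame(rows, stringsAsFactors = FALSE)
  for (j in seq_along(out)) {
    col <- out[[j]]
    if (is.double(col) && !all(is.na(col)) &&
        any(col[!is.na(col)] != round(col[!is.na(col)]))) {
      out[[j]] <- ifelse(is.na(col), NA,
                         sprintf(paste0("%.", float_digits, "f"),
                                 round_half_up(col, float_digits)))
    }
  }
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write sequences as FASTA
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(unlist(seqs)), path)
  invisible(path)
}
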