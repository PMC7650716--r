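#' Tags-per-million normalization
#'
#' TPM = 1e6 * raw / clean_total, relative to the total clean reads of the
#' same library, so the TPMs of a full library sum to one million.
#'
#' @param raw Raw count vector.
#' @param clean_total Total clean reads in the library (> 0).
#' @return Numeric TPM values.
#' @export
tpm <- function(raw, clean_total) {
  if (any(clean_total <= 0)) stop("clean_total must be positive")
  1e6 * raw / clean_total
}

#' Log2 fold change of normalized counts
#'
#' log2((tpm_treat + pseudo) / (tpm_ctrl + pseudo)). The pseudocount
#' (default 1 TPM) keeps the ratio finite when either side is zero; it is
#' surfaced in every report rather than hidden.
#'
#' @param tpm_treat,tpm_ctrl TPM values in treatment and control.
#' @param pseudo Pseudocount in TPM units (> 0, default 1).
#' @return log2 fold change.
#' @export
log2_fc <- function(tpm_treat, tpm_ctrl, pseudo = 1) {
  if (pseudo <= 0) stop("pseudo must be > 0")
  log2((tpm_treat + pseudo) / (tpm_ctrl + pseudo))
}

#' Raw-count floor across libraries
#'
#' TRUE when the maximum raw count over the libraries reaches `min_raw`
#' (default 50) in at least one library; rows failing the floor are
#' reported as `low_count` rather than tested.
#'
#' @param counts Numeric vector (one row) or matrix/data.frame
#'   (rows = features, columns = libraries).
#' @param min_raw Count floor (default 50).
#' @return Logical scalar or vector (one per row).
#' @export
count_floor <- function(counts, min_raw = 50L) {
  if (is.null(dim(counts))) return(max(counts) >= min_raw)
  apply(as.matrix(counts), 1L, max) >= min_raw
}

#' Differential expression status from a fold change
#'
#' `up` when fc >= threshold, `down` when fc <= -threshold (boundaries
#' inclusive), `unchanged` otherwise; `low_count` overrides when the
#' raw-count floor failed. No p-values are attached: one pooled library
#' per condition supports a descriptive, not inferential, call.
#'
#' @param fc log2 fold change vector.
#' @param floor_passed Logical vector from [count_floor()].
#' @param threshold Positive fold-change threshold (default 1).
#' @return Character vector in {up, down, unchanged, low_count}.
#' @export
de_call <- function(fc, floor_passed = TRUE, threshold = 1) {
  if (threshold <= 0) stop("threshold must be > 0")
  status <- ifelse(fc >= threshold, "up",
                   ifelse(fc <= -threshold, "down", "unchanged"))
  status[!rep_len(floor_passed, length(fc))] <- "low_count"
  status
}

#' Convert a log2 fold change to a linear ratio
#' @param fc log2 fold change.
#' @return 2^fc.
#' @export
fc_to_ratio <- function(fc) 2^fc

#' Build an expression matrix with raw counts and TPM
#'
#' @param counts data.frame with an identifier column (first) plus one raw
#'   count column per library.
#' @param clean_totals Named vector of clean read totals per library.
#' @return list with `counts`, `tpm` (same shape), `clean_totals`.
#' @export
build_expression <- function(counts, clean_totals) {
  libs <- setdiff(names(counts), names(counts)[1L])
  missing <- setdiff(libs, names(clean_totals))
  if (length(missing)) stop("no clean totals for: ", paste(missing, collapse = ", "))
  tpm_df <- counts
  for (lib in libs) tpm_df[[lib]] <- tpm(counts[[lib]], clean_totals[[lib]])
  list(counts = counts, tpm = tpm_df, clean_totals = clean_totals[libs])
}

#' Fold-change matrix over condition pairs
#'
#' Computes, for each row of a count matrix and each (treatment, control)
#' library pair, the log2 fold change of TPMs and its differential
#' expression status under the raw-count floor.
#'
#' @param counts data.frame: identifier column (named `name` or first
#'   column) plus raw count columns per library.
#' @param clean_totals Named vector of per-library clean totals.
#' @param pairs Named list; each element `c(treatment, control)` of
#'   library names, element names label the condition pairs.
#' @param pseudo Pseudocount in TPM (default 1).
#' @param min_raw Raw-count floor (default 50). The floor is evaluated
#'   over the two libraries of each pair.
#' @param threshold Fold-change threshold (default 1).
#' @return list of class `fc_matrix` with `fc` (data.frame `name` +
#'   one column per pair), `status` (same shape), and the parameters.
#' @export
build_fc_matrix <- function(counts, clean_totals, pairs, pseudo = 1,
                            min_raw = 50L, threshold = 1) {
  id_col <- if ("name" %in% names(counts)) "name" else names(counts)[1L]
  expr <- build_expression(counts[, c(id_col, setdiff(names(counts), id_col))],
                           clean_totals)
  fc <- data.frame(name = counts[[id_col]], stringsAsFactors = FALSE)
  status <- fc
  for (p in names(pairs)) {
    tr <- pairs[[p]][1L]; ct <- pairs[[p]][2L]
    if (!all(c(tr, ct) %in% names(counts))) {
      stop("pair '", p, "' names unknown libraries")
    }
    f <- log2_fc(expr$tpm[[tr]], expr$tpm[[ct]], pseudo)
    floor_ok <- count_floor(cbind(counts[[tr]], counts[[ct]]), min_raw)
    fc[[p]] <- f
    status[[p]] <- de_call(f, floor_ok, threshold)
  }
  structure(list(fc = fc, status = status, pseudo = pseudo,
                 min_raw = min_raw, threshold = threshold),
            class = "fc_matrix")
}

#' @export
print.fc_matrix <- function(x, ...) {
  cat("Fold-change matrix:", nrow(x$fc), "rows x", ncol(x$fc) - 1L,
      "condition pairs (pseudo =", x$pseudo, "TPM, floor =", x$min_raw,
      ", |FC| threshold =", x$threshold, ")\n")
  print(head(x$fc, 10L), ...)
  invisible(x)
}
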