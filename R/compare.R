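fc_columns <- function(matrix_df) {
  stopifnot(is.data.frame(matrix_df), "name" %in% names(matrix_df))
  setdiff(names(matrix_df), "name")
}

as_fc_df <- function(x) {
  if (inherits(x, "fc_matrix")) x$fc else x
}

#' Rows responsive in at least one condition
#'
#' @param matrix_df Fold-change matrix: data.frame with a `name` column
#'   plus one numeric log2 FC column per condition pair (or an
#'   `fc_matrix` object).
#' @param threshold Positive |FC| threshold; the boundary is inclusive.
#' @return Character vector of responsive row names, in row order.
#' @export
responsive_set <- function(matrix_df, threshold = 1) {
  stopifnot(threshold > 0)
  df <- as_fc_df(matrix_df)
  vals <- abs(as.matrix(df[, fc_columns(df), drop = FALSE]))
  df$name[apply(vals, 1L, max) >= threshold]
}

#' Global fold-change extrema
#'
#' @inheritParams responsive_set
#' @return list with `min` and `max`, each `list(value, name, column)`;
#'   ties are reported in row order.
#' @export
fc_extrema <- function(matrix_df) {
  df <- as_fc_df(matrix_df)
  cols <- fc_columns(df)
  m <- as.matrix(df[, cols, drop = FALSE])
  if (!length(m)) stop("empty fold-change matrix")
  pick <- function(idx) {
    rc <- which(m == m[idx], arr.ind = TRUE)
    rc <- rc[order(rc[, 1L], rc[, 2L]), , drop = FALSE]
    list(value = m[idx], name = df$name[rc[1L, 1L]], column = cols[rc[1L, 2L]])
  }
  list(min = pick(which.min(m)), max = pick(which.max(m)))
}

#' Directional overlap partition between two conditions
#'
#' Partitions the rows into eight disjoint sets by their regulation
#' status in conditions A and B: concordantly up or down in both,
#' discordant (regulated in both, opposite signs), regulated only in A
#' (up/down), only in B (up/down), or neither. The counts always sum to
#' the number of rows.
#'
#' @inheritParams responsive_set
#' @param colA,colB Condition pair column names.
#' @param status Optional status data.frame (same shape as the FC
#'   matrix, e.g. from [build_fc_matrix()]); rows flagged `low_count`
#'   count as unregulated. When NULL, status is derived from the
#'   threshold alone.
#' @return list of class `venn_partition`: the eight name sets plus a
#'   `counts` vector.
#' @export
venn2 <- function(matrix_df, colA, colB, threshold = 1, status = NULL) {
  df <- as_fc_df(matrix_df)
  if (inherits(matrix_df, "fc_matrix") && is.null(status)) {
    status <- matrix_df$status
  }
  stopifnot(all(c(colA, colB) %in% fc_columns(df)))
  reg <- function(col) {
    s <- if (!is.null(status)) status[[col]] else
      de_call(df[[col]], TRUE, threshold)
    ifelse(s == "up", 1L, ifelse(s == "down", -1L, 0L))
  }
  a <- reg(colA); b <- reg(colB); nm <- df$name
  sets <- list(
    both_up     = nm[a == 1L & b == 1L],
    both_down   = nm[a == -1L & b == -1L],
    discordant  = nm[a * b == -1L],
    only_A_up   = nm[a == 1L & b == 0L],
    only_A_down = nm[a == -1L & b == 0L],
    only_B_up   = nm[a == 0L & b == 1L],
    only_B_down = nm[a == 0L & b == -1L],
    neither     = nm[a == 0L & b == 0L])
  sets$counts <- vapply(sets, length, integer(1L))
  class(sets) <- "venn_partition"
  sets
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("Directional overlap partition:\n")
  print(x$counts)
  invisible(x)
}

#' Attenuation of the stress response under alternated stress
#'
#' Compares each row's fold change under a single stress with the same
#' stress applied second in an alternated treatment. A response is
#' `attenuated` when it keeps its sign but shrinks in magnitude while
#' the single-stress response was regulated, and `lost` when the
#' single-stress response was regulated but the alternated one falls
#' below the regulation threshold.
#'
#' @inheritParams responsive_set
#' @param single_col,alternated_col Column names of the single and
#'   alternated treatments.
#' @return data.frame per row: `name`, `fc_single`, `fc_alternated`,
#'   `same_sign`, `attenuated`, `lost`.
#' @export
attenuation_report <- function(matrix_df, single_col, alternated_col,
                               threshold = 1) {
  df <- as_fc_df(matrix_df)
  stopifnot(all(c(single_col, alternated_col) %in% fc_columns(df)))
  fs <- df[[single_col]]; fa <- df[[alternated_col]]
  reg_s <- abs(fs) >= threshold
  same_sign <- sign(fs) == sign(fa)
  data.frame(name = df$name, fc_single = fs, fc_alternated = fa,
             same_sign = same_sign,
             attenuated = same_sign & abs(fa) < abs(fs) & reg_s,
             lost = reg_s & abs(fa) < threshold,
             stringsAsFactors = FALSE)
}
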