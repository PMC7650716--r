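# Independent brute-force oracles. These deliberately re-derive the scoring
# and grouping semantics from first principles (plain R, exhaustive
# enumeration) so the fast implementations are checked against a second,
# unrelated route.

# Hamming distance between equal-length strings
ham <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Exhaustive-placement scorer for one tag against a catalog: enumerates
# every ungapped placement of the tag against every mature (all shifts),
# then filters by the offset/overlap bounds and picks the minimum of
# (mismatches, |off5|+|off3|, name, off5).
oracle_match <- function(tag, catalog, max_mm = 2, max_off = 2) {
  best <- NULL
  Lt <- nchar(tag)
  for (j in order(catalog$name)) {
    mat <- catalog$mature[j]
    Lm <- nchar(mat)
    pre <- catalog$precursor[j]
    mstart <- if (!is.na(pre)) regexpr(mat, pre, fixed = TRUE)[1] else NA
    for (off5 in (-Lt + 1):(Lm - 1)) {        # every placement with overlap
      off3 <- off5 + Lt - Lm
      if (abs(off5) > max_off || abs(off3) > max_off) next
      lo <- max(off5, 0); hi <- min(off5 + Lt, Lm)
      if (hi - lo < Lm - 2) next
      mm <- ham(substr(tag, lo - off5 + 1, hi - off5), substr(mat, lo + 1, hi))
      if (off5 < 0) {
        for (t in 1:(-off5)) {  # t-th base upstream of the mature 5' end
          tb <- substr(tag, -off5 - t + 1, -off5 - t + 1)
          pb <- if (!is.na(mstart) && mstart - t >= 1) {
            substr(pre, mstart - t, mstart - t)
          } else ""
          if (!identical(tb, pb)) mm <- mm + 1
        }
      }
      if (off3 > 0) {
        for (t in 1:off3) {
          tb <- substr(tag, Lt - off3 + t, Lt - off3 + t)
          p <- if (!is.na(mstart)) mstart + Lm - 1 + t else NA
          pb <- if (!is.na(p) && p <= nchar(pre)) substr(pre, p, p) else ""
          if (!identical(tb, pb)) mm <- mm + 1
        }
      }
      if (mm > max_mm) next
      key <- list(mm = mm, osum = abs(off5) + abs(off3),
                  name = catalog$name[j], off5 = off5, off3 = off3)
      if (is.null(best) ||
          mm < best$mm ||
          (mm == best$mm && key$osum < best$osum) ||
          (mm == best$mm && key$osum == best$osum && key$name < best$name) ||
          (mm == best$mm && key$osum == best$osum && key$name == best$name &&
           off5 < best$off5)) {
        best <- key
      }
    }
  }
  best
}

# Transitive closure of the pairwise variant relation via boolean matrix
# powers (independent of the union-find implementation). Returns component
# labels.
oracle_components <- function(compatible_matrix) {
  n <- nrow(compatible_matrix)
  reach <- compatible_matrix | diag(n)
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  apply(reach, 1, function(row) min(which(row)))
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# random catalog of `n` matures (some with precursors), for oracle tests
rand_catalog <- function(n, with_precursor = TRUE) {
  mature <- vapply(sample(19:26, n, replace = TRUE), rand_dna, character(1))
  pre <- ifelse(runif(n) < if (with_precursor) 0.7 else 0,
                paste0(vapply(rep(6, n), rand_dna, character(1)), mature,
                       vapply(rep(6, n), rand_dna, character(1))),
                NA)
  data.frame(name = sprintf("zma-miR%03da", seq_len(n)),
             family = sprintf("miR%03d", seq_len(n)),
             mature = mature, precursor = pre, stringsAsFactors = FALSE)
}

# random tag related to a catalog entry: positional shift + optional
# substitutions, occasionally a pure random sequence
rand_tag <- function(catalog) {
  if (runif(1) < 0.2) return(rand_dna(sample(18:28, 1)))
  j <- sample(nrow(catalog), 1)
  mat <- catalog$mature[j]
  pre <- catalog$precursor[j]
  ext <- if (!is.na(pre)) pre else mat
  mstart <- if (!is.na(pre)) regexpr(mat, pre, fixed = TRUE)[1] else 1
  off5 <- sample(-3:3, 1); off3 <- sample(-3:3, 1)
  s <- max(1, mstart + off5)
  e <- min(nchar(ext), mstart + nchar(mat) - 1 + off3)
  tag <- substr(ext, s, e)
  nsub <- sample(0:3, 1, prob = c(0.5, 0.25, 0.15, 0.1))
  if (nsub > 0 && nchar(tag) > 0) {
    ch <- strsplit(tag, "")[[1]]
    pos <- sample(length(ch), min(nsub, length(ch)))
    ch[pos] <- sample(c("A", "C", "G", "T"), length(pos), replace = TRUE)
    tag <- paste(ch, collapse = "")
  }
  tag
}
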