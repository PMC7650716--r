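#' Positional-variant compatibility of two mature sequences
#'
#' Two matures are compatible when one can be placed against the other
#' without gaps such that both end offsets are within `max_off` nt, the
#' overlap matches exactly, and the overlap covers at least the longer
#' mature minus 2 nt. This is the relation that merges identical
#' paralogs (e.g. four identical miR167 matures) and 1-2 nt end-shifted
#' paralogs into one representative group.
#'
#' @param a,b Mature sequences.
#' @param max_off Maximum absolute end offset (default 2).
#' @return Logical.
#' @export
mature_compatible <- function(a, b, max_off = 2L) {
  La <- nchar(a); Lb <- nchar(b)
  if (abs(La - Lb) > 2L * max_off) return(FALSE)
  for (off5 in -max_off:max_off) {
    off3 <- off5 + La - Lb
    if (abs(off3) > max_off) next
    lo <- max(off5, 0L); hi <- min(off5 + La, Lb)
    overlap <- hi - lo
    if (overlap < max(La, Lb) - 2L) next
    if (substr(a, lo - off5 + 1L, hi - off5) == substr(b, lo + 1L, hi)) {
      return(TRUE)
    }
  }
  FALSE
}

#' Representative group name from member catalog names
#'
#' Family label plus the sorted concatenation of the members' variant
#' letters: {zma-miR398a, zma-miR398b} becomes `miR398ab`, a letterless
#' singleton keeps the bare family name (`miR408`).
#'
#' @param members Character vector of catalog names sharing one family.
#' @return Group name.
#' @export
name_group <- function(members) {
  fam <- unique(infer_family(members))
  if (length(fam) != 1L) {
    stop("group members span several families: ", paste(fam, collapse = ", "))
  }
  suffix <- sub(".*miR[0-9]+", "", members)
  letters <- sort(unique(unlist(strsplit(gsub("[^a-z]", "", suffix), ""))))
  paste0(fam, paste(letters, collapse = ""))
}

# iterative union-find over n elements given a 2-column pair matrix
uf_components <- function(n, pairs) {
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1L]); rb <- find(pairs[k, 2L])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  vapply(seq_len(n), find, integer(1L))
}

#' Collapse annotated tags into representative miRNA groups
#'
#' Catalog entries of the same family whose mature sequences are
#' identical or positional variants of each other (see
#' [mature_compatible()], applied transitively) form one group. Tags
#' whose best hit has zero mismatches are pooled into the group of their
#' assigned mature, and group counts are the sums of member tag counts
#' per library. Hits with 1-2 mismatches (polymorphic variants) are kept
#' as separate rows flagged `polymorphic`, one per tag, rather than
#' merged into the group.
#'
#' @param annot data.frame from [annotate_tags()] (rows with NA
#'   `mirna_name` are ignored).
#' @param counts Count matrix data.frame from [merge_tag_counts()]
#'   (`sequence` plus one column per library).
#' @param catalog Catalog data.frame.
#' @return data.frame: `name`, `family`, `polymorphic`, `members`
#'   (comma-separated catalog names), `n_tags`, `anchor_seq` (most
#'   abundant member tag, ties broken lexicographically), plus one count
#'   column per library.
#' @export
group_variants <- function(annot, counts, catalog) {
  libs <- setdiff(names(counts), "sequence")
  fam <- catalog$family
  n <- nrow(catalog)
  pair_idx <- which(outer(fam, fam, "==") & upper.tri(matrix(0, n, n)),
                    arr.ind = TRUE)
  if (length(pair_idx)) {
    ok <- vapply(seq_len(nrow(pair_idx)), function(k) {
      mature_compatible(catalog$mature[pair_idx[k, 1L]],
                        catalog$mature[pair_idx[k, 2L]])
    }, logical(1L))
    pair_idx <- pair_idx[ok, , drop = FALSE]
  } else {
    pair_idx <- matrix(integer(), ncol = 2L)
  }
  comp <- uf_components(n, pair_idx)
  group_of_entry <- setNames(comp, catalog$name)

  annot <- annot[!is.na(annot$mirna_name), , drop = FALSE]
  cnt <- counts[match(annot$sequence, counts$sequence), libs, drop = FALSE]
  cnt[is.na(cnt)] <- 0L

  rows <- list()
  exact <- annot$mismatches == 0L
  for (g in sort(unique(comp))) {
    members <- catalog$name[comp == g]
    gname <- name_group(members)
    sel <- exact & annot$mirna_name %in% members
    gcnt <- if (any(sel)) colSums(cnt[sel, , drop = FALSE]) else
      setNames(numeric(length(libs)), libs)
    anchor <- NA_character_
    if (any(sel)) {
      tot <- rowSums(cnt[sel, , drop = FALSE])
      sq <- annot$sequence[sel]
      anchor <- sort(sq[tot == max(tot)])[1L]
    }
    rows[[length(rows) + 1L]] <- c(
      list(name = gname, family = unique(catalog$family[comp == g]),
           polymorphic = FALSE,
           members = paste(members, collapse = ","),
           n_tags = sum(sel), anchor_seq = anchor),
      as.list(gcnt))
  }
  poly <- which(!exact)
  for (k in seq_along(poly)) {
    i <- poly[k]
    g <- group_of_entry[[annot$mirna_name[i]]]
    gname <- name_group(catalog$name[comp == g])
    rows[[length(rows) + 1L]] <- c(
      list(name = sprintf("%s.pv%d", gname, k),
           family = annot$family[i], polymorphic = TRUE,
           members = annot$mirna_name[i], n_tags = 1L,
           anchor_seq = annot$sequence[i]),
      as.list(as.numeric(cnt[i, ])) |> setNames(libs))
  }
  out <- do.call(rbind, lapply(rows, \(r) as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Fold changes for representative groups
#'
#' Recomputes fold change from the summed member counts (never by
#' averaging member fold changes): group TPM is the TPM of the pooled
#' count, and the fold change and status follow the same rules as for
#' individual tags.
#'
#' @param groups Output of [group_variants()].
#' @param clean_totals Named clean read totals per library.
#' @param pairs Named list of `c(treatment, control)` library pairs.
#' @param pseudo,min_raw,threshold See [build_fc_matrix()].
#' @return An `fc_matrix` (see [build_fc_matrix()]).
#' @export
group_fc <- function(groups, clean_totals, pairs, pseudo = 1,
                     min_raw = 50L, threshold = 1) {
  libs <- names(clean_totals)
  counts <- groups[, c("name", libs)]
  build_fc_matrix(counts, clean_totals, pairs, pseudo, min_raw, threshold)
}
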