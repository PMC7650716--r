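#' Run the full profiling pipeline on a synthetic scenario
#'
#' Convenience driver used by the analysis scripts and the acceptance
#' checks: builds the reference, simulates every condition's library,
#' preprocesses and collapses reads to tags, annotates tags against the
#' catalog, collapses positional variants into representative groups,
#' and computes group fold changes of every treatment against the
#' control. Optionally also maps all tags to the toy genome/organelles
#' and produces per-library category summaries.
#'
#' @param config A `sim_config`.
#' @param classify Also run exact mapping, category classification and
#'   per-library summaries (slower; default FALSE).
#' @param max_mm Mismatch tolerance for catalog matching (0 or 2).
#' @param min_raw,threshold,pseudo Differential expression parameters
#'   (see [build_fc_matrix()]).
#' @return list with `ref`, `stats`, `counts`, `annot`, `groups`, `fc`,
#'   `truth`, `clean_totals`, `tag_tables`, and (when `classify`)
#'   `categories`, `genome_mapped`, `summaries`.
#' @export
profile_scenario <- function(config, classify = FALSE, max_mm = 2L,
                             min_raw = 50L, threshold = 1, pseudo = 1) {
  ref <- make_reference(config)
  tag_tables <- list(); stats <- list(); truth <- list()
  for (cond in config$conditions) {
    lib <- simulate_library(ref, cond)
    pp <- preprocess_library(lib$records, config$adapter3, library = cond)
    tag_tables[[cond]] <- pp$tags
    stats[[cond]] <- pp$stats
    truth[[cond]] <- lib$truth
  }
  stats <- do.call(rbind, stats)
  rownames(stats) <- NULL
  counts <- merge_tag_counts(tag_tables)
  clean_totals <- setNames(stats$clean, stats$library)
  annot <- annotate_tags(counts$sequence, ref$catalog, max_mm = max_mm)
  groups <- group_variants(annot, counts, ref$catalog)
  treatments <- setdiff(config$conditions, config$control)
  pairs <- setNames(lapply(treatments, \(tr) c(tr, config$control)),
                    treatments)
  fc <- group_fc(groups, clean_totals, pairs, pseudo, min_raw, threshold)
  out <- list(ref = ref, stats = stats, counts = counts, annot = annot,
              groups = groups, fc = fc,
              truth = do.call(rbind, truth),
              clean_totals = clean_totals, tag_tables = tag_tables)
  if (classify) {
    hits <- map_tags(counts$sequence, c(ref$genome, ref$organelles))
    mir_tags <- annot$sequence[!is.na(annot$mirna_name)]
    cats <- classify_tags(counts$sequence, hits, ref$annotation, mir_tags)
    out$hits <- hits
    out$categories <- cats
    out$genome_mapped <- counts$sequence %in% hits$sequence
    out$summaries <- lapply(setNames(nm = config$conditions), function(cond) {
      summarize_library(
        data.frame(sequence = counts$sequence, count = counts[[cond]],
                   stringsAsFactors = FALSE),
        cats, out$genome_mapped, stats[stats$library == cond, ],
        mirna_names = annot$mirna_name)
    })
  }
  out
}

#' Compare estimated group fold changes with simulation truth
#'
#' Joins the pipeline's group-level fold changes to the generator's
#' truth table for the given condition and reports, per group passing
#' the raw-count floor, the estimation error and whether the
#' differential expression status matches the true status.
#'
#' @param result Output of [profile_scenario()].
#' @param condition Treatment condition to evaluate.
#' @return data.frame: `group`, `true_log2fc`, `estimated_fc`, `error`,
#'   `floored`, `status`, `true_status`, `status_match`.
#' @export
recovery_table <- function(result, condition) {
  tru <- result$truth
  tru <- tru[tru$condition == condition, ]
  fc <- result$fc$fc
  st <- result$fc$status
  i <- match(tru$group, fc$name)
  est <- fc[[condition]][i]
  status <- st[[condition]][i]
  true_status <- de_call(tru$true_log2fc, TRUE,
                         result$fc$threshold)
  data.frame(group = tru$group, true_log2fc = tru$true_log2fc,
             estimated_fc = est, error = est - tru$true_log2fc,
             floored = !is.na(status) & status != "low_count",
             status = status, true_status = true_status,
             status_match = status == true_status,
             stringsAsFactors = FALSE)
}
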