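#!/usr/bin/env Rscript
# Map tags to the toy genome and organelles, classify them into
# non-coding RNA categories, summarize each library (the sequencing
# summary table analog), and detect organelle read hotspots.

suppressPackageStartupMessages(library(sRNAstress))

scenario_dir <- "scratch/analysis/scenario"
cfg <- read_sim_config(file.path(scenario_dir, "config.yaml"))
genome <- Biostrings::readDNAStringSet(file.path(scenario_dir, "genome.fa"))
organelles <- Biostrings::readDNAStringSet(
  file.path(scenario_dir, "organelles.fa"))
catalog <- read_catalog(file.path(scenario_dir, "catalog_mature.fa"),
                        file.path(scenario_dir, "catalog_meta.tsv"))
ann <- read_annotation(file.path(scenario_dir, "annotation.bed"))
counts <- read.delim("scratch/analysis/tag_counts.tsv",
                     stringsAsFactors = FALSE)
stats <- read.delim("results/preprocess_stats.tsv", stringsAsFactors = FALSE)

annot <- annotate_tags(counts$sequence, catalog, max_mm = 2)
hits <- map_tags(counts$sequence, c(genome, organelles))
cats <- classify_tags(counts$sequence, hits, ann,
                      mirna_tags = annot$sequence[!is.na(annot$mirna_name)])
mapped <- counts$sequence %in% hits$sequence
cat(sprintf("Annotated %d / %d tags to the catalog; %.2f%% of tags map\n",
            sum(!is.na(annot$mirna_name)), nrow(counts),
            100 * mean(mapped)))

summaries <- lapply(cfg$conditions, function(cond) {
  smry <- summarize_library(
    data.frame(sequence = counts$sequence, count = counts[[cond]]),
    cats, mapped, stats[stats$library == cond, ],
    mirna_names = annot$mirna_name)
  cbind(library = cond, smry)
})
write_table(do.call(rbind, summaries), "results/library_summary.tsv")
cat("Per-library category summary -> results/library_summary.tsv\n")

ctl <- cfg$control
hs <- organelle_hotspots(
  data.frame(sequence = counts$sequence, count = counts[[ctl]]),
  organelles, stats$clean[stats$library == ctl], min_total_tpm = 300)
write_table(hs, "results/organelle_hotspots.tsv")
cat("Control-library organelle hotspots (total TPM >= 300):\n")
print(hs)

write.table(annot, "scratch/analysis/tag_annotation.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
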