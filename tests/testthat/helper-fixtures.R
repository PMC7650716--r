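# Shared in-code fixtures.

ADAPTER <- "TGGAATTCTCGGGTGCCAAGG"

# small fixed catalog: two identical miR167 paralogs, a 1-nt 3' extended
# miR167 paralog, and two unrelated families; precursors give 2-nt flanks
fix_catalog <- function() {
  m167 <- "TGAAGCTGCCAGCATGATCTGA"
  pre167 <- paste0("GG", m167, "CAAGGTT")
  m167e <- paste0(m167, "C")                 # 3' +1 variant of m167
  m156 <- "TGACAGAAGAGAGTGAGCAC"
  m399 <- "TGCCAAAGGAGAGTTGCCCTG"
  data.frame(
    name = c("zma-miR167c", "zma-miR167d", "zma-miR167e",
             "zma-miR156a", "zma-miR399b"),
    family = c("miR167", "miR167", "miR167", "miR156", "miR399"),
    mature = c(m167, m167, m167e, m156, m399),
    precursor = c(pre167, pre167, paste0("GG", m167e, "AAGGTT"),
                  paste0("ATGCATGC", m156, "GGTTAACC"), NA),
    stringsAsFactors = FALSE)
}

write_tmp_fastq <- function(ids, seqs, quals = strrep("I", nchar(seqs))) {
  path <- tempfile(fileext = ".fastq")
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", quals)), path)
  path
}

# reads built as insert + adapter (+ padding), constant quality
reads_from_inserts <- function(inserts, adapter = ADAPTER, raw_len = 50) {
  seqs <- paste0(inserts, adapter)
  short <- nchar(seqs) < raw_len
  seqs[short] <- paste0(seqs[short],
                        strrep("A", raw_len - nchar(seqs[short])))
  seqs <- substr(seqs, 1, raw_len)
  data.frame(id = sprintf("r%03d", seq_along(seqs)), sequence = seqs,
             quality = strrep("I", nchar(seqs)), stringsAsFactors = FALSE)
}

# tiny cached recovery run shared by the acceptance checks
recovery_cache <- new.env(parent = emptyenv())
get_recovery_run <- function(seed = 1) {
  key <- paste0("run_", seed)
  if (is.null(recovery_cache[[key]])) {
    cfg <- sim_config_recovery(seed = seed)
    recovery_cache[[key]] <- profile_scenario(cfg)
  }
  recovery_cache[[key]]
}
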