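test_that("exact mapping finds planted occurrences on both strands", {
  set.seed(21)
  left <- rand_dna(120)
  frag <- "TGAAGCTGCCAGCATGATCTGA"
  right <- rand_dna(80)
  genome <- c(chr1 = paste0(left, frag, right))

  hits <- map_perfect(frag, genome)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 120L)
  expect_equal(hits$end, 120L + nchar(frag))
  expect_equal(hits$strand, "+")

  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(frag)))
  hits_rc <- map_perfect(rc, genome)
  expect_equal(nrow(hits_rc), 1L)
  expect_equal(hits_rc$strand, "-")
  expect_equal(hits_rc$start, 120L)   # same genomic interval

  expect_equal(nrow(map_perfect(rand_dna(30), genome)), 0L)
})

test_that("mapped intervals contain the tag sequence (strand rule)", {
  set.seed(22)
  genome <- c(chrA = rand_dna(400), chrB = rand_dna(300))
  tags <- substring(genome[["chrA"]], c(1, 50, 377), c(24, 73, 400))
  tags <- c(tags, as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(substring(genome[["chrB"]], 101, 121)))))
  hits <- map_tags(tags, genome)
  expect_true(all(tags %in% hits$sequence))
  for (k in seq_len(nrow(hits))) {
    sub <- substr(genome[[hits$contig[k]]], hits$start[k] + 1, hits$end[k])
    if (hits$strand[k] == "-") {
      sub <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sub)))
    }
    expect_equal(sub, hits$sequence[k])
  }
})

test_that("classification follows the fixed precedence", {
  ann <- data.frame(contig = "chr1",
                    start = c(100L, 110L, 400L),
                    end = c(140L, 160L, 430L),
                    name = c("t1", "r1", "m1"),
                    category = c("tRNA", "repeats", "mRNA"),
                    strand = "+", stringsAsFactors = FALSE)
  tag <- strrep("A", 24)
  hits <- data.frame(sequence = tag, contig = "chr1", start = 112L,
                     end = 136L, strand = "+", stringsAsFactors = FALSE)
  # overlaps both a tRNA and a repeat interval -> tRNA wins
  expect_equal(classify_tag(tag, hits, ann), c("tRNA"), ignore_attr = TRUE)
  # no hits -> unclassified
  expect_equal(unname(classify_tag(tag, hits[0, ], ann)), "unclassified")
  # catalog miRNA assignment overrides any overlap
  expect_equal(unname(classify_tag(tag, hits, ann, is_mirna = TRUE)), "miRNA")
})

test_that("category overlap requires at least half the tag length", {
  tag <- strrep("A", 24)
  hits <- data.frame(sequence = tag, contig = "chr1", start = 90L,
                     end = 114L, strand = "+", stringsAsFactors = FALSE)
  ann10 <- data.frame(contig = "chr1", start = 104L, end = 140L, name = "r",
                      category = "rRNA", strand = "+", stringsAsFactors = FALSE)
  # only 10 of 24 bases overlap -> below half -> unclassified
  expect_equal(unname(classify_tag(tag, hits, ann10)), "unclassified")
  # 12 of 24 -> exactly half -> classified
  ann12 <- transform(ann10, start = 102L)
  expect_equal(unname(classify_tag(tag, hits, ann12)), "rRNA")
})

test_that("catalog matching honors offsets, mismatches, and precursor validation", {
  cat <- fix_catalog()
  m <- cat$mature[cat$name == "zma-miR167c"]

  hit <- match_mirna(m, cat)
  expect_equal(hit$mirna_name, "zma-miR167c")   # lexicographic tie-break c < d
  expect_equal(c(hit$mismatches, hit$off5, hit$off3), c(0L, 0L, 0L))

  # mature missing its last 2 nt: off3 = -2, no mismatches
  hit <- match_mirna(substr(m, 1, nchar(m) - 2), cat)
  expect_equal(c(hit$off5, hit$off3, hit$mismatches), c(0L, -2L, 0L))

  # 3 internal substitutions exceed the bound
  ch <- strsplit(m, "")[[1]]
  ch[c(5, 9, 13)] <- c("A", "A", "A")  # originals G,C,C -> real changes
  expect_null(match_mirna(paste(ch, collapse = ""), cat, max_mm = 2))

  # 3' extension matching the precursor flank is validated (0 mismatches)
  m156 <- cat$mature[cat$name == "zma-miR156a"]
  hit <- match_mirna(paste0(m156, "GG"), cat)
  expect_equal(c(hit$mirna_name, hit$mismatches, hit$off3),
               c("zma-miR156a", "0", "2"))
  # a non-flank extension counts one mismatch per unvalidated base
  hit <- match_mirna(paste0(m156, "TT"), cat)
  expect_equal(hit$mismatches, 2L)
  # entry without precursor: any overhang base is a mismatch
  m399 <- cat$mature[cat$name == "zma-miR399b"]
  hit <- match_mirna(paste0("A", m399), cat)
  expect_equal(c(hit$mirna_name, hit$mismatches), c("zma-miR399b", "1"))
})

test_that("matching equals the exhaustive-placement oracle on randomized cases", {
  set.seed(42)
  n_ok <- 0
  for (rep in 1:40) {
    cat <- rand_catalog(sample(3:8, 1))
    tags <- replicate(6, rand_tag(cat))
    tags <- tags[nchar(tags) >= 16]
    got <- annotate_tags(tags, cat, max_mm = 2)
    for (i in seq_along(tags)) {
      exp <- oracle_match(tags[i], cat, max_mm = 2)
      if (is.null(exp)) {
        expect_true(is.na(got$mirna_name[i]))
      } else {
        expect_equal(got$mirna_name[i], exp$name)
        expect_equal(got$mismatches[i], exp$mm)
        expect_equal(got$off5[i], exp$off5)
        expect_equal(got$off3[i], exp$off3)
      }
      n_ok <- n_ok + 1
    }
  }
  expect_gte(n_ok, 200)
})

test_that("library summaries recompute percentages from counts", {
  tags <- data.frame(sequence = c("A1", "A2", "A3", "A4"),
                     count = c(60L, 25L, 10L, 5L), stringsAsFactors = FALSE)
  stats <- data.frame(library = "L", raw = 120L, clean = 100L,
                      discarded_adapter = 20L, discarded_quality = 0L,
                      discarded_length = 0L)
  cats <- c("miRNA", "rRNA", "miRNA", "unclassified")
  smry <- summarize_library(tags, cats, c(TRUE, TRUE, TRUE, FALSE), stats,
                            mirna_names = c("zma-miR1a", NA, "ath-miR2", NA))
  expect_equal(smry$reads[smry$category == "miRNA"], 60)       # zma only
  expect_equal(smry$pct[smry$category == "miRNA"], 60.00)
  expect_equal(smry$reads[smry$category == "other-miRNA"], 10)
  expect_equal(smry$reads[smry$category == "genome-mapped"], 95)
  expect_equal(smry$pct[smry$category == "rRNA"], 25.00)

  zero <- transform(stats, clean = 0L)
  expect_error(summarize_library(tags, cats, rep(TRUE, 4), zero),
               "percentages undefined")

  none <- summarize_library(tags, rep("rRNA", 4), rep(TRUE, 4), stats)
  expect_equal(none$pct[none$category == "miRNA"], 0.00)
})

test_that("organelle hotspots merge overlapping hits and filter by TPM", {
  set.seed(30)
  mt <- rand_dna(600)
  org <- c(mt = mt)
  # three overlapping tags spanning positions 100-153 (0-based, 53 nt)
  t1 <- substr(mt, 101, 124); t2 <- substr(mt, 115, 140); t3 <- substr(mt, 130, 153)
  # a distant singleton region and a low-abundance region
  t4 <- substr(mt, 301, 324)
  t5 <- substr(mt, 501, 524)
  tags <- data.frame(sequence = c(t1, t2, t3, t4, t5),
                     count = c(400L, 300L, 300L, 500L, 10L),
                     stringsAsFactors = FALSE)
  hs <- organelle_hotspots(tags, org, clean_total = 1e6, min_total_tpm = 100)
  expect_equal(nrow(hs), 2L)
  expect_equal(hs$span_nt[1], 53L)          # merged pileup, highest TPM first
  expect_equal(hs$total_tpm[1], 1000)
  expect_equal(hs$n_tags[1], 3L)
  expect_equal(hs$span_nt[2], 24L)
  # region below the TPM threshold is omitted
  expect_false(any(hs$start == 500L))
})
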