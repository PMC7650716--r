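test_that("adapter trimming finds exact, prefix, and mismatched occurrences", {
  insert <- "TGACAGAAGAGAGTGAGCAC"
  full <- paste0(insert, ADAPTER)
  expect_equal(trim_adapter(full, ADAPTER),
               data.frame(insert = insert, found = TRUE))

  prefix7 <- paste0(insert, substr(ADAPTER, 1, 7))   # minimum overlap
  expect_equal(trim_adapter(prefix7, ADAPTER)$insert, insert)

  none <- "ACGTACGTACGTACGTACGTACGT"
  expect_equal(trim_adapter(none, ADAPTER),
               data.frame(insert = none, found = FALSE))

  # one mismatch tolerated only for overlaps >= 10 nt
  mm10 <- paste0(insert, "TGGAAATCTC")                # 10 nt, 1 mismatch
  expect_true(trim_adapter(mm10, ADAPTER)$found)
  expect_equal(trim_adapter(mm10, ADAPTER)$insert, insert)
  mm7 <- paste0(insert, "TGGAAAT")                    # 7 nt, 1 mismatch
  expect_false(trim_adapter(mm7, ADAPTER)$found)
})

test_that("trimming picks the leftmost admissible position", {
  insert <- "ACGTACGTACGT"
  read <- paste0(insert, ADAPTER, "TT", ADAPTER)
  expect_equal(trim_adapter(read, ADAPTER)$insert, insert)
})

test_that("trimming an adapter-free insert is idempotent", {
  set.seed(5)
  inserts <- vapply(sample(18:35, 50, TRUE), rand_dna, character(1))
  tr1 <- trim_adapter(inserts, ADAPTER)
  keep <- !tr1$found   # discard rare chance hits of the adapter prefix
  tr2 <- trim_adapter(tr1$insert[keep], ADAPTER)
  expect_equal(tr2$insert, inserts[keep])
  expect_false(any(tr2$found))
})

test_that("mean-quality filter is inclusive at the threshold and fails empty inserts", {
  q40 <- strrep(rawToChar(as.raw(33 + 40)), 20)
  q10 <- strrep(rawToChar(as.raw(33 + 10)), 20)
  q20 <- strrep(rawToChar(as.raw(33 + 20)), 20)
  expect_true(quality_pass(q40, 20, min_mean_q = 20))
  expect_false(quality_pass(q10, 20, min_mean_q = 20))
  expect_true(quality_pass(q20, 20, min_mean_q = 20))   # boundary inclusive
  expect_false(quality_pass(q40, 0, min_mean_q = 20))   # empty insert
})

test_that("length filter keeps the closed 18-35 window", {
  expect_false(length_filter(strrep("A", 17)))
  expect_true(length_filter(strrep("A", 18)))
  expect_true(length_filter(strrep("A", 35)))
  expect_false(length_filter(strrep("A", 36)))
})

test_that("preprocessing collapses duplicates and balances its ledger", {
  insert <- "TGACAGAAGAGAGTGAGCAC"
  rec <- reads_from_inserts(rep(insert, 10))
  out <- preprocess_library(rec, ADAPTER, library = "L1")
  expect_equal(out$tags, data.frame(sequence = insert, count = 10L))
  expect_equal(out$stats$clean, 10L)

  # mixed library: one good read, one low-quality, one too short, one
  # adapter-only; ledger must balance and collapsing conserve reads
  bad_q <- reads_from_inserts(insert)
  bad_q$quality <- strrep(rawToChar(as.raw(33 + 10)), nchar(bad_q$sequence))
  short <- reads_from_inserts(strrep("A", 10))
  adapter_only <- reads_from_inserts("")
  rec2 <- rbind(reads_from_inserts(insert), bad_q, short, adapter_only)
  out2 <- preprocess_library(rec2, ADAPTER)
  st <- out2$stats
  expect_equal(st$raw, 4L)
  expect_equal(st$clean, 1L)
  expect_equal(st$discarded_adapter, 1L)
  expect_equal(st$discarded_quality, 1L)
  expect_equal(st$discarded_length, 1L)
  expect_equal(st$raw,
               st$clean + st$discarded_adapter + st$discarded_quality +
                 st$discarded_length)
  expect_equal(sum(out2$tags$count), st$clean)
})

test_that("a library failing the length filter yields no tags", {
  rec <- reads_from_inserts(rep(strrep("A", 12), 5))
  out <- preprocess_library(rec, ADAPTER)
  expect_equal(out$stats$clean, 0L)
  expect_equal(nrow(out$tags), 0L)
})

test_that("synthetic libraries are fully eligible: clean equals depth (generator bookkeeping)", {
  cfg <- sim_config(seed = 3, depth = 4000L,
                    conditions = c("control", "submergence"))
  ref <- make_reference(cfg)
  lib <- simulate_library(ref, "submergence")
  expect_equal(sum(lib$components$count), 4000L)
  out <- preprocess_library(lib$records, cfg$adapter3)
  expect_equal(out$stats$clean, 4000L)          # every generated read is clean
  expect_equal(sum(out$tags$count), out$stats$clean)
  expect_equal(out$stats$raw,
               out$stats$clean + out$stats$discarded_adapter +
                 out$stats$discarded_quality + out$stats$discarded_length)
})

test_that("merging per-library tag tables aligns counts with zeros", {
  t1 <- data.frame(sequence = c("AAAA", "CCCC"), count = c(3L, 1L))
  t2 <- data.frame(sequence = c("CCCC", "GGGG"), count = c(2L, 5L))
  m <- merge_tag_counts(list(a = t1, b = t2))
  expect_equal(m$sequence, c("AAAA", "CCCC", "GGGG"))
  expect_equal(m$a, c(3L, 1L, 0L))
  expect_equal(m$b, c(0L, 2L, 5L))
})
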