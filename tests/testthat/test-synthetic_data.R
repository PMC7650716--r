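test_that("reference construction is deterministic and embeds every study mature", {
  cfg <- sim_config(seed = 5, n_mirnas = 5L, n_other_mirnas = 1L,
                    depth = 1000L, conditions = c("control", "submergence"))
  d1 <- file.path(tempdir(), "scn1"); d2 <- file.path(tempdir(), "scn2")
  s1 <- simulate_scenario(cfg, d1)
  s2 <- simulate_scenario(cfg, d2)
  for (f in c("genome.fa", "catalog_mature.fa", "annotation.bed",
              "lib_control.fastq", "lib_submergence.fastq")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  ref <- s1$ref
  chr1 <- as.character(ref$genome[["chr1"]])
  zma <- ref$catalog[startsWith(ref$catalog$name, "zma"), ]
  for (m in unique(zma$mature)) expect_true(grepl(m, chr1, fixed = TRUE))
  other <- ref$catalog[!startsWith(ref$catalog$name, "zma"), ]
  for (m in other$mature) expect_false(grepl(m, chr1, fixed = TRUE))
  # every requested background category has at least one interval
  for (cat in c("rRNA", "tRNA", "snRNA", "repeats")) {
    expect_gte(sum(ref$annotation$category == cat), 1L)
  }
  # config round-trips through YAML
  cfg2 <- read_sim_config(s1$paths$config)
  expect_equal(cfg2$true_log2fc, cfg$true_log2fc)
  expect_equal(cfg2$baseline_weights, cfg$baseline_weights)
})

test_that("config invariants are enforced", {
  bad_prof <- default_isomir_profile(); bad_prof$prob[1] <- 0.5
  expect_error(sim_config(isomir_profile = bad_prof), "sum")
  flat <- data.frame(off5 = c(0, 1), off3 = c(0, 0), prob = c(0.4, 0.6))
  expect_error(sim_config(isomir_profile = flat), "largest")
  expect_error(sim_config(mirna_fraction = 0.9), "capacity")
  fc <- list(control = c(x = 1))
  expect_error(sim_config(conditions = "control", true_log2fc = fc))
  expect_error(simulate_library(make_reference(sim_config(depth = 100L)),
                                "heatwave"), "unknown condition")
})

test_that("a degenerate isomiR profile yields only exact mature reads", {
  exact_only <- data.frame(off5 = 0, off3 = 0, prob = 1)
  cfg <- sim_config(seed = 9, n_mirnas = 4L, n_other_mirnas = 0L,
                    depth = 3000L, conditions = c("control", "submergence"),
                    mirna_fraction = 0.5, isomir_profile = exact_only,
                    background_fractions = c(rRNA = 0.05),
                    organelle_hotspot_list = list())
  ref <- make_reference(cfg)
  lib <- simulate_library(ref, "control")
  pp <- preprocess_library(lib$records, cfg$adapter3)
  annot <- annotate_tags(pp$tags$sequence, ref$catalog, max_mm = 0)
  hit <- !is.na(annot$mirna_name)
  expect_true(any(hit))
  expect_true(all(annot$off5[hit] == 0 & annot$off3[hit] == 0))
  expect_true(all(annot$sequence[hit] %in% ref$catalog$mature))
  # and the annotated read mass matches the generator's miRNA bookkeeping
  mir_reads <- sum(pp$tags$count[hit])
  expect_equal(mir_reads,
               sum(lib$components$count[lib$components$class == "miRNA"]))
})

test_that("realized composition approaches the configured fractions", {
  cfg <- sim_config(seed = 31, depth = 1e5L,
                    conditions = c("control", "submergence"))
  ref <- make_reference(cfg)
  lib <- simulate_library(ref, "control")
  comp <- lib$components
  f <- cfg$mirna_fraction
  realized <- sum(comp$count[comp$class == "miRNA"]) / sum(comp$count)
  se <- sqrt(f * (1 - f) / cfg$depth)
  expect_lt(abs(realized - f), 3 * se)
  # length histogram of background reads peaks at 24 nt
  pp <- preprocess_library(lib$records, cfg$adapter3)
  hist <- attr(pp$stats, "length_histogram")
  expect_equal(names(hist)[which.max(hist)], "24")
})

test_that("null fold changes are recovered near zero at moderate depth", {
  groups <- unique(synthetic_entries(6L, 0L)$group)
  fc0 <- setNames(rep(0, 6), groups)
  cfg <- sim_config(seed = 17, n_mirnas = 6L, n_other_mirnas = 0L,
                    depth = 5e4L, conditions = c("control", "submergence"),
                    mirna_fraction = 0.3,
                    true_log2fc = list(control = fc0, submergence = fc0))
  res <- profile_scenario(cfg)
  rt <- recovery_table(res, "submergence")
  expect_true(all(rt$floored))
  expect_true(all(abs(rt$error) < 0.25))  # ~3 sigma at 2500 reads per group
})

test_that("a planted twofold induction is recovered within sampling error", {
  groups <- unique(synthetic_entries(5L, 0L)$group)
  fc <- setNames(c(2, 0, 0, 0, 0), groups)
  cfg <- sim_config(seed = 23, n_mirnas = 5L, n_other_mirnas = 0L,
                    depth = 1e5L, conditions = c("control", "stress"),
                    control = "control", mirna_fraction = 0.25,
                    true_log2fc = list(control = fc * 0, stress = fc))
  res <- profile_scenario(cfg)
  rt <- recovery_table(res, "stress")
  est <- rt$estimated_fc[rt$true_log2fc == 2]
  # binomial sampling oracle: ~5000 control reads for the induced group,
  # 3*SE(log2 ratio) ~= 0.09, well inside [1.8, 2.2]
  expect_gt(est, 1.8)
  expect_lt(est, 2.2)
})
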