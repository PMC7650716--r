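test_that("group names concatenate sorted variant letters within a family", {
  expect_equal(name_group(c("zma-miR398a", "zma-miR398b")), "miR398ab")
  expect_equal(name_group("zma-miR408"), "miR408")
  expect_equal(name_group(c("zma-miR169c", "zma-miR169r")), "miR169cr")
  expect_equal(name_group(c("zma-miR167c", "zma-miR167d", "zma-miR167e",
                            "zma-miR167g")), "miR167cdeg")
  expect_equal(name_group("zma-miR319b"), "miR319b")
  expect_error(name_group(c("zma-miR167c", "zma-miR156a")), "families")
})

test_that("mature compatibility accepts 1-2 nt end shifts with exact overlap", {
  m <- rand_dna(22)
  expect_true(mature_compatible(m, m))
  expect_true(mature_compatible(m, substr(m, 1, 20)))          # 3' -2
  expect_true(mature_compatible(m, paste0("AC", m)))           # 5' +2
  expect_false(mature_compatible(m, substr(m, 1, 19)))         # 3 nt short
  m2 <- m; substr(m2, 10, 10) <- if (substr(m, 10, 10) == "A") "C" else "A"
  expect_false(mature_compatible(m, m2))                       # internal mm
})

test_that("variants pool into one group with summed counts; distant tags stay out", {
  cat <- fix_catalog()
  m <- cat$mature[cat$name == "zma-miR167c"]
  tags <- c(m,
            substr(m, 1, nchar(m) - 1),   # 3' -1 variant
            substr(m, 2, nchar(m)),       # 5' +1 variant
            substr(m, 1, nchar(m) - 3))   # 3 nt short: no hit at all
  counts <- data.frame(sequence = tags, lib1 = c(10L, 5L, 2L, 7L))
  annot <- annotate_tags(tags, cat, max_mm = 0)
  expect_true(is.na(annot$mirna_name[4]))
  groups <- group_variants(annot, counts, cat)
  g167 <- groups[groups$name == "miR167cde", ]
  expect_equal(nrow(g167), 1L)               # c, d (identical) and e merged
  expect_equal(g167$members, "zma-miR167c,zma-miR167d,zma-miR167e")
  expect_equal(g167$lib1, 17)                # 10 + 5 + 2; the short tag is out
  expect_equal(g167$anchor_seq, m)           # most abundant member
})

test_that("polymorphic hits stay as separate flagged rows", {
  cat <- fix_catalog()
  m156 <- cat$mature[cat$name == "zma-miR156a"]
  poly <- m156
  substr(poly, 5, 5) <- if (substr(m156, 5, 5) == "G") "T" else "G"
  counts <- data.frame(sequence = c(m156, poly), lib1 = c(100L, 20L))
  annot <- annotate_tags(c(m156, poly), cat, max_mm = 2)
  groups <- group_variants(annot, counts, cat)
  expect_equal(sum(groups$polymorphic), 1L)
  pv <- groups[groups$polymorphic, ]
  expect_match(pv$name, "^miR156a\\.pv")
  expect_equal(pv$lib1, 20)
  expect_equal(groups$lib1[groups$name == "miR156a"], 100)
  # conservation: nothing double-counted, nothing lost
  expect_equal(sum(groups$lib1), sum(counts$lib1))
})

test_that("grouping matches a transitive-closure oracle on random families", {
  set.seed(77)
  n_cases <- 0
  for (rep in 1:40) {
    # a family of chained variants plus unrelated same-family singletons
    k <- sample(3:8, 1)
    base <- rand_dna(sample(20:24, 1))
    matures <- character(k)
    matures[1] <- base
    for (i in seq_len(k)[-1]) {
      if (runif(1) < 0.3) {                 # fresh unrelated mature
        matures[i] <- rand_dna(sample(20:24, 1))
        next
      }
      src <- matures[sample(i - 1, 1)]
      matures[i] <- switch(sample(3, 1),
                           src,
                           substr(src, 1, max(18, nchar(src) - sample(1:2, 1))),
                           paste0(rand_dna(sample(1:2, 1)), src))
      if (nchar(matures[i]) < 18) matures[i] <- src
    }
    matures <- vapply(matures, \(m) substr(m, 1, min(nchar(m), 26)),
                      character(1))
    cat <- data.frame(name = sprintf("zma-miR500%s", letters[1:k]),
                      family = "miR500", mature = unname(matures),
                      precursor = NA, stringsAsFactors = FALSE)
    adj <- outer(seq_len(k), seq_len(k),
                 Vectorize(\(i, j) i != j &&
                             mature_compatible(cat$mature[i], cat$mature[j])))
    want <- oracle_components(adj)
    annot <- annotate_tags(cat$mature, cat, max_mm = 0)
    counts <- data.frame(sequence = cat$mature, lib1 = rep(1L, k))
    got <- group_variants(annot, counts, cat)
    got <- got[!got$polymorphic & got$n_tags > 0, ]
    # same partition: members of each implementation group are exactly one
    # oracle component
    for (r in seq_len(nrow(got))) {
      members <- strsplit(got$members[r], ",")[[1]]
      comp <- unique(want[match(members, cat$name)])
      expect_length(comp, 1L)
      expect_setequal(members, cat$name[want == comp])
      n_cases <- n_cases + 1
    }
  }
  expect_gte(n_cases, 50)
})

test_that("group fold changes equal fold changes of pooled member counts", {
  cat <- fix_catalog()
  m <- cat$mature[cat$name == "zma-miR167c"]
  tags <- c(m, substr(m, 1, nchar(m) - 1))
  counts <- data.frame(sequence = tags, treat = c(30L, 30L), ctrl = c(10L, 20L))
  annot <- annotate_tags(tags, cat, max_mm = 0)
  groups <- group_variants(annot, counts, cat)
  totals <- c(treat = 1e5, ctrl = 1e5)
  fcm <- group_fc(groups, totals, list(stress = c("treat", "ctrl")),
                  pseudo = 1e-9, min_raw = 0L)
  got <- fcm$fc$stress[fcm$fc$name == "miR167cde"]
  expect_equal(got, log2(60 / 30), tolerance = 1e-6)
  # definitional check against quantify on the pooled counts
  pooled <- build_fc_matrix(data.frame(name = "pool", treat = 60L, ctrl = 30L),
                            totals, list(stress = c("treat", "ctrl")),
                            pseudo = 1e-9, min_raw = 0L)
  expect_equal(got, pooled$fc$stress)
  # equal pooled counts at equal depth give FC 0
  counts0 <- data.frame(sequence = tags, treat = c(15L, 25L), ctrl = c(30L, 10L))
  g0 <- group_variants(annot, counts0, cat)
  f0 <- group_fc(g0, totals, list(stress = c("treat", "ctrl")), min_raw = 0L)
  expect_equal(f0$fc$stress[f0$fc$name == "miR167cde"], 0)
})

test_that("regrouping group anchors is idempotent", {
  cat <- fix_catalog()
  m <- cat$mature[cat$name == "zma-miR167c"]
  m156 <- cat$mature[cat$name == "zma-miR156a"]
  tags <- c(m, substr(m, 1, nchar(m) - 2), m156)
  counts <- data.frame(sequence = tags, lib1 = c(50L, 10L, 30L))
  annot <- annotate_tags(tags, cat, max_mm = 0)
  g1 <- group_variants(annot, counts, cat)
  g1 <- g1[g1$n_tags > 0, ]
  counts2 <- data.frame(sequence = g1$anchor_seq, lib1 = g1$lib1)
  g2 <- group_variants(annotate_tags(g1$anchor_seq, cat, max_mm = 0),
                       counts2, cat)
  g2 <- g2[g2$n_tags > 0, ]
  expect_setequal(g2$name, g1$name)
  expect_equal(g2$lib1[match(g1$name, g2$name)], g1$lib1)
})
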