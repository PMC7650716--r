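bases <- c("A", "C", "G", "T")

rand_seq <- function(n) paste(sample(bases, n, replace = TRUE), collapse = "")

rc_seqs <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Default isomiR offset profile
#'
#' Probability of each (off5, off3) positional variant of a mature
#' miRNA: 60% of reads are the exact mature, the remainder is spread
#' symmetrically over 1-2 nt shifts/extensions at either end. The true
#' offset distribution of plant isomiRs is not well characterized; this
#' symmetric default is an explicit modeling choice, not an estimate.
#'
#' @return data.frame with `off5`, `off3`, `prob`.
#' @export
default_isomir_profile <- function() {
  data.frame(
    off5 = c(0, 0, 0, -1, 1, 0, 0, -2, 2),
    off3 = c(0, -1, 1, 0, 0, -2, 2, 0, 0),
    prob = c(0.60, 0.08, 0.08, 0.08, 0.08, 0.02, 0.02, 0.02, 0.02))
}

#' Default background composition of a library
#'
#' Fractions of clean reads per non-miRNA source, patterned on the
#' category shares observed in real maize control libraries (repeats
#' dominate, structural RNAs a few percent each, a small unmappable
#' remainder). Reads not covered by miRNA, these categories, or the
#' organelle hotspots are drawn from unannotated genomic sequence.
#'
#' @return Named numeric vector of fractions.
#' @export
default_background_fractions <- function() {
  c(mt = 0.0059, cp = 0.0122, mRNA = 0.0131, rRNA = 0.0194, tRNA = 0.0069,
    snRNA = 0.0347, snoRNA = 0.0071, lncRNA = 0.0173, repeats = 0.149,
    unmapped = 0.002)
}

#' Default organelle read hotspots
#'
#' One mitochondrial region of 53 nt at 820 TPM and one chloroplast
#' region of 32 nt at 2273 TPM, mirroring the NADH dehydrogenase
#' subunit 2 and trnL-trnF read pileups reported for maize organelles.
#'
#' @return list of hotspot descriptors (`contig`, `start`, `span`, `tpm`).
#' @export
default_hotspots <- function() {
  list(list(contig = "mt", start = 600L, span = 53L, tpm = 820),
       list(contig = "cp", start = 1200L, span = 32L, tpm = 2273))
}

# deterministic catalog skeleton: group/entry names only (no sequences)
synthetic_entries <- function(n_mirnas, n_other_mirnas) {
  rows <- list()
  for (i in seq_len(n_mirnas)) {
    fam <- paste0("miR", 100L + i)
    letters_i <- if (i %% 5L == 0L) c("a", "b") else "a"
    for (l in letters_i) {
      rows[[length(rows) + 1L]] <- data.frame(
        name = paste0("zma-", fam, l), group = name_group(paste0(fam, letters_i)),
        group_index = i, species = "zma", stringsAsFactors = FALSE)
    }
  }
  other_prefix <- c("ath", "osa", "bdi", "ptc", "stu", "mtr", "gma", "sly")
  if (n_other_mirnas > length(other_prefix)) {
    stop("at most ", length(other_prefix), " other-species miRNAs supported")
  }
  for (j in seq_len(n_other_mirnas)) {
    fam <- paste0("miR", 200L + j)
    rows[[length(rows) + 1L]] <- data.frame(
      name = paste0(other_prefix[j], "-", fam), group = fam,
      group_index = n_mirnas + j, species = other_prefix[j],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Simulation configuration for synthetic small RNA libraries
#'
#' Defines a full scenario: the toy reference (miRNA catalog embedded in
#' a genome, background annotation intervals, organelle contigs with
#' read hotspots) and the per-condition library composition with known
#' true log2 fold changes. The defaults emulate the structure of real
#' water-stress libraries: a 24-nt mode in the background length
#' distribution, ~2.5% of clean reads from miRNAs, one pooled library
#' per condition sampled multinomially (no replicate overdispersion),
#' constant Q40 qualities, and the standard small RNA 3' adapter.
#'
#' True fold changes apply to the miRNA portion only; the unannotated
#' genomic background absorbs the compositional difference so that the
#' expected TPM log-ratio of each miRNA equals its configured truth.
#'
#' @param seed Integer seed; everything downstream is deterministic in it.
#' @param n_mirnas Number of study-species miRNA groups (every fifth
#'   group gets two identical catalog entries, exercising paralog
#'   merging).
#' @param n_other_mirnas Catalog entries from other plant species whose
#'   precursors are absent from the toy genome.
#' @param depth Reads per library.
#' @param adapter3 3' adapter ligated to every read.
#' @param raw_length Uniform raw read length after padding/truncation.
#' @param conditions Condition labels; must include `control`.
#' @param control Name of the control condition.
#' @param mirna_fraction Fraction of control clean reads from the miRNA
#'   catalog.
#' @param baseline_weights Optional named per-group control weights
#'   (normalized internally); default equal.
#' @param true_log2fc Optional named list: condition -> named numeric of
#'   per-group true log2 FCs. Default cycles {-3,-1,0,1,3} over groups
#'   for the single stresses, reuses the submergence pattern when
#'   submergence is the second stress, and attenuates the drought
#'   pattern to 25% when drought is the second stress; other-species
#'   groups and the control are always 0.
#' @param isomir_profile data.frame (`off5`, `off3`, `prob`) over
#'   offsets between -2 and 2; probabilities sum to 1 with the exact mature
#'   (0,0) most likely.
#' @param background_fractions Named fractions per background source
#'   (see [default_background_fractions()]).
#' @param organelle_hotspot_list Hotspot descriptors
#'   (see [default_hotspots()]).
#' @param mature_lengths Candidate mature miRNA lengths.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_mirnas = 20L,
                       n_other_mirnas = 2L,
                       depth = 1e5L,
                       adapter3 = "TGGAATTCTCGGGTGCCAAGG",
                       raw_length = 50L,
                       conditions = c("control", "submergence", "drought",
                                      "drought_submergence",
                                      "submergence_drought"),
                       control = "control",
                       mirna_fraction = 0.025,
                       baseline_weights = NULL,
                       true_log2fc = NULL,
                       isomir_profile = default_isomir_profile(),
                       background_fractions = default_background_fractions(),
                       organelle_hotspot_list = default_hotspots(),
                       mature_lengths = 20:24) {
  stopifnot(n_mirnas >= 1L, depth >= 1L, control %in% conditions,
            nchar(adapter3) >= 7L)
  entries <- synthetic_entries(n_mirnas, n_other_mirnas)
  groups <- unique(entries$group)
  n_groups <- length(groups)

  if (is.null(baseline_weights)) {
    baseline_weights <- setNames(rep(1 / n_groups, n_groups), groups)
  }
  stopifnot(setequal(names(baseline_weights), groups),
            all(baseline_weights > 0))
  baseline_weights <- baseline_weights[groups] / sum(baseline_weights)

  if (is.null(true_log2fc)) {
    fc_set <- c(-3, -1, 0, 1, 3)
    zma_groups <- groups[seq_len(n_mirnas)]
    pattern <- setNames(rep(0, n_groups), groups)
    pattern[zma_groups] <- fc_set[(seq_len(n_mirnas) - 1L) %% 5L + 1L]
    true_log2fc <- list()
    for (cond in conditions) {
      true_log2fc[[cond]] <-
        if (cond == control) setNames(rep(0, n_groups), groups)
        else if (cond == "submergence_drought") 0.25 * pattern
        else pattern  # submergence, drought, drought_submergence
    }
  }
  stopifnot(all(conditions %in% names(true_log2fc)))
  for (cond in conditions) {
    stopifnot(setequal(names(true_log2fc[[cond]]), groups))
    true_log2fc[[cond]] <- true_log2fc[[cond]][groups]
  }
  if (any(true_log2fc[[control]] != 0)) {
    stop("control condition must have true log2 FC 0 for all miRNAs")
  }

  stopifnot(abs(sum(isomir_profile$prob) - 1) < 1e-9,
            all(abs(isomir_profile$off5) <= 2),
            all(abs(isomir_profile$off3) <= 2))
  exact <- isomir_profile$off5 == 0 & isomir_profile$off3 == 0
  if (!any(exact) ||
      max(isomir_profile$prob) > isomir_profile$prob[exact][1L] + 1e-12) {
    stop("the exact mature (0,0) must carry the largest isomiR probability")
  }
  if (min(mature_lengths) - 2L < 18L || max(mature_lengths) + 2L > 35L) {
    stop("mature lengths must keep all positional variants within 18-35 nt")
  }

  hot_w <- sum(vapply(organelle_hotspot_list, \(h) h$tpm, numeric(1L))) / 1e6
  for (cond in conditions) {
    z <- sum(baseline_weights * 2^true_log2fc[[cond]])
    used <- mirna_fraction * z + sum(background_fractions) + hot_w
    if (used > 0.99) {
      stop("library composition exceeds capacity in condition '", cond,
           "' (", round(used, 3), "); lower mirna_fraction or backgrounds")
    }
  }

  structure(list(seed = as.integer(seed), n_mirnas = as.integer(n_mirnas),
                 n_other_mirnas = as.integer(n_other_mirnas),
                 depth = as.integer(depth), adapter3 = adapter3,
                 raw_length = as.integer(raw_length),
                 conditions = conditions, control = control,
                 mirna_fraction = mirna_fraction,
                 baseline_weights = baseline_weights,
                 true_log2fc = true_log2fc,
                 isomir_profile = isomir_profile,
                 background_fractions = background_fractions,
                 organelle_hotspot_list = organelle_hotspot_list,
                 mature_lengths = mature_lengths,
                 entries = entries),
            class = "sim_config")
}

#' Power-calibrated parameter-recovery scenario
#'
#' A three-library scenario (control, submergence, drought) with 20
#' study-species miRNA groups cycling true log2 fold changes over
#' {-3, -1, 0, 1, 3} identically in both stresses. Control baselines are
#' proportional to 1 + 2^-FC, the closed-form requirement for the
#' binomial sampling error of the log2 TPM ratio to be the same for
#' every group; the miRNA fraction is set so that three standard errors
#' of the worst group stay within +/-0.2 at the configured depth (with a
#' 1.5x count margin). This deliberately enriches miRNA reads far above
#' realistic library composition: the scenario measures estimator
#' accuracy, not compositional realism.
#'
#' @param seed Integer seed.
#' @param depth Reads per library (default 1e5).
#' @return A `sim_config`.
#' @export
sim_config_recovery <- function(seed = 1L, depth = 1e5L) {
  n <- 20L
  entries <- synthetic_entries(n, 2L)
  groups <- unique(entries$group)
  fc_set <- c(-3, -1, 0, 1, 3)
  fc <- setNames(rep(0, length(groups)), groups)
  fc[groups[seq_len(n)]] <- fc_set[(seq_len(n) - 1L) %% 5L + 1L]
  w <- 1 + 2^(-fc)           # others: FC 0 -> weight 2
  w <- w / sum(w)
  # required control count for 3*SE(log2 ratio) <= 0.2, with 1.5x margin
  n_ctrl <- 1.5 * (1 + 2^(-fc)) / (0.2 * log(2) / 3)^2
  fraction <- sum(n_ctrl) / depth
  sim_config(seed = seed, n_mirnas = n, n_other_mirnas = 2L, depth = depth,
             conditions = c("control", "submergence", "drought"),
             mirna_fraction = fraction, baseline_weights = w,
             true_log2fc = list(control = fc * 0, submergence = fc,
                                drought = fc))
}

#' Build the toy reference for a simulation
#'
#' Generates mature/precursor sequences for every catalog entry, embeds
#' each study-species precursor once in the toy genome at a recorded
#' miRNA annotation interval, lays out disjoint intervals for each
#' genomic background category plus a large unannotated zone, and
#' creates organelle contigs containing the configured hotspot regions.
#' Deterministic given the config seed.
#'
#' @param config A `sim_config`.
#' @return list of class `srna_reference`: `config`, `catalog`, `groups`
#'   (per-group mature, flanks, baseline weight), `genome` and
#'   `organelles` (`DNAStringSet`), `annotation`, `layout` (internal
#'   coordinates used by [simulate_library()]).
#' @export
make_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  entries <- config$entries
  groups <- unique(entries$group)

  # one mature per group, distinct across groups
  matures <- character(0)
  for (g in groups) {
    repeat {
      m <- rand_seq(sample(config$mature_lengths, 1L))
      if (!m %in% matures) break
    }
    matures[g] <- m
  }
  # per-entry precursor: private flanks around the group's mature
  entries$mature <- matures[entries$group]
  entries$precursor <- vapply(entries$mature, function(m) {
    paste0(rand_seq(8L), m, rand_seq(8L))
  }, character(1L))
  catalog <- data.frame(name = entries$name,
                        family = infer_family(entries$name),
                        mature = entries$mature,
                        precursor = entries$precursor,
                        stringsAsFactors = FALSE)
  validate_catalog(catalog)

  # genome assembly: precursors of study-species entries + background
  # category intervals + a terminal unannotated zone
  pieces <- character(0)
  pos <- 0L
  ann <- list()
  add_piece <- function(seq) {
    pieces[[length(pieces) + 1L]] <<- seq
    start <- pos
    pos <<- pos + nchar(seq)
    c(start, pos)
  }
  add_piece(rand_seq(300L))
  zma <- entries$species == "zma"
  for (i in which(zma)) {
    iv <- add_piece(entries$precursor[i])
    ann[[length(ann) + 1L]] <- data.frame(
      contig = "chr1", start = iv[1L], end = iv[2L], name = entries$name[i],
      category = "miRNA", strand = "+", stringsAsFactors = FALSE)
    add_piece(rand_seq(150L))
  }
  genomic_cats <- c("mRNA", "rRNA", "tRNA", "snRNA", "snoRNA", "lncRNA",
                    "repeats")
  cat_iv <- list()
  for (cat in genomic_cats) {
    for (k in 1:2) {
      iv <- add_piece(rand_seq(400L))
      ann[[length(ann) + 1L]] <- data.frame(
        contig = "chr1", start = iv[1L], end = iv[2L],
        name = paste0(cat, "_", k), category = cat, strand = "+",
        stringsAsFactors = FALSE)
      cat_iv[[cat]] <- rbind(cat_iv[[cat]],
                             data.frame(start = iv[1L], end = iv[2L]))
      add_piece(rand_seq(150L))
    }
  }
  unann <- add_piece(rand_seq(6000L))
  chr1 <- paste(pieces, collapse = "")

  # organelle contigs at realistic scale (mt ~ hundreds of kb, cp ~ 140 kb)
  # so diffuse organelle reads stay sparse and hotspot pileups stand out
  organelles <- c(mt = rand_seq(200000L), cp = rand_seq(140000L))
  for (h in config$organelle_hotspot_list) {
    stopifnot(h$contig %in% names(organelles),
              h$start + h$span <= nchar(organelles[[h$contig]]),
              h$span >= 18L)
  }
  for (oc in names(organelles)) {
    ann[[length(ann) + 1L]] <- data.frame(
      contig = oc, start = 0L, end = nchar(organelles[[oc]]), name = oc,
      category = oc, strand = "+", stringsAsFactors = FALSE)
  }
  annotation <- do.call(rbind, ann)

  group_tbl <- data.frame(group = groups, mature = matures[groups],
                          stringsAsFactors = FALSE)
  first_entry <- entries[!duplicated(entries$group), ]
  fl <- catalog_flanks(data.frame(name = first_entry$group,
                                  family = NA, mature = first_entry$mature,
                                  precursor = first_entry$precursor))
  group_tbl$flank5 <- fl$flank5[match(groups, fl$name)]
  group_tbl$flank3 <- fl$flank3[match(groups, fl$name)]
  group_tbl$weight <- config$baseline_weights[groups]
  group_tbl$species <- first_entry$species[match(groups, first_entry$group)]

  structure(list(config = config, catalog = catalog, groups = group_tbl,
                 genome = Biostrings::DNAStringSet(c(chr1 = chr1)),
                 organelles = Biostrings::DNAStringSet(organelles),
                 annotation = annotation,
                 layout = list(chr1 = chr1, organelle_seqs = organelles,
                               unannotated = unann,
                               category_intervals = cat_iv)),
            class = "srna_reference")
}

# discrete insert length distribution with its mode at 24 nt
length_probs <- function(lens = 18:35, mode = 24, sd = 2.5) {
  p <- exp(-(lens - mode)^2 / (2 * sd^2))
  setNames(p / sum(p), lens)
}

sample_substrings <- function(seq_str, n, region_start, region_end,
                              len_probs) {
  width <- region_end - region_start
  lens <- as.integer(names(len_probs))
  ok <- lens <= width
  len <- sample(lens[ok], n, replace = TRUE, prob = len_probs[ok])
  start <- region_start + floor(runif(n) * (width - len + 1))  # 0-based
  ins <- substring(seq_str, start + 1L, start + len)
  minus <- runif(n) < 0.5
  ins[minus] <- rc_seqs(ins[minus])
  ins
}

#' Simulate one condition's library
#'
#' Draws the library as a single multinomial over the configured
#' components: miRNA groups (baseline weight x 2^true log2 FC), the
#' organelle hotspots, the fixed background categories, and the
#' unannotated remainder. miRNA reads are positional variants drawn
#' from the isomiR profile with extensions taken from precursor
#' context; background reads are substrings of their category intervals
#' (either strand) with a 24-nt length mode; every read then receives
#' the 3' adapter, is padded/truncated to the uniform raw length, and
#' gets constant Q40 qualities. Deterministic given the config seed and
#' condition.
#'
#' @param ref An `srna_reference` from [make_reference()].
#' @param condition One of the configured condition labels.
#' @param path Optional FASTQ output path.
#' @return list with `records` (read data.frame), `truth` (per-group
#'   true log2 FC, expected TPM and expected count), `condition`, and
#'   `components` (the realized multinomial bookkeeping: component,
#'   class, weight, count).
#' @export
simulate_library <- function(ref, condition, path = NULL) {
  stopifnot(inherits(ref, "srna_reference"))
  cfg <- ref$config
  idx <- match(condition, cfg$conditions)
  if (is.na(idx)) stop("unknown condition label: ", condition)
  set.seed((cfg$seed %% 1000003L) * 1009L + idx * 7919L)

  fc <- cfg$true_log2fc[[condition]]
  g <- ref$groups
  w_mirna <- cfg$mirna_fraction * g$weight * 2^fc[g$group]
  hs <- cfg$organelle_hotspot_list
  w_hot <- vapply(hs, \(h) h$tpm / 1e6, numeric(1L))
  w_bg <- cfg$background_fractions
  w_unann <- 1 - sum(w_mirna) - sum(w_hot) - sum(w_bg)
  if (w_unann < 0.005) stop("library composition leaves no unannotated mass")

  weights <- c(w_mirna, w_hot, w_bg, unannotated = w_unann)
  comp_class <- c(rep("miRNA", length(w_mirna)),
                  rep("hotspot", length(w_hot)),
                  rep("background", length(w_bg)), "unannotated")
  comp_name <- c(g$group,
                 vapply(hs, \(h) paste0("hotspot_", h$contig, "_", h$start),
                        character(1L)),
                 names(w_bg), "unannotated")
  counts <- as.vector(rmultinom(1L, cfg$depth, weights))
  n_g <- nrow(g); n_h <- length(hs)
  lp <- length_probs()
  prof <- cfg$isomir_profile

  inserts <- vector("list", length(counts))
  for (i in seq_len(n_g)) {            # miRNA groups
    m <- counts[i]
    if (!m) { inserts[[i]] <- character(0); next }
    ext <- paste0(g$flank5[i], g$mature[i], g$flank3[i])
    mp <- nchar(g$flank5[i]) + 1L
    Lm <- nchar(g$mature[i])
    ridx <- sample.int(nrow(prof), m, replace = TRUE, prob = prof$prob)
    inserts[[i]] <- substring(ext, mp + prof$off5[ridx],
                              mp + Lm - 1L + prof$off3[ridx])
  }
  for (k in seq_len(n_h)) {            # organelle hotspots
    h <- hs[[k]]; m <- counts[n_g + k]
    hp <- length_probs(18:min(24L, h$span))
    inserts[[n_g + k]] <- if (m) {
      sample_substrings(ref$layout$organelle_seqs[[h$contig]], m,
                        h$start, h$start + h$span, hp)
    } else character(0)
  }
  for (b in seq_along(w_bg)) {         # background categories
    cat <- names(w_bg)[b]; m <- counts[n_g + n_h + b]
    if (!m) { inserts[[n_g + n_h + b]] <- character(0); next }
    inserts[[n_g + n_h + b]] <-
      if (cat %in% c("mt", "cp")) {
        sample_substrings(ref$layout$organelle_seqs[[cat]], m, 0L,
                          nchar(ref$layout$organelle_seqs[[cat]]), lp)
      } else if (cat == "unmapped") {
        len <- sample(as.integer(names(lp)), m, replace = TRUE, prob = lp)
        vapply(len, rand_seq, character(1L))
      } else {
        iv <- ref$layout$category_intervals[[cat]]
        pick <- sample.int(nrow(iv), m, replace = TRUE,
                           prob = iv$end - iv$start)
        out <- character(m)
        for (r in seq_len(nrow(iv))) {
          sel <- pick == r
          if (any(sel)) {
            out[sel] <- sample_substrings(ref$layout$chr1, sum(sel),
                                          iv$start[r], iv$end[r], lp)
          }
        }
        out
      }
  }
  un <- ref$layout$unannotated         # unannotated remainder
  m <- counts[length(counts)]
  inserts[[length(counts)]] <- if (m) {
    sample_substrings(ref$layout$chr1, m, un[1L], un[2L], lp)
  } else character(0)

  ins <- unlist(inserts, use.names = FALSE)
  ins <- ins[sample.int(length(ins))]
  read <- paste0(ins, cfg$adapter3)
  short <- nchar(read) < cfg$raw_length
  if (any(short)) {
    pad_len <- cfg$raw_length - nchar(read[short])
    pad <- vapply(pad_len, rand_seq, character(1L))
    read[short] <- paste0(read[short], pad)
  }
  read <- substr(read, 1L, cfg$raw_length)
  records <- data.frame(
    id = sprintf("%s_%07d", condition, seq_along(read)),
    sequence = read,
    quality = strrep(rawToChar(as.raw(33L + 40L)), cfg$raw_length),
    stringsAsFactors = FALSE)

  truth <- data.frame(group = g$group, condition = condition,
                      true_log2fc = unname(fc[g$group]),
                      expected_tpm = 1e6 * w_mirna,
                      expected_count = cfg$depth * w_mirna,
                      stringsAsFactors = FALSE)
  if (!is.null(path)) write_fastq(records, path)
  list(records = records, truth = truth, condition = condition,
       components = data.frame(component = comp_name, class = comp_class,
                               weight = unname(weights), count = counts,
                               stringsAsFactors = FALSE))
}

#' Write a complete synthetic scenario to disk
#'
#' Builds the reference and one FASTQ per condition, and writes all
#' artifacts (genome, organelles, catalog FASTA + metadata, annotation
#' BED, per-condition FASTQ, truth table, config YAML) into `dir`.
#'
#' @param config A `sim_config`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, list with `ref`, `truth`, and the file `paths`.
#' @export
simulate_scenario <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ref <- make_reference(config)
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    organelles = file.path(dir, "organelles.fa"),
    catalog = file.path(dir, "catalog_mature.fa"),
    catalog_meta = file.path(dir, "catalog_meta.tsv"),
    annotation = file.path(dir, "annotation.bed"),
    truth = file.path(dir, "truth.tsv"),
    config = file.path(dir, "config.yaml"))
  write_fasta(setNames(as.character(ref$genome), names(ref$genome)),
              paths$genome)
  write_fasta(setNames(as.character(ref$organelles), names(ref$organelles)),
              paths$organelles)
  write_fasta(setNames(ref$catalog$mature, ref$catalog$name), paths$catalog)
  write.table(ref$catalog[, c("name", "family", "precursor")],
              paths$catalog_meta, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_annotation(ref$annotation, paths$annotation)
  write_sim_config(config, paths$config)
  truths <- list()
  for (cond in config$conditions) {
    fq <- file.path(dir, paste0("lib_", cond, ".fastq"))
    lib <- simulate_library(ref, cond, path = fq)
    truths[[cond]] <- lib$truth
    paths[[paste0("fastq_", cond)]] <- fq
  }
  truth <- do.call(rbind, truths)
  rownames(truth) <- NULL
  write.table(truth, paths$truth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(list(ref = ref, truth = truth, paths = paths))
}

#' Save / load a simulation configuration as YAML
#'
#' @param config A `sim_config`.
#' @param path YAML file path.
#' @return `write_sim_config`: `path` invisibly; `read_sim_config`: a
#'   rebuilt `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  x <- unclass(config)
  x$entries <- NULL
  x$baseline_weights <- as.list(x$baseline_weights)
  x$background_fractions <- as.list(x$background_fractions)
  x$true_log2fc <- lapply(x$true_log2fc, as.list)
  x$isomir_profile <- as.list(x$isomir_profile)
  x$mature_lengths <- as.integer(x$mature_lengths)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  sim_config(seed = x$seed, n_mirnas = x$n_mirnas,
             n_other_mirnas = x$n_other_mirnas, depth = x$depth,
             adapter3 = x$adapter3, raw_length = x$raw_length,
             conditions = unlist(x$conditions), control = x$control,
             mirna_fraction = x$mirna_fraction,
             baseline_weights = unlist(x$baseline_weights),
             true_log2fc = lapply(x$true_log2fc, unlist),
             isomir_profile = as.data.frame(lapply(x$isomir_profile, unlist)),
             background_fractions = unlist(x$background_fractions),
             organelle_hotspot_list = x$organelle_hotspot_list,
             mature_lengths = unlist(x$mature_lengths))
}
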