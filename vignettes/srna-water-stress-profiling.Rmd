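---
title: "Profiling small RNA libraries under water stress: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling small RNA libraries under water stress: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sRNAstress)
```

## The analysis this package implements

Maize (*Zea mays* ssp. *mays*) and its wild ancestor teosinte
(*Z. mays* ssp. *parviglumis*) respond to submergence and drought partly
through microRNAs, ~21-nt regulators that silence target mRNAs. A standard
way to profile that response is to sequence one pooled small RNA library
per condition, clean the reads, annotate them against a mature miRNA
catalog, normalize to tags per million (TPM), and call differential
expression from log2 fold-change thresholds rather than replicate-based
statistics. sRNAstress implements that pipeline as reusable, tested
functions, together with a synthetic-data generator that produces
libraries with known ground truth so every stage can be validated without
any external download.

The pipeline stages, in order:

1. **Read cleaning** (`preprocess_library`): 3' adapter trimming,
   mean-quality filtering, 18–35 nt length filtering, and collapsing of
   identical inserts into *tags* (unique sequence + per-library count),
   the atomic unit of all downstream quantification.
2. **Annotation** (`annotate_tags`, `map_tags`, `classify_tags`,
   `summarize_library`): exact genome/organelle mapping, assignment to a
   mature miRNA with bounded mismatches and 5'/3' end offsets, and
   classification of the remaining tags into non-coding RNA categories.
3. **Quantification** (`tpm`, `log2_fc`, `count_floor`, `de_call`):
   TPM normalization against the library's clean total, log2 fold change
   with a pseudocount, a raw-count floor, and threshold-based up/down
   calls.
4. **Grouping** (`group_variants`, `group_fc`): collapsing of each mature
   and its 1–2 nt positional variants (isomiRs), plus identical or
   end-shifted paralogs of the same family, into one *representative
   group* whose fold change is recomputed from summed counts.
5. **Comparison** (`responsive_set`, `fc_extrema`, `venn2`,
   `attenuation_report`): responsive-set extraction, directional overlap
   partitions between conditions, and attenuation analysis of alternated
   (sequential) stresses.
6. **Organelle hotspots** (`organelle_hotspots`) and **bench metrics**
   (`rwc`, `stc`, `ddct`).

## Models and conventions

**Tags and TPM.** A tag's abundance in a library is
`TPM = 1e6 * count / clean_total`, so each library's TPM column sums to
one million. Differential expression between a treatment and its control
is `log2((TPM_t + p) / (TPM_c + p))` with pseudocount `p = 1` TPM.
Calls use the inclusive thresholds `FC >= 1` (up) and `FC <= -1` (down),
and a row is only called at all if its raw count reaches 50 in at least
one of the two libraries; otherwise it is reported as `low_count`.
With one pooled library per condition these calls are descriptive, not
inferential — there is no dispersion to estimate — and the package
deliberately mirrors that design rather than bolting on p-values.

**Pseudocount.** Published FC tables in this field are finite
everywhere, which implies some zero-handling whose exact form is rarely
stated. We use a symmetric +1 TPM on both ratio sides: it leaves ratios
of well-expressed rows essentially untouched (1 TPM is ~0.1 reads at
10^5 depth) while bounding the FC of near-zero rows. The parameter is
exposed (`pseudo`) and reported in every `fc_matrix`; a quick
sensitivity check is one line per value:

```{r pseudo-sens, eval = FALSE}
sapply(c(0.1, 1, 10), function(p)
  build_fc_matrix(counts, totals, pairs, pseudo = p)$fc$submergence)
```

Rows above the count floor move by less than the call threshold across
this range; only `low_count` rows are sensitive, which is exactly why
the floor exists.

**Adapter trimming.** The leftmost position where a prefix of the 3'
adapter matches with at least 7 nt of overlap is the insert boundary.
One mismatch is tolerated for overlaps of 10 nt or more, none below
that — the standard small-RNA heuristic. Reads without a detectable
adapter are kept if they pass the other filters (they may be full-length
inserts); `strict_adapter = TRUE` discards them instead. Quality
filtering is a mean-PHRED criterion (default 20, inclusive) over the
trimmed insert; sliding-window trimming is out of scope because the
reads of interest are shorter than any informative window.

**miRNA matching.** A tag is compared against every catalog mature by
ungapped placement with 5' and 3' end offsets in {-2..2} and an overlap
of at least the mature length minus 2. Internal mismatches are Hamming
distance; bases extending beyond the mature ends are validated against
the precursor flanks when a precursor is known and otherwise count as
mismatches (unvalidated extensions are treated skeptically, since such
variants typically fail to map to the reference genome). The search is
run at `max_mm = 0` (exact sequences and positional variants only) or
`max_mm = 2` (tolerating polymorphisms). Each tag gets exactly one best
hit, minimizing `(mismatches, |off5| + |off3|, name)` — fractional
multi-assignment is avoided because the unit of quantification is the
unique sequence and determinism is required for reproducibility. The
compiled scorer is checked against an exhaustive R implementation on
randomized cases in the test suite.

**Classification.** A tag belongs to a category when an exact hit
overlaps an annotation interval of that category by at least half the
tag length, strand-agnostic. Conflicts resolve by fixed precedence:
miRNA, mt, cp, rRNA, tRNA, snRNA, snoRNA, lncRNA, mRNA, repeats. This
makes the categories a strict partition, so their counts are disjoint
and sum to at most the clean total. Published summary tables in this
field do not always partition (their columns can exceed 100%); the
partitioning classifier is a deliberate simplification, and percentages
are always recomputed as `100 * reads / clean` with half-up rounding to
two decimals. The clean-read denominator reproduces the published
percentage cells checked in the tests.

**Grouping.** Catalog entries of one family merge into a representative
group when their matures are identical or within the 1–2 nt end-offset
relation of each other, applied transitively (union–find, verified
against a transitive-closure oracle). Merging across families is
forbidden so paralogs are not conflated. Group names concatenate the
members' sorted variant letters (`miR167c/d/e/g` becomes `miR167cdeg`).
Tags with zero-mismatch hits pool into their mature's group; group FC is
recomputed from the summed counts, never averaged over members. Hits
with 1–2 mismatches are *kept as separate rows* flagged `polymorphic`
rather than merged — whether published analyses merged such variants is
ambiguous, and keeping them separate loses nothing. The group's anchor
sequence is its most abundant member tag, ties broken lexicographically.

**Attenuation.** "The response is maintained in trend but at lower
level" is made operational: a row is *attenuated* when its single-stress
response was regulated, the alternated response has the same sign, and
its magnitude is smaller; it is *lost* when the single-stress response
was regulated and the alternated one falls below the threshold. On the
published teosinte tables this flags miR159ab, miR164e, miR166bd,
miR319b and miR396cd as attenuated when drought follows submergence.

**Bench formulas.** `rwc = 100 (fresh - dry) / (turgid - dry)`;
`stc = sum(treated) / sum(control)` over shoot/root lengths (cm) and dry
weights (g) — the sums mix units by construction, as the coefficient is
defined for waterlogging scoring, and the function documents rather than
"fixes" this; `ddct = 2^-((Ct_t,treat - Ct_ref,treat) -
(Ct_t,ctrl - Ct_ref,ctrl))` with a single reference assay (miR166c in
the motivating study). Multi-reference geometric-mean normalization and
amplification-efficiency correction are out of scope.

## The synthetic-data generator

`sim_config()` + `make_reference()` + `simulate_library()` produce a
complete toy study:

* a catalog of ~20-species miRNA groups (every fifth group has two
  identical catalog entries to exercise paralog merging) plus a couple
  of other-plant entries whose precursors are *not* embedded in the
  genome, so they annotate to the catalog but never map;
* a genome with each study-species precursor at a recorded miRNA
  interval, two disjoint intervals per background category, and a large
  unannotated zone;
* mitochondrial and plastid contigs at realistic scale (hundreds of kb)
  carrying configurable read hotspots — defaults of 53 nt at 820 TPM
  (mt) and 32 nt at 2273 TPM (cp), mirroring reported organelle
  small RNA pileups;
* one multinomial library per condition: miRNA components weighted
  `baseline * 2^trueFC`, fixed background categories with a 24-nt length
  mode, hotspot pileups, a small unmappable fraction, and an unannotated
  remainder that absorbs compositional shifts so each miRNA's expected
  TPM log-ratio equals its configured truth; miRNA reads are isomiRs
  drawn from a configurable (off5, off3) profile with extensions taken
  from precursor context; every read then gets the standard 3' adapter
  (`TGGAATTCTCGGGTGCCAAGG`), padding/truncation to a uniform 50-nt raw
  length, and constant Q40 qualities.

Everything is deterministic given the seed: the same configuration
yields byte-identical FASTQ files.

The default isomiR profile puts 60% of the mass on the exact mature and
spreads the rest symmetrically over 1–2 nt end shifts. Real plant isomiR
offset distributions are not well characterized; this default is an
explicit, arbitrary modeling choice and is exposed for replacement.

**What the generator does not emulate** — and hence what passing tests
do *not* demonstrate about real data: sequencing errors and quality
decay, 5' adapter read-through, PCR duplicates, replicate-level
biological variance (the multinomial has no overdispersion, matching the
pooled-library design), expression-dependent ligation bias, and genuine
genomic repeat structure. Recovery results on synthetic data bound the
*estimator's* error, not the biological noise of a real experiment.

## Power calibration of the recovery scenario

For a group with `n_c` control reads and true fold change `FC`, the
binomial sampling error of the estimated log2 TPM ratio is approximately

```
SE(FC_hat) = sqrt(1/n_t + 1/n_c) / ln 2,   n_t = n_c * 2^FC
```

so requiring the same `3 * SE` for every group makes the needed control
depth proportional to `1 + 2^-FC`. `sim_config_recovery()` assigns true
FCs cycling over {-3, -1, 0, 1, 3}, sets baselines proportional to that
requirement, and chooses the miRNA fraction so that `3 * SE <= 0.2`
with a 1.5x count margin at 10^5 reads per library. Two consequences are
worth stating plainly:

* the calibrated baselines automatically balance the composition
  (`sum w * 2^FC = sum w`), so the treatment's miRNA mass equals the
  control's and the TPM ratio is unbiased;
* about half of the calibrated library is miRNA-derived — far above the
  ~1–3% of real libraries. The scenario measures estimator accuracy at a
  prescribed precision; it does not pretend to be compositionally
  realistic. The default `sim_config()` (2.5% miRNA, category fractions
  patterned on real control libraries) is the realistic counterpart used
  for the library-summary and composition checks.

Problem sizes used throughout the tests and the acceptance script —
10^5 reads per library, 3–5 libraries, ~20 miRNA groups, ~45 catalog
entries — are the package's chosen working scale for these scenarios.

## Numerical choices and degenerate inputs

* Reported percentages and fold changes round half away from zero
  (`round_half_up`), matching how printed tables round (-4.385 prints
  as -4.39), not IEEE round-half-even.
* All interval coordinates are 0-based half-open with explicit strand;
  FASTQ quality is PHRED+33 with no offset autodetection.
* `tpm` refuses a zero clean total; `summarize_library` refuses
  clean = 0 (percentages undefined); `rwc` refuses turgid = dry.
* Ties everywhere resolve deterministically: best hit by
  (mismatches, offset sum, name, off5), group anchors lexicographically,
  extrema in row order.
* An empty treated group gives `stc = 0`; an empty tag table collapses
  to a zero-row data frame rather than an error.

## Known limitations

* Exhaustive placement search is the right tool at catalog scale
  (hundreds of matures); against the full miRBase plant set a seeded
  index would be preferable.
* The classifier assigns each tag one category by precedence; reads from
  genuinely ambiguous loci (e.g. an rRNA fragment inside a repeat) are
  counted once, by design.
* Novel-miRNA discovery (hairpin folding, precursor read-distribution
  criteria) and target prediction are out of scope.
* `venn2` reports counts and membership, not diagrams; plotting is left
  to the caller.
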