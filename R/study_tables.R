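# Published summary numbers from the maize/teosinte water-stress small RNA
# profiling study (NCBI GEO accession GSE155050). These are the printed
# summary tables of that study, shipped so that the classification,
# percentage, overlap and attenuation operations can be exercised on real
# reported values without re-sequencing. Raw counts are stored; derived
# percentages are always recomputed.

#' Representative miRNA fold-change matrix under single stresses
#'
#' Log2 fold changes (treatment/control TPM) of the representative miRNA
#' groups in maize and teosinte under submergence and drought, from the
#' GSE155050 profiling study. The constitutive control row (miR166c,
#' stable in all conditions and used as the qPCR reference) is excluded
#' unless requested.
#'
#' @param include_constitutive Include the miR166c reference row.
#' @return data.frame with `name` and four log2 FC columns:
#'   `maize_submergence`, `maize_drought`, `teosinte_submergence`,
#'   `teosinte_drought`.
#' @export
stress_fc_table <- function(include_constitutive = FALSE) {
  tbl <- data.frame(
    name = c("miR156k", "miR159ab", "miR164e", "miR166bd", "miR167cdeg",
             "miR169cr", "miR319b", "miR396cd", "miR398ab", "miR398b",
             "miR408", "miR408b", "miR528ab", "miR166c"),
    maize_submergence    = c(-2.94, -2.17, -4.24, -4.39, -2.99, -3.13,
                             -0.75, -1.04, -0.38, -2.83, -1.34, -2.14,
                             -1.30, 0.00),
    maize_drought        = c(-2.99, 0.80, -1.49, -3.79, -2.48, -0.95,
                             0.80, -0.17, -0.29, -0.94, -0.51, -0.89,
                             -1.65, -0.01),
    teosinte_submergence = c(-0.86, -1.46, -0.29, -2.77, -1.62, -1.05,
                             -0.66, -0.39, -1.09, -0.69, -1.78, -2.57,
                             -2.22, -0.21),
    teosinte_drought     = c(1.09, 1.06, 1.20, -1.49, -0.33, 0.11,
                             2.17, 1.08, 0.05, 0.29, -1.76, 0.17,
                             -0.57, -0.19),
    stringsAsFactors = FALSE)
  if (include_constitutive) tbl else tbl[tbl$name != "miR166c", ] |>
    (\(d) { rownames(d) <- NULL; d })()
}

#' Teosinte fold changes under single and alternated stress
#'
#' Log2 fold changes of the representative miRNA groups in teosinte
#' under submergence, drought, drought followed by submergence, and
#' submergence followed by drought (GSE155050 study).
#'
#' @inheritParams stress_fc_table
#' @return data.frame with `name` and columns `submergence`, `drought`,
#'   `drought_submergence`, `submergence_drought`.
#' @export
alternated_fc_table <- function(include_constitutive = FALSE) {
  tbl <- data.frame(
    name = c("miR156k", "miR159ab", "miR164e", "miR166bd", "miR167cdeg",
             "miR169cr", "miR319b", "miR396cd", "miR398ab", "miR398b",
             "miR408", "miR408b", "miR528ab", "miR166c"),
    submergence         = c(-0.86, -1.46, -0.29, -2.77, -1.62, -1.05,
                            -0.66, -0.39, -1.09, -0.69, -1.78, -2.57,
                            -2.22, -0.21),
    drought             = c(1.09, 1.06, 1.20, -1.49, -0.33, 0.11,
                            2.17, 1.08, 0.05, 0.29, -1.76, 0.17,
                            -0.57, -0.19),
    drought_submergence = c(-0.54, -1.43, 0.06, -1.95, -1.87, -1.60,
                            -0.41, -0.94, -1.56, -1.92, -0.88, -0.43,
                            -3.16, -0.27),
    submergence_drought = c(1.17, 0.55, 1.09, -0.77, 0.71, 0.11,
                            0.16, 0.53, -0.58, -0.57, 0.55, -0.87,
                            -0.99, -0.19),
    stringsAsFactors = FALSE)
  if (include_constitutive) tbl else tbl[tbl$name != "miR166c", ] |>
    (\(d) { rownames(d) <- NULL; d })()
}

#' Library category read counts of the eight sequencing libraries
#'
#' Raw and clean read totals and per-category read counts of the eight
#' pooled small RNA libraries of the GSE155050 study (maize and teosinte
#' under control, submergence, drought, and the two alternated
#' treatments for teosinte). Percentages of clean reads are not stored;
#' recompute them with [summarize_counts()].
#'
#' @return data.frame with `category` plus one count column per library.
#' @export
library_category_counts <- function() {
  data.frame(
    category = c("raw", "clean", "genome-mapped", "mt", "cp", "mRNA",
                 "rRNA", "tRNA", "snRNA", "snoRNA", "lncRNA", "repeats",
                 "miRNA", "other-miRNA"),
    maize_control = c(16139354, 14897058, 14870947, 87401, 182414, 195418,
                      288257, 103451, 516999, 105518, 258027, 2219656,
                      397473, 24837),
    maize_submergence = c(26621448, 24568439, 24488359, 106625, 452301,
                          258447, 601629, 161288, 838151, 168088, 416896,
                          3623199, 248193, 21526),
    maize_drought = c(31642210, 29744161, 29696341, 134420, 459718, 342833,
                      778148, 200294, 1071157, 228389, 519449, 4820455,
                      774680, 39108),
    teosinte_control = c(20672413, 18955892, 18927434, 114741, 475121,
                         207230, 687038, 569294, 576299, 141006, 362527,
                         5064798, 180091, 6498),
    teosinte_submergence = c(28656756, 26296921, 26217672, 73980, 444434,
                             202191, 591868, 480975, 868349, 174443,
                             530505, 5305481, 98923, 5862),
    teosinte_drought = c(29063588, 26960313, 26912777, 105999, 835675,
                         256739, 588819, 553939, 890657, 190297, 528963,
                         5343314, 310478, 7393),
    teosinte_drought_submergence = c(17997037, 15760258, 15727757, 106451,
                                     973949, 238774, 1056243, 953794,
                                     421404, 111528, 231375, 4734879,
                                     47836, 6470),
    teosinte_submergence_drought = c(46522229, 41915673, 41761974, 145709,
                                     1289213, 309551, 1240514, 1426872,
                                     1220748, 256675, 719402, 9267896,
                                     350678, 13887),
    stringsAsFactors = FALSE)
}
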