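#' Relative water content of a leaf section
#'
#' RWC = 100 * (fresh - dry) / (turgid - dry), in percent. Fresh weight is
#' taken at excision, turgid weight after 24 h in deionized water, dry
#' weight after drying to constant mass.
#'
#' @param fresh_g,turgid_g,dry_g Masses in grams; must satisfy
#'   turgid >= fresh >= dry > 0.
#' @return RWC in percent, between 0 and 100.
#' @export
#' @examples
#' rwc(1.8, 2.1, 0.6)  # 80
rwc <- function(fresh_g, turgid_g, dry_g) {
  if (any(dry_g <= 0)) stop("dry weight must be positive")
  if (any(turgid_g == dry_g)) stop("turgid and dry weight are equal; RWC undefined")
  if (any(turgid_g < fresh_g) || any(fresh_g < dry_g)) {
    stop("weights must satisfy turgid >= fresh >= dry")
  }
  100 * (fresh_g - dry_g) / (turgid_g - dry_g)
}

#' Submergence tolerance coefficient
#'
#' Ratio of the summed plant measurements (shoot/root lengths in cm and
#' dry weights in g) of treated plants over control plants. The sums mix
#' units by construction, exactly as the coefficient is defined for
#' waterlogging tolerance scoring; it is a dimensionless growth index,
#' not a physical quantity.
#'
#' @param treated,control Numeric vectors, matrices or data.frames of the
#'   per-plant measurements to sum (e.g. columns length and dry weight).
#' @return STC ratio; 0 when `treated` is empty.
#' @export
#' @examples
#' stc(cbind(len = c(10, 12), dw = c(0.5, 0.6)),
#'     cbind(len = c(11, 12), dw = c(0.55, 0.62)))
stc <- function(treated, control) {
  s_ctrl <- sum(as.numeric(as.matrix(control)))
  if (!isTRUE(s_ctrl > 0)) stop("control sum must be positive")
  if (length(treated) == 0L) return(0)
  sum(as.numeric(as.matrix(treated))) / s_ctrl
}

#' Relative expression by the delta-delta-Ct method
#'
#' 2^-((Ct_target,treat - Ct_ref,treat) - (Ct_target,ctrl - Ct_ref,ctrl)),
#' with a single reference assay (the profiling study used miR166c) as
#' internal control. Values above 1 indicate higher target abundance in
#' the treatment.
#'
#' @param ct_target_treat,ct_ref_treat,ct_target_ctrl,ct_ref_ctrl
#'   Cycle-threshold values.
#' @return Relative expression ratio.
#' @export
#' @examples
#' ddct(22, 18, 20, 18)  # 0.25
ddct <- function(ct_target_treat, ct_ref_treat, ct_target_ctrl, ct_ref_ctrl) {
  ddc <- (ct_target_treat - ct_ref_treat) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddc)
}
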