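#' Copy-number calling policy
#'
#' Bundles the tunable parameters of the comparative-CT copy-number
#' pipeline: the cutoffs that bound the no-call zone, the assumed copy
#' number of the control locus, and the optional amplification-efficiency
#' correction.
#'
#' A raw diploid copy estimate with fractional part `f` is rounded down
#' when `f <= low_cutoff`, rounded up when `f >= high_cutoff`, and left
#' uncalled otherwise.  With the defaults (0.3 and 0.7) this creates a
#' symmetric no-call window of width 0.4 around each half-integer.
#'
#' When `efficiency_correction` is `TRUE` the estimate uses the per-assay
#' amplification efficiencies (fractional template gain per cycle, 1.0 for
#' perfect doubling):
#' `control_diploid_copies * (1 + eff_control)^ct_control * (1 + eff_target)^(-ct_target)`,
#' which reduces to the base-2 comparative-CT formula when both
#' efficiencies are 1.
#'
#' @param low_cutoff Fractional part at or below which estimates floor.
#' @param high_cutoff Fractional part at or above which estimates ceil.
#' @param control_diploid_copies Copies of the control locus per diploid
#'   genome (2 for a single-copy locus).
#' @param efficiency_correction Apply the per-assay efficiency correction?
#' @param eff_target,eff_control Fractional amplification efficiencies in
#'   `[0, 1.1]`; only used when `efficiency_correction = TRUE`.
#' @param sd_flag_threshold Replicate-SD (cycles) above which a
#'   sample/assay group is flagged in QC output; flagged groups are kept.
#' @return An object of class `calling_policy`.
#' @examples
#' calling_policy()
#' calling_policy(efficiency_correction = TRUE, eff_target = 0.98,
#'                eff_control = 0.97)
#' @export
calling_policy <- function(low_cutoff = 0.3, high_cutoff = 0.7,
                           control_diploid_copies = 2L,
                           efficiency_correction = FALSE,
                           eff_target = 1.0, eff_control = 1.0,
                           sd_flag_threshold = 0.5) {
  stopifnot(is.numeric(low_cutoff), is.numeric(high_cutoff),
            length(low_cutoff) == 1L, length(high_cutoff) == 1L)
  if (!(low_cutoff >= 0 && low_cutoff < high_cutoff && high_cutoff <= 1))
    stop("cutoffs must satisfy 0 <= low_cutoff < high_cutoff <= 1")
  control_diploid_copies <- as.integer(control_diploid_copies)
  if (is.na(control_diploid_copies) || control_diploid_copies < 1L)
    stop("control_diploid_copies must be a positive integer")
  for (e in c(eff_target, eff_control))
    if (!is.finite(e) || e < 0 || e > 1.1)
      stop("efficiencies must be fractions in [0, 1.1]")
  if (!is.finite(sd_flag_threshold) || sd_flag_threshold < 0)
    stop("sd_flag_threshold must be non-negative")
  structure(
    list(low_cutoff = low_cutoff, high_cutoff = high_cutoff,
         control_diploid_copies = control_diploid_copies,
         efficiency_correction = isTRUE(efficiency_correction),
         eff_target = eff_target, eff_control = eff_control,
         sd_flag_threshold = sd_flag_threshold),
    class = "calling_policy")
}

#' @export
print.calling_policy <- function(x, ...) {
  cat("Copy-number calling policy\n")
  cat(sprintf("  no-call zone: fractional part in (%.2f, %.2f)\n",
              x$low_cutoff, x$high_cutoff))
  cat(sprintf("  control locus: %d copies per diploid genome\n",
              x$control_diploid_copies))
  if (x$efficiency_correction)
    cat(sprintf("  efficiency correction ON (target %.3f, control %.3f)\n",
                x$eff_target, x$eff_control))
  else
    cat("  efficiency correction off (assumes perfect doubling)\n")
  invisible(x)
}
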