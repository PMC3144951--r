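# Comparative-CT quantification: replicate aggregation, standard-curve
# calibration, raw copy estimation and integer genotype calling.

validate_ct_wells <- function(wells) {
  if (!is.data.frame(wells))
    stop("wells must be a data.frame")
  needed <- c("sample_id", "assay", "replicate", "ct")
  missing <- setdiff(needed, names(wells))
  if (length(missing))
    stop("wells is missing column(s): ", paste(missing, collapse = ", "))
  if (nrow(wells) == 0L)
    stop("empty Ct-well table")
  if (!all(wells$assay %in% c("target", "control")))
    stop("assay values must be 'target' or 'control'")
  if (any(!is.finite(wells$ct)) || any(wells$ct <= 0) || any(wells$ct >= 60))
    stop("Ct values must be finite and in (0, 60) cycles")
  key <- paste(wells$sample_id, wells$assay, wells$replicate, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (sample_id, assay, replicate) rows in wells")
  invisible(wells)
}

#' Aggregate replicate Ct values
#'
#' Collapses replicate wells to one mean Ct per sample/assay pair, as the
#' comparative-CT method works on the mean of (typically triplicate)
#' replicates from the same DNA preparation.  The replicate SD is reported
#' for quality control; groups whose SD exceeds `sd_flag_threshold` are
#' flagged, never dropped.
#'
#' @param wells A data.frame with columns `sample_id`, `assay` (`"target"`
#'   or `"control"`), `replicate`, `ct`.
#' @param sd_flag_threshold Replicate-SD flagging threshold in cycles.
#' @return A data.frame with columns `sample_id`, `assay`, `mean_ct`,
#'   `sd_ct` (`NA` for singleton groups), `n`, `flagged`, one row per
#'   sample/assay group, in order of first appearance.
#' @examples
#' w <- data.frame(sample_id = "s1", assay = "target", replicate = 1:3,
#'                 ct = c(19.8, 20.0, 20.2))
#' aggregate_replicates(w)
#' @export
aggregate_replicates <- function(wells, sd_flag_threshold = 0.5) {
  validate_ct_wells(wells)
  key <- paste(wells$sample_id, wells$assay, sep = "\r")
  groups <- split(seq_len(nrow(wells)), factor(key, levels = unique(key)))
  out <- do.call(rbind, lapply(groups, function(idx) {
    ct <- wells$ct[idx]
    data.frame(sample_id = wells$sample_id[idx[1L]],
               assay = wells$assay[idx[1L]],
               mean_ct = mean(ct),
               sd_ct = if (length(ct) > 1L) sd(ct) else NA_real_,
               n = length(ct),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out$flagged <- !is.na(out$sd_ct) & out$sd_ct > sd_flag_threshold
  out
}

#' Fit a qPCR standard curve and estimate amplification efficiency
#'
#' Ordinary least-squares fit of Ct on log10 template quantity over a
#' dilution series.  Percent amplification efficiency follows
#' `E = (10^(-1/slope) - 1) * 100`: a slope of -3.3219 cycles per ten-fold
#' dilution corresponds to perfect per-cycle doubling (100%).
#'
#' @param series A data.frame with columns `log10_quantity` and `ct`
#'   (a `replicate` column is allowed and ignored by the fit).
#' @return An object of class `efficiency_estimate` with fields `slope`,
#'   `intercept`, `r_squared`, `efficiency_percent`, `n_levels`, `n_points`.
#' @examples
#' s <- data.frame(log10_quantity = 0:-4,
#'                 ct = 18 - (0:-4) * 3.3219)
#' fit_standard_curve(s)
#' @export
fit_standard_curve <- function(series) {
  if (!is.data.frame(series) ||
      !all(c("log10_quantity", "ct") %in% names(series)))
    stop("series must have columns log10_quantity and ct")
  levels_n <- length(unique(series$log10_quantity))
  if (levels_n < 3L)
    stop("a standard curve needs at least 3 distinct dilution levels")
  if (any(!is.finite(series$ct)) || any(!is.finite(series$log10_quantity)))
    stop("non-finite values in dilution series")
  fit <- lm(ct ~ log10_quantity, data = series)
  slope <- unname(coef(fit)[2L])
  if (!is.finite(slope) || slope >= 0)
    stop("invalid standard curve: slope must be negative ",
         "(Ct must increase as template decreases)")
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((series$ct - mean(series$ct))^2)
  structure(
    list(slope = slope,
         intercept = unname(coef(fit)[1L]),
         r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
         efficiency_percent = (10^(-1 / slope) - 1) * 100,
         n_levels = levels_n,
         n_points = nrow(series)),
    class = "efficiency_estimate")
}

#' @export
print.efficiency_estimate <- function(x, ...) {
  cat("qPCR standard curve\n")
  cat(sprintf("  slope       %8.4f cycles / log10 unit\n", x$slope))
  cat(sprintf("  intercept   %8.4f cycles\n", x$intercept))
  cat(sprintf("  R-squared   %8.5f\n", x$r_squared))
  cat(sprintf("  efficiency  %8.2f %% (%d levels, %d points)\n",
              x$efficiency_percent, x$n_levels, x$n_points))
  invisible(x)
}

#' Estimate raw diploid copy number from mean Ct values
#'
#' The comparative-CT estimate for a target locus against a single-copy
#' control locus: `2 * 2^(-(ct_target - ct_control))` under perfect
#' doubling.  With `policy$efficiency_correction` the per-assay efficiency
#' form `control_diploid_copies * (1 + eff_control)^ct_control *
#' (1 + eff_target)^(-ct_target)` is used instead; it reduces to the
#' base-2 formula when both efficiencies equal 1.
#'
#' @param mean_ct_target,mean_ct_control Mean Ct values (vectors recycle
#'   as usual).
#' @param policy A [calling_policy()].
#' @return Numeric vector of strictly positive raw diploid copy estimates.
#' @examples
#' estimate_copy_number(20, 20)         # baseline: 2 copies
#' estimate_copy_number(19, 20)         # one cycle earlier: 4 copies
#' @export
estimate_copy_number <- function(mean_ct_target, mean_ct_control,
                                 policy = calling_policy()) {
  stopifnot(inherits(policy, "calling_policy"))
  if (any(!is.finite(mean_ct_target)) || any(!is.finite(mean_ct_control)))
    stop("Ct values must be finite")
  if (any(mean_ct_target <= 0) || any(mean_ct_control <= 0))
    stop("Ct values must be positive")
  if (policy$efficiency_correction) {
    policy$control_diploid_copies *
      (1 + policy$eff_control)^mean_ct_control *
      (1 + policy$eff_target)^(-mean_ct_target)
  } else {
    policy$control_diploid_copies * 2^(-(mean_ct_target - mean_ct_control))
  }
}

#' Convert raw copy estimates to integer genotype calls
#'
#' Applies the cutoff rule: with `n = floor(raw)` and fractional part
#' `f = raw - n`, call `n` when `f <= low_cutoff`, call `n + 1` when
#' `f >= high_cutoff`, and no-call otherwise ("ambiguous fractional
#' estimate").  Estimates below `high_cutoff` (i.e. too small to round up
#' to one copy) are no-called as "below one copy".
#'
#' @param raw_estimate Numeric vector of positive raw estimates.
#' @param policy A [calling_policy()].
#' @return A data.frame with columns `raw_estimate`, `call` (integer or
#'   `NA`) and `no_call_reason` (`NA` for called rows).
#' @examples
#' call_copy_number(c(4.0, 3.25, 3.50, 3.72))
#' @export
call_copy_number <- function(raw_estimate, policy = calling_policy()) {
  stopifnot(inherits(policy, "calling_policy"))
  if (any(!is.finite(raw_estimate)) || any(raw_estimate <= 0))
    stop("raw_estimate must be finite and positive")
  n <- floor(raw_estimate)
  f <- raw_estimate - n
  call <- rep(NA_integer_, length(raw_estimate))
  reason <- rep(NA_character_, length(raw_estimate))
  below <- raw_estimate < policy$high_cutoff
  lo <- !below & f <= policy$low_cutoff
  hi <- !below & f >= policy$high_cutoff
  call[lo] <- as.integer(n[lo])
  call[hi] <- as.integer(n[hi]) + 1L
  reason[below] <- "below one copy"
  reason[!below & is.na(call)] <- "ambiguous fractional estimate"
  data.frame(raw_estimate = raw_estimate, call = call,
             no_call_reason = reason, stringsAsFactors = FALSE)
}

#' Genotype a population from a raw Ct-well table
#'
#' End-to-end comparative-CT genotyping: aggregates replicates, pairs each
#' sample's target and control mean Cts, estimates raw diploid copy number
#' and applies the calling cutoffs.  Samples missing either assay are
#' excluded with a warning; no-calls are retained with their reasons.
#'
#' @param wells Ct-well data.frame (see [aggregate_replicates()]).
#' @param policy A [calling_policy()].
#' @return A data.frame with one row per complete sample: `sample_id`,
#'   `mean_ct_target`, `mean_ct_control`, `raw_estimate`, `call`,
#'   `no_call_reason`.  The per-group QC table is attached as attribute
#'   `"qc"`.
#' @examples
#' w <- expand.grid(replicate = 1:3, assay = c("target", "control"),
#'                  sample_id = c("a", "b"), stringsAsFactors = FALSE)
#' w$ct <- ifelse(w$assay == "control", 26, 25)  # one cycle early: 4 copies
#' genotype_population(w)
#' @export
genotype_population <- function(wells, policy = calling_policy()) {
  stopifnot(inherits(policy, "calling_policy"))
  empty <- data.frame(sample_id = character(), mean_ct_target = numeric(),
                      mean_ct_control = numeric(), raw_estimate = numeric(),
                      call = integer(), no_call_reason = character(),
                      stringsAsFactors = FALSE)
  if (is.data.frame(wells) && nrow(wells) == 0L) {
    attr(empty, "qc") <- empty[, 0]
    return(empty)
  }
  agg <- aggregate_replicates(wells, sd_flag_threshold = policy$sd_flag_threshold)
  samples <- unique(agg$sample_id)
  tgt <- agg[agg$assay == "target", ]
  ctl <- agg[agg$assay == "control", ]
  complete <- samples[samples %in% tgt$sample_id & samples %in% ctl$sample_id]
  incomplete <- setdiff(samples, complete)
  if (length(incomplete))
    warning(sprintf("excluding %d sample(s) missing an assay: %s",
                    length(incomplete),
                    paste(head(incomplete, 5L), collapse = ", ")),
            call. = FALSE)
  if (!length(complete)) {
    attr(empty, "qc") <- agg
    return(empty)
  }
  ct_t <- tgt$mean_ct[match(complete, tgt$sample_id)]
  ct_c <- ctl$mean_ct[match(complete, ctl$sample_id)]
  raw <- estimate_copy_number(ct_t, ct_c, policy)
  calls <- call_copy_number(raw, policy)
  out <- data.frame(sample_id = complete,
                    mean_ct_target = ct_t,
                    mean_ct_control = ct_c,
                    raw_estimate = raw,
                    call = calls$call,
                    no_call_reason = calls$no_call_reason,
                    stringsAsFactors = FALSE)
  attr(out, "qc") <- agg
  out
}
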