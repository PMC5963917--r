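# Closed-form bench assay computations: ddCT relative expression,
# percent intron retained and exponential half-life fitting.

#' Relative expression by the delta-delta-CT method
#'
#' `dCT = ct_target - ct_ref` per condition; `ddCT = dCT_cond - dCT_ctrl`;
#' relative level `= 2^(-ddCT)` (amplification efficiency fixed at 2).
#' Scale-invariant to adding a constant to all CT values.
#'
#' @param ct_target_cond,ct_ref_cond CT values in the condition of
#'   interest (target and reference gene).
#' @param ct_target_ctrl,ct_ref_ctrl CT values in the control condition.
#' @return relative expression level (vectorised).
#' @export
ddct_relative <- function(ct_target_cond, ct_ref_cond,
                          ct_target_ctrl, ct_ref_ctrl) {
  cts <- c(ct_target_cond, ct_ref_cond, ct_target_ctrl, ct_ref_ctrl)
  if (any(!is.finite(cts)) || any(cts <= 0))
    stop("CT values must be finite and positive")
  ddct <- (ct_target_cond - ct_ref_cond) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct)
}

#' Percent of transcripts with the retained intron
#'
#' @param retained_level abundance of the intron-retained form.
#' @param total_level total transcript abundance (> 0).
#' @return percentage in \\[0, 100\\].
#' @export
percent_retained <- function(retained_level, total_level) {
  if (any(total_level <= 0)) stop("undefined: total level must be > 0")
  if (any(retained_level < 0)) stop("retained level must be >= 0")
  100 * retained_level / total_level
}

#' mRNA half-life from a transcription-shutoff decay time course
#'
#' Least-squares fit of `ln(level)` against time; `t1/2 = ln(2)/|slope|`.
#' A non-negative slope is flagged as "no decay" with an undefined
#' half-life.  Exact on noiseless exponentials.
#'
#' @param times time points (hours, >= 3).
#' @param levels normalised abundances (> 0), same length.
#' @return list with `t_half` (hours, `NA` if no decay), `slope`,
#'   `r_squared`, `no_decay`.
#' @export
half_life_fit <- function(times, levels) {
  stopifnot(length(times) == length(levels))
  if (length(times) < 3L) stop("need >= 3 timepoints")
  if (any(levels <= 0)) stop("levels must be > 0")
  fit <- stats::lm(log(levels) ~ times)
  slope <- unname(stats::coef(fit)[2L])
  r2 <- summary(fit)$r.squared
  if (slope >= 0)
    return(list(t_half = NA_real_, slope = slope, r_squared = r2,
                no_decay = TRUE))
  list(t_half = log(2) / abs(slope), slope = slope, r_squared = r2,
       no_decay = FALSE)
}
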