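#' Exponential growth rate from an optical-density curve
#'
#' `mu = ln(X / X0) / T` evaluated on the linear portion of growth,
#' operationalized as the sliding window of `window` consecutive time
#' points whose least-squares slope of `ln OD` versus time is largest.
#' Invariant to uniform scaling of the optical densities.
#'
#' @param time_h time points in hours, strictly increasing (>= 3).
#' @param od600 optical densities at 600 nm, all > 0.
#' @param window window width in points (default 4, clipped to the curve
#'   length).
#' @return growth rate `mu` per hour.
#' @export
growth_rate <- function(time_h, od600, window = 4) {
  if (length(time_h) != length(od600)) stop("time and OD lengths differ")
  if (length(time_h) < 3) stop("need >= 3 points")
  if (any(diff(time_h) <= 0)) stop("time points must be strictly increasing")
  if (any(od600 <= 0)) stop("optical densities must be positive")
  w <- min(window, length(time_h))
  ly <- log(od600)
  slopes <- vapply(seq_len(length(time_h) - w + 1), function(i) {
    idx <- i:(i + w - 1)
    tt <- time_h[idx] - mean(time_h[idx])
    sum(tt * (ly[idx] - mean(ly[idx]))) / sum(tt^2)
  }, numeric(1))
  max(slopes)
}

#' Percent bile-acid conversion from peak areas
#'
#' Disappearance mode (e.g. deconjugation of a taurine/glycine conjugate):
#' `100 * (1 - substrate_end / substrate_0)`.  Appearance mode (e.g.
#' 7-alpha oxidation product): `100 * product_end / substrate_0`.
#'
#' @param substrate_0 substrate peak area at time 0 (> 0).
#' @param substrate_end substrate peak area at the end timepoint
#'   (disappearance mode).
#' @param product_end product peak area at the end timepoint (appearance
#'   mode).
#' @param mode `"disappearance"` or `"appearance"`.
#' @return percent in `[0, 100]` for consistent inputs.
#' @export
percent_conversion <- function(substrate_0, substrate_end = NULL,
                               product_end = NULL,
                               mode = c("disappearance", "appearance")) {
  mode <- match.arg(mode)
  if (substrate_0 <= 0) stop("initial substrate area must be positive")
  if (mode == "disappearance") {
    if (is.null(substrate_end)) stop("disappearance mode needs substrate_end")
    100 * (1 - substrate_end / substrate_0)
  } else {
    if (is.null(product_end)) stop("appearance mode needs product_end")
    100 * product_end / substrate_0
  }
}

#' Relative gene expression by the 2^-ddCt method
#'
#' `dCt = Ct_target - Ct_reference` within each condition;
#' `ddCt = dCt_test - dCt_control`; fold change `2^-ddCt`, normalized to
#' the reference gene (e.g. GAPDH).
#'
#' @param ct_target_test,ct_ref_test mean Ct values in the test condition.
#' @param ct_target_control,ct_ref_control mean Ct values in the control
#'   condition.
#' @return fold change (1 = no change).
#' @export
relative_expression <- function(ct_target_test, ct_ref_test,
                                ct_target_control, ct_ref_control) {
  cts <- c(ct_target_test, ct_ref_test, ct_target_control, ct_ref_control)
  if (anyNA(cts)) stop("missing Ct value (reference gene required in both conditions)")
  if (any(cts <= 0)) stop("Ct values must be positive")
  dct_test <- ct_target_test - ct_ref_test
  dct_control <- ct_target_control - ct_ref_control
  2^(-(dct_test - dct_control))
}
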