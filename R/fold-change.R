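#' Signed fold change between two group means
#'
#' Expression ratios are reported on the signed convention used throughout
#' intensity-microarray studies: the ratio of the larger mean to the smaller,
#' carrying a positive sign when the case group is higher and a negative sign
#' when the control group is higher. The magnitude is therefore always >= 1,
#' and a 2-fold suppression prints as -2.0 rather than 0.5.
#'
#' @param mean_case numeric vector of case-group means, strictly positive.
#' @param mean_control numeric vector of control-group means, strictly
#'   positive; recycled against `mean_case` in the usual way.
#' @return numeric vector of signed fold changes with `abs(fc) >= 1`;
#'   equal means give exactly +1.
#' @examples
#' signed_fold_change(15.8, 7.2)   # +2.19...
#' signed_fold_change(18.3, 30.6)  # -1.67...
#' @export
signed_fold_change <- function(mean_case, mean_control) {
  if (!is.numeric(mean_case) || !is.numeric(mean_control))
    stop("means must be numeric")
  if (any(!is.finite(mean_case)) || any(!is.finite(mean_control)) ||
      any(mean_case <= 0) || any(mean_control <= 0))
    stop("signed fold change requires strictly positive, finite group means")
  ifelse(mean_case >= mean_control,
         mean_case / mean_control,
         -(mean_control / mean_case))
}
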