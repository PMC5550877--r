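#' Relative expression by the 2^-ddCt method
#'
#' Per group, `dCt = mean(ct_target) - mean(ct_reference)` (mean-of-Ct
#' convention); `ddCt = dCt_treatment - dCt_control`; fold change
#' `2^-ddCt`. Amplification efficiency is fixed at 2, as the method's name
#' implies.
#'
#' @param treatment,control Data frames (or lists) with numeric columns
#'   `ct_target` and `ct_reference`, one row per replicate; at least one
#'   replicate each. A warning is raised for Ct values outside (0, 45).
#' @return List of class `relative_expression` with `delta_ct_treatment`,
#'   `delta_ct_control`, `delta_delta_ct`, `fold_change`.
#' @examples
#' trt <- data.frame(ct_target = c(20, 20.4), ct_reference = c(18, 18.2))
#' ctl <- data.frame(ct_target = c(24, 24.2), ct_reference = c(18.1, 18.0))
#' ddct_fold_change(trt, ctl)$fold_change
#' @export
ddct_fold_change <- function(treatment, control) {
  dct <- function(g, what) {
    if (is.null(g$ct_target) || is.null(g$ct_reference) ||
        length(g$ct_target) == 0)
      stop_input("empty or malformed ", what, " group: need ct_target and ct_reference")
    ct <- c(g$ct_target, g$ct_reference)
    if (anyNA(ct) || any(!is.finite(ct)))
      stop_input("non-finite Ct values in ", what, " group")
    if (any(ct <= 0 | ct >= 45))
      warning("Ct values outside the usual (0, 45) range in ", what, " group")
    mean(g$ct_target) - mean(g$ct_reference)
  }
  d_trt <- dct(treatment, "treatment")
  d_ctl <- dct(control, "control")
  ddct <- d_trt - d_ctl
  structure(list(delta_ct_treatment = d_trt, delta_ct_control = d_ctl,
                 delta_delta_ct = ddct, fold_change = 2^(-ddct)),
            class = "relative_expression")
}

#' @export
print.relative_expression <- function(x, ...) {
  cat(sprintf("ddCt = %.4g - %.4g = %.4g;  fold change 2^-ddCt = %.4g\n",
              x$delta_ct_treatment, x$delta_ct_control, x$delta_delta_ct,
              x$fold_change))
  invisible(x)
}

#' Dual-luciferase relative activity
#'
#' Firefly luminescence divided by Renilla luminescence, normalized to a
#' reference reading: `(sample$firefly / sample$renilla) /
#' (reference$firefly / reference$renilla)`.
#'
#' @param sample,reference Lists (or single-row data frames) with positive
#'   numeric `firefly` and `renilla` fields.
#' @return Positive scalar relative activity.
#' @examples
#' luciferase_relative_activity(list(firefly = 50, renilla = 100),
#'                              list(firefly = 120, renilla = 120))
#' @export
luciferase_relative_activity <- function(sample, reference) {
  ratio <- function(x, what) {
    if (is.null(x$firefly) || is.null(x$renilla))
      stop_input(what, " reading needs firefly and renilla fields")
    if (!is.finite(x$renilla) || x$renilla <= 0)
      stop_input(what, " Renilla luminescence must be positive")
    if (!is.finite(x$firefly) || x$firefly <= 0)
      stop_input(what, " firefly luminescence must be positive")
    x$firefly / x$renilla
  }
  ratio(sample, "sample") / ratio(reference, "reference")
}
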