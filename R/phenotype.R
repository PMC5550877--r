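#' Percentage of a count with half-away-from-zero rounding
#'
#' `100 * count / total`, rounded half away from zero to `decimals` places —
#' the convention that reproduces printed figures such as 27.8 from 15/54
#' (base R's `round()` rounds half to even instead).
#'
#' @param count Nonnegative count, at most `total`.
#' @param total Positive total.
#' @param decimals Number of decimal places (default 1).
#' @return Rounded percentage.
#' @examples
#' percent(15, 54)   # 27.8
#' percent(40, 82)   # 48.8
#' @export
percent <- function(count, total, decimals = 1L) {
  if (length(total) != 1 || !is.finite(total) || total <= 0)
    stop_input("total must be a positive number")
  if (any(!is.finite(count)) || any(count < 0) || any(count > total))
    stop_input("count must satisfy 0 <= count <= total")
  round_half_away(100 * count / total, decimals)
}

round_half_away <- function(x, decimals = 0L) {
  s <- 10^decimals
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Germ-layer percentages from slice scores
#'
#' Sums each layer's scores across specimens and divides by the total number
#' of slices scored, times 100. Layers need not sum to 100 when slices carry
#' no layer call (or carry several).
#'
#' @param scores Data frame with columns `specimen`, `layer`, `score`
#'   (long format; one row per specimen-layer combination, missing
#'   combinations count as 0).
#' @param slices_per_specimen Number of slices scored per specimen.
#' @return Named numeric vector of percentages, one entry per layer present
#'   in `scores`, sorted by layer name.
#' @examples
#' sc <- data.frame(specimen = "t1", layer = "ectoderm", score = 5)
#' layer_percentages(sc, slices_per_specimen = 10)  # ectoderm 50
#' @export
layer_percentages <- function(scores, slices_per_specimen) {
  if (!all(c("specimen", "layer", "score") %in% names(scores)))
    stop_input("'scores' needs columns specimen, layer, score")
  if (nrow(scores) == 0 || length(unique(scores$specimen)) == 0)
    stop_input("need at least one specimen")
  if (length(slices_per_specimen) != 1 || slices_per_specimen <= 0)
    stop_input("slices_per_specimen must be positive")
  if (any(scores$score < 0)) stop_input("scores must be >= 0")
  total_slices <- slices_per_specimen * length(unique(scores$specimen))
  sums <- tapply(scores$score, scores$layer, sum)
  out <- 100 * as.numeric(sums) / total_slices
  stats::setNames(out, names(sums))[sort(names(sums))]
}

#' Compare two outcome proportions (2x2 Fisher test + odds ratio)
#'
#' Cross-tabulates `count_a / total_a` against `count_b / total_b`, computes
#' the odds ratio (with a Haldane 0.5 continuity correction when any cell is
#' zero) and the two-sided Fisher exact p-value (summing hypergeometric
#' outcomes no more probable than the observed table).
#'
#' @param count_a,total_a Successes and total in group a.
#' @param count_b,total_b Successes and total in group b.
#' @return List with `odds_ratio`, `p_value` and the 2x2 `table`.
#' @examples
#' compare_proportions(15, 54, 19, 82)
#' @export
compare_proportions <- function(count_a, total_a, count_b, total_b) {
  vals <- c(count_a, total_a, count_b, total_b)
  if (any(!is.finite(vals)) || any(vals < 0) ||
      count_a > total_a || count_b > total_b)
    stop_input("need 0 <= count <= total in both groups")
  tab <- matrix(c(count_a, total_a - count_a,
                  count_b, total_b - count_b), nrow = 2, byrow = TRUE,
                dimnames = list(group = c("a", "b"),
                                outcome = c("yes", "no")))
  if (any(rowSums(tab) == 0) || all(tab[, 1] == 0) || all(tab[, 2] == 0))
    stop_stats("degenerate 2x2 table: an all-zero margin")
  ct <- tab + if (any(tab == 0)) 0.5 else 0
  or <- (ct[1, 1] * ct[2, 2]) / (ct[1, 2] * ct[2, 1])
  # two-sided Fisher: fixed margins, sum P(tables at most as probable)
  n1 <- sum(tab[1, ]); n2 <- sum(tab[2, ]); s <- sum(tab[, 1])
  k_range <- max(0, s - n2):min(n1, s)
  probs <- stats::dhyper(k_range, n1, n2, s)
  p_obs <- stats::dhyper(tab[1, 1], n1, n2, s)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  list(odds_ratio = or, p_value = p, table = tab)
}
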