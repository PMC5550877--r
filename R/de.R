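#' Two-group differential expression (fold change + Welch's t)
#'
#' Reproduces the "differentially expressed (P < alpha) by two-fold" filter:
#' per gene, the log2 fold change is computed on linear-scale group means
#' with a pseudocount, significance comes from Welch's two-sample t-test on
#' `log2(value + pseudocount)`, and Benjamini-Hochberg q-values are reported
#' alongside. A gene is called `up` when `log2fc >= log2(fold)` and
#' `p_value < alpha`, `down` when `log2fc <= -log2(fold)` and
#' `p_value < alpha`, else `not_significant`. The two-fold default is
#' inclusive (`|log2fc| >= 1`).
#'
#' @param em An [expr_matrix()] of nonnegative linear-scale values.
#' @param control_label,perturbed_label Condition labels, each with at least
#'   two samples.
#' @param pseudocount Positive offset added before ratios and logs. Default
#'   `1e-6` times the global mean expression (scale-aware zero protection).
#' @param alpha Raw p-value threshold for calling status (default 0.05, as
#'   in the two-fold/P<0.05 rule).
#' @param fold Linear fold-change threshold for calling status (default 2).
#' @return `data.frame` with columns `gene_id`, `log2fc`, `p_value`,
#'   `q_value`, `status`, one row per gene in matrix order.
#' @examples
#' sim <- simulate_expression(sim_config(n_genes = 60, n_modules = 0,
#'                                       n_hub_genes = 0, seed = 3))
#' de <- compute_de(combine_expr(sim$control, sim$perturbed),
#'                  "control", "perturbed")
#' table(de$status)
#' @export
compute_de <- function(em, control_label, perturbed_label,
                       pseudocount = NULL, alpha = 0.05, fold = 2) {
  stopifnot(inherits(em, "expr_matrix"))
  if (!is.null(alpha) && (alpha < 0 || alpha > 1))
    stop_input("alpha must be in [0,1]")
  if (fold <= 0) stop_input("fold must be positive")
  sc <- samples_for(em, control_label)
  sp <- samples_for(em, perturbed_label)
  if (length(sc) < 2 || length(sp) < 2)
    stop_stats("each group needs at least 2 samples (control ", length(sc),
               ", perturbed ", length(sp), ")")
  if (is.null(pseudocount)) pseudocount <- 1e-6 * mean(em$values)
  if (length(pseudocount) != 1 || pseudocount < 0)
    stop_input("pseudocount must be a single nonnegative number")

  xc <- em$values[, sc, drop = FALSE]
  xp <- em$values[, sp, drop = FALSE]
  log2fc <- log2((rowMeans(xp) + pseudocount) / (rowMeans(xc) + pseudocount))

  w <- welch_t_rows(log2(xp + pseudocount), log2(xc + pseudocount))
  q <- bh_fdr(w$p)
  lfc_thr <- log2(fold)
  status <- rep("not_significant", nrow(em$values))
  status[log2fc >= lfc_thr & w$p < alpha] <- "up"
  status[log2fc <= -lfc_thr & w$p < alpha] <- "down"
  data.frame(gene_id = genes_of(em), log2fc = log2fc, p_value = w$p,
             q_value = q, status = status, row.names = NULL,
             stringsAsFactors = FALSE)
}

# Vectorized Welch two-sample t-test by row: x, y matrices (rows = genes).
# Degenerate rows (both group variances zero) get t = 0, p = 1 when means
# agree and p = 0 when they differ.
welch_t_rows <- function(x, y) {
  nx <- ncol(x); ny <- ncol(y)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (nx - 1)
  vy <- rowSums((y - my)^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  tstat <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  zero <- se2 == 0
  if (any(zero)) {
    same <- zero & (mx == my)
    tstat[same] <- 0; p[same] <- 1
    tstat[zero & !same] <- sign(mx - my)[zero & !same] * Inf
    p[zero & !same] <- 0
  }
  list(t = tstat, df = df, p = p)
}

#' Select identifiers by fold-change threshold
#'
#' Generic fold filter, e.g. "more than a five-fold change" on a table of
#' linear fold changes. Input order is preserved.
#'
#' @param fold_changes Named numeric vector of positive linear fold changes.
#' @param threshold Positive threshold.
#' @param strict If `TRUE` (default) keep `fold > threshold`; otherwise
#'   `fold >= threshold`.
#' @return List of class `fold_filter` with `selected_ids`, `threshold`,
#'   `strict`.
#' @examples
#' filter_by_fold(c(a = 6, b = 5, c = 4.9), 5)$selected_ids
#' @export
filter_by_fold <- function(fold_changes, threshold, strict = TRUE) {
  if (length(fold_changes) && is.null(names(fold_changes)))
    stop_input("fold_changes must be named")
  if (anyNA(fold_changes) || any(fold_changes <= 0))
    stop_input("fold changes must be positive and non-missing")
  if (threshold <= 0) stop_input("threshold must be positive")
  keep <- if (strict) fold_changes > threshold else fold_changes >= threshold
  structure(list(selected_ids = names(fold_changes)[keep],
                 threshold = threshold, strict = strict),
            class = "fold_filter")
}
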