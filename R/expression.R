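#' Expression matrix with sample condition labels
#'
#' Lightweight container for a genes-by-samples matrix of nonnegative,
#' normalized expression values (linear scale) plus a condition label per
#' sample. This is the substrate of the differential-expression and network
#' stages.
#'
#' @param values Numeric matrix, genes in rows (unique rownames), samples in
#'   columns (unique colnames). All values must be finite and `>= 0`.
#' @param conditions Character vector of condition labels, either named by
#'   sample id or in column order.
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   (the matrix) and `conditions` (named character vector, one label per
#'   sample).
#' @examples
#' m <- matrix(1:6, nrow = 2, dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' em <- expr_matrix(m, c(s1 = "control", s2 = "control", s3 = "treated"))
#' samples_for(em, "control")
#' @export
expr_matrix <- function(values, conditions) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_input("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_input("'values' must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop_input("duplicate gene ids in expression matrix")
  if (anyDuplicated(colnames(values)))
    stop_input("duplicate sample ids in expression matrix")
  if (anyNA(values) || any(!is.finite(values)))
    stop_input("expression values must be finite and non-missing")
  if (any(values < 0))
    stop_input("expression values must be nonnegative")
  conditions <- as.character(conditions) |> stats::setNames(
    if (is.null(names(conditions))) colnames(values) else names(conditions))
  if (length(conditions) != ncol(values))
    stop_input("need exactly one condition label per sample")
  if (!setequal(names(conditions), colnames(values)))
    stop_input("condition labels do not match sample ids")
  conditions <- conditions[colnames(values)]
  structure(list(values = values, conditions = conditions),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  tab <- table(x$conditions)
  cat("conditions:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Sample ids carrying a given condition label
#'
#' @param em An [expr_matrix()].
#' @param condition Condition label to look up.
#' @return Character vector of sample ids.
#' @export
samples_for <- function(em, condition) {
  stopifnot(inherits(em, "expr_matrix"))
  ids <- names(em$conditions)[em$conditions == condition]
  if (length(ids) == 0)
    stop_input("condition label not present in matrix: ", condition)
  ids
}

#' Genes of an expression matrix
#' @param em An [expr_matrix()].
#' @return Character vector of gene ids in matrix order.
#' @export
genes_of <- function(em) rownames(em$values)

# Combine matrices that share a gene universe (used to assemble a control
# condition with several perturbations into one object).
combine_expr <- function(...) {
  ems <- list(...)
  genes <- genes_of(ems[[1]])
  for (em in ems[-1]) {
    if (!identical(genes_of(em), genes))
      stop_input("expression matrices must share identical gene ids")
  }
  expr_matrix(do.call(cbind, lapply(ems, function(e) e$values)),
              do.call(c, lapply(ems, function(e) e$conditions)))
}
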