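#' Gene-set annotation map
#'
#' Container for term -> gene-set annotations over a gene universe, the input
#' of Fisher's exact enrichment.
#'
#' @param sets Named list of character vectors (term id -> gene ids). Every
#'   annotated gene must belong to `universe`; empty terms are not allowed.
#' @param universe Character vector, the gene universe (defaults to the union
#'   of all term genes).
#' @param term_names Optional named character vector of human-readable term
#'   names (defaults to the term ids).
#' @return Object of class `annotation_map`.
#' @export
annotation_map <- function(sets, universe = NULL, term_names = NULL) {
  if (length(sets) && is.null(names(sets))) stop_input("'sets' must be named by term id")
  if (anyDuplicated(names(sets))) stop_input("duplicate term ids")
  sets <- lapply(sets, function(g) sort(unique(as.character(g))))
  if (any(lengths(sets) == 0)) stop_input("term gene sets must be non-empty")
  if (is.null(universe)) universe <- sort(unique(unlist(sets)))
  universe <- sort(unique(as.character(universe)))
  stray <- setdiff(unlist(sets), universe)
  if (length(stray))
    stop_input("annotated genes outside universe: ",
               paste(utils::head(stray, 5), collapse = ", "))
  if (is.null(term_names))
    term_names <- stats::setNames(names(sets), names(sets))
  structure(list(sets = sets, universe = universe,
                 term_names = term_names[names(sets)]),
            class = "annotation_map")
}

#' @export
print.annotation_map <- function(x, ...) {
  cat(sprintf("annotation_map: %d terms over %d genes (term sizes %s)\n",
              length(x$sets), length(x$universe),
              if (length(x$sets)) paste(range(lengths(x$sets)), collapse = "-")
              else "-"))
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: on the sorted p-values,
#' `q_(i) = min_(j >= i) m * p_(j) / j`, clipped to `[0, 1]`, returned in the
#' original input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of adjusted values, same length and order.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_fdr <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop_input("p-values must lie in [0,1]")
  m <- length(p_values)
  if (m == 0) return(numeric())
  o <- order(p_values)
  q_sorted <- pmin(1, rev(cummin(rev(m * p_values[o] / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

#' Fisher's exact term enrichment
#'
#' One-sided (over-representation) Fisher's exact test per annotation term on
#' the 2x2 table of differentially expressed genes versus term membership
#' within the universe, with Benjamini-Hochberg q-values over all terms.
#'
#' @param de_genes Character vector of selected (e.g. differentially
#'   expressed) gene ids; must lie inside the annotation universe.
#' @param annotations An [annotation_map()].
#' @return `data.frame` sorted by p-value (ties broken by term id) with
#'   columns `term_id`, `term_name`, `k` (selected genes in term), `K` (term
#'   size in universe), `n` (selected genes in universe), `N` (universe
#'   size), `p_value`, `q_value`.
#' @examples
#' ann <- annotation_map(list(t1 = c("a", "b"), t2 = c("c", "d")),
#'                       universe = letters[1:10])
#' fisher_enrichment(c("a", "b", "c"), ann)
#' @export
fisher_enrichment <- function(de_genes, annotations) {
  if (!inherits(annotations, "annotation_map"))
    stop_input("'annotations' must be an annotation_map")
  de_genes <- unique(as.character(de_genes))
  stray <- setdiff(de_genes, annotations$universe)
  if (length(stray))
    stop_input("selected genes outside universe: ",
               paste(utils::head(stray, 10), collapse = ", "))
  if (length(annotations$universe) == 0) stop_input("empty universe")
  N <- length(annotations$universe)
  n <- length(de_genes)
  K <- lengths(annotations$sets)
  k <- vapply(annotations$sets, function(g) sum(de_genes %in% g), 1L)
  p <- fisher_p_greater(k, K, n, N)
  res <- data.frame(term_id = names(annotations$sets),
                    term_name = unname(annotations$term_names),
                    k = as.integer(k), K = as.integer(K),
                    n = n, N = N,
                    p_value = p, q_value = bh_fdr(p),
                    row.names = NULL, stringsAsFactors = FALSE)
  res[order(res$p_value, res$term_id), , drop = FALSE] |>
    `rownames<-`(NULL)
}

# One-sided (enrichment direction) Fisher exact p: upper hypergeometric
# tail P(X >= k) for X ~ Hypergeom(N, K, n). Vectorized over table cells.
fisher_p_greater <- function(k, K, n, N) {
  stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
}

#' Candidate genes from focus terms, with cross-perturbation overlap
#'
#' For each perturbation, candidates are the union over the focus terms of
#' (term genes intersected with that perturbation's differentially expressed
#' set); the overlap is their intersection across perturbations. This is the
#' "genes located in the overlapping biological processes" selection step.
#'
#' @param de_sets Named list (one element per perturbation) of character
#'   vectors of differentially expressed gene ids.
#' @param focus_terms Character vector of term ids (must exist in
#'   `annotations`).
#' @param annotations An [annotation_map()].
#' @return List of class `candidate_selection` with `candidates` (named list
#'   of sorted per-perturbation gene vectors), `focus_terms` and `overlap`
#'   (sorted intersection).
#' @export
select_focus_candidates <- function(de_sets, focus_terms, annotations) {
  if (!inherits(annotations, "annotation_map"))
    stop_input("'annotations' must be an annotation_map")
  if (length(de_sets) == 0 || is.null(names(de_sets)))
    stop_input("'de_sets' must be a non-empty named list")
  unknown <- setdiff(focus_terms, names(annotations$sets))
  if (length(unknown))
    stop_input("unknown focus terms: ", paste(unknown, collapse = ", "))
  focus_genes <- sort(unique(unlist(annotations$sets[focus_terms])))
  candidates <- lapply(de_sets, function(de) sort(intersect(focus_genes, de)))
  overlap <- sort(Reduce(intersect, candidates))
  structure(list(candidates = candidates,
                 focus_terms = as.character(focus_terms),
                 overlap = overlap),
            class = "candidate_selection")
}

#' @export
print.candidate_selection <- function(x, ...) {
  cat(sprintf("candidate_selection: %d focus terms; candidates %s; overlap %d\n",
              length(x$focus_terms),
              paste(sprintf("%s=%d", names(x$candidates),
                            lengths(x$candidates)), collapse = ", "),
              length(x$overlap)))
  invisible(x)
}
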