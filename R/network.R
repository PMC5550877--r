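#' Condition-specific Pearson co-expression network
#'
#' Computes all pairwise Pearson correlations among the requested genes over
#' the samples of one condition, converts them to two-sided p-values with the
#' t-transform `t = r * sqrt((n-2) / (1-r^2))` on `n-2` degrees of freedom
#' (`|r| = 1` maps to `p = 0`), applies Benjamini-Hochberg across all tested
#' pairs within the network, and keeps edges with `q < edge_fdr_alpha`.
#' Zero-variance genes are isolated (a warning is raised, no edges are
#' tested for them).
#'
#' @param em An [expr_matrix()].
#' @param condition_label Condition whose samples are used (at least 4).
#' @param genes Gene subset to connect (default: all genes; at least 2).
#' @param edge_fdr_alpha Edge FDR threshold (default 0.05).
#' @param log2_transform Correlate `log2(value + pseudocount)` instead of
#'   raw values (default `TRUE`): expression is roughly lognormal and
#'   Pearson correlation on the linear scale is dominated by heavy-tail
#'   outlier samples. Set to `FALSE` to correlate values as given.
#' @param pseudocount Offset for the log transform; default `1e-6` times
#'   the mean of the used submatrix.
#' @return Object of class `coexpression_network`: list with `condition`,
#'   `nodes` (all requested genes, sorted), `edges` (`data.frame` with
#'   `gene_a < gene_b`, `r`, `p_value`, `q_value`, `sign`), `n_samples`,
#'   `edge_fdr_alpha`.
#' @examples
#' sim <- simulate_expression(sim_config(n_genes = 40, n_modules = 2,
#'                                       module_size = 5, n_hub_genes = 0,
#'                                       seed = 11))
#' net <- build_network(sim$control, "control")
#' nrow(net$edges)
#' @export
build_network <- function(em, condition_label, genes = NULL,
                          edge_fdr_alpha = 0.05, log2_transform = TRUE,
                          pseudocount = NULL) {
  stopifnot(inherits(em, "expr_matrix"))
  if (edge_fdr_alpha <= 0 || edge_fdr_alpha > 1)
    stop_input("edge_fdr_alpha must be in (0,1]")
  if (is.null(genes)) genes <- genes_of(em)
  genes <- unique(as.character(genes))
  missing <- setdiff(genes, genes_of(em))
  if (length(missing))
    stop_input("genes absent from matrix: ",
               paste(utils::head(missing, 10), collapse = ", "))
  if (length(genes) < 2) stop_input("need at least 2 genes")
  samples <- samples_for(em, condition_label)
  n <- length(samples)
  if (n < 4) stop_stats("need at least 4 samples for correlation networks, got ", n)

  x <- t(em$values[genes, samples, drop = FALSE])
  if (log2_transform) {
    if (is.null(pseudocount)) pseudocount <- 1e-6 * mean(x)
    if (pseudocount < 0 || (pseudocount == 0 && any(x == 0)))
      stop_input("pseudocount must be positive when zeros are present")
    x <- log2(x + pseudocount)
  }
  sds <- apply(x, 2, stats::sd)
  ok <- sds > 0
  if (any(!ok))
    warning(sum(!ok), " zero-variance gene(s) isolated: ",
            paste(utils::head(genes[!ok], 5), collapse = ", "))
  nodes <- sort(genes)
  edges <- data.frame(gene_a = character(), gene_b = character(),
                      r = numeric(), p_value = numeric(), q_value = numeric(),
                      sign = character(), stringsAsFactors = FALSE)
  if (sum(ok) >= 2) {
    cm <- stats::cor(x[, ok, drop = FALSE])
    ut <- upper.tri(cm)
    r <- cm[ut]
    ij <- which(ut, arr.ind = TRUE)
    g1 <- colnames(cm)[ij[, 1]]
    g2 <- colnames(cm)[ij[, 2]]
    r <- pmin(1, pmax(-1, r))
    p <- ifelse(abs(r) >= 1, 0,
                2 * stats::pt(-abs(r) * sqrt((n - 2) / (1 - r^2)), n - 2))
    q <- bh_fdr(p)
    keep <- q < edge_fdr_alpha
    if (any(keep)) {
      edges <- data.frame(gene_a = pmin(g1, g2)[keep],
                          gene_b = pmax(g1, g2)[keep],
                          r = r[keep], p_value = p[keep], q_value = q[keep],
                          sign = ifelse(r[keep] >= 0, "positive", "negative"),
                          stringsAsFactors = FALSE)
      edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
      rownames(edges) <- NULL
    }
  }
  structure(list(condition = condition_label, nodes = nodes, edges = edges,
                 n_samples = n, edge_fdr_alpha = edge_fdr_alpha),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf("coexpression_network '%s': %d nodes, %d edges (FDR<%g, n=%d)\n",
              x$condition, length(x$nodes), nrow(x$edges),
              x$edge_fdr_alpha, x$n_samples))
  invisible(x)
}

#' Degree centrality
#'
#' Number of edges incident to each node ("the link numbers one node has to
#' the other"); isolated nodes are reported with degree 0.
#'
#' @param network A `coexpression_network` (or any list with `nodes` and an
#'   `edges` data frame).
#' @return Named integer vector over all nodes.
#' @export
degree_centrality <- function(network) {
  nodes <- network$nodes
  deg <- stats::setNames(integer(length(nodes)), nodes)
  if (nrow(network$edges)) {
    tab <- table(c(network$edges$gene_a, network$edges$gene_b))
    deg[names(tab)] <- as.integer(tab)
  }
  deg
}

#' K-core decomposition
#'
#' Iterative peeling: nodes of degree below K are removed for increasing K;
#' a node's core number is the largest K at which it survives, i.e. the
#' largest K such that it belongs to a subgraph where every node is
#' connected to at least K others.
#'
#' @param network A `coexpression_network`.
#' @return Named integer vector of core numbers over all nodes.
#' @export
k_core_decomposition <- function(network) {
  nodes <- network$nodes
  deg <- degree_centrality(network)
  core <- stats::setNames(integer(length(nodes)), nodes)
  active <- stats::setNames(rep(TRUE, length(nodes)), nodes)
  edges <- network$edges
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  if (nrow(edges)) {
    adj_a <- split(edges$gene_b, edges$gene_a)
    adj_b <- split(edges$gene_a, edges$gene_b)
    for (g in names(adj_a)) adj[[g]] <- c(adj[[g]], adj_a[[g]])
    for (g in names(adj_b)) adj[[g]] <- c(adj[[g]], adj_b[[g]])
  }
  k <- 0L
  while (any(active)) {
    repeat {
      peel <- names(which(active & deg <= k))
      if (length(peel) == 0) break
      for (g in peel) {
        core[g] <- k
        active[g] <- FALSE
        nb <- adj[[g]]
        nb <- nb[active[nb]]
        deg[nb] <- deg[nb] - 1L
      }
    }
    k <- k + 1L
  }
  core
}

#' Differential degree (Dif degree) table
#'
#' Per-gene network degrees in the control and perturbed networks and their
#' difference. The union of node sets is taken; a gene missing from one
#' network counts as degree 0 there. `dif_degree` is the absolute
#' difference (connectivity gains and losses both flag regulators); the
#' signed value `control - perturbed` is reported alongside.
#'
#' @param control_net,perturbed_net `coexpression_network` objects.
#' @return `data.frame` with columns `gene_id`, `degree_control`,
#'   `degree_perturbed`, `signed_dif`, `dif_degree`, sorted by gene id.
#' @export
dif_degree <- function(control_net, perturbed_net) {
  dc <- degree_centrality(control_net)
  dp <- degree_centrality(perturbed_net)
  genes <- sort(union(names(dc), names(dp)))
  degc <- ifelse(genes %in% names(dc), dc[genes], 0L)
  degp <- ifelse(genes %in% names(dp), dp[genes], 0L)
  data.frame(gene_id = genes,
             degree_control = as.integer(degc),
             degree_perturbed = as.integer(degp),
             signed_dif = as.integer(degc - degp),
             dif_degree = as.integer(abs(degc - degp)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Hub selection by differential degree, with cross-perturbation intersection
#'
#' Selects, per perturbation, the genes whose `dif_degree` strictly exceeds
#' the threshold ("a difference degree of more than eight"), and intersects
#' the selections across perturbations to nominate core regulators.
#'
#' @param tables Named list of [dif_degree()] tables (one per perturbation),
#'   or a single table.
#' @param threshold Nonnegative integer threshold (default 8; strict `>`).
#' @return Object of class `hub_selection`: list with `threshold`,
#'   `selected` (named list of sorted gene vectors) and `core_regulators`
#'   (sorted intersection).
#' @examples
#' t1 <- data.frame(gene_id = c("Olig1", "Gnao1"), dif_degree = c(12, 3))
#' t2 <- data.frame(gene_id = c("Olig1", "Zic5"), dif_degree = c(10, 9))
#' select_hubs(list(a = t1, b = t2))$core_regulators
#' @export
select_hubs <- function(tables, threshold = 8L) {
  if (is.data.frame(tables)) tables <- list(perturbation = tables)
  if (length(tables) == 0) stop_input("need at least one dif-degree table")
  if (is.null(names(tables)) || anyDuplicated(names(tables)))
    stop_input("'tables' must have unique names")
  if (threshold < 0) stop_input("threshold must be >= 0")
  selected <- lapply(tables, function(tb) {
    if (!all(c("gene_id", "dif_degree") %in% names(tb)))
      stop_input("tables need columns gene_id and dif_degree")
    sort(tb$gene_id[tb$dif_degree > threshold])
  })
  structure(list(threshold = as.integer(threshold), selected = selected,
                 core_regulators = sort(Reduce(intersect, selected))),
            class = "hub_selection")
}

#' @export
print.hub_selection <- function(x, ...) {
  cat(sprintf("hub_selection (dif degree > %d):\n", x$threshold))
  for (nm in names(x$selected))
    cat(sprintf("  %s: %s\n", nm, paste(x$selected[[nm]], collapse = ", ")))
  cat("  core regulators:", paste(x$core_regulators, collapse = ", "), "\n")
  invisible(x)
}
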