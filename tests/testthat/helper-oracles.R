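# Independent oracles and small fixture builders shared across tests.

# Exhaustive hypergeometric enumeration: one-sided (enrichment) Fisher p for
# the 2x2 table with margins (N, K, n) and overlap k, summing point
# probabilities of all tables with overlap >= k. Deliberately built from
# dhyper point masses, independent of the phyper tail call used by the
# implementation.
enum_fisher_greater <- function(k, K, n, N) {
  k_range <- max(0L, n + K - N):min(K, n)
  probs <- stats::dhyper(k_range, K, N - K, n)
  sum(probs[k_range >= k])
}

# Exhaustive two-sided Fisher p: sum of tables no more probable than observed.
enum_fisher_twosided <- function(k, K, n, N) {
  k_range <- max(0L, n + K - N):min(K, n)
  probs <- stats::dhyper(k_range, K, N - K, n)
  p_obs <- stats::dhyper(k, K, N - K, n)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Brute-force core numbers: a node's core number is the largest K such that
# some induced subgraph containing it has minimum degree >= K. Checks all
# 2^n induced subgraphs; usable for graphs with <= 12 nodes.
brute_force_cores <- function(nodes, edges) {
  n <- length(nodes)
  core <- stats::setNames(integer(n), nodes)
  if (n == 0) return(core)
  for (mask in seq_len(2^n - 1)) {
    members <- nodes[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    if (length(members) == 0) next
    sub <- edges[edges$gene_a %in% members & edges$gene_b %in% members, ,
                 drop = FALSE]
    deg <- stats::setNames(integer(length(members)), members)
    if (nrow(sub)) {
      tab <- table(c(sub$gene_a, sub$gene_b))
      deg[names(tab)] <- as.integer(tab)
    }
    mindeg <- min(deg)
    sel <- members[core[members] < mindeg]
    core[sel] <- mindeg
  }
  core
}

# Random undirected graph as a coexpression_network skeleton (for k-core and
# degree tests; correlation fields are dummies).
random_network <- function(n_nodes, p_edge, seed) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  pairs <- t(combn(nodes, 2))
  keep <- stats::runif(nrow(pairs)) < p_edge
  pairs <- pairs[keep, , drop = FALSE]
  edges <- data.frame(gene_a = pairs[, 1], gene_b = pairs[, 2],
                      r = rep(0.9, nrow(pairs)), p_value = rep(0, nrow(pairs)),
                      q_value = rep(0, nrow(pairs)),
                      sign = rep("positive", nrow(pairs)),
                      stringsAsFactors = FALSE)
  structure(list(condition = "synthetic", nodes = nodes, edges = edges,
                 n_samples = 10L, edge_fdr_alpha = 0.05),
            class = "coexpression_network")
}

# Tiny expression fixture: genes x samples from explicit vectors.
make_expr <- function(..., conditions) {
  rows <- list(...)
  vals <- do.call(rbind, rows)
  rownames(vals) <- names(rows)
  colnames(vals) <- names(conditions)
  expr_matrix(vals, conditions)
}

two_group_conditions <- function(n_ctrl, n_pert) {
  stats::setNames(rep(c("control", "perturbed"), c(n_ctrl, n_pert)),
                  sprintf("s%02d", seq_len(n_ctrl + n_pert)))
}
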