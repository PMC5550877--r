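test_that("pairwise correlation and p-values match a long-form oracle", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 4, 5, 4, 5)
  em <- make_expr(gx = x, gy = y,
                  conditions = stats::setNames(rep("c", 5), sprintf("s%d", 1:5)))
  net <- build_network(em, "c", edge_fdr_alpha = 1, log2_transform = FALSE)
  # textbook r = cov / (sd_x sd_y), computed long-form
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_hand <- r_hand * sqrt((5 - 2) / (1 - r_hand^2))
  p_hand <- 2 * stats::pt(-abs(t_hand), 3)
  expect_identical(nrow(net$edges), 1L)
  expect_equal(net$edges$r, r_hand, tolerance = 1e-12)
  expect_equal(net$edges$p_value, p_hand, tolerance = 1e-12)
  expect_equal(net$edges$p_value,
               stats::cor.test(x, y)$p.value, tolerance = 1e-10)

  # perfect correlation: p = 0 by convention, edge kept, positive sign
  em2 <- make_expr(g1 = 1:5, g2 = 1:5 * 3,
                   conditions = stats::setNames(rep("c", 5), sprintf("s%d", 1:5)))
  net2 <- build_network(em2, "c", log2_transform = FALSE)
  expect_identical(nrow(net2$edges), 1L)
  expect_equal(net2$edges$r, 1)
  expect_equal(net2$edges$p_value, 0)
  expect_identical(net2$edges$sign, "positive")

  # exactly orthogonal deviations: r = 0, p = 1, no edge at any usual alpha
  em3 <- make_expr(g1 = c(1, 2, 1, 2), g2 = c(1, 1, 2, 2),
                   conditions = stats::setNames(rep("c", 4), sprintf("s%d", 1:4)))
  net3 <- build_network(em3, "c", log2_transform = FALSE)
  expect_identical(nrow(net3$edges), 0L)
})

test_that("build_network validates inputs and isolates flat genes", {
  em <- make_expr(g1 = c(1, 2, 3, 4), g2 = c(2, 4, 6, 8), g3 = rep(7, 4),
                  conditions = stats::setNames(rep("c", 4), sprintf("s%d", 1:4)))
  expect_warning(net <- build_network(em, "c"), "zero-variance")
  expect_true("g3" %in% net$nodes)
  expect_false("g3" %in% c(net$edges$gene_a, net$edges$gene_b))

  em_small <- make_expr(g1 = 1:3, g2 = 3:1,
                        conditions = stats::setNames(rep("c", 3),
                                                     sprintf("s%d", 1:3)))
  expect_error(build_network(em_small, "c"), class = "coexhub_stats_error")
  expect_error(build_network(em, "c", genes = "g9"),
               class = "coexhub_input_error")
  expect_error(build_network(em, "c", genes = "g1"),
               class = "coexhub_input_error")
})

test_that("edge FDR is controlled on null matrices", {
  # scaled-down version of the null-edge property (full scale in acceptance)
  set.seed(77)
  fdp <- numeric(20)
  for (r in seq_len(20)) {
    vals <- matrix(2^stats::rnorm(40 * 20, 6), nrow = 40,
                   dimnames = list(sprintf("g%02d", 1:40),
                                   sprintf("s%02d", 1:20)))
    em <- expr_matrix(vals, stats::setNames(rep("c", 20), colnames(vals)))
    net <- build_network(em, "c")
    fdp[r] <- nrow(net$edges) / choose(40, 2)
  }
  expect_lte(mean(fdp), 0.05 + 3 * stats::sd(fdp) / sqrt(20) + 1e-3)
})

test_that("degree centrality counts incident edges", {
  tri <- random_network(3, 1, seed = 1)  # complete K3
  expect_identical(unname(degree_centrality(tri)), rep(2L, 3))
  empty <- random_network(5, 0, seed = 1)
  expect_identical(unname(degree_centrality(empty)), rep(0L, 5))
  # handshake identity on random graphs
  for (s in 1:5) {
    g <- random_network(12, 0.4, seed = s)
    expect_identical(sum(degree_centrality(g)), 2L * nrow(g$edges))
  }
})

test_that("k-core decomposition matches brute-force subgraph checking", {
  # triangle plus pendant: triangle nodes core 2, pendant core 1
  nodes <- c("a", "b", "c", "d")
  edges <- data.frame(gene_a = c("a", "a", "b", "c"),
                      gene_b = c("b", "c", "c", "d"),
                      r = 1, p_value = 0, q_value = 0, sign = "positive",
                      stringsAsFactors = FALSE)
  net <- structure(list(condition = "x", nodes = nodes, edges = edges,
                        n_samples = 5L, edge_fdr_alpha = 0.05),
                   class = "coexpression_network")
  expect_identical(k_core_decomposition(net),
                   c(a = 2L, b = 2L, c = 2L, d = 1L))

  # edgeless graph and clique
  expect_identical(unname(k_core_decomposition(random_network(4, 0, seed = 2))),
                   rep(0L, 4))
  expect_identical(unname(k_core_decomposition(random_network(6, 1, seed = 2))),
                   rep(5L, 6))

  # oracle equivalence on 100 random graphs with <= 8 nodes
  set.seed(3)
  for (i in 1:100) {
    n <- sample(2:8, 1)
    g <- random_network(n, stats::runif(1, 0.2, 0.9), seed = 1000 + i)
    cores <- k_core_decomposition(g)
    expect_identical(cores, brute_force_cores(g$nodes, g$edges))
    expect_true(all(cores <= degree_centrality(g)))
  }
})

test_that("dif_degree takes the union of nodes and absolute differences", {
  g1 <- random_network(6, 0.5, seed = 4)
  expect_true(all(dif_degree(g1, g1)$dif_degree == 0))

  ctrl <- random_network(6, 0.8, seed = 5)
  pert <- random_network(6, 0.2, seed = 6)
  dd <- dif_degree(ctrl, pert)
  dc <- degree_centrality(ctrl); dp <- degree_centrality(pert)
  expect_identical(dd$dif_degree, abs(as.integer(dc - dp))[order(names(dc))])
  expect_identical(dd$signed_dif, as.integer(dc - dp)[order(names(dc))])

  # gene absent from one network counts as degree 0 there
  pert_small <- pert
  pert_small$nodes <- pert$nodes[1:4]
  pert_small$edges <- pert$edges[pert$edges$gene_a %in% pert$nodes[1:4] &
                                   pert$edges$gene_b %in% pert$nodes[1:4], ]
  dd2 <- dif_degree(ctrl, pert_small)
  missing <- setdiff(ctrl$nodes, pert_small$nodes)
  rows <- dd2[dd2$gene_id %in% missing, ]
  expect_identical(rows$degree_perturbed, rep(0L, length(missing)))
  expect_identical(rows$dif_degree, rows$degree_control)
})

test_that("select_hubs applies the strict >8 rule and intersects lists", {
  zbtb18 <- data.frame(gene_id = c("Olig1", "Zic5", "Erbb2", "Numbl", "Olig2",
                                   "Gnao1"),
                       dif_degree = c(12, 11, 10, 9, 9, 8))
  foxj3 <- data.frame(gene_id = c("Olig1", "Shank1", "Erbb2", "Zic5",
                                  "Smarcd3", "Ina", "Chd7", "Olig2", "Ndn"),
                      dif_degree = c(14, 13, 12, 11, 10, 10, 9, 9, 8))
  sel <- select_hubs(list(zbtb18 = zbtb18, foxj3 = foxj3), threshold = 8)
  # dif degree exactly 8 is excluded ("more than eight")
  expect_false("Gnao1" %in% sel$selected$zbtb18)
  expect_false("Ndn" %in% sel$selected$foxj3)
  expect_identical(sel$selected$zbtb18,
                   sort(c("Olig1", "Zic5", "Erbb2", "Numbl", "Olig2")))
  expect_identical(sel$core_regulators,
                   c("Erbb2", "Olig1", "Olig2", "Zic5"))

  # single table: core regulators equal its selection
  single <- select_hubs(zbtb18, threshold = 8)
  expect_identical(single$core_regulators, single$selected$perturbation)

  expect_error(select_hubs(list(), 8), class = "coexhub_input_error")
  expect_error(select_hubs(list(a = zbtb18), -1),
               class = "coexhub_input_error")
})

test_that("planted hub is recovered from realized networks", {
  # one replicate of the recovery world (the 200-rep version runs in the
  # acceptance suite)
  cfg <- sim_config(n_genes = 200, n_samples_per_condition = 30,
                    n_modules = 1, module_size = 10, n_hub_genes = 1,
                    hub_degree = 15, rewire_fraction = 0.9, seed = 101)
  sim <- simulate_expression(cfg)
  tr <- sim$truth
  genes <- c(tr$hub_genes, unlist(tr$hub_partners),
             names(tr$module_membership)[!is.na(tr$module_membership)],
             utils::tail(tr$gene_ids, 30))
  em <- combine_expr(sim$control, sim$perturbed)
  nc <- build_network(em, "control", genes = genes)
  np <- build_network(em, "perturbed", genes = genes)
  sel <- select_hubs(list(perturbed = dif_degree(nc, np)), 8)
  expect_true(tr$hub_genes %in% sel$selected$perturbed)
})
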