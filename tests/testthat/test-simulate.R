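test_that("simulation is deterministic and respects basic invariants", {
  cfg <- sim_config(n_genes = 80, n_samples_per_condition = 10, n_modules = 2,
                    module_size = 5, n_hub_genes = 2, hub_degree = 6,
                    seed = 42)
  sim1 <- simulate_expression(cfg)
  sim2 <- simulate_expression(cfg)
  expect_identical(sim1$control$values, sim2$control$values)
  expect_identical(sim1$perturbed$values, sim2$perturbed$values)
  expect_identical(sim1$truth, sim2$truth)

  expect_true(all(sim1$control$values >= 0))
  expect_false(anyNA(sim1$control$values))
  expect_identical(genes_of(sim1$control), sim1$truth$gene_ids)
  expect_identical(dim(sim1$control$values), c(80L, 10L))

  # different seed changes the draw
  sim3 <- simulate_expression(sim_config(n_genes = 80,
                                         n_samples_per_condition = 10,
                                         n_modules = 2, module_size = 5,
                                         n_hub_genes = 2, hub_degree = 6,
                                         seed = 43))
  expect_false(identical(sim1$control$values, sim3$control$values))

  # planted edges: no self pairs, stored with gene_a < gene_b
  for (edges in sim1$truth$planted_edges_by_condition) {
    expect_true(all(edges$gene_a != edges$gene_b))
    expect_true(all(edges$gene_a < edges$gene_b))
  }
})

test_that("invalid configurations are rejected with configuration errors", {
  expect_error(sim_config(n_genes = 10, n_modules = 3, module_size = 5),
               class = "coexhub_config_error")
  expect_error(sim_config(n_hub_genes = 5, n_modules = 4),
               class = "coexhub_config_error")
  expect_error(sim_config(rewire_fraction = 1.2),
               class = "coexhub_config_error")
  expect_error(sim_config(within_module_corr = 0),
               class = "coexhub_config_error")
  expect_error(sim_config(noise_sd = -1), class = "coexhub_config_error")
  expect_error(sim_config(hub_corr = 0.9, hub_partner_corr = 0.5),
               class = "coexhub_config_error")
})

test_that("expected dif degree follows the kept-edge ceiling rule", {
  # oracle: direct count of the planted edge-set difference
  cfg <- sim_config(n_genes = 200, n_samples_per_condition = 30,
                    n_modules = 1, module_size = 10, n_hub_genes = 1,
                    hub_degree = 15, rewire_fraction = 0.9, seed = 1)
  sim <- simulate_expression(cfg)
  hub <- sim$truth$hub_genes
  count_hub_edges <- function(edges)
    sum(edges$gene_a == hub | edges$gene_b == hub)
  n_ctrl <- count_hub_edges(sim$truth$planted_edges_by_condition$control)
  n_pert <- count_hub_edges(sim$truth$planted_edges_by_condition$perturbed)
  expect_identical(n_ctrl, 15L)
  expect_identical(n_pert, 2L)  # ceiling(0.1 * 15) = 2
  expect_identical(unname(sim$truth$expected_dif_degree[hub]),
                   n_ctrl - n_pert)  # = 13

  # no rewiring removes no edges
  cfg0 <- sim_config(n_genes = 60, n_samples_per_condition = 6,
                     n_modules = 0, n_hub_genes = 1, hub_degree = 8,
                     rewire_fraction = 0, seed = 3)
  tr0 <- simulate_expression(cfg0)$truth
  expect_true(all(tr0$expected_dif_degree == 0))
  expect_identical(tr0$planted_edges_by_condition$control,
                   tr0$planted_edges_by_condition$perturbed)
})

test_that("realized correlations track their targets at large n", {
  cfg <- sim_config(n_genes = 60, n_samples_per_condition = 200,
                    n_modules = 2, module_size = 6, n_hub_genes = 1,
                    hub_degree = 8, rewire_fraction = 0.5,
                    within_module_corr = 0.8, seed = 7)
  sim <- simulate_expression(cfg)
  tr <- sim$truth
  logx <- log2(sim$control$values)
  mod1 <- names(tr$module_membership)[tr$module_membership %in% "module01"]
  cm <- stats::cor(t(logx[mod1, ]))
  expect_lt(abs(mean(cm[upper.tri(cm)]) - 0.8), 0.05)

  hub <- tr$hub_genes
  prt <- tr$hub_partners[[1]]
  ch <- stats::cor(t(logx[c(hub, prt), ]))
  expect_lt(abs(mean(ch[hub, prt]) - cfg$hub_corr), 0.07)

  # perturbed condition: kept partners retain hub_corr, removed drop
  kept <- prt[seq_len(4)]  # ceiling(0.5 * 8) = 4
  removed <- setdiff(prt, kept)
  cp <- stats::cor(t(log2(sim$perturbed$values[c(hub, prt), ])))
  expect_lt(abs(mean(cp[hub, kept]) - cfg$hub_corr), 0.1)
  expect_lt(mean(cp[hub, removed]), 0.35)
})

test_that("planted DE effects land on target and null genes stay centered", {
  cfg <- sim_config(n_genes = 300, n_samples_per_condition = 30,
                    n_modules = 0, n_hub_genes = 0, de_fraction = 0.2,
                    de_log2fc = 2, seed = 11)
  sim <- simulate_expression(cfg)
  lfc <- rowMeans(log2(sim$perturbed$values)) -
    rowMeans(log2(sim$control$values))
  tr <- sim$truth
  expect_length(tr$de_genes, 60)
  signed <- lfc[names(tr$de_genes)] * tr$de_genes
  se <- stats::sd(signed) / sqrt(length(signed))
  expect_lt(abs(mean(signed) - 2), 3 * se)

  # de_fraction = 0: symmetric null, mean log2fc centered at 0
  cfg0 <- sim_config(n_genes = 300, n_samples_per_condition = 30,
                     n_modules = 0, n_hub_genes = 0, de_fraction = 0,
                     seed = 12)
  sim0 <- simulate_expression(cfg0)
  expect_length(sim0$truth$de_genes, 0)
  lfc0 <- rowMeans(log2(sim0$perturbed$values)) -
    rowMeans(log2(sim0$control$values))
  expect_lt(abs(mean(lfc0)), 3 * stats::sd(lfc0) / sqrt(length(lfc0)))
})

test_that("multi-perturbation simulation shares planted structure", {
  cfg <- sim_config(n_genes = 120, n_samples_per_condition = 8, seed = 5)
  sim <- simulate_expression(cfg, c("pA", "pB"))
  expect_named(sim$perturbed, c("pA", "pB"))
  expect_setequal(names(sim$truth$planted_edges_by_condition),
                  c("control", "pA", "pB"))
  expect_identical(sim$truth$planted_edges_by_condition$pA,
                   sim$truth$planted_edges_by_condition$pB)
  # same conditions labelled on samples
  expect_true(all(sim$perturbed$pA$conditions == "pA"))
  # but independent noise
  expect_false(identical(unname(sim$perturbed$pA$values),
                         unname(sim$perturbed$pB$values)))
})

test_that("simulated annotations plant detectable enrichment", {
  cfg <- sim_config(n_genes = 300, n_samples_per_condition = 6,
                    n_modules = 2, module_size = 10, n_hub_genes = 2,
                    hub_degree = 10, de_fraction = 0.2, seed = 21)
  truth <- simulate_expression(cfg)$truth
  ann1 <- simulate_annotations(truth, n_terms = 30, term_size_range = c(10, 40),
                               n_enriched_terms = 3, seed = 9)
  ann2 <- simulate_annotations(truth, n_terms = 30, term_size_range = c(10, 40),
                               n_enriched_terms = 3, seed = 9)
  expect_identical(ann1, ann2)
  expect_length(ann1$sets, 30)
  expect_identical(attr(ann1, "enriched_terms"),
                   sprintf("TERM_ENRICHED_%02d", 1:3))
  expect_true(all(lengths(ann1$sets) >= 10 & lengths(ann1$sets) <= 40))

  de <- names(truth$de_genes)
  enr <- fisher_enrichment(de, ann1)
  planted_q <- enr$q_value[enr$term_id %in% attr(ann1, "enriched_terms")]
  expect_true(all(planted_q < 0.01))

  expect_error(simulate_annotations(truth, n_terms = 5, n_enriched_terms = 9),
               class = "coexhub_config_error")
  expect_error(simulate_annotations(truth, term_size_range = c(10, 400)),
               class = "coexhub_config_error")
})

test_that("truth manifest round-trips losslessly", {
  cfg <- sim_config(n_genes = 60, n_samples_per_condition = 6, n_modules = 1,
                    module_size = 5, n_hub_genes = 1, hub_degree = 6,
                    seed = 31)
  truth <- simulate_expression(cfg)$truth
  path <- withr::local_tempfile(fileext = ".json")
  write_truth_manifest(truth, path)
  back <- read_truth_manifest(path)
  expect_equal(back, truth)

  # degenerate: empty hub set still round-trips
  cfg0 <- sim_config(n_genes = 20, n_samples_per_condition = 4,
                     n_modules = 0, n_hub_genes = 0, de_fraction = 0,
                     seed = 32)
  truth0 <- simulate_expression(cfg0)$truth
  write_truth_manifest(truth0, path)
  back0 <- read_truth_manifest(path)
  expect_equal(back0, truth0)
  expect_length(back0$hub_genes, 0)

  expect_error(write_truth_manifest(truth, "/no/such/dir/x.json"),
               class = "coexhub_io_error")
  # manifest agrees with the planted edge-set difference count
  hub <- truth$hub_genes
  nd <- sum(back$planted_edges_by_condition$control$gene_a == hub |
              back$planted_edges_by_condition$control$gene_b == hub) -
    sum(back$planted_edges_by_condition$perturbed$gene_a == hub |
          back$planted_edges_by_condition$perturbed$gene_b == hub)
  expect_identical(unname(back$expected_dif_degree[hub]), nd)
})
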