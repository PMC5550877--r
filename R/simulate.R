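#' Simulation configuration for paired-condition expression data
#'
#' Describes the stated world of the synthetic generator: a control condition
#' and one or more perturbed conditions over the same genes, with (a) a
#' planted fraction of differentially expressed genes at a fixed log2 effect,
#' (b) co-expression modules driven by latent factors, and (c) designated hub
#' genes whose planted network degree drops in the perturbed condition by a
#' controllable rewiring fraction.
#'
#' On the log2 scale every gene is `baseline + noise_sd * z` with `z` a unit
#' variance Gaussian; module members share a per-module latent factor so that
#' co-member pairwise Pearson correlation equals `within_module_corr`. Each
#' hub gene forms a correlation block with its `hub_degree` partner genes:
#' in the control condition the hub correlates with every partner at
#' `hub_corr` and partners correlate pairwise at `hub_partner_corr` (the hub
#' behaves like a member of its own module). In the perturbed condition the
#' partners remain a coherent block but the hub is cut out of it: it keeps
#' correlation `hub_corr` with the `ceiling((1-rewire_fraction)*hub_degree)`
#' kept partners, while its correlation with the removed partners collapses
#' to the smallest residual that positive semidefiniteness allows (about
#' 0.2 at the defaults -- a hub cannot decouple exactly from a block its
#' kept neighbours still belong to). Values are exponentiated to the linear
#' scale.
#'
#' @param n_genes Number of genes.
#' @param n_samples_per_condition Samples per condition.
#' @param n_modules Number of co-expression modules.
#' @param module_size Genes per module.
#' @param n_hub_genes Number of planted hub genes (at most `n_modules`).
#' @param hub_degree Planted partners per hub.
#' @param hub_corr Hub-partner Pearson correlation `b` of planted edges.
#' @param hub_partner_corr Partner-partner Pearson correlation `c` within a
#'   hub's block; must satisfy `c >= b^2` (the hub loads on the block factor
#'   at `b/sqrt(c)`). `NULL` (default) uses `max(0.8, b^2 + 0.1)`.
#' @param rewire_fraction Fraction of each hub's planted edges removed in the
#'   perturbed condition; the kept count is
#'   `ceiling((1 - rewire_fraction) * hub_degree)`.
#' @param de_fraction Fraction of genes with a planted mean shift in the
#'   perturbed condition. When positive, the hub genes and their partners are
#'   always part of the differentially expressed set.
#' @param de_log2fc Planted effect size in log2 units (sign randomized per
#'   gene).
#' @param within_module_corr Target pairwise Pearson correlation of module
#'   co-members, in (0, 1).
#' @param noise_sd Log2-scale standard deviation of each gene.
#' @param seed Integer seed; identical configuration and seed give
#'   bit-identical output.
#' @return A validated list of class `sim_config`.
#' @seealso [simulate_expression()], [simulate_annotations()]
#' @export
sim_config <- function(n_genes = 200L,
                       n_samples_per_condition = 30L,
                       n_modules = 4L,
                       module_size = 10L,
                       n_hub_genes = 4L,
                       hub_degree = 15L,
                       hub_corr = 0.75,
                       hub_partner_corr = NULL,
                       rewire_fraction = 0.9,
                       de_fraction = 0.35,
                       de_log2fc = 2,
                       within_module_corr = 0.8,
                       noise_sd = 1,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_samples_per_condition = as.integer(n_samples_per_condition),
              n_modules = as.integer(n_modules),
              module_size = as.integer(module_size),
              n_hub_genes = as.integer(n_hub_genes),
              hub_degree = as.integer(hub_degree),
              hub_corr = hub_corr,
              hub_partner_corr = hub_partner_corr,
              rewire_fraction = rewire_fraction,
              de_fraction = de_fraction,
              de_log2fc = de_log2fc,
              within_module_corr = within_module_corr,
              noise_sd = noise_sd,
              seed = as.integer(seed))
  cfg <- validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, what) if (!ok) stop_config("invalid sim_config: ", what)
  chk(cfg$n_genes >= 1, "n_genes must be positive")
  chk(cfg$n_samples_per_condition >= 2, "n_samples_per_condition must be >= 2")
  chk(cfg$n_modules >= 0, "n_modules must be >= 0")
  chk(cfg$n_modules == 0 || cfg$module_size >= 2,
      "module_size must be >= 2 when modules are requested")
  chk(cfg$n_modules * cfg$module_size <= cfg$n_genes,
      "n_modules * module_size must not exceed n_genes")
  chk(cfg$n_hub_genes >= 0, "n_hub_genes must be >= 0")
  chk(cfg$n_hub_genes == 0 || cfg$n_modules == 0 ||
        cfg$n_hub_genes <= cfg$n_modules,
      "n_hub_genes must not exceed n_modules")
  chk(cfg$n_hub_genes == 0 || cfg$hub_degree >= 1,
      "hub_degree must be >= 1 when hubs are requested")
  chk(cfg$hub_degree < cfg$n_genes, "hub_degree must be below n_genes")
  layout_needed <- cfg$n_modules * cfg$module_size +
    cfg$n_hub_genes * (1L + cfg$hub_degree)
  chk(layout_needed <= cfg$n_genes,
      "n_genes too small for disjoint modules, hubs and hub partners")
  chk(cfg$hub_corr > 0 && cfg$hub_corr < 1, "hub_corr must be in (0,1)")
  if (cfg$n_hub_genes > 0 && cfg$hub_degree > 1) {
    if (is.null(cfg$hub_partner_corr))
      cfg$hub_partner_corr <- max(0.8, min(0.99, cfg$hub_corr^2 + 0.1))
    # the hub loads on the partner-block factor at b/sqrt(c), so b^2 <= c
    chk(cfg$hub_partner_corr >= cfg$hub_corr^2 &&
          cfg$hub_partner_corr < 1,
        sprintf("hub_partner_corr must lie in [hub_corr^2=%.4f, 1)",
                cfg$hub_corr^2))
    kept <- kept_edge_count(cfg$hub_degree, cfg$rewire_fraction)
    if (kept >= 1 && kept < cfg$hub_degree)
      chk(!is.null(hub_sigma(cfg$hub_degree, kept, cfg$hub_corr,
                             cfg$hub_partner_corr)),
          "hub_corr too strong relative to hub_partner_corr for partial rewiring")
  } else if (is.null(cfg$hub_partner_corr)) {
    cfg$hub_partner_corr <- 0
  }
  chk(cfg$rewire_fraction >= 0 && cfg$rewire_fraction <= 1,
      "rewire_fraction must be in [0,1]")
  chk(cfg$de_fraction >= 0 && cfg$de_fraction <= 1,
      "de_fraction must be in [0,1]")
  chk(cfg$n_modules == 0 ||
        (cfg$within_module_corr > 0 && cfg$within_module_corr < 1),
      "within_module_corr must be in (0,1)")
  chk(cfg$noise_sd > 0, "noise_sd must be positive")
  invisible(cfg)
}

# Deterministic gene layout: modules first, then hubs, then hub partners,
# then unstructured background genes.
sim_layout <- function(cfg) {
  width <- max(4L, nchar(as.character(cfg$n_genes)))
  gene_ids <- sprintf(paste0("g%0", width, "d"), seq_len(cfg$n_genes))
  module_membership <- stats::setNames(rep(NA_character_, cfg$n_genes), gene_ids)
  idx <- 0L
  module_genes <- vector("list", cfg$n_modules)
  for (m in seq_len(cfg$n_modules)) {
    members <- gene_ids[idx + seq_len(cfg$module_size)]
    module_membership[members] <- sprintf("module%02d", m)
    module_genes[[m]] <- members
    idx <- idx + cfg$module_size
  }
  hub_genes <- if (cfg$n_hub_genes > 0) gene_ids[idx + seq_len(cfg$n_hub_genes)] else character()
  idx <- idx + cfg$n_hub_genes
  partners <- stats::setNames(vector("list", cfg$n_hub_genes), hub_genes)
  for (h in seq_len(cfg$n_hub_genes)) {
    partners[[h]] <- gene_ids[idx + seq_len(cfg$hub_degree)]
    idx <- idx + cfg$hub_degree
  }
  list(gene_ids = gene_ids, module_membership = module_membership,
       module_genes = module_genes, hub_genes = hub_genes,
       partners = partners)
}

# Number of planted hub edges kept after rewiring (documented ceiling rule).
kept_edge_count <- function(hub_degree, rewire_fraction) {
  as.integer(ceiling((1 - rewire_fraction) * hub_degree))
}

# Target correlation matrix of one hub group (hub first, then partners)
# in a given condition. Control: hub-partner = b, partner-partner = c.
# Perturbed (partial rewiring): removed partners stay a coherent block (c),
# the kept pair stays coherent (c) and keeps correlation b with the hub;
# kept-removed drops to 0.75*c and the hub retains a small residual
# correlation eps with removed partners -- the smallest value (eigenvalue
# scan, 0.01 grid + 0.02 margin) that keeps the matrix positive definite,
# since cutting a hub out of a still-coherent block cannot reach exactly
# zero. eps stays well below the detection threshold of the FDR-selected
# networks the pipeline builds.
hub_sigma <- function(m, kept, b, c_blk) {
  if (m == 1) {
    r <- if (kept >= 1) b else 0
    return(matrix(c(1, r, r, 1), 2))
  }
  S <- matrix(c_blk, m + 1, m + 1)
  S[1, -1] <- b; S[-1, 1] <- b
  diag(S) <- 1
  if (kept >= m) return(S)
  if (kept == 0) {
    S[1, -1] <- 0; S[-1, 1] <- 0
    return(S)
  }
  K <- 1 + seq_len(kept); R <- setdiff(2:(m + 1), K)
  S[K, R] <- 0.8 * c_blk; S[R, K] <- 0.8 * c_blk
  S[K, K] <- min(c_blk + 0.1, 0.95)
  diag(S) <- 1
  for (eps in seq(0, 0.95, by = 0.01)) {
    S[1, R] <- eps; S[R, 1] <- eps
    ev <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
    if (ev > 0.01) {
      eps <- min(eps + 0.02, b)
      S[1, R] <- eps; S[R, 1] <- eps
      return(S)
    }
  }
  NULL
}

# Draw one condition's latent z matrix (genes x samples, unit variance rows).
# `rewired = TRUE` replaces the hub loading of removed partners with a fresh
# shared factor per hub.
sim_draw_z <- function(cfg, layout, n, rewired) {
  z <- matrix(stats::rnorm(cfg$n_genes * n), nrow = cfg$n_genes,
              dimnames = list(layout$gene_ids, NULL))
  rho <- cfg$within_module_corr
  for (m in seq_len(cfg$n_modules)) {
    f <- stats::rnorm(n)
    members <- layout$module_genes[[m]]
    z[members, ] <- sqrt(rho) * matrix(f, nrow = length(members),
                                       ncol = n, byrow = TRUE) +
      sqrt(1 - rho) * z[members, , drop = FALSE]
  }
  b <- cfg$hub_corr
  c_blk <- cfg$hub_partner_corr
  m_p <- cfg$hub_degree
  kept <- if (rewired) kept_edge_count(m_p, cfg$rewire_fraction) else m_p
  if (length(layout$hub_genes)) {
    S <- hub_sigma(m_p, kept, b, c_blk)
    cholS <- chol(S + diag(1e-9, nrow(S)))
  }
  for (h in seq_along(layout$hub_genes)) {
    hub <- layout$hub_genes[h]
    prt <- layout$partners[[h]]
    # hub first, partners next (kept partners lead); exact joint draw
    z[c(hub, prt), ] <- crossprod(
      cholS, matrix(stats::rnorm((m_p + 1) * n), nrow = m_p + 1))
  }
  z
}

sim_condition_matrix <- function(cfg, layout, baseline, shift, label, rewired) {
  n <- cfg$n_samples_per_condition
  z <- sim_draw_z(cfg, layout, n, rewired)
  log2x <- baseline + shift + cfg$noise_sd * z
  vals <- 2^log2x
  colnames(vals) <- sprintf("%s_%02d", label, seq_len(n))
  expr_matrix(vals, stats::setNames(rep(label, n), colnames(vals)))
}

sim_planted_truth <- function(cfg, layout, de_sign, labels) {
  pairs_for <- function(kept_only) {
    out <- list()
    for (h in seq_along(layout$hub_genes)) {
      prt <- layout$partners[[h]]
      if (kept_only) prt <- prt[seq_len(kept_edge_count(cfg$hub_degree,
                                                        cfg$rewire_fraction))]
      if (length(prt))
        out[[h]] <- data.frame(gene_a = pmin(layout$hub_genes[h], prt),
                               gene_b = pmax(layout$hub_genes[h], prt),
                               stringsAsFactors = FALSE)
    }
    if (length(out)) do.call(rbind, out)
    else data.frame(gene_a = character(), gene_b = character(),
                    stringsAsFactors = FALSE)
  }
  control_edges <- pairs_for(FALSE)
  perturbed_edges <- pairs_for(TRUE)
  edges <- c(list(control = control_edges),
             stats::setNames(rep(list(perturbed_edges), length(labels)), labels))
  expected <- stats::setNames(
    rep(cfg$hub_degree - kept_edge_count(cfg$hub_degree, cfg$rewire_fraction),
        length(layout$hub_genes)),
    layout$hub_genes)
  structure(list(gene_ids = layout$gene_ids,
                 de_genes = de_sign,
                 module_membership = layout$module_membership,
                 hub_genes = layout$hub_genes,
                 hub_partners = layout$partners,
                 planted_edges_by_condition = edges,
                 expected_dif_degree = expected),
            class = "planted_truth")
}

#' Simulate a control/perturbation experiment with planted structure
#'
#' Generates one control and any number of perturbed expression matrices over
#' a common gene universe, together with the planted ground truth
#' (differentially expressed genes, module membership, hub genes, planted
#' edge sets per condition and the expected differential degree of each hub).
#' All perturbations share the same planted hubs, partners, removed edges and
#' differential-expression assignment, so cross-perturbation intersection can
#' recover the planted hubs; sample-level noise is drawn independently per
#' condition.
#'
#' @param config A [sim_config()].
#' @param perturbation_labels Character vector of condition labels for the
#'   perturbed matrices (default a single `"perturbed"`).
#' @return List with elements `control` (an [expr_matrix()]), `perturbed`
#'   (an `expr_matrix` when one label is given, otherwise a named list of
#'   them) and `truth` (a `planted_truth` object).
#' @examples
#' sim <- simulate_expression(sim_config(n_genes = 50, n_modules = 1,
#'                                       n_hub_genes = 1, hub_degree = 5,
#'                                       seed = 7))
#' sim$truth$expected_dif_degree
#' @export
simulate_expression <- function(config,
                                perturbation_labels = "perturbed") {
  config <- validate_sim_config(config)
  if (length(perturbation_labels) < 1 || anyDuplicated(perturbation_labels) ||
      "control" %in% perturbation_labels)
    stop_config("perturbation labels must be unique and distinct from 'control'")
  set.seed(config$seed)
  layout <- sim_layout(config)
  baseline <- stats::runif(config$n_genes, min = 4, max = 10)

  n_de <- if (config$de_fraction == 0) 0L else
    as.integer(ceiling(config$de_fraction * config$n_genes))
  forced <- unique(c(layout$hub_genes, unlist(layout$partners)))
  de_ids <- character()
  if (n_de > 0) {
    de_ids <- forced
    pool <- setdiff(layout$gene_ids, forced)
    extra <- n_de - length(de_ids)
    if (extra > 0) de_ids <- c(de_ids, sample(pool, extra))
    de_ids <- de_ids[order(match(de_ids, layout$gene_ids))]
  }
  de_sign <- stats::setNames(sample(c(-1L, 1L), length(de_ids), replace = TRUE),
                             de_ids)
  shift <- stats::setNames(rep(0, config$n_genes), layout$gene_ids)
  shift[de_ids] <- de_sign * config$de_log2fc

  control <- sim_condition_matrix(config, layout, baseline, 0,
                                  "control", rewired = FALSE)
  perturbed <- lapply(perturbation_labels, function(lab)
    sim_condition_matrix(config, layout, baseline, shift, lab, rewired = TRUE))
  names(perturbed) <- perturbation_labels

  truth <- sim_planted_truth(config, layout, de_sign, perturbation_labels)
  list(control = control,
       perturbed = if (length(perturbed) == 1L) perturbed[[1L]] else perturbed,
       truth = truth)
}

#' @export
print.planted_truth <- function(x, ...) {
  cat(sprintf(paste0("planted_truth: %d genes, %d DE, %d modules, ",
                     "%d hubs (expected dif degree %s)\n"),
              length(x$gene_ids), length(x$de_genes),
              length(unique(stats::na.omit(x$module_membership))),
              length(x$hub_genes),
              if (length(x$expected_dif_degree))
                paste(unique(x$expected_dif_degree), collapse = "/") else "-"))
  invisible(x)
}

#' Simulate a gene-set annotation map with planted enriched terms
#'
#' Builds `n_terms` annotation terms over the simulated gene universe.
#' `n_enriched_terms` of them are drawn mostly (90 percent) from the planted
#' differentially expressed and module genes, so downstream Fisher enrichment
#' should flag them; the remainder are uniform random gene sets.
#'
#' @param truth A `planted_truth` from [simulate_expression()].
#' @param n_terms Total number of terms.
#' @param term_size_range Integer interval (length 2) of term sizes.
#' @param n_enriched_terms Number of planted enriched terms
#'   (`<= n_terms`).
#' @param seed Integer seed for the annotation stream.
#' @return An [annotation_map()] whose planted terms are named
#'   `TERM_ENRICHED_*` (also recorded in attribute `"enriched_terms"`).
#' @export
simulate_annotations <- function(truth, n_terms = 40L,
                                 term_size_range = c(10L, 60L),
                                 n_enriched_terms = 4L, seed = 1L) {
  if (!inherits(truth, "planted_truth")) stop_input("'truth' must be a planted_truth")
  n_terms <- as.integer(n_terms)
  n_enriched_terms <- as.integer(n_enriched_terms)
  if (n_enriched_terms > n_terms)
    stop_config("n_enriched_terms must not exceed n_terms")
  lo <- as.integer(min(term_size_range)); hi <- as.integer(max(term_size_range))
  universe <- truth$gene_ids
  if (hi > length(universe))
    stop_config("term sizes exceed the gene universe (", length(universe), ")")
  if (lo < 1) stop_config("term sizes must be >= 1")
  set.seed(as.integer(seed))
  pool <- unique(c(names(truth$de_genes),
                   names(truth$module_membership)[!is.na(truth$module_membership)]))
  if (length(pool) == 0) pool <- universe
  sets <- vector("list", n_terms)
  ids <- character(n_terms)
  for (i in seq_len(n_terms)) {
    size <- if (lo == hi) lo else sample(lo:hi, 1L)
    if (i <= n_enriched_terms) {
      ids[i] <- sprintf("TERM_ENRICHED_%02d", i)
      n_pool <- min(length(pool), round(0.9 * size))
      members <- sample(pool, n_pool)
      rest <- setdiff(universe, members)
      if (size - n_pool > 0)
        members <- c(members, sample(rest, min(size - n_pool, length(rest))))
    } else {
      ids[i] <- sprintf("TERM_NULL_%03d", i - n_enriched_terms)
      members <- sample(universe, size)
    }
    sets[[i]] <- sort(members)
  }
  names(sets) <- ids
  ann <- annotation_map(sets, universe = universe,
                        term_names = stats::setNames(ids, ids))
  attr(ann, "enriched_terms") <- ids[seq_len(n_enriched_terms)]
  ann
}

#' Write / read a planted-truth manifest
#'
#' Serializes a `planted_truth` object to a plain-text JSON manifest that
#' round-trips losslessly through [read_truth_manifest()].
#'
#' @param truth A `planted_truth`.
#' @param path Output file path.
#' @return `path`, invisibly (writer); a `planted_truth` (reader).
#' @export
write_truth_manifest <- function(truth, path) {
  if (!inherits(truth, "planted_truth")) stop_input("'truth' must be a planted_truth")
  dir <- dirname(path)
  if (!dir.exists(dir)) stop_io("directory does not exist: ", dir)
  payload <- list(
    gene_ids = truth$gene_ids,
    de_genes = as.list(truth$de_genes),
    module_membership = as.list(truth$module_membership),
    hub_genes = truth$hub_genes,
    hub_partners = truth$hub_partners,
    planted_edges_by_condition = lapply(truth$planted_edges_by_condition,
                                        function(df) unname(apply(df, 1, as.list))),
    expected_dif_degree = as.list(truth$expected_dif_degree))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, null = "null",
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth_manifest
#' @export
read_truth_manifest <- function(path) {
  if (!file.exists(path)) stop_io("no such file: ", path)
  p <- jsonlite::read_json(path)
  as_chr <- function(x) vapply(as.list(x), function(v)
    if (is.null(v)) NA_character_ else as.character(v), "",
    USE.NAMES = FALSE)
  edges <- lapply(p$planted_edges_by_condition, function(rows) {
    if (length(rows) == 0)
      return(data.frame(gene_a = character(), gene_b = character(),
                        stringsAsFactors = FALSE))
    data.frame(gene_a = vapply(rows, function(r) r[[1]], ""),
               gene_b = vapply(rows, function(r) r[[2]], ""),
               stringsAsFactors = FALSE)
  })
  nm <- function(x) if (is.null(x)) character() else x
  partners <- lapply(p$hub_partners, as_chr)
  names(partners) <- nm(names(p$hub_partners))
  structure(list(
    gene_ids = as_chr(p$gene_ids),
    de_genes = stats::setNames(vapply(p$de_genes, as.integer, 1L),
                               nm(names(p$de_genes))),
    module_membership = stats::setNames(as_chr(p$module_membership),
                                        nm(names(p$module_membership))),
    hub_genes = as_chr(p$hub_genes),
    hub_partners = partners,
    planted_edges_by_condition = edges,
    expected_dif_degree = stats::setNames(
      vapply(p$expected_dif_degree, as.integer, 1L),
      nm(names(p$expected_dif_degree)))),
    class = "planted_truth")
}
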