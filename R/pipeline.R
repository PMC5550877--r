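#' Pipeline configuration
#'
#' Bundles inputs and thresholds for the end-to-end analysis: simulate (or
#' read) expression data, call differential expression per perturbation,
#' run Fisher gene-set enrichment, select focus-term candidates, build
#' condition-specific co-expression networks over the cross-perturbation
#' candidate overlap, and nominate core regulators by differential degree.
#'
#' @param simulate Logical; if `TRUE` inputs are generated with
#'   [simulate_expression()] / [simulate_annotations()].
#' @param sim A [sim_config()] (simulation mode). Its seed is overridden by
#'   `seed`. The pipeline default raises `de_fraction` to 0.5 so the
#'   candidate networks contain unstructured differentially expressed genes
#'   alongside the planted hub blocks, as real focus-term gene sets do.
#' @param expression_path,gmt_path Input files (ingestion mode):
#'   a matrix readable by [read_expression()] and a GMT annotation file.
#' @param control_label Condition label of the control group.
#' @param perturbation_labels Character vector (>= 1) of perturbed condition
#'   labels.
#' @param de_alpha Raw p threshold of the DE filter (default 0.05).
#' @param de_fold Linear fold-change threshold of the DE filter (default 2,
#'   inclusive).
#' @param term_alpha Raw Fisher p threshold for calling a term enriched
#'   (default 0.01).
#' @param edge_fdr Per-network edge FDR threshold (default 0.05).
#' @param dif_threshold Strict differential-degree threshold for hub
#'   selection (default 8).
#' @param focus_terms Term ids whose genes feed the candidate selection;
#'   `NULL` (default) uses the terms enriched (raw `p < term_alpha`) in
#'   every perturbation — the "overlapping" enriched terms.
#' @param n_annotation_terms,annotation_term_size,n_enriched_terms
#'   Annotation-generator settings (simulation mode). Term sizes default to
#'   80-110 genes so the planted terms jointly cover the planted
#'   differentially expressed genes.
#' @param seed Integer seed driving all randomness of a simulated run.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = TRUE,
                            sim = sim_config(de_fraction = 0.5),
                            expression_path = NULL,
                            gmt_path = NULL,
                            control_label = "control",
                            perturbation_labels = c("perturbA", "perturbB"),
                            de_alpha = 0.05,
                            de_fold = 2,
                            term_alpha = 0.01,
                            edge_fdr = 0.05,
                            dif_threshold = 8L,
                            focus_terms = NULL,
                            n_annotation_terms = 40L,
                            annotation_term_size = c(100L, 130L),
                            n_enriched_terms = 4L,
                            seed = 1L) {
  cfg <- list(simulate = isTRUE(simulate), sim = sim,
              expression_path = expression_path, gmt_path = gmt_path,
              control_label = control_label,
              perturbation_labels = as.character(perturbation_labels),
              de_alpha = de_alpha, de_fold = de_fold,
              term_alpha = term_alpha, edge_fdr = edge_fdr,
              dif_threshold = as.integer(dif_threshold),
              focus_terms = focus_terms,
              n_annotation_terms = as.integer(n_annotation_terms),
              annotation_term_size = as.integer(annotation_term_size),
              n_enriched_terms = as.integer(n_enriched_terms),
              seed = as.integer(seed))
  if (length(cfg$perturbation_labels) < 1)
    stop_config("need at least one perturbation label")
  for (f in c("de_alpha", "term_alpha", "edge_fdr"))
    if (cfg[[f]] <= 0 || cfg[[f]] > 1)
      stop_config(f, " must be in (0,1]")
  if (cfg$de_fold <= 0) stop_config("de_fold must be positive")
  if (cfg$dif_threshold < 0) stop_config("dif_threshold must be >= 0")
  if (cfg$simulate) {
    cfg$sim <- validate_sim_config(cfg$sim)
  } else if (is.null(cfg$expression_path) || is.null(cfg$gmt_path)) {
    stop_config("ingestion mode needs expression_path and gmt_path")
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' Flat JSON object with the fields of [pipeline_config()]; the `sim` field
#' is a nested object with [sim_config()] fields.
#'
#' @param path JSON file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_io("no such file: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$sim)) raw$sim <- do.call(sim_config, as.list(raw$sim))
  do.call(pipeline_config, raw)
}

#' Run the end-to-end hub-nomination pipeline
#'
#' Executes simulate/ingest, differential expression, enrichment, candidate
#' selection, network construction, and differential-degree hub nomination,
#' writing every intermediate as a plain-text table under `output_dir`.
#' Reruns with an identical configuration produce byte-identical outputs.
#'
#' @param config A [pipeline_config()] (or a path to a JSON file for
#'   [read_pipeline_config()]).
#' @param output_dir Directory for stage outputs (created if needed).
#' @return A `run_report` list: per-stage parameter and count records, the
#'   nominated `core_regulators`, and the paths of all written files.
#' @examples
#' \donttest{
#' cfg <- pipeline_config(sim = sim_config(n_genes = 120, n_modules = 2,
#'                                         n_hub_genes = 2, seed = 5),
#'                        seed = 5)
#' rep <- run_pipeline(cfg, output_dir = tempfile("coexhub"))
#' rep$core_regulators
#' }
#' @export
run_pipeline <- function(config, output_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(output_dir) &&
      !dir.create(output_dir, recursive = TRUE, showWarnings = FALSE))
    stop_io("cannot create output directory: ", output_dir)
  paths <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(errorCondition(
        sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
        class = c("coexhub_stage_error", class(e))))
    })
  }
  out <- function(name) file.path(output_dir, name)

  # stage 1: data ---------------------------------------------------------
  data <- stage("data", {
    if (config$simulate) {
      sim_cfg <- config$sim
      sim_cfg$seed <- config$seed
      sim <- simulate_expression(sim_cfg, config$perturbation_labels)
      perturbed <- if (inherits(sim$perturbed, "expr_matrix"))
        stats::setNames(list(sim$perturbed), config$perturbation_labels)
      else sim$perturbed
      em <- do.call(combine_expr, c(list(sim$control), unname(perturbed)))
      ann <- simulate_annotations(
        sim$truth, n_terms = config$n_annotation_terms,
        term_size_range = config$annotation_term_size,
        n_enriched_terms = config$n_enriched_terms,
        # distinct named stream for the annotation artifact
        seed = (config$seed + 1000L) %% .Machine$integer.max)
      paths$truth <- out("truth_manifest.json")
      write_truth_manifest(sim$truth, paths$truth)
      list(em = em, ann = ann, truth = sim$truth)
    } else {
      list(em = read_expression(config$expression_path),
           ann = read_gmt(config$gmt_path), truth = NULL)
    }
  })
  paths$expression <- out("expression.tsv")
  write_expression(data$em, paths$expression)
  paths$annotations <- out("annotations.gmt")
  write_gmt(data$ann, paths$annotations)
  present <- config$perturbation_labels %in% data$em$conditions
  if (!all(present))
    stop_config("perturbation label(s) absent from data: ",
                paste(config$perturbation_labels[!present], collapse = ", "))

  # stage 2: differential expression --------------------------------------
  de_tables <- stage("differential_expression", {
    lapply(stats::setNames(nm = config$perturbation_labels), function(lab)
      compute_de(data$em, config$control_label, lab,
                 alpha = config$de_alpha, fold = config$de_fold))
  })
  for (lab in names(de_tables)) {
    paths[[paste0("de_", lab)]] <- out(sprintf("de_%s.tsv", lab))
    write_tsv(de_tables[[lab]], paths[[paste0("de_", lab)]])
  }
  de_sets <- lapply(de_tables, function(tb)
    sort(tb$gene_id[tb$status != "not_significant"]))

  # stage 3: enrichment ----------------------------------------------------
  enr <- stage("enrichment", {
    lapply(de_sets, function(de)
      fisher_enrichment(intersect(de, data$ann$universe), data$ann))
  })
  for (lab in names(enr)) {
    paths[[paste0("enrichment_", lab)]] <- out(sprintf("enrichment_%s.tsv", lab))
    write_tsv(enr[[lab]], paths[[paste0("enrichment_", lab)]])
  }
  significant_terms <- lapply(enr, function(tb)
    sort(tb$term_id[tb$p_value < config$term_alpha]))
  focus_terms <- config$focus_terms
  if (is.null(focus_terms))
    focus_terms <- sort(Reduce(intersect, significant_terms))
  if (length(focus_terms) == 0)
    stop_stats("no focus terms: no term is enriched in every perturbation")

  # stage 4: candidate selection ------------------------------------------
  candidates <- stage("candidates",
                      select_focus_candidates(de_sets, focus_terms, data$ann))
  paths$candidates <- out("candidates.tsv")
  cand_df <- do.call(rbind, c(
    lapply(names(candidates$candidates), function(lab)
      if (length(candidates$candidates[[lab]]))
        data.frame(set = lab, gene_id = candidates$candidates[[lab]],
                   stringsAsFactors = FALSE)),
    list(if (length(candidates$overlap))
      data.frame(set = "overlap", gene_id = candidates$overlap,
                 stringsAsFactors = FALSE))))
  if (is.null(cand_df))
    cand_df <- data.frame(set = character(), gene_id = character())
  write_tsv(cand_df, paths$candidates)
  network_genes <- candidates$overlap
  if (length(network_genes) < 2)
    stop_stats("fewer than 2 overlap genes; cannot build networks")

  # stage 5: networks ------------------------------------------------------
  nets <- stage("networks", {
    labs <- c(config$control_label, config$perturbation_labels)
    lapply(stats::setNames(nm = labs), function(lab)
      build_network(data$em, lab, genes = network_genes,
                    edge_fdr_alpha = config$edge_fdr))
  })
  for (lab in names(nets)) {
    paths[[paste0("network_", lab)]] <- out(sprintf("network_%s.tsv", lab))
    write_network(nets[[lab]], paths[[paste0("network_", lab)]])
  }

  # stage 6: degrees, k-cores, hubs ----------------------------------------
  hubs <- stage("hubs", {
    deg_tables <- lapply(stats::setNames(nm = config$perturbation_labels),
                         function(lab)
                           dif_degree(nets[[config$control_label]], nets[[lab]]))
    for (lab in names(deg_tables)) {
      cores_c <- k_core_decomposition(nets[[config$control_label]])
      cores_p <- k_core_decomposition(nets[[lab]])
      tb <- deg_tables[[lab]]
      tb$core_control <- as.integer(cores_c[tb$gene_id])
      tb$core_perturbed <- as.integer(cores_p[tb$gene_id])
      deg_tables[[lab]] <- tb
      paths[[paste0("degrees_", lab)]] <- out(sprintf("degrees_%s.tsv", lab))
      write_tsv(tb, paths[[paste0("degrees_", lab)]])
    }
    list(tables = deg_tables,
         selection = select_hubs(deg_tables, config$dif_threshold))
  })
  paths$hubs <- out("core_regulators.tsv")
  write_tsv(data.frame(gene_id = hubs$selection$core_regulators,
                       stringsAsFactors = FALSE), paths$hubs)

  report <- structure(list(
    package_version = as.character(utils::packageVersion("coexhub")),
    seed = config$seed,
    parameters = config[c("control_label", "perturbation_labels", "de_alpha",
                          "de_fold", "term_alpha", "edge_fdr",
                          "dif_threshold")],
    focus_terms = focus_terms,
    counts = list(
      genes = nrow(data$em$values),
      samples = ncol(data$em$values),
      de_up = vapply(de_tables, function(tb) sum(tb$status == "up"), 1L),
      de_down = vapply(de_tables, function(tb) sum(tb$status == "down"), 1L),
      enriched_terms = vapply(significant_terms, length, 1L),
      candidates = vapply(candidates$candidates, length, 1L),
      overlap = length(candidates$overlap),
      edges = vapply(nets, function(n) nrow(n$edges), 1L),
      hubs = vapply(hubs$selection$selected, length, 1L),
      core_regulators = length(hubs$selection$core_regulators)),
    core_regulators = hubs$selection$core_regulators,
    hub_selection = hubs$selection,
    truth = data$truth,
    paths = paths), class = "run_report")
  paths$report <- out("run_report.json")
  writable <- report[setdiff(names(report), c("hub_selection", "truth", "paths"))]
  jsonlite::write_json(writable, paths$report, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  report$paths <- paths
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("coexhub run report (seed", x$seed, ")\n")
  cat("  DE up/down:", paste(sprintf("%s %d/%d", names(x$counts$de_up),
                                     x$counts$de_up, x$counts$de_down),
                             collapse = ", "), "\n")
  cat("  enriched terms:", paste(sprintf("%s %d", names(x$counts$enriched_terms),
                                         x$counts$enriched_terms),
                                 collapse = ", "), "\n")
  cat("  candidate overlap:", x$counts$overlap, "genes\n")
  cat("  network edges:", paste(sprintf("%s %d", names(x$counts$edges),
                                        x$counts$edges), collapse = ", "), "\n")
  cat("  core regulators:", paste(x$core_regulators, collapse = ", "), "\n")
  invisible(x)
}
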