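# Plain-text readers/writers for the pipeline's interchange formats:
# expression matrices (TSV, first column gene id), sample->condition maps,
# GMT gene-set files, network edge lists and dif-degree tables.

#' Read / write an expression matrix as tab-separated text
#'
#' The matrix file has a header row of sample ids (first column `gene_id`)
#' and one row per gene; the companion condition map is two tab-separated
#' columns `sample_id`, `condition` with a header.
#'
#' @param path Matrix file path.
#' @param condition_path Condition-map file path (defaults to
#'   `<path>.conditions.tsv` next to the matrix).
#' @param em An [expr_matrix()] (writer).
#' @return An `expr_matrix` (reader); `path` invisibly (writer).
#' @export
read_expression <- function(path, condition_path = default_condition_path(path)) {
  lines <- read_lines_checked(path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(header) < 2)
    stop_io(path, ": header must contain gene_id plus at least one sample")
  samples <- header[-1]
  n_col <- length(header)
  body <- lines[-1]
  if (length(body) == 0) stop_io(path, ": no gene rows")
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != n_col)
  if (length(bad))
    stop_io(path, ": line ", bad[1] + 1L, " has ", lengths(parts)[bad[1]],
            " fields, expected ", n_col)
  genes <- vapply(parts, `[[`, "", 1L)
  vals <- matrix(NA_real_, nrow = length(genes), ncol = length(samples),
                 dimnames = list(genes, samples))
  for (i in seq_along(parts)) {
    v <- suppressWarnings(as.numeric(parts[[i]][-1]))
    if (anyNA(v))
      stop_io(path, ": non-numeric expression value on line ", i + 1L)
    vals[i, ] <- v
  }
  cond <- read_condition_map(condition_path)
  missing <- setdiff(samples, names(cond))
  if (length(missing))
    stop_io(condition_path, ": no condition for sample(s) ",
            paste(utils::head(missing, 5), collapse = ", "))
  expr_matrix(vals, cond[samples])
}

#' @rdname read_expression
#' @export
write_expression <- function(em, path,
                             condition_path = default_condition_path(path)) {
  stopifnot(inherits(em, "expr_matrix"))
  header <- paste(c("gene_id", colnames(em$values)), collapse = "\t")
  rows <- vapply(seq_len(nrow(em$values)), function(i)
    paste(c(rownames(em$values)[i],
            format_num(em$values[i, ])), collapse = "\t"), "")
  writeLines(c(header, rows), path)
  writeLines(c("sample_id\tcondition",
               paste(names(em$conditions), em$conditions, sep = "\t")),
             condition_path)
  invisible(path)
}

default_condition_path <- function(path)
  paste0(sub("\\.tsv$", "", path), ".conditions.tsv")

read_condition_map <- function(path) {
  lines <- read_lines_checked(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2)
  if (length(bad))
    stop_io(path, ": line ", bad[1], " does not have 2 tab-separated fields")
  if (identical(tolower(parts[[1]][1]), "sample_id")) parts <- parts[-1]
  stats::setNames(vapply(parts, `[[`, "", 2L), vapply(parts, `[[`, "", 1L))
}

#' Read / write GMT gene-set files
#'
#' Standard GMT: one term per line, tab-separated
#' `term_id, description, gene, gene, ...`.
#'
#' @param path File path.
#' @param universe Optional gene universe passed to [annotation_map()]
#'   (reader; defaults to the union of term genes).
#' @param annotations An [annotation_map()] (writer).
#' @return An `annotation_map` (reader); `path` invisibly (writer).
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- read_lines_checked(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad))
    stop_io(path, ": line ", bad[1],
            " has fewer than 3 fields (term, description, genes...)")
  ids <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(ids)) stop_io(path, ": duplicate term ids")
  sets <- stats::setNames(lapply(parts, function(p) p[-(1:2)]), ids)
  nms <- stats::setNames(vapply(parts, `[[`, "", 2L), ids)
  annotation_map(sets, universe = universe, term_names = nms)
}

#' @rdname read_gmt
#' @export
write_gmt <- function(annotations, path) {
  stopifnot(inherits(annotations, "annotation_map"))
  lines <- vapply(names(annotations$sets), function(id)
    paste(c(id, annotations$term_names[[id]], annotations$sets[[id]]),
          collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a co-expression network as a tab-separated edge list
#'
#' Columns `gene_a, gene_b, r, p_value, q_value, sign`; network-level fields
#' (`condition`, `n_samples`, `edge_fdr_alpha`, node list) travel in `#`
#' header comments so the file round-trips.
#'
#' @param net A `coexpression_network` (writer).
#' @param path File path.
#' @return `path` invisibly (writer); a `coexpression_network` (reader).
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "coexpression_network"))
  meta <- c(sprintf("# condition=%s", net$condition),
            sprintf("# n_samples=%d", net$n_samples),
            sprintf("# edge_fdr_alpha=%s", format_num(net$edge_fdr_alpha)),
            sprintf("# nodes=%s", paste(net$nodes, collapse = ",")))
  header <- "gene_a\tgene_b\tr\tp_value\tq_value\tsign"
  rows <- if (nrow(net$edges))
    sprintf("%s\t%s\t%s\t%s\t%s\t%s", net$edges$gene_a, net$edges$gene_b,
            format_num(net$edges$r), format_num(net$edges$p_value),
            format_num(net$edges$q_value), net$edges$sign)
  else character()
  writeLines(c(meta, header, rows), path)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  lines <- read_lines_checked(path)
  meta_lines <- grep("^# ", lines, value = TRUE)
  meta <- stats::setNames(sub("^# [^=]+=", "", meta_lines),
                          sub("^# ([^=]+)=.*$", "\\1", meta_lines))
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0 || body[1] != "gene_a\tgene_b\tr\tp_value\tq_value\tsign")
    stop_io(path, ": missing edge-list header")
  edges <- if (length(body) > 1) {
    parts <- strsplit(body[-1], "\t", fixed = TRUE)
    bad <- which(lengths(parts) != 6)
    if (length(bad)) stop_io(path, ": malformed edge row ", bad[1])
    data.frame(gene_a = vapply(parts, `[[`, "", 1L),
               gene_b = vapply(parts, `[[`, "", 2L),
               r = as.numeric(vapply(parts, `[[`, "", 3L)),
               p_value = as.numeric(vapply(parts, `[[`, "", 4L)),
               q_value = as.numeric(vapply(parts, `[[`, "", 5L)),
               sign = vapply(parts, `[[`, "", 6L),
               stringsAsFactors = FALSE)
  } else {
    data.frame(gene_a = character(), gene_b = character(), r = numeric(),
               p_value = numeric(), q_value = numeric(), sign = character(),
               stringsAsFactors = FALSE)
  }
  structure(list(condition = unname(meta[["condition"]]),
                 nodes = strsplit(meta[["nodes"]], ",", fixed = TRUE)[[1]],
                 edges = edges,
                 n_samples = as.integer(meta[["n_samples"]]),
                 edge_fdr_alpha = as.numeric(meta[["edge_fdr_alpha"]])),
            class = "coexpression_network")
}

#' Export a network to GraphML
#'
#' Minimal GraphML writer (undirected; edge attributes `r`, `q_value`,
#' `sign`) for import into viewers such as Cytoscape or igraph.
#'
#' @param net A `coexpression_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(net, path) {
  stopifnot(inherits(net, "coexpression_network"))
  esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", x, fixed = TRUE),
                          fixed = TRUE)
  nodes <- sprintf('    <node id="%s"/>', esc(net$nodes))
  edges <- if (nrow(net$edges))
    sprintf(paste0('    <edge source="%s" target="%s">',
                   '<data key="r">%s</data><data key="q">%s</data>',
                   '<data key="sign">%s</data></edge>'),
            esc(net$edges$gene_a), esc(net$edges$gene_b),
            format_num(net$edges$r), format_num(net$edges$q_value),
            net$edges$sign)
  else character()
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="r" for="edge" attr.name="r" attr.type="double"/>',
    '  <key id="q" for="edge" attr.name="q" attr.type="double"/>',
    '  <key id="sign" for="edge" attr.name="sign" attr.type="string"/>',
    sprintf('  <graph id="%s" edgedefault="undirected">', esc(net$condition)),
    nodes, edges,
    '  </graph>', '</graphml>'), path)
  invisible(path)
}

# Shared helpers ---------------------------------------------------------

read_lines_checked <- function(path) {
  if (!file.exists(path)) stop_io("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop_io(path, ": empty file")
  lines
}

# Stable numeric formatting so reruns produce byte-identical tables.
format_num <- function(x) {
  out <- formatC(x, digits = 10, format = "g")
  trimws(out)
}

write_tsv <- function(df, path) {
  cols <- lapply(df, function(col) if (is.numeric(col) && !is.integer(col))
    format_num(col) else as.character(col))
  lines <- c(paste(names(df), collapse = "\t"),
             if (nrow(df)) do.call(paste, c(cols, sep = "\t")) else character())
  writeLines(lines, path)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
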