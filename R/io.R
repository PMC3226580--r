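#' Read a GMT gene-set file
#'
#' GMT is the tab-separated gene-set format used by GSEA tools: one set per
#' line, with fields \code{name}, \code{description}, then gene identifiers.
#' Gene identifiers are treated as case-sensitive opaque strings; any
#' identifier mapping (probes, homologs) is assumed to have happened upstream.
#'
#' @param path Path to a GMT file.
#' @return A \code{gene_set_collection}: a list with elements \code{sets}
#'   (named list of character vectors, duplicates within a line collapsed
#'   with order preserved) and \code{description} (named character vector).
#' @details Malformed lines (fewer than three fields), empty sets and
#'   duplicated set names are errors, never silently repaired.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) .hp_stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) .hp_stop("GMT file is empty: ", path)
  sets <- vector("list", length(lines))
  desc <- character(length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      .hp_stop(sprintf("malformed GMT line %d: expected >= 3 tab-separated fields, got %d",
                       lineno[i], length(fields)))
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    genes <- genes[!duplicated(genes)]
    if (length(genes) == 0L)
      .hp_stop(sprintf("GMT line %d defines an empty set '%s'", lineno[i], fields[1]))
    nms[i] <- fields[1]
    desc[i] <- fields[2]
    sets[[i]] <- genes
  }
  if (anyDuplicated(nms))
    .hp_stop("duplicate gene-set name(s) in GMT: ",
             paste(unique(nms[duplicated(nms)]), collapse = ", "))
  names(sets) <- nms
  names(desc) <- nms
  structure(list(sets = sets, description = desc),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sz <- lengths(x$sets)
  cat(sprintf("gene_set_collection: %d sets, gene-set sizes %d-%d (median %g)\n",
              length(x$sets), min(sz), max(sz), stats::median(sz)))
  invisible(x)
}

#' Write a gene-set collection as GMT
#'
#' @param collection A \code{gene_set_collection}.
#' @param path Output path.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$description[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a preranked gene list (RNK)
#'
#' Two tab-separated columns: gene identifier and a signed numeric ranking
#' metric. The list is re-sorted in descending metric order regardless of
#' file order; ties are broken by ascending gene identifier so that the
#' result is fully deterministic.
#'
#' @param path Path to an RNK file.
#' @param condition_id Label attached to the list (defaults to the file name).
#' @return A \code{ranked_list}: data.frame with columns \code{gene},
#'   \code{metric}, attribute \code{condition_id}.
#' @export
read_rnk <- function(path, condition_id = basename(path)) {
  if (!file.exists(path)) .hp_stop("RNK file not found: ", path)
  df <- utils::read.delim(path, header = FALSE, colClasses = "character",
                          col.names = c("gene", "metric"))
  metric <- suppressWarnings(as.numeric(df$metric))
  if (anyNA(metric))
    .hp_stop("non-numeric ranking metric at RNK line(s): ",
             paste(which(is.na(metric)), collapse = ", "))
  if (anyDuplicated(df$gene))
    .hp_stop("duplicate gene id(s) in RNK: ",
             paste(unique(df$gene[duplicated(df$gene)]), collapse = ", "))
  ranked_list(df$gene, metric, condition_id)
}

#' Construct a ranked gene list
#'
#' @param gene Character vector of unique gene identifiers.
#' @param metric Signed numeric ranking metric, one per gene.
#' @param condition_id Label for the originating condition.
#' @return A \code{ranked_list} sorted by descending metric, ties broken by
#'   ascending gene id.
#' @export
ranked_list <- function(gene, metric, condition_id = NA_character_) {
  stopifnot(length(gene) == length(metric))
  if (anyDuplicated(gene)) .hp_stop("duplicate gene ids in ranked list")
  if (any(!is.finite(metric))) .hp_stop("non-finite ranking metric")
  ord <- order(-metric, gene, method = "radix")
  structure(data.frame(gene = as.character(gene)[ord],
                       metric = as.numeric(metric)[ord],
                       stringsAsFactors = FALSE),
            condition_id = condition_id,
            class = c("ranked_list", "data.frame"))
}

#' Write a ranked list as RNK
#' @param ranked A \code{ranked_list}.
#' @param path Output path.
#' @export
write_rnk <- function(ranked, path) {
  stopifnot(inherits(ranked, "ranked_list"))
  utils::write.table(
    data.frame(ranked$gene, sprintf("%.17g", ranked$metric)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a per-condition expression experiment
#'
#' Houses one treated-vs-control contrast: a gene-by-sample matrix of
#' normalized log-ratio expression values plus the sample grouping.
#'
#' @param values Numeric gene x sample matrix with row and column names.
#' @param sample_condition Named character vector mapping every sample
#'   (column) to \code{"treated"} or \code{"control"}.
#' @param condition_id Label for the perturbation condition.
#' @return An \code{expression_experiment} object.
#' @export
expression_experiment <- function(values, sample_condition,
                                  condition_id = NA_character_) {
  if (!is.matrix(values) || !is.numeric(values))
    .hp_stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    .hp_stop("'values' must have gene row names and sample column names")
  samples <- colnames(values)
  if (!all(samples %in% names(sample_condition)))
    .hp_stop("design is missing sample(s): ",
             paste(setdiff(samples, names(sample_condition)), collapse = ", "))
  grp <- unname(sample_condition[samples])
  if (!all(grp %in% c("treated", "control")))
    .hp_stop("sample groups must be 'treated' or 'control'")
  if (sum(grp == "treated") < 2L || sum(grp == "control") < 2L)
    .hp_stop("need >= 2 treated and >= 2 control samples, got ",
             sum(grp == "treated"), " treated / ", sum(grp == "control"),
             " control")
  structure(list(genes = rownames(values), samples = samples,
                 values = values,
                 sample_condition = stats::setNames(grp, samples),
                 condition_id = condition_id),
            class = "expression_experiment")
}

#' @export
print.expression_experiment <- function(x, ...) {
  cat(sprintf("expression_experiment '%s': %d genes, %d treated vs %d control samples\n",
              x$condition_id, length(x$genes),
              sum(x$sample_condition == "treated"),
              sum(x$sample_condition == "control")))
  invisible(x)
}

#' Read a gene x sample expression table
#'
#' @param path TSV with gene ids in the first column and sample ids in the
#'   header row.
#' @param design Named character vector sample -> \code{"treated"} /
#'   \code{"control"} covering every sample in the table.
#' @param condition_id Condition label.
#' @return An \code{expression_experiment}.
#' @export
read_expression_table <- function(path, design, condition_id = basename(path)) {
  if (!file.exists(path)) .hp_stop("expression table not found: ", path)
  df <- utils::read.delim(path, header = TRUE, row.names = 1,
                          check.names = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  expression_experiment(m, design, condition_id)
}

#' Write an expression experiment as TSV
#' @param experiment An \code{expression_experiment}.
#' @param path Output path.
#' @export
write_expression_table <- function(experiment, path) {
  stopifnot(inherits(experiment, "expression_experiment"))
  .write_tsv_matrix(experiment$values, path, id_col = "gene")
  invisible(path)
}

# full-precision TSV matrix writer shared by write_matrix and friends
.write_tsv_matrix <- function(x, path, id_col = "id") {
  header <- paste(c(id_col, colnames(x)), collapse = "\t")
  body <- vapply(seq_len(nrow(x)), function(i) {
    v <- x[i, ]
    s <- ifelse(is.na(v), "NA", sprintf("%.17g", v))
    paste(c(rownames(x)[i], s), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
}

#' Write / read a rectangular named numeric matrix
#'
#' Persists pathway-by-condition matrices (NES, nominal p, PCC) as TSV with
#' \code{NA} marking missing cells. Values are written with 17 significant
#' digits so that \code{read_matrix(write_matrix(x))} reproduces \code{x}
#' bit for bit.
#'
#' @param x Numeric matrix with row and column names; must be non-empty.
#' @param path File path.
#' @return \code{write_matrix} returns the path invisibly;
#'   \code{read_matrix} returns the matrix.
#' @export
write_matrix <- function(x, path) {
  if (!is.matrix(x) || nrow(x) < 1L || ncol(x) < 1L)
    .hp_stop("matrix to write must be non-empty")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    .hp_stop("matrix must have row and column names")
  .write_tsv_matrix(x, path)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) .hp_stop("matrix file not found: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "",
                            blank.lines.skip = FALSE)
  if (length(nf) < 2L) .hp_stop("matrix file has no data rows: ", path)
  if (length(unique(nf)) != 1L)
    .hp_stop("ragged rows in matrix file (field counts ",
             paste(unique(nf), collapse = ", "), "): ", path)
  df <- utils::read.delim(path, header = TRUE, row.names = 1,
                          check.names = FALSE, colClasses = "character",
                          na.strings = character(0))
  m <- matrix(NA_real_, nrow(df), ncol(df),
              dimnames = list(rownames(df), colnames(df)))
  for (j in seq_len(ncol(df))) {
    col <- df[[j]]
    miss <- col == "NA"
    v <- suppressWarnings(as.numeric(col))
    if (any(is.na(v) & !miss))
      .hp_stop("non-numeric value in matrix column '", colnames(df)[j], "'")
    v[miss] <- NA_real_
    m[, j] <- v
  }
  m
}

#' Export a pathway network
#'
#' Writes either a tab-separated edge list (columns \code{source},
#' \code{target}, \code{pcc}, \code{sign}, \code{p}) or GraphML carrying
#' the node attributes (significant-response count, responsiveness class,
#' degree, hub flag, group label) alongside the signed weighted edges.
#'
#' @param network A \code{pathway_network} (see \code{\link{build_network}}).
#' @param path Output path.
#' @param format \code{"edgelist"} or \code{"graphml"}.
#' @export
export_network <- function(network, path, format = c("edgelist", "graphml")) {
  stopifnot(inherits(network, "pathway_network"))
  format <- match.arg(format)
  ed <- network$edges
  if (format == "edgelist") {
    lines <- paste(c("source\ttarget\tpcc\tsign\tp"),
                   collapse = "")
    if (nrow(ed) > 0L) {
      body <- sprintf("%s\t%s\t%.17g\t%s\t%.17g", ed$from, ed$to, ed$pcc,
                      ifelse(ed$sign > 0, "+", "-"), ed$p)
      lines <- c(lines, body)
    }
    writeLines(lines, path)
  } else {
    g <- .network_igraph(network)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

.network_igraph <- function(network) {
  nodes <- data.frame(name = network$pathways,
                      degree = as.integer(network$degree),
                      stringsAsFactors = FALSE)
  if (!is.null(network$n_significant))
    nodes$n_significant <- as.integer(network$n_significant)
  if (!is.null(network$klass)) nodes$klass <- as.character(network$klass)
  if (!is.null(network$hub)) nodes$hub <- as.logical(network$hub)
  if (!is.null(network$group)) nodes$group <- as.character(network$group)
  ed <- network$edges
  edges <- data.frame(from = ed$from, to = ed$to, pcc = ed$pcc,
                      sign = ifelse(ed$sign > 0, "+", "-"), p = ed$p,
                      stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
}

#' Pathway x condition NES matrix with its nominal-p mask
#'
#' The central "meta-activity" container: normalized enrichment scores per
#' pathway and condition, the matching nominal p-values, and the
#' significance level used downstream. A missing NES cell (pathway not
#' testable in that condition, e.g. fewer than \code{min_size} mapped
#' genes) is \code{NA} in both matrices; 0 is a meaningful NES and never
#' encodes missingness.
#'
#' @param nes Numeric pathway x condition matrix (dimnames required).
#' @param p Same-shape matrix of nominal p-values.
#' @param alpha Significance level for calling a response (default 0.05).
#' @return An object of class \code{nes_matrix}.
#' @export
nes_matrix <- function(nes, p, alpha = 0.05) {
  if (!is.matrix(nes) || !is.matrix(p)) .hp_stop("'nes' and 'p' must be matrices")
  if (!identical(dim(nes), dim(p)))
    .hp_stop("NES and p matrices must have identical shape")
  if (is.null(rownames(nes)) || is.null(colnames(nes)))
    .hp_stop("NES matrix needs pathway row names and condition column names")
  if (!identical(dimnames(nes), dimnames(p)))
    .hp_stop("NES and p dimnames must agree")
  if (!identical(is.na(nes), is.na(p)))
    .hp_stop("missing NES cells must match missing p cells")
  ok <- is.finite(p)
  if (any(p[ok] < 0 | p[ok] > 1)) .hp_stop("p-values must lie in [0, 1]")
  .hp_check_number(alpha, "alpha", lower = 0, upper = 1, strict_lower = TRUE)
  structure(list(nes = nes, p = p, alpha = alpha,
                 pathways = rownames(nes), conditions = colnames(nes)),
            class = "nes_matrix")
}

#' @export
print.nes_matrix <- function(x, ...) {
  cat(sprintf("nes_matrix: %d pathways x %d conditions, alpha = %g, %d missing cells, %d significant cells\n",
              nrow(x$nes), ncol(x$nes), x$alpha, sum(is.na(x$nes)),
              sum(x$p < x$alpha, na.rm = TRUE)))
  invisible(x)
}

#' Read / write an NES matrix plus its p matrix
#'
#' @param nes_path,p_path TSV paths as produced by \code{\link{write_matrix}}.
#' @param alpha Significance level to attach.
#' @export
read_nes_matrix <- function(nes_path, p_path, alpha = 0.05) {
  nes_matrix(read_matrix(nes_path), read_matrix(p_path), alpha)
}

#' @param x An \code{nes_matrix}.
#' @rdname read_nes_matrix
#' @export
write_nes_matrix <- function(x, nes_path, p_path) {
  stopifnot(inherits(x, "nes_matrix"))
  write_matrix(x$nes, nes_path)
  write_matrix(x$p, p_path)
  invisible(c(nes = nes_path, p = p_path))
}
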