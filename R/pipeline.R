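#' Run the full analysis pipeline with a manifest
#'
#' Orchestrates simulate (optional) -> rank -> enrich -> responsiveness ->
#' network -> anti-correlation over a set of expression experiments, writing
#' every intermediate artifact (RNK lists, NES and p matrices,
#' responsiveness and NPC tables, network exports, anti-correlation table)
#' plus a JSON manifest recording the configuration, seed and an MD5 hash
#' of each output. Re-running with the same inputs and seed reproduces
#' identical hashes; per-condition random streams are derived from the
#' root seed and the condition label, so results do not depend on
#' execution order.
#'
#' @param experiments Named list of \code{\link{expression_experiment}}s,
#'   or \code{NULL} when \code{resume_nes} is given.
#' @param collection A \code{gene_set_collection}, or \code{NULL} when
#'   resuming.
#' @param out_dir Output directory (created if needed).
#' @param config A \code{\link{pipeline_config}}.
#' @param resume_nes,resume_p Paths to previously written NES / p matrices;
#'   when supplied the rank and enrich stages are skipped.
#' @param anchor,manual_seeds Passed to \code{\link{hub_analysis}}.
#' @param verbose Log per-stage counts.
#' @return The \code{\link{hub_analysis}} object, invisibly, with
#'   attribute \code{manifest} (path).
#' @export
run_full <- function(experiments = NULL, collection = NULL, out_dir,
                     config = pipeline_config(), resume_nes = NULL,
                     resume_p = NULL, anchor = NULL, manual_seeds = NULL,
                     verbose = TRUE) {
  config <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  outputs <- character(0)
  add_out <- function(p) outputs <<- c(outputs, p)

  if (!is.null(resume_nes)) {
    if (is.null(resume_p)) .hp_stop("'resume_p' required with 'resume_nes'")
    say("[resume] loading NES matrix, skipping rank/enrich stages")
    nm <- read_nes_matrix(resume_nes, resume_p, alpha = config$alpha)
  } else {
    if (is.null(experiments) || is.null(collection))
      .hp_stop("need experiments + collection, or resume_nes/resume_p")
    if (is.null(names(experiments)) || anyDuplicated(names(experiments)))
      .hp_stop("experiments must have unique condition names")
    per_cond <- vector("list", length(experiments))
    names(per_cond) <- names(experiments)
    for (cond in names(experiments)) {
      ranked <- tryCatch(
        build_ranked_list(experiments[[cond]], var_equal = config$var_equal,
                          p_floor = config$p_floor),
        error = function(e) .hp_stop("stage 'rank' failed for '", cond,
                                     "': ", conditionMessage(e)))
      rnk_path <- file.path(out_dir, paste0(cond, ".rnk"))
      write_rnk(ranked, rnk_path); add_out(rnk_path)
      per_cond[[cond]] <- tryCatch(
        enrich_collection(ranked, collection, min_size = config$min_size,
                          n_perm = config$n_perm, weight = config$weight,
                          seed = derive_seed(config$seed, "enrich", cond)),
        error = function(e) .hp_stop("stage 'enrich' failed for '", cond,
                                     "': ", conditionMessage(e)))
      say("[enrich] %s: %d genes ranked, %d sets tested, %d skipped",
          cond, nrow(ranked), nrow(per_cond[[cond]]$results),
          length(per_cond[[cond]]$skipped))
    }
    nm <- build_nes_matrix(per_cond, alpha = config$alpha)
  }
  paths <- write_nes_matrix(nm, file.path(out_dir, "nes.tsv"),
                            file.path(out_dir, "nominal_p.tsv"))
  add_out(paths[["nes"]]); add_out(paths[["p"]])

  fit <- tryCatch(
    hub_analysis(nm, config, anchor = anchor, manual_seeds = manual_seeds),
    error = function(e) .hp_stop("stage 'analysis' failed: ",
                                 conditionMessage(e)))

  f <- file.path(out_dir, "responsiveness.tsv")
  utils::write.table(fit$responsiveness, f, sep = "\t", quote = FALSE,
                     row.names = FALSE); add_out(f)
  f <- file.path(out_dir, "npc_curve.tsv")
  utils::write.table(fit$npc_curve, f, sep = "\t", quote = FALSE,
                     row.names = FALSE); add_out(f)
  write_matrix(fit$network$pcc, file.path(out_dir, "pcc.tsv"))
  add_out(file.path(out_dir, "pcc.tsv"))
  write_matrix(fit$network$pcc_p, file.path(out_dir, "pcc_p.tsv"))
  add_out(file.path(out_dir, "pcc_p.tsv"))
  export_network(fit$network, file.path(out_dir, "edges.tsv"), "edgelist")
  add_out(file.path(out_dir, "edges.tsv"))
  export_network(fit$network, file.path(out_dir, "network.graphml"), "graphml")
  add_out(file.path(out_dir, "network.graphml"))
  node_tab <- data.frame(pathway = fit$network$pathways,
                         n_significant = unname(fit$network$n_significant),
                         klass = fit$network$klass,
                         degree = unname(fit$network$degree),
                         hub = unname(fit$network$hub),
                         group = if (is.null(fit$network$group)) "none"
                                 else fit$network$group,
                         stringsAsFactors = FALSE)
  f <- file.path(out_dir, "nodes.tsv")
  utils::write.table(node_tab, f, sep = "\t", quote = FALSE,
                     row.names = FALSE); add_out(f)
  if (!is.null(fit$anticorrelation)) {
    f <- file.path(out_dir, "anticorrelation.tsv")
    utils::write.table(fit$anticorrelation, f, sep = "\t", quote = FALSE,
                       row.names = FALSE); add_out(f)
  }
  say("[network] %d edges, %d hubs; [anticorr] %s",
      nrow(fit$network$edges), sum(fit$hubs),
      if (is.null(fit$anticorrelation)) "skipped"
      else sprintf("%d seeds, %d anti-correlated", nrow(fit$seeds),
                   sum(fit$anticorrelation$anti_correlated)))

  manifest <- list(config = unclass(config), seed = config$seed,
                   outputs = as.list(stats::setNames(
                     unname(tools::md5sum(outputs)), basename(outputs))))
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  attr(fit, "manifest") <- mpath
  invisible(fit)
}

#' Render the meta-activity heatmap
#'
#' Plots the NES matrix as a sign-colored heatmap: red for activation,
#' blue for suppression, saturated where the response is significant,
#' neutral grey where missing. Rows are ordered Group A, Group B, then
#' unassigned pathways. The exact plotted values are also written as TSV
#' when \code{tsv} is given.
#'
#' @param x An \code{\link{nes_matrix}}.
#' @param groups Optional list with elements \code{A} and \code{B}.
#' @param file Optional PNG path; when \code{NULL}, draws on the active
#'   device.
#' @param tsv Optional path for the plotted value matrix.
#' @return Invisibly, the row-ordered NES matrix that was plotted.
#' @export
render_meta_activity <- function(x, groups = NULL, file = NULL, tsv = NULL) {
  stopifnot(inherits(x, "nes_matrix"))
  ord <- x$pathways
  if (!is.null(groups))
    ord <- c(intersect(ord, groups$A), intersect(ord, groups$B),
             setdiff(ord, c(groups$A, groups$B)))
  m <- x$nes[ord, , drop = FALSE]
  p <- x$p[ord, , drop = FALSE]
  # color codes: 0 missing, 1/2 weak/strong suppression, 3/4 weak/strong activation
  code <- matrix(0L, nrow(m), ncol(m))
  sig <- !is.na(p) & p < x$alpha
  code[!is.na(m) & m < 0] <- 1L
  code[!is.na(m) & m < 0 & sig] <- 2L
  code[!is.na(m) & m >= 0] <- 3L
  code[!is.na(m) & m >= 0 & sig] <- 4L
  pal <- c("grey85", "#9db8d9", "#1f4e9c", "#e3a6a1", "#b2182b")
  if (!is.null(file)) {
    grDevices::png(file, width = 120 + 14 * ncol(m),
                   height = 120 + 12 * nrow(m))
    on.exit(grDevices::dev.off())
  }
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)),
                  t(code[rev(seq_len(nrow(m))), , drop = FALSE]),
                  col = pal, zlim = c(0, 4), axes = FALSE,
                  xlab = "condition", ylab = "")
  graphics::axis(1, seq_len(ncol(m)), colnames(m), las = 2, cex.axis = 0.6)
  graphics::axis(2, seq_len(nrow(m)), rev(rownames(m)), las = 2,
                 cex.axis = 0.6)
  if (!is.null(tsv)) write_matrix(m, tsv)
  invisible(m)
}

#' Reproduce the published network statistics from a z-scored NES matrix
#'
#' Given a file holding an already z-scored pathway-by-condition NES
#' matrix (and optionally the matching nominal-p matrix plus
#' responsiveness counts), computes the summary statistics reported for
#' the original 189-pathway, 43-condition study: mean connectivity
#' degree, number of highly connected pathways (degree >= 10), number of
#' hubs and the percentage of HR pathways. Because the source texts
#' disagree on the correlation p filter, both p < 0.001 and p < 0.0001
#' are reported.
#'
#' @param zscored_nes_path TSV of z-scored NES values (\code{NA} missing).
#' @param p_path Optional TSV of nominal enrichment p-values; required
#'   for hub and HR statistics.
#' @param alpha,min_overlap,r_min,theta_resp,theta_deg As in
#'   \code{\link{pipeline_config}}.
#' @return data.frame with one row per correlation p filter:
#'   \code{p_max}, \code{mean_degree}, \code{n_highly_connected},
#'   \code{n_hubs}, \code{pct_hr}.
#' @export
reproduce_published_network <- function(zscored_nes_path, p_path = NULL,
                                        alpha = 0.05, min_overlap = 10,
                                        r_min = 0.5, theta_resp = 10,
                                        theta_deg = 10) {
  z <- read_matrix(zscored_nes_path)
  counts <- NULL
  if (!is.null(p_path)) {
    pm <- read_matrix(p_path)
    counts <- stats::setNames(
      as.integer(rowSums(pm < alpha, na.rm = TRUE)), rownames(pm))
  }
  pc <- pearson_with_p(z, min_overlap = min_overlap)
  out <- lapply(c(1e-3, 1e-4), function(pmax) {
    net <- build_network(pc$pcc, pc$p, r_min = r_min, p_max = pmax)
    n_hubs <- NA_integer_; pct_hr <- NA_real_
    if (!is.null(counts)) {
      hubs <- identify_hubs(counts[net$pathways], net$degree,
                            theta_resp, theta_deg)
      n_hubs <- sum(hubs)
      pct_hr <- 100 * mean(counts[net$pathways] >= theta_resp)
    }
    data.frame(p_max = pmax, mean_degree = mean(net$degree),
               n_highly_connected = sum(net$degree >= theta_deg),
               n_hubs = n_hubs, pct_hr = pct_hr)
  })
  do.call(rbind, out)
}
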