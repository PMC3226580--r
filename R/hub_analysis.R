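#' Hub pathway analysis of a meta-activity matrix
#'
#' The core estimator of the package. Starting from a pathway-by-condition
#' NES matrix with its nominal-p mask, it (i) counts significant responses
#' and classifies responsiveness (HR/MR/LR), (ii) z-scores the matrix
#' condition-wise and computes the pairwise Pearson meta-activity
#' correlation network with its significance filter, (iii) flags hubs as
#' pathways passing both the responsiveness and connectivity thresholds,
#' (iv) attempts the structural-balance bipartition of the signed
#' hub subgraph into Groups A and B, (v) selects seed conditions with an
#' inverted hub profile and (vi) scores every pathway's anti-correlated
#' behavior against those seeds.
#'
#' Steps (v)-(vi) require a balanced hub partition with both groups
#' holding at least \code{min_hubs} hubs and at least one seed condition;
#' otherwise the corresponding components are \code{NULL} and the reason
#' is recorded in \code{$notes}.
#'
#' @param x An \code{\link{nes_matrix}}.
#' @param config A \code{\link{pipeline_config}} holding every threshold.
#' @param anchor Optional pathway name anchoring Group A.
#' @param manual_seeds Optional manually curated seed condition labels.
#' @return An object of class \code{hub_analysis} with components
#'   \code{responsiveness}, \code{npc_curve}, \code{zscored},
#'   \code{network}, \code{hubs}, \code{partition}, \code{groups},
#'   \code{seeds}, \code{anticorrelation}, \code{config}, \code{notes}.
#' @examples
#' cfg <- simulation_config(n_pathways = 40, n_genes = 900,
#'                          n_conditions = 24, n_toxic_conditions = 12,
#'                          n_hubs_A = 4, n_hubs_B = 4,
#'                          background_fraction = 0.7, seed = 7)
#' truth <- simulate_meta_activity(cfg)
#' nm <- simulate_nes_matrix(truth, nes_noise_sd = 0.2)
#' fit <- hub_analysis(nm, pipeline_config(theta_resp = 6, theta_deg = 4,
#'                                         min_overlap = 5, p_max = 1e-3))
#' print(fit)
#' @export
hub_analysis <- function(x, config = pipeline_config(), anchor = NULL,
                         manual_seeds = NULL) {
  stopifnot(inherits(x, "nes_matrix"))
  config <- validate_config(config)
  notes <- character(0)

  resp <- responsiveness_profile(x, config$theta_hr, config$theta_mr)
  counts <- stats::setNames(resp$n_significant, resp$pathway)
  curve <- npc_curve(counts, length(x$conditions))

  z <- zscore_by_condition(x)
  pc <- pearson_with_p(z, min_overlap = config$min_overlap)
  net <- build_network(pc$pcc, pc$p, r_min = config$r_min,
                       p_max = config$p_max)
  net$n_significant <- counts[net$pathways]
  net$klass <- as.character(stats::setNames(resp$klass, resp$pathway)[net$pathways])
  hubs <- identify_hubs(counts, net$degree, config$theta_resp,
                        config$theta_deg)
  net$hub <- hubs[net$pathways]

  partition <- NULL; groups <- NULL; seeds <- NULL; anticorr <- NULL
  hub_names <- names(hubs)[hubs]
  if (length(hub_names) == 0L) {
    notes <- c(notes, "no hub pathway passes both thresholds")
  } else {
    partition <- partition_signed(net, hub_names, anchor = anchor)
    if (!partition$balanced) {
      notes <- c(notes, sprintf(
        "hub subnetwork is not structurally balanced: %d frustrated edge(s)",
        nrow(partition$frustrated)))
    } else {
      groups <- list(A = names(partition$groups)[partition$groups == "A"],
                     B = names(partition$groups)[partition$groups == "B"])
      net$group <- ifelse(net$pathways %in% groups$A, "A",
                          ifelse(net$pathways %in% groups$B, "B", "none"))
      if (length(groups$A) < config$min_hubs ||
          length(groups$B) < config$min_hubs) {
        notes <- c(notes, sprintf(
          "a hub group is below min_hubs = %d (A: %d, B: %d); seed scoring skipped",
          config$min_hubs, length(groups$A), length(groups$B)))
      } else {
        seeds <- tryCatch(
          select_seed_conditions(x, groups, min_hubs = config$min_hubs,
                                 manual = manual_seeds),
          error = function(e) { notes <<- c(notes, conditionMessage(e)); NULL })
        if (!is.null(seeds)) {
          anticorr <- assign_groups(score_pathways(x, seeds),
                                    min_group_score = config$min_group_score,
                                    anti_threshold = config$anti_threshold)
        }
      }
    }
  }
  structure(list(responsiveness = resp, npc_curve = curve, zscored = z,
                 network = net, hubs = hubs, partition = partition,
                 groups = groups, seeds = seeds, anticorrelation = anticorr,
                 nes = x, config = config, notes = notes,
                 call = match.call()),
            class = "hub_analysis")
}

#' @export
print.hub_analysis <- function(x, ...) {
  cat("Hub pathway analysis\n")
  cat(sprintf("  %d pathways x %d conditions (alpha = %g)\n",
              length(x$nes$pathways), length(x$nes$conditions), x$nes$alpha))
  tab <- table(x$responsiveness$klass)
  cat(sprintf("  responsiveness: %d HR / %d MR / %d LR\n",
              tab[["HR"]], tab[["MR"]], tab[["LR"]]))
  cat(sprintf("  network: %d edges (%d negative), mean degree %.2f\n",
              nrow(x$network$edges), sum(x$network$edges$sign < 0),
              mean(x$network$degree)))
  cat(sprintf("  hubs: %d", sum(x$hubs)))
  if (!is.null(x$groups))
    cat(sprintf(" (Group A: %d, Group B: %d)", length(x$groups$A),
                length(x$groups$B)))
  cat("\n")
  if (!is.null(x$anticorrelation)) {
    ac <- x$anticorrelation
    cat(sprintf("  seeds: %d conditions; anti-correlated pathways: %d (A: %d, B: %d)\n",
                nrow(x$seeds), sum(ac$anti_correlated),
                sum(ac$anti_correlated & ac$assigned_group == "A"),
                sum(ac$anti_correlated & ac$assigned_group == "B")))
  }
  for (n in x$notes) cat("  note: ", n, "\n", sep = "")
  invisible(x)
}

#' @export
summary.hub_analysis <- function(object, ...) {
  out <- list(
    n_pathways = length(object$nes$pathways),
    n_conditions = length(object$nes$conditions),
    class_counts = table(object$responsiveness$klass),
    n_edges = nrow(object$network$edges),
    n_negative_edges = sum(object$network$edges$sign < 0),
    mean_degree = mean(object$network$degree),
    hubs = names(object$hubs)[object$hubs],
    groups = object$groups,
    n_seeds = if (is.null(object$seeds)) 0L else nrow(object$seeds),
    anticorrelated = if (is.null(object$anticorrelation)) NULL else
      object$anticorrelation[object$anticorrelation$anti_correlated, ,
                             drop = FALSE],
    notes = object$notes)
  class(out) <- "summary.hub_analysis"
  out
}

#' @export
print.summary.hub_analysis <- function(x, ...) {
  cat(sprintf("%d pathways x %d conditions; mean degree %.2f; %d hubs\n",
              x$n_pathways, x$n_conditions, x$mean_degree, length(x$hubs)))
  if (!is.null(x$groups)) {
    cat("Group A hubs:", paste(x$groups$A, collapse = ", "), "\n")
    cat("Group B hubs:", paste(x$groups$B, collapse = ", "), "\n")
  }
  if (!is.null(x$anticorrelated) && nrow(x$anticorrelated) > 0L) {
    cat(sprintf("%d anti-correlated pathways over %d seed conditions:\n",
                nrow(x$anticorrelated), x$n_seeds))
    print(x$anticorrelated[, c("pathway", "a_score", "b_score", "n",
                               "anti_score", "assigned_group")],
          row.names = FALSE)
  }
  for (n in x$notes) cat("note: ", n, "\n", sep = "")
  invisible(x)
}

#' Plot a hub analysis
#'
#' \code{which = "hubs"} draws the responsiveness-versus-connectivity
#' scatter with hubs highlighted; \code{which = "npc"} draws the NPC
#' curve with the percentage-of-pathways overlay used to choose the
#' responsiveness cutoffs.
#'
#' @param x A \code{hub_analysis}.
#' @param which \code{"hubs"} or \code{"npc"}.
#' @param ... Passed to the underlying plot call.
#' @export
plot.hub_analysis <- function(x, which = c("hubs", "npc"), ...) {
  which <- match.arg(which)
  if (which == "hubs") {
    counts <- stats::setNames(x$responsiveness$n_significant,
                              x$responsiveness$pathway)
    deg <- x$network$degree[names(counts)]
    col <- ifelse(x$hubs[names(counts)], "red3", "grey50")
    graphics::plot(counts, deg, col = col, pch = 16,
                   xlab = "significant responses",
                   ylab = "connectivity degree", ...)
    graphics::abline(h = x$config$theta_deg, v = x$config$theta_resp,
                     lty = 2, col = "grey70")
  } else {
    cc <- x$npc_curve
    graphics::plot(cc$theta, cc$npc, type = "b", pch = 16,
                   xlab = "threshold", ylab = "NPC", ...)
    op <- graphics::par(new = TRUE)
    on.exit(graphics::par(op))
    graphics::plot(cc$theta, cc$pct_pathways, type = "l", col = "blue",
                   axes = FALSE, xlab = "", ylab = "")
    graphics::axis(4, col.axis = "blue")
  }
  invisible(x)
}
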