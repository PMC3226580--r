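#' Per-gene two-sample t-test
#'
#' Student's (pooled-variance) two-sided t-test of treated vs control
#' expression values for one gene, with the direction of change taken from
#' the sign of the treated-minus-control mean difference. Welch's unequal
#' variance form is available via \code{var_equal = FALSE}.
#'
#' @param treated,control Numeric vectors, at least 2 finite values each.
#' @param var_equal Pooled-variance test if \code{TRUE} (default).
#' @param p_floor Lower bound applied to the p-value so the downstream
#'   log-metric stays finite (default 1e-16).
#' @return A list with \code{p_value} (in \code{(0, 1]}), \code{t_statistic},
#'   \code{direction} (\code{"up"} or \code{"down"}) and \code{degenerate}
#'   (TRUE when both groups are constant and equal, in which case p = 1 and
#'   direction is reported as "up").
#' @export
gene_t_test <- function(treated, control, var_equal = TRUE, p_floor = 1e-16) {
  if (length(treated) < 2L || length(control) < 2L)
    .hp_stop("need at least 2 values per group")
  if (!all(is.finite(treated)) || !all(is.finite(control)))
    .hp_stop("non-finite expression values")
  n1 <- length(treated); n2 <- length(control)
  m1 <- mean(treated); m2 <- mean(control)
  v1 <- stats::var(treated); v2 <- stats::var(control)
  diff <- m1 - m2
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  degenerate <- FALSE
  if (se == 0) {
    if (diff == 0) {         # both groups constant and identical
      tstat <- 0; p <- 1; degenerate <- TRUE
    } else {                 # constant groups at different levels
      tstat <- sign(diff) * Inf; p <- p_floor
    }
  } else {
    tstat <- diff / se
    p <- max(2 * stats::pt(-abs(tstat), df), p_floor)
  }
  list(p_value = p, t_statistic = tstat,
       direction = if (diff < 0) "down" else "up",
       degenerate = degenerate)
}

#' Signed ranking metric log10(1/P)
#'
#' The metric used to prerank genes for enrichment: \code{log10(1/p)} with
#' a positive sign for up-regulated and negative for down-regulated genes.
#'
#' @param p_value p-value(s) in \code{(0, 1]}.
#' @param direction \code{"up"} or \code{"down"} per gene.
#' @return Signed numeric metric(s).
#' @export
ranking_metric <- function(p_value, direction) {
  if (any(!is.finite(p_value)) || any(p_value <= 0) || any(p_value > 1))
    .hp_stop("p-values must lie in (0, 1]")
  if (!all(direction %in% c("up", "down")))
    .hp_stop("direction must be 'up' or 'down'")
  ifelse(direction == "up", 1, -1) * log10(1 / p_value)
}

# vectorized pooled / Welch t-tests over the rows of a gene x sample matrix
.row_t_tests <- function(values, treated_cols, control_cols,
                         var_equal = TRUE, p_floor = 1e-16) {
  x <- values[, treated_cols, drop = FALSE]
  y <- values[, control_cols, drop = FALSE]
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  diff <- m1 - m2
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep.int(n1 + n2 - 2, length(se))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  p <- ifelse(se == 0, ifelse(diff == 0, 1, 0),
              2 * stats::pt(-abs(diff / ifelse(se == 0, 1, se)), df))
  p <- pmax(p, p_floor)
  list(p = p, direction = ifelse(diff < 0, "down", "up"))
}

#' Rank all genes of an experiment by the signed log10(1/P) metric
#'
#' Runs the per-gene t-test across the experiment and orders genes by
#' descending signed metric; ties (including the all-degenerate metric 0
#' case) fall back to ascending gene identifier, so the output never
#' depends on input row order.
#'
#' @param experiment An \code{\link{expression_experiment}}.
#' @inheritParams gene_t_test
#' @return A \code{\link{ranked_list}} with one entry per gene.
#' @export
build_ranked_list <- function(experiment, var_equal = TRUE, p_floor = 1e-16) {
  stopifnot(inherits(experiment, "expression_experiment"))
  grp <- experiment$sample_condition[experiment$samples]
  tt <- .row_t_tests(experiment$values, which(grp == "treated"),
                     which(grp == "control"), var_equal, p_floor)
  metric <- ranking_metric(tt$p, tt$direction)
  ranked_list(experiment$genes, metric, experiment$condition_id)
}
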