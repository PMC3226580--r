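#' Count significant responses per pathway
#'
#' For each pathway, the number of conditions in which its nominal
#' enrichment p-value falls below the attached significance level.
#' Missing cells (pathway untested in a condition) never count.
#'
#' @param x An \code{\link{nes_matrix}}.
#' @return Named integer vector \code{n_i}, one per pathway.
#' @export
count_significant <- function(x) {
  stopifnot(inherits(x, "nes_matrix"))
  counts <- rowSums(x$p < x$alpha, na.rm = TRUE)
  stats::setNames(as.integer(counts), x$pathways)
}

#' Normalized Pathway Coverage
#'
#' For a response-count threshold \code{theta}, NPC is the mean of
#' \code{n_i / C} over the pathways whose significant-response count
#' \code{n_i} meets the threshold, where \code{C} is the number of
#' conditions. It measures the average fraction of conditions covered by
#' the pathways surviving the threshold and is used to pick
#' responsiveness cutoffs. When no pathway survives, the value is
#' undefined and returned as \code{NA} (not 0: an empty survivor set is
#' not a data point).
#'
#' @param counts Integer vector of per-pathway significant-response counts.
#' @param C Number of conditions (>= 1).
#' @param theta Threshold (>= 0).
#' @return NPC in \code{[theta/C, 1]}, or \code{NA_real_}.
#' @export
npc <- function(counts, C, theta) {
  .hp_check_number(C, "C", lower = 1)
  .hp_check_number(theta, "theta", lower = 0)
  s <- counts[counts >= theta]
  if (length(s) == 0L) return(NA_real_)
  mean(s / C)
}

#' NPC curve over every threshold
#'
#' @inheritParams npc
#' @return data.frame with one row per \code{theta} in \code{0..C}:
#'   \code{theta}, \code{npc}, and \code{pct_pathways} (percentage of
#'   pathways with \code{n_i >= theta}).
#' @export
npc_curve <- function(counts, C) {
  .hp_check_number(C, "C", lower = 1)
  thetas <- 0:C
  data.frame(
    theta = thetas,
    npc = vapply(thetas, function(th) npc(counts, C, th), numeric(1)),
    pct_pathways = vapply(thetas, function(th) 100 * mean(counts >= th),
                          numeric(1)))
}

#' Classify pathway responsiveness
#'
#' High responsive (HR): at least \code{theta_hr} significant responses;
#' medium (MR): \code{theta_mr} to \code{theta_hr - 1}; low (LR)
#' otherwise. Defaults 10 and 5 match the published cutoffs chosen from
#' the NPC curve.
#'
#' @inheritParams npc
#' @param theta_hr,theta_mr Class thresholds, \code{theta_mr < theta_hr}.
#' @return Factor with levels \code{HR}, \code{MR}, \code{LR}.
#' @export
classify_responsiveness <- function(counts, theta_hr = 10, theta_mr = 5) {
  if (theta_mr >= theta_hr) .hp_stop("'theta_mr' must be below 'theta_hr'")
  klass <- ifelse(counts >= theta_hr, "HR",
                  ifelse(counts >= theta_mr, "MR", "LR"))
  factor(klass, levels = c("HR", "MR", "LR"))
}

#' Per-pathway responsiveness profile
#'
#' @param x An \code{\link{nes_matrix}}.
#' @inheritParams classify_responsiveness
#' @return data.frame: \code{pathway}, \code{n_significant},
#'   \code{n_conditions}, \code{klass}.
#' @export
responsiveness_profile <- function(x, theta_hr = 10, theta_mr = 5) {
  counts <- count_significant(x)
  data.frame(pathway = names(counts),
             n_significant = unname(counts),
             n_conditions = length(x$conditions),
             klass = classify_responsiveness(unname(counts), theta_hr, theta_mr),
             stringsAsFactors = FALSE)
}
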