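#' Consensus activity direction of a hub group in one condition
#'
#' Among the group's hub pathways significant (nominal p below alpha) in
#' the condition, the consensus is the sign of their mean NES. Undefined
#' (\code{NA}) when fewer than \code{min_hubs} hubs are significant or the
#' mean is exactly zero.
#'
#' @param x An \code{\link{nes_matrix}}.
#' @param group_hubs Pathway names forming the hub group.
#' @param condition Condition label.
#' @param min_hubs Minimum significant hubs for a defined consensus
#'   (default 3).
#' @return \code{+1}, \code{-1} or \code{NA_integer_}.
#' @export
consensus_direction <- function(x, group_hubs, condition, min_hubs = 3) {
  stopifnot(inherits(x, "nes_matrix"))
  if (length(group_hubs) == 0L) .hp_stop("empty hub group")
  if (!condition %in% x$conditions) .hp_stop("unknown condition: ", condition)
  if (!all(group_hubs %in% x$pathways))
    .hp_stop("unknown hub pathway(s): ",
             paste(setdiff(group_hubs, x$pathways), collapse = ", "))
  pv <- x$p[group_hubs, condition]
  sig <- !is.na(pv) & pv < x$alpha
  if (sum(sig) < min_hubs) return(NA_integer_)
  d <- sign(mean(x$nes[group_hubs, condition][sig]))
  if (d == 0) return(NA_integer_)
  as.integer(d)
}

#' Select seed conditions showing an inverted hub profile
#'
#' A condition is a seed when the consensus directions of hub Group A and
#' hub Group B are both defined and opposite: the condition exhibits the
#' inverted activity profile that anchors the anti-correlation scoring.
#' A manually curated list of condition labels may be supplied instead and
#' is validated against the matrix.
#'
#' @param x An \code{\link{nes_matrix}}.
#' @param groups List with character elements \code{A} and \code{B}
#'   naming the hub pathways of each group.
#' @param min_hubs Passed to \code{\link{consensus_direction}}.
#' @param manual Optional character vector of condition labels to use
#'   verbatim (consensus directions are still computed and must be
#'   defined and opposite).
#' @return A \code{seed_conditions} data.frame: \code{condition},
#'   \code{dir_A}, \code{dir_B}. An empty seed set is an error.
#' @export
select_seed_conditions <- function(x, groups, min_hubs = 3, manual = NULL) {
  stopifnot(inherits(x, "nes_matrix"))
  if (is.null(groups$A) || is.null(groups$B) ||
      length(groups$A) == 0L || length(groups$B) == 0L)
    .hp_stop("groups A and B must both be non-empty")
  candidates <- x$conditions
  if (!is.null(manual)) {
    unknown <- setdiff(manual, x$conditions)
    if (length(unknown) > 0L)
      .hp_stop("unknown seed condition(s): ", paste(unknown, collapse = ", "))
    candidates <- manual
  }
  da <- vapply(candidates, function(cc)
    as.integer(consensus_direction(x, groups$A, cc, min_hubs)), integer(1))
  db <- vapply(candidates, function(cc)
    as.integer(consensus_direction(x, groups$B, cc, min_hubs)), integer(1))
  keep <- if (is.null(manual)) !is.na(da) & !is.na(db) & da == -db
          else rep(TRUE, length(candidates))
  if (!is.null(manual)) {
    bad <- candidates[is.na(da) | is.na(db) | da != -db]
    if (length(bad) > 0L)
      .hp_stop("manual seed(s) without opposite defined consensuses: ",
               paste(bad, collapse = ", "))
  }
  out <- data.frame(condition = candidates[keep], dir_A = da[keep],
                    dir_B = db[keep], stringsAsFactors = FALSE,
                    row.names = NULL)
  if (nrow(out) == 0L)
    .hp_stop("no seed condition found: the scoring scheme needs seeds")
  class(out) <- c("seed_conditions", "data.frame")
  out
}

#' Score pathways against the seed conditions
#'
#' For each pathway and each seed condition where it responds
#' significantly, the pathway's NES sign is compared with the group
#' consensus directions there: a match with Group A transfers +1 to
#' A_score and -1 to B_score, a match with Group B does the reverse
#' (the two consensuses are opposite by construction, so every counted
#' response matches exactly one group). \code{n} counts the significant
#' seed responses; the anti-correlation score is
#' \code{max(A_score, B_score) / n}. Pathways with \code{n < 3} get no
#' group assignment regardless of agreement.
#'
#' @param x An \code{\link{nes_matrix}}.
#' @param seeds A \code{\link{select_seed_conditions}} result.
#' @param pathways Pathways to score (default: all in the matrix).
#' @return data.frame: \code{pathway}, \code{a_score}, \code{b_score},
#'   \code{n}, \code{anti_score} (NA when \code{n == 0}).
#' @export
score_pathways <- function(x, seeds, pathways = x$pathways) {
  stopifnot(inherits(x, "nes_matrix"), inherits(seeds, "seed_conditions"))
  conds <- seeds$condition
  dirA <- seeds$dir_A
  nesS <- x$nes[pathways, conds, drop = FALSE]
  pS <- x$p[pathways, conds, drop = FALSE]
  sig <- !is.na(pS) & pS < x$alpha & sign(nesS) != 0
  matchA <- sweep(sign(nesS), 2L, dirA, "==") & sig
  n <- rowSums(sig)
  ka <- rowSums(matchA & sig)
  a_score <- as.integer(2 * ka - n)         # +1 transfer per A match, -1 per B match
  b_score <- -a_score
  anti <- ifelse(n > 0, pmax(a_score, b_score) / n, NA_real_)
  data.frame(pathway = pathways, a_score = a_score, b_score = b_score,
             n = as.integer(n), anti_score = anti, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Assign groups and call anti-correlated pathways
#'
#' A pathway joins Group A when its A_score reaches
#' \code{min_group_score} (equivalently its B_score falls to its
#' negative), Group B symmetrically, and is called anti-correlated when
#' assigned and its anti-correlation score strictly exceeds
#' \code{anti_threshold}.
#'
#' @param scores A \code{\link{score_pathways}} result.
#' @param min_group_score Group assignment bar (default 3).
#' @param anti_threshold Strict anti-correlation bar (default 0.7).
#' @return The input with \code{assigned_group} (\code{"A"}, \code{"B"},
#'   \code{"none"}) and logical \code{anti_correlated} appended.
#' @export
assign_groups <- function(scores, min_group_score = 3, anti_threshold = 0.7) {
  grp <- ifelse(scores$a_score >= min_group_score, "A",
                ifelse(scores$b_score >= min_group_score, "B", "none"))
  grp[scores$n < 3] <- "none"
  anti <- grp != "none" & !is.na(scores$anti_score) &
    scores$anti_score > anti_threshold
  scores$assigned_group <- grp
  scores$anti_correlated <- anti
  scores
}
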