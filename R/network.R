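#' z-score the NES matrix condition-wise
#'
#' Standardizes each condition (column) of the NES matrix over its present
#' cells: subtract the column mean, divide by the column sample (n-1)
#' standard deviation. Makes heterogeneous perturbations comparable before
#' correlating pathways. Missing cells stay missing; a column with fewer
#' than 2 present values or zero variance is set entirely missing with a
#' warning.
#'
#' @param x An \code{\link{nes_matrix}} or a plain numeric matrix.
#' @return A numeric matrix of the same shape.
#' @export
zscore_by_condition <- function(x) {
  m <- if (inherits(x, "nes_matrix")) x$nes else x
  if (!is.matrix(m)) .hp_stop("input must be an nes_matrix or matrix")
  out <- m
  bad <- character(0)
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    ok <- !is.na(v)
    if (sum(ok) < 2L || stats::sd(v[ok]) == 0) {
      out[, j] <- NA_real_
      bad <- c(bad, colnames(m)[j])
      next
    }
    out[ok, j] <- (v[ok] - mean(v[ok])) / stats::sd(v[ok])
  }
  if (length(bad) > 0L)
    warning("condition(s) with <2 values or zero variance set missing: ",
            paste(bad, collapse = ", "))
  out
}

#' Pairwise Pearson correlation with significance
#'
#' Row-by-row Pearson correlation over pairwise-complete columns, with the
#' two-sided p-value for the no-correlation null from
#' \code{t = r * sqrt((n - 2) / (1 - r^2))} on \code{n - 2} degrees of
#' freedom, where \code{n} is the pairwise overlap. Pairs with overlap
#' below \code{min_overlap} (or a constant row over the overlap) are
#' missing.
#'
#' @param m Numeric matrix, rows = pathways, columns = conditions.
#' @param min_overlap Minimum complete pairs for a defined correlation
#'   (default 10).
#' @return List with symmetric matrices \code{pcc} (unit diagonal) and
#'   \code{p} plus \code{n_overlap}.
#' @export
pearson_with_p <- function(m, min_overlap = 10) {
  if (!is.matrix(m) || nrow(m) < 2L) .hp_stop("need a matrix with >= 2 rows")
  if (min_overlap < 3) .hp_stop("'min_overlap' must be >= 3")
  present <- !is.na(m)
  n <- tcrossprod(present * 1)             # pairwise overlap counts
  r <- suppressWarnings(stats::cor(t(m), use = "pairwise.complete.obs"))
  r[n < min_overlap] <- NA_real_
  over <- which(!is.na(r) & abs(r) > 1)    # guard fp overshoot
  r[over] <- sign(r[over])
  tt <- r * sqrt(pmax(n - 2, 0) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), pmax(n - 2, 1))
  p[is.na(r)] <- NA_real_
  diag(r) <- 1
  diag(p) <- 0
  dimnames(p) <- dimnames(r) <- list(rownames(m), rownames(m))
  dimnames(n) <- dimnames(r)
  list(pcc = r, p = p, n_overlap = n)
}

#' Build the signed pathway co-activity network
#'
#' Two pathways are functionally connected when the magnitude of their
#' meta-activity correlation strictly exceeds \code{r_min} (default 0.5)
#' and its p-value is below \code{p_max}. Edge sign is the sign of the
#' correlation; degree is the number of incident edges.
#'
#' @param pcc,pcc_p Symmetric matrices from \code{\link{pearson_with_p}}.
#' @param r_min Correlation magnitude threshold (strict, default 0.5).
#' @param p_max Correlation p-value threshold (default 1e-4; 1e-3 is the
#'   common alternative).
#' @return A \code{pathway_network}: pathways, the input matrices, an edge
#'   data.frame (\code{from}, \code{to}, \code{pcc}, \code{sign},
#'   \code{p}) and per-pathway \code{degree}.
#' @export
build_network <- function(pcc, pcc_p, r_min = 0.5, p_max = 1e-4) {
  stopifnot(is.matrix(pcc), identical(dim(pcc), dim(pcc_p)))
  pw <- rownames(pcc)
  np <- nrow(pcc)
  sel <- which(upper.tri(pcc) & !is.na(pcc) & abs(pcc) > r_min &
                 pcc_p < p_max, arr.ind = TRUE)
  edges <- data.frame(from = pw[sel[, 1]], to = pw[sel[, 2]],
                      pcc = pcc[sel], sign = as.integer(sign(pcc[sel])),
                      p = pcc_p[sel], stringsAsFactors = FALSE)
  degree <- stats::setNames(integer(np), pw)
  if (nrow(edges) > 0L) {
    tab <- table(c(edges$from, edges$to))
    degree[names(tab)] <- as.integer(tab)
  }
  structure(list(pathways = pw, pcc = pcc, pcc_p = pcc_p, edges = edges,
                 degree = degree, r_min = r_min, p_max = p_max),
            class = "pathway_network")
}

#' @export
print.pathway_network <- function(x, ...) {
  cat(sprintf("pathway_network: %d pathways, %d edges (%d negative), mean degree %.2f\n",
              length(x$pathways), nrow(x$edges), sum(x$edges$sign < 0),
              mean(x$degree)))
  invisible(x)
}

#' Flag hub pathways
#'
#' A hub is a pathway with both high responsiveness (significant responses
#' in at least \code{theta_resp} conditions) and high connectivity (degree
#' at least \code{theta_deg}); both thresholds default to 10.
#'
#' @param n_significant Named per-pathway significant-response counts.
#' @param degree Named per-pathway degrees over the same universe.
#' @param theta_resp,theta_deg Hub thresholds.
#' @return Named logical vector.
#' @export
identify_hubs <- function(n_significant, degree, theta_resp = 10,
                          theta_deg = 10) {
  pw <- names(n_significant)
  if (is.null(pw) || !setequal(pw, names(degree)))
    .hp_stop("responsiveness and degree must cover the same pathways")
  stats::setNames(unname(n_significant[pw]) >= theta_resp &
                    unname(degree[pw]) >= theta_deg, pw)
}

#' Two-group bipartition of a signed subnetwork
#'
#' Attempts the structural-balance two-coloring of the hub-induced signed
#' graph: a traversal keeps the color across positive edges and flips it
#' across negative edges. If every edge is consistent (the graph is
#' balanced) the two sides are labelled A and B, with A the side
#' containing \code{anchor} (per component; otherwise the larger side,
#' ties to the side holding the lexicographically smallest pathway). If
#' not, the frustrated edges are reported and no labels are assigned.
#'
#' @param network A \code{pathway_network}.
#' @param nodes Pathways to induce the subgraph on (e.g. the hubs).
#' @param anchor Optional pathway name anchoring group A.
#' @return List: \code{balanced} flag, \code{groups} (named "A"/"B"
#'   vector, or \code{NULL} when frustrated), \code{frustrated} (edge
#'   data.frame), \code{components} (membership).
#' @export
partition_signed <- function(network, nodes = network$pathways,
                             anchor = NULL) {
  stopifnot(inherits(network, "pathway_network"))
  nodes <- as.character(nodes)
  if (length(nodes) == 0L) .hp_stop("empty node set for partitioning")
  if (!all(nodes %in% network$pathways))
    .hp_stop("unknown pathway(s) in node set")
  ed <- network$edges
  ed <- ed[ed$from %in% nodes & ed$to %in% nodes, , drop = FALSE]

  color <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  comp <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  nbrs <- function(v) {
    i <- ed$from == v | ed$to == v
    data.frame(other = ifelse(ed$from[i] == v, ed$to[i], ed$from[i]),
               s = ed$sign[i], stringsAsFactors = FALSE)
  }
  frustrated <- ed[0, , drop = FALSE]
  nc <- 0L
  for (start in sort(nodes)) {
    if (!is.na(color[start])) next
    nc <- nc + 1L
    color[start] <- 1L
    comp[start] <- nc
    queue <- start
    while (length(queue) > 0L) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- nbrs(v)
      for (i in seq_len(nrow(nb))) {
        u <- nb$other[i]
        want <- if (nb$s[i] > 0) color[v] else -color[v]
        if (is.na(color[u])) {
          color[u] <- want
          comp[u] <- nc
          queue <- c(queue, u)
        } else if (color[u] != want) {
          frustrated <- rbind(frustrated,
                              ed[(ed$from == v & ed$to == u) |
                                   (ed$from == u & ed$to == v), ,
                                 drop = FALSE])
        }
      }
    }
  }
  frustrated <- unique(frustrated)
  if (nrow(frustrated) > 0L)
    return(list(balanced = FALSE, groups = NULL, frustrated = frustrated,
                components = comp))
  # orient each component: side holding the anchor (or the larger side) is A
  groups <- character(length(nodes))
  names(groups) <- names(color)
  for (k in seq_len(nc)) {
    in_k <- names(comp)[comp == k]
    side1 <- in_k[color[in_k] == 1L]
    side2 <- in_k[color[in_k] == -1L]
    a_side <- if (!is.null(anchor) && anchor %in% in_k) {
      if (anchor %in% side1) side1 else side2
    } else if (length(side1) != length(side2)) {
      if (length(side1) > length(side2)) side1 else side2
    } else if (min(side1) < min(side2)) side1 else side2
    groups[in_k] <- ifelse(in_k %in% a_side, "A", "B")
  }
  list(balanced = TRUE, groups = groups, frustrated = frustrated,
       components = comp)
}
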