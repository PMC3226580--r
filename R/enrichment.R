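#' Running-sum enrichment score
#'
#' Walks down a ranked gene list, increasing a running-sum statistic at
#' members of the gene set and decreasing it at non-members; the enrichment
#' score (ES) is the signed maximum deviation of this weighted
#' Kolmogorov-Smirnov-like random walk from zero. Hit increments at
#' position i are \code{|metric_i|^weight / sum_hits |metric|^weight}
#' (\code{weight = 0} gives the classic equal-increment statistic), miss
#' decrements are \code{1 / (N - n_hits)}. A tie between the largest
#' positive and largest negative deviation resolves to the positive one.
#'
#' @param ranked A \code{\link{ranked_list}}.
#' @param gene_set Character vector of gene identifiers.
#' @param weight Metric exponent, 0 or 1 (default 1, the weighted statistic).
#' @return List with \code{es}, \code{running_sum} (per-position walk) and
#'   \code{n_mapped} (set genes found in the list).
#' @export
enrichment_score <- function(ranked, gene_set, weight = 1) {
  stopifnot(inherits(ranked, "ranked_list"))
  if (!weight %in% c(0, 1)) .hp_stop("'weight' must be 0 or 1")
  N <- nrow(ranked)
  hits <- which(ranked$gene %in% gene_set)
  k <- length(hits)
  if (k == 0L) .hp_stop("set not represented in the ranked list")
  if (k == N) .hp_stop("set covers every ranked gene; miss decrement undefined")
  w <- if (weight == 0) rep.int(1, k) else abs(ranked$metric[hits])
  if (sum(w) == 0) w <- rep.int(1, k)  # all-zero metrics: equal weighting
  incr <- numeric(N)
  incr[hits] <- w / sum(w)
  incr[-hits] <- -1 / (N - k)
  running <- cumsum(incr)
  top <- max(running)
  bot <- min(running)
  es <- if (top >= -bot) top else bot
  list(es = es, running_sum = running, n_mapped = k)
}

# Fast ES for permutations: hit positions are given as a sorted k x m matrix
# of column-sorted positions into abs-metric vector `absw` (already ^weight).
# Uses the piecewise-linear structure of the walk: candidate extrema sit
# immediately after each hit (maxima) and immediately before each hit or at
# the end of the list (minima).
.es_from_positions <- function(pos, absw, N) {
  k <- nrow(pos); m <- ncol(pos)
  wmat <- matrix(absw[pos], k, m)
  W <- apply(wmat, 2L, cumsum)
  if (k == 1L) W <- matrix(W, 1L, m)
  Wk <- W[k, ]
  zero <- Wk == 0
  if (any(zero)) {          # degenerate all-zero metric draw: equal weights
    W[, zero] <- matrix(seq_len(k), k, sum(zero))
    Wk[zero] <- k
  }
  miss <- (pos - seq_len(k)) / (N - k)   # misses seen before i-th hit
  A <- sweep(W, 2L, Wk, "/") - miss      # walk value just after each hit
  Wprev <- rbind(0, W[-k, , drop = FALSE])
  B <- sweep(Wprev, 2L, Wk, "/") - miss  # walk value just before each hit
  top <- apply(A, 2L, max)
  bot <- pmin(apply(B, 2L, min), 0)      # walk ends at exactly 0
  ifelse(top >= -bot, top, bot)
}

#' Permutation null for the enrichment score
#'
#' Enrichment scores of random gene sets of a given size drawn uniformly
#' without replacement from the ranked list (gene-set permutation, the
#' null appropriate to preranked enrichment where no phenotype labels
#' exist). \code{exhaustive = TRUE} enumerates every subset instead, for
#' small-list validation.
#'
#' @param ranked A \code{\link{ranked_list}}.
#' @param set_size Number of genes per null set, in \code{[1, N - 1]}.
#' @param n_perm Number of permutations (ignored when exhaustive).
#' @param weight Metric exponent, 0 or 1.
#' @param seed Optional integer seed for reproducible draws.
#' @param exhaustive Enumerate all \code{choose(N, set_size)} subsets.
#' @return Numeric vector of null enrichment scores.
#' @export
permutation_null <- function(ranked, set_size, n_perm = 1000, weight = 1,
                             seed = NULL, exhaustive = FALSE) {
  stopifnot(inherits(ranked, "ranked_list"))
  N <- nrow(ranked)
  if (set_size < 1L || set_size >= N)
    .hp_stop("'set_size' must be in [1, N - 1]")
  if (!exhaustive && n_perm < 1L) .hp_stop("'n_perm' must be >= 1")
  absw <- if (weight == 0) rep.int(1, N) else abs(ranked$metric)
  if (exhaustive) {
    pos <- utils::combn(N, set_size)
  } else {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
      set.seed(seed)
    }
    pos <- vapply(seq_len(n_perm),
                  function(i) sort.int(sample.int(N, set_size)),
                  integer(set_size))
    if (set_size == 1L) pos <- matrix(pos, 1L)
  }
  .es_from_positions(pos, absw, N)
}

#' Empirical nominal p-value of an observed enrichment score
#'
#' Compares the observed ES with the same-signed portion of the permutation
#' null: \code{p = (1 + #same-sign null with |null| >= |es|) /
#' (1 + #same-sign null)}. The add-one keeps p strictly positive. When the
#' null contains no value of the observed sign the p-value is undefined and
#' returned as \code{NA}.
#'
#' @param es Observed enrichment score.
#' @param null Numeric vector of null enrichment scores.
#' @return p-value in \code{(0, 1]}, or \code{NA_real_}.
#' @export
nominal_p <- function(es, null) {
  if (length(null) == 0L) .hp_stop("empty permutation null")
  same <- null[sign(null) == sign(es)]
  if (length(same) == 0L) return(NA_real_)
  (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
}

#' Normalized enrichment score
#'
#' Normalizes the ES to the size (and metric content) of the gene set by
#' dividing by the mean absolute null ES of the same sign, the standard
#' operationalization of size normalization in preranked enrichment. Sign
#' is preserved; an empty same-sign null leaves the NES undefined
#' (\code{NA}).
#'
#' @inheritParams nominal_p
#' @return The NES, or \code{NA_real_}.
#' @export
normalized_es <- function(es, null) {
  if (length(null) == 0L) .hp_stop("empty permutation null")
  same <- null[sign(null) == sign(es)]
  if (length(same) == 0L) return(NA_real_)
  es / mean(abs(same))
}

#' Enrich every gene set of a collection against one ranked list
#'
#' Maps each set onto the ranked list, drops sets with fewer than
#' \code{min_size} mapped genes, and computes ES, NES and nominal p from a
#' shared permutation null. Nulls are cached per distinct mapped set size,
#' with the per-size random stream derived from \code{seed} and the size
#' alone, so results are identical whatever the order of sets in the
#' collection.
#'
#' @param ranked A \code{\link{ranked_list}}.
#' @param collection A \code{\link{read_gmt}} collection.
#' @param min_size Minimum mapped genes per tested set (default 10).
#' @param n_perm Permutations per null (default 1000).
#' @param weight Metric exponent, 0 or 1.
#' @param seed Integer seed; per-size substreams are derived from it.
#' @return List with \code{results} (data.frame: pathway, es, nes,
#'   nominal_p, n_mapped) and \code{skipped} (names of sets below
#'   \code{min_size}).
#' @export
enrich_collection <- function(ranked, collection, min_size = 10,
                              n_perm = 1000, weight = 1, seed = 1) {
  stopifnot(inherits(ranked, "ranked_list"),
            inherits(collection, "gene_set_collection"))
  N <- nrow(ranked)
  gene_pos <- seq_len(N)
  names(gene_pos) <- ranked$gene
  absw <- if (weight == 0) rep.int(1, N) else abs(ranked$metric)

  nm_order <- sort(names(collection$sets))  # size cache fill order fixed
  mapped <- lapply(collection$sets, function(g) unname(gene_pos[g[g %in% names(gene_pos)]]))
  sizes <- lengths(mapped)
  tested <- names(sizes)[sizes >= min_size & sizes < N]
  skipped <- setdiff(names(sizes), tested)

  null_cache <- new.env(parent = emptyenv())
  get_null <- function(k) {
    key <- as.character(k)
    if (is.null(null_cache[[key]])) {
      null_cache[[key]] <- permutation_null(
        ranked, k, n_perm = n_perm, weight = weight,
        seed = derive_seed(seed, "null", k))
    }
    null_cache[[key]]
  }

  if (length(tested) == 0L) {
    warning("no gene set passes min_size = ", min_size)
    return(list(results = data.frame(pathway = character(), es = numeric(),
                                     nes = numeric(), nominal_p = numeric(),
                                     n_mapped = integer(),
                                     stringsAsFactors = FALSE),
                skipped = skipped))
  }
  tested <- intersect(nm_order, tested)
  es <- nes <- pv <- numeric(length(tested))
  nmap <- integer(length(tested))
  for (i in seq_along(tested)) {
    pos <- sort.int(mapped[[tested[i]]])
    e <- .es_from_positions(matrix(pos, ncol = 1L), absw, N)
    null <- get_null(length(pos))
    es[i] <- e
    nes[i] <- normalized_es(e, null)
    pv[i] <- nominal_p(e, null)
    nmap[i] <- length(pos)
  }
  list(results = data.frame(pathway = tested, es = es, nes = nes,
                            nominal_p = pv, n_mapped = nmap,
                            stringsAsFactors = FALSE),
       skipped = skipped)
}

#' Assemble per-condition enrichment results into an NES matrix
#'
#' Takes one \code{\link{enrich_collection}} result per condition and
#' tabulates NES and nominal p over the union of tested pathways; cells
#' for pathways not tested in a condition (or with undefined NES) are
#' missing.
#'
#' @param results Named list (condition label -> \code{enrich_collection}
#'   output or its \code{results} data.frame). Duplicate labels are an
#'   error.
#' @param alpha Significance level to attach (default 0.05).
#' @return An \code{\link{nes_matrix}}.
#' @export
build_nes_matrix <- function(results, alpha = 0.05) {
  if (length(results) == 0L) .hp_stop("need at least one condition")
  if (is.null(names(results)) || any(!nzchar(names(results))))
    .hp_stop("conditions must be named")
  if (anyDuplicated(names(results)))
    .hp_stop("duplicate condition label(s): ",
             paste(unique(names(results)[duplicated(names(results))]),
                   collapse = ", "))
  tabs <- lapply(results, function(r) if (is.data.frame(r)) r else r$results)
  pathways <- sort(unique(unlist(lapply(tabs, `[[`, "pathway"))))
  conds <- names(results)
  nes <- p <- matrix(NA_real_, length(pathways), length(conds),
                     dimnames = list(pathways, conds))
  for (j in seq_along(conds)) {
    tab <- tabs[[j]]
    ok <- is.finite(tab$nes) & is.finite(tab$nominal_p)
    nes[tab$pathway[ok], j] <- tab$nes[ok]
    p[tab$pathway[ok], j] <- tab$nominal_p[ok]
  }
  nes_matrix(nes, p, alpha)
}
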