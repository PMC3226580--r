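#' Configuration for the synthetic perturbation study generator
#'
#' The defaults emulate a hepatic perturbation screen: 43 conditions of
#' which 20 are toxicopathological (high dose / long exposure) and the
#' rest physiological, 189 pathways of which 8 + 8 are planted hubs split
#' into two groups with mutually inverted meta-activity under the toxic
#' conditions, a background fraction of 0.75 with no planted signal (the
#' remaining ~31 pathways are weaker non-hub members of the two groups),
#' gene sets of 15-25 genes drawn without replacement from 6000 genes,
#' 4 replicates per group, unit-variance Gaussian noise and a mean
#' log-expression shift of 2.8 for member genes of an active pathway
#' (per-gene t-test power about 0.9 at 4 + 4 replicates).
#'
#' @param n_genes Total genes on the array.
#' @param n_pathways Number of pathways (gene sets).
#' @param genes_per_pathway Length-2 integer range of set sizes.
#' @param n_conditions Number of perturbation conditions.
#' @param n_toxic_conditions Conditions with the inverted profile "on".
#' @param n_hubs_A,n_hubs_B Planted hub counts per group.
#' @param effect_size Mean log-expression shift of member genes at
#'   severity 1 (unitless, >= 0).
#' @param noise_sd Gaussian noise standard deviation (> 0).
#' @param n_replicates Samples per group and condition (>= 2).
#' @param background_fraction Fraction of pathways with no planted signal.
#' @param member_response_prob Probability a non-hub group member responds
#'   in a given toxic condition (keeps members below hub thresholds).
#' @param member_effect_scale Meta-activity attenuation of non-hub members.
#' @param scheme_A_fraction Fraction of toxic conditions with Group A
#'   activated (Scheme A); the remainder activate Group B (Scheme B),
#'   mirroring the predominance of Scheme B in toxicopathological states.
#' @param seed Integer seed.
#' @return Validated list of class \code{simulation_config}.
#' @export
simulation_config <- function(n_genes = 6000, n_pathways = 189,
                              genes_per_pathway = c(15, 25),
                              n_conditions = 43, n_toxic_conditions = 20,
                              n_hubs_A = 8, n_hubs_B = 8,
                              effect_size = 2.8, noise_sd = 1,
                              n_replicates = 4,
                              background_fraction = 0.75,
                              member_response_prob = 0.35,
                              member_effect_scale = 0.8,
                              scheme_A_fraction = 0.15, seed = 1) {
  cfg <- list(n_genes = n_genes, n_pathways = n_pathways,
              genes_per_pathway = genes_per_pathway,
              n_conditions = n_conditions,
              n_toxic_conditions = n_toxic_conditions,
              n_hubs_A = n_hubs_A, n_hubs_B = n_hubs_B,
              effect_size = effect_size, noise_sd = noise_sd,
              n_replicates = n_replicates,
              background_fraction = background_fraction,
              member_response_prob = member_response_prob,
              member_effect_scale = member_effect_scale,
              scheme_A_fraction = scheme_A_fraction, seed = seed)
  .hp_check_number(n_genes, "n_genes", 1)
  .hp_check_number(n_pathways, "n_pathways", 1)
  if (length(genes_per_pathway) != 2L || genes_per_pathway[1] > genes_per_pathway[2] ||
      genes_per_pathway[1] < 1)
    .hp_stop("'genes_per_pathway' must be an increasing positive range")
  .hp_check_number(n_conditions, "n_conditions", 1)
  .hp_check_number(n_toxic_conditions, "n_toxic_conditions", 0, n_conditions)
  .hp_check_number(n_hubs_A, "n_hubs_A", 0)
  .hp_check_number(n_hubs_B, "n_hubs_B", 0)
  if (n_hubs_A + n_hubs_B > n_pathways)
    .hp_stop("more planted hubs than pathways")
  .hp_check_number(effect_size, "effect_size", 0)
  .hp_check_number(noise_sd, "noise_sd", 0, strict_lower = TRUE)
  .hp_check_number(n_replicates, "n_replicates", 2)
  .hp_check_number(background_fraction, "background_fraction", 0, 1)
  if (round(background_fraction * n_pathways) + n_hubs_A + n_hubs_B > n_pathways)
    .hp_stop("background_fraction leaves no room for the planted hubs")
  .hp_check_number(member_response_prob, "member_response_prob", 0, 1)
  .hp_check_number(member_effect_scale, "member_effect_scale", 0)
  .hp_check_number(scheme_A_fraction, "scheme_A_fraction", 0, 1)
  .hp_check_number(seed, "seed", 0, 2^31 - 1)
  class(cfg) <- "simulation_config"
  cfg
}

#' Plant the two-group inverted meta-activity structure
#'
#' Draws a severity \code{s(c) ~ Uniform(0.5, 1.5)} for each toxic
#' condition and sets the planted meta-activity of hub pathways to
#' \code{+s(c)} for the activated group and \code{-s(c)} for the
#' suppressed group, per the condition's scheme (Scheme A activates
#' Group A, Scheme B activates Group B). Physiological conditions and
#' background pathways are 0 everywhere. Non-hub group members carry the
#' group sign attenuated by \code{member_effect_scale}, but only in a
#' Bernoulli(\code{member_response_prob}) subset of toxic conditions, so
#' they respond too rarely to pass the hub thresholds while remaining
#' scoreable by the seed-condition scheme.
#'
#' @param config A \code{\link{simulation_config}}.
#' @return A \code{simulation_truth} list: \code{pathway_group}
#'   (\code{"A"}/\code{"B"}/\code{"background"}), \code{pathway_role}
#'   (\code{"hub"}/\code{"member"}/\code{"background"}),
#'   \code{condition_state}, \code{severity}, and the planted
#'   \code{meta_activity} pathway x condition matrix.
#' @export
simulate_meta_activity <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(derive_seed(config$seed, "meta"))
  np <- config$n_pathways; nc <- config$n_conditions
  pw <- sprintf("PW%03d", seq_len(np))
  cond <- sprintf("cond%02d", seq_len(nc))

  nA <- config$n_hubs_A; nB <- config$n_hubs_B
  n_bg <- round(config$background_fraction * np)
  n_mem <- np - nA - nB - n_bg
  role <- c(rep("hub", nA + nB), rep("member", max(n_mem, 0)),
            rep("background", n_bg))
  group <- c(rep("A", nA), rep("B", nB),
             rep(c("A", "B"), length.out = max(n_mem, 0)), rep("background", n_bg))
  names(role) <- names(group) <- pw

  n_tox <- config$n_toxic_conditions
  n_schemeA <- round(config$scheme_A_fraction * n_tox)
  state <- c(rep("toxic_scheme_A", n_schemeA),
             rep("toxic_scheme_B", n_tox - n_schemeA),
             rep("physiological", nc - n_tox))
  names(state) <- cond
  severity <- stats::setNames(numeric(nc), cond)
  severity[state != "physiological"] <- stats::runif(n_tox, 0.5, 1.5)

  m <- matrix(0, np, nc, dimnames = list(pw, cond))
  memb_on <- matrix(stats::runif(np * nc) < config$member_response_prob,
                    np, nc)
  for (j in seq_len(nc)) {
    if (state[j] == "physiological") next
    a_sign <- if (state[j] == "toxic_scheme_A") 1 else -1
    gsign <- ifelse(group == "A", a_sign, ifelse(group == "B", -a_sign, 0))
    amp <- ifelse(role == "hub", 1,
                  ifelse(role == "member",
                         config$member_effect_scale * memb_on[, j], 0))
    m[, j] <- gsign * amp * severity[j]
  }
  structure(list(pathway_group = group, pathway_role = role,
                 condition_state = state, severity = severity,
                 meta_activity = m, config = config),
            class = "simulation_truth")
}

#' Generate gene-level expression experiments from a planted truth
#'
#' Assigns genes to pathways without replacement (set sizes uniform in
#' \code{genes_per_pathway}; leftover genes are unannotated), then for each
#' condition builds a replicated treated/control experiment: member genes
#' of pathway p have treated mean \code{meta_activity(p, c) * effect_size}
#' and control mean 0; every value receives Gaussian(0, noise_sd) noise.
#'
#' @param truth A \code{\link{simulate_meta_activity}} result.
#' @param config The matching \code{\link{simulation_config}}.
#' @return List with \code{experiments} (per-condition
#'   \code{\link{expression_experiment}}s), \code{collection} (planted
#'   \code{gene_set_collection}) and \code{gene_pathway} (gene -> pathway
#'   map, \code{NA} for unannotated genes).
#' @export
simulate_expression <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "simulation_truth"))
  set.seed(derive_seed(config$seed, "genes"))
  pw <- rownames(truth$meta_activity)
  sizes <- sample(seq(config$genes_per_pathway[1], config$genes_per_pathway[2]),
                  length(pw), replace = TRUE)
  if (sum(sizes) > config$n_genes)
    .hp_stop("n_genes = ", config$n_genes, " too small for ", sum(sizes),
             " pathway member genes")
  genes <- sprintf("g%05d", seq_len(config$n_genes))
  shuffled <- sample(genes)
  stop_at <- cumsum(sizes)
  start_at <- c(1, stop_at[-length(stop_at)] + 1)
  sets <- lapply(seq_along(pw),
                 function(i) sort(shuffled[start_at[i]:stop_at[i]]))
  names(sets) <- pw
  gene_pathway <- stats::setNames(rep(NA_character_, config$n_genes), genes)
  for (p in pw) gene_pathway[sets[[p]]] <- p
  collection <- structure(
    list(sets = sets,
         description = stats::setNames(rep("planted", length(pw)), pw)),
    class = "gene_set_collection")

  nr <- config$n_replicates
  experiments <- vector("list", ncol(truth$meta_activity))
  names(experiments) <- colnames(truth$meta_activity)
  mu_gene <- numeric(config$n_genes)
  for (j in seq_along(experiments)) {
    cond <- colnames(truth$meta_activity)[j]
    set.seed(derive_seed(config$seed, "expr", cond))
    mu_gene[] <- 0
    annotated <- !is.na(gene_pathway)
    mu_gene[annotated] <- truth$meta_activity[gene_pathway[annotated], j] *
      config$effect_size
    vals <- matrix(stats::rnorm(config$n_genes * 2 * nr, sd = config$noise_sd),
                   config$n_genes, 2 * nr)
    vals[, seq_len(nr)] <- vals[, seq_len(nr)] + mu_gene
    samples <- c(sprintf("%s_trt%d", cond, seq_len(nr)),
                 sprintf("%s_ctl%d", cond, seq_len(nr)))
    dimnames(vals) <- list(genes, samples)
    design <- stats::setNames(rep(c("treated", "control"), each = nr), samples)
    experiments[[j]] <- expression_experiment(vals, design, cond)
  }
  list(experiments = experiments, collection = collection,
       gene_pathway = gene_pathway)
}

#' Simulate an NES matrix directly from a planted truth
#'
#' Fast fixture that bypasses the gene level: NES is the planted
#' meta-activity plus Gaussian noise; a cell is called significant with
#' probability \code{power_param} where signal is planted and at the
#' false-positive rate \code{sig_alpha} elsewhere. Significant cells get
#' p drawn below \code{alpha}, others above.
#'
#' @param truth A \code{\link{simulate_meta_activity}} result.
#' @param nes_noise_sd NES noise standard deviation (> 0).
#' @param sig_alpha False-positive significance rate for null cells.
#' @param power_param Detection probability for planted cells.
#' @param alpha Significance level attached to the matrix.
#' @param seed Integer seed (defaults to the truth's config seed).
#' @return An \code{\link{nes_matrix}}.
#' @export
simulate_nes_matrix <- function(truth, nes_noise_sd = 0.5, sig_alpha = 0.05,
                                power_param = 0.9, alpha = 0.05,
                                seed = truth$config$seed) {
  stopifnot(inherits(truth, "simulation_truth"))
  .hp_check_number(nes_noise_sd, "nes_noise_sd", 0, strict_lower = TRUE)
  .hp_check_number(sig_alpha, "sig_alpha", 0, 1)
  .hp_check_number(power_param, "power_param", 0, 1)
  set.seed(derive_seed(seed, "nes"))
  m <- truth$meta_activity
  nes <- m + matrix(stats::rnorm(length(m), sd = nes_noise_sd),
                    nrow(m), ncol(m), dimnames = dimnames(m))
  planted <- abs(m) > 0
  sig <- matrix(FALSE, nrow(m), ncol(m))
  sig[planted] <- stats::runif(sum(planted)) < power_param
  sig[!planted] <- stats::runif(sum(!planted)) < sig_alpha
  p <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
  p[sig] <- stats::runif(sum(sig), 0, alpha)
  p[!sig] <- stats::runif(sum(!sig), alpha, 1)
  nes_matrix(nes, p, alpha)
}

#' Closed-form power of the per-gene pooled t-test
#'
#' Two-sided power of the equal-variance two-sample t-test at mean shift
#' \code{delta}, common standard deviation \code{sd} and \code{n} samples
#' per group, from the noncentral t distribution.
#'
#' @param delta True mean difference.
#' @param sd Common standard deviation.
#' @param n Samples per group.
#' @param alpha Test level (default 0.05).
#' @return Power in \code{[0, 1]}.
#' @export
gene_level_power <- function(delta, sd = 1, n = 4, alpha = 0.05) {
  df <- 2 * n - 2
  ncp <- delta / (sd * sqrt(2 / n))
  tc <- stats::qt(1 - alpha / 2, df)
  (1 - stats::pt(tc, df, ncp)) + stats::pt(-tc, df, ncp)
}

#' Effect size achieving a target per-gene power
#'
#' Inverts \code{\link{gene_level_power}} in \code{delta} by root finding.
#'
#' @param power Target power in \code{(alpha, 1)}.
#' @inheritParams gene_level_power
#' @return The mean shift \code{delta}.
#' @export
effect_for_power <- function(power, sd = 1, n = 4, alpha = 0.05) {
  .hp_check_number(power, "power", alpha, 1, strict_lower = TRUE)
  stats::uniroot(function(d) gene_level_power(d, sd, n, alpha) - power,
                 interval = c(1e-6, 100), tol = 1e-9)$root
}
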