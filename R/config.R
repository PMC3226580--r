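.hp_config_defaults <- function() {
  list(
    alpha = 0.05,          # nominal significance for a pathway response
    min_size = 10,         # minimum mapped genes per tested set
    n_perm = 1000,         # permutations for the enrichment null
    weight = 1,            # running-sum metric exponent (0 or 1)
    p_floor = 1e-16,       # gene p-value floor before log10(1/P)
    var_equal = TRUE,      # pooled-variance (Student) t-test
    theta_hr = 10,         # responsiveness: HR iff n_i >= theta_hr
    theta_mr = 5,          # responsiveness: MR iff theta_mr <= n_i < theta_hr
    r_min = 0.5,           # edge iff |PCC| > r_min ...
    p_max = 1e-4,          # ... and correlation p < p_max
    min_overlap = 10,      # minimum pairwise-complete conditions for a PCC
    theta_resp = 10,       # hub: significant responses >= theta_resp
    theta_deg = 10,        # hub: connectivity degree >= theta_deg
    min_hubs = 3,          # hubs needed for a group consensus direction
    min_group_score = 3,   # group assignment bar on A_score / B_score
    anti_threshold = 0.7,  # strict anti-correlation bar on score/n
    seed = 1
  )
}

#' Pipeline configuration
#'
#' Collects every analysis threshold in one validated object. Defaults are
#' the thresholds used throughout the hub analysis: nominal alpha 0.05,
#' minimum set size 10, 1000 permutations, weighted (exponent 1) running
#' sum, responsiveness cutoffs 10/5, edge rule |PCC| > 0.5 with p < 1e-4,
#' hub thresholds 10/10, consensus over at least 3 hubs, group score bar 3
#' and strict anti-correlation bar 0.7.
#'
#' @param ... Named overrides of the defaults (unknown names are an error).
#' @return A named list of class \code{hubpath_config}.
#' @export
pipeline_config <- function(...) {
  cfg <- .hp_config_defaults()
  dots <- list(...)
  if (length(dots) > 0L) {
    if (is.null(names(dots)) || any(!nzchar(names(dots))))
      .hp_stop("configuration overrides must be named")
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown) > 0L)
      .hp_stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  validate_config(cfg)
}

#' @rdname pipeline_config
#' @param cfg A configuration list to validate.
#' @export
validate_config <- function(cfg) {
  .hp_check_number(cfg$alpha, "alpha", 0, 1, strict_lower = TRUE)
  .hp_check_number(cfg$min_size, "min_size", 1)
  .hp_check_number(cfg$n_perm, "n_perm", 1)
  if (!cfg$weight %in% c(0, 1)) .hp_stop("'weight' must be 0 or 1")
  .hp_check_number(cfg$p_floor, "p_floor", 0, 1, strict_lower = TRUE)
  .hp_check_flag(cfg$var_equal, "var_equal")
  .hp_check_number(cfg$theta_hr, "theta_hr", 0)
  .hp_check_number(cfg$theta_mr, "theta_mr", 0)
  if (cfg$theta_mr >= cfg$theta_hr)
    .hp_stop("'theta_mr' must be strictly below 'theta_hr'")
  .hp_check_number(cfg$r_min, "r_min", 0, 1)
  .hp_check_number(cfg$p_max, "p_max", 0, 1, strict_lower = TRUE)
  .hp_check_number(cfg$min_overlap, "min_overlap", 3)
  .hp_check_number(cfg$theta_resp, "theta_resp", 0)
  .hp_check_number(cfg$theta_deg, "theta_deg", 0)
  .hp_check_number(cfg$min_hubs, "min_hubs", 1)
  .hp_check_number(cfg$min_group_score, "min_group_score", 1)
  .hp_check_number(cfg$anti_threshold, "anti_threshold", 0, 1)
  .hp_check_number(cfg$seed, "seed", 0, 2^31 - 1)
  class(cfg) <- "hubpath_config"
  cfg
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file mirroring the keys of \code{\link{pipeline_config}};
#'   unknown keys are rejected.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) .hp_stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(pipeline_config, vals)
}

#' @rdname read_config
#' @param cfg A \code{hubpath_config}.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
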