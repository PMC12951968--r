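#' Pipeline configuration
#'
#' Collects every tunable threshold of the FIE detection protocol in one
#' validated object. Defaults follow the published protocol contract: tunable
#' sites require proximity of at most 5 Angstrom to a functional site, cluster
#' significance levels are 5% (standard) and 0.5% (high), conserved columns
#' are predicted sites when the conservation score exceeds 0.9 in alignments
#' with diversity-of-positions score above 70, Grantham thresholds are 64
#' (medium impact) and 109 (high impact), mutations with population VAF above
#' 1e-7 are treated as polymorphic, the mutation-copy-number boundary for
#' duplication timing is 1.5, the FIE score threshold is 3, and diversity
#' extrapolation runs to twice the observed sample size.
#'
#' @param site_distance_cutoff Angstrom; maximum distance between a cluster or
#'   hotspot residue and a functional site for tunable-site status.
#' @param cluster_sig standard cluster inclusion significance level.
#' @param cluster_high_sig high-significance cluster level (score component).
#' @param conservation_threshold per-column conservation score above which a
#'   column is a predicted functional site (strict inequality, raw scores).
#' @param dops_threshold alignment diversity-of-positions score that must be
#'   exceeded before any column is predicted.
#' @param hotspot_min_patients distinct patients (within one cancer type)
#'   required for a recurrence hotspot.
#' @param grantham_medium,grantham_high Grantham matrix thresholds for the
#'   medium (score 1) and high (score 2) substitution-impact components.
#' @param polymorphism_vaf population VAF above which a mutation is considered
#'   polymorphic and its Grantham component zeroed.
#' @param timing_cn_threshold mutation copy number separating pre- from
#'   post-duplication calls.
#' @param fie_score_threshold minimum total FIE score retained.
#' @param extrapolation_factor diversity curves extend to this multiple of the
#'   observed sample size.
#' @param bootstrap_reps bootstrap replicates for diversity CIs.
#' @param cluster_radius Angstrom; seed-and-extend neighbourhood radius for
#'   spatial clustering.
#' @param n_perm permutations for the cluster null distribution.
#' @param plddt_min optional per-residue model-quality cutoff; residues of a
#'   predicted structure with pLDDT below this are excluded when the structure
#'   carries a `plddt` column. `NA` disables the filter.
#' @param rng_seed integer seed used by stochastic stages.
#'
#' @return an object of class `funvar_config` (a named list).
#' @examples
#' cfg <- funvar_config()
#' cfg$site_distance_cutoff
#' @export
funvar_config <- function(site_distance_cutoff = 5.0,
                          cluster_sig = 0.05,
                          cluster_high_sig = 0.005,
                          conservation_threshold = 0.9,
                          dops_threshold = 70,
                          hotspot_min_patients = 2L,
                          grantham_medium = 64,
                          grantham_high = 109,
                          polymorphism_vaf = 1e-7,
                          timing_cn_threshold = 1.5,
                          fie_score_threshold = 3L,
                          extrapolation_factor = 2,
                          bootstrap_reps = 200L,
                          cluster_radius = 5.0,
                          n_perm = 999L,
                          plddt_min = NA_real_,
                          rng_seed = 1L) {
  cfg <- list(
    site_distance_cutoff = site_distance_cutoff,
    cluster_sig = cluster_sig,
    cluster_high_sig = cluster_high_sig,
    conservation_threshold = conservation_threshold,
    dops_threshold = dops_threshold,
    hotspot_min_patients = as.integer(hotspot_min_patients),
    grantham_medium = grantham_medium,
    grantham_high = grantham_high,
    polymorphism_vaf = polymorphism_vaf,
    timing_cn_threshold = timing_cn_threshold,
    fie_score_threshold = as.integer(fie_score_threshold),
    extrapolation_factor = extrapolation_factor,
    bootstrap_reps = as.integer(bootstrap_reps),
    cluster_radius = cluster_radius,
    n_perm = as.integer(n_perm),
    plddt_min = plddt_min,
    rng_seed = as.integer(rng_seed)
  )
  num <- cfg[setdiff(names(cfg), "plddt_min")]
  if (!all(vapply(num, function(x) is.numeric(x) && length(x) == 1L && is.finite(x), logical(1))))
    stop("all configuration values must be single finite numbers", call. = FALSE)
  pos <- c("site_distance_cutoff", "cluster_sig", "cluster_high_sig",
           "conservation_threshold", "dops_threshold", "hotspot_min_patients",
           "grantham_medium", "grantham_high", "polymorphism_vaf",
           "timing_cn_threshold", "fie_score_threshold", "extrapolation_factor",
           "bootstrap_reps", "cluster_radius", "n_perm")
  if (any(unlist(cfg[pos]) <= 0))
    stop("all thresholds must be positive", call. = FALSE)
  if (cfg$cluster_high_sig >= cfg$cluster_sig)
    stop("cluster_high_sig must be smaller than cluster_sig", call. = FALSE)
  structure(cfg, class = "funvar_config")
}

#' Read a configuration from a YAML or JSON file
#'
#' Keys absent from the file keep their defaults; unknown keys are an error.
#'
#' @param path YAML (or JSON, which YAML parses) file of config overrides.
#' @return a `funvar_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(funvar_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  do.call(funvar_config, vals)
}

#' @export
print.funvar_config <- function(x, ...) {
  cat("funvar configuration:\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

as_config <- function(config) {
  if (is.null(config)) return(funvar_config())
  if (!inherits(config, "funvar_config"))
    stop("config must be a funvar_config object", call. = FALSE)
  config
}
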