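#' Time one mutation relative to gene duplication
#'
#' Exact truth table over the allele-specific copy-number scenarios:
#' \itemize{
#'   \item biallelic gain (major >= 2 and minor >= 2): mutation copy number
#'     above the threshold (default 1.5) means the mutation preceded the
#'     gain (it sits on every duplicated copy), below means it followed it.
#'   \item monoallelic gain with LOH (major >= 2, minor = 0): same rule.
#'   \item monoallelic gain without LOH (major >= 2, minor = 1): above the
#'     threshold is pre-duplication; below cannot be timed, because a single
#'     mutant copy could be a post-duplication event on the gained major
#'     allele or an ungained mutation on the minor allele.
#'   \item major < 2: no gain, nothing to time against.
#' }
#' A mutation copy number exactly at the threshold is returned as untimed
#' (tie rule), as is a missing mutation copy number in a gained region.
#'
#' @param major_cn,minor_cn allele-specific copy numbers (major >= minor).
#' @param mutation_cn estimated mutation copy number, `NA` when missing.
#' @param config a [funvar_config()] (`timing_cn_threshold`).
#' @return list with `class` (`"pre"`, `"post"`, `"untimed"`, `"no_gain"`),
#'   `scenario` (`"biallelic_gain"`, `"monoallelic_LOH"`,
#'   `"monoallelic_noLOH"`, `"no_gain"`) and `reason` for untimed calls.
#' @export
time_mutation <- function(major_cn, minor_cn, mutation_cn = NA_real_,
                          config = NULL) {
  config <- as_config(config)
  if (is.na(major_cn) || is.na(minor_cn) || major_cn < 0 || minor_cn < 0)
    stop("copy numbers must be non-negative", call. = FALSE)
  if (minor_cn > major_cn)
    stop("major_cn must be >= minor_cn", call. = FALSE)
  thr <- config$timing_cn_threshold
  if (major_cn < 2)
    return(list(class = "no_gain", scenario = "no_gain", reason = NA_character_))
  scenario <- if (minor_cn >= 2) "biallelic_gain"
              else if (minor_cn == 0) "monoallelic_LOH"
              else "monoallelic_noLOH"
  if (is.na(mutation_cn))
    return(list(class = "untimed", scenario = scenario,
                reason = "missing mutation_cn in gained region"))
  if (mutation_cn < 0) stop("mutation_cn must be non-negative", call. = FALSE)
  if (mutation_cn > thr)
    return(list(class = "pre", scenario = scenario, reason = NA_character_))
  if (mutation_cn == thr)
    return(list(class = "untimed", scenario = scenario,
                reason = sprintf("mutation_cn exactly at threshold %.3g", thr)))
  if (scenario == "monoallelic_noLOH")
    return(list(class = "untimed", scenario = scenario,
                reason = "single mutant copy: post-gain on major or ungained on minor"))
  list(class = "post", scenario = scenario, reason = NA_character_)
}

#' Reconcile timing calls across tumor regions
#'
#' Multi-region sampling can time the same mutation differently in
#' different regions. A pre call in one region and a post call in another
#' reconciles to post: once a mutation is on all copies (pre), wild-type
#' copies cannot reappear to make it look post, but the reverse is possible
#' through a subclonal gain of the mutated copy. Informative calls beat
#' uninformative ones (pre or post over untimed; untimed over no_gain).
#'
#' @param classes character vector of per-region timing classes.
#' @return single reconciled class.
#' @export
reconcile_regions <- function(classes) {
  if (!length(classes)) stop("no timing calls to reconcile", call. = FALSE)
  ok <- c("pre", "post", "untimed", "no_gain")
  if (!all(classes %in% ok))
    stop("unknown timing class: ", paste(setdiff(classes, ok), collapse = ", "),
         call. = FALSE)
  if ("post" %in% classes) return("post")
  if ("pre" %in% classes) return("pre")
  if ("untimed" %in% classes) return("untimed")
  "no_gain"
}

#' Time a table of mutations, reconciling regions
#'
#' Joins mutations to per-(tumor, gene) copy-number states. When a tumor
#' has several regional states for a gene (rows repeated per region), each
#' region yields a call and the calls are reconciled with
#' [reconcile_regions()]. Mutations without a copy-number state are
#' untimed.
#'
#' @param muts mutation (or scored FIE) table with `tumor_id`, `gene` and
#'   `mutation_cn`.
#' @param cn copy-number table from [read_copy_number()].
#' @param config a [funvar_config()].
#' @return `muts` with `timing` and `timing_scenario` columns replaced.
#' @export
time_fies <- function(muts, cn, config = NULL) {
  config <- as_config(config)
  if (is.null(muts) || nrow(muts) == 0L) return(muts)
  cls <- character(nrow(muts)); scen <- character(nrow(muts))
  for (i in seq_len(nrow(muts))) {
    states <- cn[cn$tumor_id == muts$tumor_id[i] & cn$gene == muts$gene[i], ,
                 drop = FALSE]
    if (nrow(states) == 0L) {
      cls[i] <- "untimed"; scen[i] <- NA_character_
      next
    }
    calls <- lapply(seq_len(nrow(states)), function(j)
      time_mutation(states$major_cn[j], states$minor_cn[j],
                    muts$mutation_cn[i], config))
    cls[i] <- reconcile_regions(vapply(calls, `[[`, character(1), "class"))
    scen[i] <- calls[[which(vapply(calls, `[[`, character(1), "class") == cls[i])[1]]]$scenario
  }
  muts$timing <- cls
  muts$timing_scenario <- scen
  muts
}

#' Pre/post-duplication enrichment against a synonymous background
#'
#' Pearson chi-squared statistic, without continuity correction, on the
#' 2 x 2 table (FIE vs synonymous) x (pre vs post).
#'
#' @param fie_pre,fie_post counts of pre-/post-duplication FIEs.
#' @param syn_pre,syn_post counts of timed synonymous background mutations.
#' @return list with `statistic` and `p_value`.
#' @export
timing_enrichment_test <- function(fie_pre, fie_post, syn_pre, syn_post) {
  tab <- matrix(c(fie_pre, fie_post, syn_pre, syn_post), nrow = 2,
                byrow = TRUE,
                dimnames = list(c("fie", "synonymous"), c("pre", "post")))
  if (any(tab < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("a zero marginal makes the test undefined", call. = FALSE)
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value))
}
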