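#' Grantham substitution-impact component
#'
#' Scores 1 for a medium-impact change (Grantham matrix value above
#' `grantham_medium`, default 64) and 2 for a high-impact change (above
#' `grantham_high`, default 109). A polymorphic mutation - population VAF
#' above `polymorphism_vaf` (default 1e-7) - scores 0 regardless of the
#' matrix value, as common population variants are unlikely somatic drivers.
#'
#' @param ref_aa,alt_aa one-letter amino-acid codes (vectorised).
#' @param pop_vaf population variant allele frequency, `NA` when unknown.
#' @param config a [funvar_config()].
#' @return integer vector in `{0, 1, 2}`.
#' @export
grantham_component <- function(ref_aa, alt_aa, pop_vaf = NA_real_,
                               config = NULL) {
  config <- as_config(config)
  g <- grantham_distance(ref_aa, alt_aa)
  out <- ifelse(g > config$grantham_high, 2L,
                ifelse(g > config$grantham_medium, 1L, 0L))
  poly <- !is.na(pop_vaf) & pop_vaf > config$polymorphism_vaf
  out[poly] <- 0L
  as.integer(out)
}

#' Protein-sequence score components
#'
#' Grantham impact (0/1/2), hotspot membership (0/1) and known
#' disease-variant annotation (0/1); subtotal at most 4. Hotspots must come
#' from the target cohort itself - target-cohort hotspots are assessed
#' independently of any equivalent builder-cohort hotspots.
#'
#' @param muts mutation table rows to score.
#' @param hotspots [find_hotspots()] table from the target cohort.
#' @param config a [funvar_config()].
#' @return data frame `grantham`, `hotspot`, `disease_variant`.
#' @export
sequence_components <- function(muts, hotspots, config = NULL) {
  config <- as_config(config)
  data.frame(
    grantham = grantham_component(muts$ref_aa, muts$alt_aa, muts$pop_vaf, config),
    hotspot = as.integer(in_hotspot(muts, hotspots)),
    disease_variant = as.integer(!is.na(muts$disease_variant) & muts$disease_variant)
  )
}

#' Protein-structure score components
#'
#' For each representative residue: `on_known` / `on_predicted` when the
#' residue is itself a site residue of that class; `near_known` /
#' `near_predicted` when the minimum distance to the closest site of that
#' class is within `site_distance_cutoff` (lying on a site implies being
#' near it, so an on-site residue gets the combined weight of 2 per class,
#' and a residue on a known site that is also predicted reaches the maximum
#' site subtotal of 4); `high_sig_cluster` when the residue belongs to a
#' cluster with p-value at or below `cluster_high_sig`. Subtotal at most 5.
#'
#' @param rep_residues structure residue ids to score (vectorised).
#' @param sites projected functional-site table ([project_sites()]).
#' @param clusters [cluster_mutations()] output from the builder cohort.
#' @param structure the representative [domain_structure()].
#' @param config a [funvar_config()].
#' @param dist_mat optional precomputed [residue_distance_matrix].
#' @return data frame `on_known`, `near_known`, `on_predicted`,
#'   `near_predicted`, `high_sig_cluster`.
#' @export
structure_components <- function(rep_residues, sites, clusters, structure,
                                 config = NULL, dist_mat = NULL) {
  config <- as_config(config)
  ids <- residue_ids(structure)
  if (any(!rep_residues %in% ids))
    stop("residue(s) not in structure: ",
         paste(setdiff(rep_residues, ids), collapse = ", "), call. = FALSE)
  if (is.null(dist_mat)) dist_mat <- residue_distance_matrix(structure)
  known <- sites$residue_id[sites$site_kind != "predicted"]
  pred <- sites$residue_id[sites$site_kind == "predicted"]
  hi_res <- unlist(lapply(clusters, function(cl)
    if (cl$p_value <= config$cluster_high_sig) cl$residue_ids else integer(0)))
  near <- function(r, set) {
    if (!length(set)) return(0L)
    as.integer(min(dist_mat[as.character(r), as.character(set)]) <=
                 config$site_distance_cutoff)
  }
  n <- length(rep_residues)
  out <- data.frame(on_known = integer(n), near_known = integer(n),
                    on_predicted = integer(n), near_predicted = integer(n),
                    high_sig_cluster = integer(n))
  for (i in seq_len(n)) {
    r <- rep_residues[i]
    out$on_known[i] <- as.integer(r %in% known)
    out$on_predicted[i] <- as.integer(r %in% pred)
    out$near_known[i] <- max(out$on_known[i], near(r, known))
    out$near_predicted[i] <- max(out$on_predicted[i], near(r, pred))
    out$high_sig_cluster[i] <- as.integer(r %in% hi_res)
  }
  out
}

#' Family mutation-enrichment test (MutFam-style)
#'
#' One-sided exact binomial test of whether a family's domain regions carry
#' more mutations than expected from their share of the coding length:
#' `domain_mut_count` successes in `domain_mut_count + offdomain_mut_count`
#' trials against `p0 = domain_len / (domain_len + offdomain_len)`. With
#' zero total mutations the p-value is 1. When several families are tested
#' together, pass their counts as vectors: flags are then assigned after
#' Benjamini-Hochberg adjustment across the families.
#'
#' @param domain_mut_count,offdomain_mut_count mutation counts inside /
#'   outside the family's domain regions (vectorised over families).
#' @param domain_len,offdomain_len corresponding region lengths in residues.
#' @param alpha significance level for the flag (default 0.05).
#' @return data frame `p_value`, `flag`.
#' @export
mutfam_enrichment <- function(domain_mut_count, domain_len,
                              offdomain_mut_count, offdomain_len,
                              alpha = 0.05) {
  if (any(domain_len <= 0) || any(offdomain_len <= 0))
    stop("region lengths must be positive", call. = FALSE)
  n_fam <- length(domain_mut_count)
  p <- numeric(n_fam)
  for (i in seq_len(n_fam)) {
    total <- domain_mut_count[i] + offdomain_mut_count[i]
    if (total == 0L) { p[i] <- 1; next }
    p0 <- domain_len[i] / (domain_len[i] + offdomain_len[i])
    p[i] <- binom.test(domain_mut_count[i], total, p = p0,
                       alternative = "greater")$p.value
  }
  adj <- p.adjust(p, method = "BH")
  data.frame(p_value = p, flag = adj <= alpha & (domain_mut_count + offdomain_mut_count) > 0)
}

.component_names <- c("grantham", "hotspot", "disease_variant", "on_known",
                      "near_known", "on_predicted", "near_predicted",
                      "high_sig_cluster", "mutfam")
.component_max <- c(grantham = 2L, hotspot = 1L, disease_variant = 1L,
                    on_known = 1L, near_known = 1L, on_predicted = 1L,
                    near_predicted = 1L, high_sig_cluster = 1L, mutfam = 1L)

#' Total FIE score
#'
#' Arithmetic sum of the nine components. Valid ranges are enforced:
#' Grantham in {0,1,2}, all others in {0,1}; totals lie in `[0, 10]`, and
#' any mutation inside a tunable site scores at least 1 because it is by
#' construction on or near a functional site.
#'
#' @param components data frame (or single named list) holding all nine
#'   component columns.
#' @return integer vector of totals.
#' @export
total_fie_score <- function(components) {
  components <- as.data.frame(components)
  missing_cols <- setdiff(.component_names, names(components))
  if (length(missing_cols))
    stop("missing score component(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  for (nm in .component_names) {
    v <- components[[nm]]
    if (any(is.na(v)) || any(v != floor(v)) || any(v < 0) ||
        any(v > .component_max[[nm]]))
      stop("component '", nm, "' outside its allowed set {0..",
           .component_max[[nm]], "}", call. = FALSE)
  }
  as.integer(rowSums(components[, .component_names, drop = FALSE]))
}

#' Threshold filtering of scored records
#'
#' Splits scored records at the configured FIE score threshold (default 3).
#' Sub-threshold records are retained in a secondary element rather than
#' discarded, as they are useful when inspecting structures for near-miss
#' events.
#'
#' @param records scored FIE records with a `total` column.
#' @param config a [funvar_config()]; `fie_score_threshold` may be
#'   overridden there.
#' @return list with `retained` (total >= threshold) and `below`.
#' @export
apply_threshold <- function(records, config = NULL) {
  config <- as_config(config)
  if (is.null(records) || nrow(records) == 0L)
    return(list(retained = records, below = records))
  keep <- records$total >= config$fie_score_threshold
  list(retained = records[keep, , drop = FALSE],
       below = records[!keep, , drop = FALSE])
}

#' Family-level neofunctionalization flags
#'
#' `diverse_family` is true when the family's parent superfamily carries
#' strictly more than 10 distinct enzyme (EC) functions; `moonlighting` when
#' any member appears in the curated moonlighting list recorded on the
#' bundle. Both flags annotate candidate FIEs with a propensity for
#' neofunctional change; neither is a filter.
#'
#' @param records FIE records (any data frame; flags are appended).
#' @param bundle the family bundle.
#' @return `records` with logical columns `diverse_family`, `moonlighting`.
#' @export
annotate_family_flags <- function(records, bundle) {
  records$diverse_family <- bundle$ec_count_superfamily > 10L
  records$moonlighting <- isTRUE(bundle$moonlighting)
  records
}

#' Score candidate FIEs
#'
#' Orchestrates the component calculators over the candidates produced by
#' [call_fies()]: sequence components against the target cohort's own
#' hotspots, structure components against the projected sites and
#' builder-cohort clusters, the family-level mutation-enrichment component
#' (the bundle's precomputed `is_mutfam` flag when present, otherwise the
#' supplied `mutfam_flag`), the total, and the family flags.
#'
#' @param candidates [call_fies()] output (rows with `is_fie = TRUE` are
#'   scored; others are ignored).
#' @param bundle the family bundle.
#' @param sites projected site table ([project_sites()]).
#' @param clusters builder-cohort [cluster_mutations()] output.
#' @param hotspots target-cohort [find_hotspots()] table.
#' @param mutfam_flag fallback family enrichment flag when the bundle has
#'   none precomputed (default `FALSE`).
#' @param config a [funvar_config()].
#' @param dist_mat optional precomputed [residue_distance_matrix].
#' @return scored FIE record data frame (see [write_fie_table()] for the
#'   column contract; `timing` is `"untimed"` until [time_fies()] runs).
#' @export
score_fies <- function(candidates, bundle, sites, clusters, hotspots,
                       mutfam_flag = FALSE, config = NULL, dist_mat = NULL) {
  config <- as_config(config)
  fies <- candidates[candidates$is_fie, , drop = FALSE]
  if (nrow(fies) == 0L) {
    out <- data.frame()
    return(out)
  }
  seqc <- sequence_components(fies, hotspots, config)
  strc <- structure_components(fies$rep_residue, sites, clusters,
                               bundle$structure, config, dist_mat)
  fam <- if (!is.na(bundle$is_mutfam)) as.integer(isTRUE(bundle$is_mutfam))
         else as.integer(isTRUE(mutfam_flag))
  comp <- cbind(seqc, strc, mutfam = rep(fam, nrow(fies)))
  out <- data.frame(
    tumor_id = fies$tumor_id, cancer_type = fies$cancer_type,
    gene = fies$gene, funfam_id = bundle$funfam_id,
    protein_id = fies$protein_id, residue_pos = fies$residue_pos,
    rep_residue = fies$rep_residue, ref_aa = fies$ref_aa,
    alt_aa = fies$alt_aa, stringsAsFactors = FALSE)
  out <- cbind(out, comp)
  out$total <- total_fie_score(comp)
  out$timing <- "untimed"
  out <- annotate_family_flags(out, bundle)
  # carry copy-number payload for the timing stage
  out$mutation_cn <- fies$mutation_cn
  out$clonality <- fies$clonality
  rownames(out) <- NULL
  out
}

#' Enrichment of FIE genes in a known cancer-gene list
#'
#' Reporting utility (not a filter): chi-squared test, without continuity
#' correction, of the 2 x 2 table (gene has FIE or not) x (gene in the
#' supplied cancer-gene list or not) over a stated gene universe.
#'
#' @param fie_genes character vector of genes with retained FIEs.
#' @param cancer_genes known cancer-gene list.
#' @param universe all genes considered by the analysis.
#' @return `htest` from [stats::chisq.test()].
#' @export
cancer_gene_enrichment <- function(fie_genes, cancer_genes, universe) {
  universe <- unique(universe)
  tab <- table(fie = universe %in% fie_genes,
               cancer = universe %in% cancer_genes)
  stats::chisq.test(tab, correct = FALSE)
}
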