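#' Run the full FIE detection pipeline on one functional family
#'
#' Convenience wrapper chaining the stages: column map, conservation
#' profile and predicted-site columns, site projection, builder-cohort
#' aggregation, spatial clustering, builder hotspots, tunable sites,
#' candidate FIE calling on the target cohort, component scoring (against
#' the target cohort's own hotspots), threshold filtering and - when a
#' copy-number table is supplied - duplication timing.
#'
#' @param bundle a [funfam_bundle()].
#' @param builder_muts builder-cohort mutation table (defines clusters,
#'   builder hotspots and hence tunable sites).
#' @param target_muts target-cohort mutation table (scored for FIEs); may
#'   be the same table as `builder_muts`.
#' @param cn optional copy-number table ([read_copy_number()]).
#' @param config a [funvar_config()].
#' @param mutfam_flag family-level enrichment flag fallback (see
#'   [score_fies()]).
#' @return list of class `funvar_result`: `profile`, `sites`, `counts`,
#'   `clusters`, `tunable`, `candidates`, `scored` (all scored FIEs),
#'   `retained`, `below` (threshold split), `config`.
#' @export
funvar_pipeline <- function(bundle, builder_muts, target_muts = builder_muts,
                            cn = NULL, config = NULL, mutfam_flag = FALSE) {
  config <- as_config(config)
  map <- build_column_map(bundle)
  dist_mat <- residue_distance_matrix(bundle$structure)

  profile <- alignment_conservation(bundle)
  pred_cols <- predict_site_columns(profile, config)
  sites <- project_sites(bundle, pred_cols, map)

  agg <- aggregate_counts(builder_muts, map, bundle)
  clusters <- cluster_mutations(agg$counts, bundle$structure, config,
                                dist_mat = dist_mat)

  builder_hot <- find_hotspots(builder_muts, config$hotspot_min_patients)
  hot_idx <- in_hotspot(builder_muts, builder_hot)
  hot_res <- unique(agg$assignments$residue_id[hot_idx])
  hot_res <- hot_res[!is.na(hot_res)]

  tunable <- make_tunable_sites(clusters, hot_res, sites, bundle$structure,
                                config, dist_mat)
  candidates <- call_fies(target_muts, tunable, map, bundle)
  target_hot <- find_hotspots(target_muts, config$hotspot_min_patients)
  scored <- score_fies(candidates, bundle, sites, clusters, target_hot,
                       mutfam_flag, config, dist_mat)
  if (!is.null(cn) && nrow(scored) > 0L)
    scored <- time_fies(scored, cn, config)
  split <- apply_threshold(scored, config)
  structure(list(profile = profile, sites = sites, counts = agg$counts,
                 clusters = clusters, tunable = tunable,
                 candidates = candidates, scored = scored,
                 retained = split$retained, below = split$below,
                 config = config),
            class = "funvar_result")
}

#' @export
print.funvar_result <- function(x, ...) {
  n_sig <- sum(vapply(x$clusters, function(cl) cl$tier != "none", logical(1)))
  cat("funvar pipeline result\n")
  cat(sprintf("  clusters: %d (%d significant) | tunable sites: %d\n",
              length(x$clusters), n_sig, nrow(x$tunable)))
  cat(sprintf("  candidate FIEs: %d | scored: %d | retained at threshold %d: %d\n",
              sum(x$candidates$is_fie), if (is.null(x$scored)) 0L else nrow(x$scored),
              x$config$fie_score_threshold,
              if (is.null(x$retained)) 0L else nrow(x$retained)))
  invisible(x)
}
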