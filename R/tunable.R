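#' Recurrence hotspots
#'
#' A hotspot is an identical amino-acid change (same gene, same position,
#' same alternate residue) observed in at least `min_patients` distinct
#' patients of one cancer type. Counting is per cancer type: the same change
#' seen once each in two different cancer types is not a hotspot, and two
#' samples from the same patient count once.
#'
#' @param muts mutation table carrying `tumor_id` and `cancer_type`.
#' @param min_patients distinct-patient threshold (default 2).
#' @return data frame `cancer_type`, `gene`, `residue_pos`, `alt_aa`,
#'   `n_patients`.
#' @export
find_hotspots <- function(muts, min_patients = 2L) {
  if (is.null(muts) || nrow(muts) == 0L)
    return(data.frame(cancer_type = character(0), gene = character(0),
                      residue_pos = integer(0), alt_aa = character(0),
                      n_patients = integer(0)))
  key <- paste(muts$cancer_type, muts$gene, muts$residue_pos, muts$alt_aa,
               sep = "\r")
  n_pat <- tapply(muts$tumor_id, key, function(x) length(unique(x)))
  hit <- names(n_pat)[n_pat >= min_patients]
  if (!length(hit))
    return(data.frame(cancer_type = character(0), gene = character(0),
                      residue_pos = integer(0), alt_aa = character(0),
                      n_patients = integer(0)))
  parts <- do.call(rbind, strsplit(hit, "\r", fixed = TRUE))
  out <- data.frame(cancer_type = parts[, 1], gene = parts[, 2],
                    residue_pos = as.integer(parts[, 3]), alt_aa = parts[, 4],
                    n_patients = as.integer(n_pat[hit]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$cancer_type, out$gene, out$residue_pos, out$alt_aa), ]
  rownames(out) <- NULL
  out
}

# Is each mutation a member of the hotspot set?
in_hotspot <- function(muts, hotspots) {
  if (nrow(hotspots) == 0L) return(rep(FALSE, nrow(muts)))
  paste(muts$cancer_type, muts$gene, muts$residue_pos, muts$alt_aa, sep = "\r") %in%
    paste(hotspots$cancer_type, hotspots$gene, hotspots$residue_pos,
          hotspots$alt_aa, sep = "\r")
}

#' Significant 3D mutation clusters (greedy seed-and-extend, permutation test)
#'
#' Seeds are residues ordered by descending neighbourhood mutation count
#' (total count over residues within `radius`, ties broken by lower residue
#' id). A cluster is the seed plus the not-yet-assigned mutated residues
#' within `radius` of it; its score is the total mutation count it covers,
#' and each residue belongs to at most one cluster. The empirical p-value of
#' a cluster compares its score with the null distribution of the maximum
#' cluster score obtained by dropping the same number of mutations uniformly
#' over the eligible residues: `p = (1 + #{permutation max >= observed}) /
#' (1 + n_perm)`. No correction across clusters or families is applied (the
#' protocol uses raw 5% / 0.5% significance levels); set `bh = TRUE` for an
#' optional Benjamini-Hochberg adjustment across the clusters of one
#' structure.
#'
#' @param counts per-residue mutation counts (`residue_id`, `count`), e.g.
#'   `aggregate_counts(...)$counts`.
#' @param structure the representative [domain_structure()].
#' @param config a [funvar_config()] (radius, permutations, significance
#'   levels, seed).
#' @param eligible residue ids the null may place mutations on; default all
#'   structure residues.
#' @param bh apply BH across this structure's clusters (off by default).
#' @param dist_mat optional precomputed [residue_distance_matrix] for reuse.
#' @return list of clusters, each a list with `residue_ids`,
#'   `mutation_count`, `p_value`, `tier` (`"high"`, `"standard"`, `"none"`).
#' @export
cluster_mutations <- function(counts, structure, config = NULL,
                              eligible = NULL, bh = FALSE, dist_mat = NULL) {
  config <- as_config(config)
  if (is.null(counts) || nrow(counts) == 0L) return(list())
  ids <- residue_ids(structure)
  if (is.null(eligible)) eligible <- ids
  if (!all(counts$residue_id %in% ids))
    stop("counts refer to residues absent from the structure", call. = FALSE)
  if (config$n_perm < 100L) stop("n_perm must be at least 100", call. = FALSE)
  n_total <- sum(counts$count)

  if (length(ids) < 2L) {
    return(list(list(residue_ids = ids, mutation_count = n_total,
                     p_value = 1, tier = "none")))
  }
  if (is.null(dist_mat)) dist_mat <- residue_distance_matrix(structure)
  adj <- dist_mat <= config$cluster_radius

  cnt <- setNames(rep(0L, length(ids)), ids)
  cnt[as.character(counts$residue_id)] <- counts$count
  nbh <- as.numeric(adj %*% cnt)

  # seed order fixed up front: descending neighbourhood count, then residue id
  ord <- order(-nbh, ids)
  assigned <- setNames(rep(FALSE, length(ids)), ids)
  clusters <- list()
  remaining <- cnt
  for (s in ord) {
    sid <- ids[s]
    if (assigned[as.character(sid)]) next
    members <- ids[adj[s, ] & remaining[as.character(ids)] > 0 &
                     !assigned[as.character(ids)]]
    members <- sort(unique(c(if (cnt[as.character(sid)] > 0) sid, members)))
    if (!length(members)) next
    score <- sum(remaining[as.character(members)])
    assigned[as.character(members)] <- TRUE
    remaining[as.character(members)] <- 0L
    clusters[[length(clusters) + 1L]] <-
      list(residue_ids = members, mutation_count = as.integer(score))
  }
  if (!length(clusters)) return(list())

  # permutation null: N mutations dropped uniformly on eligible residues;
  # statistic is the maximum neighbourhood score
  el <- match(eligible, ids)
  set.seed(config$rng_seed)
  perm <- rmultinom(config$n_perm, n_total, rep(1 / length(el), length(el)))
  full <- matrix(0, nrow = length(ids), ncol = config$n_perm)
  full[el, ] <- perm
  null_max <- apply(adj %*% full, 2, max)

  p <- vapply(clusters, function(cl)
    (1 + sum(null_max >= cl$mutation_count)) / (1 + config$n_perm), numeric(1))
  if (bh) p <- p.adjust(p, method = "BH")
  for (i in seq_along(clusters)) {
    clusters[[i]]$p_value <- p[i]
    clusters[[i]]$tier <- if (p[i] <= config$cluster_high_sig) "high"
                          else if (p[i] <= config$cluster_sig) "standard"
                          else "none"
  }
  clusters
}

#' Tunable sites: significant clusters and hotspots near functional sites
#'
#' A cluster with a significant tier whose minimum residue-to-site distance
#' does not exceed `site_distance_cutoff` becomes a tunable site
#' (`source = "cluster"`); projected hotspot residues meeting the same
#' distance criterion become tunable sites (`source = "hotspot"`). The
#' recorded distance is the minimum over all (member residue, site residue)
#' pairs, and the site kinds attaining it are reported.
#'
#' @param clusters [cluster_mutations()] output.
#' @param hotspot_residues structure residue ids of projected hotspots
#'   (possibly empty).
#' @param sites functional-site data frame (see [project_sites()]).
#' @param structure the representative [domain_structure()].
#' @param config a [funvar_config()].
#' @param dist_mat optional precomputed [residue_distance_matrix].
#' @return data frame with one row per tunable site: `site_id`, `source`,
#'   `residue_ids` (comma-joined), `mutation_count`, `p_value`, `tier`,
#'   `min_site_distance`, `nearest_site_kinds` (comma-joined), plus class
#'   `tunable_sites`.
#' @export
make_tunable_sites <- function(clusters, hotspot_residues, sites, structure,
                               config = NULL, dist_mat = NULL) {
  config <- as_config(config)
  empty <- data.frame(site_id = character(0), source = character(0),
                      residue_ids = character(0), mutation_count = integer(0),
                      p_value = numeric(0), tier = character(0),
                      min_site_distance = numeric(0),
                      nearest_site_kinds = character(0), stringsAsFactors = FALSE)
  class(empty) <- c("tunable_sites", "data.frame")
  if (nrow(sites) == 0L) return(empty)
  if (is.null(dist_mat)) dist_mat <- residue_distance_matrix(structure)
  idx <- function(r) match(as.character(r), rownames(dist_mat))
  site_idx <- idx(sites$residue_id)

  min_site <- function(members) {
    d <- dist_mat[idx(members), site_idx, drop = FALSE]
    mn <- min(d)
    kinds <- sort(unique(sites$site_kind[apply(d, 2, min) <= mn + 1e-9]))
    list(dist = mn, kinds = kinds)
  }

  rows <- list()
  k <- 0L
  for (cl in clusters) {
    if (cl$tier == "none") next
    ms <- min_site(cl$residue_ids)
    if (ms$dist > config$site_distance_cutoff) next
    k <- k + 1L
    rows[[length(rows) + 1L]] <- data.frame(
      site_id = sprintf("cluster_%02d", k), source = "cluster",
      residue_ids = paste(cl$residue_ids, collapse = ","),
      mutation_count = cl$mutation_count, p_value = cl$p_value,
      tier = cl$tier, min_site_distance = ms$dist,
      nearest_site_kinds = paste(ms$kinds, collapse = ","),
      stringsAsFactors = FALSE)
  }
  h <- 0L
  for (r in unique(hotspot_residues)) {
    if (is.na(r)) next
    ms <- min_site(r)
    if (ms$dist > config$site_distance_cutoff) next
    h <- h + 1L
    rows[[length(rows) + 1L]] <- data.frame(
      site_id = sprintf("hotspot_%02d", h), source = "hotspot",
      residue_ids = as.character(r), mutation_count = NA_integer_,
      p_value = NA_real_, tier = NA_character_, min_site_distance = ms$dist,
      nearest_site_kinds = paste(ms$kinds, collapse = ","),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("tunable_sites", "data.frame")
  out
}

# residue ids covered by a tunable_sites table
tunable_residues <- function(tunable) {
  if (nrow(tunable) == 0L) return(integer(0))
  sort(unique(as.integer(unlist(strsplit(tunable$residue_ids, ",", fixed = TRUE)))))
}

#' Candidate FIEs: target-cohort mutations inside tunable sites
#'
#' Projects each target-cohort mutation onto the representative structure
#' and retains those whose residue belongs to any tunable site. Mutations at
#' columns gapped in the representative are logged and never FIEs.
#'
#' @param target_muts mutation table for the target cohort (may coincide
#'   with the builder cohort used for the tunable sites).
#' @param tunable a [make_tunable_sites()] table.
#' @param map a [build_column_map()] result.
#' @param bundle the family bundle.
#' @return data frame: the projectable target mutations with `rep_residue`,
#'   `is_fie`, and `tunable_source` (comma-joined provenance of the matching
#'   tunable sites, `""` for non-FIEs).
#' @export
call_fies <- function(target_muts, tunable, map, bundle) {
  if (is.null(target_muts) || nrow(target_muts) == 0L) {
    out <- cbind(as.data.frame(target_muts),
                 rep_residue = integer(0), is_fie = logical(0),
                 tunable_source = character(0))
    return(out)
  }
  res <- vapply(seq_len(nrow(target_muts)), function(i)
    project_to_representative(target_muts[i, ], map, bundle), integer(1))
  gapped <- sum(is.na(res))
  if (gapped > 0L)
    message("call_fies: ", gapped, " target mutation(s) at gapped/unmapped columns")
  tun_res <- tunable_residues(tunable)
  src <- character(nrow(target_muts))
  if (nrow(tunable) > 0L) {
    per_site <- strsplit(tunable$residue_ids, ",", fixed = TRUE)
    for (i in seq_len(nrow(target_muts))) {
      if (is.na(res[i])) next
      hit <- vapply(per_site, function(rr) as.character(res[i]) %in% rr, logical(1))
      src[i] <- paste(unique(tunable$source[hit]), collapse = ",")
    }
  }
  out <- as.data.frame(target_muts)
  out$rep_residue <- res
  out$is_fie <- !is.na(res) & res %in% tun_res
  out$tunable_source <- src
  rownames(out) <- NULL
  out
}
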