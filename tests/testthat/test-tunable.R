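test_that("hotspots require identical changes in >= 2 patients of one cancer type", {
  base <- rbind(
    make_mut("P1", 858, "L", "R", tumor_id = "pt1", cancer_type = "LUAD", gene = "EGFR"),
    make_mut("P1", 858, "L", "R", tumor_id = "pt2", cancer_type = "LUAD", gene = "EGFR"))
  hs <- find_hotspots(base)
  expect_equal(nrow(hs), 1L)
  expect_equal(hs$residue_pos, 858L)
  expect_equal(hs$n_patients, 2L)

  # same change split across cancer types: not a hotspot
  split_ct <- base
  split_ct$cancer_type <- c("LUAD", "LUSC")
  expect_equal(nrow(find_hotspots(split_ct)), 0L)

  # same patient twice (two samples): not a hotspot
  same_pt <- base
  same_pt$tumor_id <- c("pt1", "pt1")
  expect_equal(nrow(find_hotspots(same_pt)), 0L)

  # different alt_aa at the same position: not a hotspot
  diff_alt <- base
  diff_alt$alt_aa <- c("R", "Q")
  expect_equal(nrow(find_hotspots(diff_alt)), 0L)
})

test_that("residue distances are minimum inter-atomic and metric-sane", {
  s <- domain_structure(data.frame(
    residue_id = c(1L, 2L), aa = "A", atom = "CA",
    x = c(0, 3), y = c(0, 4), z = 0))
  expect_equal(residue_distance(s, 1, 1), 0)
  expect_equal(residue_distance(s, 1, 2), 5)  # 3-4-5 triangle
  expect_equal(residue_distance(s, 2, 1), 5)

  # multi-atom residues: equals the brute-force min over all atom pairs
  set.seed(7)
  multi <- domain_structure(data.frame(
    residue_id = rep(1:4, each = 3), aa = "A",
    atom = rep(c("N", "CA", "CB"), 4),
    x = runif(12, 0, 20), y = runif(12, 0, 20), z = runif(12, 0, 20)))
  for (i in 1:4) for (j in 1:4)
    expect_equal(residue_distance(multi, i, j),
                 brute_min_distance(multi, i, j), tolerance = 1e-9)
  # and the full matrix agrees with the pairwise function
  dm <- funvar:::residue_distance_matrix(multi)
  expect_equal(dm["2", "3"], residue_distance(multi, 2, 3), tolerance = 1e-9)
})

test_that("planted clusters are recovered as significant; null is not", {
  toy <- make_toy_funfam(seed = 41, n_columns = 50L,
                         n_planted_cluster_residues = 3L,
                         n_cluster_mutations = 20L)
  map <- build_column_map(toy$bundle)
  agg <- aggregate_counts(toy$builder_mutations, map, toy$bundle)
  cl <- cluster_mutations(agg$counts, toy$bundle$structure,
                          funvar_config(rng_seed = 99L))
  top <- cl[[which.max(vapply(cl, `[[`, integer(1), "mutation_count"))]]
  expect_setequal(intersect(top$residue_ids, toy$truth$cluster_residues),
                  toy$truth$cluster_residues)
  expect_lte(top$p_value, 0.005)
  expect_equal(top$tier, "high")

  # zero mutations -> no clusters
  empty <- data.frame(residue_id = integer(0), count = integer(0))
  expect_equal(cluster_mutations(empty, toy$bundle$structure), list())
})

test_that("cluster p-values match an exhaustive permutation oracle on a toy chain", {
  # 6-residue chain, neighbourhoods are +/- 1 residue at the 5 A radius;
  # 3 mutations on residues (1, 2, 2): top cluster score 3
  s <- domain_structure(data.frame(residue_id = 1:6, aa = "A", atom = "CA",
                                   x = (0:5) * 3.8, y = 0, z = 0))
  counts <- data.frame(residue_id = c(1L, 2L), count = c(1L, 2L))
  cl <- cluster_mutations(counts, s, funvar_config(n_perm = 2000L, rng_seed = 3L))
  obs <- max(vapply(cl, `[[`, integer(1), "mutation_count"))
  expect_equal(obs, 3L)

  # exact null: every one of 6^3 uniform assignments of 3 mutations
  nbr <- function(r) intersect(c(r - 1L, r, r + 1L), 1:6)
  grid <- expand.grid(m1 = 1:6, m2 = 1:6, m3 = 1:6)
  max_stat <- apply(grid, 1, function(g) {
    cnt <- tabulate(g, 6)
    max(vapply(1:6, function(r) sum(cnt[nbr(r)]), numeric(1)))
  })
  p_exact <- mean(max_stat >= obs)
  p_emp <- min(vapply(cl, `[[`, numeric(1), "p_value"))
  expect_equal(p_emp, p_exact, tolerance = 0.05)
})

test_that("degenerate structures yield the documented trivial cluster", {
  s1 <- domain_structure(data.frame(residue_id = 1L, aa = "A", atom = "CA",
                                    x = 0, y = 0, z = 0))
  cl <- cluster_mutations(data.frame(residue_id = 1L, count = 5L), s1)
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$p_value, 1)
  expect_equal(cl[[1]]$tier, "none")
})

test_that("tunable sites apply both the significance and the distance gates", {
  # residues 1..3 clustered; site residue 4 placed at controlled distances
  mk <- function(site_dist) domain_structure(data.frame(
    residue_id = 1:4, aa = "A", atom = "CA",
    x = c(0, 1, 2, 2 + site_dist), y = 0, z = 0))
  sites <- data.frame(residue_id = 4L, site_kind = "catalytic",
                      provenance = "t")
  sig_cluster <- list(list(residue_ids = 1:3, mutation_count = 10L,
                           p_value = 0.001, tier = "high"))
  nonsig_cluster <- list(list(residue_ids = 1:3, mutation_count = 2L,
                              p_value = 0.4, tier = "none"))

  near <- make_tunable_sites(sig_cluster, integer(0), sites, mk(3.2))
  expect_equal(nrow(near), 1L)
  expect_equal(near$source, "cluster")
  expect_equal(near$min_site_distance, 3.2)
  expect_equal(near$nearest_site_kinds, "catalytic")

  far <- make_tunable_sites(sig_cluster, integer(0), sites, mk(6.1))
  expect_equal(nrow(far), 0L)

  close_nonsig <- make_tunable_sites(nonsig_cluster, integer(0), sites, mk(1.0))
  expect_equal(nrow(close_nonsig), 0L)

  # hotspot residues pass through the same distance gate
  hot_near <- make_tunable_sites(list(), 3L, sites, mk(3.2))
  expect_equal(hot_near$source, "hotspot")
  hot_far <- make_tunable_sites(list(), 1L, sites, mk(3.2))
  expect_equal(nrow(hot_far), 0L)  # residue 1 is 5.2 A from the site
})

test_that("tunable-site output grows monotonically with the distance cutoff", {
  toy <- make_toy_funfam(seed = 42)
  map <- build_column_map(toy$bundle)
  agg <- aggregate_counts(toy$builder_mutations, map, toy$bundle)
  sites <- project_sites(toy$bundle, integer(0), map)
  cl <- cluster_mutations(agg$counts, toy$bundle$structure,
                          funvar_config(rng_seed = 1L))
  prev <- -1L
  for (cutoff in c(1, 3, 5, 10)) {
    tun <- make_tunable_sites(cl, integer(0), sites, toy$bundle$structure,
                              funvar_config(site_distance_cutoff = cutoff))
    expect_gte(nrow(tun), prev)
    prev <- nrow(tun)
  }
})

test_that("call_fies matches mutations to tunable residues with self-consistency", {
  toy <- make_toy_funfam(seed = 43)
  cfg <- funvar_config(rng_seed = 8L)
  res <- funvar_pipeline(toy$bundle, toy$builder_mutations, config = cfg)
  map <- build_column_map(toy$bundle)
  called <- call_fies(toy$builder_mutations, res$tunable, map, toy$bundle)
  tun_res <- sort(unique(as.integer(unlist(
    strsplit(res$tunable$residue_ids, ",")))))
  # with builder == target, every mutation projecting into a tunable residue
  # is called a FIE, and only those
  expect_equal(called$is_fie,
               !is.na(called$rep_residue) & called$rep_residue %in% tun_res)
  expect_true(any(called$is_fie))
  expect_true(all(nzchar(called$tunable_source[called$is_fie])))
  expect_false(any(nzchar(called$tunable_source[!called$is_fie])))
})

test_that("null p-values are calibrated at the 5% level", {
  # modest replicate count here; the acceptance suite runs the full design
  hits <- 0L
  n_rep <- 60L
  for (s in seq_len(n_rep)) {
    nf <- make_null_funfam(seed = 4000L + s, n_residues = 50L, n_mutations = 50L)
    cl <- cluster_mutations(nf$counts, nf$structure,
                            funvar_config(rng_seed = 8000L + s))
    if (min(vapply(cl, `[[`, numeric(1), "p_value")) <= 0.05) hits <- hits + 1L
  }
  # 99% binomial band around 0.05 for 60 trials: [0, 8]
  expect_lte(hits, qbinom(0.995, n_rep, 0.05) + 1L)
})
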