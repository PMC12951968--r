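test_that("Grantham components follow the matrix and polymorphism rule", {
  # L->R = 102: medium band (64 < 102 <= 109)
  expect_equal(grantham_component("L", "R"), 1L)
  # C->W = 215: high band
  expect_equal(grantham_component("C", "W"), 2L)
  # polymorphic zeroes the component regardless of impact
  expect_equal(grantham_component("C", "W", pop_vaf = 1e-3), 0L)
  # at the VAF threshold itself the mutation is not polymorphic (strict >)
  expect_equal(grantham_component("C", "W", pop_vaf = 1e-7), 2L)
  # L->I = 5: below the medium threshold
  expect_equal(grantham_component("L", "I"), 0L)
  # boundary: A->V = 64 is not medium (strict >)
  expect_equal(grantham_distance("A", "V"), 64)
  expect_equal(grantham_component("A", "V"), 0L)
  # V->G = 109 is medium, not high
  expect_equal(grantham_distance("V", "G"), 109)
  expect_equal(grantham_component("V", "G"), 1L)
  expect_error(grantham_component("B", "R"), "unknown amino acid")
})

test_that("the embedded Grantham matrix is symmetric with zero diagonal", {
  m <- grantham_matrix()
  expect_equal(dim(m), c(20L, 20L))
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(0, 20))
  expect_equal(range(m[upper.tri(m)]), c(5, 215))
  # component symmetry follows
  set.seed(11)
  for (k in 1:20) {
    pair <- sample(rownames(m), 2)
    expect_equal(grantham_component(pair[1], pair[2]),
                 grantham_component(pair[2], pair[1]))
  }
})

test_that("sequence components combine Grantham, hotspot and disease flags", {
  hs <- data.frame(cancer_type = "LUAD", gene = "G1", residue_pos = 10L,
                   alt_aa = "W", n_patients = 2L)
  # hotspot member, disease-annotated, high Grantham: subtotal 4
  m1 <- make_mut("P1", 10, "C", "W", disease_variant = TRUE)
  c1 <- sequence_components(m1, hs)
  expect_equal(unlist(c1), c(grantham = 2L, hotspot = 1L, disease_variant = 1L))
  # non-hotspot, no flag, conservative change: subtotal 0
  m2 <- make_mut("P1", 11, "L", "I")
  expect_equal(sum(sequence_components(m2, hs)), 0L)
  # hotspot membership alone: subtotal 1
  m3 <- make_mut("P1", 10, "L", "W")
  m3$ref_aa <- "F"  # F->W = 40, below medium
  c3 <- sequence_components(m3, hs)
  expect_equal(sum(c3), 1L)
  expect_equal(c3$hotspot, 1L)
})

test_that("structure components score on/near sites independently per class", {
  # single-atom residues on a line: 1 at x=0, site residues at known x
  s <- domain_structure(data.frame(
    residue_id = 1:5, aa = "A", atom = "CA",
    x = c(0, 4.9, 10, 17, 30), y = 0, z = 0))
  sites <- data.frame(residue_id = c(1L, 1L, 3L),
                      site_kind = c("catalytic", "predicted", "predicted"),
                      provenance = "t")
  # residue 1 is both a known and a predicted site: on+near for both = 4
  c1 <- structure_components(1L, sites, list(), s)
  expect_equal(unlist(c1), c(on_known = 1L, near_known = 1L, on_predicted = 1L,
                             near_predicted = 1L, high_sig_cluster = 0L))
  # residue 2 is 4.9 A from the known site at residue 1: near only
  c2 <- structure_components(2L, sites[1, ], list(), s)
  expect_equal(unlist(c2), c(on_known = 0L, near_known = 1L, on_predicted = 0L,
                             near_predicted = 0L, high_sig_cluster = 0L))
  # residue 5 in a p = 0.004 cluster, > 5 A from every site
  cl <- list(list(residue_ids = 5L, mutation_count = 3L, p_value = 0.004,
                  tier = "high"))
  c5 <- structure_components(5L, sites, cl, s)
  expect_equal(sum(c5[c("on_known", "near_known", "on_predicted",
                        "near_predicted")]), 0L)
  expect_equal(c5$high_sig_cluster, 1L)
  # a p = 0.04 cluster is standard-tier: no high-significance component
  cl2 <- list(list(residue_ids = 5L, mutation_count = 3L, p_value = 0.04,
                   tier = "standard"))
  expect_equal(structure_components(5L, sites, cl2, s)$high_sig_cluster, 0L)
})

test_that("family enrichment matches the exact binomial oracle", {
  # 10 of 10 mutations in a domain spanning 10% of the length
  r <- mutfam_enrichment(10L, 10L, 0L, 90L)
  expect_equal(r$p_value, 0.1^10, tolerance = 1e-9)
  expect_true(r$flag)
  # mutations proportional to length: no enrichment
  r2 <- mutfam_enrichment(10L, 100L, 90L, 900L)
  expect_gt(r2$p_value, 0.4)
  expect_false(r2$flag)
  # zero mutations
  r3 <- mutfam_enrichment(0L, 50L, 0L, 500L)
  expect_equal(r3$p_value, 1)
  expect_false(r3$flag)
  # vectorised across families with BH adjustment
  rv <- mutfam_enrichment(c(10L, 1L), c(10L, 10L), c(0L, 9L), c(90L, 90L))
  expect_equal(rv$p_value[1], 0.1^10, tolerance = 1e-9)
  expect_false(rv$flag[2])
  # cross-check a non-trivial case against binom.test directly
  expect_equal(mutfam_enrichment(7L, 25L, 13L, 75L)$p_value,
               binom.test(7, 20, 0.25, alternative = "greater")$p.value)
})

test_that("total scores sum components within the documented bounds", {
  full <- data.frame(grantham = 2L, hotspot = 1L, disease_variant = 1L,
                     on_known = 1L, near_known = 1L, on_predicted = 1L,
                     near_predicted = 1L, high_sig_cluster = 1L, mutfam = 1L)
  expect_equal(total_fie_score(full), 10L)
  minimal <- full; minimal[1, ] <- 0L; minimal$near_known <- 1L
  expect_equal(total_fie_score(minimal), 1L)
  mixed <- full; mixed[1, ] <- 0L
  mixed$grantham <- 1L; mixed$hotspot <- 1L
  mixed$on_known <- 1L; mixed$near_known <- 1L
  expect_equal(total_fie_score(mixed), 4L)
  bad <- full; bad$grantham <- 3L
  expect_error(total_fie_score(bad), "allowed set")
  bad2 <- full; bad2$hotspot <- 2L
  expect_error(total_fie_score(bad2), "allowed set")
})

test_that("exhaustive component enumeration attains the documented extremes", {
  combos <- expand.grid(grantham = 0:2, hotspot = 0:1, disease_variant = 0:1,
                        on_known = 0:1, near_known = 0:1, on_predicted = 0:1,
                        near_predicted = 0:1, high_sig_cluster = 0:1,
                        mutfam = 0:1)
  # respect the on => near implication before summing
  combos$near_known <- pmax(combos$near_known, combos$on_known)
  combos$near_predicted <- pmax(combos$near_predicted, combos$on_predicted)
  totals <- total_fie_score(combos)
  expect_equal(max(totals), 10L)
  expect_equal(min(totals), 0L)  # only tunable-site membership forces >= 1
  seq_sub <- combos$grantham + combos$hotspot + combos$disease_variant
  str_sub <- combos$on_known + combos$near_known + combos$on_predicted +
    combos$near_predicted + combos$high_sig_cluster
  site_sub <- str_sub - combos$high_sig_cluster
  expect_lte(max(seq_sub), 4L)
  expect_lte(max(str_sub), 5L)
  expect_equal(max(site_sub), 4L)
  expect_true(all(totals == seq_sub + str_sub + combos$mutfam))
})

test_that("threshold filtering keeps scores >= 3 and is monotone", {
  recs <- data.frame(total = 1:4)
  split <- apply_threshold(recs)
  expect_equal(split$retained$total, c(3L, 4L))
  expect_equal(split$below$total, c(1L, 2L))
  expect_equal(nrow(apply_threshold(recs[0, , drop = FALSE])$retained), 0L)
  all_kept <- apply_threshold(recs, funvar_config(fie_score_threshold = 1L))
  expect_equal(nrow(all_kept$retained), 4L)
  prev <- nrow(recs) + 1L
  for (t in 1:5) {
    kept <- nrow(apply_threshold(recs,
                                 funvar_config(fie_score_threshold = t))$retained)
    expect_lte(kept, prev)
    prev <- kept
  }
})

test_that("family flags use strict EC-count inequality and the moonlighting list", {
  mk_bundle <- function(ec, moon) {
    toy <- make_toy_funfam(seed = 51)
    b <- toy$bundle
    b$ec_count_superfamily <- ec
    b$moonlighting <- moon
    b
  }
  rec <- data.frame(gene = "G1")
  expect_true(annotate_family_flags(rec, mk_bundle(11L, FALSE))$diverse_family)
  expect_false(annotate_family_flags(rec, mk_bundle(10L, FALSE))$diverse_family)
  expect_true(annotate_family_flags(rec, mk_bundle(2L, TRUE))$moonlighting)
})

test_that("scored FIE records satisfy the score invariants end to end", {
  toy <- make_toy_funfam(seed = 52)
  res <- funvar_pipeline(toy$bundle, toy$builder_mutations,
                         config = funvar_config(rng_seed = 2L))
  sc <- res$scored
  expect_gt(nrow(sc), 0L)
  expect_true(all(sc$total >= 1 & sc$total <= 10))
  expect_true(all(sc$near_known >= sc$on_known))
  expect_true(all(sc$near_predicted >= sc$on_predicted))
  expect_equal(sc$total,
               sc$grantham + sc$hotspot + sc$disease_variant + sc$on_known +
                 sc$near_known + sc$on_predicted + sc$near_predicted +
                 sc$high_sig_cluster + sc$mutfam)
})
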