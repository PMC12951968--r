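test_that("observed Hill-Shannon diversity matches closed forms", {
  expect_equal(hill_shannon(abundance_vector(c(5, 5, 5, 5))), 4.0)
  expect_equal(hill_shannon(abundance_vector(c(10))), 1.0)
  # counts [4,2,2]: exp(0.5 ln2 + 2 * 0.25 * ln4) = 2 * sqrt(2)
  expect_equal(hill_shannon(abundance_vector(c(4, 2, 2))), 2 * sqrt(2),
               tolerance = 1e-12)
  expect_error(abundance_vector(integer(0)), "empty")
  expect_error(abundance_vector(c(1, 0)), "positive")
})

test_that("q = 0 and q = 2 are available behind the same interface", {
  v <- abundance_vector(c(4, 2, 2))
  expect_equal(hill_diversity(v, 0), 3)
  expect_equal(hill_diversity(v, 2), 1 / sum((c(4, 2, 2) / 8)^2))
  # equal abundances: all orders agree with the label count
  ve <- abundance_vector(c(3, 3, 3))
  for (q in 0:2) expect_equal(hill_diversity(ve, q), 3)
})

test_that("rarefaction matches brute-force subsample enumeration (n <= 12)", {
  vectors <- list(c(2, 2), c(4, 2, 2), c(1, 1, 1), c(5, 3, 2, 1, 1),
                  c(6, 6), c(3, 3, 3, 3), c(9, 1), c(2, 2, 2, 1, 1))
  for (counts in vectors) {
    v <- abundance_vector(counts)
    for (m in seq_len(v$n)) {
      expect_equal(hill_estimate(v, m)$value,
                   enumerate_rarefied_hill(counts, m), tolerance = 1e-9,
                   label = sprintf("counts [%s], m=%d",
                                   paste(counts, collapse = ","), m))
    }
  }
})

test_that("rarefaction endpoints and monotonicity hold", {
  v <- abundance_vector(c(2, 2))
  # the documented toy case: exp((2/3) ln 2) at m = 2 of n = 4
  expect_equal(hill_estimate(v, 2)$value, exp((2 / 3) * log(2)),
               tolerance = 1e-12)
  expect_equal(hill_estimate(v, 1)$value, 1.0)
  expect_equal(hill_estimate(v, v$n)$value, hill_shannon(v))
  expect_equal(hill_estimate(v, v$n)$mode, "observed")
  # monotone non-decreasing over the rarefaction range
  v2 <- abundance_vector(c(7, 4, 2, 1, 1))
  vals <- vapply(1:v2$n, function(m) hill_estimate(v2, m)$value, numeric(1))
  expect_true(all(diff(vals) >= -1e-12))
  expect_error(rarefied_hill_shannon(v2, v2$n + 1L), "extrapolated")
  expect_error(hill_estimate(v2, 0), "at least 1")
})

test_that("extrapolation is continuous, monotone and asymptotically bounded", {
  # no singletons: extrapolated value equals the observed value for all m
  v0 <- abundance_vector(c(3, 3, 3))
  for (m in c(10, 12, 50, 500))
    expect_equal(hill_estimate(v0, m)$value, 3.0, tolerance = 1e-12)
  # with singletons: continuity at m = n + 1 and monotone growth to the
  # asymptote
  v <- abundance_vector(c(4, 3, 2, 1, 1))
  obs <- hill_shannon(v)
  step <- hill_estimate(v, v$n + 1L)$value
  expect_gte(step, obs)
  expect_lt(step - obs, 0.2)  # one singleton-correction step, not a jump
  grid <- c(v$n + 1L, 2L * v$n, 5L * v$n, 50L * v$n)
  vals <- vapply(grid, function(m) hill_estimate(v, m)$value, numeric(1))
  expect_true(all(diff(vals) >= -1e-12))
  expect_true(all(vals >= obs))
  expect_error(extrapolated_hill_shannon(v, v$n), "rarefied")
  # all-singleton vectors have no defined asymptote
  vs <- abundance_vector(c(1, 1, 1))
  expect_warning(e <- extrapolated_hill_shannon(vs, 6L), "singletons")
  expect_equal(e$value, hill_shannon(vs))
})

test_that("sample coverage follows the singleton/doubleton formula", {
  expect_equal(sample_coverage(abundance_vector(c(5, 5))), 1.0)
  expect_equal(sample_coverage(abundance_vector(c(1, 1, 1))), 0.0)
  v <- abundance_vector(c(3, 2, 1, 1))
  cov <- sample_coverage(v)
  expect_gt(cov, 0); expect_lt(cov, 1)
  # direct formula evaluation: n=7, f1=2, f2=1
  expect_equal(cov, 1 - (2 / 7) * (6 * 2 / (6 * 2 + 2)), tolerance = 1e-12)
  # coverage is 1 iff there are no singletons
  expect_equal(sample_coverage(abundance_vector(c(2, 2, 3))), 1.0)
})

test_that("bootstrap intervals are deterministic and contain the estimate", {
  v <- abundance_vector(c(6, 4, 3, 2, 1, 1, 1))
  grid <- c(5L, v$n, 2L * v$n)
  ci1 <- bootstrap_ci(v, grid, B = 100L, seed = 42L)
  ci2 <- bootstrap_ci(v, grid, B = 100L, seed = 42L)
  expect_identical(ci1, ci2)
  expect_true(all(ci1$ci_low <= ci1$value & ci1$value <= ci1$ci_high))
  expect_equal(ci1$mode, c("interpolated", "observed", "extrapolated"))
  # a different seed moves the interval but not the point estimate
  ci3 <- bootstrap_ci(v, grid, B = 100L, seed = 7L)
  expect_equal(ci3$value, ci1$value)
  # degenerate single-label vector: CI collapses to [1, 1] everywhere
  cid <- bootstrap_ci(abundance_vector(c(100)), c(1L, 50L, 200L),
                      B = 60L, seed = 1L)
  expect_true(all(cid$ci_low == 1 & cid$ci_high == 1 & cid$value == 1))
  expect_error(bootstrap_ci(v, grid, B = 10L), "at least 50")
})

test_that("group comparison flags planted diversity differences only", {
  cfg <- funvar_config(bootstrap_reps = 100L, rng_seed = 9L)
  # identical vectors: overlapping CIs, not significant
  v <- abundance_vector(c(8, 5, 3, 2, 1, 1))
  same <- compare_groups(v, v, cfg)
  expect_false(same$significant)
  # planted rich vs poor communities
  set.seed(1)
  poor <- abundance_vector(table(sample(paste0("g", 1:5), 100, TRUE,
                                        prob = c(.6, .2, .1, .05, .05))))
  rich <- abundance_vector(table(sample(paste0("g", 1:50), 100, TRUE)))
  cmp <- compare_groups(poor, rich, cfg)
  expect_true(cmp$significant)
  expect_equal(cmp$higher, "post")
  expect_equal(cmp$m_compare, ceiling(2 * max(poor$n, rich$n)))
  # curve table is complete for plotting
  expect_true(all(c("group", "m", "value", "ci_low", "ci_high",
                    "log2_m", "log2_value") %in% names(cmp$curves)))
  # small groups warn but still compare
  expect_warning(compare_groups(abundance_vector(c(2, 1)), v, cfg),
                 "fewer than 5")
})

test_that("abundance stratification pulls groups out of timed records", {
  recs <- data.frame(
    gene = c("A", "A", "B", "C", "C", "D"),
    funfam_id = "FF1",
    timing = c("pre", "pre", "pre", "post", "post", "post"),
    stringsAsFactors = FALSE)
  ab <- fie_abundance(recs, "gene", "timing")
  expect_setequal(names(ab), c("pre", "post"))
  expect_equal(ab$pre$n, 3L)
  expect_equal(sort(ab$pre$counts, decreasing = TRUE), c(2L, 1L))
  expect_equal(ab$post$f1, 1L)  # D is a singleton post
})
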