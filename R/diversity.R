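#' Abundance vector of FIEs (or mutations) per gene or family
#'
#' @param x positive integer counts (optionally named by gene/family), or a
#'   character vector of labels to be tabulated (one element per FIE).
#' @return object of class `abundance_vector`: list with `labels`, `counts`,
#'   `n` (total count), `f1` (singletons) and `f2` (doubletons).
#' @examples
#' abundance_vector(c(KRAS = 9, TP53 = 4, GPI = 1))
#' @export
abundance_vector <- function(x) {
  if (is.character(x) || is.factor(x)) {
    tab <- table(x)
    counts <- as.integer(tab); labels <- names(tab)
  } else {
    counts <- as.integer(x)
    labels <- if (!is.null(names(x))) names(x) else paste0("label_", seq_along(x))
  }
  if (!length(counts)) stop("empty abundance vector", call. = FALSE)
  if (any(is.na(counts)) || any(counts <= 0))
    stop("abundance counts must be positive integers", call. = FALSE)
  structure(list(labels = labels, counts = counts, n = sum(counts),
                 f1 = sum(counts == 1L), f2 = sum(counts == 2L)),
            class = "abundance_vector")
}

#' @export
print.abundance_vector <- function(x, ...) {
  cat(sprintf("abundance vector: %d labels, n = %d (f1 = %d, f2 = %d)\n",
              length(x$counts), x$n, x$f1, x$f2))
  invisible(x)
}

as_abundance <- function(v) {
  if (inherits(v, "abundance_vector")) v else abundance_vector(v)
}

#' Observed Hill diversity
#'
#' Effective number of labels at order `q`: richness (`q = 0`), the Shannon
#' component `exp(-sum p_i log p_i)` (`q = 1`, the default used throughout),
#' or Simpson (`q = 2`).
#'
#' @param v an [abundance_vector()] (or counts coercible to one).
#' @param q Hill order.
#' @return diversity (>= 1).
#' @export
hill_diversity <- function(v, q = 1) {
  v <- as_abundance(v)
  p <- v$counts / v$n
  if (q == 0) return(length(p))
  if (q == 1) return(exp(-sum(p * log(p))))
  sum(p^q)^(1 / (1 - q))
}

#' @rdname hill_diversity
#' @export
hill_shannon <- function(v) hill_diversity(v, q = 1)

# Exact expected Shannon entropy of a size-m subsample without replacement:
# per-label hypergeometric expectation of (X/m) log(X/m).
.rarefied_entropy <- function(counts, n, m) {
  H <- 0
  for (ci in counts) {
    k <- seq_len(min(ci, m))
    H <- H - sum((k / m) * log(k / m) * dhyper(k, ci, n - ci, m))
  }
  H
}

# Chao-style asymptotic Shannon entropy estimator (singleton/doubleton
# corrected). f1 = 0 is treated as a complete sample (observed entropy).
.asymptotic_entropy <- function(v) {
  n <- v$n; f1 <- v$f1; f2 <- v$f2
  Hobs <- -sum((v$counts / n) * log(v$counts / n))
  if (f1 == 0L) return(Hobs)
  part1 <- sum(vapply(v$counts[v$counts <= n - 1L], function(ci)
    (ci / n) * sum(1 / seq(ci, n - 1L)), numeric(1)))
  A <- if (f2 > 0L) 2 * f2 / ((n - 1) * f1 + 2 * f2)
       else if (f1 > 1L) 2 / ((n - 1) * (f1 - 1) + 2)
       else 1
  part2 <- 0
  if (A < 1) {
    r <- seq_len(n - 1L)
    part2 <- (f1 / n) * (1 - A)^(1 - n) *
      (-log(A) - sum((1 / r) * (1 - A)^r))
  }
  max(part1 + part2, Hobs)  # floor at the observed entropy for monotonicity
}

.diversity_estimate <- function(m, value, mode, ci_low = NA_real_,
                                ci_high = NA_real_) {
  structure(list(m = m, value = value, mode = mode,
                 ci_low = ci_low, ci_high = ci_high),
            class = "diversity_estimate")
}

#' @export
print.diversity_estimate <- function(x, ...) {
  cat(sprintf("Hill diversity %.4f at m = %d (%s)%s\n", x$value, x$m, x$mode,
              if (!is.na(x$ci_low))
                sprintf(" [%.4f, %.4f]", x$ci_low, x$ci_high) else ""))
  invisible(x)
}

#' Rarefied, observed or extrapolated Hill diversity at sample size m
#'
#' For `m <= n` the estimate is exact: the expectation over all
#' equally-likely size-`m` subsamples drawn without replacement
#' (hypergeometric expectation per label). For `m > n` the entropy
#' (`q = 1`) is the blend `(n/m) H_obs + ((m-n)/m) H_asy` of the observed
#' entropy and the singleton/doubleton-corrected asymptotic entropy
#' estimator, which is continuous with the rarefaction curve at `m = n`,
#' monotone non-decreasing in `m` and approaches the asymptote as
#' `m -> Inf`. Orders 0 and 2 use the standard sample-size-based
#' rarefaction/extrapolation formulas.
#'
#' @param v an [abundance_vector()].
#' @param m target sample size (>= 1).
#' @param q Hill order (0, 1 or 2; default 1).
#' @return a `diversity_estimate` (list with `m`, `value`, `mode`).
#' @export
hill_estimate <- function(v, m, q = 1) {
  v <- as_abundance(v)
  n <- v$n
  if (m < 1) stop("m must be at least 1", call. = FALSE)
  if (m == n)
    return(.diversity_estimate(m, hill_diversity(v, q), "observed"))
  if (m < n) {
    value <- switch(as.character(q),
      "0" = sum(1 - exp(lchoose(n - v$counts, m) - lchoose(n, m))),
      "1" = exp(.rarefied_entropy(v$counts, n, m)),
      "2" = 1 / (1 / m + (1 - 1 / m) *
                   sum(v$counts * (v$counts - 1)) / (n * (n - 1))),
      stop("q must be 0, 1 or 2", call. = FALSE))
    return(.diversity_estimate(m, value, "interpolated"))
  }
  # extrapolation
  if (q == 1) {
    if (v$f1 == n) {
      warning("all labels are singletons; asymptote undefined, returning the observed value",
              call. = FALSE)
      return(.diversity_estimate(m, hill_diversity(v, 1), "extrapolated"))
    }
    if (n < 2L) stop("extrapolation needs n >= 2", call. = FALSE)
    Hobs <- -sum((v$counts / n) * log(v$counts / n))
    Hasy <- .asymptotic_entropy(v)
    value <- exp((n / m) * Hobs + ((m - n) / m) * Hasy)
  } else if (q == 0) {
    f0 <- .chao_f0(v)
    value <- if (v$f1 == 0L) length(v$counts)
             else length(v$counts) +
               f0 * (1 - (1 - v$f1 / (n * f0 + v$f1))^(m - n))
  } else if (q == 2) {
    value <- 1 / (1 / m + (1 - 1 / m) *
                    sum(v$counts * (v$counts - 1)) / (n * (n - 1)))
  } else stop("q must be 0, 1 or 2", call. = FALSE)
  .diversity_estimate(m, value, "extrapolated")
}

#' @rdname hill_estimate
#' @export
rarefied_hill_shannon <- function(v, m) {
  v <- as_abundance(v)
  if (m > v$n) stop("m must not exceed n for rarefaction; use extrapolated_hill_shannon",
                    call. = FALSE)
  hill_estimate(v, m, q = 1)
}

#' @rdname hill_estimate
#' @export
extrapolated_hill_shannon <- function(v, m) {
  v <- as_abundance(v)
  if (m <= v$n) stop("m must exceed n for extrapolation; use rarefied_hill_shannon",
                     call. = FALSE)
  hill_estimate(v, m, q = 1)
}

# Chao1-style estimated number of unseen labels.
.chao_f0 <- function(v) {
  n <- v$n
  if (v$f1 == 0L) return(0)
  if (v$f2 > 0L) ((n - 1) / n) * v$f1^2 / (2 * v$f2)
  else ((n - 1) / n) * v$f1 * (v$f1 - 1) / 2
}

#' Estimated sample coverage
#'
#' Chao-style coverage: `1 - (f1/n) * (n-1) f1 / ((n-1) f1 + 2 f2)`. Equals
#' 1 exactly when there are no singletons; approaches 0 when every label is
#' a singleton.
#'
#' @param v an [abundance_vector()].
#' @return coverage in `[0, 1]`.
#' @export
sample_coverage <- function(v) {
  v <- as_abundance(v)
  n <- v$n
  if (v$f1 == 0L) return(1)
  if (n == 1L) return(0)
  1 - (v$f1 / n) * ((n - 1) * v$f1 / ((n - 1) * v$f1 + 2 * v$f2))
}

# Coverage-adjusted bootstrap label distribution (observed labels with
# shrunken probabilities plus the estimated unseen mass split over f0
# pseudo-labels).
.bootstrap_probs <- function(v) {
  n <- v$n
  Chat <- sample_coverage(v)
  p <- v$counts / n
  denom <- sum(p * (1 - p)^n)
  lambda <- if (denom > 0) (1 - Chat) / denom else 0
  p_adj <- p * (1 - lambda * (1 - p)^n)
  f0 <- ceiling(.chao_f0(v))
  if (f0 > 0L && Chat < 1) c(p_adj, rep((1 - Chat) / f0, f0)) else p_adj
}

#' Bootstrap confidence intervals for the diversity curve
#'
#' Draws `B` bootstrap abundance vectors of size `n` from the
#' coverage-adjusted estimated label distribution and recomputes the
#' rarefaction/extrapolation estimate at every requested size. Percentile
#' intervals by default; `method = "normal"` uses a normal approximation
#' around the point estimate with the bootstrap standard error.
#' Deterministic under a fixed seed.
#'
#' @param v an [abundance_vector()].
#' @param m_grid sample sizes at which intervals are wanted.
#' @param B bootstrap replicates (>= 50).
#' @param seed integer seed.
#' @param conf confidence level.
#' @param q Hill order.
#' @param method `"percentile"` or `"normal"`.
#' @return data frame `m`, `mode`, `value` (point estimate from `v`),
#'   `ci_low`, `ci_high`.
#' @export
bootstrap_ci <- function(v, m_grid, B = 200L, seed = 1L, conf = 0.95, q = 1,
                         method = c("percentile", "normal")) {
  method <- match.arg(method)
  v <- as_abundance(v)
  if (B < 50L) stop("B must be at least 50", call. = FALSE)
  probs <- .bootstrap_probs(v)
  set.seed(seed)
  draws <- rmultinom(B, v$n, probs)
  boot_vals <- matrix(NA_real_, nrow = length(m_grid), ncol = B)
  for (b in seq_len(B)) {
    cb <- draws[, b]
    cb <- cb[cb > 0]
    vb <- abundance_vector(cb)
    boot_vals[, b] <- vapply(m_grid, function(m)
      suppressWarnings(hill_estimate(vb, m, q)$value), numeric(1))
  }
  est <- lapply(m_grid, function(m) suppressWarnings(hill_estimate(v, m, q)))
  alpha <- (1 - conf) / 2
  lo <- numeric(length(m_grid)); hi <- numeric(length(m_grid))
  for (i in seq_along(m_grid)) {
    if (method == "percentile") {
      qs <- quantile(boot_vals[i, ], c(alpha, 1 - alpha), names = FALSE)
    } else {
      se <- stats::sd(boot_vals[i, ])
      qs <- est[[i]]$value + c(-1, 1) * stats::qnorm(1 - alpha) * se
    }
    # intervals always contain the point estimate
    lo[i] <- min(qs[1], est[[i]]$value)
    hi[i] <- max(qs[2], est[[i]]$value)
  }
  data.frame(m = m_grid,
             mode = vapply(est, `[[`, character(1), "mode"),
             value = vapply(est, `[[`, numeric(1), "value"),
             ci_low = lo, ci_high = hi)
}

#' Compare pre- vs post-duplication diversity curves
#'
#' Builds rarefaction/extrapolation curves with bootstrap CIs for two
#' abundance vectors over a shared grid up to
#' `extrapolation_factor * max(n_pre, n_post)` and calls the difference
#' significant when the two confidence intervals do not overlap at the
#' common comparison size (the shared curve endpoint). A log2-log2 curve
#' table is emitted for plotting.
#'
#' @param pre,post [abundance_vector()]s (e.g. FIEs per gene pre- and
#'   post-duplication).
#' @param config a [funvar_config()] (`extrapolation_factor`,
#'   `bootstrap_reps`, `rng_seed`).
#' @param n_grid number of grid points per curve.
#' @param q Hill order.
#' @return object of class `diversity_comparison`: list with `curves` (long
#'   data frame: `group`, `m`, `mode`, `value`, `ci_low`, `ci_high`,
#'   `log2_m`, `log2_value`), `m_compare`, `significant`, `higher` (group
#'   with the larger point estimate at `m_compare`) and `warnings`.
#' @export
compare_groups <- function(pre, post, config = NULL, n_grid = 8L, q = 1) {
  config <- as_config(config)
  pre <- as_abundance(pre); post <- as_abundance(post)
  warns <- character(0)
  if (pre$n < 5L) warns <- c(warns, "pre group has fewer than 5 observations")
  if (post$n < 5L) warns <- c(warns, "post group has fewer than 5 observations")
  m_max <- ceiling(config$extrapolation_factor * max(pre$n, post$n))
  one <- function(v, group, seed_offset) {
    grid <- sort(unique(c(1L, pmax(1L, round(seq(1, m_max, length.out = n_grid))),
                          v$n, m_max)))
    ci <- bootstrap_ci(v, grid, B = config$bootstrap_reps,
                       seed = config$rng_seed + seed_offset, q = q)
    cbind(group = group, ci, log2_m = log2(ci$m), log2_value = log2(ci$value),
          stringsAsFactors = FALSE)
  }
  curves <- rbind(one(pre, "pre", 0L), one(post, "post", 1L))
  at <- function(g) curves[curves$group == g & curves$m == m_max, ][1, ]
  a <- at("pre"); b <- at("post")
  significant <- (a$ci_high < b$ci_low) || (b$ci_high < a$ci_low)
  higher <- if (b$value > a$value) "post" else if (a$value > b$value) "pre" else "tie"
  for (w in warns) warning(w, call. = FALSE)
  structure(list(curves = curves, m_compare = m_max, significant = significant,
                 higher = higher, warnings = warns),
            class = "diversity_comparison")
}

#' @export
print.diversity_comparison <- function(x, ...) {
  at <- x$curves[x$curves$m == x$m_compare, ]
  cat(sprintf("diversity comparison at m = %d:\n", x$m_compare))
  for (i in seq_len(nrow(at)))
    cat(sprintf("  %-5s %8.3f [%7.3f, %7.3f] (%s)\n", at$group[i], at$value[i],
                at$ci_low[i], at$ci_high[i], at$mode[i]))
  cat(sprintf("  %s (higher: %s)\n",
              if (x$significant) "significant (non-overlapping 95% CIs)"
              else "not significant (overlapping 95% CIs)", x$higher))
  invisible(x)
}

#' Abundance vectors from a timed FIE table
#'
#' Tabulates FIEs per gene (or per family), stratified by a column such as
#' `timing` or `clonality`.
#'
#' @param records timed FIE records.
#' @param group_by `"gene"` or `"funfam_id"`.
#' @param stratum_col column to stratify on (default `"timing"`).
#' @return named list of [abundance_vector()]s, one per stratum level
#'   present; levels with no records are omitted.
#' @export
fie_abundance <- function(records, group_by = c("gene", "funfam_id"),
                          stratum_col = "timing") {
  group_by <- match.arg(group_by)
  strata <- unique(records[[stratum_col]])
  out <- list()
  for (s in strata) {
    sub <- records[records[[stratum_col]] == s, , drop = FALSE]
    if (nrow(sub) == 0L) next
    out[[as.character(s)]] <- abundance_vector(as.character(sub[[group_by]]))
  }
  out
}
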