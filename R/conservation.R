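#' Per-column conservation score
#'
#' Default scorer: `(1 - H / ln 20) * (1 - gap fraction)`, where `H` is the
#' Shannon entropy of the (weighted) amino-acid distribution over the
#' column's non-gap symbols. The score is 1 exactly when the column holds a
#' single residue type with no gaps and approaches 0 as the distribution
#' flattens. An all-gap column scores 0 and carries attribute
#' `all_gap = TRUE`.
#'
#' @param column character vector of single residues/gaps (`"-"`), one per
#'   sequence.
#' @param weights per-sequence positive weights; default uniform.
#' @return score in `[0, 1]`.
#' @export
column_conservation <- function(column, weights = NULL) {
  if (!length(column)) stop("empty column", call. = FALSE)
  column <- toupper(column)
  if (is.null(weights)) weights <- rep(1, length(column))
  if (length(weights) != length(column) || any(weights <= 0))
    stop("weights must be positive, one per sequence", call. = FALSE)
  nongap <- column != "-"
  gap_frac <- 1 - sum(weights[nongap]) / sum(weights)
  if (!any(nongap)) return(structure(0, all_gap = TRUE))
  w <- tapply(weights[nongap], column[nongap], sum)
  p <- w / sum(w)
  H <- -sum(p * log(p))
  unname((1 - H / log(20)) * (1 - gap_frac))
}

#' Sequence weights for an alignment
#'
#' `"uniform"` gives every sequence weight 1; `"henikoff"` position-based
#' weights down-weight redundant sequences (Henikoff & Henikoff 1994),
#' normalised to sum to the number of sequences.
#'
#' @param alignment named character vector of gapped sequences.
#' @param method weighting scheme.
#' @return numeric weights, one per sequence.
#' @export
sequence_weights <- function(alignment, method = c("uniform", "henikoff")) {
  method <- match.arg(method)
  n <- length(alignment)
  if (method == "uniform") return(rep(1, n))
  chars <- do.call(rbind, strsplit(alignment, "", fixed = TRUE))
  w <- numeric(n)
  for (j in seq_len(ncol(chars))) {
    col <- chars[, j]
    nongap <- col != "-"
    if (!any(nongap)) next
    tab <- table(col[nongap])
    r <- length(tab)
    w[nongap] <- w[nongap] + 1 / (r * as.numeric(tab[col[nongap]]))
  }
  if (sum(w) == 0) return(rep(1, n))
  w * n / sum(w)
}

#' Conservation profile of a family alignment
#'
#' Computes the per-column conservation score and the alignment-level
#' diversity-of-positions score (DOPS), which gates site prediction: only
#' suitably diverse alignments (DOPS above the configured threshold) are
#' trusted for conserved-column site calls, since an alignment of
#' near-identical sequences scores every column as conserved.
#'
#' @param alignment named character vector of gapped sequences (or a
#'   [funfam_bundle()], whose alignment is used).
#' @param weights `"uniform"` (default), `"henikoff"`, or a numeric vector.
#' @param scorer optional replacement column scorer,
#'   `function(column, weights) -> [0,1]`, slotted in behind the same
#'   profile interface.
#' @return object of class `conservation_profile`: list with `scores`
#'   (per column), `dops`, and `all_gap` (logical per column).
#' @export
alignment_conservation <- function(alignment, weights = "uniform",
                                   scorer = column_conservation) {
  if (inherits(alignment, "funfam_bundle")) alignment <- alignment$alignment
  if (is.character(weights)) weights <- sequence_weights(alignment, weights)
  chars <- do.call(rbind, strsplit(alignment, "", fixed = TRUE))
  scores <- numeric(ncol(chars)); allgap <- logical(ncol(chars))
  for (j in seq_len(ncol(chars))) {
    s <- scorer(chars[, j], weights)
    scores[j] <- as.numeric(s)
    allgap[j] <- isTRUE(attr(s, "all_gap"))
  }
  structure(list(scores = scores, dops = dops(scores), all_gap = allgap),
            class = "conservation_profile")
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat(sprintf("conservation profile: %d columns, DOPS %.1f, %d column(s) > 0.9\n",
              length(x$scores), x$dops, sum(x$scores > 0.9)))
  invisible(x)
}

#' Diversity-of-positions score
#'
#' Default definition: `100 * (distinct score values after rounding to 3
#' decimals) / (number of columns)`. A low value means the columns carry
#' near-identical scores (an uninformative alignment); a high value means
#' the conservation signal varies across positions. The definition is
#' deliberately simple and swappable via `method`.
#'
#' @param scores per-column conservation scores.
#' @param method a `function(scores) -> [0,100]` replacing the default.
#' @return value in `[0, 100]`.
#' @export
dops <- function(scores, method = NULL) {
  if (!length(scores)) stop("dops needs at least one column score", call. = FALSE)
  if (!is.null(method)) return(method(scores))
  100 * length(unique(round(scores, 3))) / length(scores)
}

#' Predict functional-site columns from conservation
#'
#' Returns the empty set when the profile's DOPS does not exceed
#' `dops_threshold`; otherwise all columns whose raw score strictly exceeds
#' `conservation_threshold`.
#'
#' @param profile an [alignment_conservation()] result.
#' @param config a [funvar_config()].
#' @return integer vector of alignment columns (possibly empty).
#' @export
predict_site_columns <- function(profile, config = NULL) {
  config <- as_config(config)
  if (profile$dops <= config$dops_threshold) return(integer(0))
  which(profile$scores > config$conservation_threshold)
}
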