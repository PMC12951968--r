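#' Build per-member maps between sequence positions and alignment columns
#'
#' For every alignment member, a strictly increasing bijection between its
#' 1-based ungapped sequence positions and the 1-based alignment columns it
#' occupies. This is the device that lets mutations observed in any paralog,
#' and site annotations from any member, be carried onto the single
#' representative structure.
#'
#' @param bundle a [funfam_bundle()].
#' @return object of class `column_map`: a named list with, per member,
#'   `seq_to_col` (integer vector indexed by sequence position) and
#'   `col_to_seq` (integer vector indexed by column, `NA` at gaps).
#' @export
build_column_map <- function(bundle) {
  width <- nchar(bundle$alignment[[1]])
  maps <- lapply(bundle$alignment, function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    nongap <- which(chars != "-")
    col_to_seq <- rep(NA_integer_, width)
    col_to_seq[nongap] <- seq_along(nongap)
    list(seq_to_col = nongap, col_to_seq = col_to_seq)
  })
  structure(maps, class = "column_map", width = width)
}

#' Project one mutation onto the representative structure
#'
#' Composes the mutated member's position-to-column map, the representative's
#' column-to-position map and the bundle's sequence-to-structure map.
#'
#' @param mut single-row mutation record (or list) with `protein_id` and
#'   `residue_pos`.
#' @param map a [build_column_map()] result.
#' @param bundle the bundle the map was built from.
#' @return structure residue id (integer), or `NA` when the representative is
#'   gapped at the mutation's column or the position lies outside the
#'   sequence-to-structure map.
#' @export
project_to_representative <- function(mut, map, bundle) {
  pid <- as.character(mut$protein_id)
  pos <- as.integer(mut$residue_pos)
  if (!pid %in% names(map))
    stop("protein '", pid, "' is not a member of family ", bundle$funfam_id,
         call. = FALSE)
  m <- map[[pid]]
  if (pos < 1L || pos > length(m$seq_to_col))
    stop("residue_pos ", pos, " outside ungapped length of ", pid, call. = FALSE)
  col <- m$seq_to_col[pos]
  rep_pos <- map[[bundle$representative_id]]$col_to_seq[col]
  if (is.na(rep_pos)) return(NA_integer_)
  hit <- match(as.character(rep_pos), names(bundle$seq_to_struct))
  if (is.na(hit)) return(NA_integer_)
  unname(bundle$seq_to_struct[hit])
}

#' Aggregate family mutations onto representative-structure residues
#'
#' @param muts mutation table whose `protein_id` values are all family
#'   members.
#' @param map a [build_column_map()] result.
#' @param bundle the family bundle.
#' @param drop_ref_mismatch exclude mutations whose recorded `ref_aa`
#'   disagrees with the member's residue at the aligned column (isoform /
#'   sequence-version drift); they are flagged and logged either way.
#' @return list with `counts` (data frame `residue_id`, `count`), `by_gene`
#'   and `by_cancer_type` breakdown tables, `assignments` (per input
#'   mutation: projected residue, `ref_mismatch` flag), and `unprojectable`
#'   (count of mutations at columns gapped in the representative or without
#'   a structure mapping).
#' @export
aggregate_counts <- function(muts, map, bundle, drop_ref_mismatch = TRUE) {
  empty <- list(
    counts = data.frame(residue_id = integer(0), count = integer(0)),
    by_gene = data.frame(residue_id = integer(0), gene = character(0), count = integer(0)),
    by_cancer_type = data.frame(residue_id = integer(0), cancer_type = character(0), count = integer(0)),
    assignments = data.frame(residue_id = integer(0), ref_mismatch = logical(0)),
    unprojectable = 0L
  )
  if (is.null(muts) || nrow(muts) == 0L) return(empty)
  res <- integer(nrow(muts)); mism <- logical(nrow(muts))
  for (i in seq_len(nrow(muts))) {
    res[i] <- project_to_representative(muts[i, ], map, bundle)
    m <- map[[as.character(muts$protein_id[i])]]
    col <- m$seq_to_col[muts$residue_pos[i]]
    member_aa <- substr(bundle$alignment[[as.character(muts$protein_id[i])]], col, col)
    mism[i] <- !is.na(col) && toupper(member_aa) != toupper(muts$ref_aa[i])
  }
  if (any(mism))
    message("aggregate_counts: ", sum(mism), " mutation(s) with ref_aa mismatch",
            if (drop_ref_mismatch) " (excluded)" else " (kept)")
  assignments <- data.frame(residue_id = res, ref_mismatch = mism)
  use <- !is.na(res) & (!drop_ref_mismatch | !mism)
  unproj <- sum(is.na(res))
  if (!any(use)) {
    out <- empty
    out$assignments <- assignments
    out$unprojectable <- unproj
    return(out)
  }
  tab <- table(res[use])
  counts <- data.frame(residue_id = as.integer(names(tab)),
                       count = as.integer(tab))
  bg <- as.data.frame(table(residue_id = res[use], gene = muts$gene[use]),
                      stringsAsFactors = FALSE)
  bg <- bg[bg$Freq > 0L, , drop = FALSE]
  by_gene <- data.frame(residue_id = as.integer(bg$residue_id), gene = bg$gene,
                        count = as.integer(bg$Freq))
  bc <- as.data.frame(table(residue_id = res[use], cancer_type = muts$cancer_type[use]),
                      stringsAsFactors = FALSE)
  bc <- bc[bc$Freq > 0L, , drop = FALSE]
  by_cancer_type <- data.frame(residue_id = as.integer(bc$residue_id),
                               cancer_type = bc$cancer_type,
                               count = as.integer(bc$Freq))
  list(counts = counts[order(counts$residue_id), , drop = FALSE],
       by_gene = by_gene, by_cancer_type = by_cancer_type,
       assignments = assignments, unprojectable = unproj)
}

#' Project known and predicted functional sites onto the representative
#'
#' Unions the bundle's known sites (already in structure residue numbering)
#' with conservation-predicted alignment columns carried through the
#' representative's column map. Predicted columns gapped in the
#' representative are dropped with a message. Duplicate (residue, kind)
#' pairs are deduplicated.
#'
#' @param bundle a [funfam_bundle()].
#' @param predicted_columns integer vector of alignment columns (possibly
#'   empty), e.g. from [predict_site_columns()].
#' @param map optional precomputed [build_column_map()].
#' @return functional-site data frame (`residue_id`, `site_kind`,
#'   `provenance`).
#' @export
project_sites <- function(bundle, predicted_columns = integer(0), map = NULL) {
  if (is.null(map)) map <- build_column_map(bundle)
  sites <- bundle$known_sites
  if (length(predicted_columns)) {
    rep_pos <- map[[bundle$representative_id]]$col_to_seq[predicted_columns]
    res <- unname(bundle$seq_to_struct[as.character(rep_pos)])
    dropped <- sum(is.na(res))
    if (dropped > 0L)
      message("project_sites: ", dropped,
              " predicted column(s) gapped or unmapped in the representative; dropped")
    keep <- !is.na(res)
    if (any(keep))
      sites <- rbind(sites, data.frame(residue_id = as.integer(res[keep]),
                                       site_kind = "predicted",
                                       provenance = "conservation",
                                       stringsAsFactors = FALSE))
  }
  sites <- sites[!duplicated(sites[, c("residue_id", "site_kind")]), , drop = FALSE]
  rownames(sites) <- NULL
  sites
}
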