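#' Domain structure container
#'
#' A `domain_structure` is a data frame with one row per atom and columns
#' `residue_id` (author numbering, integer), `aa` (one-letter code), `atom`
#' (atom name, e.g. `"CA"`), `x`, `y`, `z` (Angstrom) and optionally `plddt`
#' (per-residue model confidence, carried in the B-factor column of predicted
#' models). Every residue must have at least one atom and all coordinates
#' must be finite.
#'
#' @param atoms data frame with the columns above.
#' @return object of class `domain_structure`.
#' @export
domain_structure <- function(atoms) {
  need <- c("residue_id", "aa", "atom", "x", "y", "z")
  if (!all(need %in% names(atoms)))
    stop("structure table must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  atoms$residue_id <- as.integer(atoms$residue_id)
  if (nrow(atoms) == 0L) stop("structure has no atoms", call. = FALSE)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite atom coordinates", call. = FALSE)
  rownames(atoms) <- NULL
  structure(atoms, class = c("domain_structure", "data.frame"))
}

#' Residue identifiers of a structure, in file order
#' @param structure a `domain_structure`.
#' @return integer vector of unique residue ids.
#' @export
residue_ids <- function(structure) unique(structure$residue_id)

#' @export
print.domain_structure <- function(x, ...) {
  cat(sprintf("domain structure: %d residues, %d atoms%s\n",
              length(residue_ids(x)), nrow(x),
              if (all(x$atom == "CA")) " (CA-only)" else ""))
  invisible(x)
}

#' Minimum inter-atomic distance between two residues
#'
#' Uses the minimum over all available atom pairs (heavy atoms when present,
#' CA-only structures fall back to the CA-CA distance). Symmetric; zero iff
#' the two residues are the same.
#'
#' @param structure a `domain_structure`.
#' @param r1,r2 residue ids.
#' @return distance in Angstrom.
#' @export
residue_distance <- function(structure, r1, r2) {
  if (r1 == r2) {
    if (!r1 %in% structure$residue_id) stop("residue not in structure: ", r1, call. = FALSE)
    return(0)
  }
  a1 <- structure[structure$residue_id == r1, c("x", "y", "z"), drop = FALSE]
  a2 <- structure[structure$residue_id == r2, c("x", "y", "z"), drop = FALSE]
  if (nrow(a1) == 0L) stop("residue not in structure: ", r1, call. = FALSE)
  if (nrow(a2) == 0L) stop("residue not in structure: ", r2, call. = FALSE)
  m1 <- as.matrix(a1); m2 <- as.matrix(a2)
  d2 <- outer(rowSums(m1^2), rowSums(m2^2), "+") - 2 * tcrossprod(m1, m2)
  sqrt(max(0, min(d2)))
}

# Pairwise minimum inter-atomic distance matrix over all residues.
# O(atoms^2) but structures here are single domains.
residue_distance_matrix <- function(structure) {
  ids <- residue_ids(structure)
  xyz <- as.matrix(structure[, c("x", "y", "z")])
  ad2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * tcrossprod(xyz)
  ad2[ad2 < 0] <- 0
  grp <- match(structure$residue_id, ids)
  n <- length(ids)
  out <- matrix(Inf, n, n, dimnames = list(ids, ids))
  # min-aggregate atom-level distances into residue blocks
  for (i in seq_len(n)) {
    ri <- which(grp == i)
    colmin <- if (length(ri) == 1L) ad2[ri, ] else apply(ad2[ri, , drop = FALSE], 2, min)
    out[i, ] <- sqrt(vapply(seq_len(n), function(j) min(colmin[grp == j]), numeric(1)))
  }
  diag(out) <- 0
  out
}

#' Read a domain structure from a PDB or mmCIF file
#'
#' Parsing is delegated to \pkg{bio3d}; protein atoms only, first chain by
#' default. The B-factor column is retained as `plddt` so predicted-model
#' confidence filters can be applied via the `plddt_min` configuration.
#'
#' @param path `.pdb` or `.cif` file.
#' @param chain optional chain identifier; default first chain in the file.
#' @return a `domain_structure`.
#' @export
read_structure <- function(path, chain = NULL) {
  if (!file.exists(path)) stop("structure file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  pdb <- if (ext == "cif") bio3d::read.cif(path, verbose = FALSE)
         else bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in ", path, call. = FALSE)
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain %in% chain, , drop = FALSE]
  aa1 <- suppressWarnings(bio3d::aa321(at$resid))
  domain_structure(data.frame(
    residue_id = as.integer(at$resno),
    aa = aa1,
    atom = at$elety,
    x = at$x, y = at$y, z = at$z,
    plddt = at$b,
    stringsAsFactors = FALSE
  ))
}

#' Drop low-confidence residues from a predicted structure
#'
#' @param structure a `domain_structure` carrying a `plddt` column.
#' @param plddt_min residues whose mean pLDDT is below this are removed;
#'   `NA` returns the structure unchanged.
#' @return filtered `domain_structure`.
#' @export
filter_plddt <- function(structure, plddt_min = NA_real_) {
  if (is.na(plddt_min) || is.null(structure$plddt)) return(structure)
  keep <- tapply(structure$plddt, structure$residue_id, mean) >= plddt_min
  ids <- as.integer(names(keep))[keep]
  if (!length(ids)) stop("no residues pass the pLDDT filter", call. = FALSE)
  domain_structure(structure[structure$residue_id %in% ids, , drop = FALSE])
}

# Write a CA-only (or multi-atom) structure as a PDB file via bio3d.
write_structure_pdb <- function(structure, path) {
  aa3 <- bio3d::aa123(structure$aa)
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(structure[, c("x", "y", "z")]))),
    resno = structure$residue_id,
    resid = aa3,
    elety = structure$atom,
    chain = rep("A", nrow(structure)),
    b = if (!is.null(structure$plddt)) structure$plddt else rep(0, nrow(structure))
  )
  invisible(path)
}
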