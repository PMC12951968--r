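#' Read a somatic missense mutation table
#'
#' Accepts the canonical minimal TSV dialect (columns `tumor_id`,
#' `cancer_type`, `gene`, `protein_id`, `residue_pos`, `ref_aa`, `alt_aa`
#' plus optional `mutation_cn`, `clonality`, `pop_vaf`, `disease_variant`,
#' `expressed`) or a MAF-like dialect whose standard column names
#' (`Tumor_Sample_Barcode`, `Hugo_Symbol`, `SWISSPROT`, `Protein_position`,
#' `Reference_Amino_Acid`, `Alternate_Amino_Acid`, `Variant_Classification`,
#' ...) are mapped onto the same fields. Rows that are not missense after
#' parsing (synonymous, i.e. `ref_aa == alt_aa`, or nonsense `*`) are dropped
#' with a message reporting the count. Missing optional columns are filled
#' with `NA`.
#'
#' @param path TSV file with a header row.
#' @param dialect `"tsv_minimal"` (default) or `"maf_like"`.
#' @return data frame of mutation records, one row per missense mutation,
#'   with class `mutation_table`. `clonality` is one of `"clonal"`,
#'   `"subclonal"`, `"unknown"`.
#' @export
read_mutations <- function(path, dialect = c("tsv_minimal", "maf_like")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("mutation file not found: ", path, call. = FALSE)
  raw <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, colClasses = "character")
  if (nrow(raw) == 0L) stop("mutation file is empty: ", path, call. = FALSE)
  if (dialect == "maf_like") {
    map <- c(Tumor_Sample_Barcode = "tumor_id", Cancer_Type = "cancer_type",
             Hugo_Symbol = "gene", SWISSPROT = "protein_id",
             Protein_position = "residue_pos",
             Reference_Amino_Acid = "ref_aa", Alternate_Amino_Acid = "alt_aa",
             Mutation_CN = "mutation_cn", Clonality = "clonality",
             gnomAD_AF = "pop_vaf", Disease_Variant = "disease_variant",
             Expressed = "expressed")
    hit <- names(raw) %in% names(map)
    names(raw)[hit] <- map[names(raw)[hit]]
    if ("Variant_Classification" %in% names(raw)) {
      drop_n <- sum(raw$Variant_Classification != "Missense_Mutation")
      if (drop_n > 0L)
        message("read_mutations: dropped ", drop_n, " non-missense rows (Variant_Classification)")
      raw <- raw[raw$Variant_Classification == "Missense_Mutation", , drop = FALSE]
    }
  }
  need <- c("tumor_id", "cancer_type", "gene", "protein_id", "residue_pos",
            "ref_aa", "alt_aa")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("mutation file lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  opt <- c("mutation_cn", "clonality", "pop_vaf", "disease_variant", "expressed")
  for (cc in setdiff(opt, names(raw))) raw[[cc]] <- NA_character_

  line_no <- seq_len(nrow(raw)) + 1L  # header is line 1
  pos <- suppressWarnings(as.numeric(raw$residue_pos))
  bad <- is.na(pos) | pos < 1 | pos != floor(pos)
  aa_ok <- function(a) toupper(a) %in% c(.grantham_aa, "*")
  bad_aa <- !aa_ok(raw$ref_aa) | !aa_ok(raw$alt_aa)
  if (any(bad | bad_aa)) {
    i <- which(bad | bad_aa)[1]
    stop(sprintf("malformed mutation row at line %d: residue_pos='%s' ref_aa='%s' alt_aa='%s'",
                 line_no[i], raw$residue_pos[i], raw$ref_aa[i], raw$alt_aa[i]),
         call. = FALSE)
  }
  ref <- toupper(raw$ref_aa); alt <- toupper(raw$alt_aa)
  keep <- ref != alt & ref != "*" & alt != "*"
  if (any(!keep))
    message("read_mutations: dropped ", sum(!keep),
            " non-missense rows (synonymous or nonsense)")
  out <- data.frame(
    tumor_id = raw$tumor_id, cancer_type = raw$cancer_type, gene = raw$gene,
    protein_id = raw$protein_id, residue_pos = as.integer(pos),
    ref_aa = ref, alt_aa = alt,
    mutation_cn = suppressWarnings(as.numeric(raw$mutation_cn)),
    clonality = ifelse(is.na(raw$clonality) | raw$clonality == "",
                       "unknown", raw$clonality),
    pop_vaf = suppressWarnings(as.numeric(raw$pop_vaf)),
    disease_variant = .parse_logical(raw$disease_variant, default = FALSE),
    expressed = .parse_logical(raw$expressed, default = NA),
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  if (!all(out$clonality %in% c("clonal", "subclonal", "unknown")))
    stop("clonality must be clonal/subclonal/unknown", call. = FALSE)
  if (any(!is.na(out$pop_vaf) & (out$pop_vaf < 0 | out$pop_vaf > 1)))
    stop("pop_vaf outside [0, 1]", call. = FALSE)
  rownames(out) <- NULL
  class(out) <- c("mutation_table", "data.frame")
  out
}

.parse_logical <- function(x, default = NA) {
  out <- rep(if (is.na(default)) NA else as.logical(default), length(x))
  x <- tolower(trimws(x))
  out[x %in% c("true", "t", "1", "yes")] <- TRUE
  out[x %in% c("false", "f", "0", "no")] <- FALSE
  out
}

#' Read per-(tumor, gene) allele-specific copy-number states
#'
#' Major and minor copy numbers are normalised so that
#' `major_cn >= minor_cn`; reversed rows are swapped with a warning.
#'
#' @param path TSV with columns `tumor_id`, `gene`, `major_cn`, `minor_cn`.
#' @return data frame of copy-number states.
#' @export
read_copy_number <- function(path) {
  if (!file.exists(path)) stop("copy-number file not found: ", path, call. = FALSE)
  raw <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("tumor_id", "gene", "major_cn", "minor_cn")
  if (!all(need %in% names(raw)))
    stop("copy-number file must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  major <- suppressWarnings(as.numeric(raw$major_cn))
  minor <- suppressWarnings(as.numeric(raw$minor_cn))
  if (any(is.na(major) | is.na(minor) | major < 0 | minor < 0 |
          major != floor(major) | minor != floor(minor)))
    stop("copy numbers must be non-negative integers", call. = FALSE)
  swap <- minor > major
  if (any(swap)) {
    warning(sum(swap), " copy-number row(s) had minor_cn > major_cn; swapped",
            call. = FALSE)
    tmp <- major[swap]; major[swap] <- minor[swap]; minor[swap] <- tmp
  }
  data.frame(tumor_id = as.character(raw$tumor_id), gene = as.character(raw$gene),
             major_cn = as.integer(major), minor_cn = as.integer(minor),
             stringsAsFactors = FALSE)
}

#' Construct a functional-family bundle
#'
#' A bundle holds everything needed to aggregate a family's mutations on its
#' representative structure: the family alignment, the representative's
#' structure, an explicit map from representative sequence positions to
#' structure residue ids, known functional-site annotations and family-level
#' metadata (parent superfamily, distinct EC count, moonlighting and
#' mutation-enrichment flags).
#'
#' @param funfam_id,superfamily_id identifiers.
#' @param alignment named character vector of equal-length gapped sequences
#'   (gap `"-"`), names are member protein ids.
#' @param representative_id member with the structure.
#' @param structure a [domain_structure()].
#' @param seq_to_struct named integer vector: names are 1-based ungapped
#'   positions of the representative sequence, values are structure residue
#'   ids.
#' @param known_sites data frame `residue_id`, `site_kind`
#'   (ligand/nucleic_acid/ppi/catalytic/predicted), `provenance`.
#' @param ec_count_superfamily distinct EC numbers in the parent superfamily.
#' @param moonlighting any member in a curated moonlighting list?
#' @param is_mutfam optional precomputed mutation-enrichment flag
#'   (overridable by [mutfam_enrichment()]); `NA` = not precomputed.
#' @return object of class `funfam_bundle`.
#' @export
funfam_bundle <- function(funfam_id, superfamily_id, alignment,
                          representative_id, structure, seq_to_struct,
                          known_sites = NULL, ec_count_superfamily = 0L,
                          moonlighting = FALSE, is_mutfam = NA) {
  if (is.null(names(alignment)) || any(names(alignment) == ""))
    stop("alignment sequences must be named by member protein_id", call. = FALSE)
  widths <- nchar(alignment)
  if (length(unique(widths)) != 1L)
    stop("ragged alignment: all rows must have equal gapped length", call. = FALSE)
  if (!representative_id %in% names(alignment))
    stop("representative '", representative_id, "' absent from alignment", call. = FALSE)
  if (!inherits(structure, "domain_structure"))
    stop("structure must be a domain_structure", call. = FALSE)
  seq_to_struct <- setNames(as.integer(seq_to_struct), names(seq_to_struct))
  rep_len <- nchar(gsub("-", "", alignment[[representative_id]]))
  sp <- as.integer(names(seq_to_struct))
  if (any(is.na(sp)) || any(sp < 1L) || any(sp > rep_len))
    stop("seq_to_struct positions outside the representative's ungapped length",
         call. = FALSE)
  if (!all(seq_to_struct %in% residue_ids(structure)))
    stop("seq_to_struct maps to residues absent from the structure", call. = FALSE)
  if (is.null(known_sites))
    known_sites <- data.frame(residue_id = integer(0), site_kind = character(0),
                              provenance = character(0), stringsAsFactors = FALSE)
  known_sites <- functional_site_set(known_sites, structure)
  structure(list(funfam_id = funfam_id, superfamily_id = superfamily_id,
                 alignment = alignment, representative_id = representative_id,
                 structure = structure, seq_to_struct = seq_to_struct,
                 known_sites = known_sites,
                 ec_count_superfamily = as.integer(ec_count_superfamily),
                 moonlighting = isTRUE(moonlighting), is_mutfam = is_mutfam),
            class = "funfam_bundle")
}

# Validate a functional-site table against the structure.
functional_site_set <- function(sites, structure,
                                kinds = c("ligand", "nucleic_acid", "ppi",
                                          "catalytic", "predicted")) {
  need <- c("residue_id", "site_kind")
  if (!all(need %in% names(sites)))
    stop("site table must have columns residue_id, site_kind", call. = FALSE)
  if (is.null(sites$provenance)) sites$provenance <- ""
  sites$residue_id <- as.integer(sites$residue_id)
  if (!all(sites$site_kind %in% kinds))
    stop("unknown site_kind; expected one of ", paste(kinds, collapse = ", "),
         call. = FALSE)
  missing_res <- setdiff(sites$residue_id, residue_ids(structure))
  if (length(missing_res))
    stop("site residue(s) not in structure: ",
         paste(missing_res, collapse = ", "), call. = FALSE)
  sites <- sites[, c("residue_id", "site_kind", "provenance"), drop = FALSE]
  rownames(sites) <- NULL
  sites
}

#' @export
print.funfam_bundle <- function(x, ...) {
  cat(sprintf("funfam bundle %s (superfamily %s): %d members x %d columns, rep %s, %d known site(s)\n",
              x$funfam_id, x$superfamily_id, length(x$alignment),
              nchar(x$alignment[[1]]), x$representative_id, nrow(x$known_sites)))
  invisible(x)
}

#' Read a functional-family bundle from a directory
#'
#' Expects `alignment.fasta` (gapped FASTA), a structure file
#' (`structure.pdb` or `structure.cif`), `sites.tsv` (columns `residue_id`,
#' `site_kind`, optional `provenance`) and `metadata.yaml` with keys
#' `funfam_id`, `superfamily_id`, `representative_id`, `seq_to_struct`
#' (mapping of sequence position to residue id), and optionally
#' `ec_count_superfamily`, `moonlighting`, `is_mutfam`.
#'
#' @param dir bundle directory.
#' @param config optional [funvar_config()]; a non-`NA` `plddt_min` filters
#'   low-confidence residues of predicted structures.
#' @return a [funfam_bundle()].
#' @export
read_funfam_bundle <- function(dir, config = NULL) {
  config <- as_config(config)
  if (!dir.exists(dir)) stop("bundle directory not found: ", dir, call. = FALSE)
  fa <- file.path(dir, "alignment.fasta")
  meta_path <- file.path(dir, "metadata.yaml")
  sites_path <- file.path(dir, "sites.tsv")
  struct_path <- file.path(dir, "structure.pdb")
  if (!file.exists(struct_path)) struct_path <- file.path(dir, "structure.cif")
  for (p in c(fa, meta_path, sites_path, struct_path))
    if (!file.exists(p)) stop("bundle file missing: ", p, call. = FALSE)

  aln_set <- Biostrings::readAAStringSet(fa)
  alignment <- setNames(as.character(aln_set), names(aln_set))
  meta <- yaml::read_yaml(meta_path)
  for (k in c("funfam_id", "superfamily_id", "representative_id", "seq_to_struct"))
    if (is.null(meta[[k]])) stop("metadata.yaml lacks key: ", k, call. = FALSE)
  s2s <- unlist(meta$seq_to_struct)
  structure <- read_structure(struct_path)
  structure <- filter_plddt(structure, config$plddt_min)
  sites <- read.delim(sites_path, sep = "\t", stringsAsFactors = FALSE)
  funfam_bundle(
    funfam_id = meta$funfam_id, superfamily_id = meta$superfamily_id,
    alignment = alignment, representative_id = meta$representative_id,
    structure = structure, seq_to_struct = s2s, known_sites = sites,
    ec_count_superfamily = meta$ec_count_superfamily %||% 0L,
    moonlighting = isTRUE(meta$moonlighting),
    is_mutfam = meta$is_mutfam %||% NA
  )
}

#' Write a functional-family bundle to a directory
#'
#' Inverse of [read_funfam_bundle()]; used by the synthetic-fixture
#' generator. Files are plain text (FASTA, PDB, TSV, YAML).
#'
#' @param bundle a [funfam_bundle()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_funfam_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  aln <- Biostrings::AAStringSet(bundle$alignment)
  Biostrings::writeXStringSet(aln, file.path(dir, "alignment.fasta"), width = 80L)
  write_structure_pdb(bundle$structure, file.path(dir, "structure.pdb"))
  write.table(bundle$known_sites, file.path(dir, "sites.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  meta <- list(
    funfam_id = bundle$funfam_id, superfamily_id = bundle$superfamily_id,
    representative_id = bundle$representative_id,
    seq_to_struct = as.list(setNames(as.integer(bundle$seq_to_struct),
                                     names(bundle$seq_to_struct))),
    ec_count_superfamily = bundle$ec_count_superfamily,
    moonlighting = bundle$moonlighting,
    is_mutfam = if (is.na(bundle$is_mutfam)) NULL else bundle$is_mutfam
  )
  yaml::write_yaml(meta, file.path(dir, "metadata.yaml"))
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.fie_columns <- c("tumor_id", "cancer_type", "gene", "funfam_id", "protein_id",
                  "residue_pos", "rep_residue", "ref_aa", "alt_aa",
                  "grantham", "hotspot", "disease_variant", "on_known",
                  "near_known", "on_predicted", "near_predicted",
                  "high_sig_cluster", "mutfam", "total", "timing",
                  "diverse_family", "moonlighting")

#' Write / read a scored FIE table
#'
#' TSV with a stable column order: identity (tumor, cancer type, gene,
#' family, residue, substitution), the nine score components, the total,
#' the timing class and the family-level flags. `read_fie_table()` is the
#' exact inverse on files written by `write_fie_table()`.
#'
#' @param records data frame of scored FIE records (see [score_fies()]).
#' @param path output TSV path.
#' @return `path` invisibly (`write_fie_table`); data frame
#'   (`read_fie_table`).
#' @export
write_fie_table <- function(records, path) {
  if (is.null(records) || nrow(records) == 0L) {
    records <- as.data.frame(setNames(rep(list(character(0)), length(.fie_columns)),
                                      .fie_columns))
  }
  missing_cols <- setdiff(.fie_columns, names(records))
  if (length(missing_cols))
    stop("FIE records lack column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  ok <- tryCatch({
    write.table(records[, .fie_columns, drop = FALSE], path, sep = "\t",
                quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop("cannot write FIE table to ", path, ": ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' @rdname write_fie_table
#' @export
read_fie_table <- function(path) {
  if (!file.exists(path)) stop("FIE table not found: ", path, call. = FALSE)
  out <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = c(tumor_id = "character", gene = "character",
                                   cancer_type = "character",
                                   funfam_id = "character",
                                   protein_id = "character"))
  missing_cols <- setdiff(.fie_columns, names(out))
  if (length(missing_cols))
    stop("not a FIE table (missing ", paste(missing_cols, collapse = ", "), ")",
         call. = FALSE)
  out
}
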