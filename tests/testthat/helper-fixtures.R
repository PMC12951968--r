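# Fixtures built in code. tiny_bundle() is small enough that every map and
# distance can be verified by hand; toy fixtures with planted truth come
# from the package's own generators.

# 3 members x 6 columns; representative P1 ungapped, P2/P3 gapped.
#   P1: A C D E F G   (seq pos 1..6 = columns 1..6, residues 11..16)
#   P2: A - D E - G   (seq pos 1..4 -> columns 1,3,4,6)
#   P3: A C - E F G   (seq pos 1..5 -> columns 1,2,4,5,6)
tiny_bundle <- function(sites = data.frame(residue_id = c(13L, 15L),
                                           site_kind = c("ligand", "catalytic"),
                                           provenance = "test")) {
  aln <- c(P1 = "ACDEFG", P2 = "A-DE-G", P3 = "AC-EFG")
  struct <- domain_structure(data.frame(
    residue_id = 11:16, aa = strsplit("ACDEFG", "")[[1]], atom = "CA",
    x = (0:5) * 3.8, y = 0, z = 0, stringsAsFactors = FALSE))
  funfam_bundle(funfam_id = "FFtiny", superfamily_id = "SFtiny",
                alignment = aln, representative_id = "P1",
                structure = struct,
                seq_to_struct = setNames(11:16, 1:6),
                known_sites = sites, ec_count_superfamily = 12L,
                moonlighting = TRUE)
}

make_mut <- function(protein_id, residue_pos, ref_aa = "A", alt_aa = "V",
                     tumor_id = "T1", cancer_type = "LUAD", gene = "G1",
                     mutation_cn = NA_real_, clonality = "unknown",
                     pop_vaf = NA_real_, disease_variant = FALSE) {
  data.frame(tumor_id = tumor_id, cancer_type = cancer_type, gene = gene,
             protein_id = protein_id, residue_pos = as.integer(residue_pos),
             ref_aa = ref_aa, alt_aa = alt_aa, mutation_cn = mutation_cn,
             clonality = clonality, pop_vaf = pop_vaf,
             disease_variant = disease_variant, expressed = NA,
             stringsAsFactors = FALSE)
}

write_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Brute-force oracle: expected Shannon-Hill diversity of a size-m subsample
# by enumerating every distinct subsample of the expanded item vector.
enumerate_rarefied_hill <- function(counts, m) {
  items <- rep(seq_along(counts), counts)
  subs <- combn(length(items), m)
  H <- apply(subs, 2, function(idx) {
    p <- table(items[idx]) / m
    -sum(p * log(p))
  })
  exp(mean(H))
}

# Brute-force oracle: minimum inter-atomic distance by double loop.
brute_min_distance <- function(structure, r1, r2) {
  a1 <- structure[structure$residue_id == r1, ]
  a2 <- structure[structure$residue_id == r2, ]
  best <- Inf
  for (i in seq_len(nrow(a1))) for (j in seq_len(nrow(a2)))
    best <- min(best, sqrt(sum((unlist(a1[i, c("x", "y", "z")]) -
                                  unlist(a2[j, c("x", "y", "z")]))^2)))
  best
}
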