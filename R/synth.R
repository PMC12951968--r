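# Synthetic fixtures with planted truth. Everything downstream of these
# generators is testable without any external database: structures are
# CA-only linear chains (3.8 A spacing) with a compact "coil" that places
# planted cluster residues and a functional site mutually within 5 A, far
# from the rest of the chain.

.random_aa <- function(n) sample(.grantham_aa, n, replace = TRUE)

# CA-only chain; residues in `special` are moved onto a circle of radius
# 2 A centred at an offset point so all pairwise special distances are
# <= 4 A while every other residue stays > 5 A away.
.chain_structure <- function(n_residues, aa, special = integer(0),
                             side_chain = FALSE) {
  x <- (seq_len(n_residues) - 1) * 3.8
  y <- rep(0, n_residues); z <- rep(0, n_residues)
  if (length(special)) {
    th <- seq(0, 2 * pi, length.out = length(special) + 1L)[seq_along(special)]
    x[special] <- 2 * cos(th)
    y[special] <- 60 + 2 * sin(th)
  }
  atoms <- data.frame(residue_id = seq_len(n_residues), aa = aa, atom = "CA",
                      x = x, y = y, z = z, stringsAsFactors = FALSE)
  if (side_chain) {
    cb <- atoms
    cb$atom <- "CB"
    cb$z <- cb$z + 1.5
    atoms <- rbind(atoms, cb)
    atoms <- atoms[order(atoms$residue_id), ]
  }
  domain_structure(atoms)
}

#' Toy functional family with planted cluster, site and hotspot truth
#'
#' Generates a deterministic (per seed) family bundle: a CA-only chain
#' structure whose planted cluster residues sit mutually within 5 A of a
#' planted ligand site, an alignment of `n_members` paralogs with a
#' controlled gap rate (the representative is ungapped, so all columns are
#' representable), and a builder-cohort mutation table that concentrates
#' `n_cluster_mutations` mutations on the planted residues over scattered
#' background mutations.
#'
#' @param seed integer seed; identical seeds give byte-identical bundles.
#' @param n_members alignment members (>= 2).
#' @param n_columns alignment columns = structure residues.
#' @param n_planted_cluster_residues planted spatial-cluster size.
#' @param site_positions structure residue ids of planted known sites;
#'   default places one site next to the planted cluster.
#' @param gap_rate per-cell gap probability in non-representative rows.
#' @param n_cluster_mutations builder mutations planted on cluster residues.
#' @param n_background_mutations builder mutations scattered uniformly.
#' @param side_chain add a dummy CB atom per residue to exercise heavy-atom
#'   distances.
#' @return list with `bundle` (a [funfam_bundle()]), `builder_mutations`
#'   (mutation table for tunable-site construction) and `truth` (list:
#'   `cluster_residues`, `site_residues`, `hotspot_tuples`).
#' @export
make_toy_funfam <- function(seed, n_members = 6L, n_columns = 40L,
                            n_planted_cluster_residues = 3L,
                            site_positions = NULL, gap_rate = 0.1,
                            n_cluster_mutations = 20L,
                            n_background_mutations = 10L,
                            side_chain = FALSE) {
  set.seed(seed)
  if (is.null(site_positions))
    site_positions <- n_planted_cluster_residues + 1L
  if (n_columns < n_planted_cluster_residues + length(site_positions))
    stop("infeasible geometry: need n_columns >= planted cluster + sites",
         call. = FALSE)
  cluster_res <- seq_len(n_planted_cluster_residues)
  if (length(intersect(cluster_res, site_positions)) > 0)
    stop("infeasible geometry: site_positions overlap the planted cluster",
         call. = FALSE)
  special <- c(cluster_res, site_positions[1])
  rep_seq <- .random_aa(n_columns)
  struct <- .chain_structure(n_columns, rep_seq, special, side_chain)

  members <- paste0("P", seq_len(n_members))
  rep_id <- members[1]
  aln <- setNames(character(n_members), members)
  aln[rep_id] <- paste(rep_seq, collapse = "")
  for (i in 2:n_members) {
    s <- rep_seq
    mut_here <- runif(n_columns) < 0.15
    s[mut_here] <- .random_aa(sum(mut_here))
    gaps <- runif(n_columns) < gap_rate
    s[gaps] <- "-"
    aln[members[i]] <- paste(s, collapse = "")
  }
  sites <- data.frame(residue_id = as.integer(site_positions),
                      site_kind = "ligand", provenance = "planted",
                      stringsAsFactors = FALSE)
  bundle <- funfam_bundle(
    funfam_id = sprintf("FF%05d", seed %% 100000L), superfamily_id = "SF1",
    alignment = aln, representative_id = rep_id, structure = struct,
    seq_to_struct = setNames(seq_len(n_columns), seq_len(n_columns)),
    known_sites = sites, ec_count_superfamily = 3L, moonlighting = FALSE)

  # builder cohort: mutations concentrated on the planted residues, with a
  # guaranteed recurrence hotspot on the first cluster residue
  planted_res <- sample(cluster_res, n_cluster_mutations, replace = TRUE)
  bg_pool <- setdiff(seq_len(n_columns), c(cluster_res, site_positions))
  bg_res <- sample(bg_pool, n_background_mutations, replace = TRUE)
  pos <- c(planted_res, bg_res)
  ref <- rep_seq[pos]
  alt <- vapply(ref, function(a) sample(setdiff(.grantham_aa, a), 1), character(1))
  builder <- data.frame(
    tumor_id = paste0("T", seq_along(pos)),
    cancer_type = "PANCAN", gene = "GENE1", protein_id = rep_id,
    residue_pos = as.integer(pos), ref_aa = ref, alt_aa = unname(alt),
    mutation_cn = NA_real_, clonality = "unknown", pop_vaf = NA_real_,
    disease_variant = FALSE, expressed = NA, stringsAsFactors = FALSE)
  # force a hotspot: two patients, same change, same position
  builder$residue_pos[1:2] <- cluster_res[1]
  builder$ref_aa[1:2] <- rep_seq[cluster_res[1]]
  builder$alt_aa[1:2] <- setdiff(.grantham_aa, rep_seq[cluster_res[1]])[1]
  class(builder) <- c("mutation_table", "data.frame")
  truth <- list(cluster_residues = cluster_res,
                site_residues = as.integer(site_positions),
                hotspot_tuples = data.frame(
                  cancer_type = "PANCAN", gene = "GENE1",
                  residue_pos = cluster_res[1],
                  alt_aa = builder$alt_aa[1], stringsAsFactors = FALSE))
  list(bundle = bundle, builder_mutations = builder, truth = truth)
}

#' Synthetic tumor cohort with planted duplication-timing truth
#'
#' Emulates a multi-tumor cohort at the level this package consumes:
#' per-(tumor, gene) allele-specific copy-number states realising all three
#' timing scenarios, and mutation records whose mutation copy number is
#' drawn around 2 (planted pre-duplication) or 1 (planted post-duplication)
#' with configurable noise. Pre-duplication mutations are concentrated in
#' `pre_genes` while post-duplication mutations are spread over
#' `post_genes`, mirroring the concentrated-early / dispersed-late pattern
#' the diversity analysis is designed to detect.
#'
#' @param seed integer seed.
#' @param n_tumors tumors in the cohort.
#' @param genes gene symbols in play.
#' @param frac_wgd fraction of tumors with whole-genome doubling (biallelic
#'   gain at every gene).
#' @param pre_rate,post_rate expected planted pre-/post-duplication
#'   mutations per tumor (Poisson).
#' @param background_rate expected untimeable background mutations per
#'   tumor (no-gain regions).
#' @param clonal_frac probability a mutation is clonal.
#' @param noise standard deviation of the mutation-copy-number draw; 0
#'   plants exact copy numbers.
#' @param pre_genes,post_genes gene subsets receiving planted pre/post
#'   mutations; defaults: first `min(3, length(genes))` genes for pre, all
#'   genes for post.
#' @param out_dir when given, `mutations.tsv` and `copy_number.tsv` are
#'   written there.
#' @return list with `mutations`, `copy_number` and `truth` (the mutation
#'   table with an `intended_class` column).
#' @export
make_cohort <- function(seed, n_tumors = 40L, genes = paste0("G", 1:20),
                        frac_wgd = 0.75, pre_rate = 2, post_rate = 2,
                        background_rate = 1, clonal_frac = 0.7, noise = 0.1,
                        pre_genes = NULL, post_genes = NULL, out_dir = NULL) {
  set.seed(seed)
  if (any(c(pre_rate, post_rate, background_rate) < 0))
    stop("rates must be non-negative", call. = FALSE)
  if (is.null(pre_genes)) pre_genes <- genes[seq_len(min(3L, length(genes)))]
  if (is.null(post_genes)) post_genes <- genes
  tumors <- sprintf("T%03d", seq_len(n_tumors))
  wgd <- runif(n_tumors) < frac_wgd

  cn <- do.call(rbind, lapply(seq_len(n_tumors), function(i) {
    # biallelic gains arise only through WGD; other tumors carry focal
    # monoallelic gains (with or without LOH) or no gain
    state <- if (wgd[i]) matrix(c(2L, 2L), length(genes), 2, byrow = TRUE)
    else {
      pick <- sample(3L, length(genes), replace = TRUE)
      # 1: monoallelic + LOH, 2: monoallelic without LOH, 3: no gain
      t(vapply(pick, function(k) switch(k, c(2L, 0L), c(2L, 1L), c(1L, 1L)),
               integer(2)))
    }
    data.frame(tumor_id = tumors[i], gene = genes, major_cn = state[, 1],
               minor_cn = state[, 2], stringsAsFactors = FALSE)
  }))

  draw_cn <- function(center, k) pmax(0, center + stats::rnorm(k, 0, noise))
  rows <- list()
  for (i in seq_len(n_tumors)) {
    cn_i <- cn[cn$tumor_id == tumors[i], ]
    gained <- cn_i$gene[cn_i$major_cn >= 2L]
    post_ok <- cn_i$gene[cn_i$major_cn >= 2L & cn_i$minor_cn != 1L]
    ungained <- cn_i$gene[cn_i$major_cn < 2L]
    n_pre <- rpois(1, pre_rate); n_post <- rpois(1, post_rate)
    n_bg <- rpois(1, background_rate)
    add <- function(gene_pool, k, center, intended) {
      pool <- intersect(gene_pool, if (intended == "pre") gained
                        else if (intended == "post") post_ok else ungained)
      if (!length(pool) || k == 0L) return(NULL)
      g <- sample(pool, k, replace = TRUE)
      ref <- .random_aa(k)
      alt <- vapply(ref, function(a) sample(setdiff(.grantham_aa, a), 1),
                    character(1))
      data.frame(tumor_id = tumors[i], cancer_type = "LUAD", gene = g,
                 protein_id = paste0("P_", g),
                 residue_pos = sample(100L, k, replace = TRUE),
                 ref_aa = ref, alt_aa = unname(alt),
                 mutation_cn = if (is.na(center)) NA_real_ else draw_cn(center, k),
                 clonality = ifelse(runif(k) < clonal_frac, "clonal", "subclonal"),
                 pop_vaf = NA_real_, disease_variant = FALSE, expressed = TRUE,
                 intended_class = intended, stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- add(pre_genes, n_pre, 2.0, "pre")
    rows[[length(rows) + 1L]] <- add(post_genes, n_post, 1.0, "post")
    rows[[length(rows) + 1L]] <- add(genes, n_bg, 1.0, "no_gain")
  }
  muts <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(muts) <- NULL
  truth <- muts
  muts$intended_class <- NULL
  class(muts) <- c("mutation_table", "data.frame")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.table(muts, file.path(out_dir, "mutations.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(cn, file.path(out_dir, "copy_number.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  list(mutations = muts, copy_number = cn, truth = truth)
}

#' Null fixture: uniform mutations on a featureless chain
#'
#' For calibrating cluster significance: `n_mutations` mutations assigned
#' uniformly at random over `n_residues` of a linear CA chain, with no
#' planted structure. Optional planted sites let the tunable-site stage be
#' exercised; with none, tunable sites are always empty.
#'
#' @param seed integer seed.
#' @param n_residues chain length.
#' @param n_mutations mutations to scatter (>= 1).
#' @param site_positions optional residues marked as known ligand sites.
#' @return list with `structure`, `counts` (per-residue table as consumed
#'   by [cluster_mutations()]) and `sites`.
#' @export
make_null_funfam <- function(seed, n_residues = 50L, n_mutations = 50L,
                             site_positions = integer(0)) {
  set.seed(seed)
  if (n_mutations < 1L) stop("n_mutations must be >= 1", call. = FALSE)
  struct <- .chain_structure(n_residues, .random_aa(n_residues))
  res <- sample(n_residues, n_mutations, replace = TRUE)
  tab <- table(res)
  counts <- data.frame(residue_id = as.integer(names(tab)),
                       count = as.integer(tab))
  sites <- data.frame(residue_id = as.integer(site_positions),
                      site_kind = rep("ligand", length(site_positions)),
                      provenance = rep("planted", length(site_positions)),
                      stringsAsFactors = FALSE)
  list(structure = struct, counts = counts, sites = sites)
}
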