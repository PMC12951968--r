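# funvar

Detection of **functional impact events (FIEs)** — somatic missense
mutations predicted to alter protein function through their action at or
near functional sites — with classification of each event's timing relative
to gene duplication and Hill–Shannon diversity analysis of the genes and
protein families affected before versus after duplication.

## Who this is for

Cancer genomics groups working with cohort mutation tables (TRACERx/TCGA
style), allele-specific copy-number calls and protein-domain resources.
Rare driver mutations are hard to call from recurrence in a single gene:
`funvar` gains power by pooling mutations from **paralogous domains that
share a functional family** (a functional subclassification of a structural
superfamily) onto one representative 3D structure, where recurrence that is
invisible at the gene level becomes visible as spatial clustering near a
shared functional site.

## The method

1. **Projection.** Mutations and site annotations from every family member
   are carried through the family's multiple-sequence alignment onto the
   single representative structure (per-member bijections between ungapped
   sequence positions and alignment columns, composed with an explicit
   sequence→structure residue map).
2. **Sites.** Known functional sites (ligand, nucleic-acid, PPI, catalytic)
   are inputs; additional sites are *predicted* as alignment columns with
   conservation score > 0.9 — computed as `(1 − H/ln 20)(1 − g)` with `H`
   the column's Shannon entropy and `g` its gap fraction — in alignments
   whose diversity-of-positions score (DOPS) exceeds 70.
3. **Tunable sites.** Spatial mutation clusters are found by greedy
   seed-and-extend within a 5 Å radius; cluster significance is an
   empirical permutation p-value against the null maximum cluster score
   (mutations dropped uniformly over eligible residues). Clusters at
   p ≤ 0.05 (standard) or p ≤ 0.005 (high), and recurrence hotspots
   (identical change in ≥ 2 patients of one cancer type), that lie within
   5 Å of a functional site are **tunable sites**.
4. **FIE score.** Target-cohort mutations inside tunable sites are scored
   as the sum of sequence components (Grantham substitution impact
   {0,1,2} with thresholds 64/109 and a polymorphism override at
   population VAF > 1e−7; hotspot {0,1}; known disease variant {0,1}),
   structure components (on/near a known site, on/near a predicted site —
   on implies near, so a site hit is worth 2 per class, 4 at most — and
   high-significance cluster membership {0,1}) and a family-level
   mutation-enrichment component {0,1}. Totals lie in [1, 10]; events with
   score ≥ 3 are retained.
5. **Timing.** Each FIE is classed pre-/post-duplication from
   allele-specific copy numbers (`major_cn`, `minor_cn`) and the mutation
   copy number: in a gained region (major ≥ 2), mutation copy number
   > 1.5 ⇒ pre, < 1.5 ⇒ post, except monoallelic gain without LOH
   (minor = 1) where < 1.5 cannot be timed. Discordant multi-region calls
   reconcile pre+post → post.
6. **Diversity.** FIEs per gene (or family) pre vs post duplication are
   compared with Hill–Shannon diversity (`exp` of Shannon entropy — the
   effective number of genes), using exact hypergeometric rarefaction,
   extrapolation to twice the observed sample size via the
   singleton/doubleton-corrected asymptotic entropy estimator,
   Chao-style sample coverage, and coverage-adjusted bootstrap 95% CIs;
   the difference is significant when CIs do not overlap at the common
   comparison size.

A synthetic-fixture module (`make_toy_funfam()`, `make_cohort()`,
`make_null_funfam()`) generates families with planted clusters, hotspots
and timing truth so the whole pipeline runs and is tested without any
external database.

## Worked example

```r
library(funvar)

toy <- make_toy_funfam(seed = 1)            # planted family fixture
cfg <- funvar_config(rng_seed = 42)
res <- funvar_pipeline(toy$bundle, toy$builder_mutations, config = cfg)
res
#> funvar pipeline result
#>   clusters: 8 (1 significant) | tunable sites: 2
#>   candidate FIEs: 20 | scored: 20 | retained at threshold 3: 17
res$tunable
#>      site_id  source residue_ids mutation_count p_value tier min_site_distance
#> 1 cluster_01 cluster       1,2,3             20   0.001 high          2.828427
#> 2 hotspot_01 hotspot           1             NA      NA <NA>          2.828427
```

The planted 3-residue cluster (residues 1–3, 20 mutations) is recovered at
p = 0.001 ("high" tier, p ≤ 0.005) and sits 2.8 Å from the planted ligand
site, so it becomes a tunable site; the planted recurrence hotspot on
residue 1 passes the same 5 Å gate independently. All 20 mutations
projecting into the tunable residues are FIE candidates; 17 score ≥ 3.

```r
coh <- make_cohort(seed = 3, noise = 0)      # planted cohort: pre FIEs in
timed <- time_fies(coh$mutations, coh$copy_number)  # 3 genes, post in 20
table(timed$timing)
#> no_gain    post     pre
#>       1      94      79
ab <- fie_abundance(timed, "gene", "timing")
compare_groups(ab$pre, ab$post, cfg)
#> diversity comparison at m = 188:
#>   pre      2.954 [  2.698,   2.994] (extrapolated)
#>   post    18.036 [ 14.880,  18.585] (extrapolated)
#>   significant (non-overlapping 95% CIs) (higher: post)
```

With noise 0 every planted timing class is recovered, and the
post-duplication events — spread over many genes — show a significantly
higher effective number of mutated genes (≈ 18 vs ≈ 3) than the
pre-duplication events concentrated in three genes.

A thin command-line front end is installed with the package
(`inst/cli/funvar`): `funvar tunable-sites`, `funvar score`,
`funvar time`, `funvar diversity`, `funvar simulate`, each taking
`--config`, `--seed` and `--out`.

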