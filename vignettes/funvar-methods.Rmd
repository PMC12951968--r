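---
title: "Methods: detecting and analysing functional impact events"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and analysing functional impact events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the model behind each stage of the package, the
assumptions those stages make, the parameters that matter, and the design
decisions taken where more than one defensible choice existed.

## The model in one paragraph

Driver mutations that act through a protein's functional sites need not
recur at one position of one gene: paralogous domains with the same
function can be "tuned" at equivalent residues in different genes and
tumor types. The package therefore pools mutations across a functional
family — paralogs whose domains share structure and function — onto one
representative structure, asks where they cluster in 3D, keeps the
clusters (and single-position recurrence hotspots) that sit within 5 Å of
a known or conservation-predicted functional site ("tunable sites"), and
calls a target cohort's mutations inside those sites functional impact
events (FIEs). Each FIE is scored by a component heuristic, timed against
gene duplication using copy numbers, and the gene/family repertoires of
early (pre-duplication) versus late (post-duplication) events are compared
with Hill–Shannon diversity.

Assumptions worth keeping in mind: one representative structure stands for
the whole family (no ensemble averaging); family membership and the
sequence→structure residue map are *inputs*, taken as correct; copy-number
states are already summarised per (tumor, gene); and mutation copy numbers
are estimated upstream.

## Projection through the alignment

For each family member a strictly increasing bijection is built between
its ungapped 1-based sequence positions and the alignment columns it
occupies. A mutation projects onto the representative iff the
representative is not gapped at the mutation's column and the position is
covered by the explicit sequence→structure map; everything else is counted
as unprojectable rather than silently dropped. A mutation whose recorded
reference residue disagrees with the member's residue at that column
(isoform or sequence-version drift) is flagged `ref_mismatch` and excluded
from clustering by default but kept in the assignment table, because such
drift is common in real accessions and should be visible, not fatal.

## Conservation and predicted sites

The per-column score is `(1 − H/ln 20) · (1 − g)`: `H` is the Shannon
entropy of the (optionally weighted) amino-acid distribution over non-gap
symbols, `g` the gap fraction. It is 1 exactly for a single-residue,
gapless column and 0 for the maximal 20-way uniform column; an all-gap
column scores 0 with a flag. Sequence weights default to uniform;
position-based weights (Henikoff-style) are available when alignments are
redundant. The scorer is an argument of `alignment_conservation()`, so a
sum-of-pairs scorer can be slotted in without touching the interface.

The diversity-of-positions score (DOPS) gates prediction: an alignment of
near-identical sequences scores every column as conserved, so conserved
columns are only trusted as predicted sites when the alignment itself is
diverse. The default DOPS is deliberately simple — 100 × (distinct column
scores after rounding to 3 decimals)/(number of columns) — and swappable
via the `method` argument of `dops()`. Prediction requires DOPS > 70 and
uses a strict inequality on the *raw* (unrounded) score: column score
> 0.9.

## Clustering and its null

Clustering is greedy seed-and-extend: residues are ranked by their
neighbourhood mutation count (total count within the 5 Å radius; ties
break to the lower residue id, making the procedure fully deterministic),
and each seed claims the not-yet-assigned mutated residues within its
radius. A cluster's score is the mutation count it covers. Significance is
an empirical permutation p-value, `(1 + #{null ≥ observed})/(1 + n_perm)`,
where the null drops the same number of mutations uniformly over the
eligible residues and records the *maximum* cluster score. Distances are
minimum inter-atomic distances over the atoms present; CA-only structures
therefore fall back to CA–CA distances under the same 5 Å cutoff.

Two consequences are intentional. First, comparing every cluster against
the null maximum makes secondary clusters conservative. Second, the max
statistic is discrete, so p-values are super-uniform: on null fixtures the
empirical rejection rate at the 5% level sits *below* 5% (typically 1–3%).
The calibration tests check one-sidedly that the rate does not exceed the
nominal level, which is the correct property for a conservative test. No
multiplicity correction is applied across clusters or families — the
protocol's contract is raw 5%/0.5% levels — but a Benjamini–Hochberg mode
is available (`bh = TRUE`).

Tunable sites are built from a *builder* cohort and applied to a *target*
cohort; the two may coincide. Hotspots in the target cohort are assessed
independently of builder-cohort hotspots.

## The FIE score

Nine components: Grantham substitution impact (0 if the matrix value is
≤ 64 or the mutation is polymorphic at population VAF > 1e−7, 1 if
> 64, 2 if > 109), hotspot membership {0,1}, known disease-variant flag
{0,1}; on/near a known site, on/near a predicted site (on implies near;
the four site components reach at most 4), high-significance cluster
membership (p ≤ 0.005) {0,1}; and family mutation enrichment {0,1}.
Totals are sums in [1, 10] for any tunable-site mutation; the retention
threshold defaults to 3, and sub-threshold records are kept in a secondary
output rather than discarded.

The Grantham cut points 64 and 109 are **configuration constants, not
derived quantities**. They are conventionally motivated as the median and
upper quartile of "possible" Grantham scores, but no quantile of the
embedded matrix reproduces them: the 190 unordered pair distances have
median 97 and upper quartile ≈ 134, and restricting to substitutions
reachable by a single nucleotide change gives 77.5 and 110.
`grantham_calibration()` exposes both recomputations so users can see the
discrepancy; the defaults remain 64/109 because downstream score
semantics (and the [1, 10] range) are defined against them.

The family enrichment component is a one-sided exact binomial test of
domain mutations against the domain's share of coding length, with BH
adjustment across families when several are tested together; a precomputed
family flag on the bundle overrides the test. Family-level
`diverse_family` (parent superfamily with strictly more than 10 distinct
EC functions) and `moonlighting` (membership of a curated list supplied as
input) are annotations for neofunctionalization triage, never filters.

## Timing

The truth table is exact and exhaustively tested: gain present means
major ≥ 2; in a gained region a mutation copy number above 1.5 is pre,
below is post, except monoallelic gain without LOH (minor = 1), where a
single mutant copy is ambiguous and stays untimed. A value of exactly 1.5
is classed untimed (tie rule) — the boundary is otherwise open on both
sides and silently assigning it to either class would misstate the
evidence. Missing mutation copy number in a gained region is untimed with
a reason. Across tumor regions, pre+post reconciles to post: a mutation on
all copies cannot regain wild-type copies, while the reverse is possible
via subclonal gain. Clonality is consumed as an input column and used only
to stratify the diversity analysis.

## Diversity

Hill–Shannon diversity (`exp` of Shannon entropy) is the effective number
of genes or families. Rarefaction is the *exact* hypergeometric
expectation of subsample entropy — not a series approximation — which is
what makes the brute-force enumeration oracle (all `choose(n, m)`
subsamples for n ≤ 12, agreement < 1e−9) possible. Extrapolation blends
entropies, `(n/m)·H_obs + ((m−n)/m)·H_asy`, with the
singleton/doubleton-corrected asymptotic entropy estimator `H_asy`; the
blend is continuous at `m = n`, monotone in `m`, and approaches the
asymptote. Two explicit conventions: with no singletons (`f1 = 0`) the
sample is treated as complete (`H_asy = H_obs`, so the curve is flat
beyond `n`), and `H_asy` is floored at `H_obs` so the curve can never bend
below the observed value; an all-singleton vector has no defined asymptote
and returns the observed value with a warning.

Sample coverage is `1 − (f1/n)·(n−1)f1/((n−1)f1 + 2f2)`. Bootstrap CIs
resample from the coverage-adjusted label distribution (observed labels
with shrunken probabilities plus the unseen mass split over the estimated
number of unseen labels), default percentile intervals, deterministic
under seed; intervals are clamped to contain the point estimate.
`compare_groups()` extends both curves to `extrapolation_factor ×
max(n_pre, n_post)` (factor 2 by default — extrapolating further outruns
the information in `f1`/`f2`) and declares significance by CI non-overlap
at that shared endpoint, the one size common to both curves; no additional
test statistic is invented. Orders q = 0 (richness) and q = 2 (Simpson)
are available behind the same interface, but q = 1 is the default because
it weighs rare and common genes evenhandedly.

## Synthetic fixtures: what they do and do not show

`make_toy_funfam()` builds CA-only chains (3.8 Å spacing) where planted
cluster residues and a planted site are moved onto a 2 Å-radius circle
60 Å away from the chain, guaranteeing mutual distances ≤ 4 Å and
isolating everything else; an option adds a dummy side-chain atom to
exercise heavy-atom distances. `make_cohort()` plants all three gain
scenarios (biallelic gains only through whole-genome doubling, default
75% of tumors; focal monoallelic gains with and without LOH otherwise),
draws mutation counts Poisson per tumor, and assigns mutation copy numbers
around 2 (pre) or 1 (post) with configurable noise; default rates (2
planted pre and post events and 1 background event per tumor, 70% clonal)
give cohorts of a few hundred mutations over 40 tumors, small enough to
run everywhere and large enough for stable diversity estimates.
`make_null_funfam()` scatters mutations uniformly for calibration.

These fixtures validate the *logic* — projection arithmetic, significance
calibration, score bounds, the timing truth table, diversity estimators —
on geometry and noise models far simpler than real data. They do not
emulate mutational signatures, correlated hotspots, alignment errors,
structure flexibility or copy-number estimation noise, so passing tests
bound correctness of the implementation, not performance on a real cohort.

## Problem sizes and numerical conventions

Test and acceptance runs use 50-residue structures, cohorts of 40–50
tumors, 999 permutations, 200 null replicates, 100 planted-recovery
replicates, 200 bootstrap replicates and 20 diversity-comparison
replicates — sizes chosen so the full suite completes in well under a
minute per stage while leaving binomial tolerances tight enough to detect
real miscalibration. Other conventions: conservation thresholds are strict
inequalities on raw scores; DOPS rounds to 3 decimals before counting
distinct values; cluster ties break to the lower residue id; distances are
Euclidean minima over available atoms; the timing boundary 1.5 maps to
untimed; diversity enumeration oracles require agreement within 1e−9;
bootstrap intervals are percentile unless requested otherwise. Degenerate
inputs are defined, not crashed: empty mutation sets give empty cluster
lists, single-residue structures give one trivial cluster with p = 1,
empty FIE tables write header-only files, and a single-label abundance
vector has diversity 1 with collapsed CIs.
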