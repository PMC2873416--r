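---
title: "Methods: domestication-selection scans on duplicated loci"
author: "domestiscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: domestication-selection scans on duplicated loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domestiscan)
```

## The scientific problem

Crop domestication leaves a recognizable molecular footprint. When a
locus is driven to fixation by artificial selection, linked variation
hitchhikes along: cultivated accessions show sharply reduced nucleotide
diversity relative to wild relatives, an excess of rare variants
(negative Tajima's D), too little polymorphism for their divergence from
an outgroup (HKA heterogeneity), and — when the favored haplotype moved
between subspecies — a gene tree at the locus that clusters all
cultivars even though genome-wide SNPs separate the subspecies. For
duplicated genes a second question arises: when did the duplication
happen, and is each copy still under purifying selection? This package
implements the full battery of statistics used to answer these questions
for a candidate locus resequenced in a cultivated/wild germplasm panel,
together with a synthetic-data generator so that every stage can be
exercised, calibrated and tested without the original resequencing data.

## Data model and missing-data rule

A `locus_alignment` holds one pre-aligned locus as an n × L character
matrix over `{A,C,G,T,-,N}` plus a population label per sample
(`japonica`, `indica`, `wild`, `outgroup`, or any other label). All
reported coordinates are 1-based inclusive, offset by
`coordinate_offset` so windows can be placed on a chromosome axis.

All diversity statistics use **site-wise complete deletion within the
analyzed population**: any column containing `-` or `N` among the
analyzed samples is dropped, and `L_eff` records the retained columns.
`-` and `N` are equivalent ("missing"). This matches the default
behavior of the classic desktop polymorphism tools that analyses of this
kind normally report, and makes `L_eff` explicit in every output row.

## Diversity statistics

For a population sample of size n at a locus with `L_eff` retained
columns:

* `S` — columns with ≥ 2 distinct bases;
* θ<sub>π</sub> — mean pairwise difference count over all n(n−1)/2
  pairs, divided by `L_eff` (computed from per-column allele counts,
  which is algebraically identical and O(L) instead of O(n²L); the test
  suite checks the identity against the brute-force pairwise oracle);
* θ<sub>W</sub> — S/(a₁·L_eff), a₁ = Σ<sub>i=1..n−1</sub> 1/i;
* Tajima's D — (π̂ − S/a₁)/√(e₁S + e₂S(S−1)) using total (not per-site)
  π̂ and the standard constants a₁, a₂, b₁, b₂, c₁, c₂, e₁, e₂; D is
  undefined (NA) exactly when S = 0.

Significance of D is assessed by a **parametric bootstrap under the
standard neutral coalescent conditional on the observed S**
(`tajima_d_test`, default 10,000 seeded replicates): genealogies are
simulated for the observed n, S mutations are placed multinomially in
proportion to branch length, and the observed D is ranked in the
simulated distribution. We chose this over the beta approximation
because it is reproducible, assumption-explicit, and exact under the
model actually simulated by the package's own generator.

"Silent-site" diversity at coding loci is approximated by all-site
diversity on noncoding regions; no synonymous-column mask is applied by
default because such masks are not standardized across tools and the
package's window tracks operate on arbitrary column ranges anyway.

Haplotype types are exact sequence-identity classes after the deletion
rule (no single-mismatch clustering), numbered by descending size with
ties broken by first occurrence; haplotype diversity is
n(1 − Σp<sub>i</sub>²)/(n − 1). Near-fixed differences between two
populations report sites where the major allele of population A has
frequency ≥ t in A and ≤ 1 − t in B; the default t = 0.95 encodes
"almost fixed".

Sliding windows advance by `step` bp over alignment columns; the number
of full windows is ⌊(L − window)/step⌋ + 1 and a trailing partial window
is reported only on request. Each window value equals the full statistic
recomputed on the column slice (tested against exactly that).

## HKA test

`polymorphism_divergence_counts` classifies columns for one locus with a
single outgroup sequence: S counts ingroup-segregating columns among
columns fully typed in the ingroup (`L_poly`), D counts
ingroup-monomorphic columns differing from the outgroup among columns
additionally typed in the outgroup (`L_div`). Ancestral state is not
inferred; divergence is counted against the single outgroup sequence.

`hka_test` offers two clearly labelled methods, because published
analyses of this design rarely state which implementation produced their
p-value and the two can differ by orders of magnitude:

* **hka1987** — the classic moment form. With per-site parameters θᵢ and
  scaled divergence time T (population-size ratio f, default 1, and
  τ = T + (1+f)/2), the moment equations
  ΣSᵢ = Σθᵢ·L_polyᵢ·a₁(nᵢ), ΣDᵢ = τ·Σθᵢ·L_divᵢ, and
  S₂ + D₂ = θ₂(L_poly₂·a₁(n₂) + L_div₂·τ) are solved (the last two
  reduce to a single root-find in τ), then
  X² = Σᵢ (Sᵢ−E[Sᵢ])²/Var[Sᵢ] + (Dᵢ−E[Dᵢ])²/Var[Dᵢ] with
  Var[Sᵢ] = E[Sᵢ] + (θᵢL_polyᵢ)²a₂(nᵢ) and
  Var[Dᵢ] = E[Dᵢ] + (θᵢL_divᵢ(1+f)/2)², referred to χ² with 1 df.
  The quadratic variance terms absorb the full no-recombination
  coalescent variance, so this form is far more conservative than a
  count-based table test — on the published candidate/reference counts
  it yields p ≈ 0.015 where the contingency form yields p ≈ 5×10⁻⁶.
* **contingency** — the 2×2 table [[S_cand, D_cand], [S_ref, D_ref]] by
  chi-square without continuity correction, with Fisher's exact p
  reported alongside (flagged when any expected cell < 5).

Fitted expectations conserve the observed totals (tested), and the
type-I error of the moment form is calibrated by simulation under one
shared θ/T (`simulate_hka_counts`, which draws S from the
coalescent-Poisson mixture and D from the exponential-Poisson mixture
matching the variance formulas above).

## Ka/Ks and duplication dating

Nei–Gojobori (1986) counting under the standard nuclear genetic code:
per codon position, the synonymous site fraction is the fraction of the
three point mutations that preserve the amino acid, excluding mutations
that create stops and renormalizing the remainder, so each codon
contributes exactly 3 sites. Differences of 2–3 positions are averaged
with equal weights over the mutational pathways that avoid stop codons
(if all pathways are blocked, unrestricted pathways are used with a
warning). Proportions pN = Nd/N and pS = Sd/S are Jukes–Cantor
corrected, d = −(3/4)ln(1 − 4p/3); p ≥ 3/4 marks saturation (NA).
Codons containing gaps, ambiguity codes or stops in either sequence are
dropped pairwise. Pathway weighting is the classic equal-weight scheme
(no transition bias) since the analyses this package supports report
plain NG86 values.

The neutrality test is Fisher's exact test on the
{nonsynonymous, synonymous} × {differences, non-differences} table with
fractional counts rounded half-up — the table construction is fixed and
documented here because published "exact test" columns generally leave
it unstated.

Duplication/divergence dating is T = Ks/(2µ); the default
µ = 6.5×10⁻⁹ substitutions per silent site per year is the commonly
used rice nuclear rate and is configurable. `mean_ks_over_pairs`
averages Ks across several flanking homolog pairs (saturated pairs
excluded with a warning) to date a segmental duplication from its whole
colinear block; e.g. Ks = 0.57 at the default rate gives ≈ 44 MY.

## Trees and incongruence

Distances: p (pairwise deletion), Jukes–Cantor, protein-p (codon-wise
translation, untranslatable codons missing), and allele-sharing
(mismatch fraction over jointly typed biallelic SNPs) for genome trees.

Neighbor joining is implemented in the package rather than delegated,
because reproducibility of the downstream monophyly verdicts requires a
fixed contract that generic implementations do not promise: Q-criterion
ties are broken by the lexicographically smallest sorted taxon-label
pair, and a negative branch length is clamped to zero with the deficit
moved to its sister branch, preserving path lengths. On additive
matrices the recovered patristic distances reproduce the input exactly
(≤ 1e-9; tested), and topologies agree with the reference `ape::nj` on
random inputs. Robinson–Foulds distance counts nontrivial bipartitions
present in exactly one tree; monophyly of a taxon set is an exact
edge-cut test on the unrooted tree. Bootstrap supports resample columns
with a fixed seed and annotate the full-data tree's internal nodes. RF
(not quartet) distance is used as the incongruence metric — standard and
exact at panel sizes of ≤ ~60 taxa.

## Synteny

Homolog pairs between two gene regions are reciprocal best hits under a
local aligner (match +1, mismatch −1, gap open −2, gap extend −1; via
Biostrings' Smith–Waterman), retained at identity ≥ 0.6 of aligned
columns and coverage ≥ 0.5 of the shorter CDS. This replaces an external
blastn dependency while keeping the thresholds explicit. The collinear
chain is the longest subsequence of pairs strictly increasing in A-order
and monotone in B-order, computed for both orientations; ties prefer the
same orientation and the chain with the lowest starting A-rank. The
chain equals exhaustive search for n ≤ 12 (tested).

## The synthetic germplasm generator

`sim_scenario` defaults encode the sampling design the analyses assume:
25 wild accessions and 25 cultivars (12 *japonica*, 13 *indica*) at a
4.6-kb locus. Time is in units of 2N generations; θ is the per-locus
scaled mutation rate under infinite sites (every mutation occupies a
fresh column). Defaults and their motivation:

* `theta = 40` — gives wild per-site diversity ≈ 0.010, matching the
  ~0.01 silent-site diversity of wild rice at such loci;
* `outgroup_divergence = 0.1` — one outgroup sequence carrying
  Poisson(0.1·L) private substitutions, matching the ~10% divergence of
  the outgroup genome used for HKA (≈ 450 differences over ~4.6 kb);
* `wild_split_time = 0.3` — the wild population comprises two demes
  (split 0.3) and the two cultivated subpopulations derive from
  different demes, reflecting the independent domestication of
  *japonica* and *indica* from divergent wild pools; this is what makes
  genome trees separate the subspecies. With no cultivated samples, or
  `wild_split_time = 0`, the wild population is panmictic — the
  configuration used for all neutral calibrations;
* `bottleneck_time = 0.05`, `severity = 0.05`, `duration = 0.025` — each
  cultivated subpopulation coalesces at 20× intensity during the
  bottleneck window, which reduces genome-background cultivated
  diversity to roughly 0.55–0.75 of wild, the ordering seen in real
  cultivar panels;
* `sweep` — star-like forced coalescence of each cultivated
  subpopulation's lineages at `sweep_time = 0.02`, a deliberate
  approximation of a hard sweep (no structured coalescent with selection
  coefficients); adequate to produce the qualitative focal-locus
  signatures at desk scale;
* `introgression` — all cultivated lineages coalesce jointly at the
  sweep time into a single haplotype that descends from a **diverged
  donor lineage** rejoining the wild pool only at the wild-deme split.
  Domestication alleles are typically old, divergent variants, and this
  choice guarantees the shared cultivated haplotype carries diagnostic
  substitutions; modelling the donor as a recent member of a sampled
  wild deme instead leaves the cultivar cluster without a single
  supporting mutation in a nontrivial fraction of replicates, an
  artifact of the approximation rather than a feature of the biology.

`simulate_germplasm_panel` applies the sweep/introgression settings only
to the focal locus; all loci share the demography. The genome-wide
genotype matrix pools the biallelic sites of the non-focal loci
(ancestral allele 0). `evolve_codon_pair` duplicates a random stop-free
coding sequence and accepts proposed point substitutions with
probability 1 (synonymous) or ω (nonsynonymous), rejecting stops, until
the accepted synonymous changes per synonymous site reach the target
pS — a deliberately simple mechanism whose realized NG86 Ka/Ks is ω by
construction up to multiple-hit noise.

What the generator does **not** emulate: intralocus recombination (so
single-locus statistics have the full no-recombination variance — window
tracks from one simulated locus are strongly autocorrelated),
recurrent/back mutation, indels and alignment error, sequencing or
consensus-calling error, and realistic rice demographic detail (growth,
migration, admixture beyond the introgression device). Passing
calibration therefore shows the statistics and the pipeline are correct
under the stated model, not that the model captures every feature of
real resequencing data.

## Numerical and policy choices

* Tie-breaks: haplotype types by size then first occurrence; NJ joins by
  lexicographic label pairs; collinear chains by orientation then lowest
  starting rank. All outputs are deterministic under the configured
  seed, and seeds are ordinary 32-bit integers.
* Degenerate inputs: statistics require n ≥ 2 (D requires n ≥ 3);
  S = 0 gives D = NA rather than 0; saturated distances (p ≥ 3/4 under
  JC) are NA and refuse tree building; zero rows/columns make the
  contingency HKA an error rather than a silent 0.
* Fractional Fisher counts are rounded half-up (not banker's rounding).
* No multiple-testing correction is applied across windows — window
  tracks are reported raw, and sweep-boundary calling is left to the
  user.

## Calibration results asserted by the test suite

The acceptance suite (and `scripts/acceptance.R`) recomputes, from
scratch at fixed seeds: printed-table Ka/Ks ratio arithmetic (6
decimals) and the 44-MY dating; oracle equivalence of π, S, D, NG86
counts, NJ branch lengths, RF and collinear chaining on small instances;
neutral-coalescent calibration at n = 10, θ = 5 over 2000 replicates
(mean S within 3 SE of θa₁ = 14.145, mean D in (−0.15, 0.05), mean
per-site π within 5% of θ/L, π and θ<sub>W</sub> agreeing within 5%);
HKA type-I error ≈ 5% over 1000 replicates; NG86 recovery of ω = 0.2
within ±0.05 over 100 pairs of 500 codons; and the two qualitative
patterns in ≥ 90% of 100 panels each — the sweep pattern (focal
cultivated π < 0.3× wild π, focal cultivated D < 0 or S = 0, focal
cultivated π below the genome-average cultivated π of the non-focal
loci, per subpopulation) and the introgression pattern (cultivar
monophyly on the focal gene tree, non-monophyly on the genome tree).
The sweep pattern is evaluated per cultivated subpopulation because
pooling *japonica* and *indica* mixes their divergence into π and D and
is not how such panels are analyzed; the "focal locus only" aspect is
the ordering focal < genome average, which is exactly the comparison
real studies report. Problem sizes (2000/1000/100 replicates, 4-locus
panels, 1-kb calibration loci) were chosen so the whole battery runs in
a few minutes on one CPU while leaving Monte-Carlo error well inside
the asserted bands.

## Known limitations

* The moment-form HKA is implemented for two loci (candidate +
  reference), not the general multi-locus case, and no
  maximum-likelihood HKA variant is provided.
* NG86 is the only Ka/Ks estimator; no codon-model ML, no
  transition/transversion bias, no site/branch models.
* The NJ implementation targets panel-scale trees (tens of taxa);
  no ML or Bayesian inference.
* VCF ingestion and de novo alignment are out of scope — inputs are
  pre-aligned FASTA plus TSV population maps and GFF-like gene tables.
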