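---
title: "Region-partitioned molecular evolution of trappin-like gene families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-partitioned molecular evolution of trappin-like gene families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trappinevo)
```

## The analysis this package implements

Trappins are small secreted host-defense proteins built from an N-terminal
transglutaminase-substrate (TGS) domain — tandem repeats of the
semi-conserved hexamer `KGQDPV` — and a C-terminal whey-acidic-protein
(WAP) domain defined by eight conserved cysteines. Several mammalian
lineages (pig, cow, nine-banded armadillo) carry recently duplicated
trappin paralog families whose protein-coding exon evolves conspicuously
faster than the surrounding noncoding DNA. `trappinevo` implements the
comparative pipeline used to characterise such families:

1. partition each ~2.1-kb three-exon gene into seven annotated regions
   (5' flank, exon 1 with its signal-peptide part, intron 1, exon 2 with
   the TGS and WAP coding parts, intron 2, the noncoding exon 3, 3' flank);
2. estimate per-region mean pairwise distances (Jukes–Cantor and
   Tamura–Nei, optionally gamma-corrected) with column-bootstrap standard
   errors;
3. test regional rate acceleration with Fisher's exact test on varied vs
   common site counts, and positive selection with a one-sided Fisher test
   on modified Nei–Gojobori synonymous/nonsynonymous counts;
4. date gene duplications on a linearized neighbor-joining tree against a
   single calibration split;
5. classify WAP domains (eight-cysteine grammar, catalytic-methionine
   rule), locate TGS repeats, and compare sequences with Harr-plot dot
   matrices;
6. summarise genome-assembly quality from cDNA/genomic-exon substitution
   counts.

Because the original inputs are database accessions, the package ships a
first-class simulator (`sim_config()`, `simulate_family()`) that generates
trappin-like families with known truth so that every stage is testable
offline.

## Distances

For a proportion $p$ of differing sites, the Jukes–Cantor distance is
$d_{JC} = -\tfrac{3}{4}\log(1 - \tfrac{4}{3}p)$. The Tamura–Nei (TN93)
distance separates the two transition classes ($A\!\leftrightarrow\!G$,
$C\!\leftrightarrow\!T$) and transversions, with base frequencies taken
from the sequence pair itself. Under gamma-distributed rate variation with
shape $a$, every $-\log(x)$ term is replaced by $a(x^{-1/a}-1)$;
`gamma_shape = Inf` recovers the plain distance. The shape parameter is an
*input* here — in practice it is estimated by external Bayesian or
likelihood software, so regional tables computed with a guessed shape are
only approximately comparable to published ones.

Conventions that matter:

* **Complete deletion.** All distances are computed after removing every
  column containing a gap or missing datum (`N`/`X`) in any row; this is
  also the denominator ("common sites") of the acceleration test.
* **Saturation.** $p \ge 0.75$ (and TN93 log arguments $\le 0$) yield `NA`
  rather than an error, so report tables can print a dash; a group mean
  with any saturated pair is itself `NA`, with the offending pairs listed.
* **Group distances** are arithmetic means over all pairs (the "average
  distance" convention of distance-software report tables).
* **Bootstrap SEs** resample alignment columns (codon columns for dn/ds)
  with replacement; 2000 replicates is the conventional setting, and a
  seed is mandatory so every report is reproducible.

## Synonymous and nonsynonymous rates

`ng_counts()` implements modified Nei–Gojobori counting. Expected
synonymous site counts weight transitions by `kappa` against 1 per
transversion (`kappa = 1` is the unweighted original; mutations to stop
codons count as nonsynonymous). Observed differences are averaged with
equal weights over all minimal mutational pathways between differing
codons, excluding pathways through stop codons (if every pathway is
blocked, all are used — this can only matter for triple differences).
`dnds()` converts the proportions $p_n = N_d/N$ and $p_s = S_d/S$ with the
Jukes–Cantor correction.

The transition/transversion weight the original study used is not
recorded; `kappa` is therefore exposed with default 1, and reproducing
published dn/ds tables may require tuning it. The positive-selection test
builds the 2×2 table `[[round(Nd), round(N−Nd)], [round(Sd), round(S−Sd)]]`
from the (fractional) counts and applies a one-sided Fisher exact test —
directional, because the hypothesis is an excess of nonsynonymous change.
The regional acceleration test is two-sided, since either region could in
principle be faster. Both choices are deliberate: the source analyses
name only "Fisher's exact test".

Display rounding follows the field's table conventions: fold changes are
rounded half-away-from-zero to one decimal (integers from 10 up,
`fold_ratio()`), dn/ds ratios to two decimals in group summaries and one
decimal in pairwise matrices.

## Trees, linearization and dating

`nj_tree()` wraps the classical neighbor-joining algorithm; negative
branch lengths, an occasional NJ artifact, are clamped to zero with the
deficit transferred to the adjacent branch. `nj_bootstrap()` attaches
majority-rule support percentages from column-resampled replicates.
Rooting requires an explicit, monophyletic outgroup; the root bisects the
outgroup edge.

`linearize()` produces a clock-like tree by setting each internal node's
height to the unweighted mean of its leaf-to-node path lengths, clamped to
be non-decreasing root-ward. This is a deliberate approximation of the
two-cluster linearized-tree construction used by clock-dating software:
simpler, deterministic, and exact on ultrametric input. Rate-deviant
lineages are *not* pruned before dating. `date_nodes()` then scales every
node height by `time / height` of one calibration split; per-lineage
datings are just repeated calls with different `calibration()` inputs.
Dating is invariant to multiplying all branch lengths by a constant, and
scales linearly in the calibration age — both properties are tested.

## Domain scanners and Harr plots

`find_wap()` matches an eight-cysteine grammar with configurable
inter-cysteine spacing ranges. The default profile
(6–9, 5–7, 4–6, 3–5, 0, 3–5, 3–4 residues between consecutive cysteines,
with C5–C6 adjacent) is patterned on the canonical WAP four-disulfide-core
signature; the true spacing tolerances of any particular alignment figure
are not machine-readable, so the profile is user-overridable.
`classify_met_rule()` labels aligned WAP peptides by the residue at a
*reference-calibrated* catalytic column (the column is supplied, not
hard-coded) — the label is advisory, because noncoding phylogeny can
overrule it (a known tenrec paralog is Met-positive yet groups with the
paralog clade).

`find_tgs_repeats()` finds maximal tandem runs of exact hexamer frames
within a Hamming distance budget of the `KGQDPV` consensus; no indels are
allowed inside a unit, consistent with "semi-conserved" fixed-length
repeats.

`harr_plot()` marks every pair of window starts whose 40-nt windows agree
at 23 or more positions (both settings adjustable), step 1, forward strand
only, dots indexed by 1-based window start. These conventions are ours;
only the 23/40 stringency itself is standard.

## The simulator: what it emulates and what it does not

`sim_config()` defaults define the study conditions:

* **Region lengths** flank5 300, exon1 90 (signal 60), intron1 400,
  exon2 450 (TGS 300 + WAP 150), intron2 500, exon3 200, flank3 300 —
  a ~2.1-kb gene with a 150-bp WAP coding part, matching the scale of the
  real genes.
* **Base rate** 0.0017 substitutions/site/My for noncoding DNA,
  back-computed from the observed armadillo noncoding divergence
  (JC ≈ 0.054) across a duplication depth of ~15.9 My.
* **Transition bias** `kappa_sim = 2`, a typical mammalian nuclear value.
* **Multipliers** exon2 × 4 (the observed acceleration is ~4.4× by JC),
  exon1 × 0.5 (signal peptides evolve slowly), everything else × 1.
* **omega** signal 0.5, TGS 1, WAP 1 by default; scenario builders set all
  three to 1 so that rate multipliers translate directly into realized
  rates.
* **Family shape** a six-gene pectinate ladder with duplications at 15.9,
  13, 10, 7 and 4 Mya, mimicking a recently expanded paralog family.

Coding regions evolve by codon-aware proposal thinning: proposals are
K2P events; nonsynonymous proposals are accepted with probability
$\min(1,\omega)$ and synonymous ones with $\min(1,1/\omega)$, so the
realized $d_N/d_S$ targets $\omega$ without a full codon rate matrix.
Proposals creating stop codons are resampled, so no emitted coding region
ever contains an internal stop.

Limitations to keep in mind when interpreting green tests: the simulator
generates **no indels** (sequences are born aligned, so the pipeline's
alignment-input contract is met without an aligner), no SINE insertions,
no gene conversion, no rate variation across sites within a region, and
$\omega$-thinning is not a mechanistic codon model. Passing recovery tests
therefore demonstrate estimator correctness under the stated generating
model, not robustness to alignment error or to the full complexity of
real genomic data.

## Numerical and testing choices

* Coordinates are 0-based half-open on the *ungapped* gene sequence; a
  region's alignment columns are the intersection over rows, and a gap
  column inherits the position of the next residue (so interior gap
  columns survive slicing and are handled by complete deletion). How the
  original analyses resolved gap columns at region boundaries is not
  recorded; this convention is documented rather than guessed.
* The pooled `noncoding` reference concatenates flank5, intron1, intron2,
  exon3 and flank3 ("entire gene except coding region"); exon 1 is
  excluded because its signal-peptide part is coding.
* Identical-sequence groups give distance 0 with SE 0; zero-column
  regions give `NA` rows rather than errors.
* Test problem sizes (the package's own choices): estimator-vs-generator
  consistency uses 3000-codon pairs 50 My apart; dating recovery uses 50
  seeded families (median within ±20% of a 15-My truth under a 96.2-My
  calibration); the acceleration test's power (≥80% at a 4× exon-2
  multiplier, α = 0.01) and size (≤3% at 1×) use 100 seeded families each;
  the positive-selection test's size uses 500–1000 neutral pairs of 150
  codons. NG counting is verified exhaustively against an independent
  pathway enumerator over all 61×61 sense-codon pairs, and NJ against all
  15 five-taxon topologies with additive distances.

## Known limitations

* TN93 with empirical pair frequencies can be undefined for degenerate
  base compositions; such pairs propagate `NA`.
* The linearization is leaf-averaging, not a generalized least-squares
  clock; for strongly rate-heterogeneous families the dated ages inherit
  that approximation (the original study's Bayesian datings with fossil
  priors are out of scope here).
* `global_pairwise_align()` is a plain Needleman–Wunsch with linear gap
  penalty intended for cDNA-vs-exon pairing, quadratic in sequence
  length; it is not a general-purpose aligner, and multiple sequence
  alignment is expected as *input*.
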