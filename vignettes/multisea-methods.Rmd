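---
title: "Statistical methods behind multisea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind multisea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multisea)
```

## The problem

A molecule rarely binds a single protein. Relating a query compound (or a
whole ligand set) to protein targets through the chemical similarity of
the targets' known ligands — rather than through protein sequence — is the
core idea of the similarity ensemble approach (SEA). The difficulty is
that the *sum* of pairwise similarities between two ligand sets grows with
set size and is dominated by chance similarity, so the sum itself is
meaningless without a calibrated null model. `multisea` implements that
calibration, the scoring machinery, a k-vote ensemble over models built on
different molecular fingerprints, and the evaluation layer used to compare
them.

## Set-set similarity and its null

Molecules are encoded as binary fingerprints (sets of on-bits); two
fingerprints are compared by the Tanimoto coefficient
$TC = c / (a + b + c)$, with $c$ the shared on-bits and $a$, $b$ the bits
unique to each. Two empty fingerprints are defined to have $TC = 0$:
featureless molecules should not look maximally similar.

The **raw score** of ligand sets $A$ and $B$ at a Tanimoto threshold $TS$
is

$$RS(A, B) = \sum_{i}\sum_{j} TC(A_i, B_j)\,[TC(A_i, B_j) \ge TS],$$

i.e. only pair similarities at or above $TS$ contribute. Under the null —
random sets drawn from a background universe — the moments of $RS$ depend
on the set-size product $s = n_A n_B$ as

$$F_{mean}(s) = \mu s, \qquad F_{sd}(s) = \phi\, s^{\eta},$$

and the standardized score $z = (RS - \mu s) / (\phi s^{\eta})$ follows an
extreme value (Gumbel) distribution when $TS$ is chosen well. The P-value
of a comparison is the Gumbel upper tail

$$P(z) = 1 - e^{x(z)}, \qquad x(z) = -\exp\!\big(-(z\pi/\sqrt{6} +
\gamma)\big), \quad \gamma = 0.577215665.$$

For $z > 28$, $e^{x}$ is within double-precision rounding of $1 + x$ and
the closed form collapses to 0 by cancellation, so the three-term Taylor
expansion $-x - x^2/2 - x^3/6$ is used instead; the two branches agree to
well within $10^{-6}$ relative at the switch. Because even the Taylor
branch underflows near $z \approx 1350$, `p_value_log10()` evaluates the
tail's logarithm directly, which keeps comparisons at the $10^{-80}$ level
(used for target-target networks) well defined. Below $z \approx -2.5$
the P-value saturates to 1 in double precision; this is a representation
limit, not a property of the formula.

## Fitting the background

`fit_background()` implements the calibration protocol:

1. Draw, for each repetition, one pair of disjoint random subsets of the
   background universe for every unordered pair of *distinct* sizes on
   the grid (defaults: 10 to 1000 in steps of 10, giving
   $\binom{100}{2} = 4950$ pairs, repeated 100 times). Same-size pairs
   are excluded — that is the only reading under which the grid yields
   exactly 4950 pairs — and the two subsets never share molecules.
2. Record each pair's raw score at every candidate $TS$ (0.00 to 0.99,
   step 0.01) in a single pass over the nonzero Tanimoto values.
3. At each $TS$, fit $\mu$ by least squares through the origin of the
   per-$s$ group means against $s$, and $(\phi, \eta)$ by ordinary least
   squares of $\log(\text{group sd})$ on $\log s$, excluding zero-spread
   groups. A $TS$ with fewer than two positive-spread groups is unusable
   (at high $TS$ almost all raw scores are exactly zero).
4. Standardize all samples at each usable $TS$ and compute a chi-square
   statistic against the zero-mean unit-variance Gumbel (location
   $-\gamma\sqrt{6}/\pi$, scale $\sqrt{6}/\pi$) with 20 equal-probability
   bins (reduced so the expected count per bin is at least 5). The $TS$
   with the smallest statistic wins; ties break to the lowest $TS$, and
   the full per-$TS$ diagnostics table is kept in the model file.

Samples from all repetitions are pooled before fitting; pooling uses all
the information and the per-$s$ group sizes stay balanced by
construction. Fitted models serialize to JSON (`write_sea_model()`)
including provider, grid, seed and diagnostics, so a model file fully
determines the scoring behaviour.

Two deliberate conventions: the model assumes the fitted laws remain
valid below the smallest fitted $s$ (a singleton query against a
30-ligand set has $s = 30$, below a grid starting at $10 \times 20$);
`compare_sets()` can flag that extrapolation. And significance is
per-comparison with no multiple-testing correction, matching how raw
$P \le 0.05$ / $0.01$ cutoffs are conventionally used with SEA.

## Fingerprint providers

Six 2D representations share one interface (`compute_fingerprints()`):

* **morgan** — circular substructure fingerprint in the ECFP spirit;
  iteratively hashed atom neighbourhoods. The radius defaults to 2 (the
  ECFP4-like convention) and is exposed as a parameter. Bits are kept as
  sparse unfolded on-bit sets so Tanimoto counts are exact.
* **atom_pair** — Carhart-style (type, type, topological distance)
  triples.
* **topological_torsion** — hashed four-atom linear paths.
* **maccs** — the 166-key MACCS set, computed by OpenBabel.
* **pharmacophore_2d** — pairs (and optionally triplets) of
  pharmacophore features with binned topological distances. Point counts
  are restricted to {2} or {2,3} and the distance bins are a
  configuration parameter; half-open bins `[lo, hi)`. Defaults use
  points {2,3} with bins (2,3), (3,4), (4,5), (5,6), (6,7), (7,20) — the
  configuration that trades fuzziness against precision best in our
  reference setting; coarser bins give fuzzier, more promiscuous
  fingerprints.
* **shed** — 10 Shannon-entropy feature-pair descriptors over the four
  pharmacophore families (acceptor, donor, hydrophobe, aromatic); each
  component is $2^{H}$ of the binned distance distribution of one family
  pair ($H$ in bits, 20 distance bins), giving values in [0, 20].
  Compared by $1 - d_{euclid}/(20\sqrt{10})$ rather than Tanimoto.

Structures are parsed with ChemmineR/OpenBabel; canonical SMILES and
molecular weight come from OpenBabel. The internal graph model treats
hydrogens implicitly through a standard valence table and does **not**
model formal charges; pharmacophore typing therefore uses the four
neutral families, and aromaticity is perceived heuristically (ring
systems whose atoms are all sp2-capable) rather than by Hückel counting.
These approximations affect only the chemistry-facing providers — the
statistical machinery is representation-agnostic — but mean that, e.g.,
charged nitrogen donors or non-planar aromatics may be typed
approximately.

## Curation

`standardize_activities()` + `build_ligand_sets()` implement the
preparation workflow: keep the largest organic fragment of each
structure (salts and co-crystallized fragments dropped), reject
molecules above 1000 Da, aggregate replicate activities by their
geometric mean in concentration space (the arithmetic mean on the
pChEMBL scale), apply the activity threshold (pChEMBL 5, 6 or 7; 5 means
10 µM), drop targets with fewer than 5 ligands, and cap targets above
3000 ligands with a diverse subset. Aggregation happens **before**
thresholding, so a molecule with activities straddling the cutoff is
judged by its mean. Identical structures listed under different
identifiers within one target are collapsed by canonical SMILES and
counted in the report. Restricting to single-protein targets is an
upstream concern (an optional `target_type` column filter), since the
package does not ship a target dictionary.

Diverse capping uses max-min (farthest-point) picking on Tanimoto
distance with a seeded random start: a standard, deterministic choice
where the workflow only demands "diverse". Unparseable structures are
counted and skipped, never fatal — bulk curation must not die on row
173,212 of a million-row table.

## Multi-voting ensemble

Different fingerprints capture different aspects of a structure, and
their SEA models largely overlap but each contributes unique true
positives. `ensemble_predict()` therefore treats each model's P-value as
a vote: a pair is significant under a k-vote scheme when at least $k$
models have $P \le \alpha$. "At least k" is the only reading under which
a 3-vote scheme means what it says; ties at $\alpha$ count as votes,
consistent with the $P \le 0.05$ convention. Missing per-model P-values
(e.g. a provider that failed on a molecule) are non-votes. Prediction
sets are nested in $k$ by construction — $k=1$ is the union and $k=5$
the intersection of the single-model positives — so the vote count is a
precision dial: the 5-vote scheme concentrates on high-precision calls,
the 1-vote scheme maximizes coverage.

## Evaluation

Predictions on a labeled pair list are scored as binary classification:
accuracy, precision, sensitivity, specificity and
$F_\beta = (1+\beta^2) P S / (\beta^2 P + S)$. Because public activity
data are incompletely labeled, false positives are systematically
over-counted, so precision-weighted measures ($F_{0.5}$, $F_{0.25}$) are
the headline metrics. All metrics are computed from integer counts;
ratios with zero denominators are reported as `NA`, never as a silent 0.

## The synthetic universe

`generate_universe()` plants target families in a random bit space:
background molecules get independent Bernoulli bits at a configurable
density; each family shares a core bit pattern plus per-molecule noise
bits, so the expected within-family Tanimoto is approximately
$c/(c + 2m)$ for core size $c$ and noise size $m$, and the mean
background similarity is $d/(2-d)$ at density $d$. The generator emits
the same activity-table and fingerprint-sidecar formats as the real
pipeline, plus a labeled test pair list, and is fully deterministic
under its seed.

What it does *not* emulate: real chemical-space topology (fingerprint
bits are independent, real substructure bits are strongly correlated),
activity cliffs, target promiscuity, or assay noise. Passing tests on
synthetic data therefore demonstrate that the statistical machinery is
correct and calibrated — not that any particular fingerprint will rank
targets well on real pharmacology.

## Problem sizes used in the tests

The package defaults keep the full reference protocol (sizes 10–1000
step 10, 100 repetitions, TS grid 0.00–0.99). The test-suite and the
acceptance script exercise the same code paths at sizes chosen for a
desk-scale calibration study: a 512-bit space at density 0.05, 600
background molecules, a 10–100 step 10 size grid with 10–20 repetitions
(900–1800 background samples), 2000 null comparisons for calibration,
and five planted families of 25 members at expected within-family
Tanimoto 0.6. The parameter-recovery check simulates the full protocol
(4950 pair products × 100 repetitions) directly from the fitted laws,
where drawing numbers is cheap; at that sample size the through-origin
mean fit recovers $\mu$ to about 2% even though the sd law dominates
the mean at large $s$.

## Known limitations

* Formal charges and stereochemistry are not modelled; deduplication is
  constitution-level.
* The Morgan, atom-pair, torsion and pharmacophore implementations are
  native to this package: bit sets are self-consistent (fixed hashing,
  deterministic) but not bit-compatible with other toolkits'
  fingerprints of the same name.
* The background fit extrapolates below the smallest fitted size
  product; for singleton queries against small sets this is the
  standard practice but remains an extrapolation.
* P-values are per-comparison; a genome-wide screen should apply its own
  multiplicity control.
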