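---
title: "Inter-protein evolutionary couplings: model, score and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inter-protein evolutionary couplings: model, score and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evcomplexr)
```

This vignette is the package's own account of the method it implements:
the statistical model, the scale-free score, every tunable parameter
with its default and rationale, what the synthetic generator does and
does not emulate, the numerical choices, and the known limitations.

## 1. From paired alignments to a global model

The input is two per-protein multiple sequence alignments and a
gene-location table per family. Within every species, homolog pairs are
matched by genomic proximity under two rules: the coding sequences must
lie on the same genomic contig, and each pair must be the closest
admissible pairing in that species. Matching is *iterative greedy*: the
globally smallest nucleotide distance in the species is taken, both loci
are removed, and the scan repeats. The method description we follow
states the closest-pair requirement but no algorithm; greedy
global-minimum matching is deterministic, one-to-one, and captures the
mutual-nearest intent. Ties are broken lexicographically by
(contig, A start, B start, A accession, B accession) so the matching is
reproducible without a seed. Pairs further apart than `max_nt` (default
10000 nt, strictly-greater excluded) are dropped. We apply this cap per
pair rather than as an outlier rule on the per-alignment distance
distribution, and expose it in the configuration. We deliberately do
*not* force one pair per species: several paralog pairs are kept when
each independently satisfies the rules, since the closest-pair rule
constrains pairings, not counts.

Matched rows are concatenated end-to-end; the A/B `boundary` is the
number of A columns and defines which residue pairs are *inter*-protein.

Two preprocessing steps precede fitting:

* **Gap-column filtering.** Columns with *more than* 80% gaps are
  removed (a column at exactly 80% is kept — the wording is "more
  than"). Column maps and the boundary are updated; the operation is
  idempotent.
* **Identity reweighting.** Each sequence receives weight
  `1 / |{t : identity(s,t) ≥ 0.8}|`; `N_eff = Σ w_s`. Identity is
  counted over the full concatenated length with gaps as ordinary
  symbols — the simplest reading of "80% or more of their residues
  identical" and common practice in direct-coupling analysis; a
  gap-excluding variant would be a straightforward extension but is not
  offered, to keep one well-defined denominator. Weighting runs *after*
  column filtering, and the `L` used in the score below is the
  post-filter length: the model is fitted on exactly those columns, so
  depth per modelled residue is the relevant ratio. Monomer-style
  analyses conventionally cluster at 90%; the threshold is a config
  field.

## 2. Pseudolikelihood maximization

The Potts model places fields `h_i(a)` and couplings `J_ij(a,b)` over
q = 21 states (gap is state 1 by convention, so gauge fixing and
gap-excluding norms can name it). The full likelihood is intractable;
the pseudolikelihood replaces it with the product of per-site
conditional multinomials. We use the *asymmetric* variant: each site's
regression is a convex problem solved independently, after which the two
estimates of each block are symmetrized,
`J_ij ← (J_ij + J_jiᵀ)/2`. The objective per site is the weighted
negative conditional log-likelihood plus
`N_eff (λ_h ‖h_r‖² + λ_J Σ_j ‖J_rj‖²)`, with defaults `λ_h = 0.01` and
`λ_J = 0.01 (L−1)` — the conventions of the pseudolikelihood
direct-coupling literature, which the method we implement cites without
printing values. Both are exposed in the configuration.

Optimization is deterministic by contract: L-BFGS-B from a zero
initialization with projected-gradient tolerance `tol = 1e-4` and
`max_iter = 500` per site. Identical inputs reproduce identical
parameters bit-for-bit; non-convergence produces a warning with the
per-site codes, not an error. `pseudolikelihood()` exposes the full
symmetric objective with its exact analytic gradient, which the test
suite verifies against central finite differences at relative error
below 1e-5.

**Scores.** Each block is moved to the zero-sum gauge (double-centering;
`zero_sum_gauge()` shows the full transformation leaves the conditional
probabilities unchanged) and summarized by the Frobenius norm of its
20×20 non-gap sub-block. The average product correction then subtracts
`mean_i · mean_j / mean_all`. Two conventions matter here:

* APC is applied to the *full* concatenated matrix, not per intra/inter
  block — inter and intra scores must share one scale because the
  reliability ratio below normalizes inter scores by their own minimum
  only; symmetrization precedes APC.
* For coupling matrices, whose diagonal is identically zero, the means
  are taken over off-diagonal entries (`exclude_diagonal = TRUE`, the
  default). With `exclude_diagonal = FALSE` the means run over all
  entries, in which case APC annihilates exactly-rank-one matrices — the
  algebraic identity the tests check. The two conventions differ by a
  factor `(n−1)/n` in the correction term and are both exposed.

Whether the published score includes APC is not stated outright, but
the score model requires couplings "approximately symmetric around a
zero mean", which raw Frobenius norms (all non-negative) are not; APC is
therefore on by default, with a flag.

## 3. The scale-free EVcomplex score

Most residue pairs are not coupled; their corrected scores form an
approximately zero-symmetric background whose width is estimated by
`|min EC_inter|` over the inter block. The raw reliability ratio and the
depth-normalized score are

```
Q_raw(i,j)  = EC_inter(i,j) / |min EC_inter|
score(i,j)  = Q_raw(i,j) / (1 + (N_eff/L)^(-1/2))
```

The ratio is invariant under positive rescaling of all inter scores;
the minimum-attaining pair sits at −1; the score increases towards
`Q_raw` as depth grows. The depth correction is implemented verbatim
with no alternatives: its functional form was chosen empirically by the
method's authors, so offering variants would silently change the
meaning of the 0.8 threshold.

If no inter score is negative the background width is undefined; the
package raises an error with guidance rather than substituting another
width estimator, because silently switching estimators would make
scores incomparable across runs. In practice this occurs only when APC
was skipped.

Thresholds (all configurable, defaults follow the published protocol):
contacts are the pairs with score **≥ 0.8** (boundary inclusive);
subunit pairs classify as *interacting* at ≥ 0.8, *weakly predicted* in
[0.75, 0.8), *rejected* below 0.75. The prose rule says "above 0.8"
while the contact rule is printed "≥ 0.8"; we resolve the boundary as
interacting for internal consistency. The sequence-sufficiency filter
requires `N_eff/L` strictly greater than 0.3. The filter is a *soft*
gate: low-depth alignments are exactly where the normalization earns its
keep, so the pipeline warns and stops unless an explicit override is
given (the CLI `score` subcommand exits non-zero without `--override`).

Species identity for pairing is established from a configurable
header-regex rule (default: UniProt-style `NAME_SPECIES` suffix). The
published protocol does not define a header grammar, so the rule is a
configuration choice rather than a constant.

## 4. Structure evaluation and restraints

Predictions are compared to a structure through an explicit two-column
mapping from alignment positions to author residue numbers — no hidden
sequence alignment to the structure is performed in this version, so the
evaluation cannot silently disagree with the user about numbering.
Distances are minimum heavy-atom distances (hydrogens excluded, model 1
of multi-model files, highest-occupancy altloc — least-surprising
conventions, configurable at the atom-loading step). A predicted pair
within 8 Å is a true positive, `precision = TP/(TP+FP)`, and pairs
unresolved in the crystal are excluded from the ratio rather than
counted as false positives (matching the missing-data shading convention
of the original contact-map figures); reports at 5/8/10/12 Å are
available. Interface residues are those with any atom strictly closer
than 6 Å to the partner chain. Restraint export writes one CNS-dialect
`assign` per contact restraining Cα–Cα to 5.0 Å with −2.0/+2.0 bounds,
and a round-trip parser recovers segids, residues and parameters
exactly.

## 5. The synthetic generator

`planted_complex_model()` builds a ground-truth Potts model: zero
fields, zero couplings except `n_inter` boundary-straddling pairs and
`n_intra` within-block pairs, each assigned a random q×q pattern scaled
to Frobenius norm `strength`. `sample_potts()` draws sequences with a
single-site Gibbs sampler (one chain, default `burn_in = 1000` sweeps,
`thin = 10`), driven by R's RNG so a seed makes runs reproducible.
Exactness is only claimed where enumeration is possible: the tests
compare the sampler to the exact Boltzmann distribution on a two-site,
two-state model and to closed-form single-site marginals.

Defaults for the recovery experiments were chosen once, as the study
conditions, and are not tuned per test: `q = 6` (a reduced alphabet
keeps the per-site regression at ~2000 parameters instead of ~24000;
the production default stays q = 21), block lengths 30 + 25, 12 planted
inter and 10 intra pairs, and `strength = 3` — with q = 6 a norm-3 block
has entries of typical size 0.5, strong enough that planted pairs
dominate the coupling ranking at n = 3000, which is precisely the regime
the recovery experiment is meant to certify. The depth experiment runs
n ∈ {200, 1000, 3000} over three sampling seeds; these sizes let the
full suite (ten PLM fits) complete in a few minutes on one CPU while
spanning the under- to well-determined regimes.

What the generator does *not* emulate: phylogenetic correlation between
sequences (samples are near-independent draws, so `N_eff ≈ N`, whereas
real alignments cluster heavily), alignment errors, gap stretches from
domain architecture, paralog mispairing, or conformational heterogeneity
of the interface. Passing recovery tests therefore certify the
inference machinery — pairing, weighting, fitting, gauge, APC, score —
not performance on real evolutionary data.

## 6. Degenerate inputs and edge rules

* Non-standard residue symbols (B, J, O, U, X, Z), `.` and `*` map to
  the gap state: the q-state model has no slot for ambiguity codes, and
  gap is the least-informative state. Canonicalization is idempotent.
* Reduced alphabets encode any symbol outside their range as gap.
* All-gap-column alignments, empty pair sets, empty inter blocks, and
  empty restraint exports raise errors rather than producing vacuous
  output.
* Gene distance across contigs is undefined (`NA`), never a number;
  nucleotide distance of overlapping or abutting intervals is 0.
* Cross-contig and >10 kb pairings are never emitted, under any tie
  pattern; matching is seed-free.

## 7. Problem sizes in the shipped experiments

The test suite and `scripts/acceptance.R` use: finite-difference
gradient checks at (L = 6, q = 4, N = 50) over all 264 parameters;
recovery at L = 55 concatenated columns with up to n = 3000 sampled
sequences; pairing oracles on up to 4×3 paralogs per species; sampler
calibration at n = 20000 two-site samples. These sizes were chosen so
each experiment is decisive for its claim yet the whole suite runs on a
laptop-class single CPU in minutes.

## 8. Known limitations

* Homomultimeric interfaces are not deconvoluted from intra-protein
  signal; pseudo-homomultimer filtering of candidate pairs is out of
  scope.
* The residue mapping to structures is user-supplied; there is no
  automatic structure-sequence alignment.
* Docking itself (HADDOCK runs, model scoring, iRMSD evaluation) is out
  of scope: the package produces the restraint files a docking protocol
  consumes.
* Upstream homolog search is consumed, not performed; the recommended
  jackhmmer setting is a bit-score inclusion threshold of half the
  monomer sequence length, which keeps evolutionary depth comparable
  across proteins of different lengths.
* The pseudolikelihood is convex per site, but the depth normalization
  is a heuristic: scores slightly below 0.8 are worth inspecting
  alongside independent biological evidence, and thresholds should not
  be read as probabilities.
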