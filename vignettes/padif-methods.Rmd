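---
title: "Per-atom interaction fingerprints: model, scoring and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Per-atom interaction fingerprints: model, scoring and simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(padifr)
```

## The problem

Docking programs are good at generating near-native poses but notoriously
mediocre at ranking them, and conventional scoring functions favour large
molecules that blanket a binding site with contacts. Interaction
fingerprints attack both problems by comparing *which* protein atoms a pose
touches, and how, against experimentally determined reference complexes —
independent of the ligand's chemotype, which is what makes the approach
friendly to scaffold hopping.

`padifr` implements a per-atom-score-contribution fingerprint: instead of a
binary present/absent contact bit per residue, each binding-site atom
carries the eight per-atom interaction-term contributions of the docking
program's empirical scoring function (`padif_terms()`). The fingerprint of
a complex is therefore an N × 8 real matrix, N being the number of cavity
atoms. The raw export mixes sign conventions — the three ChemScore-derived
terms report favourable contributions as positive, the five PLP terms as
negative — so `make_padif()` negates the first three columns, after which
**negative always means favourable**, zero means "no interaction", and
positive means repulsive. The sign map is its own inverse, which the test
suite exercises.

## Merging reference complexes

Given fingerprints of several reference complexes of the same protein (all
expressed over one cavity-atom ordering; see below for renumbering),
`merge_references()` builds a consensus:

* **median fingerprint** — per element, the median of the *strictly
  negative* reference values only. Repulsive or absent values never enter;
  if no reference is favourable at an element the median is 0. With an even
  number of favourable values the median is the mean of the central pair
  (the standard convention; nothing in the method depends on it, because
  scoring consumes signs and weights only).
* **weighting matrix** — per element, the fraction of references in which
  the element is favourable. Favourable in four of ten references ⇒ weight
  0.4. The denominator is always the *total* reference count, including
  references that are zero or repulsive there.

The weighting matrix is a frequency-based importance proxy: conserved
interactions seen in every crystal structure dominate the score, one-off
contacts barely matter. The median strengths are stored and serialized but
deliberately unused in scoring; using magnitudes as well is an obvious
extension that this package, like the published scheme, leaves aside.

## Scoring a pose

`score_pose()` compares a pose fingerprint with the merged reference. With
R the number of favourable reference elements and P the number of
favourable pose elements:

* `O_max = min(P / R, 1)` — the best overlap achievable given how many
  favourable contacts the pose makes at all;
* per reference element, the element score is `+w` if the pose is
  favourable there, `0` if silent, `−w` if repulsive;
* `O_real = |P ∩ R| / R`, `O_rel = O_real / O_max`;
* `S_tot = ΣS − (1 − O_rel)·|ΣS|`.

The relative-overlap penalty is the small-molecule fairness device: a
fragment whose three favourable contacts all sit inside the reference
pattern has `O_rel = 1` and keeps its full raw score, while a greasy
molecule that smears favourable contacts everywhere dilutes its own score.
Two properties follow and are asserted as invariants: `S_tot ≤ ΣS` always,
and the score depends only on the signs of pose values and the reference
weights, never on pose magnitudes.

Degenerate cases are pinned down explicitly:

* **R = 0** (a reference with no favourable element) leaves the score
  undefined; `score_pose()` refuses with an error rather than returning a
  conventional value, since such a reference carries no information.
* **P = 0** (an interaction-free pose) makes `O_rel` a 0/0. We set
  `O_rel := 0`, so `S_tot = 2·ΣS ≤ 0` and empty poses sink to the bottom of
  any ranking. This convention is ours — the published formulas are silent —
  and is chosen because an empty pose is the worst possible match for a
  non-empty reference.

`combined_rank()` splices a conventional docking ranking and the
fingerprint ranking: the best `ceiling(top_fraction · K)` poses by
conventional score (default 3%) head the list in conventional order, the
rest follow in fingerprint order. `ceiling` guarantees the head block is
non-empty for small K; ordering the head by the conventional score is the
natural choice since that score defines the block. Ties anywhere are broken
by pose id in C-locale lexicographic order, so every ranking is
reproducible bit for bit.

## Atom identity and renumbering

Fingerprint element (m, n) must mean the same physical atom in every table,
but atom serial numbers usually differ between crystal structures of the
same protein. Atom identity here is the quadruple (chain, residue number,
insertion code, atom name); `build_atom_map()` matches reference cavity
atoms to the docking structure's cavity by that key and reports what it
cannot match, and `renumber_table()` rewrites a reference table onto the
docking cavity's row order. A target atom with no mapped counterpart gets
an all-zero row — zero being exactly the fingerprint's "no interaction
observed" value — rather than a missing value that would poison the merge.

The on-disk formats are this package's own small TSV dialects (see
`?read_atom_score_table`); importers for any docking program's native
rescore files are future adapters behind the same types.

## Screening metrics

`roc_auc()` is the midrank Mann–Whitney estimator: the probability a random
active outranks a random decoy, ties counting one half — equivalent to the
trapezoidal area under the ROC curve and invariant under monotone score
transforms. `enrichment_factor()` is `(a_top/n_top)/(A/K)` with
`n_top = ceiling(fraction · K)`, the same ceiling convention as the
combined ranking, so EF at fraction 1 is exactly 1 and `EF_1%`/`EF_3%`
always count at least one entry.

## What the synthetic generator emulates — and what it does not

Without the docking program and curated benchmark sets, the statistical
situation the method lives in is simulated. `simulation_config()` fixes the
study conditions:

* a 30-atom cavity (240 fingerprint elements) with a **true pattern** of 20
  favourable elements, drawn from the seven terms that can host favourable
  contributions (the repulsive term is, by construction, never favourable);
* 10 reference complexes, each showing a given true element with
  probability 0.7 — key conserved contacts present in most but not all
  structures;
* favourable magnitudes half-normal with scale 2 score units (magnitudes
  only exercise I/O and sign handling; the score ignores them);
* spurious repulsive contacts at 2% per element, emulating minor clashes;
* 50 actives and 50 decoys. Every pose makes as many favourable contacts as
  the pattern has elements: an active realizes each pattern slot at its
  true element with probability 0.8 and at a uniformly random site element
  otherwise; a decoy draws all slots uniformly. This keeps the *number* of
  contacts identical across classes — so separation can only come from
  *where* the contacts are, which is the property the fingerprint claims to
  measure — and makes `active_overlap = 0` collapse exactly onto the decoy
  distribution (AUC ≈ 0.5), while `active_overlap = 1` with no noise
  recovers `S_tot = Σw` for every active.

Raw tables are emitted in the exporter's native mixed-sign convention so
the normalization step is exercised end to end. All sampling runs in a
private RNG stream derived from the config seed (references, poses and
pattern each on their own offset), leaving the caller's RNG state
untouched; identical configs give byte-identical files on any platform.

What the generator does **not** model: 3D geometry, pose clustering and
RMSD structure among poses, correlated terms on neighbouring atoms,
realistic score magnitudes, protein flexibility, or the property biases of
real decoy sets. Green simulation tests therefore demonstrate the
correctness and the intended statistical behaviour of the machinery, not
virtual-screening performance on real targets.

## Numerical choices

* Favourability is strict negativity everywhere; exact zero is "no
  interaction". Scores written to disk use the shortest decimal form that
  re-reads to the identical double, so write→read round-trips are exact and
  repeated runs are byte-identical.
* Test oracles compare the vectorized scorer against an element-by-element
  brute-force evaluator at 1e-12; the AUC against an O(n²) pairwise count
  and an external ROC library.
* Problem sizes in the test suite (fingerprints up to N = 6 for oracle
  comparisons, 500-seed Monte-Carlo for the weight-recovery check, 100
  simulated screens for separability) were chosen as the smallest sizes at
  which the binomial and AUC checks have comfortable statistical power.

## Limitations

The package scores fingerprints; it does not dock, prepare structures, or
parse any docking program's native output. Reference strength magnitudes
are carried but unused. The combined ranking assumes higher-is-better for
both inputs. AUC/EF come without confidence intervals — compute those over
seeds, as the simulation tests do.
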