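---
title: "Pairwise interaction prediction with PoSMNA descriptors: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pairwise interaction prediction with PoSMNA descriptors: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

When two drugs are taken together, one can slow down or speed up the other's
biotransformation. Most such pharmacokinetic interactions run through a
handful of cytochrome P450 isoforms — CYP1A2, CYP2B6, CYP2C19, CYP2C8,
CYP2C9, CYP2D6 and CYP3A4 — and knowing *which* isoform mediates a potential
interaction is one of the questions regulators expect to be answered during
drug development. `posmna` models this question directly at the level of the
**pair**: the two structures are treated as a single entity, without deciding
which compound is the "victim" and which the "precipitant". That choice has a
practical payoff — the method needs nothing but the two structural formulas,
so it applies to virtual, not-yet-synthesized compounds — and it dictates
most of the design below: pair keys are unordered, pair descriptors are
symmetric, and no role-specific feature ever enters the model.

## MNA descriptors and the pair product

A molecule is reduced to a hydrogen-complete colored graph: element symbol
and a binary ring flag per atom, adjacency, and nothing else. Bond orders,
charges and stereochemistry are parsed (they matter for hydrogen completion)
but are deliberately absent from the descriptor alphabet.

The Multilevel Neighborhoods of Atoms (MNA) descriptor of an atom is a
canonical string defined recursively:

```
D0(a) = label(a)
Dk(a) = label(a) "(" sorted concatenation of Dk-1 over all neighbors ")"
```

with `label(a)` the element symbol, prefixed by `-` when the atom lies on no
cycle. Hydrogens appear as neighbors (`-H(...)` substrings) but only heavy
atoms contribute centers. A molecule's descriptor set is the *set* of its
heavy-atom strings at level 2 (MNA/2) — multiplicity is discarded, because
the model's semantics are presence/absence.

Two design points deserve emphasis:

* **Ring membership means "on any cycle".** The `-` mark is binary, so the
  implementation asks only whether an atom lies on at least one cycle (an
  atom does iff it has an incident non-bridge edge). No smallest-set-of-
  smallest-rings convention is involved, and atoms on bridges *between* two
  ring systems — e.g. the benzylic CH of warfarin — are correctly acyclic.
* **The collation is not ASCII.** All sorting uses a fixed character order
  `(` < `)` < letters (ASCII order) < `-`: the acyclic mark ranks *after*
  every letter. This is the unique order consistent with the reference
  orderings this implementation reproduces, which place `C(CCC)` before
  `C(CC-H)` and run from a `C(...)` pair string down to a `-O(...)` one;
  plain ASCII would do neither. The comparator is locale-independent (it
  remaps onto contiguous bytes and radix-sorts), so descriptor files are
  byte-stable across platforms.

The pair descriptor set (PoSMNA) is the direct product of the two molecules'
MNA/2 sets: every cross pair `x y`, with the two components ordered by the
collation so that the product is symmetric in the molecules. Self-products
`x x` are kept when both molecules share a descriptor. The product of an
18-descriptor molecule (warfarin) and a 15-descriptor one (naproxen)
therefore has at most 270 pair strings, fewer when cross strings coincide.

```{r example}
library(posmna)
w <- parse_structure("CC(=O)CC(c1ccccc1)c1c(O)c2ccccc2oc1=O", id = "warfarin")
n <- parse_structure("COc1ccc2cc(C(C)C(=O)O)ccc2c1", id = "naproxen")
head(posmna_set(mna_set(w), mna_set(n)))
```

## The naive Bayes model

Training data is a table of unordered pairs, each labeled with one or more
of the seven isoforms. Per activity `a` the fitted model keeps one-vs-rest
counts — `N` pairs total, `N_a` labeled `a`, `n_d` pairs containing
descriptor `d`, and `n_ad` containing `d` and labeled `a` — from which the
smoothed conditional probability is

```
P(a|d) = (n_ad + k * p_a) / (n_d + k),   p_a = N_a / N
```

with `k = 1` by default: one pseudo-observation distributed as the prior.
Negatives are simply pairs not carrying the label; the training schema has
no explicit non-interacting pairs, and this one-vs-rest convention is a
modeling assumption, not data. A descriptor unseen in training falls back to
`p_a`, so every activity is scored over the *same* full descriptor set of
the pair.

The raw score of a pair with descriptor set `D` is the arcsine mean

```
S_a(D) = mean over d in D of arcsin(2 * P(a|d) - 1)
```

bounded in `[-pi/2, pi/2]`. The particular combiner matters less than it
looks: the calibrated quantities below depend on scores only through ranks,
so any strictly increasing transform of the per-descriptor estimates — log
odds, probability mean, arcsine — yields identical `Pa`, `Pi` and IAP. The
test suite asserts this rank invariance; the arcsine form is kept for its
symmetry and bounded range, and it is isolated behind one internal function
should a different combiner ever be wanted.

### Calibration: Pa, Pi, and the LOO distributions

`Pa` ("to be active") and `Pi` ("to be inactive") are tie-adjusted empirical
ranks of a score against the leave-one-out score distributions of the
training actives and inactives of that activity:

```
Pa(s) = [#{active LOO scores < s} + 1/2 #{= s}] / N_a
Pi(s) = [#{inactive LOO scores > s} + 1/2 #{= s}] / (N - N_a)
```

Activities are reported ranked by `dP = Pa - Pi`; a positive `dP` reads as a
predicted interaction at that isoform, and `dP > 0` is the default
qualitative YES threshold.

The LOO scores are computed *analytically*: scoring training pair `i` with
`n_d - 1`, `n_ad - [i labeled a]`, and the prior recomputed on `N - 1` pairs
is algebraically identical to retraining without the pair, and the suite
verifies the identity against brute-force refits to 1e-12. Descriptors
private to the left-out pair become unseen and take the deflated prior.

This rank construction makes one advertised property a theorem rather than
an approximation: the IAP of an activity — the probability that a random
active outscores a random inactive, ties at half weight, i.e. exactly the
Mann-Whitney AUC ROC — equals the mean of `1 - Pi` over the active LOO
scores. The half-tie convention is used consistently everywhere (score
ranks, `Pa`/`Pi`, IAP), which also gives `iap(A, B) + iap(B, A) = 1`
identically.

### Two honest caveats

* **Pair-level LOO leaks molecules.** The LOO unit is the pair; a molecule
  appearing in many pairs is never fully held out. Accuracies estimated this
  way are optimistic about generalization to unseen chemistry.
* **LOO calibration is pessimistic for tiny classes.** Removing one of very
  few positives costs its descriptors most of their support, so active LOO
  scores of a class with a handful of positives sit systematically below
  the scores fresh genuine pairs would get. Under label permutation this
  shows up as per-class IAP noticeably *below* 0.5 for classes with two or
  three positives — chance-level behavior is only approached as `N_a`
  grows. This is a property of leave-one-out count exclusion itself, not of
  the scoring rule.

## The synthetic data generator

The real training material for this problem — a few thousand curated
interacting pairs — is not redistributable, so the package ships a seeded
generator whose output exercises every interface and whose planted structure
is recoverable by construction.

* **Chemistry.** Seven decorated heteroaromatic scaffold families (pyridine,
  furan, thiophene, N-ethylpyrrole, pyridazine, isoxazole,
  N-methylimidazole), one per isoform, plus warfarin and naproxen pinned
  verbatim. Substituents (methyl, amino, hydroxyl, halogens) are placed at
  enumerated ring positions, so every generated SMILES is chemically valid
  without a repair pass.
* **Planted rules.** Each family's rule feature is an MNA/2 descriptor
  present in every member and absent outside the family. Substitution sites
  sit at graph distance ≥ 2 from a designated core atom, whose two-shell
  neighborhood — hence its descriptor — never changes under decoration; the
  scaffolds were chosen so these core descriptors are mutually disjoint
  (that is why the pyrrole is N-ethyl and the six-membered diazine is
  pyridazine: the obvious alternatives collide with another family's core).
  Rules are *derived from the generated library at run time* and the
  generator errors if a rule is unsatisfiable.
* **Imbalance.** Class sizes follow the documented composition of curated
  CYP interaction data — the dominant isoform (CYP3A4) carries ~69% of
  pairs — via largest-remainder proportional allocation with a floor of one
  pair per class.
* **Density.** The default library (80 molecules) against the default table
  (200 pairs) gives ~5 pairs per molecule. Curated interaction sets are
  dense in exactly this way — a few hundred drugs generate thousands of
  pairs — and density matters: with a sparse library, held-out pairs carry
  many descriptor products absent from training, and their scores collapse
  toward the prior fallback.
* **Noise.** Labels are flipped with probability `eps` (default 0.1) and
  reassigned to another class with probability proportional to class
  prevalence. Prevalence weighting keeps the class marginals — themselves a
  study condition — intact in expectation and keeps the effective
  contamination of every class near `eps`; uniform reassignment would make
  the rarest class (two genuine pairs) mostly mislabeled at `eps = 0.1`. A
  flip that would leave a class with no correctly labeled pair is
  suppressed, so generated tables are always fittable.

What the generator does *not* emulate: real chemical diversity within an
activity class, pharmacophores shared between classes, multi-label pairs,
and any genuine pharmacology. Passing the planted-rule tests therefore shows
that the descriptor algebra, the estimator and the calibration machinery are
correct and recoverable under controlled conditions — it does not certify
accuracy on real interaction data, which this package cannot measure without
the non-redistributable training set.

A consequence worth stating plainly: at the default scale, noisy planted
rules are *not* recovered near-perfectly, and the package does not pretend
otherwise. One mislabeled dominant-family pair landing in a class with few
positives plants the dominant family's descriptors in that class's counts;
every fresh dominant-family pair then sees an inflated `dP` there, while its
own class's `Pa` is — correctly — roughly uniform. At 200 pairs with ~69%
dominance, flips leaving the dominant class *must* land in small classes, so
top-rank recovery under 10% label noise plateaus well below the noise-free
regime (which is recovered essentially perfectly). The acceptance script
reports both regimes.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `level` | 2 | MNA neighborhood depth; 2 is the modeling standard and the depth at which the planted-rule construction is analyzed |
| `k` | 1.0 | additive smoothing, in pseudo-pairs; 0 gives raw frequencies |
| `threshold` | 0 | `dP` cutoff for a qualitative YES |
| `eps` | 0.1 | generator label-flip rate |
| `n` (library) | 80 | molecules; ~5 pairs per molecule at the default table size |
| `n_pairs` | 200 | labeled pairs; dominant class ~69% of labels |

## Numerical and degenerate-input choices

* `arcsin` arguments are clamped to `[-1, 1]` against floating rounding.
* Model JSON and report TSVs serialize numbers at 17 significant digits;
  save-load-predict is bit-identical and the writers carry no timestamps, so
  identical inputs and seed give identical bytes.
* Empty descriptor sets, empty molecules, activities without both positives
  and negatives, unsatisfiable rules, multi-component structures (without
  `strip_salts`), and tied largest fragments are all structured errors, not
  silent repairs.
* A class reduced to zero positives during LOO takes the deflated prior
  `p_a = 0` (score `-pi/2`); single-positive classes are fittable but their
  own LOO IAP is degenerate, which the validation report shows honestly.
* Test-suite problem sizes — 30-pair tables for brute-force LOO identity,
  50 random graphs for the descriptor oracle, 200-pair tables for the
  study-scale checks — were chosen as the smallest sizes at which each
  property is non-trivially exercised.

## Limitations

The numbers produced here are not comparable to any proprietary
implementation of the same ideas: the open descriptions fix the
descriptor grammar and the `Pa`/`Pi`/IAP semantics but not the exact
estimator internals, and the training data differ entirely. What this
package guarantees is internal: a documented, locale-stable descriptor
algebra; an estimator whose LOO calibration is exactly self-consistent; and
a generator whose planted structure makes every claim in the test suite
checkable from first principles.
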