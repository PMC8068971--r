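# posmna

Pairwise drug–drug interaction (DDI) prediction from structure alone.

Most pharmacokinetic drug–drug interactions happen at the metabolism level,
mediated by a small set of cytochrome P450 isoforms (CYP1A2, CYP2B6,
CYP2C19, CYP2C8, CYP2C9, CYP2D6, CYP3A4). `posmna` predicts, for an
**unordered pair** of small molecules, which of these isoforms is likely to
mediate an interaction — using only the two structural formulas, so it works
for virtual and not-yet-synthesized compounds, and without deciding which
drug is the "object" and which the "precipitant". It is aimed at
cheminformaticians and DMPK modelers who want an interpretable, count-based
baseline with exactly self-consistent validation.

## Method

Each molecule is reduced to a hydrogen-complete graph colored by element
symbol and a binary ring flag, and described by its set of canonical MNA/2
(Multilevel Neighborhoods of Atoms, level 2) strings, one per heavy atom:

    D0(a) = label(a)            label = element, '-'-prefixed when acyclic
    Dk(a) = label(a) "(" collation-sorted Dk-1 of all neighbors ")"

A pair of substances is described by the direct product of the two MNA/2
sets (PoSMNA descriptors): every cross string `x y`, symmetrized under a
fixed collation in which `(` < `)` < letters < `-`.

A naive Bayes model keeps one-vs-rest pair counts per isoform *a* and scores
a pair with descriptor set *D* by

    P(a|d) = (n_ad + k·p_a) / (n_d + k),     p_a = N_a/N,  k = 1
    S_a(D) = mean_{d∈D} arcsin(2·P(a|d) − 1)

Scores are calibrated into `Pa` ("to be active") and `Pi` ("to be inactive")
as tie-adjusted ranks against the leave-one-out score distributions of the
training actives and inactives; isoforms are reported ranked by
`ΔP = Pa − Pi`, with `ΔP > 0` read as a predicted interaction. LOO scores
are computed analytically by count exclusion (provably equal to retraining
without the pair), and accuracy is summarized per isoform by IAP — the
probability that a random active outscores a random inactive, numerically
the AUC ROC — which under this construction *exactly* equals the mean of
`1 − Pi` over active LOO scores.

Because the curated training pairs such a model is normally built from are
not redistributable, the package includes a seeded synthetic-data generator:
seven decorated heteroaromatic scaffold families (one per isoform, warfarin
and naproxen pinned verbatim), planted family-private descriptor rules,
realistic class imbalance (dominant isoform ~69% of pairs) and
prevalence-weighted label noise. See `vignettes/posmna-methods.Rmd` for the
full model and generator design.

## Worked example

```r
library(posmna)

lib  <- synth_library(seed = 1, n = 80)          # synthetic molecule library
mols <- structure(lapply(seq_len(nrow(lib)), function(i)
  parse_structure(lib$smiles[i], id = lib$id[i])), names = lib$id)
tab  <- synth_pair_table(seed = 2, lib, n_pairs = 200, eps = 0.1)

model <- ddi_fit(tab$pairs, mols)
summary(model)
#>  activity n_active n_inactive   iap
#>    CYP1A2       15        185 0.834
#>    CYP2B6        4        196 0.622
#>   CYP2C19        6        194 0.998
#>    CYP2C8        7        193 0.723
#>    CYP2C9       24        176 0.693
#>    CYP2D6       20        180 0.824
#>    CYP3A4      124         76 0.853
#> Average 0.793
```

Each row is one isoform's leave-one-out IAP on the 200 synthetic training
pairs (class sizes shown), and the final line is the unweighted mean — the
layout of a cross-validation accuracy report. On noise-free tables
(`eps = 0`) every planted class separates at IAP 1; at 10% label noise the
small classes degrade first, which is expected rank-calibration behavior at
a handful of positives.

```r
pred <- predict(model, c("warfarin", "naproxen"), molecules = mols)
pred
#>            pair_id activity      S    Pa    Pi     dP
#>  warfarin+naproxen   CYP2B6 -1.288 0.500 0.077  0.423
#>  warfarin+naproxen   CYP2C9 -0.866 0.417 0.080  0.337
#>  warfarin+naproxen   CYP2C8 -1.196 0.286 0.052  0.234
#>  warfarin+naproxen   CYP1A2 -1.000 0.267 0.059  0.207
#>  warfarin+naproxen   CYP2D6 -0.930 0.250 0.067  0.183
#>  warfarin+naproxen  CYP2C19 -1.224 0.000 0.005 -0.005
#>  warfarin+naproxen   CYP3A4  0.233 0.040 0.250 -0.210
ddi_classify(pred)
#> [1] "CYP2B6" "CYP2C9" "CYP2C8" "CYP1A2" "CYP2D6"
```

Seven rows, one per isoform, ranked by `ΔP = Pa − Pi`; positive `ΔP` rows
are the qualitative "YES" calls at the default threshold 0. (These
particular numbers come from a model trained on *synthetic* pairs, so the
ranking reflects the planted structure, not warfarin–naproxen pharmacology.)
The descriptor layer itself is checked against literature reference strings:
`posmna_set(mna_set(w), mna_set(n))` for warfarin and naproxen contains
`"C(C(CCC)C(CC-H)C(CC-H)) C(C(CCC)C(CC-H)O(CC))"` and
`"-O(-C(-C-C-O)) -O(-C(-C-O-O))"`, in that collation order.

A command-line wrapper covers the same pipeline
(`exec/posmna synth | descriptors | train | predict | validate`), with
byte-deterministic outputs under a fixed seed.

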