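---
title: "nanoRF: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{nanoRF: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanoRF)
```

## Scope

nanoRF scores the co-fractionation of every protein detected in a
multi-knockout SILAC chromosome-proteomics experiment with a target protein
complex, using a Random Forest trained on a very small positive set. This
vignette documents the statistical model, the parameters that matter, the
numerical conventions, and the design decisions that were genuinely open —
together with what the synthetic-data validation does and does not
demonstrate.

## From SILAC ratios to dependence profiles

The input is a protein-group table with one heavy/light ratio column per
experiment, plus a design table assigning each experiment a knockout
condition, replicate index, and label orientation. Orientation is resolved at
import so every stored ratio means knockout/wild-type; a ratio of 0.08 reads
"8% of the wild-type level remains on knockout chromosomes".

Ratio data are multiplicative, so replicates are averaged on the log2 scale:

$$D_{ic} = \frac{1}{|R_c|} \sum_{r \in R_c} \log_2 x_{ir},$$

the log of the geometric mean of the replicate ratios. `residual_percent()`
maps back to the percentage scale, $100 \cdot 2^{D}$. Negative dependence
means depletion from knockout chromosomes, i.e. the protein requires the
knocked-out factor for chromosomal association. An arithmetic mean of raw
ratios was the alternative; we chose geometric averaging because ratio noise
is approximately log-normal and because it makes the replicate average
consistent with the log-scale plots and the residual-percent readout used
throughout.

Two optional preprocessing steps:

* **Reference normalization** (`normalize_to_reference()`): knockouts with
  fragile chromosomes yield less material overall, inflating apparent
  depletion of everything. Dividing each experiment by an invariant reference
  protein — canonically histone H4 — removes this per-experiment yield
  factor. The reference's own ratios are set to exactly 1 rather than
  computed as $x/x$, so no floating-point residue leaks into downstream
  statistics.
* **Median imputation** (`impute_missing()`): the classifier needs a complete
  matrix, and each missing cell is filled with the median of its condition's
  present values. The operation is idempotent and never alters a present
  cell. A column with no present values is an error rather than a guess.

Per-condition volcano tables use a plain two-sided one-sample t-test of the
replicate log2 ratios against 0, with Benjamini–Hochberg adjustment across
proteins. With 2–3 replicates a moderated (shrinkage) variance would change
individual p-values; we implement the plain test and expose the replicate
count so users can judge the support behind each p-value. Zero-variance
replicate sets return a missing p-value — the t statistic is undefined there,
and reporting 0 or 1 would be an invention.

## The nanoRF score

For a target complex we grow `n_trees` classification trees (default 1000)
on the labeled rows only: the complex's known members versus a shared
negative set, typically curated cytoplasmic/ribosomal contaminants. Class
imbalance is handled by inverse-frequency class weights rather than
down-sampling, because positives can number under 10 and discarding
negatives would waste most of the training signal. `features_per_split`
defaults to the usual $\lfloor\sqrt{p}\rfloor$ rule over the condition
columns.

Scores are vote fractions in $[0, 1]$, with one crucial asymmetry:

* an **unlabeled** protein is scored by all trees;
* a **labeled** protein is scored only by the trees for which it was
  out-of-bag (the *adjusted RF score*).

Without the adjustment, training members would be scored by trees that saw
them during fitting and would pile up at 1.0, making them incomparable with
candidates on the same axis. The out-of-bag vote is the standard unbiased
estimate for bagged ensembles and is the package's interpretation of score
adjustment; it is a design decision, not a mathematical necessity. A labeled
protein that was never out-of-bag (only plausible at very small `n_trees`)
falls back to the full-forest vote with a warning and is recorded in the
result's `oob_fallback` field.

Determinism: rows are canonically sorted by `protein_id` before fitting, and
the forest is seeded from the configuration, so results depend only on
profile content, training set, and seed — never on input file order.

## Quality metrics and threshold selection

Fractionation quality is computed over the labeled proteins' adjusted scores
only (candidates have no ground truth):

* **AUC** in the Mann–Whitney form — the probability that a random positive
  outscores a random negative, ties counted ½. This equals the trapezoidal
  area under the ROC step curve and is invariant under monotone transforms of
  the scores.
* **MCC** at a threshold, prediction rule `score > t`. When any factor of the
  denominator is zero (all predictions on one side), MCC is defined as 0.
* **Threshold selection**: MCC is step-constant between observed scores, so
  scanning the midpoints of consecutive distinct scores plus the sentinels 0
  and 1 finds an exact optimum. Ties are broken toward the smallest
  threshold, which is the more inclusive calling rule for candidate
  nomination and makes the selection deterministic.

These metric primitives are implemented directly from their definitions so
that the degenerate-case and tie conventions above are explicit; the test
suite cross-checks them against brute-force pair/threshold enumeration and an
independent ROC implementation.

## Multi-nanoRF, branches, and candidates

`run_multi()` runs one independent fractionation per training set, seeding
column $k$ with `base_seed + k` so forests are independent yet the whole
matrix is reproducible. Per-complex AUC/MCC are retained: a target whose
training set does not separate from the background (poor AUC) should be
interpreted with caution or excluded, and the matrix keeps that evidence
attached.

The proteins × complexes score matrix is clustered with agglomerative
hierarchical clustering. Defaults are Euclidean distance and Ward linkage —
the conventional pairing for heat-map dendrograms of bounded score profiles —
with correlation distance and average/complete linkage available. Clustering
uses raw scores rather than threshold-binarized calls: binarization discards
the margin information that distinguishes a confident co-fractionation from a
borderline one. The tree is cut to a user-chosen number of branches; the
right number is data-specific (it depends on how many complexes were
targeted and how they overlap), so the package deliberately has no default.
Branch indices are renumbered along dendrogram leaf order, which makes branch
blocks contiguous in exported heat-map tables and the numbering reproducible.

Candidates for a complex are the unlabeled proteins sharing a branch with at
least half of the complex's training positives, ranked by their score in that
complex's column, training members excluded. "At least half" tolerates one or
two training members straying into a neighboring branch without diluting the
candidate pool across the whole tree.

## The simulator: what it emulates, and what it does not

`simulate_dataset()` generates the study conditions the pipeline targets:
several knockout conditions with 2–3 replicates, planted complexes whose
members co-deplete to a residual fraction in their cognate knockouts, a large
hitchhiker background, log-normal measurement noise, and missing values.
`default_paper_like_config()` fixes the panel emulated throughout validation:
5,058 proteins; conditions SMC2, CAP-H, CAP-D3 (2 replicates each), Scc1 (3),
SMC5 (2) — 11 experiments; planted complexes condensin I (residual 0.25 in
SMC2 and CAP-H knockouts), condensin II (0.30 in SMC2 and CAP-D3), cohesin
(0.20 in Scc1, within the 15–27% range typical of core cohesin subunits),
SMC5/6 (0.08 in SMC5), and a CPC-like complex (0.35, co-depleting with
condensin I). Member noise defaults to 0.3 log2 units and hitchhiker noise to
0.5 — contaminant ratios in chromosome preparations are empirically more
dispersed than those of structural proteins — with 10% missingness, uniform
at random by default. An optional low-abundance-biased missingness mode
doubles the dropout weight per log2 unit of depletion, because real
missingness is intensity-dependent; the default stays uniform since only the
imputation rule, not the missingness mechanism, is specified by the method.

What the simulator does **not** model: peptide-level quantification and
razor-peptide ambiguity, correlated noise between replicates processed
together, partial complex membership and substoichiometric subunits,
abundance-dependent ratio compression, and contaminants whose levels respond
to the knockouts. Passing the planted-recovery tests therefore demonstrates
that the pipeline's inference machinery is correct and well-calibrated under
its own model — not that real chromosome proteomics data will separate this
cleanly. On real data, fractionation quality must be judged per complex from
the reported AUC/MCC.

## Validation problem sizes

The test suite validates metric primitives against brute-force enumeration on
1,000 random labeled score sets; imputation properties on 100 random masked
matrices; exact dependence recovery on noise-free simulations; planted-complex
recovery on the full 5,058-protein configuration over 10 seeds (member noise
0.3, 40% of each complex withheld, 500 trees), requiring mean AUC ≥ 0.95 and
withheld-member recall ≥ 0.8; and cross-complex independence on 600-protein
simulations over 20 seeds with three disjointly planted complexes, requiring
members of each complex to stay below the other complexes' MCC-optimal
thresholds in ≥ 95% of seeds. These sizes were chosen so the whole suite
completes in well under an hour on a single core while keeping the
study-scale configuration intact where it matters.

## Known limitations

* Training sets below ~4 positives make the out-of-bag estimate noisy; the
  package enforces only the hard minimum of 2 and reports quality metrics so
  the user can judge.
* The negative set anchors what "background" means; a biased negative set
  biases every score. When no curated list is available, sampling unlabeled
  proteins is a documented fallback, not a recommendation.
* Thresholds maximize MCC on the training labels and will be optimistic for
  candidate calling when training sets are tiny.
* Branch membership depends on which complexes were targeted; adding or
  removing a nanoRF column can re-draw branch boundaries.
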