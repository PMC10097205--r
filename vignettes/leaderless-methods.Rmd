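---
title: "Methods: database scoring, balanced forests and FPR calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: database scoring, balanced forests and FPR calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Leaderless secretory proteins (LSPs) reach the plant cell surface without
the N-terminal signal peptide that routes classical secretory proteins
through the ER–Golgi pathway. Because almost no plant LSPs are
experimentally verified, a classifier cannot be trained on confirmed
positives. This package instead builds training data from *putative* LSPs:
proteins observed in cell-wall/secretome proteomics that lack any
classical secretory feature, ranked by how much company they keep with
known secreted proteins. Two classifier families are then trained: one on
the putative LSPs themselves (the LSPpred schemes) and one that
re-creates the "common features" hypothesis — classically secreted
proteins with their signal peptides computationally removed — in a
plant-specific setting (the SPLpred schemes).

# Gene classification

Input is a per-isoform annotation table (signal peptide with its cleavage
position, transmembrane-domain count, GPI-anchor flag, observation flag).
Classification is per gene:

1. Isoforms are compared on the classifying features (SP or GPI). Genes
   whose isoforms disagree become `SECRETORY_ISOFORM` and leave the
   analysis — their products cannot be confidently assigned.
2. Genes whose only secretory feature is one or more TMDs become
   `TM_ONLY` and are likewise excluded: membrane anchoring alone is not
   evidence of secretion in either direction.
3. The rest split on features × observation: `SEC` (features, observed),
   `SPT` (features, unobserved — "theoretical" secretory proteins),
   `UNCLASSIFIED` (observed without features — the LSP candidates) and
   `NONSEC` (neither).

A gene counts as observed when any isoform is observed; observation lists
(gene ids) can be merged into the per-isoform flags.

# Tiered evidence scoring

Each `UNCLASSIFIED` protein is scored in three evidence categories, each
contributing the single highest qualifying tier (0–3 points), for a
maximum total of 9:

* **Network** (PPI): tier 3 if the protein has more than one `SEC`
  partner and at most 33 `NONSEC` partners; tier 2 if more than one
  `SEC` partner but more than 33 `NONSEC`; tier 1 if one of its `SPT`
  partners itself has the clean profile (>1 `SEC`, 0 `NONSEC`). The
  cutoff 33 is a corpus-derived constant exposed as a parameter
  (`nonsec_cutoff`); other datasets should retune it.
* **PFAM** and **GO**: for each accession the protein carries, the
  category set of all carrier proteins decides the tier — tier 3 when
  carriers are exclusively `SEC`/`UNCLASSIFIED`, tier 2 when exclusively
  `SEC`/`SPT`/`UNCLASSIFIED`, tier 1 when the accession is
  *predominantly* secretory (at least half of carriers in `SEC`∪`SPT`,
  with at least one `SEC` carrier). Predominance is deliberately a
  majority criterion rather than a statistical enrichment, because the
  `NONSEC` class itself may hide unobserved LSPs and GO hierarchies make
  term frequencies uneven; terms are compared as given, with no
  hierarchy expansion.

The total maps to a confidence label: **High** at 5 points or more,
**Medium** at 3–4, **Low** below 3. A self-interaction (homodimer) is
annotated as worth 0.5 points as a category of interest, but is recorded
only — it never changes a total or a label. Design notes: tiers are
evaluated highest-first and never summed within a category, which is
what makes the 5-point High boundary attainable from two categories
(e.g. 3 + 2); the tier-1 network rule tests the *partner's* profile,
the closest reading of an ambiguous criterion, and both choices are
parameterised. Candidates whose only evidence is a homodimer annotation
stay in Low and are retained.

# Training schemes

Six labelled datasets can be assembled from a built database:

| Scheme | Positives | Negatives |
|---|---|---|
| LSPpred1 | UNCLASSIFIED High+Medium | NONSEC |
| LSPpred2 | UNCLASSIFIED High+Medium | NONSEC + SEC + SPT |
| SPLpred1 | SEC, SP removed | NONSEC intact |
| SPLpred2 | SEC, SP removed | NONSEC, mean-SP-length prefix removed |
| SPLpred3 | SEC, SP removed, Met restored | NONSEC intact |
| SPLpred4 | SEC duplicated (intact + SP-removed) | NONSEC duplicated (intact + prefix-removed) |

Low-confidence and unscored `UNCLASSIFIED` proteins are never trained
on; they are reserved as evaluation data. All isoforms of a classified
gene enter the pool, then each class is redundancy-reduced on the intact
sequences at 40% maximum pairwise identity before modification —
greedy longest-first clustering with identity defined as
global-alignment matches over alignment length, with a short-word screen
on large inputs (exact all-pair alignments below 50 sequences). The 40%
threshold balances independence of the folds against the small size of
the positive classes. SPLpred4 duplicates both classes (modified +
unmodified copies); each modified record keeps its unmodified twin
retrievable for bias analysis. Mean SP length is the half-up-rounded
mean of annotated cleavage positions.

# Features

Sequences are encoded as 166 fixed-order features
(`feature_registry()`): length, molecular weight (average residue
masses + one water), isoelectric point (bisection on the net-charge
curve with the EMBOSS pKa set), GRAVY (Kyte–Doolittle mean hydropathy);
amino-acid composition (20); per-residue Shannon entropy terms
−p·log₂p plus their total (21) — single-residue entropies are reported
separately because individual terms (glycine especially) can carry
class signal; a five-group chemical-alphabet composition (5);
composition–transition–distribution (CTD) blocks under five 3-group
property alphabets — polarity, polarizability, charge, solvent
accessibility, secondary-structure propensity (5 × 21); Kyte–Doolittle
sliding-window summaries at widths 5 and 11 (6); Moran autocorrelation
of the hydropathy series at lags 1–4 (4); and the N-glycosylation
sequon count N-X-(S/T), X ≠ P (1). The registry implements these
families with documented membership; it does not attempt to replicate
any external feature suite's exact numeric output (secondary-structure
features are propensity-alphabet CTD encodings, not predicted
structures).

Degenerate-input conventions keep every feature finite for any validated
sequence of length ≥ 1: transitions are 0 for length-1 sequences,
windows longer than the sequence collapse to the whole-sequence mean,
zero-variance autocorrelation returns 0, and non-canonical residues are
dropped (with a warning) at validation so all formulas stay defined on
the 20-letter alphabet. Min–max scaling is fitted on the training
partition only and reapplied unchanged to test and prediction data;
tree ensembles are invariant to per-feature monotone maps, so scaling
matters for reporting, not for fitting.

# Balanced random forest and FPR calibration

The positive classes are 1–2 orders of magnitude smaller than `NONSEC`,
so each tree of the forest is grown on a class-balanced bootstrap: the
majority class is downsampled with replacement to the minority count,
per tree (500 trees, unlimited depth, √p features per split — all
configurable; these follow common balanced-forest practice). Scores are
ensemble vote fractions in [0, 1].

Training runs as: stratified 75/25 train/test split; stratified 5-fold
cross-validation on the training partition; per fold, the decision
threshold is the smallest out-of-fold score cutoff whose fold FPR does
not exceed 0.05 (equivalently, maximal TPR subject to the bound — the
choice is oracle-tested against exhaustive cutoff enumeration); the
calibrated threshold is the mean of the five fold thresholds, and the
TPR estimate the mean fold TPR at them. Fold-averaged Gini importances
are ranked and the upper quartile retained (ties at the boundary all
kept). The forest is refit on the full training partition restricted to
the retained features, and the held-out test set is evaluated with
balanced accuracy — the mean of per-class accuracies, so scarce
positives weigh as much as abundant negatives — at both the calibrated
threshold (high-confidence mode) and 0.5 (low-confidence mode). A score
exactly at a threshold counts as positive. One master seed fans out
deterministically to the split, the folds and the trees.

```{r pipeline}
library(leaderless)
ds <- synthetic_benchmark(60, 600, seed = 1)
model <- train_pipeline(ds, seed = 1)
glance(model)
autoplot(model$cv)
```

# Modification bias

Removing signal peptides from training positives risks teaching the
model to recognise the *absence of an N-terminus* rather than secretion
biology. `estimate_bias()` scores paired modified/unmodified versions of
the same proteins and reports the mean signed score difference (and a
density plot via `autoplot()`). The mean difference is reported, not
thresholded: scheme selection is a judgment call that weighs accuracy
against bias, and the report is the evidence. Intact-data schemes
provide the baseline — some difference arises even without modification
because genuine features live in the N-terminal region.

# Consensus prediction

`predict_suite()` applies an LSPpred-style and an SPLpred-style bundle
and combines calls at both confidence levels. The default consensus is
AND (both modules agree), the conservative choice consistent with the
FPR-control intent; OR is available by flag.

# The synthetic generator

`generate_fixture()` emulates exactly the statistical structure the
pipeline assumes: background sequences with Swiss-Prot-like residue
frequencies; lengths normal (mean 300, sd 80) truncated at 50; signal
peptides with textbook architecture (initiator Met, K/R-enriched
n-region of 2–5 residues, hydrophobic h-region of 7–15 residues from
A/I/L/F/V/M/W, c-region of 3–7 residues ending A-X-A); an LSP-like
candidate class separated from background by a +0.10 glycine composition
shift (echoing the observation that single-residue composition and
entropy, glycine in particular, can dominate such classifiers); and
PPI/PFAM/GO tables wired so designated candidates satisfy each evidence
tier exactly, with ground truth emitted alongside. Annotation noise is
available (`observed_noise`) and defaults to 0 so round trips are exact.

What the generator does **not** emulate: realistic PPI topology beyond
the tier rules, GO hierarchy, homologous gene families (sequences are
i.i.d., so redundancy reduction rarely removes anything), length/
composition correlations, or any real proteome's class proportions.
Passing tests therefore demonstrate the machinery is correct and the
calibration holds under the stated generative model — not that the
reported accuracies transfer to real proteomes.

# Reference problem sizes and numerical choices

The package's simulation checks use 60 positives / 600 negatives per
replicate and 20 replicates for the FPR-calibration check — enough for
a Monte-Carlo standard error near 0.25 percentage points on the mean
held-out FPR while keeping a full run on one CPU in about a minute.
Other conventions: composition vectors sum to 1 within 1e-12; the pI
bisection runs 80 halvings on [0, 14] (≈ 1e-22 pH resolution); identity
ties in redundancy reduction are broken by id so clustering is
deterministic; a fold where no cutoff meets the FPR bound falls back to
a cutoff just above its highest negative score (FPR 0) with a warning.

# Known limitations

* The evidence-tier constants (cutoff 33, predominance 0.5, the 5/3
  confidence boundaries) are corpus-derived; on a new proteome they are
  starting points, not truths.
* The identity screen can in principle retain a pair above threshold if
  two related sequences share no length-5 word; below 50 sequences the
  exact path is used.
* The classifiers are intended for land-plant proteomes; applying them
  to other organisms is out of scope.
* Feature families are implemented in documented, versioned form; they
  are not numerically identical to any external feature-extraction
  suite, so fitted models are not interchangeable with models trained
  elsewhere.
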