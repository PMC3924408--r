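---
title: "Predicting plasminogen activators from sequence composition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting plasminogen activators from sequence composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgact)
```

## The problem

Plasminogen activators convert plasminogen into plasmin, the protease that
degrades fibrin clots. Two mechanistic groups exist: the bacterial
(prokaryotic) indirect activators staphylokinase (SAK, ~136 residues) and
streptokinase (SK, ~414 residues), which activate plasminogen by forming a
1:1 cofactor complex with it; and the eukaryotic direct activators tissue
plasminogen activator (tPA) and urokinase (UK), trypsin-like serine proteases
that cleave the plasminogen Arg–Val bond themselves. All four are of clinical
interest as thrombolytics, and genome projects keep producing candidate
sequences with no functional annotation. `pgact` recognises plasminogen
activators from the primary sequence alone and assigns positives to a
subfamily, using support vector machines over fixed-length composition
encodings.

## Feature encodings

Four encodings of a validated sequence of length $L$ are supported, all
ordered by the alphabetical one-letter alphabet (`aa_alphabet()`):

* **AC** (20 dimensions): the fraction of each amino acid,
  $x_a = n_a / L$. Entries sum to 1.
* **DC** (400 dimensions): overlapping adjacent-pair fractions,
  $x_{ab} = n_{ab} / (L-1)$, in row-major order (AA, AC, ..., YY). The
  denominator $L-1$ counts all dipeptide occurrences in the sequence, the
  standard convention for this encoding, so entries again sum to 1.
* **PSSM** (400 dimensions): from a position-specific scoring matrix (an
  $L \times 20$ table of PSI-BLAST log-odds scores $s_{pb}$), each score is
  squashed with the logistic sigmoid $\sigma(s) = 1/(1+e^{-s})$ and
  $x_{ab} = \frac{1}{L}\sum_{p:\,\mathrm{seq}[p]=a} \sigma(s_{pb})$.
  The sigmoid guarantees every entry lies in $[0,1]$; dividing by $L$ (rather
  than per-residue counts) makes rows of absent residues exactly zero. This
  definition is a documented convention of the package: profile "composition"
  reductions vary across tools, and only the $[0,1]$ normalised, 400-vector
  contract is fixed.
* **HYBRID** (420 dimensions): AC followed by DC.

PSSM profiles can come from three providers: `mock` (seeded integers in
$[-5,5]$ with $+4$ added to each position's own-residue column, so the whole
PSSM pipeline is testable offline), `precomputed` (a directory of
`-out_ascii_pssm` files), or `external` (a live PSI-BLAST run, 3 iterations,
e-value 0.001, against a user-supplied protein database). The iteration count
is fixed at 3 as a reasonable default for profile convergence.

## The classifier

Each binary classifier is a soft-margin SVM with the radial basis kernel in
the SVM-light parameterisation $K(x,y) = \exp(-\gamma\lVert x-y\rVert^2)$.
Because no SVM implementation is available among this package's allowed
dependencies, the dual problem is solved by a built-in sequential minimal
optimisation (SMO) solver with maximal-violating-pair working-set selection —
the classic LIBSVM scheme — over a precomputed kernel matrix (training sets
here are at most ~10^3 sequences, so the full matrix is cheap). The solver is
deterministic; the stopping tolerance defaults to the customary `1e-3` on the
KKT gap. A unit test cross-checks its decision values against an independent
SVM implementation on a small fixture.

Prediction is hierarchical, mirroring how the tool is meant to be used:

1. **Level 1** — one SVM trained with all activator subfamilies as positives
   and the non-activator class (`NEG`) as negatives. A sequence is called
   `PG` when its decision value is at least the threshold (default 0, the SVM
   margin; raising the threshold can only remove `PG` calls).
2. **Level 2** — four one-vs-rest subfamily SVMs trained on activators only
   (each subfamily against the other three; `NEG` is excluded here because
   the level-1 gate already handles it). For sequences called `PG`, the
   subfamily call is the argmax of the four decision values, with exact ties
   broken in the fixed order SAK < SK < tPA < UK. Gating level 2 on the
   level-1 call (rather than always reporting subfamily scores) is a design
   choice; the raw scores are returned alongside the call so users can
   inspect borderline cases.

The shipped per-model hyperparameters (`pga_params()`) are values optimised
on a curated SwissProt dataset of 356 activators (69 SAK, 167 SK, 11 tPA,
109 UK) against 501 regulatory-protein negatives; that dataset itself is not
redistributable, which is why the package ships a synthetic benchmark
instead (below). For example, the level-1 models use
$(\gamma, C)$ = (25, 450) for AC, (3, 375) for DC, (3, 400) for PSSM and
(1, 450) for HYBRID.

Model bundles serialise as a directory of plain-text files (one per SVM,
doubles printed with `%.17g` so reloading reproduces decision values bit for
bit) plus a JSON manifest recording the feature method and the residue
ordering; `load_model()` refuses a bundle whose ordering does not match the
running package.

## Evaluation

`cross_validate()` implements $k$-fold (default five-fold) cross-validation:
a seeded shuffle is dealt round-robin into folds (sizes differ by at most
one; optional stratification by label protects the 11-member tPA class),
each fold is held out once, and the reported accuracy, sensitivity,
specificity and MCC are the unweighted mean of the per-fold values (pooled
counts are also returned for comparison). The metric definitions are the
standard ones:

$$\mathrm{ACC} = \frac{TP+TN}{TP+TN+FP+FN},\quad
  \mathrm{SN} = \frac{TP}{TP+FN},\quad
  \mathrm{SP} = \frac{TN}{TN+FP},$$

$$\mathrm{MCC} = \frac{TP\cdot TN - FP\cdot FN}
  {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}.$$

A metric whose denominator is zero is reported as `NA` with a warning, never
silently as 0. ROC curves sweep the unique decision values in descending
order with tied scores grouped into one step; the trapezoidal AUC then equals
the probability that a random positive outscores a random negative (ties
counted half), which the tests verify against exhaustive pair enumeration.

## The synthetic benchmark

Real activator sequences are not shipped. `default_benchmark()` instead
draws a labelled dataset with the same family structure as the curated
dataset — 69 SAK, 167 SK, 11 tPA, 109 UK, 501 NEG — from editable
compositional profiles (`inst/extdata/family_profiles.tsv`):

* SAK and SK are cysteine-free, nearly tryptophan-free and strongly
  lysine-rich (real staphylokinase is notably Lys-rich, and prokaryotic
  activators lack Cys); SAK is short (120–150 residues), SK long (380–440).
* tPA and UK contain elevated Cys and Trp (disulfide-bonded, multi-domain
  eukaryotic proteases) plus extra Lys/Tyr; their profiles overlap
  deliberately so that evaluation reproduces the characteristic tPA/UK
  confusion, aggravated by the 11-member tPA class.
* NEG uses SwissProt-like background frequencies over 100–600 residues.

The tilts were set once so that the families are "hard but learnable": DC
five-fold cross-validation at the shipped defaults scores ~93–94% mean
accuracy with the SAK and SK rows of the confusion table diagonal-dominant.
Sequences are i.i.d. draws from the family composition (a first-order Markov
transition matrix can be supplied to plant genuine dipeptide structure, and
its empirical pair law is tested against the stationary distribution), so the
generator emulates *composition*, not homology: there are no domains, no
conserved motifs, no phylogenetic correlation between family members, and no
length–composition coupling beyond the per-family length ranges. A green
benchmark test therefore establishes that the pipeline recovers compositional
class structure at realistic sample sizes and imbalance — not that the
published accuracies on real proteins are reproduced, which would require the
original database snapshots.

## Numerical and degenerate-input choices

* Residue validation policies: `strict` (error), `drop`, and the default
  ingest policy `map` (B→D, Z→E, U→C, J→L, O→K, X dropped) — ambiguity codes
  are resolved to a representative residue rather than discarding whole
  records.
* Molecular weights use average (not monoisotopic) residue masses plus one
  water (18.0153 Da), matching typical web-server behaviour.
* The redundancy filter is a transparent greedy re-implementation of the
  CD-HIT contract: longest-first, a sequence joins the first retained
  representative with best-offset ungapped identity above the threshold
  (denominator: the shorter length). Exact matches always collapse, so
  threshold 1.0 removes precisely the duplicates. Word heuristics are not
  ported — at package scale the all-pairs scan is fast and the tested
  contract (no retained pair above the threshold) is what matters.
* Empty datasets flow through: statistics of an empty FASTA give an empty
  table with the full header; redundancy reduction of an empty set is empty.
* SMO warns (rather than errors) if the iteration cap is hit; the cap is far
  above what the shipped problem sizes need.

## Limitations

* Composition features carry no positional information; a shuffled activator
  sequence scores identically under AC.
* Decision values are margins, not probabilities; no calibration is applied.
* Hyperparameter search is out of scope — the shipped values are defaults,
  and users with their own data should tune $(\gamma, C)$ externally.
* The external PSSM provider requires a local BLAST+ installation and
  protein database; no database is bundled.

## A worked run

```{r example, eval = FALSE}
bench <- default_benchmark(seed = 7)
cv <- cross_validate(bench, method = "DC", k = 5, seed = 7)
cv

fit <- pga_fit(bench, method = "DC")
predict(fit, bench[c(1, 500), ])
```
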