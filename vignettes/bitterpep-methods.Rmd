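---
title: "Sequence descriptors and random-forest classification of bitter peptides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence descriptors and random-forest classification of bitter peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bitterpep)
```

## The problem

Bitter peptides are short oligopeptides, typically enriched in hydrophobic
residues, whose identification by sensory panels or chromatography is slow
and subjective. `bitterpep` implements a sequence-only classification
pipeline: each peptide is mapped to a fixed-length numeric descriptor
vector, ten descriptor families are fused into one representation, columns
that are identically zero on the fitting data are dropped, and a random
forest is trained to separate bitter (positive) from non-bitter (negative)
peptides. Model quality is reported as sensitivity, specificity, accuracy,
Matthews correlation and AUROC, under stratified 10-fold cross-validation
and on a held-out independent partition from a stratified 8:2 split.

## The ten descriptor families

All encoders are pure functions of one sequence over the 20 standard
residues (alphabetical component order `A,C,D,...,Y`; dipeptide components
row-major with the first residue as the outer loop). For a peptide of
length $N$:

* **AAC** (20): residue frequencies $f(t) = N(t)/N$.
* **TPAAC** (20 + $\lambda$): type-1 pseudo-amino-acid composition. The
  three shipped property scales (hydrophobicity, hydrophilicity,
  side-chain mass) are standardized to mean 0 and unit RMS deviation over
  the 20 residues; the residue correlation
  $\Theta(i,j)$ is the mean of the three squared scale differences;
  the sequence-order factor at lag $j$ is
  $\theta_j = \frac{1}{N-j}\sum_i \Theta(R_i, R_{i+j})$. The vector is
  $f_c / D$ for the 20 residues and $\omega\theta_j / D$ for the pseudo
  components, sharing $D = \sum_r f_r + \omega\sum_j \theta_j$, so it sums
  to 1. Defaults: $\lambda = 1$, $\omega = 0.05$.
* **APAAC** (20 + $2\lambda$): amphiphilic variant; per lag, the mean
  *product* of normalized hydrophobicities and of normalized
  hydrophilicities (interleaved), weighted by $w = 0.5$. The 0.5 weight
  is deliberately larger than the 0.05 used conventionally elsewhere;
  it is the value this pipeline is defined with, and it is configurable.
* **ASDC** (400): ordered residue pairs at *all* gaps up to $N-1$,
  normalized by the total pair count $N(N-1)/2$.
* **DPC** (400): adjacent dipeptide frequencies $N_{rs}/(N-1)$.
* **DDE** (400): each dipeptide frequency standardized against its
  codon-background expectation $T_m = (C_r/61)(C_s/61)$ with variance
  $T_m(1-T_m)/(N-1)$, using the 61 sense codons of the standard genetic
  code. Dipeptides absent from the peptide score strictly negative.
* **GAAC** (5) and **GDPC** (25): compositions over five physicochemical
  groups — aliphatic GAVLMI, aromatic FYW, positive KRH, negative DE,
  uncharged STCPNQ.
* **SOCNumber** ($2\,\mathrm{nlag}$): sequence-order-coupling numbers
  $\tau_d = \sum_i d(R_i, R_{i+d})^2$ per distance matrix.
* **QSOrder** ($2(20+\mathrm{nlag})$): per distance matrix, the 20 residue
  frequencies and the couplings share the denominator
  $\sum_r f_r + w\sum_d \tau_d$ with $w = 0.1$; each block sums to 1.

With the defaults $\lambda = \mathrm{nlag} = 1$ the dimensions are
20, 21, 22, 400, 400, 400, 5, 25, 2 and 42 — 1,337 fused columns. `nlag`
defaults to 1 rather than the value of 30 often used for long proteins:
the coupling lag must stay below the peptide length, and bitter-peptide
data contain dipeptides. Both `lambda` and `nlag` are checked against
every peptide at encode time. A generalized correlation hook
(`scale_subset` of `correlation_theta()`) allows single-property or
property-set variants of $\Theta$; the default TPAAC uses the classic
three-property form, which is what dimension $20+\lambda$ corresponds to.

## Shipped property tables

The tables live as TSV files under `inst/extdata/` with the residue order
documented in `AA_ALPHABET`, and are replaceable.

* `aa_scales.tsv` — the classic PseAAC trio: Tanford-style
  hydrophobicity, Hopp–Woods hydrophilicity, integer side-chain masses.
  Published variants of these scales exist; swapping one shifts TPAAC and
  APAAC values, which is why the files are pinned and versioned with the
  package.
* `grantham.tsv` — the Grantham chemical distance, computed from
  Grantham's composition/polarity/volume formula
  ($\alpha = 1.833$, $\beta = 0.1018$, $\gamma = 0.000399$, mean over the
  190 pairs normalized to 100) and rounded to integers. Anchor entries
  match the printed table (d(L,I) = 5, d(C,W) = 215); an entry may differ
  by one unit from some printed versions due to rounding.
* `schneider_wrede_synthetic.tsv` — a **synthetic** physicochemical
  distance matrix occupying the Schneider–Wrede slot of the
  sequence-order encoders: the RMS difference of the three normalized
  scales, rescaled so the largest pairwise distance is 1. It is symmetric
  with a zero diagonal and plays the same structural role as the
  published Schneider–Wrede matrix; users holding that matrix can drop it
  in as a TSV with the same layout. Descriptor values from this slot are
  therefore internally consistent and reproducible, but not numerically
  identical to pipelines using the published matrix.

The Grantham matrix is used on its published integer scale by default; a
`normalize = "max"` option rescales both matrices to $[0,1]$.

## Fusion and the zero-column filter

`fuse()` concatenates the ten vectors in a fixed order with qualified
column names (`AAC.A`, `DPC.AA`, `QSOrder.Grantham.lag1`, ...), so feature
matrices are column-stable across runs. `fit_zero_filter()` records the
columns with at least one nonzero entry in a fitting matrix;
`apply_schema()` subsets any compatible matrix to those columns. Only
identically-zero columns are removed — constant nonzero columns are kept —
so the filter discards no discriminative information. By default the
filter is fitted on the training partition only and then applied to the
independent partition, which avoids using test data in any fitting step;
a fit-on-everything mode (`zero_filter = "all"` in `run_benchmark()`) is
provided for comparison with workflows that filter before splitting.

## Classifiers and evaluation

The primary model is a random forest: 500 trees, $\sqrt{p}$ candidate
features per split, unrestricted depth, fitted with the `ranger` engine
single-threaded and seeded, so every fit is reproducible. Comparison
families use standard engines with library-default-style settings: RBF
SVM (`e1071`), gradient boosting (`xgboost`, 100 rounds, learning rate
0.1 — the package's gradient-boosted-tree engine), a single decision tree
(`rpart`), and L2-regularized logistic regression (`glmnet` ridge with
$\lambda = 1/n$, since the fused dimension far exceeds the sample size
and an unpenalized fit would not converge). No hyperparameter search is
performed anywhere.

Scores are probabilities of the positive class; calls use a fixed 0.5
threshold (scores equal to the threshold are called positive). Sn, Sp,
ACC and MCC come from the confusion matrix; an MCC with a degenerate
denominator is reported as 0 with an explicit flag. AUROC is computed
from midranks, i.e. the probability that a random positive outscores a
random negative with ties counted one half, which makes it invariant
under strictly monotone transforms of the scores.

Cross-validation is stratified (per-class fold sizes differ by at most
one) and seeded. Because per-fold AUROC is noisy at fold sizes of ~50,
the primary aggregate is computed on the pooled out-of-fold scores;
per-fold reports and their means are returned alongside, since both
aggregation conventions appear in the literature.

## The synthetic generator

`generate_peptides()` produces labeled fixtures that emulate the single
best-established structural property of bitter peptides — hydrophobic
enrichment — and nothing else. Negatives draw residues uniformly;
positives move probability mass `delta` from the 12 non-hydrophobic
residues onto the 8 hydrophobic ones (AVLIMFWG), so the expected
hydrophobic-fraction gap between classes is exactly `delta`. Lengths are
uniform on 2–15, mirroring real oligopeptide benchmarks and deliberately
stressing the short-peptide edge cases (`lambda`/`nlag` bounds,
dipeptides). Feasibility requires `delta` < 0.6; larger shifts would need
negative probabilities and are rejected.

What the generator does *not* emulate: positional motifs, residue
autocorrelation, length–class dependence, or the composition statistics
of real bitter peptides. Passing tests on synthetic data therefore
demonstrate that the pipeline's machinery is correct and that it recovers
a known composition signal; they say nothing about accuracy on real
bitter-peptide benchmarks, which must be measured on downloaded data.

A useful closed-form property: under this generator the class signal is
carried entirely by the hydrophobic residue count $k$ given length $L$
($k \sim \mathrm{Bin}(L, 0.4 + \delta)$ for positives vs
$\mathrm{Bin}(L, 0.4)$ for negatives). Enumerating the likelihood-ratio
distribution gives the Bayes-optimal AUROC; at `delta = 0.3` with lengths
2–15 it is 0.890. This bounds what *any* classifier can average on these
fixtures — observed fusion-RF pooled CV AUROCs of ~0.85 sit close to that
ceiling, and AUROC near 0.5 at `delta = 0` confirms the null. Short
peptides are the binding constraint: a dipeptide carries almost no
composition information, so the mixture over lengths caps the ceiling
well below 1.

## Numerical and design choices

* Pseudo-component index ranges are treated as inclusive
  (components $21 \dots 20+\lambda$, resp. $20+2\lambda$); the exclusive
  reading would leave the pseudo block empty at $\lambda = 1$,
  contradicting the 21/22 dimensions.
* TPAAC/APAAC/QSOrder denominators use $\sum_r f_r = 1$ with $f$ the
  count frequencies, stated explicitly because "normalized occurrence"
  is ambiguous in parts of the descriptor literature.
* The split takes the first `round(f * n)` of a seeded per-class shuffle;
  with 320 + 320 peptides at 8:2 this yields exactly 256 + 256 train and
  64 + 64 independent.
* Encoder oracles in the test suite are literal loop-based
  re-transcriptions of the defining formulas, kept separate from the
  vectorized implementations and compared at $10^{-10}$ per component.
* Problem sizes in the test suite (up to 200 oracle peptides, 1,000
  normalization/metric instances, 10 seeds × 3 shifts × 10-fold CV at
  200 peptides per class) were chosen as the smallest sizes at which the
  statistical assertions are stable.

## Known limitations

* The Schneider–Wrede slot ships a synthetic matrix (above); absolute
  SOCNumber/QSOrder values differ from pipelines using the published
  matrix, though all structural properties (symmetry, zero diagonal,
  ordering, normalization) are identical.
* Only composition-shifted synthetic data are bundled; no claim is made
  about real-data accuracy until the external benchmark is supplied.
* No feature selection beyond zero-column removal, no threshold tuning,
  no hyperparameter search — deliberately, to keep the pipeline identical
  to its reference design.
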