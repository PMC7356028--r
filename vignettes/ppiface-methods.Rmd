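---
title: "Methods: sequence-based pairwise interface prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence-based pairwise interface prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppiface)
```

## The problem

Given two interacting eukaryotic proteins A (length $M$) and B (length
$N$), ppiface predicts which residue pairs $(i, j)$ of the $M \times N$
pair grid form the physical interface, using only sequence-derived
information: multiple sequence alignments (MSAs) of each protein,
per-residue relative solvent accessibility (RSA) and 3-class secondary
structure (SSP) from any external predictor. A complex structure, when
available, is used solely to derive training labels and to evaluate.

The pipeline has three stages: (1) pairwise feature construction,
including a co-evolution statistic computed on a species-matched
concatenated MSA; (2) a Random Forest classifier over residue pairs;
(3) a network post-filter that removes predictions involving buried
residues or residues dominated by intra-protein co-evolution, then keeps
only spatially clustered predictions.

## The co-evolution statistic

The two MSAs are matched on a species key parsed from the FASTA headers
(configurable regex, default: first whitespace-delimited token), and rows
of shared species are concatenated A-then-B. For an A-column $i$ and
B-column $j$, the score is a perturbation sum in the style of statistical
coupling analysis: each of the 20 residues $a$ observed at column $i$
defines a condition (the row subset with $a$ at $i$), and the score
accumulates the induced shift of the column-$j$ symbol distribution,

$$\mathrm{CMI}(i,j) \;=\; \sum_{a} w(a) \sum_{b}
  p(b \mid j, X_i = a)\,\log\frac{p(b \mid j, X_i = a)}{p(b \mid j)},$$

where $b$ ranges over the 21 symbols (20 residues + gap), frequencies are
Laplace-smoothed with a per-symbol pseudocount (default $1/21$), gaps are
never used as conditions, and empty conditions contribute zero. Two
weighting modes are provided:

* **weighted** (default): $w(a) = f_i(a)$, the frequency of $a$ at column
  $i$. Each inner sum is a Kullback–Leibler divergence, so every entry is
  non-negative, and the whole sum equals the mutual information of the
  smoothed joint symbol table — which supplies an exact, independent test
  oracle. With no gaps at column $i$ and no smoothing it is exactly the
  classic plug-in mutual information of the two columns.
* **unweighted**: $w(a) = 1$, a plain sum over conditions (closer to a
  literal "sum over the 20 conditions"); retains non-negativity but not
  the MI identity.

The log base is configurable (natural log by default); downstream min–max
scaling makes the base immaterial to the classifier. No sequence
redundancy down-weighting is applied. Intra-protein matrices are computed
by concatenating a protein with itself; the result is symmetric up to
smoothing effects, and unordered intra pairs are scored by the mean of
the two oriented entries.

## Feature matrices

Nine base $M \times N$ matrices, each min–max scaled to $[0,1]$ per
matrix per complex (a global-across-complexes mode would couple scaling
to the training set; per-complex scaling is consistent with predicting on
unseen complexes and is the fixed choice):

| Feature | Construction |
|---|---|
| CMI | co-evolution matrix above |
| CCM, HCM, SCM | 20×20 charge/hydropathy/size compatibility lookups |
| RSA | outer product $\mathrm{rsa}_A(i)\cdot \mathrm{rsa}_B(j)$ |
| SSP | rank of the unordered class pair (6 combinations) |
| CP, CPE, CPB | 20×20 contact-potential lookups (all/exposed/buried) |

The published compatibility and Miyazawa–Jernigan-style contact tables
are not redistributed. `default_property_tables()` derives symmetric
stand-ins from standard scalar scales — formal charge product (opposite
charges compatible), negative absolute differences of Kyte–Doolittle
hydropathy and of residue volume, and three mutually non-affine
functions of normalized hydropathy for the contact potentials (additive,
multiplicative, min-combined; non-affine so per-matrix scaling keeps them
distinct). `read_property_table()` accepts literature tables as plain
20×20 TSV; the suite intentionally runs entirely on the generated
stand-ins.

SSP ranks: naive class-code multiplication would rank helix–helix pairs
lowest, so the 6 unordered combinations are ranked by occurrence among
positive pairs (`learn_ssp_ranks()`, scaled $r/6$, ties broken by a fixed
combo order). When no labels are available a documented default ordering
(loop-rich combinations most frequent, sheet–sheet least) stands in.

**Environment features.** Each base matrix is convolved with a decayed
ring kernel: odd size $k \in \{3,5,7\}$, weight $1 - r\cdot d$ at
Chebyshev ring distance $r$, decay $d \in [0.10, 0.25]$, normalized to
sum 1 by default (neighborhood averaging). Convolution is zero-padded so
the output keeps the input shape; borders are therefore damped, a fixed
and documented choice that matters near chain termini. The kernels are
centro-symmetric, so cross-correlation and flipped-kernel convolution
coincide. The default kernel is 5×5 at 10% decay. This yields 18
features (9 base + 9 "E"-prefixed). The kernel spec is persisted in the
trained model and enforced at prediction time.

## Labels

Structure-derived labels replace an external interface service with a
standard distance definition: a **seed** pair is any residue pair with a
heavy-atom distance below 5 Å (strict). Seeds are then **expanded**: for
each seed, all pairs within ±2 positions on both chains are added when
their representative-atom distance is at most 10 Å (inclusive). The
representative atom is Cβ with Cα fallback (configurable to Cα or
nearest-heavy-atom); the flank grid is clipped at termini, and residues
missing from the structure are never labeled. Negatives are the grid
complement.

## Classifier

Pairs from all training complexes are flattened into one table (18
features + label). The negative class is down-sampled to 5:1
negatives-per-positive (all positives kept; deterministic under seed).
Because no random-forest package is available in the supported
environment, the package ships its own compact implementation (Rcpp):
bagged CART trees, gini splits, per-node feature subsampling,
probabilities as the forest mean of leaf positive fractions, and
mean-decrease-impurity importances. Forests are reproducible under R's
RNG seed.

Model selection: stratified 75:25 split; each point of the grid (trees
{100, 300, 500} × depth {unlimited, 10, 20} × features-per-node
{sqrt, 0.3} × min leaf {1, 5} — package choices, the source method names
no ranges) is scored by 3-fold cross-validated positive-class F1 on the
75% part, then the winner is refit on the 75% part and reported once
against the 25% part. The decision threshold is fixed at 0.5;
probabilities are also returned for re-thresholding. Evaluation reports
the confusion matrix, accuracy, rank-based AUC, per-class/macro/weighted
precision–recall–F1, specificity and MCC. Leave-one-complex-out
cross-validation trains on all other complexes (down-sampled) and
evaluates each held-out complex on its full, un-sampled grid.

## Network post-filter

1. **Intra networks.** For each protein, unordered position pairs at
   sequence separation ≥ 5 are ranked by intra-CMI; the top 5% of
   candidates (count-based, default) form the intra network. A
   value-threshold alternative (scores above 95% of the candidate score
   range) is provided because the source method's own worked counts
   (157/1540, 238/2346) are closer to 10% of unfiltered pairs than to the
   stated 5% rule; the discrepancy is documented, not resolved.
2. **Residual network.** In the binary prediction matrix, rows/columns of
   buried residues (RSA = 0) and of intra-network node residues are
   zeroed (node elimination — intra edges cannot literally be removed
   from a bipartite inter graph). Idempotent; never adds a prediction.
3. **Cluster scoring.** An all-ones kernel matching the environment
   kernel size (3 or 5) is convolved over the residual matrix
   (zero-padded); predicted cells are kept only when their window sum
   strictly exceeds 2 (3×3) or 6 (5×5), about 25% window occupancy.
   Maximal scores are 9 and 25.
4. **Stretch mapping.** Survivors must lie in runs of ≥ 3 consecutive
   covered residues on both chains (interface hotspots are contiguous).

Each stage only removes pairs, so the stage sizes are monotonically
non-increasing — a tested invariant.

## The synthetic world

The generator states one fixed world rather than a tunable benchmark:
chains of 30 and 25 residues, 4 planted contacts, alignment depth 500,
coupling 0.9 (defaults of `synthetic_spec()`).

* **Geometry**: pseudo-atom chains (N/CA/CB) at 3.8 Å spacing, partner
  chain parallel at 30 Å, planted contacts brought to 4.5 Å — exactly the
  planted pairs satisfy the 5 Å seed criterion (nearest non-planted
  approach ≈ 5.3 Å), so label recovery is provable, not statistical.
* **Annotations**: surface RSA uniform in (0.05, 1]; a buried subset
  (20% of residues, disjoint from the interface) exactly 0; SSP assigned
  in runs of 3–8.
* **Covariation**: background columns i.i.d. uniform over 20 residues;
  each planted pair co-varies through a fixed random alphabet bijection
  applied per sequence with the coupling probability. The bijection model
  has closed-form mutual information (log 20 at coupling 1), which the
  oracle tests exploit.

What the generator does *not* emulate: phylogenetic correlation between
rows, indel structure, realistic backbone geometry, compositional bias,
or annotation noise. A green suite therefore establishes algorithmic
correctness against stated oracles and recovery in an idealized signal
regime — not performance on real complexes.

## Numerical choices and degenerate inputs

* Min–max scaling maps a constant matrix to all zeros (fixed convention).
* All-gap alignment columns yield zero co-evolution scores with a
  warning; alignments need ≥ 2 rows.
* $0 \log 0 = 0$ throughout; with pseudocount 0 the background can only
  vanish where the conditional does.
* Cutoffs: heavy-atom seeds use strict `<` 5 Å; the expansion cap is
  inclusive ≤ 10 Å; window-score cutoffs are strict `>`.
* Intra-network ties are broken deterministically (score, then indices).
* Down-sampling, splits, folds and forests derive all randomness from
  caller-supplied seeds; derived seeds stay within 32-bit range.

## Known limitations

* The contact-potential tables are hydropathy-derived stand-ins; users
  reproducing literature results should supply the published tables via
  `read_property_table()`.
* The permutation-null behaviour of the classifier under 5:1 imbalance is
  majority-class collapse (null F1 near 0, below the prevalence
  baseline); this is the expected uninformative behaviour and is what the
  test suite asserts.
* Per-matrix scaling discards absolute feature magnitudes across
  complexes; a sensitivity switch is left as future work.
* The PDB reader is minimal by design (ATOM records, altloc A, no
  insertion codes).
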