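---
title: "Cell-type-resolved multimorbidity: models and methods"
author: "multimorbinet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-type-resolved multimorbidity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multimorbinet)
```

## The scientific problem

Diseases that co-occur in patients more often than chance — multimorbidity —
often do so because they perturb shared molecular machinery.  Whole-organism
interactome analyses can quantify that sharing, but they blur an essential
fact: disease mechanisms act in particular cell types.  A pathway perturbed
by two diseases in the *same* cell type is a far stronger mechanistic
candidate than one perturbed in unrelated tissues.

`multimorbinet` implements an interactome-based pipeline that resolves
multimorbidity to the cell-type level.  Its inputs are four standard
objects: an undirected gene–gene interaction network merged from one or
more edge lists; a gene × cell-type expression matrix; gene–disease
association tables; and a pathway catalog in GMT format with an optional
hierarchy.  Its outputs are Multimorbidity Scores (MS) between disease
pairs/triples per cell type, Perturbation Scores (PS) for pathways per
(cell type, disease), mechanism calls, and ranked candidate genes.

## The model, stage by stage

### Expression specificity

Raw expression is standardized per gene across cell types,

$$e_{g,c} = \frac{E_{g,c} - M_g}{\mathrm{MAD}_g},$$

with $M_g$ the median and $\mathrm{MAD}_g$ the *raw* median absolute
deviation (no 1.4826 consistency factor — the robust spread is used as a
unit, not as a normal-sd estimate).  Genes with $\mathrm{MAD}_g = 0$ carry
no usable signal and are excluded (dividing by zero has no meaningful
continuation; treating constant genes as everywhere-specific would be
worse).  A gene is then *specific* to cell type $c$ iff

$$|e_{g,c}| \ge k \cdot \mathrm{IQR}(e_{g,\cdot}), \qquad k = 1.5,$$

the conventional 1.5×IQR outlier fence read multiplicatively.  Two
conventions are fixed so that results are exactly reproducible: quantiles
use linear interpolation (R's default type 7), and the IQR is computed on
the signed normalized values while the comparison uses their absolute
value.  Genes with zero IQR are never specific.

### Cell-type-specific networks

The network of cell type $c$ is the subgraph induced by *edges* joining
two $c$-specific genes; a specific gene with no specific interactor is
excluded.  Disease-gene enrichment per network is a one-sided Fisher's
exact test (equivalently the upper hypergeometric tail, which is how it
is computed) over the restricted universe — the intersection of
interactome genes and expression-profiled genes — with Benjamini–Hochberg
adjustment taken jointly across all (cell type, disease) pairs, the widest
and most conservative family.

### Pathway catalog preparation

Hierarchical catalogs trade specificity against coverage; one hierarchy
depth (default 3) is selected, then near-duplicate pathways are removed:
while any surviving pair has Sörensen–Dice overlap
$2|A \cap B|/(|A|+|B|)$ strictly above 0.5, the worst-overlapping pair is
resolved by discarding its smaller member (greedy by worst pair).  Ties on
overlap resolve toward the lexicographically earliest pair, ties on size
remove the lexicographically later id — determinism was preferred over any
unstated original ordering, and the procedure is verified to be
order-independent.  Since no formula for within-network pathway
connectivity is fixed by convention, two candidates are reported side by
side (internal edge count, and fraction of in-network pathway genes with
an internal edge) and both are labelled implementation-defined.

### Propagation and top-scoring sets

Disease genes present in a cell network become seeds with score 1, all
other genes 0.  Scores then spread by damped, degree-averaged message
passing:

$$s_g \leftarrow s_g + \lambda \cdot \frac{1}{\deg(g)} \sum_{n \in N(g)} s_n,$$

iterated `iterations` times (default 2), the whole pass repeated
`repetitions` times (default 3); between repetitions scores are
renormalized to $[0,1]$ and seeds reset to 1 so they retain maximal
influence.  This is a documented reimplementation of NetScore-style
guilt-by-association scoring, not a reproduction of any particular
codebase; all parameters are exposed, and a random-walk-with-restart
scorer (restart 0.5) can be substituted for robustness checks.

The damping factor $\lambda$ (default 0.25) is the one genuinely new
numerical choice, and it exists for a verifiable reason: an undamped
accumulation rule lets a low-degree gene two steps from the seed absorb
its hub neighbour's full score and overtake genes adjacent to the seed.
Exhaustive evaluation over every connected graph on up to 6 nodes and
every seed placement (164,030 cases) shows the undamped rule violates
distance monotonicity in thousands of cases, while any $\lambda \le 0.3$
yields zero violations at the default regime.  With damping, single-seed
scores are non-increasing in shortest-path distance — the property a
proximity score must have for "closeness to disease genes" to mean
anything.

Scores are z-standardized within the cell network using the population
standard deviation, and the top-scoring set is a threshold rule,
$S^c_d = \{g : z_g \ge 2\}$.  A threshold (rather than a fixed-size
top-k) is essential: it lets $|S|$ vary when seeds are randomized, which
the perturbation-score null requires to be non-degenerate.  A consequence
worth knowing: if a disease's seeds make up more than roughly 15–20% of a
cell network, no gene can reach $z = 2$ (for a two-point score
distribution the maximal z is $\sqrt{(1-p)/p}$) and $S$ is empty; such
(cell, disease) rows are flagged degenerate rather than silently scored.

### Multimorbidity Score

$$MS^c_{d_1,d_2} = \frac{2\,|S^c_{d_1} \cap S^c_{d_2}|}{|S^c_{d_1}| + |S^c_{d_2}|},$$

and for triples the generalized form $3|\cap|/\sum|S_i|$ (a mean-of-
pairwise variant is available behind a flag).  $MS = 0$ means detached
mechanisms, $MS = 1$ identical ones.  Significance comes from a
degree-matched permutation null: each disease's seeds are replaced by
random genes drawn within log2 degree bins of the cell network (bins are
widened with a warning when too sparse), propagation and selection are
re-run, and the add-one estimator

$$p = \frac{1 + \#\{MS_{perm} \ge MS_{obs}\}}{1 + n_{perm}}$$

is reported — never exactly zero, never above one.  Degree matching
matters because hubs reach more of the network; a null ignoring hubness
would anti-conservatively flag any hub-seeded disease pair.

### Perturbation Score and mechanisms

Two PS readings ship because two are in circulation and they are not
equivalent:

* **printed** (default): $PS = (n_p^{net}/n_p^{tot}) / (|S|/N)$ — the
  pathway's representation in the network against the top set's share of
  it.  This matches the worked arithmetic ((9/20)/(13/225) = 7.79) but is
  independent of *which* genes are in $S$: within one network every
  pathway shares the same null behaviour.
* **overlap**: $PS = (|p \cap S|/|S|) / (n_p^{net}/N)$ — enrichment of
  pathway genes inside $S$.  This is the variant that distinguishes
  pathways and the one recommended for actual analyses.

The null re-runs propagation from degree-matched random seed sets and
recomputes PS; permuted top sets are shared across pathways within one
(cell, disease), which makes testing a whole catalog cheap.  A pathway
significantly perturbed ($p < \alpha$, default 0.05) by two or more
diseases in the same cell type is called a candidate mechanism, reported
once under the maximal disease combination.

### Candidate genes

A gene in $\ge 2$ top-scoring sets of one cell type (all 3 for the
triple) is a multimorbidity candidate.  Its combination score is the
arithmetic mean of its z-scores over the combination's diseases, with the
cell network's full score vector as the reference population for z.
Candidates are ranked by the mean of their available combination scores
(stable lexicographic tie-break) and flagged *novel* iff absent from every
input disease gene set.

## The synthetic-data generator

Real inputs for this kind of analysis are large curated downloads; the
generator produces structurally faithful miniatures with known ground
truth, which is what every statistical claim in the test suite is measured
against.

* **Interactome**: preferential attachment (default 500 genes, mean
  degree 10) for a connected, heavy-tailed graph; a configuration-model
  alternative is included.
* **Expression**: per-gene log-normal baselines with multiplicative
  cross-cell-type variation following a scaled arcsine (beta(1/2,1/2))
  law — bounded and bimodal, an on/off-like profile typical of broad
  compendia.  The arcsine choice is deliberate: under Gaussian variation
  the 1.5×IQR fence misfires on ~9.5% of unplanted (gene, cell) pairs at
  8 cell types, violating the ≤5% false-positive design contract; under
  the arcsine law it sits near 4–5%.  Planted specific pairs are shifted
  upward by `specificityEffect` (default 6) times the gene's noise scale.
  No gene is randomly planted in more than 2 of 8 cell types: a gene
  shifted in 3+ cell types contaminates its own quartiles and becomes
  unrecoverable by the fence rule — and marker genes specific to one or
  two cell types are the realistic case anyway.
* **Disease modules**: connected subgraphs (default 12 genes) grown from
  random anchors, overlapping pairwise through a shared connected core of
  `round(overlap × size)` genes, so Dice overlap ≈ the overlap parameter.
* **Pathways**: random background sets (depths cycling 1/2/3), pathways
  planted inside the modules' shared core at depth 3, and constructed
  redundant near-copies (Dice > 0.5) to exercise the filter.
* **Scenario**: in the default `"module"` model, disease modules are
  planted as specific genes of exactly 2 designated "multimorbid" cell
  types — the minimal structure that makes MS cell-type-resolved.  In the
  `"random"` (null) model, seeds are uniform draws with no planted
  structure; because the permutation null also draws degree-matched
  random sets, observed and permuted statistics are exchangeable there
  and p-values should be uniform.

What the generator does *not* emulate: array-platform artifacts, sample-
level structure, correlated expression along network edges, realistic
pathway size distributions, or literature-bias in gene–disease
annotations.  Passing tests therefore demonstrate internal statistical
correctness and recoverability of planted structure — not performance on
any real compendium.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `k` | 1.5 | IQR fence multiplier for specificity |
| `depth` | 3 | pathway hierarchy level retained |
| `overlapThreshold` | 0.5 | Dice overlap above which the smaller pathway is dropped |
| `repetitions`, `iterations` | 3, 2 | propagation outer/inner loops |
| `damping` | 0.25 | neighbour-mean damping (≤ 0.3 keeps distance monotonicity) |
| `zCutoff` | 2.0 | top-scoring threshold on z |
| `nPerm` | 1000 | permutations for MS/PS nulls |
| `alpha` | 0.05 | significance level for mechanism calls |
| `psVariant` | printed | PS formula; `"overlap"` recommended for analyses |

Every stage draws its randomness from one mandatory configuration seed
through a fixed per-stage derivation, so a pipeline run is reproducible
end to end (`runPipeline` writes a manifest with per-stage output hashes
to prove it).

## Numerical and degenerate-input choices

* Quantiles: type 7 everywhere; MAD without consistency constant.
* Genes with MAD = 0 are excluded and reported; zero-IQR genes are never
  specific.  (Under type-7 quantiles a zero IQR actually implies a zero
  MAD, so the second rule is a guard rather than a reachable state.)
* Empty top-scoring sets give MS = 0 with a degeneracy flag, not an
  error; pathways absent from a network are flagged and get no p-value.
* Zero cells in association tables get the Haldane–Anscombe 0.5
  correction before the log odds ratio.
* The add-one permutation estimator bounds p in \[1/(n+1), 1\].
* Redundancy filtering and candidate ranking have total, documented tie
  orders so results are independent of input order.

## Problem sizes used for validation

The simulation suites run at deliberately modest sizes chosen as the
package's standard validation conditions: 500-gene interactomes, 8 cell
types, 3 diseases with 12-gene modules, 200 permutations, 500 null
replicates for calibration and 50 planted replicates for recovery.  At
these sizes the full validation battery completes on a laptop-class
single core.

## Known limitations

* **Discrete permutation statistics are conservative.**  MS has a rich
  value set and its permutation test calibrates to nominal level on null
  scenarios (~5% rejections at α = 0.05).  PS does not: the printed
  variant is a deterministic function of the integer $|S|$, and the
  overlap variant rides on small overlap counts; massive ties make the
  add-one estimator strictly conservative (observed rejection ~1–2.5% at
  α = 0.05 on 120-node networks).  This is a structural property of
  count-valued statistics in small networks, not a coding artifact; PS
  p-values in small networks should be read as upper bounds.
* Propagation distance-monotonicity is verified exhaustively for small
  graphs and a damping ≤ 0.3; it is not a theorem for arbitrary graphs.
* Gene identity is by case-sensitive symbol string; identifier mapping is
  upstream of this package.
* Sample-level filtering of the expression compendium is treated as
  upstream of the matrix input.
* The pipeline's functions and `runPipeline()` are the interface; there
  is no shell wrapper, since the natural user of an R package drives it
  from R.
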