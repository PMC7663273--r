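---
title: "Fuzzy proteochemometrics: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy proteochemometrics: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuzzyPCM)
```

## The problem

Given a test protein, a test compound, and a training set of proteins with
curated ligand interactions, fuzzyPCM estimates whether the pair interacts.
Three situations arise in practice: a new compound against known targets
(classical SAR territory), a new protein against known ligands (sequence
comparison territory), and — the hard case — a pair in which *both* objects
are new.  The package handles all three with one integration formula whose
only moving part is how the per-protein "belonging coefficients" are
obtained.

## The model

### Sequence layer

A test sequence $Q$ (length $m$) is compared with each training sequence
$K$ through ungapped segments of fixed frame length $F$.  For a segment
starting at $i$ in $Q$ under shift $h$,

$$R_{ih} = \sum_{j=i}^{i+F-1} \mathrm{sim}(q_j, k_{j+h}),$$

with residue identity as the similarity metric (1 if the residues are equal
standard amino acids, else 0; ambiguous residues B, Z, X never match).  The
positional score of position $p$ is the best full segment covering it at
any shift:

$$S_{pk} = \max_{h,\,i:\ p-F < i \le p} R_{ih}.$$

Segments must lie fully inside both sequences: the sum has exactly $F$
terms, and any overhang convention would need padding semantics the model
does not define.  Positions near the ends still receive scores because some
window with $p-F < i \le p$ remains valid whenever $|Q| \ge F$.  Both
shifts' signs are enumerated, subject only to containment in $K$.

### Integration layer

Each training protein $k$ carries coefficients $a_k$ (ability to interact
with compound $C$) and $b_k$ (inability).  The per-position integrated
score, its arcsine-scale average, the sequence-free prior, and the final
estimate are

$$t_p = \frac{\sum_k S_{pk}(a_k - b_k)}{\sum_k S_{pk}(a_k + b_k)}, \qquad
t = \sin\Bigl[\tfrac1m \sum_p \arcsin t_p\Bigr],$$

$$t_0 = \frac{\sum_k (a_k - b_k)}{\sum_k (a_k + b_k)}, \qquad
B(C) = \frac{t - t_0}{1 - t\,t_0}.$$

$B$ ranges from $-1$ (no interaction) to $+1$ (interaction); $0$ is the
undetermined result.  $B$ contrasts what the sequence similarity says
against what the coefficients alone would say: a protein resembling the
interactors more than the prior expects scores positive.

In **binary** mode, $(a_k, b_k)$ is $(1,0)$ for an established interactor
of $C$, $(0,1)$ for an established non-interactor, and $(0,0)$ for an
unmeasured pair, which then drops out of every sum.  In **fuzzy** mode,
$a_k = P_a$ and $b_k = P_i$ from the ligand-structure classifier below —
this is what makes a prediction possible when $C$ has no measured targets
at all.

### Ligand layer

Compounds are fingerprinted by multilevel-neighborhood-of-atoms (MNA)
descriptors: the level-0 descriptor of an atom is its element with the
hydrogen count (`CH3`, `OH`, ...), and level $k$ appends the sorted
multiset of the neighbors' level-$(k-1)$ strings.  The set over all atoms
and levels 0..L (default L = 2) is the fingerprint; it depends only on the
molecular graph, so atom order is irrelevant.

Per target, a naive-Bayes model counts each descriptor's occurrences among
the target's interacting and non-interacting ligands.  For a query
compound, each class's Laplace-smoothed log-odds (α = 1) is computed
against the target's whole ligand pool as background and squashed through
the logistic, giving $P_a$ from the interacting class and $P_i$ from the
non-interacting class.  Computing both classes against a common background
— rather than against each other — keeps $P_a$ and $P_i$ independent
estimates (they need not sum to 1), which matches their downstream role as
two separate weights.  Descriptors unseen in the target's pool carry no
evidence, so a compound sharing nothing with the training data receives
exactly the prior.  A target whose non-interacting class is empty after a
leave-one-out exclusion is flagged degenerate and falls back to the global
negative prior for $P_i$; curated sets contain few explicit negatives, so
failing instead would disable many targets.

## Curation

Raw affinity records (IC50, Ki or Kd; nmol/L) are integrated per pair
against a cutoff (1.0 or 10.0 µmol/L):

1. Fixed values always win; the median (mean of central two when even)
   is compared inclusively with the cutoff.
2. A mix of upper and lower bounds without fixed values is excluded —
   whether the areas fail to intersect (<100 with >5000) or bracket a
   two-sided range (>100 with <5000).  Touching bounds count as
   non-intersecting.
3. Lower bounds only: index 0 if the maximal bound exceeds the cutoff
   (strictly), else excluded.
4. Upper bounds only: index 1 if the minimal bound is below the cutoff
   (strictly), else excluded.

Ligand structures are normalized by the chemistry toolkit at its defaults;
the curator then removes charged compounds, removes masses strictly above
1250 Da, and merges records with identical MNA set and molecular weight
(the same compound under two registry ids).  If merged twins carry
contradictory indices for the same protein, the pair is dropped as
contradictory data.  Finally the eligibility fixpoint iteratively removes
proteins with fewer than three established (index 1) ligands and ligands
with fewer than three established targets; index-0 links do not count
toward the thresholds.  The result is the unique maximal feasible sub-map,
independent of removal order (tested against one-at-a-time greedy removal
in random orders).  Each (parameter, cutoff) dataset is built
independently; a pair excluded under one parameter may well be present
under another.

## Evaluation scenarios

All three scenarios are leave-one-out and pool every scored pair of a
dataset into one ROC; AUC is the midrank Mann–Whitney statistic (a
per-ligand macro-average is available behind a flag).  Only pairs with a
curated index are scored — unmeasured pairs are not assumed negative.

1. **New ligand**: each ligand is removed from the Bayes statistics and
   scored against its indexed targets by $P_a - P_i$.
2. **New target**: each protein is held out; $B$ is computed in binary
   mode for its indexed ligands.  A ligand losing its last established
   interactor when the protein is removed is skipped with a warning.
3. **Both new**: the double LOO — the protein leaves the sequence set and
   the ligand leaves the Bayes statistics; fuzzy $(P_a, P_i)$ coefficients
   replace the binary ones.  Truth labels remain the binary indices.

## Numerical choices

* Zero denominators in $t_p$ and $t_0$ mean "no information" and yield the
  neutral value 0, consistent with $B = 0$ being the undetermined result.
* $t = t_0$ (including both $\pm 1$) gives $B = 0$ exactly; at the
  removable singularity $|1 - t t_0| < 10^{-12}$ with $t \ne t_0$, the
  limit $\mathrm{sign}(t - t_0)$ is returned.
* arcsine inputs are clipped to $[-1, 1]$; excursions beyond $10^{-9}$ are
  an error rather than silently clipped.
* All sorts are lexicographic and no randomness enters fitting or
  prediction, so outputs are bit-stable.
* The scoring kernel is C++ (one pass per diagonal with a running window
  sum); it is tested for exact equality against a naive enumeration of all
  (i, h) segment pairs.

## The synthetic benchmark

Real curated sets from public bioactivity databases are external inputs;
the package instead ships a generator whose defaults define the test
conditions used throughout: 5 specificity classes, 40 proteins of length
300, 120 ligands, full class-matched measurement coverage plus mismatched
pairs measured with probability 0.5, fixed values 10–500 nM for
interactors and 30–500 µM for non-interactors (safely on either side of
both cutoffs), 15% of pairs converted to label-preserving interval
brackets, and no label noise by default.  Proteins are per-class random
templates (5% per-copy mutation) carrying a planted 20-residue class
motif; ligands are alkyl scaffolds ending in a class-specific functional
group.  One seed drives all randomness; the generator restores the
caller's RNG state.

This emulates the *structure* of a curation problem — heterogeneous
relations, duplicate compounds, eligibility cascades, class-determined
interaction — but not real data's difficulty: real protein families share
ancestry rather than being independent templates, real ligand classes
overlap chemically, and real labels are noisy and biased.  Passing the
pipeline checks therefore demonstrates correctness of the machinery, not
the accuracy level to expect on real bioactivity data.  On these defaults
the planted signal is strong by construction, and the expected qualitative
ordering (the double-LOO scenario at or slightly below the known-ligand
scenario) is asserted rather than any real-data AUC.

Problem sizes in the shipped tests (toy 4×4 set, 8-protein/16-ligand
quick fixture, and the 40×120 default fixture for the pipeline checks)
were chosen so the whole suite runs comfortably on a laptop.

## Known limitations

* Identity is the only shipped residue metric; the plug-in point for
  substitution matrices exists but is untested territory.
* No gapped alignment and no per-frame ensembling: each frame (7 or 30) is
  evaluated separately.
* The Pa/Pi estimator is a documented surrogate of the original activity-
  spectra software's unpublished calibration; absolute probability values
  are not comparable with it, only the induced rankings.
* $B$ is not calibrated to a posterior probability.
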