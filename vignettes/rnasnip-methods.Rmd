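---
title: "Scoring local RNA structure disruption by point mutations"
author: "rnasnip package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring local RNA structure disruption by point mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnasnip)
```

## The problem

A single nucleotide substitution can reshape the equilibrium ensemble of
secondary structures of an mRNA or noncoding RNA and thereby disturb a
regulatory element — a riboSNitch.  Global comparisons of wild-type and
mutant ensembles dilute such effects: on long molecules, small
probability fluctuations far from the variant accumulate and drown the
local signal.  This package scores the *local* structural change: it
finds the sequence interval over which the two ensembles differ most,
and calibrates that score against simulated null distributions so that
each variant receives an empirical P value.

## Ensembles and their comparison

For a sequence $x$, the Boltzmann ensemble assigns each secondary
structure $\psi$ probability $p_x(\psi) \propto e^{-E(\psi,x)/RT}$.  The
ensemble is summarized by the base pair probability matrix $P$ with
entries $P_{ij}$, computed by McCaskill's inside–outside dynamic
program.  Wild-type and mutant matrices $P$ and $P^*$ are compared by

* the Euclidean distance $d(P,P^*) = \sqrt{\sum_{i<j}(P_{ij}-P^*_{ij})^2}$
  (each unordered pair counted once),
* the Pearson correlation $r(P,P^*)$ over the same entries,
* the same two measures on positional profiles: the total pairing
  probability $\pi_i = \sum_j P_{ij}$, or its upstream/downstream split
  $\xi^<_i, \xi^>_i$ (the unpaired probability $\xi^0_i$ is determined
  by these and excluded), and
* the ensemble distance $\delta$, the Euclidean distance between the two
  structure distributions themselves, computed from partition functions
  with halved thermal energy plus a cross term over structures formable
  by both sequences with averaged energies.

### Localization

For an interval $[k,l]$, restricted profiles
$\pi_i[k,l] = \sum_{j \in [k,l]} P_{ij}$ are evaluated in constant time
per position from the interval pairing tables $M_{ik}$ (probability that
$i$ pairs into $[k, i-1]$) and $N_{il}$ (into $[i+1, l]$).  The local
disruption score is

$$d_{\max} = \max_{[k,l]}\; d_{[k,l]}(\pi, \pi^*), \qquad
  r_{\min} = \min_{[k,l]}\; r_{[k,l]}(\pi, \pi^*),$$

maximized/minimized over all intervals of length at least `minLen`
(default 50 nt) that are *self-contained*: the expected number of base
pairs inside the interval must be at least $\alpha$ (default 1) times
the expected number of positions pairing across its boundary, for the
wild-type or the mutant ensemble.  Base pairs with probability below
`pThr` (default 0.01) are discarded beforehand as noise; the filter is
applied uniformly, also inside the self-containedness sums.  Ties
resolve to the smallest start, then the smallest end, which makes the
optimizer deterministic.  If no interval can be scored (possible for
$r$ when every admissible restriction is constant, e.g. on structure-free
sequences), the full sequence is reported with an undefined score and
P value 1.

The profile basis ($\pi$) is the package's default for $d_{\max}$ and
$r_{\min}$: it is the quantity the $M/N$ recursion serves and the basis
of the scanning approximation below.  The full-matrix and $\xi^{<>}$
bases are available as options and are used in the measure-comparison
study (`measureCorrelationStudy()`), which reproduces, at reduced scale,
the observation that all $P$-derived local measures rank variants
similarly while $\delta$ behaves differently.

### Scanning approximation for long sequences

Long molecules are folded with a scanning method: pair probabilities
are averaged over all windows of length $W$ (default 200) containing
the pair, and pairs with span beyond $L$ (default 120) are excluded.
The built-in engine folds every window globally and applies the span
cap to the averaged output; at the sequence ends only fully contained
windows enter the average (the window set is truncated, not extended or
re-centred — scanning engines differ in their end heuristics and this
is the simplest defensible convention).  The screening score

$$d^\#(k)^2 = \sum_{i=k}^{k+h'-1} (\hat\pi_i - \hat\pi^*_i)^2$$

integrates differences of span-limited profiles
$\hat\pi_i = \sum_{|j-i|\le h''} P_{ij}$ over a short window of
$h' = 20$ positions (the size of a typical protein or miRNA binding
site), with pair span capped at $h'' = 120$.  A sliding recursion
updates $d^\#$ in constant time per position.  The integration window
is $[k, k+h'-1]$ — exactly $h'$ positions; conventions differ by one
position in the literature and this one keeps window counts symmetric.
After locating the peak $k^*$ (smallest position on ties), the exact
restricted distance is re-optimized over ends
$l \in (k^*, \min(n, k^* + h'' + h')]$; the cap keeps the exact step
within the span the scanning fold could see.  When a variant is given,
the scan covers starts within $h''$ of the substituted position:
profile differences vanish beyond the reach of the windows containing
the variant, so a genome-wide scan per variant would only re-discover
the same peak.

## Folding engines

Two engines stand behind every operation:

* **builtin** — an exact McCaskill inside–outside implementation over a
  deliberately simple energy model: each admissible pair (GC, AU, GU)
  contributes a fixed energy (defaults $-3$, $-2$, $-1$ RT) and hairpin
  loops enclose at least 3 bases.  This model is *not* meant to rival
  nearest-neighbour parameters; its purpose is verifiability.  Every
  quantity the package computes — pair probabilities, profiles,
  restricted measures, $\delta$ — is checked against exhaustive
  enumeration of all structures for sequences up to 12 nt, to $10^{-8}$.
  The recursions rescale by a per-nucleotide factor so partition
  functions of several-hundred-nt sequences stay inside double range;
  probabilities are scale-invariant.  The ensemble distance combines
  five partition functions that almost cancel near $\delta = 0$; they
  are evaluated in extended precision under one common scale.
* **thermo** — the ViennaRNA programs `RNAfold -p` (global) and
  `RNAplfold` (scanning) invoked on multi-record FASTA batches.  This
  is the production engine; the Gumbel calibration below behaves best
  under it.

A practical note on the scanning fold: the window-averaged matrix is
not the marginal of any single ensemble, and its per-position sums can
exceed 1 (RNAplfold output shows the same behaviour).  Probability
conservation is therefore only asserted for global folds.

## Empirical P values

A raw distance is meaningless without a reference: the same $d_{\max}$
can be extreme for one sequence composition and typical for another.
Null distributions are simulated by drawing random sequences (i.i.d.
residues with a target G+C content), applying one random substitution
at a stated position, and scoring the variant through the *same*
pipeline as real data.  Distances $d$ follow an extreme-value law: the
transform $x = 1 - \log d$ is fitted by maximum likelihood with a
Gumbel distribution ($d = 0$, meaning no structural change, is excluded
from the fit and assigned P value 1 by convention).  Correlations are
fitted by a beta distribution after $y = (r+1)/2$.  The P value of an
observed $d$ is the Gumbel CDF at $1 - \log d$ — the transform is
decreasing, so this is the upper tail of $d$; for $r$ it is the beta
CDF at $y$.

Fitted parameters are tabulated per (sequence length, G+C bin,
substitution position) cell and persisted as JSON.  Positions are
binned by their *mirrored* relative position $\min(p, n-p+1)/n$: for
i.i.d. random sequences the null law is exactly invariant under
sequence reversal, so positions $p$ and $n+1-p$ share a cell, halving
the simulation cost.  Position binning matters: near the sequence ends
a substitution can reach fewer pairing partners and null scores run
systematically lower, so a single central bin would overstate P values
there.  Queries clamp G+C to $[0.2, 0.8]$ and use the nearest cell.
A full production-scale grid (lengths 400–1600 in steps of 100, G+C
20–80% in steps of 10, positions per nucleotide, thousands of draws per
cell) is reproducible with `buildBackgroundTable()` given compute; the
tables built by the tests and the acceptance script restrict the grid
to the cells their queries touch (one length, one G+C bin, four
mirrored position bins) — a problem-size choice, not a method change.

Two diagnostics accompany every fit.  `ksCheck()` reports the
Kolmogorov–Smirnov statistic of the transformed sample against the
fitted family, warning (not failing) on deviation.  The fit-quality
statistic $\rho$ — the Pearson correlation between fitted and
rank-based P values on a null sample — is computed by
`fitQualityStudy()`.  A model-dependence finding worth stating plainly:
under the thermodynamic engine the transformed null is almost exactly
Gumbel-shaped (skewness $\approx 1.2$; held-out P values uniform, KS
$p \approx 0.85$), while under the builtin pair-energy model it is
nearly symmetric, so the Gumbel family fits the bulk imperfectly (KS
rejects, with deviations at *large* P).  The decision-relevant region
is calibrated for both engines — the fraction of null variants below
$P = 0.1$ sits inside the exact binomial band, and $\rho \ge 0.99$ —
but full-range uniformity should only be expected from the
thermodynamic route.

## The three analysis modes

1. **Mode 1 (exact, short range).**  A window of $\pm$`winsizeFold`
   (default 200 nt, adjustable 200–800 in multiples of 50) around the
   substitution is cut out — clipped one-sidedly at sequence ends, with
   the P value lookup using the actual folded length — folded globally
   for both alleles, and $d_{\max}$ and $r_{\min}$ reported with their
   P values.  Multi-substitution variants are centred on their mean
   position and must fit one window.
2. **Mode 2 (scanning, long range).**  The full sequence is folded with
   the scanning method, $d^\#$ locates the peak near the variant, and
   the anchored exact re-optimization yields the reported score.
3. **Mode 3 (screening).**  All $3n$ substitutions of a sequence are
   scored in stage 1 by $d^\#$ against its own background table;
   candidates with $P < t_1$ (default 0.4) are re-scored through the
   mode-1 path, and variants with refined $P < t_2$ (default 0.1) are
   reported.  Each stage is calibrated against a table built with its
   own folding route (`stage2Config` lets the refinement stage run a
   different engine), but the *joint* flagged rate is only close to
   nominal when both stages share one energy model: the two P values
   must co-vary, and mixing engines decorrelates them — in the
   independence limit the two-stage rate would fall to
   $t_1 \cdot t_2 = 4\%$.  Reported intervals are merged into maximal
   regions with the count of supporting variants.

On a calibrated null with engine-consistent stages, stage 1 passes
roughly its nominal $40\%$; because $d^\#$ only approximates the exact
interval distance, the final report retains somewhat less than the
nominal $10\%$ of null variants (the acceptance script computes this
rate from scratch).

## Synthetic data and what the tests show

`makeHairpinFixture()` builds molecules with one strong, aperiodic stem
(mixed GC/AU pairs pin the helix register; a pure GC stem would slide
between near-isoenergetic registers) in random low-GC context, with
labelled stem-breaking and loop (structure-preserving) substitutions.
Designed stem pairs fold at probability $> 0.5$; disruptive
substitutions abolish their designed pair and receive systematically
lower $P(d_{\max})$ than loop substitutions (sign test across seeded
fixtures).  `nullSample()`/`measureCorrelationStudy()` generate the
i.i.d. random-sequence conditions described above.

What this synthetic world does *not* emulate: real transcripts have
correlated composition, repeats, long-range structure beyond the span
caps, protein binding, and co-transcriptional folding.  Passing tests
demonstrate that the machinery is exact (against enumeration and brute
force), deterministic, and calibrated on its stated null — not that the
energy model predicts any particular molecule's biology.

## Numerical and design choices

* Coordinates are 1-based and inclusive everywhere.
* DNA input is accepted; `T` maps to `U` with a one-time message.
* Optimizer ties: smallest $k$, then smallest $l$; $d^\#$ peak ties:
  smallest $k$.
* Pairs with probability below $10^{-14}$ are skipped as potential
  *enclosing* helices in the outside recursion; the induced error is
  bounded by $n^2 \cdot 10^{-14}$, far below the $10^{-8}$ oracle
  tolerance.
* The interval optimizer evaluates profile bases in $O(n)$ per interval
  from row cumulants (the $M/N$ tables), and matrix bases in $O(1)$ per
  interval from triangle-recursion tables of the required sums, so the
  full scan is $O(n^3)$/$O(n^2)$ rather than $O(n^4)$.
* Dense matrices cap the practical sequence length at a few thousand
  nt; scanning results for full-length mRNAs beyond that would need a
  banded representation (a known limitation).
* Problem sizes used by the shipped checks: oracle equivalence at
  $n \le 12$ (100 sequences); optimizer equivalence at $n \le 200$
  (50 instances); fit quality from 1000 global-fold and 250–400
  scanning-fold null draws at length 400, G+C 0.5–0.6, substitution at
  position 200; screening calibration on one exhaustively screened
  400-nt null sequence (1200 variants) for the headline number and a
  length-300 variant in the tests; 20 hairpin fixtures.  These sizes
  are the package's reproducibility compromise; all of them scale up by
  changing arguments, not code.

## Limitations

The builtin energy model ignores stacking, loop entropies and dangles;
it exists for verifiability and speed, and P values under it use its
own null tables.  Indels are not supported (alignment of unequal-length
ensembles is a different problem).  The local version of $\delta$ and a
correlation-based scanning score are deliberately absent — the latter
because correlation measures perform poorly in the scanning regime.
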