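---
title: "Network enrichment analysis for driver prioritization: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network enrichment analysis for driver prioritization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netdriver)
```

## The problem

A tumor genome typically carries many somatic alterations, of which only a
few (the *drivers*) contribute to tumor fitness; the rest are *passengers*.
Frequency-based methods can only flag genes mutated recurrently across large
cohorts. netdriver instead scores each alteration in its **functional
context**: a driver should be unusually well connected, in a global
gene--gene functional-coupling network, to the other alterations of the same
genome and to known cancer pathways, whereas a passenger should look like a
randomly chosen gene of the same connectivity.

## The enrichment statistic

For a query gene $i$ and a gene set $G$ (with $i$ always treated as external
to $G$), let $n_{iG}$ be the number of network edges between $i$ and members
of $G$. Because node degrees in interactomes are heavy-tailed, $n_{iG}$ is
meaningless without a degree-aware null. The null is obtained by
Maslov--Sneppen rewiring: repeated double-edge swaps that preserve every
node's degree and the total edge count while erasing the specific wiring.
Over $R$ rewired replicas (default $R = 25$) the replica counts give
$\bar n_{iG}$ and $\sigma_{iG}$, and

$$z_{iG} = \frac{n_{iG} - \bar n_{iG}}{\sigma_{iG}},$$

converted to a one-sided upper-tail normal p-value (enrichment is
directional; a two-sided convention is available because significance
bridges in the literature quote either). A *shared-neighbor* variant counts
$\sum_{j \in G\setminus\{i\}} |N(i) \cap N(j)|$ instead of direct edges,
which is more sensitive on sparse networks. The same machinery applied to
within-set edge counts gives a *coherence* test for a whole gene set.

One ensemble of 25 rewired replicas per network (per master seed) serves
every test in a run: this matches the per-network randomization design and
makes cohort-scale runs tractable, at the cost of shared Monte-Carlo noise
across tests from the same run.

### Numerical choices for the randomization null

* The replica standard deviation uses `ddof = 1` (unbiased small-sample
  estimator over 25 replicas).
* **Degenerate null.** When all replica counts coincide
  ($\sigma_{iG} = 0$), $z$ is defined as 0 if the observation equals the
  null mean. If the observation differs, the only statement 25 unmoved
  randomizations support is the one-sided permutation bound
  $p \ge 1/(R+1)$, so $z$ is set to $\pm\Phi^{-1}(1 - 1/(R+1))$
  ($\approx \pm 1.77$ at $R = 25$) rather than an arbitrarily large value.
  This matters in practice: for a degree-3 gene against a 25-gene target
  set on a sparse network, all-zero replica counts occur with probability
  around 0.15, and treating the degenerate case as $z = \pm 40$ turned
  single chance edges into guaranteed driver calls. The bounded value also
  keeps degenerate cases below the benchmark's $z = 1.97$ ROC termination
  threshold.
* Rewiring performs `swap_factor` double-edge-swap *trials* per edge
  (default 100); trials that would create a self-loop or duplicate edge are
  rejected. Mixing is verified directly (edge-set Jaccard overlap with the
  original below 0.1 at the default), rather than by counting accepted
  swaps.
* Zero p-values entering Fisher's combination are floored at $10^{-300}$ so
  logarithms stay finite.

## The three parallel tests and their combination

Each alteration is evaluated by up to three independent tests:

1. **1point-vs-MGS** -- a point mutation against the rest of its own
   sample's mutated gene set (MGS; per-sample duplicates collapsed). MGSs
   with fewer than 3 mapped genes (after removing the query) are not
   amenable; the component is *skipped*, not imputed as $p = 1$, so the
   degrees of freedom of the combination shrink. Such genes can still be
   called through the pathway test, mirroring the observation that strong
   drivers often sit in small MGSs.
2. **1CNA-vs-MGS** -- a copy-number-altered gene against the MGS of every
   genome carrying the alteration; the per-genome one-sided p-values are
   combined with Fisher's method ($\mathrm{df} = 2 N_{\text{own MGS}}$).
3. **1-vs-CPW** -- any gene against the cancer-pathway (CAN) collection.
   Per-pathway z-scores are summed and divided by a normalization factor
   (default 10.16), because the member overlap of real cancer-pathway
   collections makes the per-set tests strongly correlated; the normalized
   sum is referred to the standard normal, with $z^* \ge 2.97$
   (i.e. $30.17/10.16$) as the significance cutoff. Negative per-pathway
   z-scores are included in the sum by default (a floor-at-zero option
   exists).

CNA genes additionally pass a **co-occurrence screen**: a gene qualifies as
a candidate driver only if its carrier-sample pattern co-occurs with at
least one point-mutated gene at a raw one-sided Fisher-exact $p < 0.01$
over the samples having both data types. The per-gene screen p-value is the
Bonferroni-corrected minimum over tested partners. CNA--CNA pairs are never
tested (contiguous segments make them positionally interdependent).

The available component p-values of each event are combined with Fisher's
method, $\chi^2 = -2\sum \ln p_i \sim \chi^2_{2k}$, ranked, and adjusted by
Benjamini--Hochberg within each event class (point events; CNA genes); an
event is called a driver when its adjusted combined p is strictly below
0.01. The components are not guaranteed independent, so combined p-values
should be read as a ranking device more than calibrated probabilities.

### Calibrating the 1-vs-CPW normalization factor

The default factor 10.16 is the published value, defined as the
no-intercept linear-fit coefficient of the summed CAN z-scores on the
super-pathway z-score for one particular large, strongly overlapping
cancer-pathway collection. The factor is a property of the *collection*,
not of the method: a collection of a few disjoint sets concentrates a
member's entire signal in one summand, and dividing by 10.16 would erase
it. `calibrate_cpw_factor()` therefore re-derives the factor for any
collection by the same recipe, regressing the summed z on the
super-pathway z over a probe panel (all mapped super-pathway members plus
an equal number of random non-members). `driver_scan(cpw_factor = NULL)`
applies this calibration automatically; the synthetic-cohort analyses use
it, since their five disjoint planted modules are structurally unlike the
collection the published factor was fit on.

## CNA calling

Gene-level $\log_2$ copy-number values are thresholded at
$|\log_2| > 0.35$ (strict), both gains and losses; a gene enters the
analysis only when called in at least 3 genomes. Both the threshold and
the genome minimum are exposed as parameters (`cna_tau`, `min_genomes`).

## Benchmarking candidate networks

Networks are compared by their ability to recapitulate known pathway
membership. For every set $G$ and member $i$, the true test
$z(i, G\setminus\{i\})$ is paired with a null test of a degree-matched
substitute gene (within a relative degree window of $\pm 10\%$, widened
geometrically until a candidate exists; never a member of $G$) against the
same target, so the true- and false-positive axes share their scale. ROC
curves sweep decreasing z thresholds, terminate at $z = 1.97$ (the lowest
formally significant score -- which is why the area under the curve is not
comparable between networks), and are summarized by the ratio $Y/X$ at the
first point where the empirical FDR $X/(X+Y)$ reaches 0.1, plus the total
count of recapitulated true members. Substitutes may be previously unknown
true members, so the false-positive estimate is conservative -- acceptable
for *comparing* networks. A curve that never reaches FDR 0.1 reports its
terminal ratio flagged as a lower bound; $X = 0$ reports an infinite ratio,
flagged.

## The synthetic-data generator

`synthetic_cohort()` produces a complete study with known ground truth:

* a Barabasi--Albert network (default 1000 genes, mean degree ~6) giving
  the heavy-tailed degree context of real interactomes;
* 5 disjoint planted modules of 15 genes with intra-module edge
  probability 0.6, collected as CAN pathways with their union as the
  super-pathway;
* 50 samples, each with 5 drivers drawn from one or two modules plus 20
  passengers drawn from non-module genes (mutation-class labels are
  arbitrary and never filtered on);
* per-module CNA segments: 10 contiguous genes on a synthetic chromosome,
  exactly one of which is a module gene (the planted CNA driver), shifted
  by $\pm 0.5$ in $\log_2$ units in 20% of samples over Gaussian noise
  (sd 0.1). Carrier samples also receive point mutations in two module
  partners adjacent to the driver in the network -- a CNA driver's
  co-occurring mutations are functionally coupled to it, which is exactly
  the structure the screen and the 1CNA-vs-MGS test exploit.

The generator reproduces the *statistical* structure the method assumes --
drivers network-adjacent to co-mutated genes and to cancer modules,
passengers degree-random, segment hitchhikers sharing the driver's carrier
pattern but not its wiring. It does not emulate mutation signatures,
subclonality, purity, or realistic per-gene mutation rates, so passing
tests demonstrate internal consistency and recoverability under the
method's assumptions, not performance on real tumors.

## Problem sizes and frozen test bounds

The test suite runs the full method at reduced but non-trivial scale,
chosen once as representative conditions: the default synthetic scenario
above for the end-to-end checks; ER(1000, mean degree 10) networks with
25 randomizations and 2000 null pairs for z calibration; 50 pairs against
the configuration-model closed form $k_i K_G / 2E$; ER(400) networks with
5 planted modules, 20 seeds, for the benchmark-dominance check. Empirical
bounds (driver-vs-passenger AUROC $\ge 0.90$, passenger call rate
$\le 0.05$, planted network beating its rewired counterpart in at least
19 of 20 seeds) were fixed from a one-time pilot at development seeds and
are enforced as regression bounds thereafter.

Two calibration facts from those pilots are worth knowing. First, the
|z| > 1.96 rate on true null pairs is about 6.9%, not 5%: with a 25-replica
empirical null the statistic has t-like tails, and the counts are discrete.
Second, per-pair deviations from the configuration-model closed form are
t-distributed, so the oracle check asserts that at least 46 of 50 pairs lie
within 3 standard errors rather than demanding all 50.

## Known limitations

* Component p-values are not independent, and the z-to-normal conversion
  extrapolates beyond what 25 randomizations can empirically support;
  combined p-values are ranking scores first.
* The co-occurrence screen is Bonferroni-conservative over partners and
  one-sided (enrichment only); mutual exclusivity is out of scope.
* Edge confidences are used only as a load-time cutoff; all statistics
  treat the network as unweighted.
* No identifier mapping is performed: gene symbols are uppercased and
  matched literally, and unmapped query genes are reported, not guessed.
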