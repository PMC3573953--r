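---
title: "Molecular species delimitation by minimum consensus: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular species delimitation by minimum consensus: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motudelim)
```

## The problem

Meiofaunal invertebrates — and many other poorly sampled groups — often
hide several reproductively isolated species under a single morphology.
Molecular delimitation methods can reveal these cryptic lineages, but
every method has a failure mode of its own: distance thresholds depend
on an a-priori species hypothesis, haplotype networks oversplit on
fast-evolving mitochondrial markers, and tree-based likelihood methods
are sensitive to the reconstruction of their input tree.  The strategy
implemented here is therefore deliberately conservative: several
independent delimitation methods are run in parallel on several
markers, and a pair of specimens is separated in the final *secondary
species hypothesis* (SSH) only when **no** method with data for both
places them in the same entity.  Entities recognised by only some
methods are ignored — at the price of false negatives (lumping), never
false positives (oversplitting), which keeps taxonomic inflation out of
downstream biogeography and conservation work.

`motudelim` implements that whole workflow — per-method partitions,
consensus, and a multispecies-coalescent benchmark generator that makes
the pipeline testable end to end without any downloads.

## Per-method models

### Distances and fixed thresholds

Pairwise distances are computed with pairwise deletion by default (each
pair is compared on the sites where both sequences are determined;
ambiguity codes are excluded like missing data).  `p` is the
uncorrected proportion of differing sites; `JC69` applies
$d = -\tfrac{3}{4}\log(1 - \tfrac{4}{3}p)$ and `K80` the two-parameter
form $d = -\tfrac12 \log\!\big((1-2P-Q)\sqrt{1-2Q}\big)$ with
transition/transversion proportions $P$ and $Q$.  Saturated pairs
(undefined logarithm, which deep mitochondrial divergences do produce)
are reported as `Inf` with a warning rather than an error, so that
threshold clustering still works.  Internally all distances are
fractions; percentages appear only in reports, rounded to two decimals.

`threshold_cluster()` takes the connected components of the graph with
an edge wherever $d \le t$ — single linkage, i.e. chaining below the
cutoff, which is what the classical "fixed threshold" tools do.  The
default pipeline applies the published 11% COI threshold for
congeneric molluscan species pairs.  `agreement_range()` inverts the
question: the interval of thresholds that reproduce a given partition
is $[\max_c h_c,\; d_{\min}^{\text{inter}})$, with $h_c$ the
single-linkage merge height of cluster $c$; an empty interval means no
threshold reproduces the partition.

### Automatic barcode gap discovery

`abgd_partition()` sorts all pairwise distances and scores every
consecutive rank gap by its width relative to the mean width of the
other gaps in a surrounding rank window (half-width
$\max(3, n/50)$ by default).  A gap qualifies if it ends above the
prior limit to intraspecific divergence $P$ — gaps entirely below $P$
are intraspecific by assumption — and its width exceeds $X$ times the
local mean.  Two numerical choices matter and are documented here
because they were genuinely open:

* among qualifying gaps the **most significant** one (largest
  width-to-local-mean ratio) is used, not the first by rank: with a
  hundred or more intraspecific gaps, the chance that some noise gap
  exceeds $X$ times its local mean is near one, so "first qualifying"
  systematically fires inside the intraspecific mode;
* when the local window is entirely tied (distances on short markers
  are quantised to multiples of $1/L$), the window carries no scale and
  the global mean gap is used instead — otherwise any positive gap
  adjacent to a tie block would be infinitely "significant";
* if the chosen gap does not actually disconnect the component (single
  linkage can chain across a rank gap), the next most significant gap
  is tried before giving up.

The initial split takes single-linkage components below the chosen
gap; the procedure recurses within each component until no gap is
found (depth-capped at 20).  No gap at the top level returns a single
cluster — the "no barcoding gap" outcome.  `prior_scan()` repeats this
over log-spaced priors and reports the range of priors over which each
distinct partition is stable.  The default $X$ follows the original
tool (1.5); the pipeline default is 1.2, the setting under which the
gap is recoverable on data of this shape.

### Statistical parsimony networks

`parsnet_partition()` collapses identical sequences into haplotypes
(under the site-exclusion rule an ambiguous site cannot separate two
sequences, so collapsing may chain through ambiguous intermediates —
this is intentional and documented), counts mutational steps between
haplotypes (a contiguous gap run counts as one step, treating an indel
as a single event; `gap_mode = "ignore"` is available), and connects
haplotypes up to the connection limit $j^\*$.  The probability that a
$j$-step connection is parsimonious is modelled as the probability
that $j$ substitutions hit $j$ distinct sites when each substitution
lands uniformly on one of $L$ sites,
$P_j = \prod_{i=0}^{j-1}(1 - i/L)$, and $j^\*$ is the largest $j$ with
$P_j \ge 0.95$ (the classical confidence level; configurable).
Unconnected networks are the candidate entities; network-internal
topology is never computed because only the component structure is
used for delimitation.  On data of the study's shape this method
oversplits relative to the consensus — as its original application
did — which is harmless under the minimum-consensus rule.

### Single-threshold GMYC

`gmyc_fit()` places a single age threshold $T$ on an ultrametric tree.
Nodes older than $T$ are treated as diversification events of a
Yule-type process with hazard $\lambda_1 k^{p_1}$ ($k$ =
species-level lineages, singleton lines included); nodes younger than
$T$ are within-cluster coalescences with class hazard
$\lambda_2 \sum_c (m_c(m_c-1))^{p_2}$ over the clusters defined by the
lineages crossing $T$.  Each inter-event interval $x_i$ contributes
$h_i \exp(-H_i x_i)$, where $H_i$ is the total hazard during the
interval and $h_i$ the hazard of the class of the closing event —
competing risks over the waiting times, so the null and alternative
models are densities over the same outcome.  A coalescent event is
scored on its tipward side (the interval it closes in backward time),
the textbook convention for coalescent likelihoods.

Numerical design:

* candidate thresholds are the midpoints between consecutive distinct
  node ages (the likelihood only changes when the crossing pattern
  does), plus the degenerate threshold-at-root configuration;
* within a class, the rate $\lambda$ is profiled out analytically
  ($\hat\lambda = E/I(p)$ with $E$ events and exposure
  $I(p)=\sum_i a_i^p x_i$), leaving a deterministic one-dimensional
  search over the exponent $p \in [0, 8]$ — this replaces a
  multi-start quasi-Newton over four parameters and cannot be trapped
  in a local optimum of the profiled coordinate;
* the **null model** is the single-population coalescent
  $\lambda (n(n-1))^p$ over the whole tree, which is exactly the
  threshold-at-root configuration of the mixed model, so the
  alternative nests the null and the likelihood-ratio statistic is
  never negative.  The LR is referred to $\chi^2_3$ (three extra
  parameters); the mixture-boundary caveat applies and the test is in
  practice conservative here (about 1–2 rejections per 100 pure
  single-population coalescent trees at $\alpha = 0.05$);
* tied or zero node ages are perturbed by $10^{-9}\times$ root age
  with a topology-aware tie-break (a child never becomes older than
  its parent);
* `gmyc_delimit()` — the distance-based entry point used by the
  pipeline — collapses zero-distance specimens before building the
  UPGMA tree and expands the clusters afterwards.  Duplicate sequences
  create zero-length cherries whose "instantaneous" branching the
  continuous-rate model explains by driving the threshold to the tips;
  removing duplicates before a GMYC fit is standard practice.

Only the single-threshold model is implemented; fit records carry
`model = "single-threshold"` so results cannot be confused with
multiple-threshold variants.

### Reciprocal monophyly (primary species hypothesis)

`psh_from_trees()` enumerates clades of the concatenated tree from the
largest down and accepts a clade as a MOTU when no gene tree violates
its monophyly (fewer than two members present in a gene tree is
*insufficient data*, never a veto), its support meets the bar (default
75, a moderate bootstrap value; disabled when the tree carries no
supports), and it is not nested in an already accepted clade.  Every
unassigned ingroup leaf becomes a singleton MOTU; the "similar
relative branch length" criterion used informally in empirical work
has no published cutoff, so the terminal-branch/median-stem ratio is
reported as a diagnostic rather than used as a gate.  Outgroups are
excluded via an explicit ingroup list since monophyly statements are
meaningless across the root.

### Bayesian support aggregation

Posterior speciation probabilities from repeated runs (four prior
combinations on ancestral population size $\theta$ and divergence
times $\tau$, different algorithms and seeds) are averaged per node;
a node is supported at mean PP $\ge 0.95$ (inclusive), and flagged
ambiguous when some prior combinations support it and others do not.
The sampler itself is out of scope — results enter as tables, and
`bpp_partition()` turns a guide tree plus aggregated support into a
partition (unsupported splits collapse) that joins the consensus like
any other method.

## The minimum-consensus rule

"Uncontradicted positive identification" is formalised pairwise: the
SSH is the set of connected components of the graph with an edge
between two specimens whenever at least one data-bearing partition
lumps them.  Pairs covered by no method at all are also lumped —
never split on absence of evidence — and counted as *evidence-free*.
Consequences worth knowing:

* one lumping method vetoes a split supported by all others (the
  ambiguous-MOTU behaviour of the original study design);
* specimens missing a marker are still separated if the remaining
  markers separate them (this is why dropout species do not collapse);
* transitive chaining is possible: if method 1 lumps $a,b$ and method
  2 lumps $b,c$, then $a,b,c$ form one unit even if no method lumps
  $a,c$ directly.  This is a property of any conservative
  component-based rule and is covered by a dedicated test;
* methods enter unweighted, and with a single method the SSH is that
  method's partition (given full coverage).

`corroboration_report()` renders the result as a units-by-methods
matrix (split / lump / no data), the machine-readable analogue of a
method-by-entity summary figure.

## The benchmark generator

`build_benchmark_dataset()` emulates the statistical structure the
analysis assumes: a Yule species tree over 12 species, root age
`tau_scale`; per-species sample sizes drawn uniformly from 1–10 so
singletons occur; one coalescent genealogy per linkage group (16S and
COI share one mitochondrial genealogy at five times the nuclear rate;
28S is separate), with pairwise coalescence rate $2/\theta$
constrained within species-tree branches, so incomplete lineage
sorting emerges when internodes are short relative to $\theta$;
JC69/K80 sequences simulated site-independently; and complete COI
dropout for three randomly chosen species, mirroring universal
barcoding primers failing on some lineages.

Two generator choices deserve justification:

* **Node-age floor.** Interspecific divergences are compressed into
  `[min_depth_frac, 1] × tau_scale` (default 0.5).  The emulated
  system is an old radiation: its smallest interspecific distances are
  of the same order as its largest, and no splits date to the recent
  past.  An unconstrained Yule tree would place some splits arbitrarily
  close to the present, which describes a different (and much harder)
  inference problem than the one this analysis design addresses.
* **Scale calibration.** `theta = 0.002` and `tau_scale = 0.04`
  (separation ratio 20) were chosen once so that the simulated
  mitochondrial markers show maximum intraspecific p-distances of
  roughly 2–5% and minimum interspecific p-distances of roughly
  15–30%, the regime reported for the study system; they are settings,
  not hard-coded constants.

What the generator does **not** emulate: alignment error and masking,
indels, rate variation across sites, nuclear pseudogenes, population
structure within species, and migration/introgression.  A pipeline
that passes the recovery experiment is therefore validated for the
idealised regime "deep, old splits; shallow coalescence; clean
alignments" — not certified against contamination or recent-radiation
data.

## Validation and known limitations

The test suite verifies each operation against independent oracles
(exhaustive pair enumeration, a naive UPGMA, closed-form coalescent
and substitution expectations, brute-force consensus components) and
runs an end-to-end recovery experiment: at the study design with
reduced marker lengths (200/150/200 bp, which keeps the hundred-seed
experiment around a minute), the pipeline's SSH equals the true
partition in roughly nine datasets out of ten (96/100 on the test
suite's seed panel; 88–92% on other panels we measured).  The
residual failures are themselves informative and split into two
modes, both properties of the data rather than of the code.  In about
one dataset in twenty, a species lacking COI carries a deep
intraspecific coalescent divergence (8–15% on 16S) that *every*
covering method splits — on the observed markers the data genuinely
look like two species.  This is exactly the ambiguous-MOTU situation
reported in empirical work of this design, where such a split
survives only if one method happens to dissent.  And in about one
dataset in twenty-five, the minimum interspecific COI p-distance —
expected around 17% — fluctuates below the 11% threshold at 200 bp
(binomial noise with σ ≈ 2.7% and many pairs), so the fixed-threshold
method lumps a species pair and the conservative rule propagates the
lump; at full marker length this mode disappears.

Single-threshold GMYC deserves a caveat of its own: at a separation
ratio of 20 it recovers the exact true partition in only ~85% of
simulated gene trees, because deep intraspecific haplogroup splits are
absorbed as "young species" (its documented oversplitting tendency);
from ratio ~30 upward recovery is essentially complete.  In the
pipeline this is harmless — GMYC oversplits are vetoed by the other
methods — but GMYC output alone should not be read as a species
hypothesis on data of this shape.

Problem sizes used throughout the tests (a hundred specimens, markers
of a few hundred sites) were chosen as the scale at which the
experiments are informative yet quick to rerun; all constants are
arguments, and nothing prevents running the identical code on
full-length markers.

## A worked run

```{r, eval = FALSE}
library(motudelim)
bench <- build_benchmark_dataset(msc_sim_settings(seed = 1))
report <- run_pipeline(bench$alignments, seed = 1)
render_report(report)
partition_ari(report$ssh, bench$truth)
```
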