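---
title: "Methods: sex-biased networks and nodes of sexual conflict"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sex-biased networks and nodes of sexual conflict}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(sexbiasnet)
```

## The problem

Sexually reproducing species express a large fraction of their genome
differently in males and females. When a gene's interaction partners pull
it toward male- and female-favoured states simultaneously, the locus is a
candidate site of *interlocus sexual conflict*. sexbiasnet identifies such
candidates in two steps: it scores every gene's expression sex-bias from
male and female RNA-seq read depths, then overlays the scores on an
undirected gene–gene interaction network to find (i) *indirect* conflict
nodes — sex-unbiased genes wired to both strongly male- and strongly
female-biased partners — and (ii) *direct* conflict pairs — edges joining a
strongly male-biased gene to a strongly female-biased one.

## The sex-bias statistic

For samples $i = 1,\dots,k$ within one sex, let $N_{ig}$ be the total read
depth of gene $g$ in sample $i$ (a per-base depth sum over the gene's
coding sequence), $N_i = \sum_g N_{ig}$ the sample's total depth, and
$N = \sum_i N_i$. Each sample gets weight $w_i = N_i / N$, and the sex's
depth-weighted gene mean is $\bar N_g = \sum_i w_i N_{ig}$, with
$\hat N = N / k$ the average total per sample. The per-gene statistic is

$$ b_g = \log_2\!\left[ \frac{\bar N^m_g}{\bar N^f_g} \right] - B,
   \qquad B = \log_2\!\left[ \frac{\hat N^m}{\hat N^f} \right], $$

where $B$ is the global read bias that absorbs systematic depth differences
between the male and female libraries. Genes silent in every sample are
discarded; all other values are capped to $[-10, 10]$ (a 1000-fold
difference), which also maps genes expressed in only one sex to the cap
with the sign of the expressed sex, keeping ratios finite without a
pseudocount.

Three choices here were genuinely open and are worth stating:

* **Depth-proportional weights.** $w_i = N_i/N$ gives deeper samples
  *more* weight, the opposite of the usual per-library depth
  normalisation. We implement the definition verbatim rather than
  substituting the conventional inverse normalisation; the two agree
  exactly when libraries are equally deep, and the package's
  property tests (global-scale invariance, sex-swap antisymmetry, and a
  loop-based independent evaluation to 1e-12) pin down the implemented
  form. Weights, $N$ and $k$ are computed separately within each sex.
* **Cap after centring.** The cap is applied to the final value
  $\log_2(\bar N^m_g/\bar N^f_g) - B$, not to the raw ratio. Since the cap
  exists to keep one-sex-only genes finite, applying it last is the only
  order in which a single cap value achieves that for every gene.
* **Two classification schemes in one analysis.** Network labelling uses a
  four-fold window (`bias_scheme(2)`: $b > 2$ male, $b < -2$ female, else
  unbiased). Conflict detection is far more stringent: partners must
  exceed 32-fold ($|b| > 5$, strict inequality) and the focal unbiased
  gene must be within two-fold ($|b| \le 1$, inclusive). Genes between the
  two cutoffs are deliberately `unclassified` under the stringent scheme —
  they are neither credible conflict partners nor credibly unbiased — so a
  fourth label exists whenever `unbiased_cutoff < biased_cutoff`.

## Subnetworks and their summaries

The interactome is an undirected simple graph: all evidence types
(protein–protein, TF–target, genetic) are flattened, direction discarded,
reversed duplicates collapsed, self-loops dropped. Before any summary the
network is restricted to genes holding a bias value, and nodes left
edgeless by the restriction are removed — a gene enters the analysis only
through an interaction.

The **X–Y subnetwork** (classes `M`, `F`, `U`, wildcard `A`) contains every
class-X node with at least one class-Y neighbour, plus the unique X–Y
edges. Edge counts are symmetric in X and Y by construction; across a
partition of labels the class-pair edge counts sum to the total edge count,
and the per-class X–A node counts sum to the number of non-isolated nodes.
Both identities are enforced as property tests.

Each of the 13 reported subnetworks (A-A, U-A, U-U, U-F, U-M, F-A, F-U,
F-F, F-M, M-A, M-U, M-F, M-M) is summarised by node count, unique edge
count, the edges-per-node ratio, and the mean, SD, 25th and 75th
percentile of node degree. Degree has two defensible definitions and the
package exposes both: `"full"` counts a node's edges in the whole analysis
network (under which the A-A row satisfies mean degree $= 2E/N$ exactly —
the handshake lemma — which is how the default was inferred), `"within"`
counts only the subnetwork's own edges. Every summary records which mode
produced it.

## Power-law tails

Interaction-network degree distributions are typically power-law only in
their upper tail, so fitting the whole range understates the tail's
steepness. The package bins degrees into fixed-width windows ([1,5],
[6,10], … for the default width 5, counts unnormalised), discards degrees
below a per-subnetwork cutoff, and fits ordinary least squares to
$(\log_{10}\text{midpoint}, \log_{10}\text{count})$ over nonzero bins whose
lower edge is at or above the cutoff; at least three usable bins are
required. Choices: the bin representative is the arithmetic midpoint
(lower-edge and geometric-mean alternatives were considered and rejected
for simplicity); zero-count bins are excluded (their log is undefined);
base 10 on both axes (the slope is base-invariant); cutoffs default to
values chosen where empirical strict-network distributions straighten, and
are configurable per subnetwork. Cutoff selection is deliberately manual —
automated cutoff estimation and likelihood-based exponent estimators are
out of scope, though the reported exponent field is estimator-agnostic.

A caveat the test suite makes explicit: on finite samples from a truncated
power law this binned-OLS estimator is flat-biased, because the far tail
contributes a run of one-count bins that tilt the regression. The
generator test therefore compares the network's fitted exponent against
the same estimator applied to an ideal i.i.d. draw from the configured law
(a sampling oracle sharing the bias), rather than against the nominal
exponent; on well-populated supports (e.g. 20,000 draws on [5, 500]) the
estimator lands within a few tenths of the truth and is tested directly.

## Conflict detection

With the stringent scheme, `find_indirect()` returns unbiased genes
($|b| \le 1$) having at least one neighbour with $b > 5$ and one with
$b < -5$; `find_direct()` returns every edge whose endpoints sit beyond
$+5$ and $-5$. The direct result is reported both as pairs (edges) and as
the per-side gene projections, which differ whenever one gene opposes
several partners; both counts are emitted. Outputs are sorted
lexicographically so repeated runs are byte-identical. Boundary handling
is strict for "biased" and inclusive for "unbiased", so with disjoint
windows a gene can never be both a conflict bridge and a conflict partner.

## Set statistics

Overlap between two gene lists drawn from a shared universe is tested with
the hypergeometric distribution: enrichment tail $P[X \ge k]$, depletion
tail $P[X \le k]$, and a two-tailed value of twice the smaller tail capped
at 1 (the minimum-likelihood-sum alternative exists in the literature; the
doubled tail was chosen as the default for its simplicity and
conservatism). The universe defaults to all genes in the analysis network
and is configurable — overlap conclusions can be sensitive to it, so it is
always reported. Rank concordance between two bias tables uses
tie-corrected Kendall $\tau_b$ over the shared genes.

## The synthetic study

`synthetic_config()` defines a ground-truthed study used by every test:

* **Counts.** Negative-binomial (dispersion 0.1, a moderate bulk-RNA-seq
  value) around gene baselines drawn log-normally (median 3000, sdlog 1).
  The baseline unit is total read depth summed over a gene's CDS — depth
  sums in the thousands, as deep whole-body libraries produce — not raw
  read counts. Two samples per sex, matching the two-male/two-female
  whole-body design, with log-normal library-size factors (sdlog 0.2).
  Planted biased classes (10% male, 10% female by default) receive a
  64-fold effect split symmetrically ($\times 2^{e/2}$ in one sex,
  $\div 2^{e/2}$ in the other) so the planted $b$ equals the effect
  regardless of baseline; 5% of genes are all-zero to exercise the
  discard rule.
* **Interactome.** A configuration model: degrees drawn from
  $p(k) \propto k^{-\gamma}$ (default $\gamma = 2.5$) on $[k_{\min},
  k_{\max}]$, with $k_{\min}$ set from the target mean degree via the
  heavy-tail mean relation and $k_{\max} = \sqrt{n \cdot \bar k}$ (the
  structural cutoff under which a simple realisation stays uncorrelated),
  realised exactly by degree-preserving edge switching. Conflict motifs
  are wired explicitly on top; with `exact_motifs = TRUE`, background
  edges that would create accidental motifs are removed and any gene
  isolated by the cleanup is re-attached to a same-class partner (such
  edges cannot form motifs), so recovery tests can demand exact equality
  with the planted truth.

What the generator does *not* emulate: tissue- and stage-specific
expression, isoform structure, mappability artefacts, correlated
biological replicates, and degree–expression correlations present in
curated interactomes. Passing tests therefore demonstrate the pipeline's
correctness and statistical behaviour under a clean generative model, not
the biological validity of conflict calls on real data.

One behaviour of the real statistic shows up clearly in simulation: $B$ is
estimated from the very libraries that contain the planted classes, so
with only 100 genes per biased class the classes' random baseline totals
move $B$ by roughly $\pm 0.1$, shifting every $b_g$ coherently. At a
64-fold effect against a 32-fold threshold this costs a few percentage
points of sensitivity on whichever sex the shift disfavours; the package's
recovery test plants male genes and verifies $\ge 95\%$ sensitivity with
$\le 1\%$ false positives among unbiased genes, and the acceptance script
reports both sexes' recovery.

## Problem sizes and runtime

The test suite and acceptance script run on scaled studies chosen to keep
statistical properties visible: 1,000 genes for bias recovery, 500–1,000
genes for conflict exactness, 10,000 nodes for the degree-tail comparison,
20,000 sampled degrees for the estimator check, and exhaustive
hypergeometric enumeration up to a universe of 12. These sizes are the
package's own validation choices; the pipeline itself is routinely run on
genome-scale inputs (tens of thousands of genes, hundreds of thousands of
edges) in seconds.

## Known limitations

* The depth-proportional weighting is implemented as defined; if the
  intended behaviour was inverse-depth normalisation, results differ
  whenever library depths are unequal.
* The binned-OLS exponent is a descriptive statistic, not a calibrated
  estimator; compare exponents only between fits sharing binning, cutoff
  and support.
* Whether a published "direct conflict" count refers to pairs or per-side
  genes can be ambiguous; this package always emits both.
* Reproducing published analyses end-to-end requires the original bias
  table and edge lists as inputs; the package validates against them when
  they are supplied (see the replication test) and against planted
  synthetic truth otherwise.
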