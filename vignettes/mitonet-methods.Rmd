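---
title: "Methods: anchored co-expression networks with mitonet"
author: "mitonet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: anchored co-expression networks with mitonet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitonet)
```

## The problem

Co-expression networks interpret transcriptome compendia through
guilt-by-association: genes whose expression rises and falls together
across many tissues and conditions are likely co-regulated or act in the
same process. mitonet reconstructs such a network *anchored* on a
predefined gene set — the motivating use case is the mRNA complement of
the mitochondrial proteome (roughly 1,100–1,500 nuclear-encoded genes
plus the 37 genes of the mitochondrial genome itself) profiled across a
large multi-tissue RNA-seq atlas. The output is an undirected weighted
graph whose hubs, modules and disconnected sub-networks can be read
biologically, overlaid with differential-expression contrasts, and
extended with transcription factors.

## The association screen: PCIT

Raw pairwise correlation is too permissive at atlas scale: with a
thousand genes, hundreds of thousands of pairs are tested and indirect
associations (x–z correlation induced by a shared partner y) abound.
mitonet screens pairs with the partial correlation and information
theory (PCIT) rule. For every unordered trio of genes $(x, y, z)$ the
three first-order partial correlations are computed, e.g.

$$ r_{xy.z} = \frac{r_{xy} - r_{xz}\,r_{yz}}
  {\sqrt{(1-r_{xz}^2)(1-r_{yz}^2)}}, $$

the correlation of $x$ and $y$ after removing the linear effect of $z$.
The trio's data-driven tolerance is the mean attenuation

$$ \epsilon = \frac{1}{3}\left(
   \left|\frac{r_{xy.z}}{r_{xy}}\right| +
   \left|\frac{r_{xz.y}}{r_{xz}}\right| +
   \left|\frac{r_{yz.x}}{r_{yz}}\right| \right), $$

and within the trio the pair $(x,y)$ is *eliminated* iff
$|r_{xy}| \le |\epsilon\, r_{xz}|$ **and**
$|r_{xy}| \le |\epsilon\, r_{yz}|$ — its direct association is
explainable through the third gene. A pair is significant overall iff
no trio eliminates it. There is no p-value machinery: the tolerance
replaces multiple-testing correction.

Worked trio ($r_{xy}=0.9$, $r_{xz}=0.8$, $r_{yz}=0.6$):

```{r trio}
trio_tolerance(0.9, 0.8, 0.6)
r <- matrix(c(1, .9, .8, .9, 1, .6, .8, .6, 1), 3, 3,
            dimnames = list(c("x","y","z"), c("x","y","z")))
pcit_significance(r)$significant
```

The y–z association (0.6) is eliminated because it is below both
$\epsilon \cdot 0.9 \approx 0.801$ and $\epsilon \cdot 0.8 \approx 0.712$;
the two stronger edges survive.

### Numerical conventions

Several degenerate cases need explicit conventions; these are applied
identically in the vectorized C++ path and the plain-R brute-force
oracle (`pcit_brute_force()`), which exists precisely so the two can be
compared bit for bit:

* **Zero direct correlations.** A tolerance ratio whose denominator has
  magnitude below $10^{-12}$ contributes 0 to $\epsilon$; otherwise an
  orthogonal pair would make the tolerance undefined.
* **Zero tolerance.** A trio with $\epsilon = 0$ (e.g. an all-zero
  correlation structure) eliminates nothing. Without this guard the
  $\le$ comparisons would void every pair of an empty system; with it,
  all pairs of a zero matrix are significant and vanish at the
  threshold step instead, which is where magnitude filtering belongs.
* **Two genes.** No trio exists, so the single pair is vacuously
  significant.
* **Collinear genes.** Off-diagonal $|r| = 1$ makes a partial-correlation
  denominator vanish and is rejected with an error; perfectly duplicated
  transcripts must be deduplicated upstream. Zero-variance genes are
  likewise rejected by `correlation_matrix()`, by name.
* **Order independence.** Gene ids are sorted before trio enumeration
  and the mask mapped back, so floating-point summation order — and
  therefore the output mask — does not depend on input row order.
* **Absolute ratios.** Whether the tolerance should use signed or
  absolute partial/direct ratios is a genuinely open convention; mitonet
  uses absolute values throughout, which keeps $\epsilon$ positive and
  the elimination rule monotone in edge strength.

### Thresholding

Surviving correlations are filtered on magnitude: the default keeps
$|r| \ge 0.7$, inclusive. A strict reading ("greater than 0.7") differs
only on a measure-zero set for continuous data; the comparison is
exposed as the `inclusive` flag. Negative edges that pass the magnitude
bar are kept by default (`keep_negative = FALSE` drops them); in dense
positively co-regulated systems the 0.7 bar typically removes all
negative correlations on its own.

## Network topology

The network is assembled with igraph. The node set is exactly the set
of edge endpoints: an anchor gene with no surviving association is not
a node, which is why a network can have fewer nodes than the anchor set
has genes. Degree, connected components (reported largest first) and
neighborhoods are standard.

**Radiality** is reported per node as a closeness-like centrality
normalized to $[0,1]$ within each connected component: for node $v$ in
component $C$ with unweighted diameter $\Delta_C \ge 1$,

$$ \mathrm{Rad}(v) = \frac{\Delta_C + 1 - \bar d(v)}{\Delta_C}, $$

with $\bar d(v)$ the mean hop-count distance from $v$ to the other
nodes of $C$. A node adjacent to every other node of its component
scores exactly 1; singleton components are reported as missing rather
than 0 (cross-component distances are undefined, not infinite). Edge
weights are carried as attributes but ignored for distances, matching
the usual network-analyzer reporting. The exact normalization behind
published radiality tables is rarely stated; this convention reproduces
their $[0,1]$ scale and is validated in the test suite against a
brute-force BFS all-pairs-shortest-path oracle rather than against any
external table.

Community detection and force-directed layout are deliberately out of
scope: published module boundaries in figures of this kind are drawn by
eye on a layout, and mitonet provides components, neighborhoods and
attribute queries instead of attempting to re-derive them.

## Differential-expression overlay

The pipeline consumes a long-format table of per-contrast log2 fold
changes (with an optional DE flag) — fitting the DE model itself is a
job for edgeR/limma upstream. Before overlay, genes can be filtered on
expression support with the standard CPM rule: keep a gene iff it shows
at least `min_cpm` (default 1) counts per million in at least
`ceiling(min_fraction * n_samples)` samples (default half; the ceiling
implements "at least half" for odd counts; the boundary is inclusive on
both sides).

Node classification is deliberately dual-mode, because published
"unaffected" categories are sometimes defined by test significance and
sometimes by fold-change magnitude:

* with a DE flag: `up`/`down` by fold-change sign when flagged,
  `unaffected` otherwise (a zero fold change is `unaffected` even when
  flagged);
* without: sign of the fold change, with magnitudes at or below a
  configurable floor (default 0) classified `unaffected`.

Genes absent from the table are always `unaffected` — every node gets a
class, never an error. `consistent_genes()` returns the genes classified
in the same direction in *every* contrast (a gene missing any contrast is
not consistent), optionally restricted to a scope such as one
sub-network's members — the query behind statements like "gene X is
consistently downregulated in every breed-by-diet contrast".

## Transcription-factor augmentation

A second network is built from the union of the anchor set and a TF
catalog, run through the same PCIT + threshold pipeline. TFs are then
filtered by their connectivity profile: a TF-only node is excluded iff
it has strictly more TF-only neighbors than anchor-side neighbors.
Three conventions are adopted and tested:

* genes that are both TF and anchor ("both") count on the anchor side
  of a neighbor tally and are themselves exempt from removal;
* equality retains the TF ("more than" is strict);
* filtering is single-pass — counts are evaluated on the unfiltered
  graph and removals are simultaneous. An iterated-to-fixed-point
  variant would be a different algorithm (leaf TFs hanging off an
  excluded TF would be re-admitted once their neighbor disappears); the
  test suite pins the single-pass semantics on a hand-built graph.

Retained TFs are ranked by degree and, separately, by radiality, with
ties broken by gene id.

## The synthetic-data generator

Every stage is testable against planted ground truth from
`synthetic_spec()` + `generate_expression()` / `generate_counts()` /
`generate_overlay()`. The generative model:

* **Log-normal marginals.** Expression is drawn in log space and
  exponentiated: gene $g$'s value is
  $\exp(\mu_g + 0.5\, z_g)$ with $\mu_g \sim U(\log 1, \log 400)$, so
  values are non-negative and right-skewed like FPKM. The log-scale
  standard deviation of 0.5 keeps the exponentiation-induced correlation
  attenuation small (a planted 0.9 emerges as roughly 0.89 on the
  expression scale), so planted correlations are asserted empirically on
  the exponentiated values, the scale the pipeline actually correlates.
* **Compound-symmetric modules.** Within a module of correlation
  $\rho$, $z_g = \sqrt{\rho}\, f + \sqrt{1-\rho}\,\varepsilon_g$ with a
  shared factor $f$ — the simplest positive-definite planted structure
  with one recall/precision knob; $\rho < 1$ is enforced. Cross-block
  correlation is exactly zero. Negative-correlation blocks are a
  non-goal (the networks of interest retain positive edges).
* **Isolated cluster.** One tight block (default 28 genes at
  $\rho = 0.95$) has zero correlation to everything else, emulating the
  organelle-encoded sub-network that separates from the main component;
  its genes are flagged `is_organelle_encoded` and localization
  "inner membrane". This gives `network_components()` a planted answer.
* **TFs.** Half of the TF genes (round-robin) are attached to modules at
  the module's $\rho$; the rest are independent. An attached TF should
  outrank free TFs by degree, which is the planted truth behind
  `rank_tf()` tests.
* **Counts.** Poisson draws with library sizes uniform on
  $[5\times10^5, 2\times10^6]$ and gene rates of 10–500 CPM, except the
  planted low-expression genes (default 5, carved from the background
  block) at 0.05 CPM — far enough below the 1-CPM bar that they, and
  exactly they, fail the default filter with overwhelming probability.
* **Overlay.** Planted consistent genes (a seeded fraction, default
  0.1) get one sign per gene, magnitudes uniform on $[0.3, 2.5]$ in all
  contrasts, and `is_de = TRUE` everywhere; the rest get independent
  $N(0,1)$ fold changes and per-(gene, contrast) DE flags at rate 0.3.
  Under DE-aware classification the planted set is recovered exactly
  (an unplanted gene would need all $k$ DE flags *and* one sign:
  probability $2 \cdot 0.3^6 \cdot 0.5^6 \approx 2\times10^{-5}$ at
  $k = 6$); under sign-only classification the unplanted genes show the
  analytic $2 \cdot 0.5^k$ accidental-consistency rate, and the tests
  check that binomial expectation instead.

The reference conditions (the defaults) are 5 modules × 20 genes at
$\rho = 0.85$, 40 background genes, the 28-gene isolated cluster, 20
TFs, 200 samples, 6 contrasts. Six contrasts mirror a two-breed ×
three-diet differential-expression design; 200 samples is a realistic
multi-tissue atlas subset at which a 0.85 planted correlation clears
the 0.7 threshold with large margin while background pairs (null
correlation sd $\approx 1/\sqrt{200} \approx 0.07$) essentially never
do. The full-scale feasibility check uses 1,139 genes × 723 samples —
the magnitude of a real mitoproteome-anchored atlas analysis; the trio
screen is $O(n^3)$ (about $2.5\times10^8$ trios at that size) and runs
in seconds in the compiled path.

What the generator does **not** emulate: tissue hierarchy and batch
structure, count overdispersion beyond Poisson, length-dependent FPKM
biases, negatively correlated blocks, and correlated-but-not-DE
confounding. Passing tests therefore demonstrate algorithmic
correctness and planted-structure recovery, not performance on real
atlases, where correlation structure is far less block-diagonal.

## Determinism and reproducibility

All generators take an explicit integer seed and restore the caller's
RNG state; identical spec + seed gives bit-identical outputs.
`run_pipeline()` writes every result as plain text (TSV, SIF, GraphML,
JSON) with no timestamps, so a fixed configuration reproduces every
output file byte for byte — asserted in the test suite by comparing two
complete runs. Expression TSVs are written with 17 significant digits
so a write/read round trip is exact.

## Worked end-to-end example

```{r pipeline}
spec <- synthetic_spec(
  n_samples = 60, modules = data.frame(size = c(8, 8), rho = c(0.85, 0.85)),
  n_background_genes = 10, isolated_cluster_size = 6, tf_count = 6,
  n_low_genes = 3, seed = 7)
out <- file.path(tempdir(), "demo")
rep <- run_pipeline(pipeline_config(out_dir = out, synthetic = spec))
str(rep$network)
str(rep$planted_recovery)
```

## Known limitations

* PCIT semantics follow the published trio-elimination description;
  implementations differ in degenerate-case handling, and the
  conventions above (absolute ratios, the two zero guards, inclusive
  thresholding) are this package's documented choices, pinned by the
  brute-force oracle rather than by comparison to other software.
* The radiality normalization cannot be validated against published
  tables without their underlying networks; only the mathematical
  properties (range, complete-graph case, oracle agreement) are
  asserted.
* The trio screen is exact $O(n^3)$; beyond roughly $10^4$ genes a
  pre-filter on the anchor set (the intended usage) is the practical
  route, not this implementation.
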