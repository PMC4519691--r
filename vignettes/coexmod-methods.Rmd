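---
title: "Methods: weighted co-expression modules and network-based annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted co-expression modules and network-based annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexmod)
```

## The problem

Roughly two fifths of the genes in a typical plant genome have no
functional annotation. When such genes respond strongly to an
environmental stress, their network context is often the only usable
evidence of what they do: genes that are tightly co-expressed with,
well-connected to, and share regulatory elements with characterized
stress genes are likely part of the same response program. `coexmod`
implements that chain of reasoning as a reusable pipeline for
multi-tissue, multi-stage stress expression studies: build a weighted
co-expression network, find its modules and score their statistical
quality, map stress-responsive differential expression onto the modules,
select well-connected (hub) responders that lack annotation, transfer
labels through conserved cross-species network neighborhoods, query the
network with guide genes, and scan promoters for known cis-elements.

## The network model

Given a log2 expression matrix of $n$ genes over $m$ arrays, the
unsigned weighted adjacency is

$$a_{ij} = |\mathrm{cor}(x_i, x_j)|^{\beta},$$

with soft-threshold power $\beta$ (default 8, chosen on the approximate
scale-free topology criterion; `pick_soft_threshold()` reports the
signed $R^2$ of the log-log degree-distribution fit per candidate
power). The clustering similarity is the topological overlap measure

$$\mathrm{TOM}_{ij} = \frac{\ell_{ij} + a_{ij}}
  {\min(k_i, k_j) + 1 - a_{ij}}, \qquad
  \ell_{ij} = \sum_{u} a_{iu} a_{uj}, \quad k_i = \sum_{j \ne i} a_{ij},$$

which rewards shared neighborhoods on top of direct connection; modules
are branches of the average-linkage dendrogram of $1 - \mathrm{TOM}$.

### Tree cutting

`cluster_tom()` uses a static cut at `cut_height` (default 0.995)
followed, for `deep_split` in 1..4, by one secondary within-branch
re-cut at the {0.95, 0.90, 0.85, 0.80} quantile of the branch's own
join heights. When the re-cut produces at least two sub-branches of
`min_module_size`, they replace the branch and the remaining genes fall
to `"grey"`; otherwise the branch stays whole. This is a deliberate
simplification of the adaptive ("dynamic") tree-cut algorithm: it keeps
the same tunable granularity with far less machinery, at the cost of
the adaptive algorithm's per-branch height modeling and PAM-style
reassignment stage. Cut heights are applied with a $10^{-9}$ relative
tolerance so that exactly tied merge heights (common in synthetic data)
land below the cut. Module labels follow the fixed size-ranked palette
(turquoise, blue, brown, ...), so partitions are deterministic.

### Module quality by permutation

`module_quality()` scores each module with four statistics spanning the
density and connectivity families: mean intramodular adjacency, mean
absolute intramodular correlation, the Spearman correlation between
intramodular and whole-network connectivity, and mean absolute
correlation with the module mean profile. Each statistic is standardized
against `n_perm` (default 200) random gene sets of the same size drawn
from all network genes; `Zsummary` is the mean of the density and
connectivity medians and `psummary` the median add-one-corrected
empirical p-value, so the smallest attainable `psummary` at 200
permutations is $1/201 \approx 0.005$. `Zsummary > 10` with `psummary`
at that floor is the conventional strong-evidence threshold. We compute
quality (self-resampling) statistics rather than cross-dataset
preservation because a single expression study is being assessed.

### Alternative inference and consensus

Four alternative networks support the consensus analysis: Pearson and
Spearman soft-threshold adjacencies, and context-likelihood-of-relatedness
(CLR) scores over two dependence estimators — binned mutual information
and an approximate maximal information coefficient. CLR standardizes
each pair's MI against both genes' background MI distributions,
$z_{ij} = \sqrt{\max(0,t_i)^2 + \max(0,t_j)^2}$, which removes
gene-specific MI baselines (the scores are invariant to adding a
constant to all MI values). The MIC approximation searches only
equal-frequency grid partitions with $b_x b_y \le n^{0.6}$, not the full
dynamic program, and is labeled approximate throughout. Networks are
thresholded to an edge list and clustered with Markov clustering (MCL):
self-loops at each node's maximum incident weight, column
normalization, then alternating expansion (power 2) and inflation
(default 2.0) with pruning at $10^{-5}$ until the update change falls
under $10^{-6}$.

Two wiring choices matter at desk scale (hundreds of genes, 36 arrays)
and are deliberate: the MI histogram uses 5 bins in the pipeline
(roughly $\sqrt{m}$ for 36 arrays; the function default of 10 suits
larger designs), and the pipeline retains the top 5% of pairs before
MCL. Markov clustering at inflation 2 over-fragments very sparse
graphs, so the retention quantile is set to give a mean degree in the
twenties; both parameters are exposed in the configuration.

## Differential expression and module profiles

`call_degs()` computes, per gene and (tissue, stage) cell, the linear
fold change as the ratio of arm means (back-transformed from log2,
matching the fold-change convention of classic microarray software) and
a Welch two-sample t-test on log2 values. The Welch test is a declared
stand-in for the original software's unspecified test. A gene is `up`
when fold $\ge$ `fc_threshold` (default 4) and $p \le 0.05$; no
multiple-testing correction is applied by default, matching the
raw-p convention of the emulated workflow (a Benjamini-Hochberg option
exists). `ubiquitous_degs()` intersects calls across all contrasts;
`module_deg_profile()` tabulates per-module DEG percentages — the
computation that identifies drought-responsive modules.

## Candidate selection and annotation transfer

Hubs are the top `top_frac` (default 20%) of weighted degree within a
module, with ceiling rounding — chosen so that a 1,344-gene module
yields exactly 269 hubs — and lexicographic tie-breaking at the cutoff.
Candidates are hubs that are ubiquitously up-regulated and
uncharacterized. For each candidate with a reference-species ortholog,
the ortholog's top 100 reference neighbors (ranked by total edge
weight) are mapped back; a reference edge is *conserved* when its
back-mapped endpoints have target adjacency at least `edge_min`
(default: the target network's 95th-percentile adjacency; published
workflows display conserved edges without printing a cutoff, so the
threshold is an explicit design choice here, and both reference-side
and target-side counts are reported). Term transfer uses
the one-sided hypergeometric tail over the annotated conserved
neighbors against the whole-network universe, assigning the top term at
$p \le 0.05$. Candidates without orthologs are reported as
untransferable rather than dropped, preserving the attrition
information.

The guide-gene query (`guide_subnetwork()`) ranks all genes by
adjacency to one known gene and keeps the ceiling top 5%, classifying
neighbors at the secondary twofold threshold — the workflow used when a
transcription factor has no ortholog in the model species.

## Promoter cis-element scanning

`iupac_scan()` matches IUPAC consensus motifs by bitwise intersection
of base sets on both strands, reporting every overlapping window;
reverse-strand hits carry the leftmost forward coordinate. An `N` in a
*sequence* is treated as an unknown base and matches nothing unless the
motif position is itself `N`. Palindromic motifs hit both strands at
the same window; `collapse_palindromes` removes the duplicate on
request. Enrichment uses presence/absence hypergeometric tests with BH
q-values. De novo motif discovery and motif alignment are out of scope:
the library is data (a small built-in set of published consensi ships
for the demo).

## The synthetic data generator

Because the original microarray study depends on external databases and
probe-level preprocessing, the package ships a generator that emulates
the *statistical structure* the analysis assumes, with full ground
truth. Gene log2 expression is a latent-factor model:

$$x_{gs} = b_g + \lambda_g f_{m(g), c(s)} + I_{\text{stress}}(s)\,
  \delta_{g,c(s)} + \varepsilon_{gs},$$

with per-gene baselines $b_g \sim N(8, 1.5^2)$, one factor value per
(module, tissue-stage cell) shared by both treatment arms, loadings
calibrated so two module genes correlate at `within_module_cor`
(default 0.7; hubs +0.2), and noise $\varepsilon \sim N(0, 0.5^2)$.
Module factor profiles over the six design cells are QR-decorrelated:
distinct modules are distinct expression programs, which is what makes
the planted partition identifiable from only six cells. Background
genes are pure noise, so the unassigned label is recoverable. The
default design is 3 tissues x 2 stages x 2 treatments x 3 replicates =
36 arrays, 18 stress and 18 control.

Treatment effects follow the structure seen in drought studies: module
1 is the stress-responsive module — every member is mildly induced in
proportion to its loading (`stress_shift`, default 1 on log2, about
twofold) and a designated set of ubiquitous responders inside it is
strongly induced in every cell; other modules carry cell-specific
responders. Planted responder folds are drawn log2-uniform between
`2*deg_fold` and `4*deg_fold` (8-16x at the default fourfold calling
threshold). Strong responders sit well above the calling threshold by
design: planting effects exactly at the threshold would make recovery a
coin flip on the fold-estimate noise rather than a test of the calling
machinery, and genuinely drought-induced marker genes (dehydrins,
LEA proteins) are routinely induced an order of magnitude. Truth
records the total fold of each designated responder, so fold-change
oracles recompute exactly; the sub-threshold module-wide induction is
intentionally not listed as planted effects.

Uncharacterized status and ortholog coverage are sampled stratified
over the hub-and-ubiquitous pool so that the candidate chain always
produces both transferable and untransferable candidates (mirroring
real ortholog attrition) while the global fractions keep their
configured values. The reference network places edges only between
orthologs of same-module genes, weights hub-incident edges higher,
keeps a configurable edge fraction and jitters weights. Promoters are
i.i.d. uniform DNA with module-specific motifs embedded at recorded
positions and strands in responder genes.

What the generator does *not* emulate — and what passing tests
therefore do not establish about real arrays: probe-level structure
(PM/MM probes, CDF layouts), spatial artifacts, batch effects,
intensity-dependent variance, heavy-tailed expression distributions,
correlated background genes, and overlapping or nested modules. The
generator's output corresponds to an already-summarized, normalized
expression matrix (what one downloads from GEO), which is why the
pipeline's rank-invariant normalization defaults to the raw file-input
path only.

## Preprocessing notes

Rank-invariant normalization iterates the invariant-probe selection
(rank difference below 0.05 of the set size) to a fixed point, then
fits a monotone piecewise-linear map on the log2 scale through the
invariant points, after trimming points more than 3 MAD off the
consensus log-ratio — a gene can be rank-consistent in two arrays yet
sit far off the technical-bias curve (a strongly induced gene that is
top-ranked in both), and such points must not bend the map. Tail
slopes come from the outer 2% (at least 5) of invariant points;
fewer than 10 invariant probes triggers a median-scaling fallback with
a warning. Even so, normalizing arrays in which a large fraction of
genes shifts coherently in one direction attenuates extreme folds;
this is a known property of all reference-based normalizations, and is
clearly visible at the few-hundred-gene scale of the synthetic data
where one module is a fifth of the transcriptome. The baseline array
defaults to the median-total-intensity column (the original study does
not state its choice). Probe filtering requires intensity above 20 in
half the samples; probe-to-gene collapse keeps the probe with the
highest max-across-contrasts fold change, ties to the lexicographically
smaller probe id, and discards probes mapping to multiple genes.

## Problem sizes and reproducibility

The shipped demonstration and the acceptance script run the full
workflow on the default 500-gene, 36-array configuration with 200
quality permutations — sizes chosen so a complete run takes well under
a minute on one core while every stage still has enough signal to be
measured. All randomness flows from one root seed through per-stage
substreams (`stage_seed()`), so runs are bitwise reproducible,
including the JSON manifest of output checksums. The pipeline functions
and this package's exported API are the supported interface; a thin
command-line wrapper (`inst/scripts/coexmod`) covers the demo,
config-driven runs, and dataset simulation.

## Known limitations

* The tree cut is the simplified static-plus-secondary form described
  above, not the adaptive hybrid algorithm; very unevenly sized or
  nested modules may be split or absorbed differently.
* The MIC search is restricted to equal-frequency grids; it
  underestimates the full statistic for some dependence shapes.
* Welch's t-test with three replicates per arm has limited power;
  borderline folds near the threshold will be missed, which the
  fold distribution of the generator deliberately avoids conflating
  with machinery errors.
* Dense matrices only; the implementation is comfortable to a few
  thousand genes, beyond which memory for the TOM becomes the limit.
* Ontology terms are flat labels; no graph-aware enrichment.
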