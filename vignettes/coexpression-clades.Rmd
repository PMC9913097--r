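---
title: "Coexpression trees, driver-gene clades and term enrichment: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coexpression trees, driver-gene clades and term enrichment: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexclade)
```

## The model

`coexclade` treats genome-wide coexpression as a hierarchy rather than a
graph. For a genes × samples expression matrix, every gene pair gets a
Pearson correlation coefficient $r$, transformed to a distance

$$d = 1 - r, \qquad d \in [0, 2],$$

so that $d = 0$ means identical profiles and $d = 2$ perfect
anti-correlation. UPGMA (unweighted pair-group average linkage) turns the
distance matrix into a rooted ultrametric tree: at every step the two
clusters with the minimal *average* inter-cluster distance merge at a node
of height equal to half that distance. Genes sharing a low clade are
coexpressed; the tree as a whole encodes a cophenetic distance matrix
(twice the height of each pair's lowest common ancestor) whose agreement
with the input distances (`distance_fit_summary()`) measures clustering
quality.

The method assumes roughly linear co-variation on a log scale (Pearson
$r$ on log2 expression), that genes with constant profiles carry no
coexpression signal (they are removed, since $r$ is undefined for them),
and that an *average-linkage* hierarchy is an adequate summary — UPGMA is
preferred over neighbour joining here precisely because its ultrametric
output supports the clade-size semantics below.

### Driver-gene clades

The coexpressed neighbourhood of a **driver gene** is a clade anchored at
one of the driver leaf's ancestors. The user-facing size knob is the
**internal node count** $k$: `clade_at(tree, driver, k)` returns the
subtree rooted at the $k$-th ancestor (1 = parent). Because ancestor
clades are nested, size is non-decreasing in $k$, and a clade is never
allowed to exceed 25% of all genes (`ceiling(0.25 * leaves)`; "up to 25%"
is read as inclusive). When a request exceeds the cap the largest
compliant $k' < k$ is substituted and the result flagged `capped`.

`default_clade()` picks, along the whole ancestor path, the clade whose
leaf count is closest to 25 genes — small enough to read, large enough to
support enrichment. Two open points were resolved as follows:

- **Ties** ($|s_1 - 25| = |s_2 - 25|$): the *smaller* clade wins —
  conservative output with fewer false co-members.
- **Cap vs. target on small trees.** On a tree with fewer than ~100
  leaves the 25% cap is below the 25-gene target, and enforcing it would
  make the "closest to 25" rule unattainable by construction. The default
  selection therefore applies the cap only when the cap is at least the
  target; explicit `clade_at()` calls always enforce it. On genome-scale
  trees (tens of thousands of genes) the two rules never conflict.

Re-anchoring the query on another gene of the same clade restarts the
internal-node count from that gene's leaf, so the same $k$ may give a
different clade — intended behaviour, since $k$ is defined relative to
the driver.

### Enrichment statistics

For a clade of $n$ genes in a universe of $N$ genes, a term annotating
$K$ universe genes and $k$ of the clade genes is scored with the
hypergeometric upper tail $P(X \ge k)$, evaluated through the log-space
distribution function (`phyper(..., log.p = TRUE)`) so that extreme
values do not underflow. Per category, p-values are Benjamini–Hochberg
adjusted, rows with adjusted $p \le 0.05$ are reported in ascending raw-p
order (ties: descending over-representation rate, then term id), together
with the expected count $nK/N$, the over-representation rate
$k/(nK/N)$ and the hit percentage $100\,k/K$.

Two conventions the literature leaves open:

- **Universe** $N$: all genes present in the coexpression tree, not only
  annotated ones — the hit percentage is defined against "all available
  genes". Any other universe can be passed explicitly.
- **BH family** $m$: only terms with at least one clade hit are tested,
  and only they count towards $m$. Terms that cannot be observed in the
  clade contribute no hypothesis; `attr(result, "n_tested")` records the
  family size so the choice is auditable.

Gene identifiers are matched case-sensitively on stable ids; versioned
ids are truncated at the first dot on both sides of every comparison.

### Representative-sample pruning

To study condition-independent coexpression, the sample tree is reduced
to its $n$ most distinct leaves before the gene tree is built:
`prune_to_n()` repeatedly locates the cherry with the lowest parent — the
two most mutually similar remaining samples — and deletes one member,
contracting the parent. Deletion never re-estimates heights, so
cophenetic distances among survivors are exactly preserved and the
minimal surviving pairwise distance is non-decreasing as $n$ shrinks.
Which member dies: the one with the smaller summed cophenetic distance to
all other leaves (keep the outlier). On an exactly ultrametric tree
cherry members are equidistant from every third leaf, so this sum always
ties and the lexicographically larger label is deleted — a deterministic
convention rather than a data-driven choice, made explicit here because
alternative pruning rules (e.g. deleting by branch support or by
expression depth) would be equally defensible.

### Smoothed quantile normalization

`qsmooth_normalize()` implements group-aware (tissue-aware) smoothed
quantile normalization. Per quantile $u$ of the sorted sample profiles,
the total sum of squares across samples ($SST_u$) is split into between-
and within-group parts, and the normalized value for a sample in group
$g$ is the convex combination

$$w_u\,\bar Q_u + (1 - w_u)\,\bar Q_{u,g}, \qquad
  w_u = 1 - SSB_u / SST_u,$$

with $\bar Q$ the grand and $\bar Q_{\cdot,g}$ the group mean quantile
profile. Where groups agree ($SSB_u \approx 0$) this is plain quantile
normalization; where they differ, group profiles survive. Raw weights are
smoothed by a running median over a window of 5% of the quantiles
(`runmed`, endrule "constant"); values return to gene positions via each
sample's rank order, ties receiving the mean of their tied-rank values.
A single group reduces to plain quantile normalization (with a warning);
the suite checks that case against `limma::normalizeQuantiles`.

### Family scan

`family_clade_scan()` locates concentrations of a gene family (e.g. a
receptor repertoire) on the tree. Rather than sliding a fixed window
along an arbitrary leaf ordering, every internal-node clade of at least
`min_size` leaves is scored by family count, and clades are reported
greedily in order of decreasing count (smaller clade first at equal
count) subject to pairwise disjointness. The tie rule matters: the root
always carries the maximal count, and preferring the smaller clade at
equal count is what lets a tight family clade, rather than the whole
tree, surface as the top hit. Reported counts therefore sum to at most
the family's leaf total.

## Tunable parameters

| Parameter | Where | Default | Meaning |
|---|---|---|---|
| `within_r` | `make_module_matrix()` | 0.9 | target within-module Pearson correlation (dimensionless) |
| `target` | `default_clade()` | 25 genes | ideal displayed clade size |
| `cap_fraction` | clade functions | 0.25 | maximal clade size as fraction of all genes |
| `alpha` | `enrich()` | 0.05 | FDR threshold for reported terms |
| `window` | `qsmooth_normalize()` | 0.05 | running-median weight-smoothing window (fraction of quantiles) |
| `min_size` | `family_clade_scan()` | 2 leaves | smallest clade scanned |
| `suffix` | `filter_gene_ids()` | `"_PAR_Y"` | versioned-id suffix removed before clustering |

## Numerical conventions

- Zero replacement before log2 uses the single *global* minimum non-zero
  value (the rule is stated in the singular), not per-gene or per-sample
  minima.
- The zero-standard-deviation filter tests exact constancy
  (`max == min`), which is deterministic and matches "zero standard
  deviation" literally; near-constant genes pass and are instead guarded
  by the zero-variance error in `pearson_matrix()`.
- After $d = 1 - r$, the diagonal is forced to exactly 0 and
  floating-point excursions outside $[0, 2]$ are clamped.
- UPGMA ties (two cluster pairs at the same minimal distance) merge the
  pair whose lexicographically smallest leaf labels sort first, and
  sibling order is the merge-operand order — byte-identical trees across
  platforms. The suite cross-checks cophenetic matrices against
  `hclust(method = "average")` and a from-scratch average-linkage oracle.
- All trees are `ape` `phylo` objects; ultrametricity is maintained to
  $<10^{-9}$ of root height and asserted in the tests.

## What the synthetic data do and do not show

`make_module_matrix()` draws each module gene as
$\sqrt{\rho}\,z + \sqrt{1-\rho}\,\varepsilon$ with a shared latent sample
profile $z$, so the expected within-module correlation is exactly $\rho$
— chosen because the closed form makes calibration testable.
`make_grouped_samples()` produces Poisson-free rounded $2^{x}$ counts
with group offsets, enough for the sample tree to separate groups
cleanly. Neither generator models RNA-seq mean–variance structure
(negative binomial dispersion), library-size gradients, batch effects or
correlated background modules. Passing the recovery suites therefore
demonstrates that the pipeline's logic is correct — planted structure in,
planted structure out — not that real-tissue compendia will yield clades
of any particular quality. Test and acceptance runs use matrices of
40–1000 genes and 50–100 samples and trees of up to 1000 leaves, sizes at
which every stage completes in seconds; genome-scale use ($5\times10^4$
genes) is dominated by the $O(n^2)$ double-precision distance matrix
(~25 GB) and the $O(n^3)$-ish UPGMA loop, and is the regime the package's
file formats (PHYLIP, Newick) exist to checkpoint.

## Known limitations

- Pearson correlation only; rank-based or proportionality measures are
  out of scope.
- The pure-R UPGMA targets correctness and determinism, not
  genome-scale speed.
- Enrichment consumes pre-built GMT files; no ontology retrieval or
  propagation is performed.
- One driver gene per query; multi-driver intersection clades are not
  supported.
- The JSON query document is validated structurally in-package (shipped
  schema: `inst/schema/query_result.schema.json`).
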