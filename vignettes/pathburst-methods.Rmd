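---
title: "Methods: ortholog projection, crosstalk, expression overlay and sunburst encoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ortholog projection, crosstalk, expression overlay and sunburst encoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathburst)
```

## The data model

The central object is a rooted forest of pathways: each pathway has at
most one parent, and each node carries a (possibly empty) set of directly
annotated gene symbols. The gene complement of a pathway is the union of
direct annotations over the node and all of its descendants, so an
ancestor's gene set always contains each descendant's. Gene identity is
the upper-cased symbol; Entrez IDs are carried on expression records for
reporting and as the deduplication key when present, but pathway
membership (from GMT, which has no Entrez column) is matched by symbol.

We deliberately allow direct gene annotations on internal nodes, not
just leaves: curated hierarchies do not guarantee that a parent's
complement is exactly the union of its children, and the union semantics
covers both cases.

Two structural conventions fix all downstream determinism:

- roots are depth 1, so "level two" is the second ring of the sunburst;
- siblings are ordered lexicographically by pathway id, giving a single
  canonical depth-first layout order used by level queries, reports, and
  the radial layout.

A pathway with two parents is rejected rather than duplicated: the
radial layout requires a tree, and there is no principled duplication
rule for the gene-set statistics.

## Ortholog projection

Given an ortholog map (reference gene → target gene, many-to-many), let
`M` be the set of reference genes with at least one target ortholog. A
pathway with gene complement `G` is

- **complete** when `G ⊆ M` and `G ≠ ∅`,
- **empty** when `G ∩ M = ∅`,
- **partial** otherwise.

Orthology is evaluated on the reference side only: how many target genes
a reference gene maps to does not change whether the gene "can be
identified" in the target, so multiplicity affects nothing. Gene-less
pathways are classified empty but flagged (`geneless`) so the degenerate
case stays visible in reports rather than silently inflating the empty
class.

Status is monotone under map growth (empty → partial → complete), and a
complete parent forces every descendant to be complete or gene-less;
both properties are exercised in the test suite.

The per-pathway ortholog table reports, for each orthologous gene, a
"number of gene products in the pathway". No precise gene-level
definition of that quantity exists for a hierarchy, so we define it as
the number of leaf sub-pathways under the selected pathway whose gene
set contains the gene — a membership multiplicity that is well defined
on any forest. It is isolated in one internal function and easy to
replace. Rate-limiting status is consumed as an input annotation
(symbol → 0/1) and defaults to false for unannotated genes; we do not
attempt to infer it.

## Crosstalk

Crosstalk is shared membership: at a fixed hierarchy level, a gene
belonging to `k ≥ 2` of the level's pathways is a cross-talking gene
product, and every pathway pair sharing at least one gene gets an edge
weighted by the shared-gene count. Two consequences are used as test
invariants: a gene in `k` pathways touches exactly `C(k, 2)` edges, and
the union of shared genes over all edges equals the cross-talking gene
set.

The level defaults to 2 — the first level at which pathway families are
distinct yet broad — and is configurable. A gene in only one pathway has
crosstalk count 0, not 1: the count answers "how many pathways does this
gene interconnect", which requires at least two memberships. Edges are
only computed among same-level pathways; levels of a tree are disjoint,
so a pathway can never share genes with its own ancestor at the same
level.

## Expression overlay

Expression input is a headered TSV of Entrez ID (optional), symbol, and
log2 ratio between two biological states. The ratio column is taken as
already log2-transformed; a `linear_ratio` switch applies `log2` on load.
Records with missing or non-finite ratios are dropped with a counted
warning; duplicate records for one gene keep the largest `|log2 ratio|`
(the most conservative choice that never hides a strong signal).

At cutoff `c > 0` (default 1, i.e. two-fold), a matched gene is up if
`log2 ratio ≥ c`, down if `≤ −c` — the boundary counts as differentially
expressed — and unchanged otherwise. Each pathway's summary counts up
and down genes among its *orthologous* genes and reports the DE ratio
`(n_up + n_down) / n_ortho`, defined as 0 for pathways without
orthologous genes. Restricting the numerator's matching to orthologous
genes is what bounds the ratio by 1; records that match pathway genes
without target orthologs are tallied separately (`n_unmapped`) instead
of distorting the ratio. The denominator counts distinct orthologous
genes; protein-level multiplicity is not modelled.

Useful order relations hold by construction and are tested: DE counts
are non-increasing in the cutoff, and a parent's DE count dominates each
child's (gene sets are unions).

## Order-of-magnitude markers

A non-negative magnitude `v` is decomposed as `A × 10^B` with integer
`B` and real `A`, shown as a wide bar (`B`) and a narrow bar (`A`), both
on linear 0–10 scales — 99 becomes `9.9 × 10^1`. Two boundary policies
are package decisions:

- `0 < v < 1` keeps `B = 0` and `A = v`: negative exponents are not
  representable on a 0–10 scale, and this choice preserves the exact
  round trip `decode(encode(v)) = v`.
- `v ≥ 10^11` saturates to `A = 10, B = 10` with an explicit `saturated`
  flag; decoding a saturated encoding is an error rather than a silently
  wrong magnitude.

Floating-point `log10` at power-of-ten boundaries is guarded so that
`encode(10^k)` is exactly `(1, k)` for `k = 0…10`; the encoding is
lexicographically monotone in `(B, A)` for values ≥ 1.

## Sunburst layout and SVG

Depth maps to concentric rings (`r = inner_radius + (depth−1) ·
ring_width`, defaults 40 and 20 user units — arbitrary geometry
constants, fully configurable). Angular spans are proportional to leaf
counts: roots partition the full circle; each node's children partition
the parent's interval in lexicographic order. Leaf-proportional
weighting is our choice — equal weight per leaf pathway keeps deep
branches readable and is the convention of the standard radial-partition
layout family. Spans conserve to 1e−9 (root spans sum to 2π; child
spans sum to the parent's) and sibling intervals are half-open and
disjoint; both are acceptance-tested on 200 random forests.

Arc fills encode either ortholog status (green `#33a02c`, yellow
`#ffd92f`, purple `#7b3294` for complete/partial/empty) or the DE ratio
through a sequential white→red ramp. OOMM bars are drawn radially along
each arc's outer edge at its angular midpoint; crosstalk edges become
chords (quadratic curves through the center) between the arcs' angular
midpoints at their inner radii, carrying the shared-gene count.

The renderer writes SVG 1.1 text directly with fixed 4-decimal number
formatting and stable element order, so identical input produces
byte-identical output — important both for caching and for testing.
Interactive affordances of a browser viewer (click-to-expand, dragging a
sub-pathway out) are replaced by re-invocation rooted at a sub-pathway:
`sunburst_layout(h, root = id)` (CLI `--root`) lays the subtree out as
its own full-circle sunburst, and `max_depth` prunes rings. A full-circle
arc (a sole root) is drawn with its end angle pulled in by 1e−6 radians,
since an SVG arc with coincident endpoints collapses.

## Synthetic data

The generators emulate the study's input shapes with one integer seed
per call (bit-stable reruns):

- **Hierarchy**: a complete `b`-ary forest (defaults: 2 roots, depth 3,
  branching 3 — 26 pathways, 18 leaves), 8 unique genes per leaf, after
  which a `crosstalk_fraction` (default 0.1) of genes is inserted into a
  second random leaf. Synthetic symbols (`G000001`…) carry fabricated
  Entrez IDs in a reserved high range (from 9×10⁸) to avoid colliding
  with real identifiers.
- **Ortholog map**: each reference gene included independently with
  probability `ortho_coverage` (default 0.7); target symbols are
  reference symbols suffixed `_T`.
- **Expression**: a fraction `frac_de` (default 0.3) of orthologous
  genes get ratios of magnitude `de_effect` (default 2, sign
  equiprobable) plus Gaussian noise (sd 0.1); the rest draw uniformly
  from (−0.9, 0.9), strictly inside the default cutoff.
- **Rate limiting**: independent Bernoulli flags.

These defaults are the package's standing study conditions. The
generator reproduces input *shapes*, not real Reactome topology: real
hierarchies are unbalanced, gene-set sizes are heavy-tailed, crosstalk
is concentrated in signaling hubs, and expression noise is not
homoscedastic. Passing tests therefore demonstrate correctness of the
set arithmetic, classification, statistics and geometry — not that any
biological conclusion transfers.

Property tests use moderate sizes (forests of ≤ 15 pathways, ≤ 30
genes, 200 random instances per invariant; one overlay-recovery run at
1008 genes), chosen so each oracle comparison stays exhaustive and the
suite runs in well under a minute.

## Numerical and degenerate-input choices

- Tolerances: angular conservation asserted at 1e−9; OOMM round trip at
  1e−9 relative.
- Ties: all sibling and report orderings are lexicographic; table
  sorting is stable so repeated sorts are idempotent.
- Degenerate inputs: empty relation streams give gene-set-only forests;
  gene-less pathways are empty-but-flagged; depth queries beyond the
  tree height return empty; an empty arc list is a rendering error.
- Exit codes in the CLI: 0 success, 1 data/parse error, 2 usage or
  missing file.

## Known limitations

- Reaction-level Reactome detail (complexes, catalysts, literature) is
  out of scope; the hierarchy is pathway-and-gene-set only.
- Ortholog inference itself is not performed; maps are inputs.
- No differential-expression statistics (no dispersion models or FDR):
  the overlay consumes precomputed ratios and a hard cutoff.
- Crosstalk is undirected shared membership; no mechanistic
  directionality.
- Multi-parent (DAG) hierarchies are rejected; supporting them would
  require a duplication policy for spans and gene-set statistics.
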