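---
title: "Integrating phosphoproteome and transcriptome on a directed signaling network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating phosphoproteome and transcriptome on a directed signaling network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosphowalk)
```

## The problem

A phospho-antibody array measures, for a few hundred signaling proteins, how
much a specific phosphosite's occupancy changes after a short stimulus (for
example a secreted factor acting on brown adipocytes). In parallel, qPCR or
expression profiling measures how downstream genes respond in tissue. The
question this package addresses is mechanistic: **which of the measured
signaling proteins plausibly carry the stimulus to the transcription factors
(TFs) that control a gene of interest**, and which TFs actually changed
activity?

`phosphowalk` implements the full chain as reusable, tested pieces:

1. **Phospho processing** — per-site log2 fold changes, sign adjustment by
   curated regulatory effects, per-protein representative sites, and
   threshold-based treatment response sets (Venn fields).
2. **Annotation layers** — for each phosphosite, membership of the substrate
   ("self"), its upstream kinases, and its regulated interaction partners in
   five functional categories, plus complete-linkage row clustering.
3. **Network proximity** — random walk with return on a directed signaling
   network, giving visiting probabilities from each assay protein to every
   TF, a `-log10` distance, per-gene ranking and a Mann–Whitney closeness
   test.
4. **TF activity** — analytic rank enrichment of TF regulons against an
   expression signature, with confidence-grade filtering and the p-value /
   phosphorylation selection rules that combine both data types.
5. **Synthetic data** — a generator for every input with planted ground
   truth, so the whole chain is testable offline.

## Models and conventions

### Sign-adjusted fold changes

For a site with replicate-averaged control intensity $c$ and treated
intensity $x$, the fold change is $\log_2(x/c)$ (replicates are averaged per
condition first; the mean is used for linearity). Curated annotation gives
each site an effect sign $s \in \{+1, -1\}$: phosphorylation that activates
the protein keeps its sign, inhibitory phosphorylation flips it, so that
positive adjusted values always mean *functional activation*. Sites with no
curated sign are excluded from sign-adjusted outputs (their direction is
uninterpretable), with the exclusion count reported.

A protein joins the "up" set of a treatment when **any** of its sites has an
adjusted ratio of at least the threshold (default 2), the "down" set when
any site is at or below the reciprocal. Because the any-site rule can in
principle fire in both directions for one protein under one treatment, the
site with the largest $|\text{adjusted } \log_2\text{FC}|$ decides the
direction (ties go to "up"); this keeps the up/down fields of each
treatment disjoint, which the Venn summary relies on. Across treatments a
protein may perfectly well be up under one and down under another.

The representative site of a protein is the one maximizing
$|\log_2\text{FC}|$ of the raw (unsigned) change — on the log scale a 2x
increase and a 0.5x decrease are equally extreme, which is the reading we
adopt for "highest absolute fold change". Ties break lexicographically by
site so outputs are reproducible.

### Annotation layers

For categories $C$ (defaults: angiogenesis **A**, inflammation **I**, lipid
metabolism/thermogenesis **L**, neurogenesis **N**, cell cycle/survival
**C**) each phosphosite row gets three values per category: a binary "self"
membership of the substrate, and the *proportions* of its kinases and of
its regulated interaction partners annotated to the category. The
denominator is the row's own kinase (or partner) set — an empty set scores
0, not NA, matching the convention of gray-scale annotation heatmaps.
Category gene sets arrive as resolved GMT files; resolving GO terms to gene
sets (descendant closure) is upstream curation, not this package's job.

Row clustering uses Euclidean distance with complete linkage
(`stats::hclust`). Leaf ordering is made fully deterministic: at every
merge, the subtree with the lower merge height is placed first, ties broken
by the lexicographically smallest leaf. Determinism is preferred over
aesthetic leaf rotation.

### Random walk with return

The directed network carries signal from regulators to targets; the walk
runs **forward** along edge direction, so proximity measures how easily a
signaling protein's influence reaches a TF. With column-stochastic
transition operator $W$ (each node spreads its mass equally over its
out-edges), return probability $r$ and seed vector $e_s$:

$$p_{t+1} = (1 - r)\, W p_t + r\, e_s, \qquad p_0 = e_s$$

applied for $T$ iterations (defaults $r = 0.5$, $T = 15$; at these values
the iterate is numerically indistinguishable from the fixed point
$r(I - (1-r)W)^{-1} e_s$ on the graphs we target). Mass on dangling nodes
(out-degree 0) is returned to the seed; the alternative, uniform teleport,
was rejected because it dilutes seed specificity. With this rule $p_t$ is a
probability vector at every step, which the tests assert to $10^{-12}$.

Distance is $-\log_{10} p$; unreachable TFs get probability 0 and distance
$\infty$, and always sort last. A gene's distance from a protein aggregates
the distances to the gene's TFs; the default is the **minimum** (one strong
route to one controlling TF suffices to influence the gene), with the mean
available for sensitivity analysis. Edge signs are carried through ingest
but ignored by the walk — the proximity measure is sign-agnostic.

The closeness test splits assay proteins into "altered" (any site with raw
fold change above 1.5) and the rest, and compares their aggregated
distances with a Mann–Whitney test, one-sided by default because the
hypothesis is directional (altered proteins sit *closer*). The exact
distribution is used for small tie-free samples, the tie-corrected normal
approximation otherwise.

### TF activity

Regulons (TF-target sets with a mode of regulation $m_g \in \{+1,-1\}$ and
curation grade A-E) are filtered to grades up to D by default; duplicate
TF-target pairs keep their best grade. The expression signature is rank
transformed to $q_g = \Phi^{-1}\!\big(\mathrm{rank}_g/(G+1)\big)$, symmetric
about 0, and a TF with $n$ targets present scores

$$\mathrm{NES} = \frac{1}{\sqrt{n}} \sum_{g \in \text{targets}} m_g\, q_g,
\qquad p = 2\,\Phi(-|\mathrm{NES}|).$$

This is a deliberate simplification of the msVIPER family of estimators:
the pleiotropy and shadow corrections and target-weight likelihoods are
omitted. The statistic depends only on target ranks and modes, is exactly
antisymmetric under mode negation, and its normal null is slightly
conservative for large regulons in small signatures (sampling without
replacement shrinks the true variance by the finite-population factor
$(G-n)/(G-1)$); the tests verify agreement with a 10,000-draw permutation
null within Monte-Carlo error and type-I calibration at $\alpha = 0.05$.
Regulons with fewer than 3 targets in the signature are skipped — below
that the normal approximation and the rank signal are both meaningless.

Selection rules mirror the display conventions of the analysis this
package generalizes: TFs of a gene with activity $p < 0.2$ (no multiple
testing correction — it is a display cut, not an inference), ordered by p;
and, independently, TFs of the gene whose best phosphosite exceeds a
1.5-fold raw increase under the stimulus. The intersection of the two lists
is the headline integration output.

qPCR input can be normalized with `normalize_expression()`: each gene is
divided by the geometric mean of four housekeeping genes per sample.

### Symbols

All protein and gene identifiers are uppercased at every ingest boundary
(one code path), following the convention of representing mouse assay
results by standard human gene symbols. Non-trivial orthologs need an
explicit mapping before ingest; uppercasing is not an ortholog map.

## The synthetic world

The generator is a pure function of a scenario object and its seed
(sub-streams are derived per component). Defaults, chosen once:

| knob | default | rationale |
|---|---|---|
| nodes / edges | 200 / 600 | mid-size curated-network density (~3 edges/node), small enough for 200-replicate tests on one CPU |
| graph model | preferential attachment (in-degree) | heavy-tailed degree, qualitatively like curated signaling networks; Erdős–Rényi by flag |
| TFs / target-gene TFs | 15 / 3 | a gene of interest typically has a handful of curated TFs |
| assay proteins | 40 | scaled-down antibody panel |
| sites per protein | 1-4 | typical antibody coverage |
| background noise | 0.25 log2 units | modest array noise: 2x planted effects are clearly separated but not trivially so |
| planted response magnitude | uniform on (1.1, 2.2) log2 | safely past the 2x rule |
| unknown-sign fraction | 0.2 | a sizeable minority of sites lack curated effect signs |
| regulon size / planted shift | 25 targets / 1 SD | matches the recovery conditions the tests assert |

The planted regulator emits *only* its planted edges (its walk mass is not
diluted by random wiring); everything else about the network is random.
Planted phosphosites are activating sites whose raw phosphorylation moves;
the unknown-sign fraction applies to planted and background sites alike,
and all emitted ground truth (Venn memberships, altered proteins) is
enumerated directly from the generated tables, so truth and data can never
drift apart.

By default the antibody panel contains signaling proteins only. The
`tfs_on_assay` flag additionally places the target gene's TFs on the panel
with planted responses; this is needed by fixtures that exercise the
TF-phosphorylation filter, and it changes the character of the proximity
benchmark — a TF is trivially proximal to itself (visiting probability at
least $r$), so with the flag on, the gene's own TFs occupy the top ranks
and the planted-regulator recovery question is only meaningful among the
remaining proteins. The recovery test therefore runs on the default world.

What a green test does **not** establish: the generator does not mimic real
curated content (no realistic kinase-substrate bias, no literature-driven
regulon overlap, no antibody cross-reactivity), so passing recovery tests
demonstrates the algorithms, not the biology of any particular dataset.

## Numerical choices and degenerate inputs

* Sites with zero control intensity cannot be ratioed and are dropped with
  a message; negative intensities are an error.
* Probability 0 maps to distance `Inf` (IEEE), never to a large sentinel.
* All ranking ties break lexicographically after the ranking key.
* Deterministic TSV/JSON writers render numbers at full precision
  (`%.17g`), so identical runs are byte-identical and generated tables
  round-trip losslessly.
* Thresholds are validated (`venn_ratio > 1`, `k > 0`, grades in A-E);
  empty groups in the closeness test raise an error naming the group.

## Known limitations

* The walk direction (forward) and the distance transform
  ($-\log_{10} p$) are reasoned conventions; analyses that conceive
  proximity as upstream reachability should transpose the edge list at
  ingest.
* The activity estimator is intentionally simpler than msVIPER; shadowed
  regulons (shared targets) are not deconvolved.
* Pathway enrichment, Venn rendering and figure-quality graphics are out
  of scope; outputs are tables, JSON and a Newick tree.
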