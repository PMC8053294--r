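---
title: "Impact, flux and regulon activation-state inference: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Impact, flux and regulon activation-state inference: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diaflux)
```

## The problem

After a bulk RNA-seq contrast has been reduced to a per-gene table of log2
fold-changes, raw P-values and FDR-adjusted P-values, the biological
questions are downstream: which pathways are most affected and in which
direction, which transcription factors (TFs) plausibly drive the observed
changes, and how do the affected pathways, genes and regulators connect?
`diaflux` implements that downstream chain. It deliberately starts from the
statistics table: count-level modelling (normalization, dispersion
estimation, the negative-binomial test itself) is the job of edgeR, DESeq2
or limma, and their output is this package's input.

## The impact/flux score

For a gene set $S$ (a pathway's members or a TF's targets) evaluated
against an analyzed universe $U$ (the genes present in the table) with DEG
list $D_\alpha = \{g : \mathrm{FDR}(g) \le \alpha\}$, let
$B = S \cap U$ be the set's background and $D = B \cap D_\alpha$ its
differentially expressed members. The score combines three ingredients:

$$\pi = \frac{|D|}{|B|}, \qquad
  m = \frac{1}{|D|}\sum_{g \in D} |\mathrm{lfc}_g|, \qquad
  s = \frac{1}{|D|}\sum_{g \in D} -\log_{10} p_g,$$

into the **impact** $I = 100\,\pi\, m\, s$, a non-negative measure of how
strongly and how confidently the set responds. Its signed counterpart, the
**flux**, is $F = I \cdot d$ with the direction term

$$d = \frac{\sum_{g \in D} \mathrm{lfc}_g}{\sum_{g \in D} |\mathrm{lfc}_g|}
  \in [-1, 1],$$

a magnitude-weighted mean sign: $d = +1$ when every differentially
expressed member is upregulated, $-1$ when all are downregulated,
intermediate when the set is mixed. Positive flux reads as activation,
negative as inhibition. Degenerate cases are defined explicitly: an empty
background or an empty $D$ gives $m = s = d = 0$ and $I = F = 0$.

Three properties follow from the construction and are enforced by
property-style tests:

* $|F| \le I$, with equality exactly when the DEG of the set share one
  sign of fold-change;
* $I$ is unchanged by DEG outside the set, and weakly decreases when
  non-responding members are added (through $\pi$'s denominator);
* holding membership and significance fixed, doubling every fold-change
  doubles $m$ and hence $I$.

**Design choices.** The multiplicative form and the factor 100 are this
package's definition; the factor puts typical single-set scores of a
several-hundred-DEG experiment on the 0–300 scale conventional for this
family of summaries. Any clamping to a display range is presentational and
never applied to stored values. The significance term uses the **raw**
P-value (base-10 log) by default because the adjusted value is already
consumed by the selection step; `sig_stat = "fdr"` switches to the adjusted
one. The magnitude-weighted direction is the default because it is the
variant that guarantees $|F| \le I$; the count-based alternative
$(n_{up} - n_{down})/n_{deg}$ is available via
`direction_method = "count"`. The background for $\pi$ is the analyzed
universe, not the genome: a gene that was never tested cannot dilute a
pathway.

## DEG selection and hierarchy summaries

Selection is a plain inclusive threshold on the FDR column
(`select_deg()`), with 0.10 as the working default and 0.05 reported
alongside in the pipeline's DEG summary; genes with a fold-change of
exactly zero are counted in neither direction and flagged separately.
Pathway scores aggregate over a three-level hierarchy
(pathway → subcategory → category) by the arithmetic mean of impact and of
flux across member pathways with non-empty background. Averaging signed
fluxes (rather than rescaling by impact) is a deliberate choice: it keeps
the aggregate interpretable as "the average signed response of the group's
pathways", at the cost that $|F| \le I$ is no longer guaranteed after
averaging — the aggregate is reported, not re-bounded. Top-N up/down
rankings filter on flux sign first, then order by impact; all ties
anywhere in the package break lexicographically by set id so that reruns
and input permutations are byte-stable.

## Regulon enrichment and activation-state calls

Each regulon is tested for over-representation of the DEG list with the
one-sided hypergeometric tail $P(X \ge k)$ where $N = |U|$, $K = |B|$,
$n = |D_\alpha|$ and $k$ is the observed overlap — equivalent to a
one-sided Fisher exact test, computed exactly. The family for
Benjamini–Hochberg correction is **all** regulons tested, not only the
reported survivors; ranks run 1..T by ascending P-value. A regulon with no
member in the universe is reported with $k = 0$ and $P = 1$ rather than
dropped, so the family size is visible in the output. Significant regulons
(FDR ≤ 0.05 by default) then receive an impact and flux over their target
sets, and the **predicted state** is the flux sign: Activated ($F > 0$),
Inhibited ($F < 0$), or Indeterminate at exactly zero — a label needed
only for the measure-zero boundary, which real tables essentially never
hit but the simulator can construct. Web tools that integrate several
ChIP-seq evidence libraries by rank aggregation solve a related but
different problem; this package's single-library exact test is not an
emulation of any such tool's composite ranking, and its FDR values are not
comparable to theirs.

Gene-set matching is exact and case-sensitive by default; a
`normalize_case` flag upper-cases identifiers on input for workflows that
mix symbol conventions (numeric identifiers are unaffected). Duplicate
gene rows in an input table collapse to the record with the smallest raw
P-value (ties: smallest $|$lfc$|$, then first occurrence). A P-value of
exactly zero is rejected at validation rather than clamped, because the
significance term needs finite $-\log_{10} p$; upstream tools that
underflow to zero should be exported at higher precision.

## Pathway networks

The pathway-link graph is undirected — "up- and downstream" neighbours are
treated symmetrically — and neighbourhood expansion is breadth-first:
`expand_neighborhood()` keeps every pathway within `levels` link steps of
any seed, annotated with its shortest-path distance, with the seeds
themselves at level 0. `map_genes_to_network()` then attaches the DEG
(only the DEG: the display layer is for the genes driving the scores)
contained in retained pathways, and `attach_tf_layer()` adds significant
regulons with regulation edges to their overlapping DEG already in view.
TFs with no regulated gene in view are pruned; isolated pathways are kept
(their isolation is informative). The result is constrained tri-partite:
pathway–pathway, gene–pathway and TF–gene edges only. Exports are sorted
(kind, then id) so repeated exports are byte-identical.

## The synthetic study generator

`simulate_study()` provides the test bed. Null genes draw
$\mathrm{lfc} \sim N(0, \mathrm{se})$; each planted set has a direction
and a responding fraction of members drawing
$\mathrm{lfc} \sim \mathrm{dir}\cdot N(\mu_{eff}, \sigma_{eff})$; P-values
are the two-sided normal tail of $z = \mathrm{lfc}/\mathrm{se}$ (floored
at $10^{-300}$ to keep $-\log_{10} p$ finite) and the FDR column is BH
over all genes. This is the simplest generative model that yields jointly
consistent (lfc, P, FDR) triples shaped like an edgeR export. The defaults
— 10,000 genes, 50 sets of 40, 5 activated + 5 inhibited planted sets,
$\mu_{eff} = 1.5$, $\sigma_{eff} = 0.3$, $\mathrm{se} = 0.3$, responding
fraction 0.8 — put roughly 3–4% of genes past FDR ≤ 0.10, the regime of a
moderate-powered bulk liver contrast (a few hundred DEG among ~10⁴
analyzed genes), split nearly evenly between directions. Planted sets are
pairwise disjoint so each carries an unambiguous direction; null sets are
sampled freely and may overlap anything. The hierarchy assigns sets
round-robin to synthetic subcategories and categories, and the link graph
connects sets sharing at least one gene.

What the generator does **not** emulate: count-level noise and
library-size effects (simulation starts at the statistics table),
correlation between genes within a set beyond shared planted effects,
partially overlapping regulons with conflicting directions, and id-mapping
noise. Passing recovery tests therefore demonstrates that the chain of
selection → enrichment → scoring → state call is correct and well
calibrated under its own model, not that any particular biological claim
holds in real data.

All randomness flows from one integer seed through three derived streams
(gene effects, set membership, planted effects) using R's Mersenne-Twister
with inversion sampling for normals, which is stable across platforms;
identical configurations are byte-identical across runs and machines.

## Numerical and testing choices

Exact enrichment is verified against exhaustive enumeration of all draws
for every configuration up to a universe of 12; BH against a naive
step-up implementation on random vectors; the scoring formula against a
hand-computed worked example (background 5, DEG {+2 at $10^{-4}$, −1 at
$10^{-2}$} → $\pi = 0.4$, $m = 1.5$, $s = 3$, $I = 180$, $d = 1/3$,
$F = 60$) and an independent re-implementation on random instances; BFS
levels against Floyd–Warshall on all small random graphs. The flux bound
is checked on 10,000 random instances, planted-signal recovery on 100
seeded default simulations (every planted regulon significant in ≥95% of
runs, states always matching the planted direction), and null calibration
on 50 simulations without planted effects. These problem sizes were chosen
to make each property decisive at conventional binomial tolerances while
the whole suite remains quick to run. Report files are written at 6
significant digits; round-trips are exact at that precision.

## Worked example

```{r example}
fx <- fixture_small()
compute_impact(fx$sets$sets$PWY_A, fx$table, fdr_cutoff = 0.10,
               set_id = "PWY_A")[c("proportion", "magnitude",
                                   "significance", "impact",
                                   "direction", "flux")]
tf_state_report(fx$sets, fx$table, fdr_cutoff_deg = 0.10,
                fdr_cutoff_tf = 0.10)[, c("tf_id", "impact", "flux",
                                          "predicted_state", "pvalue",
                                          "fdr")]
```

## Known limitations

* The impact scale is this package's own convention; scores are comparable
  within an analysis, and across analyses only under the same universe and
  cutoff. No claim of numerical equality with other impact-style tools is
  made.
* Subcategory/category aggregates are unweighted means; a single
  high-impact pathway can dominate a small group.
* The enrichment test conditions on the DEG list as fixed; it inherits
  whatever selection variability the upstream FDR threshold carries.
* The simulator's independence assumptions make its power estimates
  optimistic relative to correlated real data.
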