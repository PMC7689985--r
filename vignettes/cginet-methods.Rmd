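---
title: "Methods: multi-relational graph convolution for chemical-gene interaction prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-relational graph convolution for chemical-gene interaction prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cginet)
```

## The problem and the graph

Chemical–gene interactions (CGIs) are typed: a chemical *increases*,
*decreases*, or *affects* some action of a gene (its activity, expression,
cleavage, ...), written canonically as `"degree^action"`. `cginet` predicts
unobserved typed CGIs by link prediction in an integrated heterogeneous graph
with three node classes — chemicals, genes, pathways — and five relation
layers:

* four **binary association subgraphs**: chemical–chemical, gene–gene,
  chemical–pathway, gene–pathway;
* one **multi-interaction subgraph**: the typed chemical–gene layer, with one
  relation per interaction type.

At real scale such graphs are assembled from curated databases (STITCH-style
chemical associations, CTD-style interactions and pathway annotations). This
package is deliberately self-contained: a synthetic generator emulates the
structure of such a graph at desk scale so that every pipeline stage is
exercisable and testable offline. Identifier mapping and database parsing are
out of scope.

Curation-style preprocessing is available as two composable operations:
`filter_rare_types()` keeps interaction types with at least `min_edges`
observations (inclusive bound, default 180), and `trim_association_graphs()`
deletes chemicals/genes that occur only in the cc/gg layers. Their order is
left to the caller, since different curation pipelines apply them in
different orders.

## Latent links from network substructures

Two network motifs justify promoting unobserved pairs to edges:

* **S-G**: chemical $c$ interacts with gene $g_1$ (typed), and $g_1$
  associates with $g_2$. This suggests a candidate link $(c, r, g_2)$ of the
  same type.
* **S-G-P**: an S-G whose chemical and genes additionally share a pathway,
  grounding the suggestion in a mechanism. By default the pathway must be
  shared by $c$, $g_1$ *and* $g_2$ (the `"strict"` reading); a `"loose"` mode
  requiring only $c$ and $g_1$ is available because the motif drawing admits
  both readings.

For each type $r$, every candidate pair is scored by its support
$\hat N_i^r$, the number of distinct S-G-P instances implying it. A candidate
is a **definite latent link** iff

$$\hat N_i^r \ge \max\!\big(2,\ \lambda \cdot \max_j \hat N_j^r\big),$$

with inclusive cutoff; the floor of 2 means support-1 candidates are never
promoted, and larger $\lambda$ (in $(0,1]$) strictly shrinks the set.
Mining runs on **training** edges only — latent links feed the encoder, and
deriving them from held-out edges would leak labels. `coverage_stats()`
reports, per type, the fraction of interactions participating in at least one
S-G (resp. S-G-P) instance; S-G-P coverage can never exceed S-G coverage.

## Encoder

All encoders are 2-layer relational graph convolutions. A layer updates node
$i$ as

$$h_i' = \sigma\Big(\sum_r \sum_{j \in N_i^r}
  \tfrac{1}{\sqrt{|N_i^r||N_j^r|}}\, W_r h_j
  \;+\; c_i\, W_{\text{self}}\, h_i\Big),
  \qquad c_i = \sum_{r\,:\,|N_i^r|>0} \tfrac{1}{|N_i^r|},$$

with $\sigma = \mathrm{ReLU}$ on both layers and all $1/|N|$ factors defined
as 0 when the count is 0 (isolated nodes map to zero). Three numerical
choices deserve explanation:

* **Self transformation.** The textbook form of this update adds the
  untransformed $\tfrac{1}{|N_i^r|} h_i$, which is only dimension-consistent
  when consecutive layers have equal width — never the case here (widths
  halve). We therefore carry the self term through a per-node-class weight
  matrix $W_{\text{self}}$ (an embedding lookup at the one-hot input layer),
  which reduces exactly to the textbook form for square layers with identity
  self weight; `rgcn_layer()` exposes that reduction. The self coefficient is
  accumulated once per relation in which the node has neighbors; a
  `self_mode = "global"` flag switches to a single $1/\sum_r |N_i^r|$ factor.
* **One-hot inputs.** Node features are one-hot, never materialized: the
  first layer of each encoder is an embedding lookup (row $i$ of a
  first-layer weight matrix is $W\,x_i$), one table per relation-direction
  plus the self table.
* **Direction-specific weights.** cc/gg are undirected and symmetrized;
  cp/gp/cg pass messages in both directions with separate weight matrices per
  direction, since the update needs neighbor sets on both endpoints and the
  relation layers carry no orientation.

Three perspectives share this machinery:

* **Total graph** (`gcn_total`): one 2-layer pass over all five layers at
  once, widths 32, 16.
* **CG only** (`gcn_cg`): the same, restricted to the typed chemical–gene
  layer — the focused single-layer baseline.
* **Subgraph** (`cginet1/2/3`): a **binary stage** (widths 128, 64) embeds
  chemicals from cc/cp and genes from gg/gp, with pathways acting as message
  sources; its outputs initialize an **interaction stage** (widths 32, 16)
  over the typed layer. In the interaction stage, definite latent links add a
  second message channel, scaled by a per-type **latent rate** $\mu^r$ and
  normalized by $1/\sqrt{|N_i^r|\,|\mathcal L_l^r|}$, where $|\mathcal
  L_l^r|$ is the sender's latent degree (clamped at 1; the receiver factor
  follows the zero-degree convention). Latent and labeled messages share the
  same weight matrices. $\mu^r$ is trainable in `cginet2` (parameterized as
  the logistic of a free scalar, so it stays in $(0,1)$ under any optimizer
  step) and fixed to 1 in `cginet3`.

Typed adjacencies are built from training edges only, so held-out
interactions can never leak into message passing.

## Decoder, loss, and training

Given final embeddings $z$, a typed pair is scored with the DEDICOM bilinear
form

$$g(z_i, r, z_j) = z_i^\top D_r\, R\, D_r\, z_j, \qquad
  \mathcal P_r^{ij} = \sigma\big(g(z_i, r, z_j)\big),$$

with a per-type diagonal $D_r$ and one global matrix $R$ shared by all types,
letting rare types borrow from frequent ones. Both are Glorot-initialized
(fan-in/fan-out $(d, d)$ for the diagonal, which the Glorot recipe does not
itself specify for diagonal matrices).

Training pairs each positive edge with one negative obtained by corrupting
the gene side: the replacement gene is drawn with probability proportional to
$d(g)^{3/4}$ of its training interaction degree (summed over types by
default; per-type degrees behind a flag), redrawn while the corrupted triple
is a known training edge. Zero-degree genes have probability 0 unless all
degrees are 0 (then uniform). The objective is the margin loss

$$\ell = \sum_{(i,r,j)} \max\big(0,\ \mathcal P_r^{in} - \mathcal P_r^{ij} + m\big),$$

summed (not averaged) over the batch — averaging would only rescale the
learning rate — and minimized end-to-end with Adam. Negatives are resampled
every epoch, one per positive, which is the standard ratio for margin losses.
There is no autodifferentiation framework in this stack, so forward and
reverse passes are hand-written; the reverse pass is verified against central
finite differences in the test suite (relative error $\sim 10^{-11}$ on
every variant). Validation metrics are logged per epoch but never used for
early stopping; training runs the configured number of epochs.

Defaults (changeable via `train_config()` / `encoder_config()`):

| parameter      | default | meaning                                    |
|----------------|---------|--------------------------------------------|
| `epochs`       | 10      | passes over the positive training edges    |
| `batch_size`   | 128     | positives per Adam step                    |
| `learning_rate`| 0.001   | Adam step size                             |
| `margin`       | 0.1     | hinge margin on probabilities              |
| `dropout`      | 0.1     | dropout on dense layer inputs (training)   |
| `lambda`       | 0.5     | latent threshold (0.4 for `cginet2`)       |
| widths         | 32, 16 / 128, 64, 32, 16 | total / subgraph encoders |

Dropout acts on dense layer inputs only; the one-hot input layer is an
embedding lookup with no activations to thin. (A node-dropout variant on the
lookup tables was evaluated during development and degraded held-out ranking
at this scale.)

## Evaluation

Interaction edges are split 8:1:1 into train/validation/test per type
(largest-remainder apportionment, deterministic per seed; types with fewer
than 3 edges refuse to split). Each type is scored on its fold positives
against the same number of sampled negatives — pairs of that type absent from
*all* folds, drawn uniformly. The 1:1 uniform-negative protocol is a design
choice (common in this model family) and the largest caveat when comparing
absolute metric values across studies, which typically leave their negative
protocol unstated. Reported metrics per type: AUROC (Mann–Whitney, ties one
half), AUPRC (step-wise average precision, tied scores ordered
pessimistically), and AP@k (precision averaged at the positive ranks within
the top $k = 20$, normalized by $\min(k, P)$). Macro averages are unweighted
means over evaluated types; types without fold positives are skipped with a
warning. Ranking ties are broken by id through a stable sort so reports are
bit-reproducible.

## The synthetic generator

`synthetic_spec()` / `generate_graph()` produce a tri-partite node universe
with the five relation layers:

* cc/gg are Erdős–Rényi $G(n,m)$ graphs; cp/gp are uniform random bipartite
  layers. (Degree-skewed families were considered but uniform layers keep
  expected motif counts analytically tractable.)
* Interaction-type frequencies decay geometrically (ratio 0.3, per-type floor
  8), so the most frequent of the default 6 types carries roughly 70% of
  edges and the top two roughly 90% — mirroring the extreme imbalance of
  curated CGI data, where a fifth of the types cover the vast majority of
  interactions.
* Each type's edges are generated in three labeled strata: `seeded` edges
  placed uniformly at random; `planted` edges added only where a seeded edge
  $(c, r, g_1)$, an association $(g_1, g_2)$ and a pathway shared by $c, g_1,
  g_2$ already exist (the S-G-P closure — every planted edge is therefore
  witnessed by at least one S-G-P instance); and uniform `noise` edges. The
  defaults are 100 chemicals, 150 genes, 20 pathways, ~1500 interactions,
  `planted_fraction = 0.5`, `noise_fraction = 0.1`. If the association layers
  are too sparse to supply the requested closures, generation fails with an
  explicit error rather than silently degrading the signal.

The generator emulates *topology*, not biology: there are no chemical
structures, no ontologies, no realistic identifier schemes, and the
association layers are uncorrelated random graphs. Passing tests on this
fixture demonstrate that the implementation is internally correct and that
the pipeline can exploit planted substructure signal; they say nothing about
predictive performance on real curated data.

## What desk-scale experiments can and cannot show

The test suite trains on the canonical fixture (~250 nodes, ~1500
interactions, 10 epochs — the standard hyperparameters throughout, roughly
110 Adam steps) and evaluates per-type test AUROC/AUPRC/AP@20 averaged over
three initialization seeds; `scripts/acceptance.R` re-runs the same protocol
from scratch. Three findings from systematic measurement during development
are worth recording:

* A structural upper bound: scoring test pairs directly by their S-G-P
  support (computed from training edges) reaches macro AUROC ≈ 0.84 on the
  fixture. It is below 1 because seeded and noise test edges are uniform
  draws, unpredictable by construction.
* Transductive memorization dominates at this scale. Every node owns
  first-layer lookup rows, and with hundreds-to-thousands of Adam steps the
  models drive training pairs' scores up while suppressing the remaining
  pairs of training-active chemicals — which is exactly where held-out
  positives live. Held-out ranking therefore *degrades* with longer training,
  and a frozen random-weight encoder with only the decoder trained
  generalizes better (macro AUROC ≈ 0.7) than any fully trained
  configuration. At the literature's scale (~10⁵ nodes, ~10⁶ edges, the same
  10 epochs) the per-node parameter pressure is orders of magnitude smaller,
  which is why fixed-epoch training without early stopping is viable there.
* As a consequence, desk-scale comparisons between encoder variants mostly
  reflect how fast each overfits (capacity), not representation quality; the
  relative ordering of the variants fluctuates across seeds. Conclusions
  about the subgraph perspective or latent links should not be drawn from
  fixture-scale runs.

## Known limitations

* The model is transductive: embeddings exist only for nodes present at
  training time; new nodes require retraining.
* Encoders are fixed at two layers; no attention, gating, or alternative
  decoders.
* The evaluation negative protocol (1:1 uniform) is configurable but its
  absolute metric values are not comparable to studies using other
  protocols.
* Multiplicity of interactions is not modeled; duplicate triples collapse.
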