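# cginet

Predicting **typed chemical–gene interactions** (CGIs) — e.g. *chemical X
decreases the activity of gene Y*, written `decreases^activity` — by link
prediction in an integrated heterogeneous graph of chemicals, genes, and
pathways. The package is aimed at computational drug-discovery work where the
question is not just *whether* a chemical and a gene interact but *how*.

The graph has five relation layers: four binary association subgraphs
(chemical–chemical, gene–gene, chemical–pathway, gene–pathway) and one
multi-interaction subgraph of typed chemical–gene edges. `cginet` implements
the CGINet model family on top of it:

* a **2-layer relational graph convolutional encoder**, either over the whole
  graph at once (`gcn_total`), over the chemical–gene layer only (`gcn_cg`),
  or in two stages (`cginet1/2/3`): initial embeddings learned on the binary
  association subgraphs are transferred to the multi-interaction subgraph for
  focused learning. A layer update is
  $h_i' = \sigma\big(\sum_r \sum_{j \in N_i^r} \frac{1}{\sqrt{|N_i^r||N_j^r|}} W_r h_j + \frac{1}{|N_i^r|} W_{\mathrm{self}} h_i\big)$;
* **latent links** mined from network substructures: an *S-G* motif (chemical
  c interacts with gene g1, g1 associates with g2) suggests the link c–g2; an
  *S-G-P* motif additionally requires a pathway shared by c, g1, g2. A
  candidate with support $\hat N$ (its number of S-G-P instances) becomes a
  message-passing edge iff $\hat N \ge \max(2, \lambda \max_j \hat N_j)$.
  `cginet2` scales latent messages by a trainable per-type latent rate
  $\mu^r \in (0,1)$; `cginet3` fixes $\mu = 1$;
* a **DEDICOM tensor-decomposition decoder** scoring a pair as
  $z_i^\top D_r R D_r z_j$ with per-type diagonal $D_r$ and a global $R$
  shared across types, followed by a logistic link;
* **end-to-end training** with gene-side negative sampling ($p(g) \propto
  d(g)^{3/4}$), a hinge (margin) ranking loss
  $\sum \max(0, \mathcal P^{in}_r - \mathcal P^{ij}_r + m)$, and Adam —
  forward and reverse passes are written in plain R/Matrix and verified
  against finite differences;
* per-type **evaluation** (AUROC, AUPRC, AP@20 against 1:1 sampled
  non-edges) with macro averages, and a **synthetic generator** that plants a
  controlled fraction of interactions explained by S-G-P closures, so the
  whole pipeline runs and is testable without any external database.

## Worked example

```r
library(cginet)

fx <- default_fixture()          # canonical synthetic graph + 8:1:1 split
fx$graph
#> cgi_graph: 100 chemicals, 150 genes, 20 pathways
#>   cc: 300  gg: 900  cp: 600  gp: 900 edges
#>   cg: 1506 typed interactions across 6 type(s)

coverage_stats(fx$graph)[, c("type", "n_cgi", "prop_sg", "prop_sgp")]
#>                   type n_cgi prop_sg  prop_sgp
#> 1 increases^expression  1051       1 0.9181732
#> 2 decreases^expression   315       1 0.9428571
#> 3   affects^expression    95       1 0.9052632
#> 4   increases^activity    28       1 0.9642857
#> 5   decreases^activity     9       1 0.8888889
#> 6     affects^activity     8       1 0.8750000
```

Most interactions sit in at least one S-G motif (`prop_sg`), and about 90%
are grounded by a shared pathway (`prop_sgp`) — the synthetic fixture plants
half of its edges through exactly that S-G-P closure. Mining promotes the
well-supported candidates to latent links:

```r
lat <- mine_latent_links(fx$graph, fx$split, lambda = 0.5)
lat
#> cgi_latent: 5225 candidate link(s), 210 definite (lambda = 0.5, strict)
```

Train the latent-link variant with fixed latent rate (`cginet3`) and evaluate
on the held-out test fold:

```r
model <- cginet_model(fx$graph, fx$split, "cginet3", latent = lat, seed = 1)
model <- train_cginet(model, train_config(seed = 1), quiet = TRUE)
tail(model$loss_log, 3)
#>    epoch  mean_loss val_auroc val_auprc
#> 8      8 0.08392146 0.7091237 0.7464640
#> 9      9 0.07968424 0.7381587 0.7628472
#> 10    10 0.07597323 0.7340949 0.7588747

evaluate_model(model, fold = "test", seed = 99, quiet = TRUE)
#> cgi_eval <cginet3, test fold>: macro AUROC 0.700, AUPRC 0.738, AP@20 0.706
```

The per-epoch mean hinge loss falls from the margin baseline (0.1: positives
and negatives indistinguishable) as the model learns to rank held-out
interactions above sampled non-edges. Candidate genes for one chemical and
type are ranked with:

```r
H <- encode(model)
head(rank_genes(H, model$params, "C0004", "increases^expression",
                known_edges = split_fold(fx$split, "train")), 3)
#>   chemical     interaction_type  gene     score probability known
#> 1    C0004 increases^expression G0034 0.2650170   0.5658692     0
#> 2    C0004 increases^expression G0116 0.2377013   0.5591471     0
#> 3    C0004 increases^expression G0150 0.1749996   0.5436386     0
```

See `vignettes/cginet-methods.Rmd` for the model, its assumptions, the
synthetic-data design, and known limitations — including why desk-scale
training runs are dominated by transductive overfitting and what fixture
experiments can and cannot demonstrate.

## Command line

A thin CLI wraps the same functions (`exec/cginet`):

```sh
cginet generate    --spec spec.yaml --out graphdir --seed 5
cginet mine-latent --graph graphdir --split split.tsv --lambda 0.5 --out latent.tsv
cginet train       --graph graphdir --variant cginet3 --seed 1 --out rundir
cginet evaluate    --model rundir/model.rds --graph graphdir \
                   --split rundir/split.tsv --fold test --out rundir
```

All TSV dialects are documented in `?load_graph`, `?write_split`,
`?write_latent_links`, and `?write_eval_report`.

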