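# Shared builders and independent oracles used across the test files.
# Oracles are deliberately naive (exhaustive loops, dense arithmetic) and
# never call the implementation paths they check.

# Hand-enumerable toy graph: 3 chemicals, 4 genes, 2 pathways.
toy_graph <- function() {
  cgi_graph(
    chemicals = c("c1", "c2", "c3"),
    genes = c("g1", "g2", "g3", "g4"),
    pathways = c("p1", "p2"),
    cc = data.frame(a = "c1", b = "c2"),
    gg = data.frame(a = c("g1", "g1", "g2"), b = c("g2", "g3", "g3")),
    cp = data.frame(a = c("c1", "c1"), b = c("p1", "p2")),
    gp = data.frame(a = c("g1", "g2", "g3"), b = c("p1", "p1", "p2")),
    cg = data.frame(chemical = c("c1", "c1"),
                    type = "increases^activity",
                    gene = c("g1", "g4"))
  )
}

# Fast random multi-relational graph for property tests.
small_synth <- function(seed = 7, planted_fraction = 0.5,
                        noise_fraction = 0.1) {
  generate_graph(synthetic_spec(
    n_chemicals = 25, n_genes = 30, n_pathways = 8, n_types = 3,
    n_cg_edges = 120, cc_edges = 40, gg_edges = 120, cp_edges = 75,
    gp_edges = 120, min_type_edges = 12,
    planted_fraction = planted_fraction, noise_fraction = noise_fraction,
    seed = seed))
}

# Random homogeneous multi-relational instance for the layer oracle.
random_layer_instance <- function(n, n_rel, d_in, d_out, seed) {
  set.seed(seed)
  adjacency <- lapply(seq_len(n_rel), function(r) {
    m <- matrix(stats::rbinom(n * n, 1, 0.25), n, n)
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    diag(m) <- 0
    Matrix::Matrix(m, sparse = TRUE)
  })
  weights <- lapply(seq_len(n_rel), function(r) matrix(stats::rnorm(d_in * d_out), d_in, d_out))
  list(h = matrix(stats::rnorm(n * d_in), n, d_in), adjacency = adjacency,
       weights = weights,
       self_weight = matrix(stats::rnorm(d_in * d_out), d_in, d_out))
}

# Dense brute-force evaluation of the relational layer update: explicit double
# loop over relations and node pairs, with the zero-degree convention.
dense_rgcn_oracle <- function(h, adjacency, weights, self_weight = NULL,
                              activation = "relu") {
  n <- nrow(h)
  d_out <- ncol(weights[[1]])
  out <- matrix(0, n, d_out)
  for (i in seq_len(n)) {
    acc <- numeric(d_out)
    for (r in seq_along(adjacency)) {
      A <- as.matrix(adjacency[[r]])
      deg <- rowSums(A)
      if (deg[i] == 0) next
      for (j in seq_len(n)) {
        if (A[i, j] != 0 && deg[j] > 0) {
          acc <- acc + (1 / sqrt(deg[i] * deg[j])) * as.numeric(h[j, ] %*% weights[[r]])
        }
      }
      hs <- if (is.null(self_weight)) h[i, ] else as.numeric(h[i, ] %*% self_weight)
      acc <- acc + (1 / deg[i]) * hs
    }
    out[i, ] <- acc
  }
  if (activation == "relu") pmax(out, 0) else out
}

# Exhaustive S-G enumeration: loop over all (chemical, gene, gene) triples.
brute_sg <- function(graph, type) {
  cg_keys <- pair_key_t(graph$cg$chemical[graph$cg$type == type],
                        graph$cg$gene[graph$cg$type == type])
  gg_keys <- c(pair_key_t(graph$gg$a, graph$gg$b),
               pair_key_t(graph$gg$b, graph$gg$a))
  out <- list()
  for (c1 in graph$chemicals) for (g1 in graph$genes) for (g2 in graph$genes) {
    if (g1 != g2 &&
        pair_key_t(c1, g1) %in% cg_keys &&
        pair_key_t(g1, g2) %in% gg_keys) {
      out[[length(out) + 1]] <- data.frame(chemical = c1, gene_known = g1,
                                           gene_target = g2,
                                           stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(chemical = character(), gene_known = character(),
                      gene_target = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# Exhaustive S-G-P enumeration over all quadruples (strict shared pathway).
brute_sgp <- function(graph, type) {
  sg <- brute_sg(graph, type)
  cp_keys <- pair_key_t(graph$cp$a, graph$cp$b)
  gp_keys <- pair_key_t(graph$gp$a, graph$gp$b)
  out <- list()
  for (r in seq_len(nrow(sg))) for (p in graph$pathways) {
    if (pair_key_t(sg$chemical[r], p) %in% cp_keys &&
        pair_key_t(sg$gene_known[r], p) %in% gp_keys &&
        pair_key_t(sg$gene_target[r], p) %in% gp_keys) {
      out[[length(out) + 1]] <- cbind(sg[r, , drop = FALSE],
                                      data.frame(pathway = p,
                                                 stringsAsFactors = FALSE))
    }
  }
  if (!length(out)) {
    return(data.frame(chemical = character(), gene_known = character(),
                      gene_target = character(), pathway = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

pair_key_t <- function(a, b) paste(a, b, sep = "||")

motif_df_key <- function(df) {
  sort(do.call(paste, c(as.list(df), sep = "||")))
}

# Exhaustive pairwise AUROC (ties one half).
brute_auroc <- function(pos, neg) {
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}
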