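test_that("layer update matches hand evaluation on canonical toys", {
  # two nodes, one relation, mutual edge, identity weights: h1' = h2 + h1
  adj <- Matrix::sparseMatrix(i = c(1, 2), j = c(2, 1), x = 1, dims = c(2, 2))
  h <- matrix(c(1, 2, 3, 4), 2, 2)
  out <- rgcn_layer(h, list(adj), list(diag(2)), activation = "identity")
  expect_equal(out, h[c(2, 1), ] + h)
  # path graph 1-2-3: middle node gets (1/sqrt 2)(h1 + h3) + h2 / 2
  adj3 <- Matrix::sparseMatrix(i = c(1, 2, 2, 3), j = c(2, 1, 3, 2), x = 1,
                               dims = c(3, 3))
  h3 <- matrix(rnorm(6), 3, 2)
  out3 <- rgcn_layer(h3, list(adj3), list(diag(2)), activation = "identity")
  expect_equal(out3[2, ], (h3[1, ] + h3[3, ]) / sqrt(2) + h3[2, ] / 2)
  # isolated node maps to the zero vector
  adj_iso <- Matrix::sparseMatrix(i = 1, j = 2, x = 1, dims = c(3, 3))
  adj_iso <- adj_iso + Matrix::t(adj_iso)
  expect_equal(rgcn_layer(h3, list(adj_iso), list(diag(2)),
                          activation = "identity")[3, ], c(0, 0))
})

test_that("sparse layer equals dense brute force on random graphs", {
  for (seed in 41:50) {
    inst <- random_layer_instance(n = sample(5:20, 1), n_rel = 3,
                                  d_in = 4, d_out = 3, seed = seed)
    got <- rgcn_layer(inst$h, inst$adjacency, inst$weights,
                      self_weight = inst$self_weight, activation = "relu")
    want <- dense_rgcn_oracle(inst$h, inst$adjacency, inst$weights,
                              self_weight = inst$self_weight)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("the global self-term alternative divides by the total degree", {
  inst <- random_layer_instance(n = 8, n_rel = 2, d_in = 3, d_out = 3, seed = 5)
  got <- rgcn_layer(inst$h, inst$adjacency, inst$weights,
                    activation = "identity", self_mode = "global")
  deg <- Reduce(`+`, lapply(inst$adjacency, Matrix::rowSums))
  per_rel <- rgcn_layer(inst$h, inst$adjacency, inst$weights,
                        activation = "identity")
  coef_rel <- Reduce(`+`, lapply(inst$adjacency, function(A) {
    d <- Matrix::rowSums(A); ifelse(d > 0, 1 / d, 0)
  }))
  expect_equal(got, per_rel - coef_rel * inst$h + ifelse(deg > 0, 1 / deg, 0) * inst$h)
})

test_that("total-graph encoding stacks two layers deterministically", {
  gen <- small_synth()
  sp <- split_cg_edges(gen$graph, seed = 2)
  cfg <- encoder_config("total", dims = c(8, 6))
  H1 <- encode_total(gen$graph, sp, cfg, seed = 4)
  H2 <- encode_total(gen$graph, sp, cfg, seed = 4)
  expect_identical(H1, H2)
  expect_equal(ncol(H1$chemical), 6)
  expect_equal(nrow(H1$gene), length(gen$graph$genes))
  expect_equal(ncol(H1$pathway), 6)
  expect_true(all(vapply(H1, function(m) all(is.finite(m)), TRUE)))
  # all-zero weights give all-zero embeddings
  plan_params <- with(list(), {
    adj <- build_adjacencies(gen$graph, sp)
    plan <- cginet:::build_plan(gen$graph, adj, cfg)
    p <- cginet:::with_seed(4, cginet:::init_encoder_params(plan, cfg))
    lapply(p, function(x) x * 0)
  })
  H0 <- encode_total(gen$graph, sp, cfg, params = plan_params)
  expect_true(all(H0$chemical == 0) && all(H0$gene == 0))
})

test_that("binary stage embeds from association layers only", {
  gen <- small_synth()
  cfg <- encoder_config("subgraph", dims = c(8, 6, 5, 4))
  H <- encode_binary_stage(gen$graph, cfg, seed = 3)
  expect_equal(ncol(H$chemical), 6)
  expect_equal(ncol(H$pathway), 6)  # produced as sources, not forwarded
  # a chemical with no cc/cp edges is isolated in this stage
  g <- gen$graph
  g$chemicals <- c(g$chemicals, "ZZZ_lonely")
  H2 <- encode_binary_stage(g, cfg, seed = 3)
  expect_equal(unname(H2$chemical[length(g$chemicals), ]), rep(0, 6))
  # under default widths the initial embedding has width 64
  expect_equal(ncol(encode_binary_stage(gen$graph, seed = 1)$chemical), 64)
})

test_that("interaction stage consumes latent links per latent_mode", {
  gen <- small_synth()
  sp <- split_cg_edges(gen$graph, seed = 2)
  lat <- mine_latent_links(gen$graph, sp, lambda = 0.5)
  cfg0 <- encoder_config("subgraph", dims = c(8, 6, 5, 4))
  init <- encode_binary_stage(gen$graph, cfg0, seed = 3)
  expect_error(encode_interaction_stage(gen$graph, sp, latent = lat,
                                        initial = init, config = cfg0),
               "latent_mode")
  cfg1 <- encoder_config("subgraph", dims = c(8, 6, 5, 4),
                         latent_mode = "fixed")
  expect_error(encode_interaction_stage(gen$graph, sp, latent = NULL,
                                        initial = init, config = cfg1),
               "requires mined latent links")
  Z <- encode_interaction_stage(gen$graph, sp, lat, init, cfg1, seed = 6)
  expect_equal(ncol(Z$chemical), 4)
  # an empty latent set under mu = 1 reduces exactly to latent_mode none
  empty <- lat
  empty$links$definite <- FALSE
  Z_empty <- encode_interaction_stage(gen$graph, sp, empty, init, cfg1, seed = 6)
  Z_none <- encode_interaction_stage(gen$graph, sp, NULL, init, cfg0, seed = 6)
  expect_identical(Z_empty, Z_none)
})

test_that("latent neighbors add mu-weighted messages through shared weights", {
  # one chemical, two genes; labeled edge c-g1, latent link c-g2
  g <- cgi_graph("c1", c("g1", "g2"), character(),
                 cg = data.frame(c = "c1", t = "affects^binding", g = "g1"))
  sp <- structure(data.frame(chemical = "c1", type = "affects^binding",
                             gene = "g1", fold = "train",
                             stringsAsFactors = FALSE),
                  class = c("cgi_split", "data.frame"))
  lat <- structure(list(links = data.frame(chemical = "c1",
                                           type = "affects^binding",
                                           gene = "g2", support = 2L,
                                           definite = TRUE,
                                           stringsAsFactors = FALSE),
                        lambda = 0.5, pathway_mode = "strict"),
                   class = "cgi_latent")
  d <- 3
  cfg <- encoder_config("subgraph", dims = c(d, d, d, d),
                        latent_mode = "fixed", self_loop = FALSE)
  init <- list(chemical = matrix(c(1, 2, 4), 1, d),
               gene = rbind(c(0, 1, 0), c(5, 1, 2)))
  # identity weights for both layers and directions
  params <- list()
  for (k in 1:2) for (w in c("c_g.affects^binding", "g_c.affects^binding")) {
    params[[paste0("int", k, ".", w)]] <- diag(d)
  }
  Z <- encode_interaction_stage(g, sp, lat, init, cfg, params = params)
  # layer 1, chemical: labeled message h_g1 (normalizers 1) plus the latent
  # message 1 * h_g2 -- the spec'd "h_labeled + h_latent" pre-activation.
  l1_c <- pmax(init$gene[1, ] + init$gene[2, ], 0)
  # layer 1, genes: g1 receives h_c; g2 has labeled degree 0, so the latent
  # normalizer 1/sqrt(|N||L|) is 0 by the zero-degree convention.
  l1_g1 <- pmax(init$chemical[1, ], 0)
  expect_equal(unname(Z$chemical[1, ]), pmax(l1_g1, 0))
  expect_equal(unname(Z$gene[1, ]), pmax(l1_c, 0))
  expect_equal(unname(Z$gene[2, ]), rep(0, d))
})

test_that("node relabeling permutes embeddings consistently", {
  gen <- small_synth()
  sp <- split_cg_edges(gen$graph, seed = 2)
  cfg <- encoder_config("total", dims = c(6, 4))
  adj <- build_adjacencies(gen$graph, sp)
  plan <- cginet:::build_plan(gen$graph, adj, cfg)
  params <- cginet:::with_seed(8, cginet:::init_encoder_params(plan, cfg))
  H <- encode_total(gen$graph, sp, cfg, params = params)
  # relabel chemicals with a prefix that reverses their sort order
  n_c <- length(gen$graph$chemicals)
  relabel <- stats::setNames(sprintf("X%03d", rev(seq_len(n_c))),
                             gen$graph$chemicals)
  g2 <- gen$graph
  g2$chemicals <- unname(sort(relabel))
  g2$cc$a <- unname(relabel[g2$cc$a]); g2$cc$b <- unname(relabel[g2$cc$b])
  g2$cc <- cginet:::canonical_pairs(g2$cc)
  g2$cp$a <- unname(relabel[g2$cp$a])
  g2$cg$chemical <- unname(relabel[g2$cg$chemical])
  g2$cg <- g2$cg[order(g2$cg$type, g2$cg$chemical, g2$cg$gene), ]
  sp2 <- sp; sp2$chemical <- unname(relabel[sp2$chemical])
  # permute the chemical-indexed parameter rows the same way
  perm <- match(gen$graph$chemicals, names(sort(relabel[gen$graph$chemicals])))
  params2 <- params
  for (nm in names(params2)) {
    if (nm %in% c("tot1.cc", "tot1.p_c",
                  paste0("tot1.g_c.", cg_types(gen$graph)),
                  "tot1.self.chemical")) {
      old <- params2[[nm]]
      params2[[nm]][match(relabel, sort(relabel)), ] <- old
    }
  }
  H2 <- encode_total(g2, sp2, cfg, params = params2)
  expect_equal(H2$chemical[match(relabel, sort(relabel)), ], H$chemical,
               tolerance = 1e-10)
  expect_equal(H2$gene, H$gene, tolerance = 1e-10)
})
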