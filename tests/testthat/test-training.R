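make_split <- function(graph, seed = 1) split_cg_edges(graph, seed = seed)

test_that("negative sampler follows the degree^(3/4) distribution", {
  # degrees {g1: 1, g2: 16}: 16^(3/4) = 8, so p = {1/9, 8/9}
  cg <- rbind(data.frame(chemical = "c1", type = "affects^binding", gene = "g1"),
              data.frame(chemical = sprintf("c%02d", 2:17),
                         type = "affects^binding", gene = "g2"))
  # pad with a second type so every type has >= 3 edges for the split
  cg <- rbind(cg, data.frame(chemical = sprintf("c%02d", 2:4),
                             type = "increases^activity", gene = "g1"))
  g <- cgi_graph(c("c1", sprintf("c%02d", 2:17)), c("g1", "g2"), character(),
                 cg = cg)
  sp <- split_cg_edges(g, ratios = c(1, 0, 0), seed = 1)
  sampler <- build_sampler(g, sp)
  expect_equal(unname(sampler$probs[c("g1", "g2")]),
               c((1 + 3)^0.75, 8) / ((1 + 3)^0.75 + 8))
  # per-type degrees via the flag
  st <- build_sampler(g, sp, per_type = TRUE)
  expect_equal(unname(st$probs[["affects^binding"]][c("g1", "g2")]),
               c(1 / 9, 8 / 9))
  # all-equal degrees give the uniform distribution
  g2 <- cgi_graph(c("c1", "c2", "c3"), c("g1", "g2"), character(),
                  cg = data.frame(c = c("c1", "c2", "c1", "c3"),
                                  t = "affects^binding",
                                  g = c("g1", "g2", "g2", "g1")))
  s2 <- build_sampler(g2, split_cg_edges(g2, c(1, 0, 0), seed = 1))
  expect_equal(unname(s2$probs), c(0.5, 0.5))
})

test_that("empirical sampling frequencies pass a chi-square test", {
  g <- cgi_graph(sprintf("c%02d", 1:20), paste0("g", 1:4), character(),
                 cg = data.frame(
                   chemical = rep(sprintf("c%02d", 1:20), 2),
                   type = "affects^binding",
                   gene = rep(c("g1", "g2", "g3", "g4"), c(20, 10, 6, 4))))
  sp <- split_cg_edges(g, c(1, 0, 0), seed = 1)
  sampler <- build_sampler(g, sp)
  # draw against a chemical with no known edges so nothing is rejected
  extra <- cgi_graph(c(sprintf("c%02d", 1:20), "cXX"), paste0("g", 1:4),
                     character(), cg = g$cg)
  draws <- sample_negative(sampler, rep("cXX", 10000), "affects^binding",
                           seed = 77)
  tab <- table(factor(draws, levels = paste0("g", 1:4)))
  p <- stats::chisq.test(as.vector(tab), p = unname(sampler$probs))$p.value
  expect_gt(p, 0.01)
})

test_that("negative draws avoid known training edges and are seed-stable", {
  gen <- small_synth()
  sp <- make_split(gen$graph, 3)
  sampler <- build_sampler(gen$graph, sp)
  train <- split_fold(sp, "train")
  negs <- sample_negative(sampler, train$chemical, train$type, seed = 5)
  expect_equal(length(negs), nrow(train))
  expect_false(any(paste(train$chemical, train$type, negs) %in%
                     paste(train$chemical, train$type, train$gene)))
  expect_identical(sample_negative(sampler, train$chemical, train$type,
                                   seed = 5), negs)
  # a chemical linked to every sampleable gene but one must receive that gene
  g <- cgi_graph(c("c1", "c2"), paste0("g", 1:4), character(),
                 cg = data.frame(c = c(rep("c1", 3), "c2"),
                                 t = "affects^binding",
                                 g = paste0("g", 1:4)))
  sp1 <- split_cg_edges(g, c(1, 0, 0), seed = 1)
  s1 <- build_sampler(g, sp1)
  expect_warning(got <- sample_negative(s1, "c1", "affects^binding", seed = 2),
                 regexp = NA)
  expect_equal(unique(got), "g4")
  # degenerate graphs exhaust the retry budget with a clear error
  expect_error(sample_negative(s1, "c2", "affects^binding", seed = 2,
                               max_retries = 3),
               regexp = NA) # c2 can still draw g1..g3
  s0 <- s1; s0$probs[c("g1", "g2", "g3")] <- 0
  s0$probs["g4"] <- 1
  expect_error(sample_negative(s0, "c2", "affects^binding", seed = 2),
               "retry budget")
})

test_that("hinge loss implements the margin rule", {
  expect_equal(hinge_loss(0.9, 0.3, 0.1), 0)    # beyond the margin: no penalty
  expect_equal(hinge_loss(0.4, 0.5, 0.1), 0.2)
  expect_equal(hinge_loss(0.7, 0.7, 0.1), 0.1)  # equality costs the margin
  p <- runif(50); q <- runif(50)
  l <- hinge_loss(p, q, 0.1)
  expect_true(all(l >= 0 & l < 1 + 0.1))
})

test_that("analytic gradients of loss(sigmoid(score)) match finite differences", {
  set.seed(71)
  d <- 4
  for (rep in 1:5) {
    zi <- rnorm(d); zj <- rnorm(d); zn <- rnorm(d)
    D <- runif(d, 0.5, 1.5); R <- matrix(rnorm(d * d), d)
    m <- 0.4
    loss <- function(zi, zj, zn, D, R) {
      hinge_loss(edge_probability(dedicom_score(zi, zj, D, R)),
                 edge_probability(dedicom_score(zi, zn, D, R)), m)
    }
    base <- loss(zi, zj, zn, D, R)
    if (base == 0 || base == m) next  # avoid the hinge kink
    p_pos <- edge_probability(dedicom_score(zi, zj, D, R))
    p_neg <- edge_probability(dedicom_score(zi, zn, D, R))
    gp <- cginet:::dedicom_backward(matrix(zi, 1), matrix(zj, 1), D, R,
                                    -p_pos * (1 - p_pos))
    gn <- cginet:::dedicom_backward(matrix(zi, 1), matrix(zn, 1), D, R,
                                    p_neg * (1 - p_neg))
    eps <- 1e-6
    fd <- function(f) vapply(seq_len(d), function(q) {
      (f(q, eps) - f(q, -eps)) / (2 * eps)
    }, 0)
    fd_zi <- fd(function(q, e) { z <- zi; z[q] <- z[q] + e; loss(z, zj, zn, D, R) })
    fd_zj <- fd(function(q, e) { z <- zj; z[q] <- z[q] + e; loss(zi, z, zn, D, R) })
    fd_D <- fd(function(q, e) { v <- D; v[q] <- v[q] + e; loss(zi, zj, zn, v, R) })
    expect_equal(as.numeric(gp$dzi + gn$dzi), fd_zi, tolerance = 1e-4)
    expect_equal(as.numeric(gp$dzj), fd_zj, tolerance = 1e-4)
    expect_equal(as.numeric(gp$dD + gn$dD), fd_D, tolerance = 1e-4)
    fd_R <- (loss(zi, zj, zn, D, R + eps * outer(1:d == 2, 1:d == 3)) -
             loss(zi, zj, zn, D, R - eps * outer(1:d == 2, 1:d == 3))) / (2 * eps)
    expect_equal((gp$dR + gn$dR)[2, 3], fd_R, tolerance = 1e-4)
  }
})

test_that("end-to-end encoder gradients match finite differences", {
  gen <- small_synth()
  sp <- make_split(gen$graph, 3)
  model <- cginet_model(gen$graph, sp, "cginet3", dims = c(5, 4, 4, 3), seed = 2)
  econf <- model$config; econf$dropout <- 0
  train <- split_fold(sp, "train")
  idx <- 1:10
  ci <- match(train$chemical[idx], gen$graph$chemicals)
  gi <- match(train$gene[idx], gen$graph$genes)
  ni <- (gi + 5 - 1) %% length(gen$graph$genes) + 1
  loss_fn <- function(params) {
    H <- cginet:::encoder_forward(model$plan, params, econf)$H
    pos <- cginet:::score_batch(params, H, ci, train$type[idx], gi)
    neg <- cginet:::score_batch(params, H, ci, train$type[idx], ni)
    sum(hinge_loss(edge_probability(pos$s), edge_probability(neg$s), 0.3))
  }
  params <- model$params
  fw <- cginet:::encoder_forward(model$plan, params, econf)
  pos <- cginet:::score_batch(params, fw$H, ci, train$type[idx], gi)
  neg <- cginet:::score_batch(params, fw$H, ci, train$type[idx], ni)
  p_pos <- edge_probability(pos$s); p_neg <- edge_probability(neg$s)
  act <- hinge_loss(p_pos, p_neg, 0.3) > 0
  gp <- cginet:::dedicom_backward(pos$zi, pos$zj, pos$D, params$dec.R,
                                  ifelse(act, -1, 0) * p_pos * (1 - p_pos))
  gn <- cginet:::dedicom_backward(neg$zi, neg$zj, neg$D, params$dec.R,
                                  ifelse(act, 1, 0) * p_neg * (1 - p_neg))
  d <- model$plan$d_embed
  dZc <- matrix(0, model$plan$n[["chemical"]], d)
  dZg <- matrix(0, model$plan$n[["gene"]], d)
  for (r in seq_along(idx)) {
    dZc[ci[r], ] <- dZc[ci[r], ] + gp$dzi[r, ] + gn$dzi[r, ]
    dZg[gi[r], ] <- dZg[gi[r], ] + gp$dzj[r, ]
    dZg[ni[r], ] <- dZg[ni[r], ] + gn$dzj[r, ]
  }
  grads <- cginet:::encoder_backward(model$plan, params, econf, fw$caches,
                                     list(chemical = dZc, gene = dZg), fw$mu)
  eps <- 1e-5
  set.seed(9)
  for (nm in sample(names(grads), 6)) {
    q <- sample(length(params[[nm]]), 1)
    pp <- params; pp[[nm]][q] <- pp[[nm]][q] + eps
    pm <- params; pm[[nm]][q] <- pm[[nm]][q] - eps
    fd <- (loss_fn(pp) - loss_fn(pm)) / (2 * eps)
    expect_equal(grads[[nm]][q], fd, tolerance = 1e-4)
  }
})

test_that("training runs, logs, decreases loss, and is deterministic", {
  gen <- small_synth()
  sp <- make_split(gen$graph, 3)
  model <- cginet_model(gen$graph, sp, "cginet1", dims = c(12, 8, 6, 4),
                        seed = 4)
  # zero epochs returns the initialized model untouched
  m0 <- train_cginet(model, train_config(epochs = 0), quiet = TRUE)
  expect_false(m0$trained)
  expect_identical(m0$params, model$params)
  tc <- train_config(epochs = 6, seed = 4)
  m1 <- train_cginet(model, tc, quiet = TRUE)
  expect_equal(nrow(m1$loss_log), 6)
  expect_lt(m1$loss_log$mean_loss[6], m1$loss_log$mean_loss[1])
  expect_true(all(is.finite(m1$loss_log$mean_loss)))
  m2 <- train_cginet(model, tc, quiet = TRUE)
  expect_identical(m1$loss_log, m2$loss_log)       # bit-exact reruns
  expect_identical(m1$params, m2$params)
  # per-pair loss stays within the margin-plus-slack bound during training
  expect_true(all(m1$loss_log$mean_loss < 1 + tc$margin))
})

test_that("latent rates stay in (0, 1) while training cginet2", {
  gen <- small_synth()
  sp <- make_split(gen$graph, 3)
  model <- cginet_model(gen$graph, sp, "cginet2", dims = c(8, 6, 5, 4),
                        seed = 5)
  m <- train_cginet(model, train_config(epochs = 3, learning_rate = 0.05,
                                        seed = 5), quiet = TRUE)
  mus <- cginet:::mu_values(m$config, m$params, m$plan$types)
  expect_true(all(mus > 0 & mus < 1))
  expect_false(identical(mus, cginet:::mu_values(model$config, model$params,
                                                 model$plan$types)))
})

test_that("checkpoints round-trip a trained model", {
  gen <- small_synth()
  sp <- make_split(gen$graph, 3)
  dir <- withr::local_tempdir()
  model <- cginet_model(gen$graph, sp, "cginet1", dims = c(8, 6, 5, 4), seed = 6)
  m <- train_cginet(model, train_config(epochs = 2, seed = 6), out_dir = dir,
                    quiet = TRUE)
  expect_true(file.exists(file.path(dir, "checkpoint_epoch2.rds")))
  expect_true(file.exists(file.path(dir, "loss_log.tsv")))
  m2 <- load_checkpoint(file.path(dir, "checkpoint_epoch2.rds"), gen$graph, sp)
  expect_identical(m2$params, m$params)
  expect_identical(encode(m2), encode(m))
})
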