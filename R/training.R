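#' Training configuration
#'
#' Defaults follow the model's standard hyperparameters: 10 epochs, minibatch
#' size 128, Adam learning rate 0.001, hinge margin 0.1, dropout 0.1.
#'
#' @param epochs Number of passes over the positive training edges.
#' @param batch_size Positive edges per optimizer step.
#' @param learning_rate Adam learning rate.
#' @param margin Hinge-loss margin `m` (> 0).
#' @param dropout Dropout rate handed to the encoder.
#' @param lambda Latent-link threshold coefficient (used when a variant mines
#'   latent links).
#' @param seed Integer seed controlling initialization, dropout, shuffling and
#'   negative sampling.
#' @return A `cgi_train_config`.
#' @export
train_config <- function(epochs = 10, batch_size = 128, learning_rate = 0.001,
                         margin = 0.1, dropout = 0.1, lambda = 0.5, seed = 1) {
  stopifnot(epochs >= 0, batch_size >= 1, learning_rate > 0, margin > 0,
            dropout >= 0, dropout < 1, lambda > 0, lambda <= 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, margin = margin,
                 dropout = dropout, lambda = lambda, seed = as.integer(seed)),
            class = "cgi_train_config")
}

#' Degree-biased negative sampler over genes
#'
#' Replacement genes for negative examples are drawn with probability
#' proportional to `d(g)^(3/4)`, where `d(g)` is the gene's training-edge
#' degree in the interaction layer (summed over types by default). Zero-degree
#' genes get probability 0 unless every degree is 0, in which case the
#' distribution is uniform.
#'
#' @param graph A `cgi_graph`.
#' @param split A `cgi_split`; degrees come from its training fold.
#' @param per_type Use per-type degrees (one distribution per interaction
#'   type) instead of total degrees.
#' @return A `cgi_sampler`: gene ids, sampling probabilities, and a key index
#'   of known training edges for rejection.
#' @export
build_sampler <- function(graph, split, per_type = FALSE) {
  train <- split_fold(split, "train")
  degree_probs <- function(edges) {
    deg <- table(factor(edges$gene, levels = graph$genes))
    w <- as.numeric(deg)^0.75
    if (sum(w) == 0) w <- rep(1, length(w))
    stats::setNames(w / sum(w), graph$genes)
  }
  probs <- if (per_type) {
    lapply(stats::setNames(nm = cg_types(graph)), function(ty) {
      degree_probs(train[train$type == ty, , drop = FALSE])
    })
  } else {
    degree_probs(train)
  }
  structure(list(genes = graph$genes, probs = probs, per_type = per_type,
                 known = triple_key(train$chemical, train$type, train$gene)),
            class = "cgi_sampler")
}

#' Draw negative genes for a batch of positive edges
#'
#' Corrupts the gene side of each (chemical, type, gene) positive: a
#' replacement gene is drawn from the sampler distribution and redrawn (up to
#' `max_retries` times) while (chemical, type, replacement) is a known
#' training edge. Draws come from the current RNG stream; pass `seed` for a
#' self-contained deterministic call.
#'
#' @param sampler A `cgi_sampler`.
#' @param chemicals,types Character vectors (recycled to common length).
#' @param seed Optional seed.
#' @param max_retries Retry budget per edge before erroring (degenerate
#'   graphs where a chemical interacts with almost every gene).
#' @return Character vector of replacement gene ids.
#' @export
sample_negative <- function(sampler, chemicals, types, seed = NULL,
                            max_retries = 100) {
  n <- max(length(chemicals), length(types))
  chemicals <- rep_len(chemicals, n)
  types <- rep_len(types, n)
  draw <- function() {
    out <- character(n)
    for (i in seq_len(n)) {
      p <- if (sampler$per_type) sampler$probs[[types[i]]] else sampler$probs
      for (try in seq_len(max_retries)) {
        g <- sample(sampler$genes, 1, prob = p)
        if (!(triple_key(chemicals[i], types[i], g) %in% sampler$known)) break
        g <- NA_character_
      }
      if (is.na(g)) {
        stop("negative sampling retry budget exhausted for chemical ",
             chemicals[i], " under type ", types[i], call. = FALSE)
      }
      out[i] <- g
    }
    out
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Margin (hinge) ranking loss
#'
#' `max(0, p_neg - p_pos + m)` per positive/negative pair; a pair whose
#' positive probability beats the negative by more than the margin `m`
#' contributes nothing. Batch loss is the sum.
#'
#' @param p_pos,p_neg Probabilities of the positive and its paired negative.
#' @param margin Margin `m` (> 0).
#' @return Vector of per-pair losses.
#' @export
hinge_loss <- function(p_pos, p_neg, margin = 0.1) {
  pmax(0, p_neg - p_pos + margin)
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# ---- model object ----------------------------------------------------------

#' Model variants
#'
#' * `gcn_cg`: 2-layer GCN on the chemical-gene layer only.
#' * `gcn_total`: 2-layer GCN on the whole multi-relational graph.
#' * `cginet1`: subgraph perspective, no latent links.
#' * `cginet2`: subgraph perspective, latent links with trainable per-type
#'   latent rate `mu` (default `lambda = 0.4`).
#' * `cginet3`: subgraph perspective, latent links with `mu = 1`
#'   (default `lambda = 0.5`).
#'
#' @return Character vector of variant names.
#' @export
cginet_variants <- function() {
  c("gcn_cg", "gcn_total", "cginet1", "cginet2", "cginet3")
}

variant_encoder_config <- function(variant, dims = NULL, dropout = 0.1,
                                   self_loop = TRUE) {
  switch(variant,
         gcn_cg = encoder_config("cg", dims, dropout),
         gcn_total = encoder_config("total", dims, dropout),
         cginet1 = encoder_config("subgraph", dims, dropout,
                                  latent_mode = "none", self_loop = self_loop),
         cginet2 = encoder_config("subgraph", dims, dropout,
                                  latent_mode = "trainable",
                                  self_loop = self_loop),
         cginet3 = encoder_config("subgraph", dims, dropout,
                                  latent_mode = "fixed", self_loop = self_loop),
         stop("unknown variant: ", variant, call. = FALSE))
}

default_lambda <- function(variant) if (variant == "cginet2") 0.4 else 0.5

#' Assemble an untrained model
#'
#' Builds training adjacencies, mines latent links when the variant needs
#' them, and initializes encoder and decoder parameters (Glorot uniform,
#' deterministic for a seed).
#'
#' @param graph A `cgi_graph`.
#' @param split A `cgi_split` of its interaction edges.
#' @param variant One of [cginet_variants()].
#' @param latent Optional pre-mined `cgi_latent`; mined automatically (at
#'   `lambda`) for latent variants when omitted.
#' @param lambda Latent threshold used when mining; defaults to 0.4 for
#'   `cginet2` and 0.5 for `cginet3`.
#' @param dims,dropout Passed to [encoder_config()].
#' @param seed Initialization seed.
#' @return A `cginet_model` (untrained).
#' @export
cginet_model <- function(graph, split, variant = "cginet1", latent = NULL,
                         lambda = NULL, dims = NULL, dropout = 0.1, seed = 1) {
  variant <- match.arg(variant, cginet_variants())
  config <- variant_encoder_config(variant, dims, dropout)
  if (config$latent_mode != "none" && is.null(latent)) {
    latent <- mine_latent_links(graph, split,
                                lambda = lambda %||% default_lambda(variant))
  }
  adj <- build_adjacencies(graph, split)
  latent_adj <- if (config$latent_mode == "none") NULL
                else latent_adjacencies(latent, graph)
  plan <- build_plan(graph, adj, config, latent_adj)
  params <- with_seed(seed, {
    p <- init_encoder_params(plan, config)
    c(p, init_decoder_params(plan$d_embed, plan$types))
  })
  structure(list(variant = variant, config = config, params = params,
                 plan = plan, graph = graph, split = split, latent = latent,
                 seed = as.integer(seed), trained = FALSE, loss_log = NULL),
            class = "cginet_model")
}

#' @export
print.cginet_model <- function(x, ...) {
  cat(sprintf("cginet_model <%s>: %s, %d parameter tensors, d_embed = %d\n",
              x$variant, if (x$trained) "trained" else "untrained",
              length(x$params), x$plan$d_embed))
  invisible(x)
}

#' Compute node embeddings with a model
#'
#' Runs the model's encoder in evaluation mode (no dropout).
#'
#' @param model A `cginet_model`.
#' @return Named list of embedding matrices with node-id rownames.
#' @export
encode <- function(model) {
  H <- encoder_forward(model$plan, model$params, model$config,
                       training = FALSE)$H
  ids <- list(chemical = model$graph$chemicals, gene = model$graph$genes,
              pathway = model$graph$pathways)
  for (cl in names(H)) rownames(H[[cl]]) <- ids[[cl]]
  H
}

# Score a batch of (chemical index, type, gene index) triples given encoder
# output. Returns scores plus the pieces needed for the backward pass.
score_batch <- function(params, H, ci, types, gi) {
  d <- length(params$dec.R[1, ])
  zi <- H$chemical[ci, , drop = FALSE]
  zj <- H$gene[gi, , drop = FALSE]
  D <- t(vapply(types, function(ty) params[[paste0("dec.D.", ty)]],
                numeric(d)))
  list(s = dedicom_score(zi, zj, D, params$dec.R), zi = zi, zj = zj, D = D)
}

#' Train a model end-to-end
#'
#' Minibatched hinge-loss training: every epoch shuffles the positive
#' training edges, pairs each positive with one freshly drawn degree-biased
#' negative (gene-side corruption), and takes one Adam step per minibatch on
#' the summed hinge loss. Encoder and decoder parameters (and, for
#' `cginet2`, the latent rates) are updated jointly. Runs are deterministic
#' for a given `train_config$seed`.
#'
#' @param model A `cginet_model` from [cginet_model()].
#' @param config A `cgi_train_config`.
#' @param out_dir Optional directory; when given, a per-epoch checkpoint
#'   (`checkpoint_epoch<k>.rds`) and a running `loss_log.tsv` are written.
#' @param quiet Suppress per-epoch progress messages.
#' @return The trained `cginet_model`, with a `loss_log` data frame
#'   (`epoch`, `mean_loss`, `val_auroc`, `val_auprc`).
#' @export
train_cginet <- function(model, config = train_config(), out_dir = NULL,
                         quiet = FALSE) {
  sampler <- build_sampler(model$graph, model$split)
  train <- split_fold(model$split, "train")
  ci <- match(train$chemical, model$graph$chemicals)
  gi <- match(train$gene, model$graph$genes)
  n_pos <- nrow(train)
  params <- model$params
  econf <- model$config
  econf$dropout <- config$dropout
  state <- adam_init(params)
  log <- data.frame(epoch = integer(), mean_loss = numeric(),
                    val_auroc = numeric(), val_auprc = numeric())
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      perm <- sample.int(n_pos)
      neg_genes <- sample_negative(sampler, train$chemical[perm],
                                   train$type[perm])
      ni <- match(neg_genes, model$graph$genes)
      total_loss <- 0
      batch_starts <- seq(1, n_pos, by = config$batch_size)
      for (b in batch_starts) {
        rows <- b:min(b + config$batch_size - 1, n_pos)
        idx <- perm[rows]
        fw <- encoder_forward(model$plan, params, econf, training = TRUE)
        pos <- score_batch(params, fw$H, ci[idx], train$type[idx], gi[idx])
        neg <- score_batch(params, fw$H, ci[idx], train$type[idx], ni[rows])
        p_pos <- edge_probability(pos$s)
        p_neg <- edge_probability(neg$s)
        losses <- hinge_loss(p_pos, p_neg, config$margin)
        if (!all(is.finite(losses))) {
          stop("non-finite loss at epoch ", epoch, call. = FALSE)
        }
        total_loss <- total_loss + sum(losses)
        active <- losses > 0
        ds_pos <- ifelse(active, -1, 0) * p_pos * (1 - p_pos)
        ds_neg <- ifelse(active, 1, 0) * p_neg * (1 - p_neg)
        gpos <- dedicom_backward(pos$zi, pos$zj, pos$D, params$dec.R, ds_pos)
        gneg <- dedicom_backward(neg$zi, neg$zj, neg$D, params$dec.R, ds_neg)
        grads <- list(dec.R = gpos$dR + gneg$dR)
        dDrows <- gpos$dD + gneg$dD
        for (ty in unique(train$type[idx])) {
          sel <- train$type[idx] == ty
          grads[[paste0("dec.D.", ty)]] <-
            colSums(dDrows[sel, , drop = FALSE])
        }
        d <- model$plan$d_embed
        dZc <- matrix(0, model$plan$n[["chemical"]], d)
        dZg <- matrix(0, model$plan$n[["gene"]], d)
        dzi <- gpos$dzi + gneg$dzi
        for (r in seq_along(idx)) {
          dZc[ci[idx[r]], ] <- dZc[ci[idx[r]], ] + dzi[r, ]
          dZg[gi[idx[r]], ] <- dZg[gi[idx[r]], ] + gpos$dzj[r, ]
          dZg[ni[rows[r]], ] <- dZg[ni[rows[r]], ] + gneg$dzj[r, ]
        }
        egrads <- encoder_backward(model$plan, params, econf, fw$caches,
                                   list(chemical = dZc, gene = dZg), fw$mu)
        for (nm in names(egrads)) {
          grads[[nm]] <- if (is.null(grads[[nm]])) egrads[[nm]]
                         else grads[[nm]] + egrads[[nm]]
        }
        upd <- adam_step(params, grads, state, config$learning_rate)
        params <- upd$params
        state <- upd$state
      }
      model$params <- params
      val <- tryCatch({
        ev <- evaluate_model(model, fold = "valid", seed = config$seed,
                             quiet = TRUE)
        c(ev$macro$auroc, ev$macro$auprc)
      }, error = function(e) c(NA_real_, NA_real_))
      row <- data.frame(epoch = epoch, mean_loss = total_loss / n_pos,
                        val_auroc = val[1], val_auprc = val[2])
      log <- rbind(log, row)
      if (!quiet) {
        message(sprintf("epoch %d: mean loss %.4f, val AUROC %.3f", epoch,
                        row$mean_loss, row$val_auroc))
      }
      if (!is.null(out_dir)) {
        save_checkpoint(model, file.path(out_dir,
                                         sprintf("checkpoint_epoch%d.rds", epoch)))
        utils::write.table(log, file.path(out_dir, "loss_log.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
      }
    }
  })
  model$params <- params
  model$trained <- config$epochs > 0
  model$loss_log <- log
  model
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single RDS archive (format version 1) holding the
#' variant, configs, seed, and all trainable tensors; the graph itself is not
#' stored. `load_checkpoint` re-attaches the tensors to a model rebuilt from
#' the same graph and split.
#'
#' @param model A `cginet_model`.
#' @param path Checkpoint file.
#' @param graph,split The graph and split the checkpoint was trained on.
#' @return `save_checkpoint`: `path`, invisibly. `load_checkpoint`: a
#'   `cginet_model`.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(format = "cginet-checkpoint", version = 1L,
               variant = model$variant, config = model$config,
               params = model$params, seed = model$seed,
               latent = model$latent, trained = model$trained,
               loss_log = model$loss_log), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path, graph, split) {
  ck <- readRDS(path)
  if (!identical(ck$format, "cginet-checkpoint")) {
    stop(path, " is not a model checkpoint", call. = FALSE)
  }
  model <- cginet_model(graph, split, variant = ck$variant, latent = ck$latent,
                        dims = ck$config$dims, dropout = ck$config$dropout,
                        seed = ck$seed)
  model$params <- ck$params
  model$trained <- ck$trained
  model$loss_log <- ck$loss_log
  model
}
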