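#' Encoder configuration
#'
#' Three encoder perspectives are supported:
#' * `"subgraph"`: two chained 2-layer relational GCNs. The binary stage
#'   embeds chemicals, genes and pathways from the association layers
#'   (cc/gg/cp/gp); its outputs initialize the interaction stage, which passes
#'   messages over the typed chemical-gene layer and, optionally, over mined
#'   latent links. Layer widths default to 128, 64 (binary) and 32, 16
#'   (interaction).
#' * `"total"`: a single 2-layer relational GCN over all five relation layers
#'   at once (widths 32, 16).
#' * `"cg"`: a single 2-layer relational GCN over the typed chemical-gene
#'   layer only (widths 32, 16).
#'
#' `latent_mode` controls latent-link message passing in the interaction
#' stage: `"none"` ignores latent links, `"trainable"` scales them by a
#' learned per-type latent rate `mu` in (0, 1) (parameterized as the logistic
#' of a free scalar), `"fixed"` uses `mu = 1` for every type.
#'
#' @param perspective One of `"subgraph"`, `"total"`, `"cg"`.
#' @param dims Layer widths: length 4 for `"subgraph"`
#'   (`d1_bin, d2_bin, d1_int, d2_int`), length 2 otherwise.
#' @param dropout Dropout rate on dense layer inputs during training,
#'   in `[0, 1)`.
#' @param activation `"relu"` (default) or `"identity"`.
#' @param latent_mode `"none"`, `"trainable"`, or `"fixed"` (subgraph only).
#' @param self_loop Keep the per-relation self pass-through term in every
#'   layer (default TRUE). `FALSE` drops it from the interaction stage
#'   update.
#' @return A `cgi_encoder_config`.
#' @export
encoder_config <- function(perspective = c("subgraph", "total", "cg"),
                           dims = NULL, dropout = 0.1,
                           activation = c("relu", "identity"),
                           latent_mode = c("none", "trainable", "fixed"),
                           self_loop = TRUE) {
  perspective <- match.arg(perspective)
  activation <- match.arg(activation)
  latent_mode <- match.arg(latent_mode)
  if (is.null(dims)) {
    dims <- if (perspective == "subgraph") c(128, 64, 32, 16) else c(32, 16)
  }
  n_dims <- if (perspective == "subgraph") 4L else 2L
  stopifnot(length(dims) == n_dims, all(dims >= 1),
            dropout >= 0, dropout < 1, is.logical(self_loop))
  if (latent_mode != "none" && perspective != "subgraph") {
    stop("latent_mode = \"", latent_mode,
         "\" requires the subgraph perspective", call. = FALSE)
  }
  structure(list(perspective = perspective, dims = as.integer(dims),
                 dropout = dropout, activation = activation,
                 latent_mode = latent_mode, self_loop = self_loop),
            class = "cgi_encoder_config")
}

# ---- message-passing plans -------------------------------------------------
# A "stage" is one 2-layer relational GCN: a node-class universe, a list of
# directed relation operators (normalized sparse matrices), per-class self
# coefficients, and layer widths. The subgraph perspective chains two stages.

make_dir <- function(key, target, source, raw, wkey = key,
                     mu_type = NA_character_, labeled_raw = NULL) {
  latent <- !is.null(labeled_raw)
  A <- if (latent) normalize_latent(raw, labeled_raw) else normalize_direction(raw)
  deg_raw <- if (latent) labeled_raw else raw
  list(key = key, wkey = wkey, target = target, source = source,
       A = A, rowdeg = Matrix::rowSums(deg_raw),
       latent = latent, mu_type = mu_type)
}

binary_dirs <- function(adj) {
  list(make_dir("cc", "chemical", "chemical", adj$cc),
       make_dir("gg", "gene", "gene", adj$gg),
       make_dir("c_p", "chemical", "pathway", adj$cp),
       make_dir("p_c", "pathway", "chemical", Matrix::t(adj$cp)),
       make_dir("g_p", "gene", "pathway", adj$gp),
       make_dir("p_g", "pathway", "gene", Matrix::t(adj$gp)))
}

interaction_dirs <- function(adj, latent_adj = NULL) {
  dirs <- list()
  for (ty in names(adj$cg)) {
    dirs <- c(dirs, list(
      make_dir(paste0("c_g.", ty), "chemical", "gene", adj$cg[[ty]]),
      make_dir(paste0("g_c.", ty), "gene", "chemical", Matrix::t(adj$cg[[ty]]))))
    if (!is.null(latent_adj)) {
      dirs <- c(dirs, list(
        make_dir(paste0("lat.c_g.", ty), "chemical", "gene", latent_adj[[ty]],
                 wkey = paste0("c_g.", ty), mu_type = ty,
                 labeled_raw = adj$cg[[ty]]),
        make_dir(paste0("lat.g_c.", ty), "gene", "chemical",
                 Matrix::t(latent_adj[[ty]]), wkey = paste0("g_c.", ty),
                 mu_type = ty, labeled_raw = Matrix::t(adj$cg[[ty]]))))
    }
  }
  dirs
}

make_stage <- function(id, classes, n, layer_dims, onehot, in_dim, dirs,
                       self_loop) {
  selfcoef <- NULL
  if (self_loop) {
    selfcoef <- lapply(stats::setNames(nm = classes), function(cl) {
      coef <- numeric(n[[cl]])
      for (d in dirs) {
        if (!d$latent && d$target == cl) {
          coef <- coef + ifelse(d$rowdeg > 0, 1 / d$rowdeg, 0)
        }
      }
      coef
    })
  }
  list(id = id, classes = classes, n = n, layer_dims = as.integer(layer_dims),
       onehot = onehot, in_dim = in_dim, dirs = dirs, selfcoef = selfcoef)
}

# Assemble the full message-passing plan for a model variant.
build_plan <- function(graph, adj, config, latent_adj = NULL) {
  n <- c(chemical = length(graph$chemicals), gene = length(graph$genes),
         pathway = length(graph$pathways))
  d <- config$dims
  if (config$perspective == "subgraph") {
    if (config$latent_mode == "none" && !is.null(latent_adj)) {
      stop("latent links supplied but latent_mode is \"none\"", call. = FALSE)
    }
    if (config$latent_mode != "none" && is.null(latent_adj)) {
      stop("latent_mode = \"", config$latent_mode,
           "\" requires mined latent links", call. = FALSE)
    }
    stages <- list(
      make_stage("bin", c("chemical", "gene", "pathway"), n, d[1:2],
                 onehot = TRUE, in_dim = NA_integer_, binary_dirs(adj),
                 self_loop = TRUE),
      make_stage("int", c("chemical", "gene"), n, d[3:4],
                 onehot = FALSE, in_dim = d[2],
                 interaction_dirs(adj, latent_adj),
                 self_loop = config$self_loop))
  } else if (config$perspective == "total") {
    stages <- list(
      make_stage("tot", c("chemical", "gene", "pathway"), n, d,
                 onehot = TRUE, in_dim = NA_integer_,
                 c(binary_dirs(adj), interaction_dirs(adj)), self_loop = TRUE))
  } else {
    stages <- list(
      make_stage("cgo", c("chemical", "gene"), n, d,
                 onehot = TRUE, in_dim = NA_integer_, interaction_dirs(adj),
                 self_loop = TRUE))
  }
  list(stages = stages, d_embed = d[length(d)],
       types = names(adj$cg), n = n)
}

# ---- parameters ------------------------------------------------------------

glorot <- function(nr, nc) {
  limit <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -limit, limit), nr, nc)
}

weight_name <- function(stage_id, k, wkey) paste0(stage_id, k, ".", wkey)
self_name <- function(stage_id, k, class) paste0(stage_id, k, ".self.", class)

# Initialize all encoder weights (Glorot uniform) for a plan, drawing from the
# current RNG stream in a fixed order.
init_encoder_params <- function(plan, config) {
  params <- list()
  for (stage in plan$stages) {
    in_dim <- stage$in_dim
    for (k in seq_along(stage$layer_dims)) {
      out_dim <- stage$layer_dims[k]
      onehot_k <- stage$onehot && k == 1
      for (dir in stage$dirs) {
        wn <- weight_name(stage$id, k, dir$wkey)
        if (is.null(params[[wn]])) {
          nr <- if (onehot_k) plan$n[[dir$source]] else in_dim
          params[[wn]] <- glorot(nr, out_dim)
        }
      }
      if (!is.null(stage$selfcoef)) {
        for (cl in stage$classes) {
          nr <- if (onehot_k) plan$n[[cl]] else in_dim
          params[[self_name(stage$id, k, cl)]] <- glorot(nr, out_dim)
        }
      }
      in_dim <- out_dim
    }
  }
  if (config$latent_mode == "trainable") {
    for (ty in plan$types) params[[paste0("mu.", ty)]] <- 0 # logistic(0) = 0.5
  }
  params
}

# Per-type latent rates implied by config/params.
mu_values <- function(config, params, types) {
  switch(config$latent_mode,
         none = NULL,
         fixed = stats::setNames(rep(1, length(types)), types),
         trainable = stats::setNames(
           vapply(types, function(ty) stats::plogis(params[[paste0("mu.", ty)]]),
                  0), types))
}

apply_activation <- function(P, activation) {
  if (activation == "relu") pmax(P, 0) else P
}

# ---- forward pass ----------------------------------------------------------

# Run one stage. H_in: named list of dense input matrices (ignored when the
# stage consumes one-hot inputs). Returns final per-class activations plus the
# per-layer cache needed for backpropagation.
stage_forward <- function(stage, params, config, H_in = NULL, mu = NULL,
                          training = FALSE) {
  H <- H_in
  cache <- vector("list", length(stage$layer_dims))
  for (k in seq_along(stage$layer_dims)) {
    onehot_k <- stage$onehot && k == 1
    masks <- NULL
    Hd <- H
    if (!onehot_k && training && config$dropout > 0) {
      # dropout acts on dense layer inputs; the one-hot input layer is left
      # intact (an embedding lookup has no activations to thin)
      masks <- lapply(stats::setNames(nm = stage$classes), function(cl) {
        m <- matrix(stats::runif(length(H[[cl]])) >= config$dropout,
                    nrow(H[[cl]]), ncol(H[[cl]]))
        m / (1 - config$dropout)
      })
      Hd <- lapply(stats::setNames(nm = stage$classes),
                   function(cl) H[[cl]] * masks[[cl]])
    }
    P <- lapply(stats::setNames(nm = stage$classes), function(cl) {
      matrix(0, stage$n[[cl]], stage$layer_dims[k])
    })
    for (dir in stage$dirs) {
      W <- params[[weight_name(stage$id, k, dir$wkey)]]
      M <- if (onehot_k) as.matrix(dir$A %*% W)
           else as.matrix(dir$A %*% (Hd[[dir$source]] %*% W))
      if (!is.na(dir$mu_type)) M <- mu[[dir$mu_type]] * M
      P[[dir$target]] <- P[[dir$target]] + M
    }
    if (!is.null(stage$selfcoef)) {
      for (cl in stage$classes) {
        sw <- params[[self_name(stage$id, k, cl)]]
        P[[cl]] <- P[[cl]] +
          if (onehot_k) stage$selfcoef[[cl]] * sw
          else (stage$selfcoef[[cl]] * Hd[[cl]]) %*% sw
      }
    }
    H <- lapply(P, apply_activation, activation = config$activation)
    for (cl in stage$classes) {
      if (!all(is.finite(H[[cl]]))) {
        stop("non-finite activations in stage \"", stage$id, "\" layer ", k,
             call. = FALSE)
      }
    }
    cache[[k]] <- list(Hd = Hd, masks = masks, P = P)
  }
  list(H = H, cache = cache)
}

# Full encoder forward over all stages of a plan.
encoder_forward <- function(plan, params, config, training = FALSE) {
  H <- NULL
  caches <- vector("list", length(plan$stages))
  mu <- mu_values(config, params, plan$types)
  for (s in seq_along(plan$stages)) {
    out <- stage_forward(plan$stages[[s]], params, config, H_in = H, mu = mu,
                         training = training)
    caches[[s]] <- out$cache
    H <- out$H
  }
  list(H = H, caches = caches, mu = mu)
}

# ---- public encoding operations -------------------------------------------

#' Encode all nodes with the total-graph perspective
#'
#' A 2-layer relational GCN over all five relation layers at once. One-hot
#' node features are realized as embedding lookups (row i of a first-layer
#' weight matrix stands for W x_i).
#'
#' @param graph A `cgi_graph`.
#' @param split Optional `cgi_split`; typed message passing then uses training
#'   edges only.
#' @param config A `cgi_encoder_config` with `perspective = "total"`.
#' @param params Optional parameter list from a trained model; freshly
#'   initialized (from `seed`) when omitted.
#' @param seed Seed for parameter initialization.
#' @return List of per-class embedding matrices (`chemical`, `gene`,
#'   `pathway`), each rows-per-node with the final layer width.
#' @export
encode_total <- function(graph, split = NULL, config = encoder_config("total"),
                         params = NULL, seed = 1) {
  stopifnot(config$perspective == "total")
  adj <- build_adjacencies(graph, split)
  plan <- build_plan(graph, adj, config)
  if (is.null(params)) params <- with_seed(seed, init_encoder_params(plan, config))
  encoder_forward(plan, params, config)$H
}

#' Encode chemicals, genes and pathways from the binary association layers
#'
#' The first stage of the subgraph perspective: chemicals aggregate from
#' chemical and pathway neighbors, genes from gene and pathway neighbors;
#' pathway embeddings are produced as message sources but not forwarded to
#' the interaction stage.
#'
#' @inheritParams encode_total
#' @param config A `cgi_encoder_config` with `perspective = "subgraph"`.
#' @return List of per-class initial embeddings (width `dims[2]`, default 64).
#' @export
encode_binary_stage <- function(graph, config = encoder_config("subgraph"),
                                params = NULL, seed = 1) {
  stopifnot(config$perspective == "subgraph")
  adj <- build_adjacencies(graph)
  stage <- make_stage("bin", c("chemical", "gene", "pathway"),
                      c(chemical = length(graph$chemicals),
                        gene = length(graph$genes),
                        pathway = length(graph$pathways)),
                      config$dims[1:2], onehot = TRUE, in_dim = NA_integer_,
                      binary_dirs(adj), self_loop = TRUE)
  plan <- list(stages = list(stage), d_embed = config$dims[2],
               types = character(), n = stage$n)
  if (is.null(params)) params <- with_seed(seed, init_encoder_params(plan, config))
  stage_forward(stage, params, config)$H
}

#' Encode final embeddings on the interaction subgraph
#'
#' The second stage of the subgraph perspective: starting from the initial
#' embeddings, chemicals and genes exchange messages across training
#' interaction edges of each type and (depending on `latent_mode`) across
#' definite latent links, scaled by the latent rate `mu` and normalized by
#' the labeled degree of the receiver and the latent degree of the sender.
#'
#' @inheritParams encode_total
#' @param latent A `cgi_latent` from [mine_latent_links()], or `NULL`.
#'   Supplying one with `latent_mode = "none"` is a configuration error.
#' @param initial Named list with `chemical` and `gene` input embedding
#'   matrices (e.g. from [encode_binary_stage()]).
#' @param config A `cgi_encoder_config` with `perspective = "subgraph"`.
#' @return List with final `chemical` and `gene` embeddings (width `dims[4]`,
#'   default 16).
#' @export
encode_interaction_stage <- function(graph, split, latent = NULL, initial,
                                     config = encoder_config("subgraph"),
                                     params = NULL, seed = 1) {
  stopifnot(config$perspective == "subgraph")
  if (!is.null(latent) && config$latent_mode == "none") {
    stop("latent links supplied but latent_mode is \"none\"", call. = FALSE)
  }
  if (is.null(latent) && config$latent_mode != "none") {
    stop("latent_mode = \"", config$latent_mode,
         "\" requires mined latent links", call. = FALSE)
  }
  adj <- build_adjacencies(graph, split)
  latent_adj <- if (is.null(latent)) NULL else latent_adjacencies(latent, graph)
  stage <- make_stage("int", c("chemical", "gene"),
                      c(chemical = length(graph$chemicals),
                        gene = length(graph$genes)),
                      config$dims[3:4], onehot = FALSE, in_dim = config$dims[2],
                      interaction_dirs(adj, latent_adj),
                      self_loop = config$self_loop)
  plan <- list(stages = list(stage), d_embed = config$dims[4],
               types = names(adj$cg), n = stage$n)
  if (is.null(params)) params <- with_seed(seed, init_encoder_params(plan, config))
  mu <- mu_values(config, params, plan$types)
  stage_forward(stage, params, config,
                H_in = initial[c("chemical", "gene")], mu = mu)$H
}
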