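#' DEDICOM tensor-decomposition decoder
#'
#' Scores a typed chemical-gene pair as the bilinear form
#' \deqn{g(z_i, r, z_j) = z_i^T D_r \, R \, D_r z_j}
#' with a per-interaction-type diagonal matrix `D_r` (stored as a vector) and
#' one global square matrix `R` shared by all types, so that rare types can
#' borrow statistical strength from frequent ones. Probabilities are the
#' logistic of the score.
#'
#' @name dedicom-decoder
NULL

#' Initialize decoder parameters
#'
#' `R` is a Glorot-uniform `d x d` matrix; each `D_r` is a Glorot-uniform
#' vector of length `d` (the diagonal, with fan-in/fan-out taken as `(d, d)`).
#' Draws come from the current RNG stream.
#'
#' @param d Embedding width.
#' @param types Character vector of interaction-type ids.
#' @return Named list: `dec.R` plus one `dec.D.<type>` vector per type.
#' @export
init_decoder_params <- function(d, types) {
  params <- list(dec.R = glorot(d, d))
  for (ty in types) params[[paste0("dec.D.", ty)]] <- glorot(d, d)[, 1]
  params
}

#' Score typed chemical-gene pairs
#'
#' Vectorized over rows: `zi` and `zj` are matrices with one pair per row.
#'
#' @param zi,zj Embedding matrices (pairs x d), or single vectors.
#' @param D Diagonal of `D_r` for the pair's interaction type (length d), or
#'   a pairs x d matrix for mixed-type batches.
#' @param R The global d x d matrix.
#' @return Numeric vector of scores, one per row.
#' @export
dedicom_score <- function(zi, zj, D, R) {
  if (is.null(dim(zi))) zi <- matrix(zi, 1)
  if (is.null(dim(zj))) zj <- matrix(zj, 1)
  d <- ncol(R)
  if (ncol(zi) != d || ncol(zj) != d) {
    stop("embedding width does not match decoder parameters", call. = FALSE)
  }
  if (is.null(dim(D))) D <- matrix(D, nrow(zi), d, byrow = TRUE)
  u <- zi * D
  v <- zj * D
  rowSums((u %*% R) * v)
}

#' Convert a raw score into an interaction probability
#'
#' The logistic function `1 / (1 + exp(-s))`, numerically stable over the
#' full double range.
#'
#' @param s Numeric vector of scores.
#' @return Probabilities in (0, 1).
#' @export
edge_probability <- function(s) {
  stopifnot(all(is.finite(s)))
  stats::plogis(s)
}

# Gradients of sum(ds * score) w.r.t. the decoder inputs and parameters.
# ds: per-pair upstream gradient. Returns dzi, dzj (pairs x d), dD (pairs x d,
# to be accumulated per type), dR (d x d).
dedicom_backward <- function(zi, zj, D, R, ds) {
  if (is.null(dim(D))) D <- matrix(D, nrow(zi), ncol(R), byrow = TRUE)
  u <- zi * D
  v <- zj * D
  uR <- u %*% R      # rows: z_i D R
  Rv <- v %*% t(R)   # rows: (R D z_j)^T
  dzi <- ds * (Rv * D)
  dzj <- ds * (uR * D)
  dD <- ds * (zi * Rv + zj * uR)
  dR <- crossprod(ds * u, v)
  list(dzi = dzi, dzj = dzj, dD = dD, dR = dR)
}

#' Rank candidate genes for a chemical under one interaction type
#'
#' Scores every candidate gene against the chemical, sorts by probability
#' (descending, ties broken by gene id for reproducibility), and flags
#' candidates that are already known edges rather than dropping them.
#'
#' @param embeddings List with `chemical` and `gene` embedding matrices whose
#'   rownames are node ids.
#' @param params Decoder parameter list (from a trained model).
#' @param chemical Chemical id.
#' @param type Interaction type id.
#' @param candidate_genes Character vector of gene ids; default all genes in
#'   `embeddings$gene`.
#' @param known_edges Optional data frame with `chemical`, `type`, `gene`
#'   columns (e.g. training edges); matching candidates get `known = 1`.
#' @return Data frame: `chemical`, `type` (as `interaction_type`), `gene`,
#'   `score`, `probability`, `known`, ordered by decreasing probability.
#' @export
rank_genes <- function(embeddings, params, chemical, type,
                       candidate_genes = NULL, known_edges = NULL) {
  Zc <- embeddings$chemical
  Zg <- embeddings$gene
  if (is.null(candidate_genes)) candidate_genes <- rownames(Zg)
  if (!length(candidate_genes)) {
    return(data.frame(chemical = character(), interaction_type = character(),
                      gene = character(), score = numeric(),
                      probability = numeric(), known = integer(),
                      stringsAsFactors = FALSE))
  }
  stopifnot(chemical %in% rownames(Zc), all(candidate_genes %in% rownames(Zg)))
  D <- params[[paste0("dec.D.", type)]]
  if (is.null(D)) stop("no decoder parameters for type ", type, call. = FALSE)
  zi <- Zc[rep(chemical, length(candidate_genes)), , drop = FALSE]
  zj <- Zg[candidate_genes, , drop = FALSE]
  s <- dedicom_score(zi, zj, D, params$dec.R)
  known <- integer(length(candidate_genes))
  if (!is.null(known_edges)) {
    kk <- known_edges[known_edges$type == type &
                        known_edges$chemical == chemical, "gene"]
    known <- as.integer(candidate_genes %in% kk)
  }
  out <- data.frame(chemical = chemical, interaction_type = type,
                    gene = candidate_genes, score = s,
                    probability = edge_probability(s), known = known,
                    stringsAsFactors = FALSE)
  reset_rownames(out[order(-out$probability, out$gene), , drop = FALSE])
}
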