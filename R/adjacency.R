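#' Sparse relation adjacencies for message passing
#'
#' Builds one 0/1 sparse adjacency per relation: symmetric square matrices for
#' cc/gg, bipartite matrices for cp/gp (chemical x pathway, gene x pathway),
#' and one chemical x gene matrix per interaction type. When a split is
#' supplied, the typed adjacencies are built from TRAIN edges only, so held-out
#' interactions can never leak into message passing. Row/column sums are the
#' per-node neighbor counts `|N_i^r|` for the two message directions of each
#' relation.
#'
#' @param graph A `cgi_graph`.
#' @param split Optional `cgi_split`; if supplied, typed adjacencies use the
#'   training fold only.
#' @return A `cgi_adjacency`: list with `cc`, `gg`, `cp`, `gp` (sparse
#'   matrices with node-id dimnames) and `cg`, a named list of per-type
#'   matrices.
#' @export
build_adjacencies <- function(graph, split = NULL) {
  n_c <- length(graph$chemicals)
  n_g <- length(graph$genes)
  n_p <- length(graph$pathways)
  sq <- function(edges, ids) {
    i <- match(edges$a, ids); j <- match(edges$b, ids)
    # canonical pairs are unique and loop-free, so no (i, j) cell repeats
    Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1,
                         dims = c(length(ids), length(ids)),
                         dimnames = list(ids, ids))
  }
  bip <- function(edges, rows, cols) {
    Matrix::sparseMatrix(i = match(edges$a, rows), j = match(edges$b, cols),
                         x = 1, dims = c(length(rows), length(cols)),
                         dimnames = list(rows, cols))
  }
  cg_edges <- if (is.null(split)) graph$cg else split_fold(split, "train")
  cg <- lapply(stats::setNames(nm = cg_types(graph)), function(ty) {
    e <- cg_edges[cg_edges$type == ty, , drop = FALSE]
    Matrix::sparseMatrix(i = match(e$chemical, graph$chemicals),
                         j = match(e$gene, graph$genes), x = 1,
                         dims = c(n_c, n_g),
                         dimnames = list(graph$chemicals, graph$genes))
  })
  structure(list(cc = sq(graph$cc, graph$chemicals),
                 gg = sq(graph$gg, graph$genes),
                 cp = bip(graph$cp, graph$chemicals, graph$pathways),
                 gp = bip(graph$gp, graph$genes, graph$pathways),
                 cg = cg),
            class = "cgi_adjacency")
}

#' Neighbor counts for one relation direction
#' @param mat A sparse adjacency (targets x sources).
#' @return Integer vector of per-target neighbor counts (row sums).
#' @export
neighbor_counts <- function(mat) {
  stats::setNames(as.integer(Matrix::rowSums(mat)), rownames(mat))
}

# Symmetrically normalized message operator for one direction: entry (i, j) is
# 1/sqrt(|N_i| |N_j|) on edges, with the zero-degree convention (factor 0 when
# either count is 0 -- vacuous on edges, but kept for clarity).
normalize_direction <- function(mat) {
  rd <- Matrix::rowSums(mat)
  cd <- Matrix::colSums(mat)
  ri <- ifelse(rd > 0, 1 / sqrt(rd), 0)
  ci <- ifelse(cd > 0, 1 / sqrt(cd), 0)
  Matrix::Diagonal(x = ri) %*% mat %*% Matrix::Diagonal(x = ci)
}

# Normalized operator for latent links: receiver degree is the LABELED degree
# |N_i^r| (zero-degree convention applies), sender degree is the latent degree
# |L_l^r| clamped at 1.
normalize_latent <- function(lat, labeled) {
  rd <- Matrix::rowSums(labeled)
  ld <- pmax(Matrix::colSums(lat), 1)
  ri <- ifelse(rd > 0, 1 / sqrt(rd), 0)
  Matrix::Diagonal(x = ri) %*% lat %*% Matrix::Diagonal(x = 1 / sqrt(ld))
}
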