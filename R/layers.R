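#' One relational graph-convolution layer
#'
#' Updates node states over a homogeneous node set connected by one or more
#' relations:
#' \deqn{h_i' = \sigma\Big(\sum_r \sum_{j \in N_i^r}
#'   \frac{1}{\sqrt{|N_i^r|\,|N_j^r|}} W_r h_j + \frac{1}{|N_i^r|} h_i\Big)}
#' The self term is contributed once per relation in which the node has at
#' least one neighbor; all `1/|N|` factors are defined as 0 when the count is
#' 0, so isolated nodes map to the zero vector (before activation). When input
#' and output widths differ, the self pass-through must be carried by a
#' `self_weight` matrix.
#'
#' @param h Numeric matrix of node states (nodes x d_in).
#' @param adjacency List of square 0/1 sparse adjacency matrices, one per
#'   relation (symmetric for undirected relations).
#' @param weights List of `d_in x d_out` matrices, parallel to `adjacency`.
#' @param self_weight Optional `d_in x d_out` matrix for the self term;
#'   `NULL` (identity) requires `d_in == d_out`.
#' @param activation `"relu"` or `"identity"`.
#' @param self_mode `"per_relation"` (self term weighted `1/|N_i^r|` once per
#'   relation with neighbors, as in the update rule above) or `"global"`
#'   (weighted once by the reciprocal of the total degree over all relations).
#' @return Numeric matrix of updated states (nodes x d_out).
#' @examples
#' adj <- Matrix::sparseMatrix(i = c(1, 2), j = c(2, 1), x = 1, dims = c(2, 2))
#' h <- diag(2)
#' rgcn_layer(h, list(adj), list(diag(2)), activation = "identity")
#' @export
rgcn_layer <- function(h, adjacency, weights, self_weight = NULL,
                       activation = c("relu", "identity"),
                       self_mode = c("per_relation", "global")) {
  activation <- match.arg(activation)
  self_mode <- match.arg(self_mode)
  stopifnot(is.matrix(h), length(adjacency) == length(weights))
  d_out <- ncol(weights[[1]])
  if (is.null(self_weight) && ncol(h) != d_out) {
    stop("self_weight is required when input and output widths differ",
         call. = FALSE)
  }
  P <- matrix(0, nrow(h), d_out)
  selfcoef <- numeric(nrow(h))
  total_deg <- numeric(nrow(h))
  for (r in seq_along(adjacency)) {
    A <- adjacency[[r]]
    stopifnot(nrow(A) == nrow(h), ncol(A) == nrow(h),
              nrow(weights[[r]]) == ncol(h))
    P <- P + as.matrix(normalize_direction(A) %*% (h %*% weights[[r]]))
    deg <- Matrix::rowSums(A)
    selfcoef <- selfcoef + ifelse(deg > 0, 1 / deg, 0)
    total_deg <- total_deg + deg
  }
  if (self_mode == "global") {
    selfcoef <- ifelse(total_deg > 0, 1 / total_deg, 0)
  }
  hs <- selfcoef * h
  P <- P + if (is.null(self_weight)) hs else hs %*% self_weight
  out <- apply_activation(P, activation)
  if (!all(is.finite(out))) {
    stop("non-finite output in rgcn_layer", call. = FALSE)
  }
  out
}
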