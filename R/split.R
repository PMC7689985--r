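#' Split typed interactions into train/validation/test folds
#'
#' Randomly partitions the interaction edges of each type with the given
#' ratios (default 8:1:1), independently per type, deterministically for a
#' given seed. Fold sizes follow largest-remainder apportionment, so they
#' match the ratios within one edge.
#'
#' @param graph A `cgi_graph`.
#' @param ratios Numeric triple (train, valid, test); non-negative, sum 1,
#'   train > 0.
#' @param seed Integer seed; the same seed reproduces the split bit-exactly.
#' @return A `cgi_split`: the interaction table with an added `fold` column
#'   (`train`/`valid`/`test`), with `ratios` and `seed` attributes.
#' @export
split_cg_edges <- function(graph, ratios = c(0.8, 0.1, 0.1), seed = 1) {
  stopifnot(length(ratios) == 3, all(ratios >= 0), ratios[1] > 0)
  if (abs(sum(ratios) - 1) > 1e-8) stop("ratios must sum to 1", call. = FALSE)
  counts <- cg_type_counts(graph)
  small <- names(counts)[counts < 3]
  if (length(small)) {
    stop("interaction type(s) with fewer than 3 edges cannot be split (",
         paste(small, collapse = ", "),
         "); raise min_edges in filter_rare_types()", call. = FALSE)
  }
  cg <- graph$cg
  cg$fold <- NA_character_
  with_seed(seed, {
    for (ty in cg_types(graph)) {
      idx <- which(cg$type == ty)
      sizes <- apportion(length(idx), ratios)
      perm <- sample(idx)
      cg$fold[perm] <- rep(c("train", "valid", "test"), sizes)
    }
  })
  structure(cg, class = c("cgi_split", "data.frame"),
            ratios = ratios, seed = seed)
}

#' Extract one fold of a split
#' @param split A `cgi_split`.
#' @param fold One of `"train"`, `"valid"`, `"test"`.
#' @return Data frame of `chemical`, `type`, `gene` rows in that fold.
#' @export
split_fold <- function(split, fold = c("train", "valid", "test")) {
  fold <- match.arg(fold)
  out <- as.data.frame(split)[split$fold == fold,
                              c("chemical", "type", "gene"), drop = FALSE]
  reset_rownames(out)
}

#' A copy of the graph whose interaction layer is the training fold only
#'
#' Used so that latent-link mining and message passing never see held-out
#' edges.
#'
#' @param graph A `cgi_graph`.
#' @param split The matching `cgi_split`.
#' @return A `cgi_graph` with `cg` restricted to training edges.
#' @export
training_graph <- function(graph, split) {
  graph$cg <- split_fold(split, "train")
  graph
}

#' Write / read a split manifest TSV
#'
#' Columns: chemical_id, interaction_type, gene_id, fold.
#'
#' @param split A `cgi_split`.
#' @param path Output file.
#' @return `write_split` returns `path` invisibly; `read_split` returns a
#'   `cgi_split` (without ratio/seed provenance).
#' @export
write_split <- function(split, path) {
  utils::write.table(as.data.frame(split), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  df <- read_edge_tsv(path, 4L)
  names(df) <- c("chemical", "type", "gene", "fold")
  bad <- setdiff(unique(df$fold), c("train", "valid", "test"))
  if (length(bad)) {
    stop("unknown fold label(s) in ", path, ": ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(df, class = c("cgi_split", "data.frame"))
}
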