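#' S-G and S-G-P substructure mining and latent-link selection
#'
#' An S-G substructure is a triangle-like motif: chemical `c` has a typed
#' interaction with gene `g1`, and `g1` associates with gene `g2`; it suggests
#' a candidate link between `c` and `g2` of the same type. An S-G-P
#' substructure additionally requires a pathway shared by the chemical and the
#' genes, grounding the candidate in a mechanism. Candidate links supported by
#' enough S-G-P instances (relative threshold `lambda`, absolute floor 2) are
#' promoted to "definite" latent links and used as extra message-passing edges
#' in the interaction-stage encoder.
#'
#' @name latent-links
NULL

#' Enumerate S-G substructures of one interaction type
#'
#' @param graph A `cgi_graph` (use [training_graph()] to mine on training
#'   edges only).
#' @param type Interaction type id.
#' @return Data frame with columns `chemical`, `gene_known`, `gene_target`:
#'   all (c, g1, g2) with a (c, type, g1) interaction, a g1-g2 association,
#'   and g1 != g2.
#' @export
enumerate_sg <- function(graph, type) {
  cg <- graph$cg[graph$cg$type == type, , drop = FALSE]
  empty <- data.frame(chemical = character(), gene_known = character(),
                      gene_target = character(), stringsAsFactors = FALSE)
  if (nrow(cg) == 0 || nrow(graph$gg) == 0) return(empty)
  # both orientations of the undirected gene-gene layer
  gg <- data.frame(gene_known = c(graph$gg$a, graph$gg$b),
                   gene_target = c(graph$gg$b, graph$gg$a),
                   stringsAsFactors = FALSE)
  out <- merge(data.frame(chemical = cg$chemical, gene_known = cg$gene,
                          stringsAsFactors = FALSE),
               gg, by = "gene_known")
  out <- out[, c("chemical", "gene_known", "gene_target")]
  out <- unique(out)
  reset_rownames(out[order(out$chemical, out$gene_known, out$gene_target), ,
                     drop = FALSE])
}

#' Enumerate S-G-P substructures of one interaction type
#'
#' Extends each S-G instance with a pathway. Under the default `"strict"`
#' reading the pathway must be shared by the chemical and both genes; under
#' `"loose"` it must be shared by the chemical and the known gene only. One
#' instance is emitted per qualifying pathway.
#'
#' @inheritParams enumerate_sg
#' @param pathway_mode `"strict"` (pathway common to c, g1, g2) or `"loose"`
#'   (common to c and g1).
#' @return Data frame with columns `chemical`, `gene_known`, `gene_target`,
#'   `pathway`.
#' @export
enumerate_sgp <- function(graph, type, pathway_mode = c("strict", "loose")) {
  pathway_mode <- match.arg(pathway_mode)
  sg <- enumerate_sg(graph, type)
  empty <- data.frame(chemical = character(), gene_known = character(),
                      gene_target = character(), pathway = character(),
                      stringsAsFactors = FALSE)
  if (nrow(sg) == 0 || nrow(graph$cp) == 0 || nrow(graph$gp) == 0) return(empty)
  cp <- data.frame(chemical = graph$cp$a, pathway = graph$cp$b,
                   stringsAsFactors = FALSE)
  out <- merge(sg, cp, by = "chemical")
  gp_key <- pair_key(graph$gp$a, graph$gp$b)
  out <- out[pair_key(out$gene_known, out$pathway) %in% gp_key, , drop = FALSE]
  if (pathway_mode == "strict") {
    out <- out[pair_key(out$gene_target, out$pathway) %in% gp_key, , drop = FALSE]
  }
  out <- out[, c("chemical", "gene_known", "gene_target", "pathway")]
  reset_rownames(out[order(out$chemical, out$gene_known, out$gene_target,
                           out$pathway), , drop = FALSE])
}

#' Count S-G-P support for candidate latent links
#'
#' A candidate is a (chemical, gene_target) pair implied by at least one
#' substructure instance and not already a known edge of the type; its support
#' is the number of distinct instances implying it.
#'
#' @param instances Output of [enumerate_sgp()] (or [enumerate_sg()]).
#' @param known_edges Data frame with `chemical` and `gene` columns: the known
#'   (training) edges of the same type.
#' @return Data frame with columns `chemical`, `gene`, `support`, sorted by
#'   decreasing support.
#' @export
count_support <- function(instances, known_edges) {
  empty <- data.frame(chemical = character(), gene = character(),
                      support = integer(), stringsAsFactors = FALSE)
  if (nrow(instances) == 0) return(empty)
  instances <- unique(instances)
  key <- pair_key(instances$chemical, instances$gene_target)
  known <- pair_key(known_edges$chemical, known_edges$gene)
  key <- key[!(key %in% known)]
  if (!length(key)) return(empty)
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  out <- data.frame(chemical = vapply(parts, `[`, "", 1L),
                    gene = vapply(parts, `[`, "", 2L),
                    support = as.integer(tab), stringsAsFactors = FALSE)
  reset_rownames(out[order(-out$support, out$chemical, out$gene), , drop = FALSE])
}

#' Select definite latent links by relative support threshold
#'
#' A candidate with support `N` is definite iff
#' `N >= max(2, max(all supports) * lambda)` (inclusive cutoff). Support-1
#' candidates are therefore never definite.
#'
#' @param candidates Output of [count_support()].
#' @param lambda Threshold coefficient in (0, 1]. Values above 0.5 may leave
#'   some types with no definite links.
#' @return `candidates` with an added logical `definite` column.
#' @export
select_definite <- function(candidates, lambda) {
  stopifnot(lambda > 0, lambda <= 1)
  if (nrow(candidates) == 0) {
    candidates$definite <- logical()
    return(candidates)
  }
  cutoff <- max(2, max(candidates$support) * lambda)
  candidates$definite <- candidates$support >= cutoff
  candidates
}

#' Mine latent links for every interaction type
#'
#' Runs the S-G-P pipeline per type on TRAINING edges only: enumeration,
#' support counting, and definite selection.
#'
#' @param graph A `cgi_graph`.
#' @param split A `cgi_split` for `graph`.
#' @param lambda Threshold coefficient in (0, 1].
#' @param pathway_mode Passed to [enumerate_sgp()].
#' @return A `cgi_latent`: list with `links` (data frame: `chemical`, `type`,
#'   `gene`, `support`, `definite`), `lambda`, and `pathway_mode`.
#' @export
mine_latent_links <- function(graph, split, lambda = 0.5,
                              pathway_mode = c("strict", "loose")) {
  pathway_mode <- match.arg(pathway_mode)
  tg <- training_graph(graph, split)
  per_type <- lapply(cg_types(graph), function(ty) {
    train <- tg$cg[tg$cg$type == ty, , drop = FALSE]
    cand <- count_support(enumerate_sgp(tg, ty, pathway_mode), train)
    cand <- select_definite(cand, lambda)
    if (nrow(cand)) cand$type <- ty
    cand
  })
  links <- do.call(rbind, per_type[vapply(per_type, nrow, 0L) > 0])
  if (is.null(links)) {
    links <- data.frame(chemical = character(), gene = character(),
                        support = integer(), definite = logical(),
                        type = character(), stringsAsFactors = FALSE)
  }
  links <- links[, c("chemical", "type", "gene", "support", "definite")]
  structure(list(links = reset_rownames(links), lambda = lambda,
                 pathway_mode = pathway_mode),
            class = "cgi_latent")
}

#' @export
print.cgi_latent <- function(x, ...) {
  cat(sprintf("cgi_latent: %d candidate link(s), %d definite (lambda = %g, %s)\n",
              nrow(x$links), sum(x$links$definite), x$lambda, x$pathway_mode))
  invisible(x)
}

#' Definite latent links as per-type sparse adjacencies
#'
#' @param latent A `cgi_latent`.
#' @param graph The `cgi_graph` it was mined from.
#' @return Named list (by type) of chemical x gene 0/1 sparse matrices.
#' @export
latent_adjacencies <- function(latent, graph) {
  lapply(stats::setNames(nm = cg_types(graph)), function(ty) {
    d <- latent$links[latent$links$type == ty & latent$links$definite, ,
                      drop = FALSE]
    Matrix::sparseMatrix(i = match(d$chemical, graph$chemicals),
                         j = match(d$gene, graph$genes), x = 1,
                         dims = c(length(graph$chemicals), length(graph$genes)),
                         dimnames = list(graph$chemicals, graph$genes))
  })
}

#' Write mined latent links as TSV
#'
#' Columns: chemical_id, interaction_type, gene_id, support_count,
#' definite (0/1).
#'
#' @param latent A `cgi_latent`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_latent_links <- function(latent, path) {
  df <- latent$links
  df$definite <- as.integer(df$definite)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Substructure coverage statistics per interaction type
#'
#' For each type, the number and fraction of its interactions (c, type, g)
#' whose gene appears as the known or the target gene of some same-type S-G
#' (resp. S-G-P) instance involving the same chemical. Types are sorted by
#' interaction count (descending) and stratified into `n_groups` groups of
#' near-equal size.
#'
#' @param graph A `cgi_graph`.
#' @param pathway_mode Passed to [enumerate_sgp()].
#' @param n_groups Number of frequency strata (default 5).
#' @return Data frame with one row per type: `type`, `n_cgi`, `n_sg`,
#'   `prop_sg`, `n_sgp`, `prop_sgp`, `group`.
#' @export
coverage_stats <- function(graph, pathway_mode = c("strict", "loose"),
                           n_groups = 5) {
  pathway_mode <- match.arg(pathway_mode)
  counts <- cg_type_counts(graph)
  types <- names(counts)
  rows <- lapply(types, function(ty) {
    edges <- graph$cg[graph$cg$type == ty, , drop = FALSE]
    ekey <- pair_key(edges$chemical, edges$gene)
    covered <- function(inst) {
      if (nrow(inst) == 0) return(0L)
      in_motif <- c(pair_key(inst$chemical, inst$gene_known),
                    pair_key(inst$chemical, inst$gene_target))
      sum(ekey %in% in_motif)
    }
    n_sg <- covered(enumerate_sg(graph, ty))
    n_sgp <- covered(enumerate_sgp(graph, ty, pathway_mode))
    data.frame(type = ty, n_cgi = nrow(edges),
               n_sg = n_sg, prop_sg = n_sg / nrow(edges),
               n_sgp = n_sgp, prop_sgp = n_sgp / nrow(edges),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$group <- ceiling(seq_len(nrow(out)) * n_groups / nrow(out))
  reset_rownames(out)
}
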