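#' Construct an integrated multi-relational chemical/gene/pathway graph
#'
#' The graph holds three node classes and five relation layers: four binary
#' association subgraphs (chemical-chemical, gene-gene, chemical-pathway,
#' gene-pathway) and one multi-interaction subgraph of typed chemical-gene
#' edges. Node ids are strings; ordering is the sorted order of ids so that
#' internal indices are deterministic. Undirected cc/gg edges are stored once
#' in canonical (pmin, pmax) form; duplicate edges and triples are collapsed.
#'
#' @param chemicals,genes,pathways Character vectors of node ids.
#' @param cc,gg Two-column data frames of undirected within-class edges.
#' @param cp,gp Two-column data frames (chemical/gene id, pathway id).
#' @param cg Three-column data frame: chemical id, interaction type
#'   (`"degree^action"`), gene id.
#' @return An object of class `cgi_graph`.
#' @export
cgi_graph <- function(chemicals, genes, pathways,
                      cc = NULL, gg = NULL, cp = NULL, gp = NULL, cg = NULL) {
  empty2 <- data.frame(a = character(), b = character(), stringsAsFactors = FALSE)
  empty3 <- data.frame(chemical = character(), type = character(),
                       gene = character(), stringsAsFactors = FALSE)
  chemicals <- sort(unique(as.character(chemicals)))
  genes <- sort(unique(as.character(genes)))
  pathways <- sort(unique(as.character(pathways)))
  if (length(intersect(chemicals, genes)) || length(intersect(chemicals, pathways)) ||
      length(intersect(genes, pathways))) {
    stop("node ids must be unique across node classes", call. = FALSE)
  }

  check_nodes <- function(ids, universe, relation, side) {
    bad <- setdiff(unique(ids), universe)
    if (length(bad)) {
      stop(sprintf("unknown %s id(s) in %s edges: %s", side, relation,
                   paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
    }
  }

  dedup_report <- function(n_in, n_out, relation) {
    if (n_in > n_out) {
      message(sprintf("collapsed %d duplicate %s edge(s)", n_in - n_out, relation))
    }
  }

  prep_pairs <- function(df, universe, relation) {
    if (is.null(df) || nrow(df) == 0) return(empty2)
    df <- data.frame(a = as.character(df[[1]]), b = as.character(df[[2]]),
                     stringsAsFactors = FALSE)
    check_nodes(c(df$a, df$b), universe, relation, "node")
    out <- canonical_pairs(df, relation)
    dedup_report(sum(df$a != df$b), nrow(out), relation)
    reset_rownames(out)
  }

  prep_bip <- function(df, left, right, relation, left_name, right_name) {
    if (is.null(df) || nrow(df) == 0) return(empty2)
    df <- data.frame(a = as.character(df[[1]]), b = as.character(df[[2]]),
                     stringsAsFactors = FALSE)
    check_nodes(df$a, left, relation, left_name)
    check_nodes(df$b, right, relation, right_name)
    out <- canonical_bipartite(df)
    dedup_report(nrow(df), nrow(out), relation)
    reset_rownames(out)
  }

  cc <- prep_pairs(cc, chemicals, "cc")
  gg <- prep_pairs(gg, genes, "gg")
  cp <- prep_bip(cp, chemicals, pathways, "cp", "chemical", "pathway")
  gp <- prep_bip(gp, genes, pathways, "gp", "gene", "pathway")

  if (is.null(cg) || nrow(cg) == 0) {
    cg <- empty3
  } else {
    cg <- data.frame(chemical = as.character(cg[[1]]),
                     type = as.character(cg[[2]]),
                     gene = as.character(cg[[3]]), stringsAsFactors = FALSE)
    check_nodes(cg$chemical, chemicals, "cg", "chemical")
    check_nodes(cg$gene, genes, "cg", "gene")
    parse_interaction_type(unique(cg$type))
    n_in <- nrow(cg)
    cg <- unique(cg)
    cg <- reset_rownames(cg[order(cg$type, cg$chemical, cg$gene), , drop = FALSE])
    dedup_report(n_in, nrow(cg), "cg")
  }

  structure(list(chemicals = chemicals, genes = genes, pathways = pathways,
                 cc = cc, gg = gg, cp = cp, gp = gp, cg = cg),
            class = "cgi_graph")
}

#' @export
print.cgi_graph <- function(x, ...) {
  cat("cgi_graph:",
      length(x$chemicals), "chemicals,",
      length(x$genes), "genes,",
      length(x$pathways), "pathways\n")
  cat(sprintf("  cc: %d  gg: %d  cp: %d  gp: %d edges\n",
              nrow(x$cc), nrow(x$gg), nrow(x$cp), nrow(x$gp)))
  cat(sprintf("  cg: %d typed interactions across %d type(s)\n",
              nrow(x$cg), length(cg_types(x))))
  invisible(x)
}

#' Interaction types present in a graph
#' @param graph A `cgi_graph`.
#' @return Sorted character vector of type ids (the relation vocabulary of the
#'   multi-interaction subgraph).
#' @export
cg_types <- function(graph) sort(unique(graph$cg$type))

#' Per-type interaction counts
#' @param graph A `cgi_graph`.
#' @return Named integer vector, descending by count (ties by type id).
#' @export
cg_type_counts <- function(graph) {
  tab <- table(graph$cg$type)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  counts[order(-counts, names(counts))]
}

read_edge_tsv <- function(path, ncols) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != ncols)
  if (length(bad)) {
    stop(sprintf("malformed line %d in %s: expected %d tab-separated fields",
                 idx[bad[1]], path, ncols), call. = FALSE)
  }
  if (!length(fields)) {
    return(as.data.frame(matrix(character(), ncol = ncols),
                         stringsAsFactors = FALSE))
  }
  as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
}

#' Load a multi-relational graph from TSV files
#'
#' Reads a node manifest (`node_id <TAB> node_class`) plus up to five
#' headerless edge files: two-column association layers (`cc`, `gg`, `cp`,
#' `gp`) and the three-column typed interaction layer `cg`
#' (`chemical <TAB> interaction_type <TAB> gene`). Lines starting with `#`
#' are skipped. Unknown node ids or interaction types raise errors; duplicate
#' edges are collapsed with a message.
#'
#' @param node_manifest Path to the node manifest TSV.
#' @param edge_files Named character vector or list mapping relation names
#'   (subset of `cc`, `gg`, `cp`, `gp`, `cg`) to file paths.
#' @return A `cgi_graph`.
#' @export
load_graph <- function(node_manifest, edge_files) {
  nodes <- read_edge_tsv(node_manifest, 2L)
  names(nodes) <- c("node_id", "node_class")
  bad <- setdiff(unique(nodes$node_class), c("chemical", "gene", "pathway"))
  if (length(bad)) {
    stop("unknown node class(es) in ", node_manifest, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  edge_files <- as.list(edge_files)
  bad <- setdiff(names(edge_files), c("cc", "gg", "cp", "gp", "cg"))
  if (length(bad)) {
    stop("unknown relation name(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  missing <- !vapply(edge_files, file.exists, logical(1))
  if (any(missing)) {
    stop("edge file(s) not found: ",
         paste(unlist(edge_files[missing]), collapse = ", "), call. = FALSE)
  }
  get_edges <- function(rel, ncols) {
    if (is.null(edge_files[[rel]])) NULL else read_edge_tsv(edge_files[[rel]], ncols)
  }
  cgi_graph(chemicals = nodes$node_id[nodes$node_class == "chemical"],
            genes = nodes$node_id[nodes$node_class == "gene"],
            pathways = nodes$node_id[nodes$node_class == "pathway"],
            cc = get_edges("cc", 2L), gg = get_edges("gg", 2L),
            cp = get_edges("cp", 2L), gp = get_edges("gp", 2L),
            cg = get_edges("cg", 3L))
}

#' Write a graph to the TSV dialect read by [load_graph()]
#'
#' @param graph A `cgi_graph`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_graph <- function(graph, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(nodes = file.path(dir, "nodes.tsv"),
             cc = file.path(dir, "cc.tsv"), gg = file.path(dir, "gg.tsv"),
             cp = file.path(dir, "cp.tsv"), gp = file.path(dir, "gp.tsv"),
             cg = file.path(dir, "cg.tsv"))
  nodes <- data.frame(
    node_id = c(graph$chemicals, graph$genes, graph$pathways),
    node_class = rep(c("chemical", "gene", "pathway"),
                     c(length(graph$chemicals), length(graph$genes),
                       length(graph$pathways))),
    stringsAsFactors = FALSE)
  write_tsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  write_tsv(nodes, paths[["nodes"]])
  for (rel in c("cc", "gg", "cp", "gp", "cg")) write_tsv(graph[[rel]], paths[[rel]])
  invisible(paths)
}

#' Drop interaction types with too few edges
#'
#' Restricts the multi-interaction subgraph to types observed in at least
#' `min_edges` interactions (inclusive bound); all triples of dropped types are
#' removed. The default reflects the curation rule of keeping only types with
#' at least 180 observed interactions.
#'
#' @param graph A `cgi_graph`.
#' @param min_edges Minimum per-type interaction count (>= 1).
#' @return A `cgi_graph` with the filtered interaction layer.
#' @export
filter_rare_types <- function(graph, min_edges = 180) {
  stopifnot(min_edges >= 1)
  counts <- cg_type_counts(graph)
  keep <- names(counts)[counts >= min_edges]
  if (!length(keep)) {
    stop("no interaction types survive min_edges = ", min_edges,
         "; no relations survive", call. = FALSE)
  }
  graph$cg <- reset_rownames(graph$cg[graph$cg$type %in% keep, , drop = FALSE])
  graph
}

#' Trim association layers to nodes anchored in cp/gp/cg
#'
#' Removes from the cc/gg layers every node (with its incident cc/gg edges)
#' that participates in none of the chemical-pathway, gene-pathway, or
#' chemical-gene layers, then restricts the chemical and gene node lists to
#' nodes appearing in at least one surviving edge. Idempotent.
#'
#' @param graph A `cgi_graph`.
#' @return The trimmed `cgi_graph`.
#' @export
trim_association_graphs <- function(graph) {
  anchored_c <- unique(c(graph$cp$a, graph$cg$chemical))
  anchored_g <- unique(c(graph$gp$a, graph$cg$gene))
  keep_cc <- graph$cc$a %in% anchored_c & graph$cc$b %in% anchored_c
  keep_gg <- graph$gg$a %in% anchored_g & graph$gg$b %in% anchored_g
  graph$cc <- reset_rownames(graph$cc[keep_cc, , drop = FALSE])
  graph$gg <- reset_rownames(graph$gg[keep_gg, , drop = FALSE])
  graph$chemicals <- sort(unique(c(graph$cc$a, graph$cc$b, anchored_c)))
  graph$genes <- sort(unique(c(graph$gg$a, graph$gg$b, anchored_g)))
  graph
}
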