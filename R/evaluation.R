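#' Sample evaluation negatives for one interaction type
#'
#' Draws `n` chemical-gene pairs of the given type that appear in no fold
#' (train, validation, or test) of that type, uniformly at random,
#' deterministically for a seed.
#'
#' @param graph A `cgi_graph`.
#' @param split A `cgi_split`.
#' @param type Interaction type id.
#' @param n Number of non-edges to draw (>= 1).
#' @param seed Integer seed.
#' @return Data frame with `chemical` and `gene` columns.
#' @export
sample_eval_negatives <- function(graph, split, type, n, seed = 1) {
  stopifnot(n >= 1)
  n_c <- length(graph$chemicals)
  n_g <- length(graph$genes)
  known <- split[split$type == type, , drop = FALSE]
  known_cells <- (match(known$chemical, graph$chemicals) - 1) * n_g +
    match(known$gene, graph$genes)
  n_free <- n_c * n_g - length(known_cells)
  if (n_free < n) {
    stop("only ", n_free, " non-edges exist for type ", type,
         "; cannot sample ", n, call. = FALSE)
  }
  cells <- with_seed(seed, {
    if (n_c * n_g <= 2e6) {
      free <- setdiff(seq_len(n_c * n_g), known_cells)
      sample(free, n)
    } else {
      out <- integer(0)
      while (length(out) < n) {
        cand <- sample.int(n_c * n_g, n)
        cand <- setdiff(cand, c(known_cells, out))
        out <- c(out, cand)
      }
      out[seq_len(n)]
    }
  })
  data.frame(chemical = graph$chemicals[(cells - 1) %/% n_g + 1],
             gene = graph$genes[(cells - 1) %% n_g + 1],
             stringsAsFactors = FALSE)
}

#' Ranking metrics: AUROC, AUPRC, AP@k
#'
#' `auroc` is the Mann-Whitney probability that a random positive outscores a
#' random negative, with ties counted one half. `auprc` is the area under the
#' precision-recall curve by the step-wise rule (precision averaged at each
#' positive's rank; no trapezoids), with tied scores ordered pessimistically
#' (negatives first). `ap_at_k` averages precision at the positive ranks
#' within the top `k`, divided by `min(k, total positives)`.
#'
#' @param scores_pos,scores_neg Numeric score vectors (both non-empty).
#' @return A number in `[0, 1]`.
#' @export
auroc <- function(scores_pos, scores_neg) {
  if (!length(scores_pos) || !length(scores_neg)) {
    stop("auroc is undefined for empty score sets", call. = FALSE)
  }
  r <- rank(c(scores_pos, scores_neg))
  np <- length(scores_pos)
  nn <- length(scores_neg)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' @rdname auroc
#' @export
auprc <- function(scores_pos, scores_neg) {
  if (!length(scores_pos) || !length(scores_neg)) {
    stop("auprc is undefined for empty score sets", call. = FALSE)
  }
  labels <- c(rep(1L, length(scores_pos)), rep(0L, length(scores_neg)))
  scores <- c(scores_pos, scores_neg)
  ord <- order(-scores, labels) # ties: negatives ranked ahead (pessimistic)
  labels <- labels[ord]
  hits <- cumsum(labels)
  mean((hits / seq_along(labels))[labels == 1])
}

#' @rdname auroc
#' @param ranked_labels 0/1 vector of relevance labels in rank order (best
#'   first).
#' @param k Cutoff rank (>= 1).
#' @export
ap_at_k <- function(ranked_labels, k = 20) {
  stopifnot(k >= 1)
  n_pos <- sum(ranked_labels == 1)
  if (n_pos == 0) return(0)
  top <- ranked_labels[seq_len(min(k, length(ranked_labels)))]
  prec <- cumsum(top) / seq_along(top)
  sum(prec[top == 1]) / min(k, n_pos)
}

#' Evaluate a trained model per interaction type
#'
#' Scores the positives of the chosen fold against sampled non-edges
#' (`neg_ratio` negatives per positive, default 1:1) for each type, computes
#' AUROC, AUPRC and AP@k, and macro-averages over the evaluated types. Types
#' with no positives in the fold are skipped with a warning and excluded from
#' the macro average. Ranking ties are broken by id via a stable sort, so
#' reports are reproducible.
#'
#' @param model A trained `cginet_model`.
#' @param fold `"valid"` or `"test"`.
#' @param k AP@k cutoff (default 20).
#' @param neg_ratio Negatives sampled per positive.
#' @param seed Seed for negative sampling.
#' @param quiet Suppress skip warnings.
#' @return A `cgi_eval`: list with `per_type` (data frame: `interaction_type`,
#'   `n_pos`, `n_neg`, `auroc`, `auprc`, `ap_at_k`), `macro` (named list of
#'   unweighted means), and `metadata` (variant, seed, lambda, latent mode,
#'   fold, k).
#' @export
evaluate_model <- function(model, fold = c("test", "valid"), k = 20,
                           neg_ratio = 1, seed = 1, quiet = FALSE) {
  fold <- match.arg(fold)
  graph <- model$graph
  split <- model$split
  H <- encode(model)
  edges <- split_fold(split, fold)
  rows <- list()
  for (ty in cg_types(graph)) {
    pos <- edges[edges$type == ty, , drop = FALSE]
    if (nrow(pos) == 0) {
      if (!quiet) {
        warning("type ", ty, " has no ", fold, " positives; skipped",
                call. = FALSE)
      }
      next
    }
    n_neg <- max(1L, round(neg_ratio * nrow(pos)))
    neg <- sample_eval_negatives(graph, split, ty, n_neg, seed = seed)
    D <- model$params[[paste0("dec.D.", ty)]]
    score_pairs <- function(df) {
      dedicom_score(H$chemical[df$chemical, , drop = FALSE],
                    H$gene[df$gene, , drop = FALSE], D, model$params$dec.R)
    }
    s_pos <- score_pairs(pos)
    s_neg <- score_pairs(neg)
    # stable id-ordered ranking for the truncated metric
    all_ids <- c(pair_key(pos$chemical, pos$gene),
                 pair_key(neg$chemical, neg$gene))
    scores <- c(s_pos, s_neg)
    labels <- c(rep(1L, nrow(pos)), rep(0L, nrow(neg)))
    ord <- order(-scores, all_ids)
    rows[[ty]] <- data.frame(
      interaction_type = ty, n_pos = nrow(pos), n_neg = nrow(neg),
      auroc = auroc(s_pos, s_neg), auprc = auprc(s_pos, s_neg),
      ap_at_k = ap_at_k(labels[ord], k), stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no interaction type has ", fold, " positives",
                          call. = FALSE)
  per_type <- reset_rownames(do.call(rbind, rows))
  macro <- list(auroc = mean(per_type$auroc), auprc = mean(per_type$auprc),
                ap_at_k = mean(per_type$ap_at_k))
  structure(list(per_type = per_type, macro = macro,
                 metadata = list(variant = model$variant, seed = seed,
                                 lambda = model$latent$lambda,
                                 latent_mode = model$config$latent_mode,
                                 fold = fold, k = k)),
            class = "cgi_eval")
}

#' @export
print.cgi_eval <- function(x, ...) {
  cat(sprintf("cgi_eval <%s, %s fold>: macro AUROC %.3f, AUPRC %.3f, AP@%d %.3f\n",
              x$metadata$variant, x$metadata$fold, x$macro$auroc,
              x$macro$auprc, x$metadata$k, x$macro$ap_at_k))
  print(x$per_type)
  invisible(x)
}

#' Write evaluation reports as TSV
#'
#' `report.tsv` holds the per-type table; `report_macro.tsv` one row of macro
#' averages with run metadata.
#'
#' @param eval A `cgi_eval`.
#' @param dir Output directory.
#' @return Invisibly, the two file paths.
#' @export
write_eval_report <- function(eval, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(dir, "report.tsv")
  p2 <- file.path(dir, "report_macro.tsv")
  utils::write.table(eval$per_type, p1, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  macro <- data.frame(variant = eval$metadata$variant,
                      seed = eval$metadata$seed,
                      auroc = eval$macro$auroc, auprc = eval$macro$auprc,
                      ap_at_k = eval$macro$ap_at_k)
  utils::write.table(macro, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2))
}
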