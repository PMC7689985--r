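`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG seed, evaluates `expr`, and restores the caller's RNG state so
#' that seeded helpers never perturb the global random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Collision-free composite keys for edge identity (node ids never contain \r).
# Zero-length input yields zero keys (paste() would recycle to length 1).
pair_key <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) return(character(0))
  paste(a, b, sep = "\r")
}
triple_key <- function(a, b, c) {
  if (length(a) == 0L || length(b) == 0L || length(c) == 0L) return(character(0))
  paste(a, b, c, sep = "\r")
}

# Canonicalize an undirected edge table: pmin/pmax ordering, self-loops
# dropped, duplicates collapsed, rows sorted.
canonical_pairs <- function(df, what = "edge") {
  if (nrow(df) == 0) {
    return(data.frame(a = character(), b = character(), stringsAsFactors = FALSE))
  }
  a <- pmin(df[[1]], df[[2]])
  b <- pmax(df[[1]], df[[2]])
  keep <- a != b
  n_loops <- sum(!keep)
  if (n_loops > 0) {
    message(sprintf("dropping %d self-loop(s) in %s edges", n_loops, what))
  }
  out <- unique(data.frame(a = a[keep], b = b[keep], stringsAsFactors = FALSE))
  out[order(out$a, out$b), , drop = FALSE]
}

# Deduplicate + sort a bipartite edge table.
canonical_bipartite <- function(df) {
  out <- unique(data.frame(a = as.character(df[[1]]), b = as.character(df[[2]]),
                           stringsAsFactors = FALSE))
  out[order(out$a, out$b), , drop = FALSE]
}

reset_rownames <- function(df) {
  rownames(df) <- NULL
  df
}

# Largest-remainder apportionment of n into parts proportional to `ratios`;
# ties go to earlier entries. Guarantees sum(out) == n and |out - n*ratios| <= 1.
apportion <- function(n, ratios) {
  exact <- n * ratios / sum(ratios)
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- exact - base
    extra <- order(-frac, seq_along(frac))[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}
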