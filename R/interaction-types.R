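#' Interaction-type vocabulary
#'
#' A typed chemical-gene interaction combines a degree (`increases`,
#' `decreases`, or `affects`) with a free-text action (e.g. `activity`,
#' `expression`, `cleavage`), written canonically as `"degree^action"`.
#'
#' @name interaction-types
NULL

cgi_degrees <- c("increases", "decreases", "affects")

#' Parse canonical interaction-type identifiers
#'
#' @param x Character vector of `"degree^action"` identifiers.
#' @return A data frame with columns `id`, `degree`, and `action`, one row per
#'   element of `x`.
#' @examples
#' parse_interaction_type("increases^activity")
#' @export
parse_interaction_type <- function(x) {
  x <- as.character(x)
  parts <- strsplit(x, "^", fixed = TRUE)
  ok <- lengths(parts) == 2L
  degree <- ifelse(ok, vapply(parts, `[`, "", 1L), NA_character_)
  action <- ifelse(ok, vapply(parts, `[`, "", 2L), NA_character_)
  ok <- ok & degree %in% cgi_degrees & !is.na(action) & nzchar(action)
  if (!all(ok)) {
    stop("invalid interaction type id(s): ",
         paste(unique(x[!ok]), collapse = ", "),
         " (expected \"degree^action\" with degree one of ",
         paste(cgi_degrees, collapse = "/"), ")", call. = FALSE)
  }
  data.frame(id = x, degree = degree, action = action,
             stringsAsFactors = FALSE)
}

# Actions used by the synthetic vocabulary, with parent groupings mirroring the
# kind of hierarchy curated interaction ontologies use (e.g. cleavage and
# phosphorylation are forms of metabolic processing).
.cgi_action_catalog <- data.frame(
  action = c("expression", "activity", "phosphorylation", "localization",
             "transport", "cleavage", "secretion", "uptake", "acetylation",
             "degradation", "binding", "sumoylation"),
  parent = c(NA, NA, "metabolic processing", NA,
             NA, "metabolic processing", "transport", "transport",
             "metabolic processing", "metabolic processing", NA,
             "metabolic processing"),
  stringsAsFactors = FALSE
)

#' Construct a synthetic interaction-type vocabulary
#'
#' Cycles degrees over a catalog of plausible actions to produce `n` distinct
#' canonical type identifiers, each with an optional parent type.
#'
#' @param n Number of interaction types.
#' @return Data frame with columns `id`, `degree`, `action`, `parent_type`.
#' @export
cgi_type_vocabulary <- function(n) {
  stopifnot(n >= 1)
  grid <- expand.grid(degree = cgi_degrees,
                      action = .cgi_action_catalog$action,
                      stringsAsFactors = FALSE)
  if (n > nrow(grid)) {
    stop("at most ", nrow(grid), " synthetic interaction types are available")
  }
  grid <- grid[seq_len(n), , drop = FALSE]
  data.frame(
    id = paste0(grid$degree, "^", grid$action),
    degree = grid$degree,
    action = grid$action,
    parent_type = .cgi_action_catalog$parent[match(grid$action,
                                                   .cgi_action_catalog$action)],
    stringsAsFactors = FALSE
  )
}
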