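#' Assemble a function-prediction dataset
#'
#' Bundles the tables the cascade consumes: protein sequences, multi-label
#' annotations, pairwise alignment hits and weighted interaction edges.
#' Interaction edges given in a foreign identifier space (e.g. a network
#' database's own accession scheme) are translated through `id_map`; edges
#' whose endpoints cannot be mapped are dropped, so unmapped proteins simply
#' lack interaction evidence.
#'
#' Alignment hits are aggregated to one score per (query, subject) pair by
#' maximum, and interaction edges are undirected (duplicate and reversed
#' edges collapse to the heaviest).
#'
#' @param annotations Data frame with columns `protein`, `category`.
#' @param sequences Optional data frame with columns `protein`, `sequence`
#'   (required as soon as PseAAC evidence is used).
#' @param similarity Optional data frame with columns `query`, `subject`,
#'   `score` (non-negative alignment scores, e.g. bit scores).
#' @param interactions Optional data frame with columns `protein1`,
#'   `protein2`, `weight` (non-negative combined scores).
#' @param id_map Optional data frame with columns `protein`, `network_id`
#'   mapping annotation-space identifiers to the interaction file's space.
#' @param scheme Function scheme, see [funcat_scheme()].
#' @return An object of class `fc_dataset` (a named list of tibbles).
#' @export
fc_dataset <- function(annotations, sequences = NULL, similarity = NULL,
                       interactions = NULL, id_map = NULL,
                       scheme = funcat_scheme()) {
  scheme <- validate_scheme(scheme)
  annotations <- need_cols(annotations, c("protein", "category"),
                           "annotations")
  annotations$protein <- as.character(annotations$protein)
  annotations$category <- as.integer(annotations$category)
  bad <- setdiff(unique(annotations$category), scheme$category)
  if (length(bad))
    abort(sprintf("Annotation uses category %d, not in the scheme.", bad[1]))

  if (!is.null(sequences)) {
    sequences <- need_cols(sequences, c("protein", "sequence"), "sequences")
    sequences$protein <- as.character(sequences$protein)
    if (anyDuplicated(sequences$protein))
      abort("Duplicate protein in `sequences`.")
  }
  if (!is.null(similarity)) {
    similarity <- need_cols(similarity, c("query", "subject", "score"),
                            "similarity")
    check_nonneg(similarity$score, "similarity scores")
    similarity <- similarity |>
      mutate(query = as.character(query), subject = as.character(subject)) |>
      group_by(query, subject) |>
      summarise(score = max(score), .groups = "drop")
  }
  if (!is.null(interactions)) {
    interactions <- need_cols(interactions,
                              c("protein1", "protein2", "weight"),
                              "interactions")
    check_nonneg(interactions$weight, "interaction weights")
    interactions <- interactions |>
      mutate(protein1 = as.character(protein1),
             protein2 = as.character(protein2))
    if (!is.null(id_map)) {
      id_map <- need_cols(id_map, c("protein", "network_id"), "id_map")
      back <- setNames(as.character(id_map$protein),
                       as.character(id_map$network_id))
      interactions <- interactions |>
        mutate(protein1 = unname(back[protein1]),
               protein2 = unname(back[protein2])) |>
        filter(!is.na(protein1), !is.na(protein2))
    }
    # undirected: canonical endpoint order, heaviest weight wins
    if (nrow(interactions))
      interactions <- interactions |>
        mutate(a = pmin(protein1, protein2), b = pmax(protein1, protein2)) |>
        group_by(a, b) |>
        summarise(weight = max(weight), .groups = "drop") |>
        rename(protein1 = a, protein2 = b)
    else
      interactions <- select(interactions, protein1, protein2, weight)
  }
  structure(list(annotations = as_tibble(annotations),
                 sequences = if (!is.null(sequences)) as_tibble(sequences),
                 similarity = if (!is.null(similarity)) as_tibble(similarity),
                 interactions = if (!is.null(interactions))
                   as_tibble(interactions),
                 scheme = scheme),
            class = "fc_dataset")
}

#' @export
print.fc_dataset <- function(x, ...) {
  n <- length(unique(x$annotations$protein))
  cat("<fc_dataset>\n")
  cat(sprintf("  proteins annotated : %d (%d labels, %d categories)\n",
              n, nrow(distinct(x$annotations, protein, category)),
              nrow(x$scheme)))
  cat(sprintf("  sequences          : %s\n",
              if (is.null(x$sequences)) "none" else nrow(x$sequences)))
  cat(sprintf("  similarity hits    : %s\n",
              if (is.null(x$similarity)) "none" else nrow(x$similarity)))
  cat(sprintf("  interaction edges  : %s\n",
              if (is.null(x$interactions)) "none" else nrow(x$interactions)))
  invisible(x)
}

need_cols <- function(x, cols, what) {
  if (!is.data.frame(x) || !all(cols %in% names(x)))
    abort(sprintf("`%s` must be a data frame with columns %s.", what,
                  paste0("`", cols, "`", collapse = ", ")))
  as_tibble(x)
}

check_nonneg <- function(x, what) {
  if (anyNA(x) || any(!is.finite(x)) || any(x < 0))
    abort(sprintf("All %s must be finite and non-negative.", what))
  invisible(x)
}
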