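#' Functional category schemes
#'
#' `funcat_scheme()` returns the default scheme: the 24 top-level categories
#' of the Functional Catalogue (FunCat) together with the number of annotated
#' mouse proteins per category in the reference collection, which the
#' synthetic benchmark generator uses as default sampling weights.  Any tibble
#' with unique integer `category` numbers and `label` strings (at least two
#' rows) is accepted wherever a scheme is expected, so small custom schemes
#' can be used in tests and experiments.
#'
#' @return A tibble with columns `category` (integer), `label` (character)
#'   and `weight` (double; relative annotation frequency).
#' @examples
#' funcat_scheme()
#' @export
funcat_scheme <- function() {
  path <- system.file("extdata", "funcat_scheme.tsv", package = "funcascade")
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  tbl$category <- as.integer(tbl$category)
  tbl
}

validate_scheme <- function(scheme) {
  if (!is.data.frame(scheme) || !all(c("category", "label") %in% names(scheme)))
    abort("`scheme` must be a data frame with columns `category` and `label`.")
  if (nrow(scheme) < 2L) abort("A function scheme needs at least 2 categories.")
  if (anyDuplicated(scheme$category))
    abort("Scheme category numbers must be unique.")
  scheme$category <- as.integer(scheme$category)
  scheme
}

#' Build the binary function-indicator matrix
#'
#' Turns long-format annotations (one row per protein/category pair) into the
#' K x n indicator matrix D with `d[j, i] = 1` when protein i carries
#' category j.  Columns follow the order in which proteins first appear.
#'
#' @param annotations A data frame with columns `protein` and `category`.
#' @param scheme A function scheme, see [funcat_scheme()].
#' @return An integer matrix with categories as rows (rownames are category
#'   numbers) and proteins as columns, classed `"fc_annotation_matrix"`; the
#'   scheme is attached as attribute `"scheme"`.
#' @examples
#' ann <- tibble::tibble(protein = "mc10000007", category = c(8L, 10L))
#' D <- annotation_matrix(ann)
#' which(D[, 1] == 1L)
#' @export
annotation_matrix <- function(annotations, scheme = funcat_scheme()) {
  scheme <- validate_scheme(scheme)
  if (!is.data.frame(annotations) ||
      !all(c("protein", "category") %in% names(annotations)))
    abort("`annotations` must have columns `protein` and `category`.")
  ann <- distinct(annotations, protein, category)
  bad <- setdiff(unique(ann$category), scheme$category)
  if (length(bad)) {
    culprit <- ann$protein[match(bad[1], ann$category)]
    abort(sprintf("Unknown category %s for protein '%s'.", bad[1], culprit))
  }
  ids <- unique(as.character(annotations$protein))
  D <- matrix(0L, nrow = nrow(scheme), ncol = length(ids),
              dimnames = list(scheme$category, ids))
  if (nrow(ann))
    D[cbind(match(ann$category, scheme$category), match(ann$protein, ids))] <- 1L
  structure(D, class = c("fc_annotation_matrix", class(D)), scheme = scheme)
}

#' Order function categories by score
#'
#' Sorts a score vector from highest to lowest to obtain the ranked function
#' sequence: the top-scoring category is the 1st-order prediction, the next
#' the 2nd-order prediction, and so on.  Equal scores are broken by ascending
#' category number so the ranking is deterministic.
#'
#' @param scores Either a numeric vector named by category number, or a data
#'   frame with columns `category` and `score` (as produced by the
#'   `score_by_*()` functions).
#' @param scheme Optional scheme; defaults to the categories present in
#'   `scores`.
#' @return A tibble with columns `rank`, `category` and `score`, one row per
#'   category, scores non-increasing down the rows.
#' @examples
#' s <- c(`1` = 0.2, `2` = 0.9, `3` = 0.9)
#' rank_functions(s) # ties: category 2 before 3
#' @export
rank_functions <- function(scores, scheme = NULL) {
  if (is.data.frame(scores)) {
    cats <- as.integer(scores$category)
    vals <- as.numeric(scores$score)
  } else {
    if (is.null(names(scores)))
      abort("`scores` must be named by category number (or be a data frame).")
    cats <- as.integer(names(scores))
    vals <- as.numeric(scores)
  }
  if (!is.null(scheme)) {
    scheme <- validate_scheme(scheme)
    if (!setequal(cats, scheme$category))
      abort("`scores` must cover exactly the scheme's categories.")
  }
  if (anyNA(vals) || any(!is.finite(vals)))
    abort("All scores must be finite.")
  ord <- order(-vals, cats)
  tibble(rank = seq_along(ord), category = cats[ord], score = vals[ord])
}

# ranked category matrix (K x n) from a K x n score matrix, ties by
# ascending category number (rownames of the score matrix)
rank_matrix <- function(S) {
  cats <- as.integer(rownames(S))
  apply(S, 2L, function(v) cats[order(-v, cats)])
}
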