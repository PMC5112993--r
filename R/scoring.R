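#' Evidence-weighted function scores for one query protein
#'
#' Each scorer computes the same weighted vote: the score of category `j` is
#' the sum, over annotated reference proteins carrying evidence for the
#' query, of the evidence weight times the reference's indicator for `j`
#' (`w = D s` in matrix form).  The three scorers differ only in the
#' evidence: alignment scores to homologues (`score_by_similarity`),
#' interaction combined scores (`score_by_interaction`) or PseAAC cosine
#' similarity to every reference (`score_by_pseaac`).
#'
#' Evidence for reference proteins absent from `refs` is ignored.  When no
#' usable evidence remains, `score_by_similarity()` and
#' `score_by_interaction()` return a zero-row tibble — the "no homologue" /
#' "no interaction" condition the cascade consumes — rather than failing.
#'
#' @param hits Data frame with columns `subject` (reference protein) and
#'   `score` (non-negative alignment score).
#' @param edges Data frame with columns `partner` and `weight`.
#' @param query_pseaac Numeric PseAAC vector of the query.
#' @param refs_pseaac Numeric matrix of reference PseAAC vectors, one row per
#'   protein (rownames are protein identifiers).
#' @param refs An annotation matrix, see [annotation_matrix()].
#' @return A tibble with columns `category`, `score` and `source`; zero rows
#'   signal absent evidence (similarity / interaction only).
#' @examples
#' D <- annotation_matrix(tibble::tibble(protein = "mc10000007",
#'                                       category = c(8L, 10L)))
#' score_by_similarity(tibble::tibble(subject = "mc10000007", score = 100), D)
#' @export
score_by_similarity <- function(hits, refs) {
  weighted_vote(hits, c("subject", "score"), refs, "similarity")
}

#' @rdname score_by_similarity
#' @export
score_by_interaction <- function(edges, refs) {
  weighted_vote(edges, c("partner", "weight"), refs, "interaction")
}

#' @rdname score_by_similarity
#' @export
score_by_pseaac <- function(query_pseaac, refs_pseaac, refs) {
  if (!is.matrix(refs_pseaac) || is.null(rownames(refs_pseaac)))
    abort("`refs_pseaac` must be a matrix with protein rownames.")
  keep <- intersect(rownames(refs_pseaac), colnames(refs))
  if (!length(keep))
    abort("No reference PseAAC vectors match the annotation matrix.")
  sims <- drop(cosine_matrix(refs_pseaac[keep, , drop = FALSE],
                             matrix(query_pseaac, nrow = 1)))
  ev <- tibble(protein = keep, w = as.numeric(sims))
  vote_from_weights(ev, refs, "pseaac")
}

weighted_vote <- function(evidence, cols, refs, source) {
  if (is.null(evidence) || !nrow(evidence)) return(empty_scores(source))
  if (!is.data.frame(evidence) || !all(cols %in% names(evidence)))
    abort(sprintf("Evidence must have columns %s.",
                  paste0("`", cols, "`", collapse = ", ")))
  ev <- tibble(protein = as.character(evidence[[cols[1]]]),
               w = as.numeric(evidence[[cols[2]]]))
  check_nonneg(ev$w, "evidence weights")
  ev <- filter(ev, protein %in% colnames(refs))
  if (!nrow(ev)) return(empty_scores(source))
  ev <- ev |> group_by(protein) |> summarise(w = max(w), .groups = "drop")
  vote_from_weights(ev, refs, source)
}

vote_from_weights <- function(ev, refs, source) {
  s <- drop(refs[, ev$protein, drop = FALSE] %*% ev$w)
  tibble(category = as.integer(rownames(refs)), score = as.numeric(s),
         source = source)
}

empty_scores <- function(source) {
  tibble(category = integer(), score = numeric(), source = character())
}

#' Cascade prediction for one query protein
#'
#' Applies the sequential cascade: score by sequence similarity when the
#' query has at least one alignment hit to an annotated reference; otherwise
#' by interaction partners; otherwise by the PseAAC cosine vote, which is
#' defined for every query with a feature vector.  The winning branch is
#' recorded, so every query is predicted whenever the reference set is
#' non-empty.
#'
#' @inheritParams score_by_similarity
#' @return A tibble with columns `branch`, `rank`, `category`, `score`.
#' @export
predict_combined <- function(refs, hits = NULL, edges = NULL,
                             query_pseaac = NULL, refs_pseaac = NULL) {
  if (ncol(refs) == 0L) abort("The reference set is empty.")
  s <- score_by_similarity(hits, refs)
  if (!nrow(s)) s <- score_by_interaction(edges, refs)
  if (!nrow(s)) {
    if (is.null(query_pseaac) || is.null(refs_pseaac))
      abort("No similarity or interaction evidence and no PseAAC vectors.")
    s <- score_by_pseaac(query_pseaac, refs_pseaac, refs)
  }
  ranked <- rank_functions(s)
  dplyr::bind_cols(tibble(branch = rep(s$source[1], nrow(ranked))), ranked)
}

#' Predict functions for a set of query proteins
#'
#' Batch interface over a dataset: every query is scored against the full
#' annotated reference set (its own annotation and self-hits are never used)
#' and ranked.  `method = "combined"` runs the cascade; the single-branch
#' methods score only queries that carry that kind of evidence and drop the
#' rest, mirroring how each branch alone covers only part of a proteome.
#'
#' @param dataset An [fc_dataset()].
#' @param queries Character vector of query protein identifiers; defaults to
#'   all annotated proteins in the dataset.
#' @param method `"combined"` (the cascade), `"similarity"`, `"interaction"`
#'   or `"pseaac"`.
#' @param lambda,weight PseAAC encoding parameters, see [pseaac_vector()].
#' @return A tibble with columns `protein`, `branch`, `rank`, `category`,
#'   `score` (24 rows per predicted query under the default scheme).
#' @export
predict_functions <- function(dataset, queries = NULL,
                              method = c("combined", "similarity",
                                         "interaction", "pseaac"),
                              lambda = 50, weight = 0.15) {
  method <- arg_match(method)
  stopifnot(inherits(dataset, "fc_dataset"))
  D <- annotation_matrix(dataset$annotations, dataset$scheme)
  ref_ids <- colnames(D)
  if (is.null(queries)) queries <- ref_ids
  queries <- as.character(queries)
  eng <- cascade_scores(dataset, D, ref_ids, queries, method,
                        lambda = lambda, weight = weight)
  predictions_to_tibble(eng, D)
}

# Vectorised scoring engine shared by predict_functions() and the
# cross-validation drivers.  Returns, for the queries that are covered,
# the chosen branch and the 24-score column.
cascade_scores <- function(dataset, D, ref_ids, query_ids, method,
                           lambda = 50, weight = 0.15, pseaac_rows = NULL) {
  nq <- length(query_ids)
  S <- evidence_mat(dataset$similarity, c("query", "subject", "score"),
                    ref_ids, query_ids, directed = TRUE)
  E <- evidence_mat(dataset$interactions, c("protein1", "protein2", "weight"),
                    ref_ids, query_ids, directed = FALSE)
  has_sim <- colSums(S) > 0
  has_int <- colSums(E) > 0
  branch <- rep(NA_character_, nq)
  scores <- matrix(0, nrow(D), nq, dimnames = list(rownames(D), query_ids))
  use_sim <- switch(method, combined = has_sim, similarity = has_sim,
                    interaction = rep(FALSE, nq), pseaac = rep(FALSE, nq))
  use_int <- switch(method, combined = !has_sim & has_int,
                    interaction = has_int,
                    similarity = rep(FALSE, nq), pseaac = rep(FALSE, nq))
  use_pse <- switch(method, combined = !has_sim & !has_int,
                    pseaac = rep(TRUE, nq),
                    similarity = rep(FALSE, nq),
                    interaction = rep(FALSE, nq))
  if (any(use_sim)) {
    scores[, use_sim] <- D %*% S[, use_sim, drop = FALSE]
    branch[use_sim] <- "similarity"
  }
  if (any(use_int)) {
    scores[, use_int] <- D %*% E[, use_int, drop = FALSE]
    branch[use_int] <- "interaction"
  }
  if (any(use_pse)) {
    V <- if (is.function(pseaac_rows)) pseaac_rows()
         else pseaac_rows %||% dataset_pseaac(dataset,
                                              union(ref_ids,
                                                    query_ids[use_pse]),
                                              lambda = lambda,
                                              weight = weight)
    Cq <- cosine_matrix(V[ref_ids, , drop = FALSE],
                        V[query_ids[use_pse], , drop = FALSE])
    # a query never votes for itself
    self <- intersect(query_ids[use_pse], ref_ids)
    if (length(self))
      Cq[cbind(match(self, ref_ids),
               match(self, query_ids[use_pse]))] <- 0
    scores[, use_pse] <- D %*% Cq
    branch[use_pse] <- "pseaac"
  }
  covered <- !is.na(branch)
  list(query_ids = query_ids, branch = branch, scores = scores,
       covered = covered)
}

# refs x queries dense evidence matrix; self pairs always dropped
evidence_mat <- function(tbl, cols, ref_ids, query_ids, directed) {
  M <- matrix(0, length(ref_ids), length(query_ids),
              dimnames = list(ref_ids, query_ids))
  if (is.null(tbl) || !nrow(tbl)) return(M)
  a <- as.character(tbl[[cols[1]]])
  b <- as.character(tbl[[cols[2]]])
  w <- as.numeric(tbl[[cols[3]]])
  if (directed) {
    qs <- b; qq <- a # hits: query aligned to subject (reference)
    put <- function(subj, qry) {
      keep <- subj %in% ref_ids & qry %in% query_ids & subj != qry
      if (any(keep)) {
        idx <- cbind(match(subj[keep], ref_ids), match(qry[keep], query_ids))
        M[idx] <<- pmax(M[idx], w[keep])
      }
    }
    put(qs, qq)
  } else {
    put <- function(subj, qry) {
      keep <- subj %in% ref_ids & qry %in% query_ids & subj != qry
      if (any(keep)) {
        idx <- cbind(match(subj[keep], ref_ids), match(qry[keep], query_ids))
        M[idx] <<- pmax(M[idx], w[keep])
      }
    }
    put(b, a)
    put(a, b)
  }
  M
}

dataset_pseaac <- function(dataset, ids, lambda, weight) {
  if (is.null(dataset$sequences))
    abort("PseAAC scoring needs sequences in the dataset.")
  seqs <- setNames(dataset$sequences$sequence, dataset$sequences$protein)
  missing <- setdiff(ids, names(seqs))
  if (length(missing))
    abort(sprintf("No sequence for protein '%s' (PseAAC needed).",
                  missing[1]))
  pseaac_matrix(seqs[ids], lambda = lambda, weight = weight)
}

predictions_to_tibble <- function(eng, D) {
  keep <- which(eng$covered)
  if (!length(keep))
    return(tibble(protein = character(), branch = character(),
                  rank = integer(), category = integer(), score = numeric()))
  cats <- as.integer(rownames(D))
  out <- lapply(keep, function(i) {
    v <- eng$scores[, i]
    ord <- order(-v, cats)
    tibble(protein = eng$query_ids[i], branch = eng$branch[i],
           rank = seq_along(cats), category = cats[ord],
           score = as.numeric(v[ord]))
  })
  bind_rows(out)
}
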