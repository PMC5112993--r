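#' Order-k prediction accuracy
#'
#' `ACC_j` is the fraction of evaluated proteins whose j-th-ranked category
#' is among their true categories.  Because every ranking is a full
#' permutation of the scheme, the accuracies over all orders sum to the mean
#' number of true labels per protein, for any predictor.
#'
#' @param per_protein A data frame with list-columns `order` (the ranked
#'   category sequence) and `truth` (the true category set), as found in the
#'   `per_protein` element of an evaluation report, or an `fc_eval` object.
#' @param j Optional single order index; when given, returns that `ACC_j` as
#'   a bare number.
#' @return A tibble with columns `order_index` and `accuracy`, or a single
#'   number when `j` is supplied.
#' @export
order_accuracy <- function(per_protein, j = NULL) {
  if (inherits(per_protein, "fc_eval")) per_protein <- per_protein$per_protein
  if (!is.data.frame(per_protein) ||
      !all(c("order", "truth") %in% names(per_protein)))
    abort("`per_protein` needs list-columns `order` and `truth`.")
  if (!nrow(per_protein))
    abort("Accuracy is undefined on an empty evaluation.")
  K <- length(per_protein$order[[1]])
  hit <- vapply(seq_len(nrow(per_protein)), function(i)
    per_protein$order[[i]] %in% per_protein$truth[[i]], logical(K))
  acc <- rowMeans(matrix(hit, nrow = K))
  if (!is.null(j)) {
    j <- check_count(j, "j")
    if (j > K) abort("`j` exceeds the scheme size.")
    return(acc[j])
  }
  tibble(order_index = seq_len(K), accuracy = acc)
}

#' Leave-one-out cross-validation
#'
#' Each annotated protein is held out in turn and predicted from the other
#' n - 1: its own alignment hits to itself, interaction self-loops and
#' PseAAC self-similarity are never used, and its annotation column receives
#' no vote.  Single-branch methods evaluate only the proteins covered by
#' that branch's evidence (the branch's natural testing set); the combined
#' cascade covers every protein.
#'
#' @param dataset An [fc_dataset()].
#' @inheritParams predict_functions
#' @return An object of class `fc_eval`; see [tidy.fc_eval()],
#'   [glance.fc_eval()] and [autoplot.fc_eval()].
#' @export
loo_cv <- function(dataset, method = c("combined", "similarity",
                                       "interaction", "pseaac"),
                   lambda = 50, weight = 0.15) {
  method <- arg_match(method)
  stopifnot(inherits(dataset, "fc_dataset"))
  D <- annotation_matrix(dataset$annotations, dataset$scheme)
  ids <- colnames(D)
  if (length(ids) < 2L) abort("Leave-one-out needs at least 2 proteins.")
  eng <- cascade_scores(dataset, D, ids, ids, method,
                        lambda = lambda, weight = weight)
  pp <- engine_per_protein(eng, D)
  new_fc_eval(per_protein = pp, protocol = "loo", method = method,
              n_total = length(ids), scheme = attr(D, "scheme"))
}

#' Repeated ten-fold cross-validation
#'
#' Proteins are randomly partitioned into `folds` near-equal parts (sizes
#' differ by at most one); each part is predicted using only the remaining
#' parts as references, so no evidence involving any test protein — including
#' hits between two test proteins — contributes.  The partition is repeated
#' `repeats` times and per-order accuracies are summarised as mean and
#' sample standard deviation across repeats.  Fully reproducible from
#' `seed`, which is recorded in the report.
#'
#' @inheritParams loo_cv
#' @param repeats Number of independent random partitions (default 5).
#' @param folds Number of folds (default 10).
#' @param seed Integer seed controlling the partitions.
#' @return An object of class `fc_eval` with a per-repeat `accuracy` table
#'   and a `summary` table (mean +/- sd per order).
#' @export
ten_fold_cv <- function(dataset, repeats = 5, folds = 10, seed = 1,
                        method = c("combined", "similarity", "interaction",
                                   "pseaac"),
                        lambda = 50, weight = 0.15) {
  method <- arg_match(method)
  stopifnot(inherits(dataset, "fc_dataset"))
  repeats <- check_count(repeats, "repeats")
  folds <- check_count(folds, "folds")
  D <- annotation_matrix(dataset$annotations, dataset$scheme)
  ids <- colnames(D)
  n <- length(ids)
  if (n < folds)
    abort(sprintf("Need at least %d proteins for %d-fold CV.", folds, folds))

  # PseAAC vectors are fold-independent; encode at most once, on demand
  V <- NULL
  provider <- function() {
    if (is.null(V))
      V <<- dataset_pseaac(dataset, ids, lambda = lambda, weight = weight)
    V
  }

  pp_all <- vector("list", repeats)
  withr::with_seed(seed, {
    for (r in seq_len(repeats)) {
      assign <- sample(rep_len(seq_len(folds), n))
      parts <- vector("list", folds)
      for (f in seq_len(folds)) {
        test <- ids[assign == f]
        train <- ids[assign != f]
        eng <- cascade_scores(dataset, D[, train, drop = FALSE], train,
                              test, method, lambda = lambda,
                              weight = weight, pseaac_rows = provider)
        parts[[f]] <- engine_per_protein(eng, D)
      }
      pp_all[[r]] <- mutate(bind_rows(parts), repeat_id = r,
                            .before = 1L)
    }
  })
  new_fc_eval(per_protein = bind_rows(pp_all), protocol = "kfold",
              method = method, n_total = n, scheme = attr(D, "scheme"),
              seed = seed, folds = folds, repeats = repeats)
}

# per-protein rows (protein, branch, order, truth) for covered queries;
# truth is looked up in the full annotation matrix D
engine_per_protein <- function(eng, D) {
  keep <- which(eng$covered)
  cats <- as.integer(rownames(D))
  tibble(
    protein = eng$query_ids[keep],
    branch = eng$branch[keep],
    order = lapply(keep, function(i) {
      v <- eng$scores[, i]
      cats[order(-v, cats)]
    }),
    truth = lapply(eng$query_ids[keep], function(id)
      cats[D[, id] == 1L])
  )
}

new_fc_eval <- function(per_protein, protocol, method, n_total, scheme,
                        seed = NA_integer_, folds = NA_integer_,
                        repeats = NA_integer_) {
  if (protocol == "kfold") {
    accuracy <- per_protein |>
      group_by(repeat_id) |>
      dplyr::group_modify(~ order_accuracy(.x)) |>
      ungroup()
    summary <- accuracy |>
      group_by(order_index) |>
      summarise(mean_acc = mean(accuracy),
                sd_acc = stats::sd(accuracy), .groups = "drop")
    n_eval <- nrow(filter(per_protein, repeat_id == 1L))
  } else {
    accuracy <- order_accuracy(per_protein)
    summary <- NULL
    n_eval <- nrow(per_protein)
  }
  bs <- per_protein |>
    group_by(branch) |>
    summarise(n_proteins = n(),
              acc1 = mean(map2_lgl(order, truth, ~ .x[1] %in% .y)),
              .groups = "drop") |>
    mutate(proportion = n_proteins / sum(n_proteins))
  structure(list(per_protein = per_protein, accuracy = accuracy,
                 summary = summary, branch_stats = bs, protocol = protocol,
                 method = method, n_evaluated = n_eval, n_total = n_total,
                 scheme = scheme, seed = seed, folds = folds,
                 repeats = repeats),
            class = "fc_eval")
}

#' @export
print.fc_eval <- function(x, ...) {
  cat(sprintf("<fc_eval: %s, method = %s>\n", x$protocol, x$method))
  cat(sprintf("  proteins evaluated: %d of %d\n", x$n_evaluated, x$n_total))
  g <- glance(x)
  cat(sprintf("  ACC_1 = %.4f  ACC_2 = %.4f  ACC_3 = %.4f\n",
              g$acc1, g$acc2, g$acc3))
  if (x$protocol == "kfold")
    cat(sprintf("  %d repeats of %d-fold CV (seed %d)\n",
                x$repeats, x$folds, x$seed))
  invisible(x)
}

#' Tidy an evaluation report
#'
#' One row per prediction order: the accuracy `ACC_j`, and for repeated
#' k-fold reports also the sample standard deviation across repeats.
#'
#' @param x An `fc_eval` object.
#' @param ... Unused.
#' @return A tibble with columns `order_index`, `accuracy` (and `sd` for
#'   k-fold reports).
#' @method tidy fc_eval
#' @export
tidy.fc_eval <- function(x, ...) {
  if (x$protocol == "kfold")
    return(x$summary |> rename(accuracy = mean_acc, sd = sd_acc))
  x$accuracy
}

#' One-line summary of an evaluation report
#'
#' @inheritParams tidy.fc_eval
#' @return A one-row tibble: protocol, method, proteins evaluated and total,
#'   coverage, and the first three order accuracies.
#' @method glance fc_eval
#' @export
glance.fc_eval <- function(x, ...) {
  acc <- tidy(x)$accuracy
  tibble(protocol = x$protocol, method = x$method,
         n_evaluated = x$n_evaluated, n_total = x$n_total,
         coverage = x$n_evaluated / x$n_total,
         acc1 = acc[1], acc2 = acc[2], acc3 = acc[3])
}

#' Plot order accuracies
#'
#' Accuracy against prediction order; repeated k-fold reports show the
#' mean with +/- one standard deviation across repeats.
#'
#' @param object An `fc_eval` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fc_eval
#' @export
autoplot.fc_eval <- function(object, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = order_index, y = accuracy)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "prediction order", y = "accuracy") +
    ggplot2::theme_minimal()
  if ("sd" %in% names(df))
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = accuracy - sd, ymax = accuracy + sd), width = 0.3)
  p
}

#' Candidate novel annotations ("false-wrong" first-order predictions)
#'
#' Proteins whose top-ranked category is not among their current annotations
#' but whose second-ranked category is.  Because current annotation is
#' incomplete, these top predictions are candidate missing functions rather
#' than plain errors; they are grouped by the branch that produced them.
#'
#' @param x An `fc_eval` object or its `per_protein` table.
#' @return A tibble with columns `protein`, `branch`, `first_choice`
#'   (the putative novel category) and `second_choice` (the confirmed one);
#'   a `repeat_id` column is retained for k-fold reports.
#' @export
false_wrong_candidates <- function(x) {
  pp <- if (inherits(x, "fc_eval")) x$per_protein else x
  if (!is.data.frame(pp) || !all(c("order", "truth") %in% names(pp)))
    abort("Need a per-protein table with `order` and `truth` columns.")
  keep <- vapply(seq_len(nrow(pp)), function(i) {
    o <- pp$order[[i]]
    !(o[1] %in% pp$truth[[i]]) && (o[2] %in% pp$truth[[i]])
  }, logical(1))
  out <- pp[keep, , drop = FALSE]
  out$first_choice <- map_int(out$order, 1L)
  out$second_choice <- map_int(out$order, 2L)
  cols <- intersect(c("repeat_id", "protein", "branch", "first_choice",
                      "second_choice"), names(out))
  as_tibble(out[, cols])
}
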