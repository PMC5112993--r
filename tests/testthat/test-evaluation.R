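pp_row <- function(order, truth, protein = "p", branch = "similarity") {
  tibble::tibble(protein = protein, branch = branch,
                 order = list(order), truth = list(truth))
}

test_that("order accuracy counts rank-j hits", {
  pp <- dplyr::bind_rows(
    pp_row(c(3L, 1L, 2L), 3L, "a"),   # 1st right
    pp_row(c(2L, 3L, 1L), 2L, "b"),   # 1st right
    pp_row(c(1L, 2L, 3L), 3L, "c"))   # 1st wrong
  expect_equal(order_accuracy(pp, 1), 2 / 3)
  # a protein annotated with every category hits at every order
  sat <- pp_row(1:24, 1:24)
  expect_equal(order_accuracy(sat)$accuracy, rep(1, 24))
  expect_error(order_accuracy(pp[0, ]), "empty")
})

test_that("accuracies over all orders sum to the mean label count", {
  withr::with_seed(111, {
    for (k in 1:10) {
      n <- sample(5:40, 1)
      pp <- dplyr::bind_rows(lapply(seq_len(n), function(i)
        pp_row(sample.int(24), sort(sample.int(24, sample(1:6, 1))),
               paste0("p", i))))
      acc <- order_accuracy(pp)$accuracy
      expect_equal(sum(acc), mean(lengths(pp$truth)), tolerance = 1e-12)
    }
  })
})

twin_dataset <- function() {
  fc_dataset(
    annotations = ann_long(list(t1 = 2L, t2 = 2L)),
    similarity = tibble::tibble(query = c("t1", "t2"),
                                subject = c("t2", "t1"), score = c(80, 80)),
    scheme = toy_scheme(3))
}

test_that("leave-one-out transfers annotation between twin proteins", {
  ev <- loo_cv(twin_dataset())
  expect_equal(order_accuracy(ev, 1), 1)
  expect_equal(ev$branch_stats$n_proteins, 2L)
  expect_equal(ev$branch_stats$branch, "similarity")
})

test_that("a held-out protein's own labels never shape its prediction", {
  base <- twin_dataset()
  flipped <- fc_dataset(
    annotations = ann_long(list(t1 = 3L, t2 = 2L)), # t1's labels flipped
    similarity = base$similarity, scheme = toy_scheme(3))
  o1 <- dplyr::filter(loo_cv(base)$per_protein, protein == "t1")$order[[1]]
  o2 <- dplyr::filter(loo_cv(flipped)$per_protein, protein == "t1")$order[[1]]
  expect_equal(o1, o2)
})

test_that("leave-one-out walks a hand-enumerable five-protein cascade", {
  # a <-> b homologous (shared category 1); c -- d interacting (c:2, d:3);
  # e has no evidence at all and must fall through to PseAAC.
  ds <- fc_dataset(
    annotations = ann_long(list(a = 1L, b = 1L, c = 2L, d = 3L, e = 4L)),
    sequences = tibble::tibble(
      protein = c("a", "b", "c", "d", "e"),
      sequence = c("AAAAACCCCC", "AAAAACCCCD", "DDDDDEEEEE",
                   "DDDDDEEEEF", "GGGGGHHHHH")),
    similarity = tibble::tibble(query = c("a", "b"), subject = c("b", "a"),
                                score = c(55, 55)),
    interactions = tibble::tibble(protein1 = "c", protein2 = "d",
                                  weight = 700),
    scheme = toy_scheme(4))
  ev <- loo_cv(ds)
  pp <- ev$per_protein
  branch_of <- setNames(pp$branch, pp$protein)
  expect_equal(unname(branch_of[c("a", "b", "c", "d", "e")]),
               c("similarity", "similarity", "interaction", "interaction",
                 "pseaac"))
  top <- setNames(vapply(pp$order, `[`, 1L, 1), pp$protein)
  # a <- b's label (1); b <- a's label (1); c <- d's label (3); d <- c's (2)
  expect_equal(unname(top[c("a", "b", "c", "d")]), c(1L, 1L, 3L, 2L))
  expect_equal(order_accuracy(ev, 1), 2 / 5)
  # branch counts sum to the number of evaluated proteins
  expect_equal(sum(ev$branch_stats$n_proteins), 5L)
  expect_equal(sum(ev$branch_stats$proportion), 1)
})

test_that("datasets with only sequences fall entirely to the PseAAC branch", {
  withr::with_seed(121, {
    ds <- fc_dataset(
      annotations = ann_long(setNames(as.list(sample.int(4, 6, TRUE)),
                                      paste0("p", 1:6))),
      sequences = tibble::tibble(protein = paste0("p", 1:6),
                                 sequence = replicate(6, random_sequence(30))),
      scheme = toy_scheme(4))
    ev <- loo_cv(ds)
    expect_equal(ev$branch_stats$branch, "pseaac")
    expect_equal(ev$branch_stats$n_proteins, 6L)
    expect_equal(ev$n_evaluated, 6L)
  })
})

test_that("single-branch evaluation covers only proteins with that evidence", {
  ds <- fc_dataset(
    annotations = ann_long(list(a = 1L, b = 1L, c = 2L)),
    similarity = tibble::tibble(query = "a", subject = "b", score = 10),
    interactions = tibble::tibble(protein1 = "a", protein2 = "c",
                                  weight = 500),
    scheme = toy_scheme(3))
  expect_equal(loo_cv(ds, method = "similarity")$n_evaluated, 1L)
  expect_equal(loo_cv(ds, method = "interaction")$n_evaluated, 2L)
  expect_equal(glance(loo_cv(ds, method = "interaction"))$coverage, 2 / 3)
})

test_that("k-fold partitions are balanced and cover every protein once", {
  withr::with_seed(131, {
    n <- 23
    sets <- setNames(as.list(sample.int(24, n, TRUE)), paste0("p", 1:n))
    ds <- fc_dataset(
      annotations = ann_long(sets),
      sequences = tibble::tibble(protein = paste0("p", 1:n),
                                 sequence = replicate(n, random_sequence(25))),
      similarity = tibble::tibble(query = paste0("p", 1:n),
                                  subject = paste0("p", c(2:n, 1)),
                                  score = runif(n, 10, 90)))
    ev <- ten_fold_cv(ds, repeats = 3, seed = 7)
    for (r in 1:3) {
      pp <- dplyr::filter(ev$per_protein, repeat_id == r)
      expect_setequal(pp$protein, paste0("p", 1:n))
      expect_equal(nrow(pp), n) # exactly one test fold per protein
    }
    # hits between two held-out proteins never count: with the partner in
    # the same fold the similarity branch cannot fire
    same_fold <- vapply(seq_len(n), function(i) {
      pp <- dplyr::filter(ev$per_protein, repeat_id == 1)
      br <- pp$branch[pp$protein == paste0("p", i)]
      br != "similarity"
    }, logical(1))
    expect_true(any(same_fold)) # fold sizes 2-3 make collisions certain
  })
})

test_that("k-fold reports are reproducible from the seed", {
  withr::with_seed(141, {
    n <- 30
    sets <- setNames(lapply(1:n, function(i) sample.int(24, 2)),
                     paste0("p", 1:n))
    ds <- fc_dataset(
      annotations = ann_long(sets),
      interactions = tibble::tibble(protein1 = sample(names(sets), 60, TRUE),
                                    protein2 = sample(names(sets), 60, TRUE),
                                    weight = runif(60, 100, 900)) |>
        dplyr::filter(protein1 != protein2))
  })
  e1 <- ten_fold_cv(ds, repeats = 2, seed = 99, method = "interaction")
  e2 <- ten_fold_cv(ds, repeats = 2, seed = 99, method = "interaction")
  expect_identical(e1$accuracy, e2$accuracy)
  expect_identical(e1$per_protein, e2$per_protein)
  e3 <- ten_fold_cv(ds, repeats = 2, seed = 100, method = "interaction")
  expect_false(identical(e1$per_protein, e3$per_protein))
  # repeat summary is the sample standard deviation across repeats
  acc1 <- dplyr::filter(e1$accuracy, order_index == 1)$accuracy
  expect_equal(dplyr::filter(tidy(e1), order_index == 1)$sd, sd(acc1))
  expect_error(ten_fold_cv(ds, repeats = 0), "positive integer")
})

test_that("false-wrong candidates are exactly 1st-wrong-2nd-right proteins", {
  pp <- dplyr::bind_rows(
    pp_row(c(5L, 2L, 1L, 3L, 4L), 2L, "in"),       # 1st wrong, 2nd right
    pp_row(c(5L, 2L, 1L, 3L, 4L), 5L, "out_first"), # 1st right
    pp_row(c(5L, 2L, 1L, 3L, 4L), 9L, "out_both"))  # both wrong
  fw <- false_wrong_candidates(pp)
  expect_equal(fw$protein, "in")
  expect_equal(fw$first_choice, 5L)
  expect_equal(fw$second_choice, 2L)
})

test_that("evaluation accessors summarise and plot", {
  ev <- loo_cv(twin_dataset())
  td <- tidy(ev)
  expect_equal(names(td), c("order_index", "accuracy"))
  g <- glance(ev)
  expect_equal(g$acc1, 1)
  expect_equal(g$coverage, 1)
  expect_s3_class(autoplot(ev), "ggplot")
})
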