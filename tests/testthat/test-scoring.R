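test_that("similarity voting matches hand-computed matrix-vector products", {
  D <- annotation_matrix(ann_long(list(mc10000007 = c(8L, 10L))))
  w <- score_by_similarity(tibble::tibble(subject = "mc10000007",
                                          score = 100), D)
  expect_equal(w$score[w$category %in% c(8, 10)], c(100, 100))
  expect_equal(sum(w$score), 200)
  expect_equal(unique(w$source), "similarity")

  D2 <- annotation_matrix(ann_long(list(a = 1L, b = c(1L, 2L))))
  w2 <- score_by_similarity(tibble::tibble(subject = c("a", "b"),
                                           score = c(3, 5)), D2)
  expect_equal(w2$score[1:3], c(8, 5, 0))
})

test_that("interaction voting weights annotations by combined score", {
  D <- annotation_matrix(ann_long(list(p = 12L)))
  y <- score_by_interaction(tibble::tibble(partner = "p", weight = 900), D)
  expect_equal(y$score[12], 900)
  expect_equal(sum(y$score), 900)

  # identical weights to {1} and {2}: tie resolved upward when ranked
  D2 <- annotation_matrix(ann_long(list(a = 1L, b = 2L)), toy_scheme(3))
  y2 <- score_by_interaction(tibble::tibble(partner = c("a", "b"),
                                            weight = c(7, 7)), D2)
  expect_equal(y2$score[1], y2$score[2])
  expect_equal(rank_functions(y2)$category[1:2], c(1L, 2L))
})

test_that("PseAAC voting sums cosine weights over all references", {
  # reference vectors with cosines 0.9 and 0.6 to the query (1, 0)
  refs_pseaac <- rbind(a = c(0.9, sqrt(1 - 0.81)), b = c(0.6, 0.8))
  D <- annotation_matrix(ann_long(list(a = 1L, b = c(1L, 2L))),
                         toy_scheme(3))
  r <- score_by_pseaac(c(1, 0), refs_pseaac, D)
  expect_equal(r$score, c(1.5, 0.6, 0), tolerance = 1e-12)

  # a query identical to its only reference scores its categories 1
  D1 <- annotation_matrix(ann_long(list(a = 3L)), toy_scheme(4))
  r1 <- score_by_pseaac(c(2, 2), rbind(a = c(1, 1)), D1)
  expect_equal(r1$score[3], 1, tolerance = 1e-12)
})

test_that("absent evidence yields the distinguishable empty condition", {
  D <- annotation_matrix(ann_long(list(a = 1L)))
  expect_equal(nrow(score_by_similarity(NULL, D)), 0L)
  expect_equal(nrow(score_by_similarity(
    tibble::tibble(subject = "unknown", score = 5), D)), 0L)
  expect_equal(nrow(score_by_interaction(
    tibble::tibble(partner = character(), weight = numeric()), D)), 0L)
})

test_that("all three scorers match the brute-force vote on random instances", {
  withr::with_seed(91, {
    for (k in 1:30) {
      n <- sample(2:50, 1)
      K <- sample(c(4L, 24L), 1)
      sets <- lapply(seq_len(n), function(i) sample.int(K, sample(1:3, 1)))
      names(sets) <- paste0("r", seq_len(n))
      D <- annotation_matrix(ann_long(sets), toy_scheme(K))
      m <- sample.int(n, sample(seq_len(n), 1))
      wts <- setNames(round(runif(length(m), 0, 100), 3), names(sets)[m])
      expected <- oracle_vote(as.list(wts), sets, K)
      w <- score_by_similarity(tibble::tibble(subject = names(wts),
                                              score = unname(wts)), D)
      y <- score_by_interaction(tibble::tibble(partner = names(wts),
                                               weight = unname(wts)), D)
      expect_equal(w$score, expected, tolerance = 1e-9)
      expect_equal(y$score, expected, tolerance = 1e-9)
    }
  })
})

test_that("scores are linear and additive in the evidence", {
  withr::with_seed(101, {
    sets <- lapply(1:20, function(i) sample.int(24, 2))
    names(sets) <- paste0("r", 1:20)
    D <- annotation_matrix(ann_long(sets))
    ev1 <- tibble::tibble(subject = paste0("r", 1:10), score = runif(10, 1, 9))
    ev2 <- tibble::tibble(subject = paste0("r", 11:20), score = runif(10, 1, 9))
    s1 <- score_by_similarity(ev1, D)$score
    s2 <- score_by_similarity(ev2, D)$score
    both <- score_by_similarity(dplyr::bind_rows(ev1, ev2), D)$score
    expect_equal(both, s1 + s2, tolerance = 1e-12)
    doubled <- score_by_similarity(dplyr::mutate(ev1, score = 2 * score), D)
    expect_equal(doubled$score, 2 * s1, tolerance = 1e-12)
    expect_equal(rank_functions(doubled)$category,
                 rank_functions(tibble::tibble(category = doubled$category,
                                               score = s1))$category)
  })
})

test_that("the cascade tries similarity, then interaction, then PseAAC", {
  D <- annotation_matrix(ann_long(list(a = 1L, b = 2L, c = 3L)),
                         toy_scheme(4))
  V <- rbind(a = c(1, 0), b = c(0, 1), c = c(1, 1))
  hits <- tibble::tibble(subject = "a", score = 50)
  edges <- tibble::tibble(partner = "b", weight = 900)

  p1 <- predict_combined(D, hits = hits, edges = edges,
                         query_pseaac = c(1, 0), refs_pseaac = V)
  expect_equal(p1$branch[1], "similarity")
  expect_equal(p1$category[1], 1L)

  p2 <- predict_combined(D, hits = NULL, edges = edges)
  expect_equal(p2$branch[1], "interaction")
  expect_equal(p2$category[1], 2L)

  p3 <- predict_combined(D, query_pseaac = c(0, 1), refs_pseaac = V)
  expect_equal(p3$branch[1], "pseaac")
  expect_setequal(p3$rank, 1:4)

  expect_error(predict_combined(D[, 0]), "empty")
  expect_error(predict_combined(D), "No similarity or interaction")
})

test_that("batch prediction never lets a query vote for itself", {
  # twins: identical sequences, mutual hits, different annotations
  ds <- fc_dataset(
    annotations = ann_long(list(t1 = 1L, t2 = 2L)),
    sequences = tibble::tibble(protein = c("t1", "t2"),
                               sequence = c("ACDEF", "ACDEF")),
    similarity = tibble::tibble(query = c("t1", "t2", "t1"),
                                subject = c("t2", "t1", "t1"),
                                score = c(60, 60, 999)),
    scheme = toy_scheme(3))
  p <- predict_functions(ds)
  top <- dplyr::filter(p, rank == 1)
  # each twin inherits the other's label; the self-hit of t1 is discarded
  expect_equal(top$category[top$protein == "t1"], 2L)
  expect_equal(top$category[top$protein == "t2"], 1L)
  expect_true(all(top$branch == "similarity"))
})
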