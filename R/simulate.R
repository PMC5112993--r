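#' Generate a synthetic function-prediction benchmark
#'
#' Builds a fully synthetic dataset with the statistical structure the
#' cascade exploits: skewed multi-label category frequencies, homology
#' clusters whose members share annotations and exchange alignment hits,
#' an interaction network with tunable guilt-by-association (GBA) strength,
#' a configurable fraction of orphan proteins with neither hits nor edges,
#' and sequences whose residue usage is tilted by the protein's categories
#' so the PseAAC fallback carries a weak signal.
#'
#' @section Interaction model:
#' `gba_strength` is the probability that an edge joins two proteins sharing
#' at least one category.  Edges are a mixture of functional-module edges
#' (partner drawn with probability proportional to the squared Jaccard
#' overlap of annotation sets; combined score increasing in the overlap) and
#' uniform random pairs, mixed so that the realised sharing rate equals
#' `gba_strength` exactly.  Setting `gba_strength = "chance"` (or to the
#' dataset's random-pair sharing rate) therefore yields a network that is
#' exactly a uniform random graph — the natural null in which interaction
#' partners carry no information about function.
#'
#' @param n_proteins Number of proteins.
#' @param scheme Function scheme; defaults to the 24 FunCat top categories.
#' @param category_weights Sampling weights per category; defaults to the
#'   scheme's `weight` column (the reference mouse annotation counts) or
#'   uniform weights if absent.
#' @param labels_per_protein Mean number of categories per protein
#'   (default 3.107, the reference collection's 38,766 labels over 12,478
#'   proteins); drawn as `1 + Poisson(mean - 1)`, capped at the scheme size.
#' @param homology_fraction Fraction of proteins placed in homology
#'   clusters (default 0.8; about 82% of the reference proteins have
#'   homologues).
#' @param n_clusters Number of homology clusters; default gives a mean
#'   cluster size of about 4, and never exceeds `n_clustered / 2` so every
#'   cluster has at least two members.
#' @param extra_label_prob Probability that a clustered protein carries one
#'   extra category beyond its cluster's shared set (default 0.25).
#' @param gba_strength Probability that an interaction edge joins
#'   label-sharing proteins, or `"chance"` for the random-graph null
#'   (default 0.9).
#' @param orphan_fraction Fraction of proteins with neither hits nor edges
#'   (default 0.03, mirroring the reference cascade's PseAAC-only share).
#' @param edges_per_protein Mean interaction degree (default 10).
#' @param hit_score_range Base range of within-cluster alignment scores.
#' @param hit_overlap_bonus Score added per shared category in a hit.
#' @param sequence_length_range Integer range of sequence lengths.
#' @param tilt_sd Standard deviation of the per-category residue-usage
#'   tilts on the log scale (default 0.3; weak signal by design).
#' @param seed Integer seed; fixes every random choice.
#' @return An [fc_dataset()] whose `annotations` are the ground truth.
#' @examples
#' d <- generate_dataset(n_proteins = 60, seed = 7)
#' d
#' @export
generate_dataset <- function(n_proteins = 500,
                             scheme = funcat_scheme(),
                             category_weights = NULL,
                             labels_per_protein = 3.107,
                             homology_fraction = 0.8,
                             n_clusters = NULL,
                             extra_label_prob = 0.25,
                             gba_strength = 0.9,
                             orphan_fraction = 0.03,
                             edges_per_protein = 10,
                             hit_score_range = c(40, 50),
                             hit_overlap_bonus = 20,
                             sequence_length_range = c(80, 300),
                             tilt_sd = 0.3,
                             seed = 1) {
  scheme <- validate_scheme(scheme)
  n <- check_count(n_proteins, "n_proteins")
  check_fraction(homology_fraction, "homology_fraction")
  check_fraction(orphan_fraction, "orphan_fraction")
  check_fraction(extra_label_prob, "extra_label_prob")
  if (orphan_fraction + homology_fraction > 1)
    abort("Infeasible config: orphan_fraction + homology_fraction > 1.")
  chance_gba <- identical(gba_strength, "chance")
  if (!chance_gba) check_fraction(gba_strength, "gba_strength")
  if (labels_per_protein < 1)
    abort("`labels_per_protein` must be at least 1.")
  K <- nrow(scheme)
  wts <- category_weights %||% scheme$weight %||% rep(1, K)
  if (length(wts) != K || any(wts < 0) || sum(wts) <= 0)
    abort("`category_weights` must be non-negative, one per category.")

  withr::with_seed(seed, {
    ids <- sprintf("sp%05d", seq_len(n))
    perm <- sample.int(n)
    n_orph <- round(n * orphan_fraction)
    n_hom <- min(round(n * homology_fraction), n - n_orph)
    orphan <- perm[seq_len(n_orph)]
    clustered <- perm[n_orph + seq_len(n_hom)]

    draw_labels <- function(k) sort(sample.int(K, min(k, K), prob = wts))
    label_counts <- pmin(1L + rpois(n, labels_per_protein - 1), K)

    labels <- vector("list", n)
    for (i in setdiff(seq_len(n), clustered))
      labels[[i]] <- draw_labels(label_counts[i])

    sim <- NULL
    if (n_hom >= 2L) {
      nc <- n_clusters %||% max(1L, round(n_hom / 4))
      nc <- max(1L, min(nc, n_hom %/% 2L))
      cluster_of <- rep_len(seq_len(nc), n_hom)
      cluster_labels <- lapply(seq_len(nc), function(cl)
        draw_labels(label_counts[clustered[match(cl, cluster_of)]]))
      for (j in seq_len(n_hom)) {
        lab <- cluster_labels[[cluster_of[j]]]
        if (runif(1) < extra_label_prob)
          lab <- union(lab, draw_labels(1L))
        labels[[clustered[j]]] <- sort(lab)
      }
      sim <- cluster_hits(ids, clustered, cluster_of, labels,
                          hit_score_range, hit_overlap_bonus)
    } else if (n_hom == 1L) {
      labels[[clustered[1]]] <- draw_labels(label_counts[clustered[1]])
    }

    M <- matrix(0L, n, K)
    for (i in seq_len(n)) M[i, labels[[i]]] <- 1L

    edges <- NULL
    pool <- setdiff(seq_len(n), orphan)
    if (length(pool) >= 2L && edges_per_protein > 0)
      edges <- gba_edges(ids, pool, M, gba_strength, chance_gba,
                         edges_per_protein)

    tau <- matrix(rnorm(K * 20L, 0, tilt_sd), K, 20L)
    lens <- sample(sequence_length_range[1]:sequence_length_range[2], n,
                   replace = TRUE)
    seqs <- vapply(seq_len(n), function(i) {
      logit <- colSums(tau[labels[[i]], , drop = FALSE])
      p <- exp(logit - max(logit))
      paste(sample(AA20, lens[i], replace = TRUE, prob = p / sum(p)),
            collapse = "")
    }, character(1))

    ann <- tibble(protein = rep(ids, lengths(labels)),
                  category = as.integer(unlist(labels)))
    fc_dataset(annotations = ann,
               sequences = tibble(protein = ids, sequence = seqs),
               similarity = sim, interactions = edges, scheme = scheme)
  })
}

# all within-cluster pairs, score = base + bonus * |shared labels| + noise,
# reported in both directions like an all-vs-all search
cluster_hits <- function(ids, clustered, cluster_of, labels, base_range,
                         bonus) {
  qs <- character(0); ss <- character(0); sc <- numeric(0)
  for (cl in unique(cluster_of)) {
    mem <- clustered[cluster_of == cl]
    if (length(mem) < 2L) next
    prs <- utils::combn(mem, 2L)
    ov <- vapply(seq_len(ncol(prs)), function(k)
      length(intersect(labels[[prs[1, k]]], labels[[prs[2, k]]])),
      integer(1))
    s <- runif(ncol(prs), base_range[1], base_range[2]) + bonus * ov
    qs <- c(qs, ids[prs[1, ]], ids[prs[2, ]])
    ss <- c(ss, ids[prs[2, ]], ids[prs[1, ]])
    sc <- c(sc, s, s)
  }
  if (!length(qs)) return(NULL)
  tibble(query = qs, subject = ss, score = sc)
}

# mixture of functional-module edges and uniform random pairs, mixed so the
# realised label-sharing rate equals gba_strength (see generate_dataset)
gba_edges <- function(ids, pool, M, g, chance_gba, edges_per_protein) {
  Mp <- M[pool, , drop = FALSE]
  ov <- Mp %*% t(Mp)
  sz <- rowSums(Mp)
  J <- ov / (outer(sz, sz, "+") - ov)
  diag(J) <- 0
  np <- length(pool)
  share <- ov > 0
  diag(share) <- FALSE
  s0 <- mean(share[upper.tri(share)])
  if (chance_gba) {
    phi <- 0; psi <- 0
  } else if (g >= s0) {
    phi <- if (s0 < 1) (g - s0) / (1 - s0) else 0
    psi <- 0
  } else {
    phi <- 0
    psi <- 1 - g / s0
  }
  n_edges <- round(np * edges_per_protein / 2)
  from <- integer(n_edges); to <- integer(n_edges); w <- numeric(n_edges)
  kind <- runif(n_edges)
  p_idx <- sample.int(np, n_edges, replace = TRUE)
  for (e in seq_len(n_edges)) {
    p <- p_idx[e]
    if (kind[e] < phi && any(share[p, ])) {
      pr <- J[p, ]^2
      q <- sample.int(np, 1L, prob = pr)
      w[e] <- round(400 + 550 * J[p, q] + runif(1, 0, 50))
    } else if (kind[e] < psi && any(!share[p, -p])) {
      cand <- which(!share[p, ]); cand <- cand[cand != p]
      q <- cand[sample.int(length(cand), 1L)]
      w[e] <- round(runif(1, 400, 1000))
    } else {
      q <- sample.int(np - 1L, 1L)
      if (q >= p) q <- q + 1L
      w[e] <- round(runif(1, 400, 1000))
    }
    from[e] <- pool[p]; to[e] <- pool[q]
  }
  tibble(protein1 = ids[from], protein2 = ids[to], weight = w)
}

#' Label-sharing rate of random protein pairs
#'
#' The probability that two distinct proteins drawn at random share at least
#' one category — the chance level against which guilt-by-association
#' structure is measured, and the `gba_strength` value at which
#' [generate_dataset()] produces a purely random interaction network.
#'
#' @param annotations A data frame with columns `protein` and `category`,
#'   or an [fc_dataset()].
#' @return A single number in `[0, 1]`.
#' @export
label_sharing_rate <- function(annotations) {
  if (inherits(annotations, "fc_dataset"))
    annotations <- annotations$annotations
  if (length(unique(annotations$category)) < 2L)
    return(1)
  D <- t(annotation_matrix(annotations,
                           scheme = tibble(category =
                                             sort(unique(annotations$category)),
                                           label = "")))
  share <- (D %*% t(D)) > 0
  mean(share[upper.tri(share)])
}

check_fraction <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    abort(sprintf("`%s` must be a fraction in [0, 1].", what))
  invisible(x)
}
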