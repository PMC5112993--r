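# Independent brute-force reference implementations used to cross-check the
# package.  Everything here is written as plain loops over the defining
# formulas, deliberately sharing no code with the package internals.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

oracle_normalize <- function(v) {
  v <- v[AA]
  mu <- sum(v) / 20
  ms <- sum((v - mu)^2) / 20
  (v - mu) / sqrt(ms)
}

# lag factors by explicit double loop, zero-padded to lambda
oracle_corr <- function(sequence, prop, lambda) {
  x <- strsplit(sequence, "")[[1]]
  f <- prop[x]
  n <- length(f)
  out <- numeric(lambda)
  for (i in seq_len(lambda)) {
    if (i <= n - 1) {
      acc <- 0
      for (k in 1:(n - i)) acc <- acc + (f[k] - f[k + i])^2
      out[i] <- acc / (n - i)
    }
  }
  out
}

# full shared-denominator PseAAC by explicit loops
oracle_pseaac <- function(sequence, props, lambda, w) {
  x <- strsplit(sequence, "")[[1]]
  counts <- sapply(AA, function(a) sum(x == a))
  f <- counts / sum(counts)
  C <- lapply(props, function(p) oracle_corr(sequence, p, lambda))
  S <- 0
  for (ci in C) for (c1 in ci) S <- S + c1
  denom <- sum(f) + w * S
  c(f / denom, unlist(lapply(C, function(ci) w * ci / denom)))
}

oracle_cosine <- function(a, b) {
  num <- 0; na <- 0; nb <- 0
  for (i in seq_along(a)) {
    num <- num + a[i] * b[i]
    na <- na + a[i]^2
    nb <- nb + b[i]^2
  }
  num / (sqrt(na) * sqrt(nb))
}

# weighted vote by explicit double loop; ann = named list protein -> set,
# weights = named numeric protein -> evidence weight
oracle_vote <- function(weights, ann, K) {
  out <- numeric(K)
  for (j in seq_len(K)) {
    for (p in names(weights)) {
      if (j %in% ann[[p]]) out[j] <- out[j] + weights[[p]]
    }
  }
  out
}

random_sequence <- function(n) paste(sample(AA, n, replace = TRUE),
                                     collapse = "")

# small scheme for hand-built fixtures
toy_scheme <- function(K = 4) {
  tibble::tibble(category = seq_len(K), label = paste0("cat", seq_len(K)))
}

ann_long <- function(sets) {
  tibble::tibble(protein = rep(names(sets), lengths(sets)),
                 category = as.integer(unlist(sets)))
}

polarity <- function() {
  p <- aa_properties()
  setNames(p$polarity, p$amino_acid)
}
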