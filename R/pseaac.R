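#' Lag correlation factors of a property profile along a sequence
#'
#' For each lag `i = 1..lambda` computes the mean squared difference of the
#' property value between residues `i` positions apart:
#' `C_i = mean over k of (F(X_k) - F(X_{k+i}))^2`.
#' These factors carry the sequence-order information that plain amino-acid
#' composition discards.
#'
#' Lags longer than the sequence allows (`i > N - 1`) are zero-padded so the
#' result always has length `lambda`, keeping feature vectors comparable
#' across proteins of different lengths.  Non-standard residues (B, J, O, U,
#' X, Z) act as gaps: they carry no property value and no correlation pair
#' spans them.
#'
#' @param sequence A single amino-acid string.
#' @param property A numeric property profile named by the 20 standard
#'   amino-acid letters (used as supplied; standardise first with
#'   [normalize_property()] if needed).
#' @param lambda Number of lags (positive integer).
#' @return Numeric vector of length `lambda`, all entries >= 0.
#' @examples
#' pol <- setNames(aa_properties()$polarity, aa_properties()$amino_acid)
#' correlation_factors("AC", pol, lambda = 1) # (-0.591 - (-1.343))^2
#' @export
correlation_factors <- function(sequence, property, lambda) {
  property <- check_property_vector(property)
  lambda <- check_count(lambda, "lambda")
  f <- residue_profile(sequence, property)
  if (sum(!is.na(f)) < 2L)
    abort("Sequence too short: need at least 2 standard residues.")
  corr_factors_profile(f, lambda)
}

# property values along the sequence; NA marks a non-standard residue (gap)
residue_profile <- function(sequence, property) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    abort("`sequence` must be a single non-empty string.")
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  unname(property[chars])
}

# core of Eq.-5-style lag factors over a profile with NA gaps
corr_factors_profile <- function(f, lambda) {
  out <- numeric(lambda)
  if (!anyNA(f)) {
    n <- length(f)
    lmax <- min(lambda, n - 1L)
    for (i in seq_len(lmax)) {
      d <- f[seq_len(n - i)] - f[(1L + i):n]
      out[i] <- mean(d * d)
    }
    return(out)
  }
  # split into maximal gap-free segments; a lag pair never crosses a gap
  runs <- split(f[!is.na(f)], cumsum(is.na(f))[!is.na(f)])
  for (i in seq_len(lambda)) {
    ssq <- 0
    npair <- 0L
    for (seg in runs) {
      n <- length(seg)
      if (n > i) {
        d <- seg[seq_len(n - i)] - seg[(1L + i):n]
        ssq <- ssq + sum(d * d)
        npair <- npair + (n - i)
      }
    }
    if (npair > 0L) out[i] <- ssq / npair
  }
  out
}

#' Encode one sequence as a pseudo amino acid composition vector
#'
#' Combines the composition frequencies of the 20 standard amino acids with
#' `lambda` lag correlation factors for each property profile, producing a
#' vector of length `20 + m * lambda` (270 with the default five properties
#' and `lambda = 50`).  All blocks share one denominator
#' `sum(f) + weight * S`, where `S` sums the correlation factors over all
#' properties and lags, so the full vector is non-negative and sums to one.
#' Set `denominator = "per_property"` for the alternative convention in which
#' the first 20 entries are the plain composition and each property block is
#' normalised by its own `1 + weight * sum(C)` (that variant does not sum to
#' one).
#'
#' @inheritParams correlation_factors
#' @param properties Data frame of property profiles, see [aa_properties()].
#' @param weight Sequence-order weight (omega), default 0.15.
#' @param lambda Number of lags per property, default 50.
#' @param normalize Standardise property columns with [normalize_property()]
#'   before use (default `FALSE`: the packaged factor scores are used as
#'   published).
#' @param denominator `"shared"` (default) or `"per_property"`.
#' @return Named numeric vector of length `20 + m * lambda`.
#' @examples
#' v <- pseaac_vector("MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ")
#' length(v); sum(v)
#' @export
pseaac_vector <- function(sequence, properties = aa_properties(),
                          lambda = 50, weight = 0.15, normalize = FALSE,
                          denominator = c("shared", "per_property")) {
  denominator <- arg_match(denominator)
  lambda <- check_count(lambda, "lambda")
  if (!is.numeric(weight) || length(weight) != 1L || !is.finite(weight) ||
      weight <= 0)
    abort("`weight` must be a single positive number.")
  props <- property_list(properties, normalize = normalize)
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  if (!length(chars))
    abort("`sequence` must be non-empty.")
  counts <- tabulate(match(chars, AA20), nbins = 20L)
  if (sum(counts) == 0L)
    abort("Sequence contains no standard amino-acid residues.")
  f <- counts / sum(counts)
  single <- sum(counts) < 2L
  C <- lapply(props, function(p) {
    if (single) return(numeric(lambda))
    corr_factors_profile(unname(p[chars]), lambda)
  })
  if (denominator == "shared") {
    denom <- 1 + weight * sum(unlist(C))
    v <- c(f, weight * unlist(C)) / denom
  } else {
    blocks <- lapply(C, function(ci) weight * ci / (1 + weight * sum(ci)))
    v <- c(f, unlist(blocks))
  }
  names(v) <- c(AA20, unlist(lapply(names(props), function(p)
    paste0(p, "_", seq_len(lambda)))))
  v
}

#' Encode a table of sequences as PseAAC features
#'
#' Data-frame-first wrapper around [pseaac_vector()]: one row in, one row of
#' features out.
#'
#' @param sequences A data frame with columns `protein` and `sequence`.
#' @inheritParams pseaac_vector
#' @return A tibble with a `protein` column followed by one numeric column
#'   per PseAAC entry (270 with the defaults).
#' @examples
#' seqs <- tibble::tibble(protein = c("p1", "p2"),
#'                        sequence = c("ACDEFGHIK", "MNPQRSTVWY"))
#' dim(pseaac(seqs, lambda = 2))
#' @export
pseaac <- function(sequences, properties = aa_properties(), lambda = 50,
                   weight = 0.15, normalize = FALSE,
                   denominator = c("shared", "per_property")) {
  if (!is.data.frame(sequences) ||
      !all(c("protein", "sequence") %in% names(sequences)))
    abort("`sequences` must have columns `protein` and `sequence`.")
  M <- pseaac_matrix(setNames(sequences$sequence,
                              as.character(sequences$protein)),
                     properties = properties, lambda = lambda,
                     weight = weight, normalize = normalize,
                     denominator = denominator)
  dplyr::bind_cols(tibble(protein = rownames(M)), as_tibble(M))
}

# named character vector of sequences -> n x (20 + m*lambda) matrix
pseaac_matrix <- function(seqs, properties = aa_properties(), lambda = 50,
                          weight = 0.15, normalize = FALSE,
                          denominator = "shared") {
  rows <- lapply(seqs, pseaac_vector, properties = properties,
                 lambda = lambda, weight = weight, normalize = normalize,
                 denominator = denominator)
  M <- do.call(rbind, rows)
  rownames(M) <- names(seqs)
  M
}

#' Cosine similarity between two feature vectors
#'
#' `a . b / (|a| |b|)`; lies in `[0, 1]` for non-negative vectors such as
#' PseAAC encodings, equals 1 for identical directions.
#'
#' @param a,b Numeric vectors of equal length, neither all-zero.
#' @return A single number.
#' @examples
#' cosine_similarity(c(1, 1), c(1, 0)) # 1/sqrt(2)
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b))
    abort("Vectors must have equal length.")
  na <- sqrt(sum(a * a))
  nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0)
    abort("Cosine similarity is undefined for an all-zero vector.")
  sum(a * b) / (na * nb)
}

# rows of A vs rows of B -> |A| x |B| cosine matrix
cosine_matrix <- function(A, B = A) {
  An <- A / sqrt(rowSums(A * A))
  Bn <- B / sqrt(rowSums(B * B))
  An %*% t(Bn)
}

check_count <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 ||
      x != as.integer(x))
    abort(sprintf("`%s` must be a positive integer.", what))
  as.integer(x)
}
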