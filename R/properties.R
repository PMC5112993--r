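#' Physicochemical property profiles of the 20 amino acids
#'
#' Returns the five published property factor scores used by the PseAAC
#' encoder: polarity, secondary structure, molecular volume, codon diversity
#' and electrostatic charge.  These are factor scores summarising larger
#' panels of physicochemical indices and are used as published (they are
#' already on a standardised scale); pass them through [normalize_property()]
#' only if you need exact zero-mean / unit-mean-square profiles, or when
#' supplying a raw property scale of your own.
#'
#' @param properties Optional character vector selecting a subset (and order)
#'   of the property columns.
#' @return A tibble with column `amino_acid` (the 20 standard one-letter
#'   codes) and one numeric column per property.
#' @examples
#' aa_properties()
#' aa_properties(c("polarity", "electrostatic_charge"))
#' @export
aa_properties <- function(properties = NULL) {
  path <- system.file("extdata", "aa_properties.tsv", package = "funcascade")
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(properties)) {
    missing <- setdiff(properties, names(tbl))
    if (length(missing))
      abort(sprintf("Unknown property column(s): %s",
                    paste(missing, collapse = ", ")))
    tbl <- tbl[, c("amino_acid", properties)]
  }
  tbl
}

#' Standardise an amino-acid property profile
#'
#' Centers a property profile L(X) to mean zero over the 20 standard amino
#' acids and scales it so that the mean of its squares is one:
#' `F(X) = (L(X) - mean(L)) / sqrt(mean((L - mean(L))^2))`.
#' The operation is idempotent: an already standardised profile is returned
#' unchanged (up to floating point).
#'
#' @param x A numeric vector of length 20 named by the standard amino-acid
#'   letters, or a data frame with an `amino_acid` column and one or more
#'   numeric property columns (each column is standardised independently).
#' @return An object of the same shape as `x`.
#' @examples
#' p <- setNames(seq(2, 40, by = 2), funcascade:::AA20)
#' f <- normalize_property(p)
#' mean(f); mean(f^2)
#' @export
normalize_property <- function(x) UseMethod("normalize_property")

#' @export
normalize_property.default <- function(x) {
  x <- check_property_vector(x)
  mu <- mean(x)
  ms <- mean((x - mu)^2)
  if (ms == 0)
    abort("Degenerate property: all 20 values are identical.")
  out <- (x - mu) / sqrt(ms)
  out[AA20]
}

#' @export
normalize_property.data.frame <- function(x) {
  if (!"amino_acid" %in% names(x))
    abort("Property tables need an `amino_acid` column.")
  for (col in setdiff(names(x), "amino_acid")) {
    v <- setNames(x[[col]], x$amino_acid)
    x[[col]] <- as.numeric(normalize_property(v)[x$amino_acid])
  }
  x
}

check_property_vector <- function(x) {
  if (!is.numeric(x) || is.null(names(x)))
    abort("A property profile is a numeric vector named by amino acid.")
  if (!setequal(names(x), AA20) || length(x) != 20L)
    abort("Malformed property table: need exactly the 20 standard amino acids.")
  if (anyNA(x) || any(!is.finite(x)))
    abort("Property values must be finite.")
  x[AA20]
}

# data frame -> named list of property vectors (in column order)
property_list <- function(properties, normalize = FALSE) {
  if (!is.data.frame(properties) || !"amino_acid" %in% names(properties))
    abort("`properties` must be a data frame with an `amino_acid` column.")
  cols <- setdiff(names(properties), "amino_acid")
  if (!length(cols)) abort("`properties` has no property columns.")
  out <- lapply(cols, function(col) {
    v <- check_property_vector(setNames(properties[[col]],
                                        properties$amino_acid))
    if (normalize) normalize_property(v) else v
  })
  names(out) <- cols
  out
}
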