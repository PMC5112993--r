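#' Read protein sequences from FASTA
#'
#' Record identifiers are taken up to the first whitespace in the header;
#' sequences are upper-cased.  Duplicate identifiers and empty records are
#' rejected.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `protein` and `sequence`.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (!length(set))
    return(tibble(protein = character(), sequence = character()))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    abort(sprintf("Duplicate FASTA record ID '%s' in %s.",
                  ids[duplicated(ids)][1], path))
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs)))
    abort(sprintf("Empty FASTA record '%s' in %s.",
                  ids[!nzchar(seqs)][1], path))
  tibble(protein = unname(ids), sequence = unname(seqs))
}

#' Write sequences to FASTA
#'
#' @param sequences A data frame with columns `protein` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  sequences <- need_cols(sequences, c("protein", "sequence"), "sequences")
  set <- Biostrings::AAStringSet(setNames(sequences$sequence,
                                          sequences$protein))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read multi-label annotations
#'
#' Expects the variable-width CSV layout in which the first field of each
#' row is the protein identifier and every further field is one of the
#' scheme's category numbers.  Duplicate categories within a row are
#' collapsed with a warning; an out-of-scheme category or a repeated protein
#' identifier is an error that names the offending row.
#'
#' @param path Path to the annotation CSV.
#' @param scheme Function scheme, see [funcat_scheme()].
#' @return A tibble with columns `protein` and `category` (long format,
#'   one row per label).
#' @export
read_annotations <- function(path, scheme = funcat_scheme()) {
  scheme <- validate_scheme(scheme)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(tibble(protein = character(), category = integer()))
  seen <- character(0)
  rows <- vector("list", length(lines))
  for (k in seq_along(lines)) {
    fields <- trimws(strsplit(lines[k], ",", fixed = TRUE)[[1]])
    if (length(fields) < 2L)
      abort(sprintf("Line %d of %s: need a protein ID and >= 1 category.",
                    k, path))
    id <- fields[1]
    if (id %in% seen)
      abort(sprintf("Line %d of %s: duplicate protein ID '%s'.", k, path, id))
    seen <- c(seen, id)
    cats <- suppressWarnings(as.integer(fields[-1]))
    if (anyNA(cats))
      abort(sprintf("Line %d of %s: non-integer category.", k, path))
    bad <- setdiff(cats, scheme$category)
    if (length(bad))
      abort(sprintf("Line %d of %s: category %d is not in the scheme.",
                    k, path, bad[1]))
    if (anyDuplicated(cats)) {
      warn(sprintf("Line %d of %s: duplicate categories collapsed.", k, path))
      cats <- unique(cats)
    }
    rows[[k]] <- tibble(protein = id, category = sort(cats))
  }
  bind_rows(rows)
}

#' Write annotations as variable-width CSV
#'
#' @param annotations A data frame with columns `protein` and `category`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  annotations <- need_cols(annotations, c("protein", "category"),
                           "annotations")
  rows <- annotations |>
    group_by(protein) |>
    summarise(line = paste(c(protein[1], sort(category)), collapse = ","),
              .groups = "drop")
  writeLines(rows$line, path)
  invisible(path)
}

#' Read pairwise alignment hits
#'
#' Accepts the standard 12-column tab-separated alignment format (query and
#' subject in columns 1-2, bit score in column 12) or a minimal 3-column
#' (query, subject, score) dialect; the dialect is detected from the first
#' line.  Multiple local alignments for the same (query, subject) pair are
#' collapsed to the maximum score.
#'
#' @param path Path to the tab-separated hits file.
#' @return A tibble with columns `query`, `subject`, `score`.
#' @export
read_similarity <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(tibble(query = character(), subject = character(),
                  score = numeric()))
  nfield <- length(strsplit(lines[1], "\t", fixed = TRUE)[[1]])
  score_col <- if (nfield >= 12L) 12L else if (nfield == 3L) 3L else
    abort(sprintf("%s: expected 12-column or 3-column tab-separated hits.",
                  path))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < score_col)
  if (length(bad))
    abort(sprintf("Line %d of %s: too few fields.", bad[1], path))
  tbl <- tibble(query = vapply(parts, `[[`, "", 1L),
                subject = vapply(parts, `[[`, "", 2L),
                score = suppressWarnings(
                  as.numeric(vapply(parts, `[[`, "", score_col))))
  if (anyNA(tbl$score))
    abort(sprintf("Line %d of %s: non-numeric score.",
                  which(is.na(tbl$score))[1], path))
  if (any(tbl$score < 0))
    abort(sprintf("Line %d of %s: negative score.",
                  which(tbl$score < 0)[1], path))
  tbl |> group_by(query, subject) |>
    summarise(score = max(score), .groups = "drop")
}

#' Read weighted interaction edges
#'
#' Tab-separated `protein1 protein2 weight` rows.  Edges are undirected:
#' duplicated and reversed pairs are collapsed to the heaviest weight.
#'
#' @param path Path to the tab-separated edge file.
#' @return A tibble with columns `protein1`, `protein2`, `weight`.
#' @export
read_interactions <- function(path) {
  tbl <- read_3col(path, c("protein1", "protein2", "weight"))
  if (!nrow(tbl)) return(tbl)
  if (any(tbl$weight < 0))
    abort(sprintf("%s: negative interaction weight.", path))
  tbl |>
    mutate(a = pmin(protein1, protein2), b = pmax(protein1, protein2)) |>
    group_by(a, b) |>
    summarise(weight = max(weight), .groups = "drop") |>
    rename(protein1 = a, protein2 = b)
}

#' Read an identifier mapping table
#'
#' Tab-separated two-column file mapping annotation-space protein IDs to
#' network-space IDs.  Proteins without a mapping simply lack interaction
#' evidence.
#'
#' @param path Path to the tab-separated mapping file.
#' @return A tibble with columns `protein` and `network_id`.
#' @export
read_id_map <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(tibble(protein = character(), network_id = character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad))
    abort(sprintf("Line %d of %s: expected 2 tab-separated fields.",
                  bad[1], path))
  tibble(protein = vapply(parts, `[[`, "", 1L),
         network_id = vapply(parts, `[[`, "", 2L))
}

read_3col <- function(path, nms) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    out <- tibble(a = character(), b = character(), w = numeric())
    names(out) <- nms
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    abort(sprintf("Line %d of %s: expected 3 tab-separated fields.",
                  bad[1], path))
  w <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  if (anyNA(w))
    abort(sprintf("Line %d of %s: non-numeric weight.",
                  which(is.na(w))[1], path))
  out <- tibble(a = vapply(parts, `[[`, "", 1L),
                b = vapply(parts, `[[`, "", 2L), w = w)
  names(out) <- nms
  out
}

#' Read a plain-text key/value configuration file
#'
#' Lines of `key = value` or `key<TAB>value`; blank lines and `#` comments
#' are ignored.  Recognised keys include `lambda`, `omega`, `seed`, `folds`
#' and `repeats` (coerced to numbers) and `properties` (comma-separated).
#'
#' @param path Path to the configuration file.
#' @return A named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "[=\t]", perl = TRUE)[[1]]
    if (length(kv) < 2L)
      abort(sprintf("Malformed config line: '%s'.", ln))
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    out[[key]] <- switch(key,
      lambda = , omega = , seed = , folds = , repeats = as.numeric(val),
      properties = trimws(strsplit(val, ",", fixed = TRUE)[[1]]),
      val)
  }
  out
}

#' Write or read a dataset fixture directory
#'
#' `write_dataset()` materialises an [fc_dataset()] as plain-text files
#' (`sequences.fasta`, `annotations.csv`, `similarity.tsv`,
#' `interactions.tsv`), which `read_dataset()` reassembles.
#'
#' @param dataset An [fc_dataset()].
#' @param dir Directory to write to / read from (created if needed).
#' @param scheme Scheme used when reading back.
#' @return `write_dataset()` returns `dir` invisibly; `read_dataset()`
#'   returns an [fc_dataset()].
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "fc_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_annotations(dataset$annotations, file.path(dir, "annotations.csv"))
  if (!is.null(dataset$sequences))
    write_fasta(dataset$sequences, file.path(dir, "sequences.fasta"))
  if (!is.null(dataset$similarity))
    readr::write_tsv(dataset$similarity, file.path(dir, "similarity.tsv"),
                     col_names = FALSE)
  if (!is.null(dataset$interactions))
    readr::write_tsv(dataset$interactions,
                     file.path(dir, "interactions.tsv"), col_names = FALSE)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir, scheme = funcat_scheme()) {
  maybe <- function(f, reader, ...) {
    p <- file.path(dir, f)
    if (file.exists(p)) reader(p, ...) else NULL
  }
  fc_dataset(
    annotations = read_annotations(file.path(dir, "annotations.csv"),
                                   scheme = scheme),
    sequences = maybe("sequences.fasta", read_fasta),
    similarity = maybe("similarity.tsv", read_similarity),
    interactions = maybe("interactions.tsv", read_interactions),
    id_map = maybe("id_map.tsv", read_id_map),
    scheme = scheme)
}
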