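# ---- sequence input -------------------------------------------------------

#' Read sequences from FASTA or FASTQ
#'
#' The format is sniffed from the first record character (`>` FASTA, `@`
#' FASTQ); plain and gzipped files are handled. Sequences are uppercased;
#' FASTQ qualities are ignored. Record ids are the header up to the first
#' whitespace.
#'
#' @param path Path to a FASTA/FASTQ file, optionally gzipped.
#' @return A tibble with columns `id`, `seq`, `length`.
#' @export
read_sequences <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  con <- gzfile(path, "rt")
  first <- tryCatch({
    l <- readLines(con, n = 1)
    if (length(l) == 0) "" else substr(l, 1, 1)
  }, finally = close(con))
  fmt <- switch(first, ">" = "fasta", "@" = "fastq",
                stop("cannot sniff sequence format of ", path,
                     " (expected FASTA or FASTQ)", call. = FALSE))
  ss <- tryCatch(
    Biostrings::readBStringSet(path, format = fmt),
    error = function(e)
      stop("parse error reading ", fmt, " file ", path, ": ",
           conditionMessage(e), call. = FALSE)
  )
  ids <- sub("\\s.*$", "", names(ss))
  tibble::tibble(
    id = ids,
    seq = toupper(as.character(ss, use.names = FALSE)),
    length = Biostrings::width(ss)
  )
}

#' Write sequences as FASTA
#'
#' @param seqs A tibble with `id` and `seq` columns, or a named character
#'   vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stbl <- as_sequence_tbl(seqs)
  writeLines(paste0(">", stbl$id, "\n", stbl$seq), path)
  invisible(path)
}

# ---- tabular outputs ------------------------------------------------------

tool_header <- function(params = list()) {
  ver <- as.character(utils::packageVersion("subseedr"))
  c(paste0("# subseedr ", ver),
    if (length(params))
      paste0("# ", names(params), "=", vapply(params, as.character,
                                              character(1))))
}

write_commented_tsv <- function(df, path, params = list()) {
  body <- readr::format_tsv(df)
  writeLines(c(tool_header(params), sub("\n$", "", body)), path)
  invisible(path)
}

#' Write and read seed records as TSV
#'
#' The file starts with `#`-commented header lines naming the tool version
#' and the run parameters, followed by tab-separated records in a
#' deterministic order (sequence id, window, order). Coordinates are
#' 0-based; position tuples are comma-joined. `read_seeds()` reconstructs
#' the tibble, including the `positions` list-column.
#'
#' @param seeds A seed tibble.
#' @param path Output path.
#' @param params Named list recorded in the header.
#' @return `path` (writer) or the seed tibble (reader).
#' @export
write_seeds <- function(seeds, path, params = list()) {
  out <- dplyr::arrange(seeds, .data$id, .data$window, .data$order)
  out$positions <- vapply(out$positions, paste, character(1), collapse = ",")
  out$omega <- sprintf("%.0f", out$omega)
  write_commented_tsv(out, path, params)
}

#' @rdname write_seeds
#' @export
read_seeds <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        col_types = readr::cols(
                          id = "c", window = "i", order = "i", seed = "c",
                          positions = "c", pivot = "i", psi = "d",
                          omega = "d", .default = readr::col_guess()))
  df$positions <- lapply(strsplit(df$positions, ",", fixed = TRUE),
                         as.integer)
  tibble::as_tibble(df[c("id", "window", "order", "seed", "positions",
                         "pivot", "psi", "omega",
                         setdiff(names(df), c("id", "window", "order", "seed",
                                              "positions", "pivot", "psi",
                                              "omega")))])
}

#' Write seed matches or overlap candidate pairs as TSV
#'
#' `write_matches()` emits one row per seed match with comma-joined aligned
#' positions; `write_pairs()` emits overlap candidate pairs with their
#' shared-seed counts.
#'
#' @param matches A match tibble from [collect_matches()] (optionally
#'   labeled).
#' @param pairs The `pairs` tibble of an `overlap_result`, or the result
#'   itself.
#' @param path Output path.
#' @param params Named list recorded in the header.
#' @return `path`, invisibly.
#' @export
write_matches <- function(matches, path, params = list()) {
  out <- dplyr::arrange(matches, .data$id_a, .data$id_b, .data$window_a,
                        .data$window_b)
  out$pos_a <- vapply(out$pos_a, paste, character(1), collapse = ",")
  out$pos_b <- vapply(out$pos_b, paste, character(1), collapse = ",")
  write_commented_tsv(out, path, params)
}

#' @rdname write_matches
#' @export
read_matches <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  df$pos_a <- lapply(strsplit(as.character(df$pos_a), ",", fixed = TRUE),
                     as.integer)
  df$pos_b <- lapply(strsplit(as.character(df$pos_b), ",", fixed = TRUE),
                     as.integer)
  tibble::as_tibble(df)
}

#' @rdname write_matches
#' @export
write_pairs <- function(pairs, path, params = list()) {
  if (inherits(pairs, "overlap_result")) pairs <- pairs$pairs
  write_commented_tsv(dplyr::arrange(pairs, .data$id_a, .data$id_b),
                      path, params)
}

#' Write a truth alignment or truth intervals as TSV
#'
#' @param truth A tibble (aligned pairs `pos_a`/`pos_b`, or read intervals).
#' @param path Output path.
#' @param params Named list recorded in the header.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path, params = list()) {
  write_commented_tsv(truth, path, params)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  tibble::as_tibble(readr::read_tsv(path, comment = "#",
                                    show_col_types = FALSE))
}
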