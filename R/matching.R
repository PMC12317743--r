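# key columns used to declare two seed records identical
match_key_cols <- function(seeds) {
  rc <- "key" %in% names(seeds)
  cols <- if (rc) c("key_order", "key") else c("order", "seed")
  if ("table_set" %in% names(seeds)) cols <- c("table_set", cols)
  cols
}

#' Collect seed matches between two seed sets
#'
#' A match is emitted for every pair of records, one from each input, with
#' identical key: equal (table set, order index, seed string), or equal
#' (table set, canonical order, canonical string) when both inputs carry
#' strand-canonical keys from [canonicalize_rc()]. Matches pooled over
#' repeated table sets are obtained by stacking runs with a distinguishing
#' `table_set` column before calling this function.
#'
#' Each match implies aligned character pairs: the j-th chosen position of
#' one record pairs with the j-th of the other (with one side reversed when
#' the two records lie on opposite canonical strands). Positions are
#' returned as absolute 0-based coordinates on the parent sequences.
#'
#' @param seeds_a,seeds_b Seed tibbles (see [seed_sequences()]); both plain
#'   or both rc-canonicalized.
#' @return A tibble with one row per match: `id_a`, `id_b`, `window_a`,
#'   `window_b`, the key columns, and list-columns `pos_a`, `pos_b` of
#'   aligned absolute positions (index-aligned pairs).
#' @export
collect_matches <- function(seeds_a, seeds_b) {
  rc_a <- "key" %in% names(seeds_a)
  rc_b <- "key" %in% names(seeds_b)
  if (rc_a != rc_b)
    stop("cannot match strand-canonical seeds against plain seeds",
         call. = FALSE)
  keys <- match_key_cols(seeds_a)
  prep <- function(s, suffix) {
    s <- dplyr::mutate(s,
      abspos = purrr::map2(.data$positions, .data$window, ~ .x + .y))
    cols <- c("id", "window", "abspos", keys,
              if (rc_a) "flipped" else NULL)
    s <- s[cols]
    names(s)[names(s) %in% c("id", "window", "abspos", "flipped")] <-
      paste0(c("id", "window", "pos", if (rc_a) "flipped" else NULL),
             "_", suffix)
    s
  }
  a <- prep(seeds_a, "a")
  b <- prep(seeds_b, "b")
  m <- dplyr::inner_join(a, b, by = keys, relationship = "many-to-many")
  if (rc_a && nrow(m) > 0) {
    # opposite canonical strands: j-th char of one pairs with the
    # (len-j+1)-th of the other
    flip <- m$flipped_a != m$flipped_b
    m$pos_b[flip] <- lapply(m$pos_b[flip], rev)
  }
  dplyr::select(m, dplyr::all_of(c("id_a", "id_b", "window_a", "window_b",
                                   keys, "pos_a", "pos_b")))
}

#' Label seed matches against a truth alignment
#'
#' A match is labeled true when strictly more than half of its aligned
#' character pairs appear in the ground-truth alignment (a substituted
#' position still counts as an aligned pair).
#'
#' @param matches A match tibble from [collect_matches()].
#' @param truth A tibble of ground-truth aligned position pairs with columns
#'   `pos_a`, `pos_b` (absolute, 0-based).
#' @return `matches` with a logical column `true`.
#' @export
label_matches <- function(matches, truth) {
  truth_set <- paste(truth$pos_a, truth$pos_b)
  lab <- purrr::map2_lgl(matches$pos_a, matches$pos_b, function(pa, pb) {
    hits <- sum(paste(pa, pb) %in% truth_set)
    hits > length(pa) / 2
  })
  dplyr::mutate(matches, true = lab)
}

#' Seed-match precision
#'
#' Number of true matches over all matches; `NA` (not 0) when there are no
#' matches.
#'
#' @param matches A labeled match tibble (see [label_matches()]).
#' @return A fraction in `[0, 1]`, or `NA_real_`.
#' @export
match_precision <- function(matches) {
  if (nrow(matches) == 0) return(NA_real_)
  mean(matches$true)
}

#' Segment sensitivity of seed matches
#'
#' Partitions the read (the `a` side of the matches) into fixed-length
#' segments and reports the fraction of segments containing the start of at
#' least one true seed match. A match is attributed to the single segment
#' containing its leftmost aligned position on the read. A final partial
#' segment counts as a segment only if it is at least half the segment
#' length.
#'
#' @param matches A labeled match tibble.
#' @param read_length Length of the read.
#' @param segment_length Segment size in bp (default 200).
#' @return A fraction in `[0, 1]`, or `NA` if the read has no segments.
#' @export
segment_sensitivity <- function(matches, read_length, segment_length = 200) {
  n_full <- read_length %/% segment_length
  rem <- read_length - n_full * segment_length
  n_seg <- n_full + (rem >= segment_length / 2)
  if (n_seg == 0) return(NA_real_)
  true_m <- dplyr::filter(matches, .data$true)
  if (nrow(true_m) == 0) return(0)
  starts <- vapply(true_m$pos_a, min, numeric(1))
  seg <- starts %/% segment_length
  seg <- seg[seg < n_seg] # starts inside a dropped partial tail are ignored
  length(unique(seg)) / n_seg
}

#' Coverage of true and false seed matches
#'
#' A character of the first sequence is encompassed by a match if it lies
#' within the span from the match's smallest to largest aligned position on
#' that sequence. Overlapping spans are counted once (interval union).
#'
#' @param matches A labeled match tibble.
#' @param seq_length Length of the first (`a`-side) sequence.
#' @return A one-row tibble with `true_coverage` and `false_coverage`,
#'   fractions in `[0, 1]`.
#' @export
match_coverage <- function(matches, seq_length) {
  span_frac <- function(m) {
    if (nrow(m) == 0) return(0)
    lo <- vapply(m$pos_a, min, numeric(1))
    hi <- vapply(m$pos_a, max, numeric(1))
    ir <- IRanges::reduce(IRanges::IRanges(start = lo + 1, end = hi + 1))
    sum(IRanges::width(ir)) / seq_length
  }
  tibble::tibble(
    true_coverage = span_frac(dplyr::filter(matches, .data$true)),
    false_coverage = span_frac(dplyr::filter(matches, !.data$true))
  )
}

#' Overlap detection from shared seeds
#'
#' Reports a pair of reads as an overlap candidate when the two reads share
#' at least one seed key. Ground truth: two reads truly overlap when their
#' source intervals on the reference overlap by at least `min_overlap` bp.
#' Sensitivity is the fraction of ground-truth pairs that are reported;
#' precision the fraction of reported pairs that are true.
#'
#' @param seeds A seed tibble covering all reads (plain or rc-canonical).
#' @param reads A tibble with columns `id`, `start`, `end` giving each
#'   read's source interval on the reference (0-based, `end` exclusive).
#' @param min_overlap Minimum reference overlap in bp for a true pair
#'   (default 15).
#' @return An object of class `overlap_result`: a list with `pairs` (tibble
#'   `id_a`, `id_b`, `n_shared`, `true`), `sensitivity`, `precision`,
#'   `n_truth`, `n_reported`.
#' @export
detect_overlaps <- function(seeds, reads, min_overlap = 15) {
  keys <- match_key_cols(seeds)
  dk <- dplyr::distinct(seeds[c("id", keys)])
  cand <- dplyr::inner_join(dk, dk, by = keys,
                            relationship = "many-to-many",
                            suffix = c("_a", "_b"))
  cand <- dplyr::filter(cand, .data$id_a < .data$id_b)
  cand <- dplyr::count(cand, .data$id_a, .data$id_b, name = "n_shared")

  ir <- IRanges::IRanges(start = reads$start + 1, end = reads$end)
  hits <- IRanges::findOverlaps(ir, minoverlap = min_overlap,
                                drop.self = TRUE, drop.redundant = TRUE)
  truth <- tibble::tibble(
    id_a = pmin(reads$id[S4Vectors::queryHits(hits)],
                reads$id[S4Vectors::subjectHits(hits)]),
    id_b = pmax(reads$id[S4Vectors::queryHits(hits)],
                reads$id[S4Vectors::subjectHits(hits)])
  )
  truth <- dplyr::distinct(truth)

  truth_key <- paste(truth$id_a, truth$id_b)
  cand_key <- paste(cand$id_a, cand$id_b)
  cand <- dplyr::mutate(cand, true = cand_key %in% truth_key)
  n_correct <- sum(cand$true)
  structure(list(
    pairs = cand,
    sensitivity = if (nrow(truth) == 0) NA_real_ else n_correct / nrow(truth),
    precision = if (nrow(cand) == 0) NA_real_ else n_correct / nrow(cand),
    n_truth = nrow(truth),
    n_reported = nrow(cand)
  ), class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat("overlap detection:", x$n_reported, "reported pairs,",
      x$n_truth, "ground-truth pairs\n")
  cat("  sensitivity =", format(x$sensitivity, digits = 4),
      " precision =", format(x$precision, digits = 4), "\n")
  invisible(x)
}

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname detect_overlaps
#' @param x An `overlap_result`.
#' @param ... Unused.
#' @method glance overlap_result
#' @export
glance.overlap_result <- function(x, ...) {
  tibble::tibble(sensitivity = x$sensitivity, precision = x$precision,
                 n_truth = x$n_truth, n_reported = x$n_reported)
}

# ---- baseline substring seeders ------------------------------------------

#' Baseline substring seeders
#'
#' `seed_kmers()` emits every length-k substring of each sequence as a seed
#' (one record per position). `seed_minimizers()` emits, for every length-n
#' window, the k-mer minimizing a seeded hash; repeating with different
#' `hash_seed` values gives independent minimizer orders. Both return
#' tibbles shaped like [seed_sequences()] output so they can feed
#' [collect_matches()] and [detect_overlaps()].
#'
#' @param seqs Sequences as for [seed_sequences()].
#' @param k Seed (k-mer) length.
#' @param n Window length for minimizers (`n >= k`).
#' @param hash_seed Integer seed for the minimizer hash order.
#' @return A seed tibble with columns `id`, `window`, `order`, `seed`,
#'   `positions` (window-local offsets).
#' @export
seed_kmers <- function(seqs, k) {
  stbl <- as_sequence_tbl(seqs)
  out <- purrr::map2(stbl$id, toupper(stbl$seq), function(id, x) {
    L <- nchar(x)
    if (L < k) return(NULL)
    w <- 0:(L - k)
    tibble::tibble(
      id = id, window = as.integer(w), order = 1L,
      seed = substring(x, w + 1, w + k),
      positions = rep(list(0:(k - 1)), length(w))
    )
  })
  dplyr::bind_rows(out)
}

# base-4 integer codes of all k-mers of x; NA where a k-mer holds an
# out-of-alphabet symbol (exact for k <= 26: 4^26 < 2^53)
kmer_codes <- function(x, k, alphabet = c("A", "C", "G", "T")) {
  sym <- encode_symbols(chars_of(x), alphabet) - 1
  L <- length(sym)
  if (L < k) return(numeric(0))
  code <- numeric(L - k + 1)
  for (j in seq_len(k)) code <- code * 4 + sym[j:(L - k + j)]
  code
}

#' @rdname seed_kmers
#' @export
seed_minimizers <- function(seqs, n, k, hash_seed = 1L) {
  if (k > n) stop("minimizer needs k <= n", call. = FALSE)
  if (k > 26) stop("minimizer hash supports k <= 26", call. = FALSE)
  stbl <- as_sequence_tbl(seqs)
  ab <- local_seed(hash_seed, {
    c(sample.int(2^20, 1) * 2 + 1, sample.int(2^20, 1))
  })
  p <- 2^31 - 1
  out <- purrr::map2(stbl$id, toupper(stbl$seq), function(id, x) {
    L <- nchar(x)
    if (L < n) return(NULL)
    codes <- kmer_codes(x, k)
    h <- (ab[1] * codes + ab[2]) %% p
    h[is.na(h)] <- Inf # k-mers containing out-of-alphabet symbols rank last
    w <- 0:(L - n)
    off <- vapply(w, function(s) {
      hw <- h[(s + 1):(s + n - k + 1)]
      which.min(hw) - 1L # ties: leftmost
    }, integer(1))
    tibble::tibble(
      id = id, window = as.integer(w), order = 1L,
      seed = substring(x, w + off + 1, w + off + k),
      positions = lapply(off, function(o) as.integer(o:(o + k - 1)))
    )
  })
  dplyr::bind_rows(out)
}
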