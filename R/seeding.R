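# coerce sequence input to tibble(id, seq)
as_sequence_tbl <- function(seqs) {
  if (is.data.frame(seqs)) {
    if (!all(c("id", "seq") %in% names(seqs)))
      stop("sequence data frame needs columns `id` and `seq`", call. = FALSE)
    return(tibble::as_tibble(seqs[c("id", "seq")]))
  }
  if (is.character(seqs)) {
    ids <- names(seqs)
    if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
    return(tibble::tibble(id = ids, seq = unname(seqs)))
  }
  stop("`seqs` must be a character vector or a data frame with id/seq",
       call. = FALSE)
}

check_seeding_params <- function(tables, n, t, mode, k0) {
  k <- tables$k
  bits <- max(1, ceiling(log2(length(tables$alphabet))))
  kcap <- floor(52 / bits)
  if (k > kcap)
    stop("the seeder supports k <= ", kcap, " for a ",
         length(tables$alphabet), "-symbol alphabet (exact tie-resolution ",
         "codes)", call. = FALSE)
  if (n < k) stop("window length `n` must be >= k", call. = FALSE)
  if (t < 1 || t > k) stop("`t` must be in 1..k", call. = FALSE)
  if (mode == "rc" && !isTRUE(tables$rc_symmetric))
    stop("mode = \"rc\" requires reverse-complement-symmetric tables ",
         "(see generate_symmetric_tables())", call. = FALSE)
  if (mode == "w" && k0 < 1)
    stop("mode = \"w\" requires a prefix length k0 >= 1", call. = FALSE)
  invisible(TRUE)
}

seed_one_sequence <- function(id, x, tables, n, t) {
  sym <- encode_symbols(chars_of(x), tables$alphabet)
  sym0 <- ifelse(is.na(sym), -1L, sym - 1L)
  res <- cpp_seed_sequence(
    as.integer(sym0), as.integer(n), as.integer(t),
    tables$k, tables$d,
    as.numeric(tables$AF), as.numeric(tables$BF1), as.numeric(tables$BF2),
    as.integer(tables$CF),
    as.numeric(tables$AR), as.numeric(tables$BR1), as.numeric(tables$BR2),
    as.integer(tables$CR),
    as.numeric(tables$AP), as.numeric(tables$BP1), as.numeric(tables$BP2),
    as.integer(tables$CP),
    tables$alphabet
  )
  if (res$skipped > 0)
    rlang::inform(paste0("sequence `", id, "`: skipped ", res$skipped,
                         " window(s) containing non-alphabet symbols"))
  out <- tibble::tibble(
    id = id,
    window = as.integer(res$window),
    order = as.integer(res$order),
    seed = res$seed,
    positions = lapply(seq_len(nrow(res$positions)),
                       function(r) as.integer(res$positions[r, ])),
    pivot = as.integer(res$pivot),
    psi = res$psi,
    omega = res$omega
  )
  # exact score ties between distinct strings (flagged by the DP) are
  # re-resolved against the enumeration oracle, which applies the full tie
  # rule; beyond the (deliberately tight) guard the DP's lex-min answer
  # stands — with symmetric tables a structural tie touches roughly 1% of
  # window-orders, so the per-tie resolution cost must stay small
  tied <- which(res$tie)
  if (length(tied) > 0 && choose(n, tables$k) <= TIE_ENUM_GUARD) {
    for (r in tied) {
      w <- out$window[r]
      orc <- oracle_seed_window(substr(x, w + 1, w + n), tables,
                                orders = out$order[r])
      out$seed[r] <- orc$seed
      out$positions[[r]] <- orc$positions[[1]] # window-local offsets
      out$pivot[r] <- orc$pivot
      out$psi[r] <- orc$psi
      out$omega[r] <- orc$omega
    }
  }
  out
}

#' Compute subsequence seeds for every window of each sequence
#'
#' Slides a length-`n` window over each input sequence and, for every
#' window, computes the minimal length-k subsequence under each of the first
#' `t` of the k orders defined by `tables`, by dynamic programming. Each
#' record carries the chosen positions (0-based offsets within the window),
#' the pivot offset, and the score pair.
#'
#' Modes:
#' * `"plain"`: one record per (window, order).
#' * `"rc"`: as plain, plus strand-canonical key columns
#'   (see [canonicalize_rc()]); requires symmetric tables.
#' * `"w"`: substring-prefix variant. Each seed is the literal `k0`-length
#'   prefix starting at the window start, concatenated with a subsequence
#'   seed of the following length-`n` window; emitted seeds have length
#'   `k0 + k` and positions cover the `k0` contiguous prefix offsets plus
#'   the subsequence offsets shifted by `k0`. The `"rc"` canonicalization is
#'   not defined for this concatenated variant and is refused.
#'
#' Windows containing symbols outside the table alphabet (e.g. `N`) emit no
#' seeds; a notice reports how many were skipped. Sequences shorter than the
#' span of one window yield no records, with a notice.
#'
#' @param seqs Character vector of sequences (optionally named) or a data
#'   frame with columns `id` and `seq`.
#' @param tables An `abck_tables` object.
#' @param n Window length (`>= k`).
#' @param t Number of orders to emit per window, in `1..k` (default `k`).
#' @param mode One of `"plain"`, `"rc"`, `"w"`.
#' @param k0 Prefix length for mode `"w"`; defaults to `floor(k / 2)`.
#' @return A tibble with columns `id`, `window` (0-based start), `order`,
#'   `seed`, `positions` (list of 0-based offset vectors), `pivot`, `psi`,
#'   `omega`; in rc mode additionally `key`, `key_order`, `flipped`.
#' @examples
#' tb <- generate_random_tables(4, 3, rng_seed = 1)
#' seed_sequences(c(r1 = "ACGTACGTAC"), tb, n = 6, t = 2)
#' @export
seed_sequences <- function(seqs, tables, n, t = tables$k,
                           mode = c("plain", "rc", "w"),
                           k0 = floor(tables$k / 2)) {
  mode <- match.arg(mode)
  validate_abck_tables(tables)
  check_seeding_params(tables, n, t, mode, k0)
  stbl <- as_sequence_tbl(seqs)
  if (mode == "w") return(seed_sequences_2w(stbl, tables, n, t, k0))

  out <- purrr::map2(stbl$id, toupper(stbl$seq), function(id, x) {
    if (nchar(x) < n) {
      rlang::inform(paste0("sequence `", id, "` is shorter than one window (",
                           nchar(x), " < ", n, "); no seeds emitted"))
      return(NULL)
    }
    seed_one_sequence(id, x, tables, n, t)
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0)
    res <- tibble::tibble(id = character(), window = integer(),
                          order = integer(), seed = character(),
                          positions = list(), pivot = integer(),
                          psi = numeric(), omega = numeric())
  if (mode == "rc") res <- canonicalize_rc(res, tables)
  res
}

#' Seed a single window
#'
#' Convenience wrapper: treats `x` as one window of its own length and
#' returns the `t` seed records.
#'
#' @param x A window string.
#' @param tables An `abck_tables` object.
#' @param t Number of orders (default k).
#' @return A tibble of `t` seed records (see [seed_sequences()]).
#' @export
seed_window <- function(x, tables, t = tables$k) {
  seed_sequences(c(window = x), tables, n = nchar(x), t = t)
}

# substring-prefix variant: prefix of length k0 + seeds of trailing window
seed_sequences_2w <- function(stbl, tables, n, t, k0) {
  k <- tables$k
  out <- purrr::map2(stbl$id, toupper(stbl$seq), function(id, x) {
    N <- nchar(x)
    if (N < k0 + n) {
      rlang::inform(paste0("sequence `", id, "` is shorter than k0 + n (",
                           N, " < ", k0 + n, "); no seeds emitted"))
      return(NULL)
    }
    plain <- seed_one_sequence(id, x, tables, n, t)
    plain <- dplyr::filter(plain, .data$window >= k0) # trailing windows
    w2 <- plain$window - k0
    prefix <- substr(rep(x, length(w2)), w2 + 1, w2 + k0)
    tibble::tibble(
      id = id,
      window = as.integer(w2),
      order = plain$order,
      seed = paste0(prefix, plain$seed),
      positions = lapply(seq_along(w2), function(r)
        as.integer(c(0:(k0 - 1), plain$positions[[r]] + k0))),
      pivot = as.integer(plain$pivot + k0),
      psi = plain$psi,
      omega = plain$omega
    )
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0)
    res <- tibble::tibble(id = character(), window = integer(),
                          order = integer(), seed = character(),
                          positions = list(), pivot = integer(),
                          psi = numeric(), omega = numeric())
  res
}

#' Attach strand-canonical keys to seed records
#'
#' With reverse-complement-symmetric tables, the i-th seed of a window
#' equals the reverse complement of the (k-i+1)-th seed of the window's
#' reverse complement. Canonicalizing each record to
#' `key = min(seed, revcomp(seed))` (lexicographically) and
#' `key_order = i` or `k-i+1` accordingly makes a window and its reverse
#' complement yield identical key multisets, so seeds can be matched without
#' knowing the strand.
#'
#' @param seeds A seed tibble from [seed_sequences()].
#' @param tables The (symmetric) `abck_tables` used to produce it.
#' @return The tibble with additional columns `key`, `key_order`, `flipped`
#'   (whether the canonical string is the reverse complement of the stored
#'   seed).
#' @export
canonicalize_rc <- function(seeds, tables) {
  if (!isTRUE(tables$rc_symmetric))
    stop("canonical keys require reverse-complement-symmetric tables",
         call. = FALSE)
  k <- tables$k
  if (nrow(seeds) > 0 && any(nchar(seeds$seed) != k))
    stop("canonical keys are defined for plain length-k seeds only ",
         "(not for the substring-prefix variant)", call. = FALSE)
  if (nrow(seeds) == 0)
    return(dplyr::mutate(seeds, key = character(), key_order = integer(),
                         flipped = logical()))
  rc <- reverse_complement(seeds$seed, tables$complement)
  flipped <- rc < seeds$seed
  palind <- rc == seeds$seed
  key_order <- ifelse(palind, pmin(seeds$order, k - seeds$order + 1L),
                      ifelse(flipped, k - seeds$order + 1L, seeds$order))
  dplyr::mutate(seeds,
                key = ifelse(flipped, rc, seeds$seed),
                key_order = as.integer(key_order),
                flipped = flipped & !palind)
}
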