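# ---- symbol encoding ------------------------------------------------------

# split a string into single characters
chars_of <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# 1-based symbol indices into tables$alphabet; NA for out-of-alphabet symbols
encode_symbols <- function(s, alphabet) {
  if (length(s) == 1 && nchar(s) != 1) s <- chars_of(s)
  match(s, alphabet)
}

#' Reverse complement of a DNA string
#'
#' @param x Character vector of sequences.
#' @param complement_map Named character vector (default Watson-Crick).
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(x, complement_map = DNA_COMPLEMENT) {
  vapply(x, function(s) {
    ch <- rev(chars_of(s))
    paste(unname(complement_map[ch]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# ---- score functions ------------------------------------------------------

new_score <- function(psi, omega, d) {
  structure(list(psi = psi, omega = omega, d = d), class = "seed_score")
}

#' @export
print.seed_score <- function(x, ...) {
  cat("seed score: psi =", x$psi, "(mod", paste0(x$d, ")"),
      " omega =", format(x$omega, scientific = FALSE), "\n")
  invisible(x)
}

score_part <- function(sym, A, B1, B2, C, d) {
  psi <- 0; omega <- 0
  for (l in seq_along(sym)) {
    s <- sym[l]
    psi <- (psi + C[l, s]) %% d
    omega <- omega * B1[l, psi + 1, s] + A[l, psi + 1, s] * B2[l, psi + 1, s]
  }
  c(psi, omega)
}

#' Forward and reverse part scores
#'
#' Evaluate the forward score pair (psi_F, omega_F) or reverse score pair
#' (psi_R, omega_R) of a string of length at most k-1 by the left-to-right
#' recurrence: psi accumulates residues from the `C` table modulo d, and
#' omega is updated as `omega * B1 + A * B2` with table entries indexed by
#' the position within the part, the current psi residue, and the symbol.
#' The empty string scores (0, 0). For `score_reverse()` the argument is
#' given in pivot-outward order: its first character is the one adjacent to
#' the pivot.
#'
#' @param s A string (or character vector of single characters), length
#'   `<= k - 1`.
#' @param tables An `abck_tables` object.
#' @return A `seed_score` object with fields `psi`, `omega`, `d`.
#' @examples
#' tb <- generate_random_tables(5, 3, rng_seed = 0)
#' score_forward("ACG", tb)
#' @export
score_forward <- function(s, tables) {
  sym <- encode_symbols(s, tables$alphabet)
  if (length(sym) > tables$k - 1)
    stop("part string must have length <= k - 1", call. = FALSE)
  if (anyNA(sym)) stop("symbol outside the table alphabet", call. = FALSE)
  v <- score_part(sym, tables$AF, tables$BF1, tables$BF2, tables$CF, tables$d)
  new_score(v[1], v[2], tables$d)
}

#' @rdname score_forward
#' @export
score_reverse <- function(s, tables) {
  sym <- encode_symbols(s, tables$alphabet)
  if (length(sym) > tables$k - 1)
    stop("part string must have length <= k - 1", call. = FALSE)
  if (anyNA(sym)) stop("symbol outside the table alphabet", call. = FALSE)
  v <- score_part(sym, tables$AR, tables$BR1, tables$BR2, tables$CR, tables$d)
  new_score(v[1], v[2], tables$d)
}

#' Pivot score of a length-k string under order i
#'
#' Order i scores a length-k string z by picking its i-th character as the
#' pivot: the characters left of the pivot are scored pivot-outward with the
#' reverse tables, the characters right of it with the forward tables, and
#' the two part scores are combined through the pivot tables:
#' `psi = (psi_R + CP[i][z_i] + psi_F) mod d` and
#' `omega = omega_R * BP[i][z_i]_1 + AP[i][z_i] + omega_F * BP[i][z_i]_2`.
#'
#' @param z A length-k string.
#' @param i Pivot index in `1..k`.
#' @param tables An `abck_tables` object.
#' @return A `seed_score` object.
#' @examples
#' tb <- generate_random_tables(4, 3, rng_seed = 0)
#' pivot_score("ACGT", 2, tb)
#' @export
pivot_score <- function(z, i, tables) {
  sym <- encode_symbols(z, tables$alphabet)
  k <- tables$k
  if (length(sym) != k) stop("`z` must have length k", call. = FALSE)
  if (anyNA(sym)) stop("symbol outside the table alphabet", call. = FALSE)
  if (i < 1 || i > k) stop("pivot index `i` must be in 1..k", call. = FALSE)
  d <- tables$d
  rv <- score_part(rev(sym[seq_len(i - 1)]),
                   tables$AR, tables$BR1, tables$BR2, tables$CR, d)
  fv <- score_part(sym[seq_len(k - i) + i],
                   tables$AF, tables$BF1, tables$BF2, tables$CF, d)
  p <- sym[i]
  psi <- (rv[1] + tables$CP[i, p] + fv[1]) %% d
  omega <- rv[2] * tables$BP1[i, p] + tables$AP[i, p] + fv[2] * tables$BP2[i, p]
  new_score(psi, omega, d)
}

#' Compare two seed scores
#'
#' Scores are ranked by smaller psi first; on equal psi, the larger omega
#' ranks first. Returns -1 if `a` ranks strictly before `b`, +1 if after,
#' 0 if equal.
#'
#' @param a,b `seed_score` objects with the same modulus `d`.
#' @return -1, 0 or +1.
#' @export
compare_scores <- function(a, b) {
  if (!identical(a$d, b$d))
    stop("scores computed under different moduli `d`", call. = FALSE)
  if (a$psi != b$psi) return(if (a$psi < b$psi) -1L else 1L)
  if (a$omega != b$omega) return(if (a$omega > b$omega) -1L else 1L)
  0L
}

# ---- brute-force enumeration ---------------------------------------------

ENUM_GUARD <- 1e6
# ceiling for per-tie oracle re-resolution inside the seeder (cheap enough
# to run on ~1% of window-orders under symmetric tables)
TIE_ENUM_GUARD <- 2e4

#' Enumerate all distinct length-k subsequences of a string
#'
#' Enumerates the `choose(n, k)` position tuples of `x`, spells each one, and
#' returns the distinct subsequence strings with, for each, its canonical
#' witness tuple: the lexicographically smallest position tuple spelling it.
#' Guarded to `choose(n, k) <= 1e6`; larger inputs are meant for the dynamic
#' program, not enumeration.
#'
#' @param x A string.
#' @param k Subsequence length.
#' @return A tibble with columns `seed` (distinct subsequence string) and
#'   `positions` (list of 0-based strictly increasing integer vectors).
#' @examples
#' enumerate_subsequences("ACGT", 2)
#' @export
enumerate_subsequences <- function(x, k) {
  n <- nchar(x)
  if (k < 1 || k > n) stop("need 1 <= k <= nchar(x)", call. = FALSE)
  if (choose(n, k) > ENUM_GUARD)
    stop("choose(", n, ", ", k, ") exceeds the enumeration guard (1e6); ",
         "use the dynamic-programming seeder instead", call. = FALSE)
  ch <- chars_of(x)
  pos <- utils::combn(n, k)        # columns in lexicographic tuple order
  strs <- apply(pos, 2, function(p) paste(ch[p], collapse = ""))
  first <- !duplicated(strs)
  tibble::tibble(
    seed = strs[first],
    positions = lapply(which(first), function(j) as.integer(pos[, j] - 1L))
  )
}

#' Jaccard similarity of subsequence sets
#'
#' `|S_k(x) intersect S_k(y)| / |S_k(x) union S_k(y)|` over distinct
#' length-k subsequence strings, by exact enumeration.
#'
#' @param x,y Strings.
#' @param k Subsequence length.
#' @return A number in `[0, 1]`.
#' @export
jaccard_subsequences <- function(x, y, k) {
  sx <- enumerate_subsequences(x, k)$seed
  sy <- enumerate_subsequences(y, k)$seed
  length(intersect(sx, sy)) / length(union(sx, sy))
}

# vectorized pivot scores for a candidate matrix: Z is M x k of symbol
# indices; returns list(psi, omega) vectors of length M for order i
pivot_scores_matrix <- function(Z, i, tables) {
  M <- nrow(Z); k <- tables$k; d <- tables$d
  psiR <- numeric(M); omgR <- numeric(M)
  if (i > 1) {
    for (l in seq_len(i - 1)) {
      sym <- Z[, i - l]
      psiR <- (psiR + tables$CR[cbind(l, sym)]) %% d
      idx <- cbind(l, psiR + 1, sym)
      omgR <- omgR * tables$BR1[idx] + tables$AR[idx] * tables$BR2[idx]
    }
  }
  psiF <- numeric(M); omgF <- numeric(M)
  if (i < k) {
    for (l in seq_len(k - i)) {
      sym <- Z[, i + l]
      psiF <- (psiF + tables$CF[cbind(l, sym)]) %% d
      idx <- cbind(l, psiF + 1, sym)
      omgF <- omgF * tables$BF1[idx] + tables$AF[idx] * tables$BF2[idx]
    }
  }
  sym <- Z[, i]
  list(
    psi = (psiR + tables$CP[cbind(i, sym)] + psiF) %% d,
    omega = omgR * tables$BP1[cbind(i, sym)] + tables$AP[cbind(i, sym)] +
      omgF * tables$BP2[cbind(i, sym)]
  )
}

#' Brute-force optimal subsequence under one order
#'
#' Enumerates every length-k subsequence of `x` and returns the one ranked
#' first under order `i` (smallest psi, then largest omega). Ties between
#' distinct strings are broken toward the lexicographically smaller string;
#' the reported position tuple is the lexicographically smallest tuple
#' spelling the winning string. This enumeration is the ground-truth oracle
#' for the dynamic-programming seeder.
#'
#' @param x A window string.
#' @param i Order index in `1..k`.
#' @param tables An `abck_tables` object.
#' @return A one-row tibble with columns `order`, `seed`, `positions`
#'   (list of 0-based offsets), `pivot` (0-based offset of the pivot
#'   character), `psi`, `omega`.
#' @examples
#' tb <- generate_random_tables(3, 2, rng_seed = 0)
#' oracle_argmin("ACGTA", 2, tb)
#' @export
oracle_argmin <- function(x, i, tables) {
  oracle_seed_window(x, tables, t = NULL, orders = i)
}

# brute-force seeds for several orders at once (shared enumeration)
#
# Tie rule among candidates with identical (psi, omega): the
# lexicographically smaller string, comparing symbols in alphabet order;
# with rc-symmetric tables the smaller *canonical* string min(z, rc(z))
# takes priority (a plain lexicographic preference is not strand-symmetric
# and would break the rc seed-set guarantee on exact ties). The reported
# tuple is the lexicographically smallest position tuple spelling the
# winning string (combn enumerates tuples in lexicographic order).
oracle_seed_window <- function(x, tables, t = tables$k, orders = seq_len(t)) {
  n <- nchar(x); k <- tables$k
  if (k > n) stop("window shorter than k", call. = FALSE)
  if (choose(n, k) > ENUM_GUARD)
    stop("choose(", n, ", ", k, ") exceeds the enumeration guard (1e6)",
         call. = FALSE)
  ch <- chars_of(x)
  sym <- encode_symbols(ch, tables$alphabet)
  if (anyNA(sym)) stop("symbol outside the table alphabet", call. = FALSE)
  S <- length(tables$alphabet)
  pos <- utils::combn(n, k)
  Z <- matrix(sym[pos], nrow = ncol(pos), ncol = k, byrow = TRUE)
  strs <- apply(pos, 2, function(p) paste(ch[p], collapse = ""))
  # base-S big-endian codes: numeric order == lex order in alphabet-index
  # terms (exact in doubles as long as S^k < 2^53, enforced by the k cap)
  code <- numeric(nrow(Z))
  for (j in seq_len(k)) code <- code * S + (Z[, j] - 1)
  canon <- code
  if (isTRUE(tables$rc_symmetric)) {
    comp_idx <- match(tables$complement, tables$alphabet)
    rccode <- numeric(nrow(Z))
    for (j in seq_len(k)) rccode <- rccode * S + (comp_idx[Z[, k - j + 1]] - 1)
    canon <- pmin(code, rccode)
  }
  out <- lapply(orders, function(i) {
    sc <- pivot_scores_matrix(Z, i, tables)
    best <- order(sc$psi, -sc$omega, canon, code, method = "radix")[1]
    tibble::tibble(
      order = as.integer(i), seed = strs[best],
      positions = list(as.integer(pos[, best] - 1L)),
      pivot = as.integer(pos[i, best] - 1L),
      psi = sc$psi[best], omega = sc$omega[best]
    )
  })
  dplyr::bind_rows(out)
}
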