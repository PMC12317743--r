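#' @useDynLib subseedr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
NULL

# A-table entries are drawn from [0, 2^40). Scores accumulate at most k+1
# terms with +/-1 multipliers, so |omega| <= (k+1)*2^40; this stays exactly
# representable in a double (< 2^53) for k <= 8190, which is enforced below.
A_RANGE <- 2^40
MAX_K <- 8190

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# draw m integers uniformly from [0, 2^40), exactly, using two 20-bit draws
draw_a_entries <- function(m) {
  hi <- sample.int(2^20, m, replace = TRUE) - 1
  lo <- sample.int(2^20, m, replace = TRUE) - 1
  hi * 2^20 + lo
}

draw_signs <- function(m) sample(c(-1, 1), m, replace = TRUE)

new_abck_tables <- function(fields) {
  structure(fields, class = "abck_tables")
}

check_table_params <- function(k, d, alphabet) {
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || k < 2 || k != floor(k))
    stop("`k` must be a single integer >= 2", call. = FALSE)
  if (k > MAX_K)
    stop("`k` must be <= ", MAX_K, " for exact integer score arithmetic",
         call. = FALSE)
  if (!is.numeric(d) || length(d) != 1 || is.na(d) || d < 1 || d != floor(d))
    stop("`d` must be a single integer >= 1", call. = FALSE)
  if (d > 32)
    warning("`d` = ", d, " exceeds the recommended soft limit of 32",
            call. = FALSE)
  if (!is.character(alphabet) || length(alphabet) < 1 ||
      anyDuplicated(alphabet) || any(nchar(alphabet) != 1))
    stop("`alphabet` must be distinct single characters", call. = FALSE)
  invisible(TRUE)
}

#' Generate a random set of ABCk tables
#'
#' The k orders over length-k strings used for subsequence seeding are
#' defined by nine integer tables: forward tables (`AF`, `BF`, `CF`), reverse
#' tables (`AR`, `BR`, `CR`), and pivot tables (`AP`, `BP`, `CP`). `A` tables
#' hold integers in `[0, 2^40)`, `B` tables hold pairs of signs (stored here
#' as two arrays of +1/-1), and `C` tables hold residues modulo `d`. Entries
#' are drawn independently and uniformly from their ranges; the result is a
#' deterministic function of `rng_seed`.
#'
#' @param k Seed (subsequence) length, an integer >= 2.
#' @param d Modulus for the primary score; also the number of independent
#'   residue lanes in the dynamic program. Values above 32 are allowed but
#'   trigger a warning (soft limit).
#' @param alphabet Character vector of distinct single characters; default
#'   DNA `c("A","C","G","T")`.
#' @param rng_seed Integer seed; identical seeds give entrywise-identical
#'   tables.
#' @return An object of class `abck_tables`: a list with elements `k`, `d`,
#'   `alphabet`, the tensors `AF`, `AR` (`k x d x |alphabet|`), `AP`
#'   (`k x |alphabet|`), sign arrays `BF1`, `BF2`, `BR1`, `BR2`
#'   (`k x d x |alphabet|`), `BP1`, `BP2` (`k x |alphabet|`), residue tables
#'   `CF`, `CR`, `CP` (`k x |alphabet|`), and flags `rc_symmetric`,
#'   `complement`, `rng_seed`.
#' @examples
#' tb <- generate_random_tables(k = 4, d = 3, rng_seed = 1)
#' tb$k
#' @seealso [generate_symmetric_tables()] for the reverse-complement
#'   symmetric construction, [save_tables()] / [load_tables()].
#' @export
generate_random_tables <- function(k, d, alphabet = c("A", "C", "G", "T"),
                                   rng_seed = 1L) {
  check_table_params(k, d, alphabet)
  S <- length(alphabet)
  out <- local_seed(rng_seed, {
    kds <- k * d * S
    ks <- k * S
    list(
      AF = array(draw_a_entries(kds), dim = c(k, d, S)),
      AR = array(draw_a_entries(kds), dim = c(k, d, S)),
      AP = matrix(draw_a_entries(ks), k, S),
      BF1 = array(draw_signs(kds), dim = c(k, d, S)),
      BF2 = array(draw_signs(kds), dim = c(k, d, S)),
      BR1 = array(draw_signs(kds), dim = c(k, d, S)),
      BR2 = array(draw_signs(kds), dim = c(k, d, S)),
      BP1 = matrix(draw_signs(ks), k, S),
      BP2 = matrix(draw_signs(ks), k, S),
      CF = matrix(sample.int(d, ks, replace = TRUE) - 1, k, S),
      CR = matrix(sample.int(d, ks, replace = TRUE) - 1, k, S),
      CP = matrix(sample.int(d, ks, replace = TRUE) - 1, k, S)
    )
  })
  tb <- new_abck_tables(c(
    list(k = as.integer(k), d = as.integer(d), alphabet = alphabet),
    out,
    list(rc_symmetric = FALSE, complement = NULL,
         rng_seed = as.integer(rng_seed))
  ))
  validate_abck_tables(tb)
  tb
}

#' Generate reverse-complement-symmetric ABCk tables
#'
#' Builds tables constrained so that order i applied to a string z gives the
#' same score as order k-i+1 applied to the reverse complement of z. Under
#' this constraint a length-n window and its reverse complement select
#' identical seed sets (the i-th seed of one equals the (k-i+1)-th seed of
#' the other, reverse-complemented), so strand need not be known at seeding
#' time.
#'
#' The construction samples the forward tables and the first half of the
#' pivot tables freely, then fills the mirrored entries: reverse tables
#' mirror forward tables under the complement map, and pivot entries at
#' position k-i+1 for the complement symbol copy (for `B`, with swapped sign
#' components) those at position i.
#'
#' @inheritParams generate_random_tables
#' @param complement_map Named character vector mapping each alphabet symbol
#'   to its complement; must be a fixed-point-free involution (default
#'   Watson-Crick).
#' @return An `abck_tables` object with `rc_symmetric = TRUE`.
#' @examples
#' tb <- generate_symmetric_tables(k = 4, d = 3, rng_seed = 1)
#' tb$rc_symmetric
#' @export
generate_symmetric_tables <- function(k, d, alphabet = c("A", "C", "G", "T"),
                                      complement_map = DNA_COMPLEMENT,
                                      rng_seed = 1L) {
  check_table_params(k, d, alphabet)
  if (!all(sort(names(complement_map)) == sort(alphabet)) ||
      !all(complement_map %in% alphabet))
    stop("`complement_map` must map the alphabet onto itself", call. = FALSE)
  comp_idx <- match(complement_map[alphabet], alphabet)
  if (any(comp_idx == seq_along(alphabet)))
    stop("`complement_map` has a fixed point; symmetric tables require a ",
         "fixed-point-free involution (e.g. A<->T, C<->G)", call. = FALSE)
  if (any(comp_idx[comp_idx] != seq_along(alphabet)))
    stop("`complement_map` must be an involution", call. = FALSE)

  S <- length(alphabet)
  out <- local_seed(rng_seed, {
    kds <- k * d * S
    ks <- k * S
    AF <- array(draw_a_entries(kds), dim = c(k, d, S))
    BF1 <- array(draw_signs(kds), dim = c(k, d, S))
    BF2 <- array(draw_signs(kds), dim = c(k, d, S))
    CF <- matrix(sample.int(d, ks, replace = TRUE) - 1, k, S)
    # reverse tables are the forward tables with the symbol axis permuted by
    # the complement (an involution): AR[l, j, comp(s)] = AF[l, j, s]
    AR <- AF[, , comp_idx, drop = FALSE]
    BR1 <- BF1[, , comp_idx, drop = FALSE]
    BR2 <- BF2[, , comp_idx, drop = FALSE]
    CR <- CF[, comp_idx, drop = FALSE]
    dim(AR) <- dim(BR1) <- dim(BR2) <- c(k, d, S)
    dim(CR) <- c(k, S)

    # pivot tables: AP[k-i+1, comp(s)] = AP[i, s], CP likewise,
    # BP[k-i+1, comp(s)] = swap(BP[i, s])
    AP <- matrix(0, k, S)
    BP1 <- matrix(0, k, S)
    BP2 <- matrix(0, k, S)
    CP <- matrix(0L, k, S)
    half <- ceiling(k / 2)
    for (i in seq_len(half)) {
      im <- k - i + 1L
      if (i < im) {
        AP[i, ] <- draw_a_entries(S)
        BP1[i, ] <- draw_signs(S)
        BP2[i, ] <- draw_signs(S)
        CP[i, ] <- sample.int(d, S, replace = TRUE) - 1
        AP[im, comp_idx] <- AP[i, ]
        CP[im, comp_idx] <- CP[i, ]
        BP1[im, comp_idx] <- BP2[i, ]
        BP2[im, comp_idx] <- BP1[i, ]
      } else {
        # middle position (odd k): one free symbol per complement pair
        reps <- which(seq_len(S) < comp_idx)
        AP[i, reps] <- draw_a_entries(length(reps))
        BP1[i, reps] <- draw_signs(length(reps))
        BP2[i, reps] <- draw_signs(length(reps))
        CP[i, reps] <- sample.int(d, length(reps), replace = TRUE) - 1
        AP[i, comp_idx[reps]] <- AP[i, reps]
        CP[i, comp_idx[reps]] <- CP[i, reps]
        BP1[i, comp_idx[reps]] <- BP2[i, reps]
        BP2[i, comp_idx[reps]] <- BP1[i, reps]
      }
    }
    list(AF = AF, AR = AR, AP = AP, BF1 = BF1, BF2 = BF2, BR1 = BR1,
         BR2 = BR2, BP1 = BP1, BP2 = BP2, CF = CF, CR = CR, CP = CP)
  })
  tb <- new_abck_tables(c(
    list(k = as.integer(k), d = as.integer(d), alphabet = alphabet),
    out,
    list(rc_symmetric = TRUE, complement = complement_map[alphabet],
         rng_seed = as.integer(rng_seed))
  ))
  validate_abck_tables(tb)
  tb
}

#' Validate an ABCk table set
#'
#' Checks dimensions, value ranges (signs in B tables, residues in C tables,
#' bounded A entries) and, for symmetric tables, the entrywise mirror
#' constraints. Called by the generators and by [load_tables()].
#'
#' @param tables An `abck_tables` object.
#' @return The tables, invisibly; errors name the offending field.
#' @export
validate_abck_tables <- function(tables) {
  if (!inherits(tables, "abck_tables")) stop("not an `abck_tables` object")
  k <- tables$k; d <- tables$d; S <- length(tables$alphabet)
  dim3 <- c(k, d, S); dim2 <- c(k, S)
  chk_dim <- function(nm, want) {
    x <- tables[[nm]]
    got <- if (is.matrix(x)) dim(x) else dim(x)
    if (is.null(got) || length(got) != length(want) || !all(got == want))
      stop("table `", nm, "` has wrong shape", call. = FALSE)
  }
  for (nm in c("AF", "AR", "BF1", "BF2", "BR1", "BR2")) chk_dim(nm, dim3)
  for (nm in c("AP", "BP1", "BP2", "CF", "CR", "CP")) chk_dim(nm, dim2)
  for (nm in c("AF", "AR", "AP")) {
    x <- tables[[nm]]
    if (any(x < 0 | x >= A_RANGE | x != floor(x)))
      stop("table `", nm, "` has entries outside [0, 2^40)", call. = FALSE)
  }
  for (nm in c("BF1", "BF2", "BR1", "BR2", "BP1", "BP2")) {
    if (!all(tables[[nm]] %in% c(-1, 1)))
      stop("table `", nm, "` has entries other than +1/-1", call. = FALSE)
  }
  for (nm in c("CF", "CR", "CP")) {
    x <- tables[[nm]]
    if (any(x < 0 | x >= d | x != floor(x)))
      stop("table `", nm, "` has entries outside [0, d)", call. = FALSE)
  }
  if (isTRUE(tables$rc_symmetric)) {
    comp_idx <- match(tables$complement, tables$alphabet)
    rev_i <- rev(seq_len(k))
    ok <- all(tables$AR[, , comp_idx] == tables$AF) &&
      all(tables$BR1[, , comp_idx] == tables$BF1) &&
      all(tables$BR2[, , comp_idx] == tables$BF2) &&
      all(tables$CR[, comp_idx] == tables$CF) &&
      all(tables$AP[rev_i, comp_idx] == tables$AP) &&
      all(tables$CP[rev_i, comp_idx] == tables$CP) &&
      all(tables$BP1[rev_i, comp_idx] == tables$BP2) &&
      all(tables$BP2[rev_i, comp_idx] == tables$BP1)
    if (!ok)
      stop("rc_symmetric is set but the mirror constraints do not hold",
           call. = FALSE)
  }
  invisible(tables)
}

#' @export
print.abck_tables <- function(x, ...) {
  cat("ABCk order tables\n")
  cat("  k =", x$k, " d =", x$d,
      " alphabet =", paste(x$alphabet, collapse = ""), "\n")
  cat("  rc_symmetric =", x$rc_symmetric, " rng_seed =", x$rng_seed, "\n")
  invisible(x)
}

#' Save / load ABCk tables
#'
#' Tables are serialized as self-describing JSON: a header with `k`, `d`,
#' the alphabet, mode and seed, plus the flattened integer arrays
#' (column-major). The round trip is entrywise lossless. Loading validates
#' every invariant and rejects malformed files with an error naming the
#' offending field; `d > 32` is accepted with a warning (soft limit).
#'
#' @param tables An `abck_tables` object.
#' @param path File path.
#' @return `save_tables()` returns `path` invisibly; `load_tables()` returns
#'   the reconstructed `abck_tables` object.
#' @examples
#' tb <- generate_random_tables(4, 3, rng_seed = 7)
#' f <- tempfile(fileext = ".json")
#' save_tables(tb, f)
#' tb2 <- load_tables(f)
#' identical(tb$AF, tb2$AF)
#' @export
save_tables <- function(tables, path) {
  validate_abck_tables(tables)
  arrs <- c("AF", "AR", "AP", "BF1", "BF2", "BR1", "BR2", "BP1", "BP2",
            "CF", "CR", "CP")
  payload <- list(
    format = "subseedr-abck-tables",
    version = 1L,
    k = tables$k, d = tables$d, alphabet = tables$alphabet,
    rc_symmetric = tables$rc_symmetric,
    complement = as.list(tables$complement),
    rng_seed = tables$rng_seed
  )
  for (nm in arrs) payload[[nm]] <- as.vector(tables[[nm]])
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_tables
#' @export
load_tables <- function(path) {
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                      error = function(e)
                        stop("cannot parse table file: ", conditionMessage(e),
                             call. = FALSE))
  if (!identical(payload$format, "subseedr-abck-tables"))
    stop("table file format: missing or wrong `format` field", call. = FALSE)
  for (nm in c("k", "d", "alphabet"))
    if (is.null(payload[[nm]]))
      stop("table file format: missing field `", nm, "`", call. = FALSE)
  k <- as.integer(payload$k); d <- as.integer(payload$d)
  S <- length(payload$alphabet)
  if (d > 32)
    warning("loaded tables have d = ", d,
            " above the recommended soft limit of 32", call. = FALSE)
  shape <- function(nm, dm) {
    x <- payload[[nm]]
    if (is.null(x) || length(x) != prod(dm))
      stop("table file format: field `", nm, "` missing or wrong length",
           call. = FALSE)
    array(as.numeric(x), dim = dm)
  }
  fields <- list(k = k, d = d, alphabet = as.character(payload$alphabet))
  for (nm in c("AF", "AR", "BF1", "BF2", "BR1", "BR2"))
    fields[[nm]] <- shape(nm, c(k, d, S))
  for (nm in c("AP", "BP1", "BP2", "CF", "CR", "CP"))
    fields[[nm]] <- matrix(shape(nm, c(k, S)), k, S)
  comp <- unlist(payload$complement)
  fields$rc_symmetric <- isTRUE(payload$rc_symmetric)
  fields$complement <- if (length(comp)) comp else NULL
  fields$rng_seed <- as.integer(payload$rng_seed %||% NA_integer_)
  tb <- new_abck_tables(fields)
  validate_abck_tables(tb)
  tb
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate expr with a locally seeded RNG, restoring global state afterwards
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}
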