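# Independent reference implementations used as test oracles. These are
# written directly from the score definitions / textbook DPs and share no
# code with the package internals.

ALPH <- c("A", "C", "G", "T")

rand_dna <- function(n) paste(sample(ALPH, n, replace = TRUE), collapse = "")

# direct recursive evaluation of the part-score recurrence
ref_part_score <- function(s, A, B1, B2, C, d) {
  sym <- match(strsplit(s, "")[[1]], ALPH)
  rec <- function(l) {
    if (l == 0) return(c(psi = 0, omega = 0))
    prev <- rec(l - 1)
    psi <- (prev[["psi"]] + C[l, sym[l]]) %% d
    omega <- prev[["omega"]] * B1[l, psi + 1, sym[l]] +
      A[l, psi + 1, sym[l]] * B2[l, psi + 1, sym[l]]
    c(psi = psi, omega = omega)
  }
  rec(length(sym))
}

ref_pivot_score <- function(z, i, tb) {
  zc <- strsplit(z, "")[[1]]
  k <- tb$k
  rev_part <- paste(rev(zc[seq_len(i - 1)]), collapse = "")
  fwd_part <- paste(zc[seq_len(k - i) + i], collapse = "")
  rv <- ref_part_score(rev_part, tb$AR, tb$BR1, tb$BR2, tb$CR, tb$d)
  fv <- ref_part_score(fwd_part, tb$AF, tb$BF1, tb$BF2, tb$CF, tb$d)
  p <- match(zc[i], ALPH)
  c(psi = (rv[["psi"]] + tb$CP[i, p] + fv[["psi"]]) %% tb$d,
    omega = rv[["omega"]] * tb$BP1[i, p] + tb$AP[i, p] +
      fv[["omega"]] * tb$BP2[i, p])
}

# textbook Levenshtein DP
ref_edit_distance <- function(x, y) {
  a <- strsplit(x, "")[[1]]
  b <- strsplit(y, "")[[1]]
  prev <- 0:length(b)
  for (i in seq_along(a)) {
    cur <- c(i, numeric(length(b)))
    for (j in seq_along(b)) {
      cur[j + 1] <- min(prev[j + 1] + 1, cur[j] + 1,
                        prev[j] + (a[i] != b[j]))
    }
    prev <- cur
  }
  prev[length(b) + 1]
}

# textbook longest-common-subsequence DP
ref_lcs_length <- function(x, y) {
  a <- strsplit(x, "")[[1]]
  b <- strsplit(y, "")[[1]]
  prev <- numeric(length(b) + 1)
  for (i in seq_along(a)) {
    cur <- numeric(length(b) + 1)
    for (j in seq_along(b)) {
      cur[j + 1] <- if (a[i] == b[j]) prev[j] + 1 else max(prev[j + 1], cur[j])
    }
    prev <- cur
  }
  prev[length(b) + 1]
}

# shared fixture tables (small, deterministic)
tb_plain_64 <- generate_random_tables(k = 6, d = 4, rng_seed = 100)
tb_sym_64 <- generate_symmetric_tables(k = 6, d = 4, rng_seed = 100)

expect_seed_records_equal <- function(a, b) {
  expect_equal(a$seed, b$seed)
  expect_equal(a$psi, b$psi)
  expect_equal(a$omega, b$omega)
  expect_equal(a$pivot, b$pivot)
  expect_equal(a$positions, b$positions)
}
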