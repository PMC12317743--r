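test_that("empty and single-character part scores follow the base case", {
  tb <- tb_plain_64
  for (f in list(score_forward, score_reverse)) {
    s <- f("", tb)
    expect_equal(s$psi, 0)
    expect_equal(s$omega, 0)
  }
  # one unrolling from the zero base
  for (ch in ALPH) {
    s <- score_forward(ch, tb)
    sym <- match(ch, ALPH)
    psi <- tb$CF[1, sym] %% tb$d
    expect_equal(s$psi, psi)
    expect_equal(s$omega, tb$AF[1, psi + 1, sym] * tb$BF2[1, psi + 1, sym])
  }
})

test_that("part and pivot scores match an independent recursive evaluation", {
  set.seed(11)
  for (r in 1:500) {
    k <- sample(3:8, 1)
    d <- sample(1:6, 1)
    tb <- generate_random_tables(k, d, rng_seed = r)
    s <- rand_dna(sample(0:(k - 1), 1))
    ref <- ref_part_score(s, tb$AF, tb$BF1, tb$BF2, tb$CF, d)
    got <- score_forward(s, tb)
    expect_equal(got$psi, unname(ref[["psi"]]))
    expect_equal(got$omega, unname(ref[["omega"]]))
    refr <- ref_part_score(s, tb$AR, tb$BR1, tb$BR2, tb$CR, d)
    gotr <- score_reverse(s, tb)
    expect_equal(gotr$omega, unname(refr[["omega"]]))

    z <- rand_dna(k)
    i <- sample(k, 1)
    refp <- ref_pivot_score(z, i, tb)
    gotp <- pivot_score(z, i, tb)
    expect_equal(gotp$psi, unname(refp[["psi"]]))
    expect_equal(gotp$omega, unname(refp[["omega"]]))
  }
})

test_that("with rc-symmetric tables, reverse scores are forward scores of the complement", {
  tb <- tb_sym_64
  comp <- tb$complement
  set.seed(5)
  for (r in 1:50) {
    s <- rand_dna(sample(1:4, 1))
    sc <- paste(unname(comp[strsplit(s, "")[[1]]]), collapse = "")
    a <- score_forward(s, tb)
    b <- score_reverse(sc, tb)
    expect_equal(a$psi, b$psi)
    expect_equal(a$omega, b$omega)
  }
})

test_that("pivot edge cases reduce to a single part plus pivot entry", {
  tb <- tb_plain_64
  z <- "ACGTAC"
  k <- 6
  # i = k: forward part empty
  sk <- pivot_score(z, k, tb)
  rv <- score_reverse(paste(rev(strsplit(z, "")[[1]][1:(k - 1)]),
                            collapse = ""), tb)
  p <- match(substr(z, k, k), ALPH)
  expect_equal(sk$psi, (rv$psi + tb$CP[k, p]) %% tb$d)
  expect_equal(sk$omega, rv$omega * tb$BP1[k, p] + tb$AP[k, p])
  # i = 1: reverse part empty
  s1 <- pivot_score(z, 1, tb)
  fv <- score_forward(substr(z, 2, k), tb)
  p1 <- match(substr(z, 1, 1), ALPH)
  expect_equal(s1$psi, (tb$CP[1, p1] + fv$psi) %% tb$d)
  expect_equal(s1$omega, tb$AP[1, p1] + fv$omega * tb$BP2[1, p1])
})

test_that("score comparison ranks by psi then larger omega and is consistent", {
  mk <- function(psi, omega) structure(list(psi = psi, omega = omega, d = 5),
                                       class = "seed_score")
  expect_equal(compare_scores(mk(0, 5), mk(1, 1e9)), -1L)
  expect_equal(compare_scores(mk(2, 7), mk(2, 3)), -1L)
  expect_equal(compare_scores(mk(3, 4), mk(3, 4)), 0L)
  expect_error(compare_scores(mk(0, 0), structure(
    list(psi = 0, omega = 0, d = 7), class = "seed_score")), "moduli")

  set.seed(2)
  for (r in 1:200) {
    trio <- replicate(3, mk(sample(0:2, 1), sample(-5:5, 1)),
                      simplify = FALSE)
    ab <- compare_scores(trio[[1]], trio[[2]])
    ba <- compare_scores(trio[[2]], trio[[1]])
    expect_equal(ab, -ba) # antisymmetry
    bc <- compare_scores(trio[[2]], trio[[3]])
    ac <- compare_scores(trio[[1]], trio[[3]])
    if (ab <= 0 && bc <= 0) expect_lte(ac, 0) # transitivity
  }
})

test_that("subsequence enumeration yields distinct strings with lex-min witnesses", {
  e <- enumerate_subsequences("AAAA", 2)
  expect_equal(e$seed, "AA")
  expect_equal(e$positions[[1]], c(0L, 1L))

  e2 <- enumerate_subsequences("ACGT", 4)
  expect_equal(e2$seed, "ACGT")

  e3 <- enumerate_subsequences("ACGT", 2)
  expect_equal(nrow(e3), 6L) # all C(4,2) pairs distinct

  e4 <- enumerate_subsequences("ABAB", 2)
  expect_equal(sort(e4$seed), c("AA", "AB", "BA", "BB"))
  expect_equal(e4$positions[[match("AB", e4$seed)]], c(0L, 1L))
})

test_that("jaccard similarity of subsequence sets matches set enumeration", {
  expect_equal(jaccard_subsequences("ACGTAC", "ACGTAC", 4), 1)
  expect_equal(jaccard_subsequences("AAAA", "CCCC", 2), 0)
  # independent set computation straight from position tuples
  brute <- function(x, y, k) {
    subs <- function(s) {
      ch <- strsplit(s, "")[[1]]
      unique(apply(combn(length(ch), k), 2,
                   function(p) paste(ch[p], collapse = "")))
    }
    sx <- subs(x); sy <- subs(y)
    length(intersect(sx, sy)) / length(union(sx, sy))
  }
  expect_equal(jaccard_subsequences("ACGTAC", "ACGGAC", 4),
               brute("ACGTAC", "ACGGAC", 4))
  set.seed(8)
  for (r in 1:10) {
    x <- rand_dna(9); y <- rand_dna(9)
    expect_equal(jaccard_subsequences(x, y, 5), brute(x, y, 5))
  }
})

test_that("similar strings share long subsequences; shared seeds bound edit distance", {
  set.seed(13)
  # guarantee: edit distance e implies a common subsequence of length >= n-e
  for (r in 1:40) {
    n <- sample(8:14, 1)
    e <- sample(0:4, 1)
    pr <- random_pair_with_edit_distance(n, e, rng_seed = r)
    expect_gte(ref_lcs_length(pr$x, pr$y), n - e)
  }
  # converse: a shared length-k subsequence implies edit distance <= 2(n-k)
  for (r in 1:40) {
    n <- 10
    k <- sample(5:9, 1)
    x <- rand_dna(n); y <- rand_dna(n)
    if (jaccard_subsequences(x, y, k) > 0)
      expect_lte(ref_edit_distance(x, y), 2 * (n - k))
  }
})

test_that("the enumeration guard triggers for oversized inputs", {
  expect_error(enumerate_subsequences(strrep("ACGT", 20), 40), "guard")
})

test_that("oracle argmin is trivial on singleton sets and rc-consistent", {
  tb <- tb_plain_64
  for (i in 1:6) {
    o <- oracle_argmin("ACGTAC", i, tb)
    expect_equal(o$seed, "ACGTAC")
    expect_equal(o$positions[[1]], 0:5)
  }
  tbs <- tb_sym_64
  set.seed(21)
  for (r in 1:25) {
    x <- rand_dna(10)
    i <- sample(6, 1)
    a <- oracle_argmin(x, i, tbs)
    b <- oracle_argmin(reverse_complement(x), 6 - i + 1, tbs)
    expect_equal(a$seed, reverse_complement(b$seed))
  }
})
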