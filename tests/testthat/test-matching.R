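# compact constructor for hand-built seed records
mk_seeds <- function(id, window, order, seed, positions) {
  tibble::tibble(id = id, window = as.integer(window),
                 order = as.integer(order), seed = seed,
                 positions = positions,
                 pivot = vapply(positions, function(p) p[1], integer(1)),
                 psi = 0, omega = 0)
}

test_that("a sequence matched against itself matches every seed identically", {
  tb <- tb_plain_64
  set.seed(30)
  x <- rand_dna(30)
  s <- seed_sequences(c(a = x), tb, n = 10)
  m <- collect_matches(s, s)
  # every record matches itself (plus any genuine duplicate seeds)
  self <- dplyr::filter(m, .data$window_a == .data$window_b)
  expect_equal(nrow(self), nrow(s))
  expect_true(all(mapply(identical, self$pos_a, self$pos_b)))
})

test_that("equal strings under different order indices do not match", {
  a <- mk_seeds("x", 0, 1, "ACGT", list(0:3))
  b <- mk_seeds("y", 0, 2, "ACGT", list(0:3))
  expect_equal(nrow(collect_matches(a, b)), 0L)
  b2 <- mk_seeds("y", 0, 1, "ACGT", list(0:3))
  expect_equal(nrow(collect_matches(a, b2)), 1L)
})

test_that("mixing canonical and plain seed sets is refused", {
  plain <- mk_seeds("x", 0, 1, "ACGT", list(0:3))
  rc <- canonicalize_rc(
    seed_sequences(c(y = "ACGTACGTAC"), tb_sym_64, n = 10), tb_sym_64)
  expect_error(collect_matches(plain, rc), "canonical")
})

test_that("matches between mutated copies equal a quadratic double loop", {
  tb <- tb_plain_64
  set.seed(31)
  x <- rand_dna(80)
  mut <- mutate_sequence(x, 0.08, rng_seed = 7)
  sa <- seed_sequences(c(a = x), tb, n = 12, t = 3)
  sb <- seed_sequences(c(b = mut$y), tb, n = 12, t = 3)
  m <- collect_matches(sa, sb)
  # oracle: all record pairs with equal (order, seed)
  brute <- 0L
  for (i in seq_len(nrow(sa)))
    for (j in seq_len(nrow(sb)))
      if (sa$order[i] == sb$order[j] && sa$seed[i] == sb$seed[j])
        brute <- brute + 1L
  expect_equal(nrow(m), brute)
  # absolute positions line up with the window offsets
  r <- which(m$window_a == min(m$window_a))[1]
  rec <- sa[sa$window == m$window_a[r] & sa$order == m$order[r], ]
  expect_equal(m$pos_a[[r]], rec$positions[[1]] + rec$window)
})

test_that("labels use the strict majority rule on aligned pairs", {
  truth <- tibble::tibble(pos_a = 0:9, pos_b = 0:9)
  m_all <- tibble::tibble(pos_a = list(0:5), pos_b = list(0:5))
  expect_true(label_matches(m_all, truth)$true)
  # exactly half (k even) is NOT enough
  m_half <- tibble::tibble(pos_a = list(c(0:2, 20:22)),
                           pos_b = list(c(0:2, 20:22)))
  expect_false(label_matches(m_half, truth)$true)
  # floor(k/2) + 1 correct pairs is enough
  m_maj <- tibble::tibble(pos_a = list(c(0:3, 20, 21)),
                          pos_b = list(c(0:3, 20, 21)))
  expect_true(label_matches(m_maj, truth)$true)
  # empty truth labels everything false
  expect_false(label_matches(m_all,
                             tibble::tibble(pos_a = integer(),
                                            pos_b = integer()))$true)
})

test_that("precision is the true fraction and missing when no matches", {
  m <- tibble::tibble(true = c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(match_precision(m), 0.75)
  expect_equal(match_precision(m[m$true, ]), 1)
  expect_equal(match_precision(m[0, ]), NA_real_)
})

test_that("segment sensitivity counts 200 bp segments with a true match", {
  # a 1000 bp read has exactly 5 segments
  mk <- function(starts, true = TRUE)
    tibble::tibble(pos_a = lapply(starts, function(s) s + 0:5),
                   pos_b = lapply(starts, function(s) s + 0:5),
                   true = true)
  all5 <- mk(c(10, 250, 450, 650, 850))
  expect_equal(segment_sensitivity(all5, 1000), 1.0)
  three <- mk(c(10, 450, 850))
  expect_equal(segment_sensitivity(three, 1000), 0.6)
  expect_equal(segment_sensitivity(mk(c(10), true = FALSE), 1000), 0)
  # final partial segment: counted iff >= 100 bp
  expect_equal(segment_sensitivity(all5, 1120), 5 / 6) # 120 bp tail counts
  expect_equal(segment_sensitivity(all5, 1080), 5 / 5) # 80 bp tail dropped
  # a true match in a dropped tail is ignored
  tail_only <- mk(c(1010))
  expect_equal(segment_sensitivity(tail_only, 1080), 0)
})

test_that("coverage is an interval union over match spans", {
  none <- tibble::tibble(pos_a = list(), pos_b = list(),
                         true = logical())
  expect_equal(unlist(match_coverage(none, 100)),
               c(true_coverage = 0, false_coverage = 0))
  one <- tibble::tibble(pos_a = list(10:15), pos_b = list(0:5), true = TRUE)
  expect_equal(match_coverage(one, 100)$true_coverage, 6 / 100)
  # overlapping spans count once; duplication is idempotent
  two <- tibble::tibble(pos_a = list(10:19, 15:24, 10:19),
                        pos_b = list(0:9, 0:9, 0:9),
                        true = TRUE)
  expect_equal(match_coverage(two, 100)$true_coverage, 15 / 100)
  mixed <- tibble::tibble(pos_a = list(0:9, 50:59), pos_b = list(0:9, 0:9),
                          true = c(TRUE, FALSE))
  cv <- match_coverage(mixed, 100)
  expect_equal(cv$true_coverage, 0.1)
  expect_equal(cv$false_coverage, 0.1)
})

test_that("adding a true match never decreases sensitivity metrics", {
  base <- tibble::tibble(pos_a = list(10:15), pos_b = list(10:15),
                         true = TRUE)
  more <- dplyr::bind_rows(base,
                           tibble::tibble(pos_a = list(300:305),
                                          pos_b = list(300:305), true = TRUE))
  expect_gte(segment_sensitivity(more, 1000), segment_sensitivity(base, 1000))
  expect_gte(match_coverage(more, 1000)$true_coverage,
             match_coverage(base, 1000)$true_coverage)
})

test_that("overlap detection agrees with hand-built fixtures", {
  # duplicate reads: shared seeds and a true overlap
  seeds <- dplyr::bind_rows(
    mk_seeds("r1", 0, 1, "ACGTAC", list(0:5)),
    mk_seeds("r2", 0, 1, "ACGTAC", list(0:5)),
    mk_seeds("r3", 0, 1, "GGGTTT", list(0:5)))
  reads <- tibble::tibble(id = c("r1", "r2", "r3"),
                          start = c(0, 0, 500), end = c(100, 100, 600))
  res <- detect_overlaps(seeds, reads)
  expect_equal(res$pairs$id_a, "r1")
  expect_equal(res$pairs$id_b, "r2")
  expect_true(res$pairs$true)
  expect_equal(res$sensitivity, 1)
  expect_equal(res$precision, 1)
  expect_equal(glance(res)$n_reported, 1L)

  # 14 bp of interval overlap is below the 15 bp truth threshold
  reads14 <- tibble::tibble(id = c("a", "b"), start = c(0, 86),
                            end = c(100, 200))
  s14 <- dplyr::bind_rows(mk_seeds("a", 0, 1, "AAAAAA", list(0:5)),
                          mk_seeds("b", 0, 1, "AAAAAA", list(0:5)))
  r14 <- detect_overlaps(s14, reads14)
  expect_equal(r14$n_truth, 0L)
  expect_equal(r14$precision, 0)
  reads15 <- tibble::tibble(id = c("a", "b"), start = c(0, 85),
                            end = c(100, 200))
  expect_equal(detect_overlaps(s14, reads15)$n_truth, 1L)
})

test_that("overlap detection matches a quadratic oracle on a synthetic read set", {
  tb <- tb_plain_64
  rs <- make_overlap_readset(ref_length = 1500, n_reads = 60,
                             read_length = c(80, 140), rate = 0.03,
                             rng_seed = 41)
  seeds <- seed_sequences(rs$reads[c("id", "seq")], tb, n = 12, t = 2)
  res <- detect_overlaps(seeds, rs$reads)

  ids <- rs$reads$id
  key_sets <- lapply(ids, function(i) {
    s <- seeds[seeds$id == i, ]
    unique(paste(s$order, s$seed))
  })
  names(key_sets) <- ids
  brute_cand <- character(0)
  brute_truth <- character(0)
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (ids[i] >= ids[j]) next
      pair <- paste(ids[i], ids[j])
      if (length(intersect(key_sets[[i]], key_sets[[j]])) > 0)
        brute_cand <- c(brute_cand, pair)
      ov <- min(rs$reads$end[i], rs$reads$end[j]) -
        max(rs$reads$start[i], rs$reads$start[j])
      if (ov >= 15) brute_truth <- c(brute_truth, pair)
    }
  }
  expect_equal(sort(paste(res$pairs$id_a, res$pairs$id_b)), sort(brute_cand))
  expect_equal(res$n_truth, length(brute_truth))
  n_correct <- length(intersect(brute_cand, brute_truth))
  expect_equal(res$sensitivity, n_correct / length(brute_truth))
  expect_equal(res$precision, n_correct / length(brute_cand))
})

test_that("baseline seeders emit all k-mers and hashed window minima", {
  x <- c(r = "ACGTACGTTGCA")
  ak <- seed_kmers(x, 4)
  expect_equal(nrow(ak), 12 - 4 + 1)
  expect_equal(ak$seed[1], "ACGT")
  expect_equal(ak$positions[[1]], 0:3)

  mn <- seed_minimizers(x, n = 8, k = 4, hash_seed = 5)
  expect_equal(nrow(mn), 12 - 8 + 1)
  # minimizers are a subset of the k-mer seed set (string at position)
  akk <- paste(ak$window, ak$seed)
  mnk <- paste(mn$window + vapply(mn$positions, min, integer(1)), mn$seed)
  expect_true(all(mnk %in% akk))
  # each reported minimizer attains the window minimum of the same hash
  codes <- subseedr:::kmer_codes(as.character(x), 4)
  ab <- subseedr:::local_seed(5L, c(sample.int(2^20, 1) * 2 + 1,
                                    sample.int(2^20, 1)))
  h <- (ab[1] * codes + ab[2]) %% (2^31 - 1)
  for (r in seq_len(nrow(mn))) {
    w <- mn$window[r]
    off <- min(mn$positions[[r]])
    expect_equal(h[w + off + 1], min(h[(w + 1):(w + 8 - 4 + 1)]))
  }
  # different hash seeds give different orders somewhere
  mn2 <- seed_minimizers(x, n = 8, k = 4, hash_seed = 6)
  expect_true(is.data.frame(mn2))
})
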