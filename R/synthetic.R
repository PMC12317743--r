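# ---- simulators -----------------------------------------------------------

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

#' Random string pair with a prescribed edit distance
#'
#' Generates a random length-n string and a copy carrying `e` edits at
#' distinct positions (substitutions plus balanced insertion/deletion pairs,
#' so both strings have length n), then verifies the realized Levenshtein
#' distance with a standard edit-distance routine and resamples until it is
#' exactly `e`.
#'
#' @param n String length.
#' @param e Target edit distance, `0 <= e <= n`.
#' @param alphabet Symbol set (default DNA).
#' @param rng_seed Integer seed; the pair is a deterministic function of it.
#' @param max_tries Resampling cap before giving up.
#' @return A list with elements `x`, `y` (strings) and `e`.
#' @export
random_pair_with_edit_distance <- function(n, e,
                                           alphabet = c("A", "C", "G", "T"),
                                           rng_seed = 1L, max_tries = 1000L) {
  if (e < 0 || e > n) stop("need 0 <= e <= n", call. = FALSE)
  local_seed(rng_seed, {
    for (try in seq_len(max_tries)) {
      x <- random_dna(n, alphabet)
      if (e == 0) return(list(x = x, y = x, e = 0L))
      ch <- chars_of(x)
      # balanced indels keep |y| = n; remaining edits are substitutions
      n_indel <- if (e >= 2) sample(0:(e %/% 2), 1) else 0L
      n_sub <- e - 2 * n_indel
      pos <- sample.int(n, n_sub + 2 * n_indel)
      y <- ch
      if (n_sub > 0) {
        for (p in pos[seq_len(n_sub)]) {
          y[p] <- sample(setdiff(alphabet, ch[p]), 1)
        }
      }
      if (n_indel > 0) {
        del <- sort(pos[n_sub + seq_len(n_indel)])
        y <- y[-del]
        ins_at <- sample.int(length(y) + 1, n_indel, replace = TRUE)
        for (j in seq_len(n_indel)) {
          at <- ins_at[j]
          y <- append(y, sample(alphabet, 1), after = at - 1)
        }
      }
      ystr <- paste(y, collapse = "")
      if (utils::adist(x, ystr) == e) return(list(x = x, y = ystr, e = as.integer(e)))
    }
    stop("could not realize edit distance ", e, " after ", max_tries,
         " attempts", call. = FALSE)
  })
}

#' Mutate a sequence under a per-position error model
#'
#' At each position of `x`, independently with probability `rate`, applies
#' an edit that is a substitution, insertion, or deletion with probability
#' `rate/3` each. Substituted positions remain aligned pairs in the emitted
#' truth alignment; inserted characters (placed before the current position)
#' are unaligned in `y`; deleted positions of `x` are unaligned.
#'
#' @param x Input string.
#' @param rate Per-position error rate in `[0, 1)`.
#' @param alphabet Symbol set.
#' @param rng_seed Integer seed.
#' @return A list with `y` (mutated string), `truth` (tibble of 0-based
#'   aligned position pairs `pos_a` on `x`, `pos_b` on `y`), and `n_edits`.
#' @export
mutate_sequence <- function(x, rate, alphabet = c("A", "C", "G", "T"),
                            rng_seed = 1L) {
  if (rate < 0 || rate >= 1) stop("need 0 <= rate < 1", call. = FALSE)
  ch <- chars_of(x)
  n <- length(ch)
  local_seed(rng_seed, {
    u <- stats::runif(n)
    # 0 = keep, 1 = substitution, 2 = insertion, 3 = deletion
    act <- ifelse(u >= rate, 0L,
                  ifelse(u < rate / 3, 1L, ifelse(u < 2 * rate / 3, 2L, 3L)))
    out_chars <- character(0)
    pos_a <- integer(0)
    pos_b <- integer(0)
    ylen <- 0L
    for (i in seq_len(n)) {
      a <- act[i]
      if (a == 2L) { # insertion before position i; x_i itself is kept
        out_chars <- c(out_chars, sample(alphabet, 1), ch[i])
        ylen <- ylen + 2L
        pos_a <- c(pos_a, i - 1L)
        pos_b <- c(pos_b, ylen - 1L)
      } else if (a == 3L) { # deletion
      } else if (a == 1L) { # substitution: aligned, different character
        out_chars <- c(out_chars, sample(setdiff(alphabet, ch[i]), 1))
        ylen <- ylen + 1L
        pos_a <- c(pos_a, i - 1L)
        pos_b <- c(pos_b, ylen - 1L)
      } else {
        out_chars <- c(out_chars, ch[i])
        ylen <- ylen + 1L
        pos_a <- c(pos_a, i - 1L)
        pos_b <- c(pos_b, ylen - 1L)
      }
    }
    list(
      y = paste(out_chars, collapse = ""),
      truth = tibble::tibble(pos_a = pos_a, pos_b = pos_b),
      n_edits = sum(act != 0L)
    )
  })
}

#' Simulate a read set for overlap detection
#'
#' Draws a random reference of length `ref_length`, extracts `n_reads`
#' intervals with lengths uniform in `read_length`, mutates each extract
#' under the per-position error model, and assigns each read a random
#' strand (reverse-complementing the mutated extract when minus). The
#' source intervals are recorded so ground-truth overlapping pairs can be
#' computed.
#'
#' @param ref_length Reference length in bp.
#' @param n_reads Number of reads.
#' @param read_length Length-2 numeric range (or single value) for read
#'   lengths.
#' @param rate Per-position error rate.
#' @param rng_seed Integer seed.
#' @return A list with `reference` (string) and `reads`: a tibble with
#'   columns `id`, `seq`, `start`, `end` (0-based, end-exclusive source
#'   interval), `strand`.
#' @export
make_overlap_readset <- function(ref_length, n_reads,
                                 read_length = c(200, 400), rate = 0.05,
                                 rng_seed = 1L) {
  if (length(read_length) == 1) read_length <- rep(read_length, 2)
  local_seed(rng_seed, {
    reference <- random_dna(ref_length)
    lens <- sample(read_length[1]:read_length[2], n_reads, replace = TRUE)
    starts <- vapply(lens, function(L) sample.int(ref_length - L + 1, 1) - 1L,
                     integer(1))
    strands <- sample(c("+", "-"), n_reads, replace = TRUE)
    seeds <- sample.int(.Machine$integer.max, n_reads)
    seqs <- character(n_reads)
    for (r in seq_len(n_reads)) {
      frag <- substr(reference, starts[r] + 1, starts[r] + lens[r])
      mut <- mutate_sequence(frag, rate, rng_seed = seeds[r])
      seqs[r] <- if (strands[r] == "-") reverse_complement(mut$y) else mut$y
    }
    list(
      reference = reference,
      reads = tibble::tibble(
        id = sprintf("read%04d", seq_len(n_reads)),
        seq = seqs,
        start = as.integer(starts),
        end = as.integer(starts + lens),
        strand = strands
      )
    )
  })
}

# ---- collision probability -----------------------------------------------

#' Estimate seed hash-collision probability by edit-distance category
#'
#' Simulates string pairs binned by exact edit distance and, for each
#' category, estimates the probability that two length-n strings produce at
#' least one identical seed. A pair collides at repeat budget `t` when any
#' of the first `t` orders yields the same seed string for both strings
#' (each string is treated as a single window). With one order the
#' probability approximates the subsequence Jaccard similarity; with `t`
#' orders it is boosted toward `1 - (1 - p)^t` when the orders behave
#' independently.
#'
#' @param tables An `abck_tables` object (defines n via the `n` argument,
#'   k and d).
#' @param n Window (string) length.
#' @param categories Integer vector of edit distances to simulate.
#' @param t_values Repeat budgets to report (each in `1..k`).
#' @param n_pairs Pairs per category (desk-scale default 2000).
#' @param rng_seed Integer seed.
#' @return An object of class `collision_estimate`: a list with `estimates`
#'   (tibble `e`, `t`, `p_hat`, `n_pairs`), `per_order` (tibble `e`,
#'   `order`, `p_hat` for single-order collisions), and the parameters.
#' @export
estimate_collision_probability <- function(tables, n,
                                           categories = 1:10,
                                           t_values = c(1, 10, tables$k),
                                           n_pairs = 2000L,
                                           rng_seed = 1L) {
  k <- tables$k
  t_values <- unique(pmin(pmax(as.integer(t_values), 1L), k))
  tmax <- max(t_values)
  pair_seeds <- local_seed(rng_seed, {
    matrix(sample.int(.Machine$integer.max, length(categories) * n_pairs),
           nrow = n_pairs)
  })
  # bypass the tibble-building path: seed strings only, straight from the DP
  fast_seeds <- function(x) {
    sym <- match(chars_of(x), tables$alphabet) - 1L
    cpp_seed_sequence(sym, n, tmax, tables$k, tables$d,
                      as.numeric(tables$AF), as.numeric(tables$BF1),
                      as.numeric(tables$BF2), as.integer(tables$CF),
                      as.numeric(tables$AR), as.numeric(tables$BR1),
                      as.numeric(tables$BR2), as.integer(tables$CR),
                      as.numeric(tables$AP), as.numeric(tables$BP1),
                      as.numeric(tables$BP2), as.integer(tables$CP),
                      tables$alphabet)$seed
  }
  est <- list(); per_order <- list()
  for (ci in seq_along(categories)) {
    e <- categories[ci]
    # collide[p, i] : do the pair's seeds under order i agree?
    collide <- matrix(FALSE, n_pairs, tmax)
    for (p in seq_len(n_pairs)) {
      pr <- random_pair_with_edit_distance(n, e, tables$alphabet,
                                           rng_seed = pair_seeds[p, ci])
      collide[p, ] <- fast_seeds(pr$x) == fast_seeds(pr$y)
    }
    any_first <- function(tt) rowSums(collide[, seq_len(tt), drop = FALSE]) > 0
    est[[ci]] <- tibble::tibble(
      e = as.integer(e), t = t_values,
      p_hat = vapply(t_values, function(tt) mean(any_first(tt)), numeric(1)),
      n_pairs = as.integer(n_pairs)
    )
    per_order[[ci]] <- tibble::tibble(
      e = as.integer(e), order = seq_len(tmax), p_hat = colMeans(collide)
    )
  }
  structure(list(
    estimates = dplyr::bind_rows(est),
    per_order = dplyr::bind_rows(per_order),
    n = n, k = k, d = tables$d, t_values = t_values,
    n_pairs = as.integer(n_pairs), rng_seed = as.integer(rng_seed)
  ), class = "collision_estimate")
}

#' Collision probability of repeated seeding with independent tables
#'
#' The reference repetition scheme: `t` independently generated table sets,
#' each contributing its first-order seed; a pair collides when any of the
#' `t` runs produces the same seed for both strings. The multi-order scheme
#' aims to reproduce this probability with a single table set, so comparing
#' the two estimates measures how independently the k joint orders behave.
#'
#' @param k,d Table parameters for each independent set.
#' @param n Window (string) length.
#' @param t Number of independent table sets.
#' @param categories Integer vector of edit distances.
#' @param n_pairs Pairs per category.
#' @param rng_seed Integer seed (drives both table generation and pairs).
#' @return A `collision_estimate` whose `estimates` hold the pooled
#'   probability at repeat budget `t`.
#' @export
estimate_collision_independent <- function(k, d, n, t,
                                           categories = 1:10,
                                           n_pairs = 2000L,
                                           rng_seed = 1L) {
  seeds <- local_seed(rng_seed, sample.int(.Machine$integer.max, t + 1))
  tabs <- lapply(seq_len(t),
                 function(i) generate_random_tables(k, d, rng_seed = seeds[i]))
  targs <- lapply(tabs, function(tb) {
    list(as.numeric(tb$AF), as.numeric(tb$BF1), as.numeric(tb$BF2),
         as.integer(tb$CF), as.numeric(tb$AR), as.numeric(tb$BR1),
         as.numeric(tb$BR2), as.integer(tb$CR), as.numeric(tb$AP),
         as.numeric(tb$BP1), as.numeric(tb$BP2), as.integer(tb$CP))
  })
  alphabet <- tabs[[1]]$alphabet
  first_seed <- function(x, a) {
    sym <- match(chars_of(x), alphabet) - 1L
    do.call(cpp_seed_sequence,
            c(list(sym, n, 1L, as.integer(k), as.integer(d)), a,
              list(alphabet)))$seed
  }
  pair_seeds <- local_seed(seeds[t + 1], {
    matrix(sample.int(.Machine$integer.max, length(categories) * n_pairs),
           nrow = n_pairs)
  })
  est <- list()
  for (ci in seq_along(categories)) {
    e <- categories[ci]
    hit <- logical(n_pairs)
    for (p in seq_len(n_pairs)) {
      pr <- random_pair_with_edit_distance(n, e, alphabet,
                                           rng_seed = pair_seeds[p, ci])
      for (a in targs) {
        if (first_seed(pr$x, a) == first_seed(pr$y, a)) {
          hit[p] <- TRUE
          break
        }
      }
    }
    est[[ci]] <- tibble::tibble(e = as.integer(e), t = as.integer(t),
                                p_hat = mean(hit),
                                n_pairs = as.integer(n_pairs))
  }
  structure(list(
    estimates = dplyr::bind_rows(est),
    per_order = NULL,
    n = n, k = as.integer(k), d = as.integer(d), t_values = as.integer(t),
    n_pairs = as.integer(n_pairs), rng_seed = as.integer(rng_seed)
  ), class = "collision_estimate")
}

#' @export
print.collision_estimate <- function(x, ...) {
  cat("seed collision probability estimates (n =", x$n, ", k =", x$k,
      ", d =", x$d, ",", x$n_pairs, "pairs/category)\n")
  print(tidyr::pivot_wider(x$estimates, id_cols = "e",
                           names_from = "t", values_from = "p_hat",
                           names_prefix = "t="), n = Inf)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' Tidiers for collision estimates
#'
#' `tidy()` returns one row per (edit-distance category, repeat budget) with
#' the estimated collision probability and its binomial standard error;
#' `glance()` summarizes the experiment.
#'
#' @param x A `collision_estimate`.
#' @param ... Unused.
#' @method tidy collision_estimate
#' @export
tidy.collision_estimate <- function(x, ...) {
  dplyr::mutate(x$estimates,
                std_error = sqrt(.data$p_hat * (1 - .data$p_hat) /
                                   .data$n_pairs))
}

#' @rdname tidy.collision_estimate
#' @method glance collision_estimate
#' @export
glance.collision_estimate <- function(x, ...) {
  tibble::tibble(n = x$n, k = x$k, d = x$d,
                 n_categories = length(unique(x$estimates$e)),
                 n_pairs = x$n_pairs, rng_seed = x$rng_seed)
}

#' Plot collision probability against edit distance
#'
#' One curve per repeat budget t, mirroring the standard way
#' locality-sensitive seeding schemes are characterized.
#'
#' @param object A `collision_estimate`.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @method autoplot collision_estimate
#' @export
autoplot.collision_estimate <- function(object, ...) {
  ggplot2::ggplot(object$estimates,
                  ggplot2::aes(x = .data$e, y = .data$p_hat,
                               colour = factor(.data$t))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "edit distance", y = "P(at least one seed collision)",
                  colour = "t",
                  title = sprintf("n = %d, k = %d, d = %d",
                                  object$n, object$k, object$d)) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @export
ggplot2::autoplot
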