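# Shared fixtures and independent oracles, built in code.

# Pool from a named count specification, e.g. make_pool(ANTI = 13, PRO = 7).
make_pool <- function(..., id = "pool1") {
  counts <- c(...)
  response_pool(id, rep(names(counts), counts))
}

# A tiny deterministic two-platform corpus with all three evaluation
# categories; n messages per stratum, pool size N.
tiny_profile <- function(n = 4L, N = 10L, seed = 11L) {
  strata <- list()
  for (pf in c("facebook", "twitter")) {
    for (lab in c("ANTI", "PRO", "NEU")) {
      alpha <- stats::setNames(rep(0.3, 5), sentiment_labels())
      alpha[lab] <- 2.5
      strata[[length(strata) + 1L]] <-
        list(platform = pf, label = lab, n = n, alpha = alpha)
    }
  }
  generator_profile("tiny", strata, pool_size = N, seed = seed)
}

tiny_corpus <- function(n = 4L, N = 10L, seed = 11L) {
  generate_corpus(tiny_profile(n, N, seed))
}

# Sequence-level brute-force oracle for the machine-decision distribution:
# enumerates every label sequence of length m (5^m of them), weights by the
# i.i.d. draw probability under p = counts/N, and applies the same
# plurality-with-pool-proportional-tie rule analytically. Independent of the
# composition-based implementation in the package.
brute_force_distribution <- function(pool, m) {
  labels <- sentiment_labels()
  p <- pool$counts / pool$n
  grid <- as.matrix(expand.grid(rep(list(seq_len(5L)), m)))
  out <- stats::setNames(numeric(5L), labels)
  for (r in seq_len(nrow(grid))) {
    seq_labels <- grid[r, ]
    prob <- prod(p[seq_labels])
    if (prob == 0) next
    counts <- tabulate(seq_labels, nbins = 5L)
    tied <- which(counts == max(counts))
    if (length(tied) == 1L) {
      out[tied] <- out[tied] + prob
    } else {
      w <- pool$counts[tied]
      out[tied] <- out[tied] + prob * w / sum(w)
    }
  }
  out
}

# Random pool with between 2 and 5 labels present, N <= 20.
random_pool <- function(id = "rp") {
  k <- sample(2:5, 1L)
  labs <- sample(sentiment_labels(), k)
  n <- sample(5:20, 1L)
  counts <- as.vector(stats::rmultinom(1L, n - k, rep(1 / k, k))) + 1L
  response_pool(id, rep(labs, counts))
}
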