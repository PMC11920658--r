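test_that("sample_instances draws uniformly with replacement from the pool", {
  all_anti <- make_pool(ANTI = 4)
  set.seed(1)
  expect_identical(sample_instances(all_anti, 5L), rep("ANTI", 5L))

  # same seed -> same draw
  half <- make_pool(ANTI = 10, PRO = 10)
  d1 <- withr::with_seed(9, sample_instances(half, 50L))
  d2 <- withr::with_seed(9, sample_instances(half, 50L))
  expect_identical(d1, d2)

  # binomial sampling bound: ANTI fraction ~ 0.5 at 3 SE for m = 10000
  frac <- mean(withr::with_seed(4, sample_instances(half, 10000L)) == "ANTI")
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("plurality_decision returns the mode and breaks ties pool-proportionally", {
  pool <- make_pool(ANTI = 10, PRO = 10)
  expect_identical(plurality_decision(c("ANTI", "PRO", "ANTI"), pool), "ANTI")
  expect_identical(plurality_decision(rep("ANTI", 5), pool), "ANTI")

  # symmetric tie -> each side wins about half the time
  wins <- withr::with_seed(21, vapply(1:2000, function(i)
    plurality_decision(c("ANTI", "PRO"), pool), character(1)))
  expect_lt(abs(mean(wins == "ANTI") - 0.5), 3 * sqrt(0.25 / 2000))

  # asymmetric pool: tie between ANTI and PRO broken 15:5
  pool2 <- make_pool(ANTI = 15, PRO = 5)
  wins2 <- withr::with_seed(22, vapply(1:2000, function(i)
    plurality_decision(c("ANTI", "PRO"), pool2), character(1)))
  expect_lt(abs(mean(wins2 == "ANTI") - 0.75), 3 * sqrt(0.1875 / 2000))
})

test_that("monte_carlo_accuracy hits closed forms and is order-deterministic", {
  spec <- decision_spec(3L, iterations = 10000L, seed = 77L)
  expect_equal(monte_carlo_accuracy(make_pool(NEU = 20), "NEU", spec)$accuracy, 1)
  expect_equal(monte_carlo_accuracy(make_pool(NEU = 20), "ANTI", spec)$accuracy, 0)

  # 13/7 two-label pool, m = 3: P(win) = 3 p^2 (1-p) + p^3 at p = 0.65
  a_true <- 3 * 0.65^2 * 0.35 + 0.65^3
  mc <- monte_carlo_accuracy(make_pool(ANTI = 13, PRO = 7), "ANTI", spec)
  expect_lt(abs(mc$accuracy - a_true), 3 * sqrt(a_true * (1 - a_true) / 10000))

  # substream depends only on (seed, message id, m): repeated calls agree
  mc2 <- monte_carlo_accuracy(make_pool(ANTI = 13, PRO = 7), "ANTI", spec)
  expect_identical(mc$accuracy, mc2$accuracy)
})

test_that("decision_distribution matches hand-computable cases", {
  # normalization on an arbitrary pool and m
  d <- decision_distribution(make_pool(ANTI = 7, NEU = 6, IR = 4, MIX = 3), 9L)
  expect_equal(sum(d), 1, tolerance = 1e-12)

  # 10/10 pool, m = 2: 0.25 + 0.25 outright, 0.5 tie mass split evenly
  d2 <- decision_distribution(make_pool(ANTI = 10, PRO = 10), 2L)
  expect_equal(unname(d2), c(0.5, 0.5, 0, 0, 0), tolerance = 1e-12)

  # 13/7, m = 3 closed form
  d3 <- decision_distribution(make_pool(ANTI = 13, PRO = 7), 3L)
  expect_equal(unname(d3[["ANTI"]]), 0.71825, tolerance = 1e-12)
})

test_that("decision_distribution equals the sequence-level brute-force oracle", {
  set.seed(501)
  for (rep in 1:60) {
    pool <- random_pool()
    m <- sample(1:5, 1L)
    expect_equal(decision_distribution(pool, m),
                 brute_force_distribution(pool, m), tolerance = 1e-10)
  }
})

test_that("exact_accuracy obeys K_1 identity, asymptotic mode selection, and symmetry", {
  set.seed(77)
  for (rep in 1:25) {
    pool <- random_pool()
    h <- sample(sentiment_labels(), 1L)
    expect_equal(exact_accuracy(pool, h, 1L)$accuracy,
                 unname(pool$counts[h] / pool$n), tolerance = 1e-12)
  }
  expect_equal(exact_accuracy(make_pool(MIX = 6), "MIX", 4L)$accuracy, 1)
  expect_equal(exact_accuracy(make_pool(ANTI = 10, PRO = 10), "PRO", 2L)$accuracy,
               0.5, tolerance = 1e-12)
  # unique mode -> accuracy tends to 1 as m grows; at odd m with two labels
  # the exact value is the binomial tail P(X > m/2), X ~ Bin(m, 13/20)
  expect_equal(exact_accuracy(make_pool(ANTI = 13, PRO = 7), "ANTI", 51L)$accuracy,
               1 - pbinom(25, 51, 0.65), tolerance = 1e-12)
  expect_gte(exact_accuracy(make_pool(ANTI = 13, PRO = 7), "ANTI", 151L)$accuracy,
             0.999)
})

test_that("Monte Carlo converges to the enumeration oracle across random pools", {
  set.seed(88)
  pools <- replicate(12, random_pool(), simplify = FALSE)
  for (pool in pools) {
    h <- sample(names(pool$counts)[pool$counts > 0], 1L)
    for (m in c(2L, 3L, 5L)) {
      a <- exact_accuracy(pool, h, m)$accuracy
      spec <- decision_spec(m, iterations = 4000L, seed = 99L)
      mc <- monte_carlo_accuracy(pool, h, spec)$accuracy
      expect_lt(abs(mc - a), 3 * sqrt(a * (1 - a) / 4000) + 1e-9)
    }
  }
})

test_that("full_pool_decision is the whole-pool plurality with proportional ties", {
  expect_identical(full_pool_decision(make_pool(ANTI = 12, NEU = 8)), "ANTI")
  expect_identical(full_pool_decision(make_pool(IR = 5)), "IR")
  wins <- withr::with_seed(5, vapply(1:2000, function(i)
    full_pool_decision(make_pool(ANTI = 10, PRO = 10)), character(1)))
  expect_lt(abs(mean(wins == "ANTI") - 0.5), 3 * sqrt(0.25 / 2000))
})

test_that("corpus_accuracy and corpus_decisions are invariant to message order", {
  bundle <- tiny_corpus(n = 3L, N = 10L)
  rev_bundle <- corpus_bundle(bundle$messages[rev(seq_len(nrow(bundle$messages))), ],
                              bundle$pools)
  a1 <- corpus_accuracy(bundle, 3L, iterations = 200L, seed = 13L)
  a2 <- corpus_accuracy(rev_bundle, 3L, iterations = 200L, seed = 13L)
  a2 <- a2[match(a1$message_id, a2$message_id), ]
  expect_equal(a1$accuracy, a2$accuracy)

  d1 <- corpus_decisions(bundle, 3L, seed = 13L)
  d2 <- corpus_decisions(rev_bundle, 3L, seed = 13L)
  expect_identical(d1[sort(names(d1))], d2[sort(names(d2))])
})
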