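test_that("aggregate_K computes mean and across-message SE", {
  acc <- data.frame(m = 3L, accuracy = c(1, 0, 1, 0))
  s <- aggregate_K(acc, "facebook", "ANTI")
  expect_equal(s$k_m, 0.5)
  expect_equal(s$se, sqrt(1 / 3) / 2, tolerance = 1e-12)  # sd/sqrt(n), n-1 denom
  expect_equal(s$n, 4L)

  s2 <- aggregate_K(data.frame(m = 5L, accuracy = rep(0.7, 10)), "twitter", "ALL")
  expect_equal(s2$k_m, 0.7)
  expect_equal(s2$se, 0)

  expect_error(aggregate_K(data.frame(m = c(1L, 3L), accuracy = c(0.5, 0.5))),
               class = "pluralvote_mixed_m")
  # list-of-message_accuracy input also works
  s3 <- aggregate_K(list(exact_accuracy(make_pool(ANTI = 13, PRO = 7), "ANTI", 1L),
                         exact_accuracy(make_pool(ANTI = 5, PRO = 15), "ANTI", 1L)))
  expect_equal(s3$k_m, mean(c(13 / 20, 5 / 20)))
})

test_that("ratio_to_reference is a guarded percentage", {
  base <- aggregate_K(data.frame(m = 20L, accuracy = c(0.5, 0.5)), "facebook", "ANTI")
  half <- aggregate_K(data.frame(m = 1L, accuracy = c(0.25, 0.25)), "facebook", "ANTI")
  expect_equal(ratio_to_reference(base, base), 100)
  expect_equal(ratio_to_reference(half, base), 50)
  zero <- aggregate_K(data.frame(m = 20L, accuracy = c(0, 0)), "facebook", "ANTI")
  expect_error(ratio_to_reference(half, zero), class = "pluralvote_zero_reference")
  other <- aggregate_K(data.frame(m = 20L, accuracy = c(0.5, 0.5)), "twitter", "ANTI")
  expect_error(ratio_to_reference(half, other), class = "pluralvote_schema_error")
})

test_that("confusion_table counts human x machine decisions with correct marginals", {
  bundle <- tiny_corpus(n = 3L, N = 10L)
  ids <- bundle$messages$message_id
  # perfect decisions -> diagonal
  perfect <- stats::setNames(bundle$messages$human_label, ids)
  ct <- confusion_table(bundle, perfect, "facebook")
  expect_equal(sum(diag(ct$counts)), sum(bundle$messages$platform == "facebook"))
  expect_equal(sum(ct$counts) - sum(diag(ct$counts)), 0L)

  # row marginals equal category sizes and survive permutation
  real <- corpus_decisions(bundle, 3L, seed = 2L)
  ct2 <- confusion_table(bundle, real, "facebook")
  expect_equal(unname(ct2$row_marginals[c("ANTI", "PRO", "NEU")]),
               rep(3L, 3))
  perm <- sample(ids)
  ct3 <- confusion_table(bundle, real[perm], "facebook")
  expect_equal(ct3$counts, ct2$counts)

  expect_error(confusion_table(bundle, real[-1], "facebook"),
               class = "pluralvote_missing_decision")
})

test_that("misclassification_flows reproduces printed contingency arithmetic", {
  # weaker-model ANTI row: 151 correct, 30 NEU / 13 IR / 6 PRO wrong
  ct <- pluralvote:::confusion_from_row(
    "ANTI", c(ANTI = 151, NEU = 30, IR = 13, PRO = 6))
  fl <- misclassification_flows(ct, "ANTI")
  expect_equal(fl$rate, 100 * 49 / 200)
  expect_equal(fl$flows[["NEU"]], 100 * 30 / 49)
  expect_equal(fl$flows[["IR"]], 100 * 13 / 49)
  expect_equal(fl$flows[["PRO"]], 100 * 6 / 49)
  expect_equal(sum(fl$flows), 100, tolerance = 1e-9)

  # diagonal row -> zero rate, no flows
  ct0 <- pluralvote:::confusion_from_row("PRO", c(PRO = 50))
  fl0 <- misclassification_flows(ct0, "PRO")
  expect_equal(fl0$rate, 0)
  expect_length(fl0$flows, 0)

  expect_error(misclassification_flows(ct0, "NEU"),
               class = "pluralvote_empty_category")
})

test_that("mann_whitney_u matches hand enumeration, identities, and wilcox.test", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$u_statistic, 0)

  r2 <- mann_whitney_u(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(r2$u_statistic, 16 / 2)

  set.seed(10)
  a <- runif(15); b <- runif(12)
  ra <- mann_whitney_u(a, b); rb <- mann_whitney_u(b, a)
  expect_equal(ra$u_statistic + rb$u_statistic, 15 * 12)
  # independent reference: stats::wilcox.test reports the same U and its
  # normal-approximation p with continuity correction
  w <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(ra$u_statistic, unname(w$statistic))
  expect_equal(ra$p_value, w$p.value, tolerance = 1e-10)

  # tied data: midranks + tie-corrected variance, still matches wilcox.test
  at <- c(0, 0, 1, 1, 1, 0.5); bt <- c(0, 1, 1, 0.5, 0.5)
  rt <- mann_whitney_u(at, bt)
  wt <- stats::wilcox.test(at, bt, exact = FALSE, correct = TRUE)
  expect_equal(rt$u_statistic, unname(wt$statistic))
  expect_equal(rt$p_value, wt$p.value, tolerance = 1e-10)

  # degenerate pooled sample: flagged, p = 1
  rd <- mann_whitney_u(rep(1, 5), rep(1, 4))
  expect_true(rd$degenerate)
  expect_equal(rd$p_value, 1)

  expect_error(mann_whitney_u(1, c(1, 2)),
               class = "pluralvote_degenerate_samples")

  # p-value invariant under a common monotone transform
  r_raw <- mann_whitney_u(a, b)
  r_tr <- mann_whitney_u(exp(3 * a), exp(3 * b))
  expect_equal(r_raw$p_value, r_tr$p_value)
  expect_equal(r_raw$u_statistic, r_tr$u_statistic)
})

test_that("summarize_corpus lays out platform x category x m with reference ratios", {
  bundle <- tiny_corpus(n = 3L, N = 10L)
  res <- summarize_corpus(bundle, m_values = c(1L, 3L, 5L), method = "exact")
  expect_equal(nrow(res$summary), 2 * 4 * 3)  # platforms x (3 cats + ALL) x m
  ref_rows <- res$summary[res$summary$m == 5L, ]
  expect_true(all(is.na(ref_rows$ratio_to_ref)))
  non_ref <- res$summary[res$summary$m != 5L, ]
  expect_true(all(is.finite(non_ref$ratio_to_ref)))

  # aggregate at m=1 equals mean pool share of the human label (exact method)
  fb_anti <- res$summary[res$summary$platform == "facebook" &
                           res$summary$category == "ANTI" & res$summary$m == 1L, ]
  ids <- bundle$messages$message_id[bundle$messages$platform == "facebook" &
                                      bundle$messages$human_label == "ANTI"]
  shares <- vapply(bundle$pools[ids], function(p) p$counts[["ANTI"]] / p$n, 0)
  expect_equal(fb_anti$k_m, mean(shares), tolerance = 1e-12)
})

test_that("compare_categories produces all pairwise tests and flags degeneracy", {
  bundle <- tiny_corpus(n = 3L, N = 10L)
  res <- summarize_corpus(bundle, m_values = c(1L, 3L), method = "exact")
  cmp <- compare_categories(res$per_message)
  expect_equal(nrow(cmp), 2 * 2 * 3)  # platforms x m x pairs
  expect_true(all(cmp$u >= 0 & cmp$u <= 9))
  expect_true(all(cmp$p >= 0 & cmp$p <= 1))
})
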