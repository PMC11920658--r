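# Aggregation of per-message accuracies into K_m summaries, confusion and
# misclassification-flow tables, and between-category rank tests.

#' Aggregate per-message accuracies into a K_m summary
#'
#' `k_m` is the arithmetic mean of per-message accuracies; `se` is the
#' standard error of that mean across messages (sample standard deviation,
#' n - 1 denominator, divided by sqrt(n)). The SE is across messages, not
#' across Monte Carlo iterations: it describes how variable per-message
#' accuracy is within the category.
#'
#' @param per_message Either a list of `message_accuracy` objects or a data
#'   frame with columns `m` and `accuracy` (as from [corpus_accuracy()]). All
#'   entries must share one `m`.
#' @param platform Platform tag for the output row.
#' @param category Category tag (`"ANTI"`, `"PRO"`, `"NEU"`, ... or `"ALL"`).
#' @return One-row data frame: `platform`, `category`, `m`, `n`, `k_m`, `se`,
#'   `ratio_to_ref` (NA; filled by [ratio_to_reference()] or
#'   [summarize_corpus()]).
#' @export
aggregate_K <- function(per_message, platform = "all", category = "ALL") {
  if (!is.data.frame(per_message)) {
    per_message <- data.frame(
      m = vapply(per_message, `[[`, 0L, "m"),
      accuracy = vapply(per_message, `[[`, 0, "accuracy"))
  }
  n <- nrow(per_message)
  if (n < 1L) {
    stop_pluralvote("need at least one per-message accuracy",
                    class = "pluralvote_schema_error")
  }
  if (length(unique(per_message$m)) != 1L) {
    stop_pluralvote("per-message accuracies mix different m values",
                    class = "pluralvote_mixed_m")
  }
  a <- per_message$accuracy
  data.frame(platform = platform, category = category,
             m = per_message$m[[1]], n = n, k_m = mean(a),
             se = if (n >= 2L) stats::sd(a) / sqrt(n) else NA_real_,
             ratio_to_ref = NA_real_, stringsAsFactors = FALSE)
}

#' Percentage ratio of a K_m to its large-m reference
#'
#' @param summary_m,summary_ref One-row summaries from [aggregate_K()] for the
#'   same platform and category; `summary_ref` is the reference (largest m).
#' @return `100 * k_m / k_ref`.
#' @export
ratio_to_reference <- function(summary_m, summary_ref) {
  if (!identical(summary_m$platform, summary_ref$platform) ||
      !identical(summary_m$category, summary_ref$category)) {
    stop_pluralvote("summaries compare different platform/category cells",
                    class = "pluralvote_schema_error")
  }
  if (summary_ref$k_m == 0) {
    stop_pluralvote("reference accuracy is zero",
                    class = "pluralvote_zero_reference")
  }
  100 * summary_m$k_m / summary_ref$k_m
}

#' Human x machine confusion table
#'
#' @param bundle A [corpus_bundle()].
#' @param decisions Named character vector mapping message id to machine
#'   decision (e.g. from [corpus_decisions()]); every message of the selected
#'   platform must have one.
#' @param platform Platform to tabulate, or `"all"`.
#' @param m The m at which decisions were taken (metadata only).
#' @return An object of class `confusion_table` with a 5x5 `counts` matrix
#'   (rows = human label, columns = machine decision) and row marginals.
#' @export
confusion_table <- function(bundle, decisions, platform = "all", m = NA) {
  stopifnot(inherits(bundle, "corpus_bundle"))
  msgs <- bundle$messages
  if (!identical(platform, "all")) msgs <- msgs[msgs$platform == platform, ]
  missing_ids <- setdiff(msgs$message_id, names(decisions))
  if (length(missing_ids)) {
    stop_pluralvote(sprintf("missing decisions for %d message(s)",
                            length(missing_ids)),
                    class = "pluralvote_missing_decision")
  }
  counts <- matrix(0L, 5L, 5L,
                   dimnames = list(human = sentiment_labels(),
                                   machine = sentiment_labels()))
  if (nrow(msgs)) {
    tab <- table(factor(msgs$human_label, sentiment_labels()),
                 factor(decisions[msgs$message_id], sentiment_labels()))
    counts <- counts + unclass(tab)
  }
  structure(list(platform = platform, m = m, counts = counts,
                 row_marginals = rowSums(counts)),
            class = "confusion_table")
}

# Build a confusion_table directly from one known row of counts; handy for
# worked examples where only a single human category's breakdown is given.
confusion_from_row <- function(human_label, machine_counts,
                               platform = "all", m = NA) {
  assert_label(human_label)
  counts <- matrix(0L, 5L, 5L,
                   dimnames = list(human = sentiment_labels(),
                                   machine = sentiment_labels()))
  counts[human_label, names(machine_counts)] <- as.integer(machine_counts)
  structure(list(platform = platform, m = m, counts = counts,
                 row_marginals = rowSums(counts)),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  cat(sprintf("<confusion_table platform=%s m=%s>\n", x$platform, x$m))
  print(x$counts)
  invisible(x)
}

#' Misclassification rate and flow shares for one human category
#'
#' For the given human-label row of a confusion table: the misclassification
#' rate is the percentage of that category's messages whose machine decision
#' differs from the human label; each flow share is the percentage of those
#' misclassified messages that went to a particular wrong label. Shares sum
#' to 100 whenever any misclassification exists.
#'
#' @param table A `confusion_table`.
#' @param category Human label of the row to analyse.
#' @return List with `rate` (percent), `flows` (named percent vector over
#'   wrong labels with positive counts; empty when rate is 0), `n_total`,
#'   `n_misclassified`.
#' @export
misclassification_flows <- function(table, category) {
  stopifnot(inherits(table, "confusion_table"))
  assert_label(category)
  row <- table$counts[category, ]
  total <- sum(row)
  if (total == 0L) {
    stop_pluralvote(sprintf("no messages with human label %s", category),
                    class = "pluralvote_empty_category")
  }
  wrong <- row[setdiff(sentiment_labels(), category)]
  n_mis <- sum(wrong)
  rate <- 100 * n_mis / total
  flows <- if (n_mis > 0L) 100 * wrong[wrong > 0L] / n_mis else numeric(0)
  list(rate = rate, flows = flows, n_total = total, n_misclassified = n_mis)
}

#' Mann-Whitney U rank test between two accuracy samples
#'
#' U is computed from rank sums with midranks for ties; the two-sided p-value
#' uses the normal approximation with tie-corrected variance and a continuity
#' correction. `u_statistic` is reported for `sample_a`; swapping the samples
#' gives the complement `n1*n2 - U`.
#'
#' @param sample_a,sample_b Numeric vectors (e.g. per-message accuracies of
#'   two sentiment categories), each of length >= 2.
#' @return List of class `rank_test_result`: `u_statistic`, `n1`, `n2`,
#'   `z_value`, `p_value`, `degenerate` (TRUE when all pooled values are
#'   identical, in which case p = 1 is returned and flagged).
#' @export
mann_whitney_u <- function(sample_a, sample_b) {
  n1 <- length(sample_a); n2 <- length(sample_b)
  if (n1 < 2L || n2 < 2L) {
    stop_pluralvote("both samples need at least 2 observations",
                    class = "pluralvote_degenerate_samples")
  }
  pooled <- c(sample_a, sample_b)
  r <- rank(pooled)  # midranks
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  nn <- n1 + n2
  ties <- table(pooled)
  degenerate <- length(ties) == 1L
  mu <- n1 * n2 / 2
  tie_term <- sum(ties^3 - ties) / (nn * (nn - 1))
  sigma2 <- n1 * n2 / 12 * ((nn + 1) - tie_term)
  if (degenerate || sigma2 <= 0) {
    z <- 0; p <- 1
  } else {
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
    if (u == mu) z <- 0
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  structure(list(u_statistic = u, n1 = n1, n2 = n2, z_value = z,
                 p_value = p, degenerate = degenerate),
            class = "rank_test_result")
}

#' @export
print.rank_test_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %.1f (n1=%d, n2=%d), z = %.3f, p = %.4g%s\n",
              x$u_statistic, x$n1, x$n2, x$z_value, x$p_value,
              if (x$degenerate) " [degenerate: all values identical]" else ""))
  invisible(x)
}

#' Full K_m summary table for a corpus
#'
#' Computes per-message accuracies at every requested `m` and aggregates them
#' per (platform, category in ANTI/PRO/NEU/ALL), with the ratio column
#' referenced to the largest `m`.
#'
#' @param bundle A [corpus_bundle()].
#' @param m_values Integer vector of m values; the largest is the reference.
#' @param method,iterations,seed Passed to [corpus_accuracy()].
#' @return List with `summary` (data frame, one row per platform x category x
#'   m) and `per_message` (data frame of all per-message accuracies).
#' @export
summarize_corpus <- function(bundle, m_values = c(1L, 3L, 5L, 7L, 9L, 11L, 20L),
                             method = c("monte_carlo", "exact"),
                             iterations = 1000L, seed = 1L) {
  method <- match.arg(method)
  stopifnot(length(m_values) >= 1L, all(m_values >= 1L))
  m_values <- sort(unique(as.integer(m_values)))
  per_message <- do.call(rbind, lapply(m_values, function(m) {
    corpus_accuracy(bundle, m, method = method,
                    iterations = iterations, seed = seed)
  }))
  platforms <- unique(bundle$messages$platform)
  cats <- intersect(sentiment_labels(), unique(bundle$messages$human_label))
  rows <- list()
  for (pf in platforms) {
    for (cat_ in c(cats, "ALL")) {
      sel <- per_message$platform == pf &
        (cat_ == "ALL" | per_message$human_label == cat_)
      ref <- aggregate_K(per_message[sel & per_message$m == max(m_values), ],
                         pf, cat_)
      for (m in m_values) {
        s <- aggregate_K(per_message[sel & per_message$m == m, ], pf, cat_)
        s$ratio_to_ref <- if (m == max(m_values)) NA_real_
                          else ratio_to_reference(s, ref)
        rows[[length(rows) + 1L]] <- s
      }
    }
  }
  list(summary = do.call(rbind, rows), per_message = per_message)
}

#' Pairwise between-category rank tests
#'
#' Mann-Whitney U tests on per-message accuracies for every pair of human
#' categories, per platform and per m.
#'
#' @param per_message Data frame from [corpus_accuracy()] /
#'   [summarize_corpus()]`$per_message`.
#' @return Data frame: `platform`, `category_a`, `category_b`, `m`, `u`, `z`,
#'   `p`, `degenerate`.
#' @export
compare_categories <- function(per_message) {
  cats <- intersect(sentiment_labels(), unique(per_message$human_label))
  if (length(cats) < 2L) {
    stop_pluralvote("need at least two categories to compare",
                    class = "pluralvote_schema_error")
  }
  rows <- list()
  for (pf in unique(per_message$platform)) {
    for (m in sort(unique(per_message$m))) {
      for (i in seq_len(length(cats) - 1L)) for (j in seq((i + 1L), length(cats))) {
        a <- per_message$accuracy[per_message$platform == pf &
                                    per_message$m == m &
                                    per_message$human_label == cats[i]]
        b <- per_message$accuracy[per_message$platform == pf &
                                    per_message$m == m &
                                    per_message$human_label == cats[j]]
        if (length(a) < 2L || length(b) < 2L) {
          stop_pluralvote(sprintf("category with < 2 messages on %s", pf),
                          class = "pluralvote_degenerate_samples")
        }
        res <- mann_whitney_u(a, b)
        rows[[length(rows) + 1L]] <-
          data.frame(platform = pf, category_a = cats[i], category_b = cats[j],
                     m = m, u = res$u_statistic, z = res$z_value,
                     p = res$p_value, degenerate = res$degenerate,
                     stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
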