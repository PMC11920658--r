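# Core decision engine: plurality machine decisions over m response
# instances resampled with replacement from a pool of N, with tie-breaking by
# extra pool draws; Monte Carlo concurrence accuracy and an exact
# enumeration counterpart.
#
# "Majority" is implemented as plurality (the modal label): with five
# categories an absolute majority often does not exist, yet every resampling
# round must yield a decision. Ties at the maximal count are broken by
# drawing single extra instances uniformly from the full pool until one lands
# in the tied set — which is equivalent to picking among the tied labels with
# probability proportional to their pool counts, the form used throughout
# because it also has a closed form for the exact enumeration.

#' Decision protocol specification
#'
#' @param m Number of response instances resampled per decision (>= 1).
#' @param iterations Monte Carlo iterations per message. Default 1000.
#' @param seed Integer seed. Each (message, m) pair derives an independent
#'   substream from it, so message order never changes any result.
#' @param tie_policy Fixed to `"pool_proportional"`: ties are resolved by
#'   extra pool draws, i.e. proportionally to the tied labels' pool counts.
#' @return An object of class `decision_spec`.
#' @export
decision_spec <- function(m, iterations = 1000L, seed = 1L,
                          tie_policy = "pool_proportional") {
  stopifnot(m >= 1L, iterations >= 1L)
  tie_policy <- match.arg(tie_policy)
  structure(list(m = as.integer(m), iterations = as.integer(iterations),
                 seed = as.integer(seed), tie_policy = tie_policy),
            class = "decision_spec")
}

#' Resample m instances from a pool
#'
#' Draws `m` labels i.i.d. uniformly over the pool's N instances, with
#' replacement, using the current RNG state.
#'
#' @param pool A [response_pool()].
#' @param m Number of draws (>= 1).
#' @return Character vector of `m` labels.
#' @export
sample_instances <- function(pool, m) {
  stopifnot(inherits(pool, "response_pool"), m >= 1L)
  pool$instances[sample.int(pool$n, m, replace = TRUE)]
}

# Resolve a tie among `tied` labels by pool-proportional choice (equivalent
# to redrawing single pool instances until one hits the tied set).
break_tie <- function(tied, pool) {
  if (length(tied) == 1L) return(tied)
  w <- pool$counts[tied]
  if (sum(w) == 0) w <- rep(1, length(tied))  # unreachable in normal use
  sample(tied, 1L, prob = w)
}

#' Plurality decision over sampled labels
#'
#' Returns the label with the maximal count among `sampled_labels`; a tie at
#' the maximum is broken by extra draws from the pool (see [decision_spec()]).
#'
#' @param sampled_labels Non-empty character vector of labels.
#' @param pool The [response_pool()] the labels were resampled from (used only
#'   for tie-breaking).
#' @return A single label.
#' @export
plurality_decision <- function(sampled_labels, pool) {
  stopifnot(length(sampled_labels) >= 1L)
  counts <- label_counts(sampled_labels)
  tied <- names(counts)[counts == max(counts)]
  break_tie(tied, pool)
}

# One realized machine decision for each of `iterations` resampling rounds.
# Count-equivalent to sample_instances + plurality_decision: the multinomial
# draw is the tally of m uniform-with-replacement pool draws.
simulate_decisions <- function(pool, m, iterations, seed = NULL) {
  run <- function() {
    p <- pool$counts / pool$n
    cnts <- stats::rmultinom(iterations, m, prob = p)
    mx <- apply(cnts, 2L, max)
    top <- cnts == matrix(mx, nrow = 5L, ncol = iterations, byrow = TRUE)
    winners <- sentiment_labels()[max.col(t(cnts), ties.method = "first")]
    for (j in which(colSums(top) > 1L)) {
      winners[j] <- break_tie(sentiment_labels()[top[, j]], pool)
    }
    winners
  }
  if (is.null(seed)) run() else with_substream(seed, run())
}

message_accuracy <- function(message_id, m, accuracy, method) {
  structure(list(message_id = message_id, m = as.integer(m),
                 accuracy = accuracy, method = method),
            class = "message_accuracy")
}

#' Monte Carlo concurrence accuracy for one message
#'
#' Runs `spec$iterations` independent resample-then-decide rounds, records
#' for each whether the machine decision concurs with the human label, and
#' returns the mean concurrence ("accuracy"). Deterministic given
#' `spec$seed`: the substream depends only on (seed, message id, m).
#'
#' @param pool A [response_pool()].
#' @param human_label The message's human label.
#' @param spec A [decision_spec()].
#' @return A `message_accuracy` object (fields `message_id`, `m`, `accuracy`,
#'   `method = "monte_carlo"`).
#' @export
monte_carlo_accuracy <- function(pool, human_label, spec) {
  stopifnot(inherits(spec, "decision_spec"))
  assert_label(human_label)
  sub <- substream_seed(spec$seed, "mc", pool$message_id, spec$m)
  decisions <- simulate_decisions(pool, spec$m, spec$iterations, seed = sub)
  message_accuracy(pool$message_id, spec$m, mean(decisions == human_label),
                   "monte_carlo")
}

# All count-compositions of m over k categories, as a k-column matrix.
compositions <- function(m, k) {
  if (k == 1L) return(matrix(m, ncol = 1L))
  out <- lapply(0:m, function(first) {
    cbind(first, compositions(m - first, k - 1L))
  })
  do.call(rbind, out)
}

#' Exact distribution of the machine decision
#'
#' Enumerates every count-composition of `m` over the labels present in the
#' pool, weights it by its multinomial probability under `p = counts/N`,
#' assigns its mass to the unique plurality label, and splits the mass of
#' tie compositions across the tied labels proportionally to their pool
#' counts. The exact counterpart of the Monte Carlo procedure.
#'
#' @param pool A [response_pool()].
#' @param m Number of resampled instances (>= 1).
#' @return Named probability vector over the five labels (sums to 1).
#' @export
decision_distribution <- function(pool, m) {
  stopifnot(inherits(pool, "response_pool"), m >= 1L)
  present <- names(pool$counts)[pool$counts > 0L]
  p <- pool$counts[present] / pool$n
  comp <- compositions(as.integer(m), length(present))
  logp <- lgamma(m + 1) - rowSums(lgamma(comp + 1)) +
    as.vector(comp %*% log(p))
  prob <- exp(logp)
  out <- stats::setNames(numeric(5L), sentiment_labels())
  mx <- apply(comp, 1L, max)
  for (i in seq_len(nrow(comp))) {
    tied <- present[comp[i, ] == mx[i]]
    if (length(tied) == 1L) {
      out[tied] <- out[tied] + prob[i]
    } else {
      w <- pool$counts[tied]
      out[tied] <- out[tied] + prob[i] * w / sum(w)
    }
  }
  out
}

#' Exact concurrence accuracy
#'
#' The probability that the plurality decision over `m` resampled instances
#' equals `human_label`: [decision_distribution()] evaluated at the human
#' label. Serves as the analytic oracle for [monte_carlo_accuracy()].
#'
#' @inheritParams monte_carlo_accuracy
#' @param m Number of resampled instances.
#' @return A `message_accuracy` object with `method = "exact"`.
#' @export
exact_accuracy <- function(pool, human_label, m) {
  assert_label(human_label)
  acc <- unname(decision_distribution(pool, m)[human_label])
  message_accuracy(pool$message_id, m, acc, "exact")
}

#' Plurality decision over the whole pool
#'
#' The reference decision based on all N instances, without resampling; ties
#' at the maximal count are broken by the same pool-proportional rule. This is
#' the `K_20`-style reference when N = 20.
#'
#' @param pool A [response_pool()].
#' @param seed Optional seed for the tie-break draw; default uses the current
#'   RNG state.
#' @return A single label.
#' @export
full_pool_decision <- function(pool, seed = NULL) {
  tied <- names(pool$counts)[pool$counts == max(pool$counts)]
  if (length(tied) == 1L || is.null(seed)) return(break_tie(tied, pool))
  with_substream(substream_seed(seed, "full", pool$message_id),
                 break_tie(tied, pool))
}

#' Per-message accuracies for a whole corpus
#'
#' @param bundle A [corpus_bundle()].
#' @param m Number of resampled instances.
#' @param method `"monte_carlo"` (default) or `"exact"`.
#' @param iterations,seed Monte Carlo protocol (ignored for `"exact"`).
#' @return Data frame with columns `message_id`, `platform`, `human_label`,
#'   `m`, `accuracy`, `method`.
#' @export
corpus_accuracy <- function(bundle, m, method = c("monte_carlo", "exact"),
                            iterations = 1000L, seed = 1L) {
  stopifnot(inherits(bundle, "corpus_bundle"))
  method <- match.arg(method)
  spec <- decision_spec(m, iterations = iterations, seed = seed)
  acc <- vapply(seq_len(nrow(bundle$messages)), function(i) {
    pool <- bundle$pools[[bundle$messages$message_id[i]]]
    h <- bundle$messages$human_label[i]
    if (method == "exact") exact_accuracy(pool, h, m)$accuracy
    else monte_carlo_accuracy(pool, h, spec)$accuracy
  }, numeric(1))
  data.frame(message_id = bundle$messages$message_id,
             platform = bundle$messages$platform,
             human_label = bundle$messages$human_label,
             m = as.integer(m), accuracy = acc, method = method,
             stringsAsFactors = FALSE)
}

#' One realized machine decision per message
#'
#' Used for confusion tables: at a stated `m` and seed, performs a single
#' resample-and-decide round per message (or the full-pool plurality when
#' `m = "full"`), each message on its own substream.
#'
#' @param bundle A [corpus_bundle()].
#' @param m Integer number of resampled instances, or `"full"` for the
#'   whole-pool plurality.
#' @param seed Integer seed.
#' @return Named character vector of decisions, names are message ids.
#' @export
corpus_decisions <- function(bundle, m, seed = 1L) {
  stopifnot(inherits(bundle, "corpus_bundle"))
  ids <- bundle$messages$message_id
  stats::setNames(vapply(ids, function(id) {
    pool <- bundle$pools[[id]]
    if (identical(m, "full")) {
      full_pool_decision(pool, seed = seed)
    } else {
      simulate_decisions(pool, as.integer(m), 1L,
                         seed = substream_seed(seed, "decide", id, m))
    }
  }, character(1)), ids)
}
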