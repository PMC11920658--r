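# Dirichlet-multinomial generator of synthetic response pools.
#
# Each message in a stratum (platform x human label) gets a latent label
# distribution p ~ Dirichlet(alpha); its N response instances are drawn i.i.d.
# from p. The Dirichlet level produces the between-message heterogeneity in
# instance agreement that per-message accuracy variation implies; the
# concentration sum(alpha) controls how strong that heterogeneity is (small
# concentration = near-degenerate messages that the model gets consistently
# right or consistently wrong).

#' Construct a synthetic-response generator profile
#'
#' @param name Profile name.
#' @param strata List of strata; each a list with `platform`, `label`
#'   (the human label of the stratum), `n` (number of messages) and `alpha`
#'   (positive numeric of length 5, named by [sentiment_labels()]).
#' @param pool_size Number of response instances per message (N). Default 20.
#' @param seed Integer seed; every message gets a deterministic substream
#'   derived from it.
#' @return An object of class `generator_profile`.
#' @export
generator_profile <- function(name, strata, pool_size = 20L, seed = 1L) {
  stopifnot(pool_size >= 1L, length(strata) >= 1L)
  strata <- lapply(strata, function(s) {
    stopifnot(s$n >= 1L)
    alpha <- s$alpha
    if (is.null(names(alpha))) names(alpha) <- sentiment_labels()
    alpha <- alpha[sentiment_labels()]
    if (any(!is.finite(alpha)) || any(alpha <= 0)) {
      stop_pluralvote("every alpha entry must be strictly positive",
                      class = "pluralvote_profile_error")
    }
    assert_label(s$label, "stratum label")
    list(platform = s$platform, label = s$label, n = as.integer(s$n),
         alpha = alpha)
  })
  structure(list(name = name, strata = strata,
                 pool_size = as.integer(pool_size), seed = as.integer(seed)),
            class = "generator_profile")
}

# Printed K_1 (SE) per stratum used to calibrate the default profiles: the
# analytic expected K_1 under the generator is alpha_h/sum(alpha) and the
# variance of the per-message human-label share is K1(1-K1)/(sum(alpha)+1),
# so both the level and the spread of one-shot accuracy pin down alpha.
.default_targets <- list(
  gpt35_like = list(
    facebook = list(ANTI = c(0.657, 0.023), PRO = c(0.452, 0.025),
                    NEU  = c(0.428, 0.024)),
    twitter  = list(ANTI = c(0.614, 0.025), PRO = c(0.411, 0.025),
                    NEU  = c(0.444, 0.026))),
  gpt4turbo_like = list(
    facebook = list(ANTI = c(0.856, 0.023), PRO = c(0.828, 0.024),
                    NEU  = c(0.661, 0.038)),
    twitter  = list(ANTI = c(0.789, 0.027), PRO = c(0.773, 0.028),
                    NEU  = c(0.704, 0.040))))

# How mass that does not land on the human label is shared among the other
# four labels, loosely following the observed misclassification flows
# (dominant NEU/IR confusion for the weaker model, almost-all-NEU confusion
# for the stronger one).
.default_flows <- list(
  gpt35_like = list(
    ANTI = c(PRO = 0.12, NEU = 0.61, MIX = 0.01, IR = 0.26),
    PRO  = c(ANTI = 0.13, NEU = 0.60, MIX = 0.02, IR = 0.25),
    NEU  = c(ANTI = 0.35, PRO = 0.35, MIX = 0.05, IR = 0.25)),
  gpt4turbo_like = list(
    ANTI = c(PRO = 0.03, NEU = 0.93, MIX = 0.02, IR = 0.02),
    PRO  = c(ANTI = 0.04, NEU = 0.90, MIX = 0.03, IR = 0.03),
    NEU  = c(ANTI = 0.35, PRO = 0.45, MIX = 0.10, IR = 0.10)))

.stratum_sizes <- c(ANTI = 200L, PRO = 200L, NEU = 100L)

# Solve for alpha from a (K1, SE-of-K1) target at m = 1.
calibrate_alpha <- function(k1, se1, n, flow) {
  conc <- k1 * (1 - k1) / (n * se1^2) - 1
  conc <- max(conc, 0.05)  # keep Dirichlet proper even for extreme targets
  alpha <- c(k1 * conc, (1 - k1) * conc * flow / sum(flow))
  names(alpha)[1] <- setdiff(sentiment_labels(), names(flow))
  alpha[sentiment_labels()]
}

#' Default generator profiles
#'
#' Two ready-made profiles, `gpt35_like` and `gpt4turbo_like`, with the
#' standard evaluation design (200 ANTI + 200 PRO + 100 NEU messages per
#' platform, two platforms, N = 20 instances per message). Per-stratum alphas
#' are calibrated so that the analytic expected one-shot accuracy
#' ([expected_K1()]) and its between-message spread match the corresponding
#' published one-shot estimates for each model tier.
#'
#' @param seed Integer seed stored in both profiles. Default 20.
#' @return Named list of two [generator_profile()] objects.
#' @export
#' @examples
#' p <- default_profiles()$gpt4turbo_like
#' expected_K1(p$strata[[1]]$alpha, "ANTI")
default_profiles <- function(seed = 20L) {
  build <- function(name) {
    strata <- list()
    for (platform in PLATFORMS) {
      for (lab in names(.stratum_sizes)) {
        tgt <- .default_targets[[name]][[platform]][[lab]]
        alpha <- calibrate_alpha(tgt[1], tgt[2], .stratum_sizes[[lab]],
                                 .default_flows[[name]][[lab]])
        strata[[length(strata) + 1L]] <-
          list(platform = platform, label = lab,
               n = .stratum_sizes[[lab]], alpha = alpha)
      }
    }
    generator_profile(name, strata, pool_size = 20L, seed = seed)
  }
  list(gpt35_like = build("gpt35_like"),
       gpt4turbo_like = build("gpt4turbo_like"))
}

#' Analytic expected one-shot accuracy under the generator
#'
#' Under the Dirichlet-multinomial generator the expected per-message share of
#' the human label — which equals expected accuracy at m = 1, where no tie is
#' possible — has the closed form `alpha_h / sum(alpha)`.
#'
#' @param alpha Positive numeric of length 5 (named by label, or in canonical
#'   order).
#' @param human_label The stratum's human label.
#' @return Probability in (0, 1].
#' @export
expected_K1 <- function(alpha, human_label) {
  if (is.null(names(alpha))) names(alpha) <- sentiment_labels()
  if (any(alpha <= 0)) {
    stop_pluralvote("alpha must be strictly positive",
                    class = "pluralvote_profile_error")
  }
  assert_label(human_label)
  unname(alpha[[human_label]] / sum(alpha))
}

# Shared per-message draw: both generate_corpus() and the profile-driven mock
# backend use this exact routine, so they produce identical pools for the
# same (seed, message_id).
draw_pool_instances <- function(alpha, n_instances, seed, message_id) {
  with_substream(substream_seed(seed, "pool", message_id), {
    g <- stats::rgamma(5L, shape = alpha)
    p <- g / sum(g)
    sample(sentiment_labels(), n_instances, replace = TRUE, prob = p)
  })
}

stratum_message_ids <- function(stratum) {
  sprintf("%s_%s_%04d", stratum$platform, stratum$label, seq_len(stratum$n))
}

#' Generate a synthetic corpus from a profile
#'
#' For each message of each stratum, draws a latent label distribution
#' `p ~ Dirichlet(alpha)` and then `pool_size` i.i.d. instance labels from
#' `p`. Fully deterministic given the seed: each message id owns an
#' independent substream, so stratum order and message order are irrelevant.
#'
#' @param profile A [generator_profile()].
#' @param seed Optional seed override; defaults to the profile's own seed.
#' @return A [corpus_bundle()].
#' @export
generate_corpus <- function(profile, seed = NULL) {
  stopifnot(inherits(profile, "generator_profile"))
  if (is.null(seed)) seed <- profile$seed
  messages <- list()
  pools <- list()
  for (stratum in profile$strata) {
    ids <- stratum_message_ids(stratum)
    messages[[length(messages) + 1L]] <-
      data.frame(message_id = ids, platform = stratum$platform,
                 human_label = stratum$label,
                 text = sprintf("synthetic message %s", ids),
                 stringsAsFactors = FALSE)
    for (id in ids) {
      pools[[id]] <- response_pool(
        id, draw_pool_instances(stratum$alpha, profile$pool_size, seed, id))
    }
  }
  corpus_bundle(do.call(rbind, messages), pools)
}

#' Read / write a generator profile as YAML
#'
#' @param profile A [generator_profile()].
#' @param path YAML file path.
#' @return `write_profile` returns `path` invisibly; `read_profile` returns a
#'   [generator_profile()].
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "generator_profile"))
  yaml::write_yaml(list(
    name = profile$name, pool_size = profile$pool_size, seed = profile$seed,
    strata = lapply(profile$strata, function(s) {
      list(platform = s$platform, label = s$label, n = s$n,
           alpha = as.list(s$alpha))
    })), path)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  raw <- yaml::read_yaml(path)
  generator_profile(
    name = raw$name,
    strata = lapply(raw$strata, function(s) {
      list(platform = s$platform, label = s$label, n = s$n,
           alpha = unlist(s$alpha))
    }),
    pool_size = raw$pool_size, seed = raw$seed)
}
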