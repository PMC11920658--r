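---
title: "Plurality-vote reliability of LLM sentiment annotation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plurality-vote reliability of LLM sentiment annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pluralvote)
```

## The problem

When a large language model is asked to classify the same social media
message repeatedly — each time in a fresh session — its answers vary because
decoding samples from a distribution over tokens. A practical protocol for
turning such a stochastic annotator into a usable coder is: collect a pool of
N independent response instances per message (here N = 20), then define the
*machine decision* as the plurality label among m instances resampled from
the pool with replacement, breaking ties with extra pool draws. Comparing
machine decisions with a human expert label yields a per-message
*concurrence* indicator, and its average over resampling rounds a per-message
*accuracy*. The mean accuracy over all messages of a human-label category is
the category-level summary `K_m`; `K_20`, the plurality over the full pool,
is the reference against which `K_m/K_20` ratios quantify how little is lost
by asking the model only m times.

This package implements that evaluation pipeline for the five-category
heated-tobacco-product (HTP) sentiment scheme — ANTI, PRO, NEU, MIX, IR —
together with a synthetic response generator, so every stage can be tested
end to end without an API call.

## The decision model

For a message with pool counts $c = (c_1,\dots,c_5)$, $\sum_j c_j = N$,
resampling m instances with replacement is multinomial sampling with
$p = c/N$. The machine decision is the modal label of the draw; "majority" is
implemented as plurality (the mode) because with five categories an absolute
majority frequently does not exist, yet every round must produce a decision.

**Tie rule.** A tie at the maximal count is broken by repeatedly drawing one
extra instance uniformly from the full pool until the drawn label belongs to
the tied set. Because a draw outside the tied set is simply ignored and
redrawn, this process selects tied label $j$ with probability
$c_j / \sum_{k \in \text{tied}} c_k$ — so the implementation chooses among
tied labels proportionally to their pool counts, which is exactly equivalent
and closed-form friendly. An alternative reading — append the extra draw to
the tally and re-evaluate the plurality, which can enlarge the tie set in
edge cases — was considered and not adopted; the two differ only on rare
configurations and the proportional rule admits exact enumeration. Tied
labels always have positive pool count (they were sampled), so termination
is guaranteed. Even m is permitted; ties simply occur more often.

**Monte Carlo path.** `monte_carlo_accuracy()` repeats
sample-then-decide `iterations` times (default 1000) and averages the
concurrence indicator. A multinomial tally draw stands in for the m
individual uniform draws — the two are distributionally identical and the
tally is what the decision depends on.

**Exact path.** `decision_distribution()` enumerates all count-compositions
of m over the labels present in the pool
($\binom{m+k-1}{k-1} \le 10{,}626$ for $m = 20, k = 5$), weights each by its
multinomial probability, assigns each composition's mass to its plurality
label, and splits tie mass pool-proportionally. `exact_accuracy()` is this
distribution evaluated at the human label: the analytic limit of the Monte
Carlo estimate. At m = 1 no tie is possible and exact accuracy reduces to
the pool share of the human label — a useful identity exploited by the
tests. The test suite also checks the enumeration against an independent
sequence-level brute force (all $5^m$ label sequences, $m \le 5$).

**Determinism.** One master seed is set per run; every (message, m, purpose)
triple derives its own substream via a 32-bit string hash, so message order,
stratum order, and file row order can never change any result.

## Aggregation and inference

`aggregate_K()` averages per-message accuracies into `K_m` and reports the
standard error **across messages** (sample SD with n − 1 denominator over
$\sqrt n$), not across Monte Carlo iterations: the quantity of interest is
how variable per-message accuracy is within a category, and with 1000
iterations the Monte Carlo noise per message is an order of magnitude
smaller than the across-message spread. `ratio_to_reference()` forms the
percentage `100 * K_m / K_ref` with the largest requested m as reference.

Confusion tables (`confusion_table()`) tabulate human label against one
*realized* decision per message at a stated m and seed — a single
realization, not an average, because a contingency table needs integer
counts; the seed is recorded in the run sidecar so the table is replayable.
`misclassification_flows()` converts one row into a misclassification rate
(percent of the category's messages decided wrongly) and flow shares
(percent of the wrong decisions going to each wrong label; shares sum to
100 whenever any misclassification exists).

`mann_whitney_u()` compares per-message accuracy distributions between two
categories: U from rank sums with midranks, two-sided p from the normal
approximation with tie-corrected variance and continuity correction.
Two-sided was chosen because no direction is privileged a priori;
`stats::wilcox.test` with the same options is used as an independent
reference in the tests, while the package's own implementation keeps the
statistic, tie handling, and degenerate-sample flagging explicit. When all
pooled values are identical the result is flagged `degenerate` and p = 1 is
returned rather than an error, since downstream sweeps over many (platform,
m) cells must not abort on one degenerate cell. Per-category tests use
per-message accuracies at a given m as the observation unit.

## The synthetic generator

`generate_corpus()` draws, for each message of a stratum
(platform × human label), a latent label distribution
$p \sim \text{Dirichlet}(\alpha)$ and then N i.i.d. instance labels from
$p$. The Dirichlet layer is the minimal hierarchy that produces
between-message heterogeneity in instance agreement — some messages are
easy (the model nearly always answers the same), others genuinely ambiguous
— which is exactly the structure that makes `K_m` rise with m.

Two analytic facts drive calibration:

* expected one-shot accuracy: $E[p_h] = \alpha_h / \alpha_0$ with
  $\alpha_0 = \sum_j \alpha_j$ (`expected_K1()`);
* between-message variance of the human-label share:
  $\mathrm{Var}(p_h) = K_1 (1 - K_1) / (\alpha_0 + 1)$.

`default_profiles()` provides `gpt35_like` and `gpt4turbo_like` profiles
with the standard design — 200 ANTI + 200 PRO + 100 NEU messages per
platform (facebook = long form, twitter = short form), N = 20 — whose
per-stratum $\alpha$ is solved from the published one-shot estimates: the
level from the printed `K_1` and the concentration $\alpha_0$ from the
printed across-message SE at m = 1 (so
$\alpha_0 = K_1(1-K_1)/(n\,\mathrm{SE}^2) - 1$, floored at 0.05 to keep the
Dirichlet proper). K_1 rather than K_20 anchors the calibration because only
K_1 has a closed form under the generator. The resulting concentrations are
small (0.1–3), i.e. strongly bimodal per-message agreement — consistent
with the large across-message SEs the protocol reports. Mass off the human
label is spread over the other four labels with fixed weights that mimic the
observed misclassification flows (mostly NEU/IR confusion for the weaker
tier, almost-all-NEU for the stronger tier); these weights shape confusion
tables only, not `K_m`.

What the generator does **not** emulate: message text (pools are label
only), correlation between platforms or between messages, any drift across
instances within a pool (instances are exchangeable), or model updates over
time. A green test therefore establishes that the decision/aggregation
machinery is correct under the stated sampling model — not that any
particular LLM achieves these accuracies.

## Numerical choices and edge cases

* Enumeration works in log space (`lgamma`) and redistributes tie mass
  exactly; the distribution sums to 1 within 1e-12 and matches brute force
  within 1e-10.
* Label parsing is strict: trim whitespace/punctuation, upcase, exact match
  against the five names. Malformed responses are a hard error in file
  readers and a counted, retried, then message-rejecting condition in the
  collection adapter — repairing model output is deliberately out of scope,
  and how (or whether) the original protocol repaired malformed responses is
  unknown, so strictness is a package policy, not a claim about that
  protocol.
* `aggregate_K()` with a single message returns `se = NA` rather than a
  misleading 0.
* The K_20-style reference uses the full-pool plurality without resampling
  (`full_pool_decision()`); resampled m = 20 remains available through the
  generic path, and with 1000 iterations the two differ only through tie
  configurations.
* SEs, ratios, and percentages are kept at full precision internally and
  rounded only at presentation time (`cmd_report()`).

## Known limitations

* The published headline `K_m`, SE, and U values were computed on response
  data that is not publicly deposited; they are reproducible here only in
  distributional shape via the calibrated generator, not numerically.
* The normal approximation in the rank test is inaccurate for very small
  strata (n < ~10); the pipeline's intended use has n ≥ 100 per category.
* The Dirichlet–multinomial's true between-message dispersion is a
  calibration choice anchored to printed m = 1 SEs, not an observed fact
  about any specific model's response distributions.

## A worked run

```{r, eval = FALSE}
dir <- tempfile(); dir.create(dir)
config <- run_config(profile = "gpt4turbo_like", seed = 7L,
                     corpus_dir = dir, out_dir = dir,
                     m_values = c(1, 3, 5, 7, 9, 11, 20), iterations = 1000)
cmd_simulate(config)   # messages.csv + responses.csv (1000 messages x 20)
cmd_evaluate(config)   # summary.csv (56 rows) + confusion.csv
cmd_compare(config)    # comparisons.csv (42 pairwise rank tests)
cmd_report(file.path(dir, "summary.csv"), format = "md")
```
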