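# Optional collection layer: renders the coding scheme into prompts and
# gathers N response instances per message from a pluggable backend. A
# backend is a function(prompt, session) -> raw response string; `session`
# carries (message_id, instance_index, attempt) and marks each request as an
# independent fresh session (no carried chat context). Real network backends
# are out of test scope; the deterministic mocks below make the layer fully
# testable offline.

#' Construct a coding scheme
#'
#' @param instructions Task instructions shown before the message.
#' @param label_definitions Named character vector or list mapping each of the
#'   five labels to its definition text; all five must be non-empty.
#' @param formatting_rules Response formatting rules appended to the prompt.
#' @return Object of class `coding_scheme`.
#' @export
coding_scheme <- function(instructions, label_definitions, formatting_rules) {
  label_definitions <- unlist(label_definitions)
  missing_defs <- setdiff(sentiment_labels(), names(label_definitions))
  if (length(missing_defs) || any(!nzchar(label_definitions[sentiment_labels()]))) {
    stop_pluralvote("all five labels need non-empty definitions",
                    class = "pluralvote_schema_error")
  }
  structure(list(instructions = instructions,
                 label_definitions = label_definitions[sentiment_labels()],
                 formatting_rules = formatting_rules),
            class = "coding_scheme")
}

#' Default heated-tobacco-product coding scheme
#'
#' A stand-in scheme mirroring the structure (not the exact wording, which is
#' unpublished) of the codebook given to human coders: category definitions
#' for ANTI/PRO/NEU/MIX/IR plus strict one-token formatting rules.
#'
#' @return A [coding_scheme()].
#' @export
default_coding_scheme <- function() {
  coding_scheme(
    instructions = paste(
      "You are classifying the sentiment of a social media message about",
      "heated tobacco products (HTPs): devices that heat processed tobacco",
      "to deliver nicotine without combustion. Assign exactly one category",
      "from the coding scheme below."),
    label_definitions = c(
      ANTI = "The message expresses a negative attitude toward HTPs (health risks, support for restrictions, criticism of products or marketing).",
      PRO = "The message expresses a positive attitude toward HTPs (benefits, satisfaction, promotion, opposition to restrictions).",
      NEU = "The message is relevant to HTPs but expresses no positive or negative attitude (news, factual statements, questions).",
      MIX = "The message contains both positive and negative attitudes toward HTPs.",
      IR = "The message is irrelevant to HTPs."),
    formatting_rules = paste(
      "Respond with exactly one token: ANTI, PRO, NEU, MIX, or IR.",
      "Do not explain your choice."))
}

#' Render the prompt for one message
#'
#' Deterministic concatenation of instructions, message text, the five label
#' definitions, and formatting rules; byte-identical across calls.
#'
#' @param message One-row data frame or list with `message_id` and `text`.
#' @param scheme A [coding_scheme()].
#' @return A single prompt string containing every label name.
#' @export
build_prompt <- function(message, scheme) {
  stopifnot(inherits(scheme, "coding_scheme"))
  text <- message$text
  if (is.null(text) || is.na(text) || !nzchar(text)) {
    stop_pluralvote(sprintf("message %s has no text",
                            message$message_id %||% "?"),
                    class = "pluralvote_missing_text")
  }
  defs <- sprintf("%s: %s", names(scheme$label_definitions),
                  scheme$label_definitions)
  paste(c(scheme$instructions, "", "MESSAGE:", text, "", "CODING SCHEME:",
          defs, "", scheme$formatting_rules), collapse = "\n")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Collect N response instances for one message
#'
#' Issues `n` independent fresh-session requests to the backend and parses
#' each raw response with [parse_label()]. An unparseable response is retried
#' up to `max_retries` times (with a fresh session each attempt); if still
#' unparseable the whole message is rejected with a condition of class
#' `pluralvote_rejected_message` carrying the parse-failure count.
#'
#' @param backend `function(prompt, session)` returning one raw response
#'   string; `session` is `list(message_id, instance_index, attempt)`.
#' @param message One-row data frame or list with `message_id` and `text`.
#' @param scheme A [coding_scheme()].
#' @param n Pool size to collect (default 20).
#' @param max_retries Retries per instance after a parse failure (default 2).
#' @return A [response_pool()] with exactly `n` instances.
#' @export
collect_instances <- function(backend, message, scheme, n = 20L,
                              max_retries = 2L) {
  stopifnot(is.function(backend), n >= 1L)
  prompt <- build_prompt(message, scheme)
  id <- as.character(message$message_id)
  failures <- 0L
  instances <- character(n)
  for (i in seq_len(n)) {
    label <- NULL
    for (attempt in 0:max_retries) {
      raw <- tryCatch(
        backend(prompt, list(message_id = id, instance_index = i - 1L,
                             attempt = attempt)),
        error = function(e) {
          stop_pluralvote(sprintf("backend error for message %s: %s",
                                  id, conditionMessage(e)),
                          class = "pluralvote_backend_error")
        })
      label <- tryCatch(parse_label(raw), pluralvote_unparseable_label =
                          function(e) NULL)
      if (!is.null(label)) break
      failures <- failures + 1L
    }
    if (is.null(label)) {
      cond <- structure(
        class = c("pluralvote_rejected_message", "pluralvote_error",
                  "error", "condition"),
        list(message = sprintf(
          "message %s rejected after %d parse failure(s)", id, failures),
          call = sys.call(-1), message_id = id, parse_failures = failures))
      stop(cond)
    }
    instances[i] <- label
  }
  response_pool(id, instances)
}

#' Deterministic mock backends
#'
#' `mock_constant_backend` always answers with one fixed raw string.
#' `mock_profile_backend` answers according to a [generator_profile()]: for a
#' given message id it reproduces, instance by instance, exactly the pool
#' that [generate_corpus()] would draw for that message (shared substream
#' contract), so collection through the adapter and direct generation agree
#' bit for bit.
#'
#' @param response Fixed raw response string.
#' @return A backend `function(prompt, session)`.
#' @export
mock_constant_backend <- function(response) {
  force(response)
  function(prompt, session) response
}

#' @rdname mock_constant_backend
#' @param profile A [generator_profile()].
#' @param messages Message table mapping `message_id` to (`platform`,
#'   `human_label`), used to locate each message's stratum.
#' @export
mock_profile_backend <- function(profile, messages) {
  stopifnot(inherits(profile, "generator_profile"))
  strata_key <- vapply(profile$strata, function(s)
    paste(s$platform, s$label), character(1))
  function(prompt, session) {
    row <- messages[messages$message_id == session$message_id, ]
    if (nrow(row) != 1L) {
      stop(sprintf("unknown message id %s", session$message_id))
    }
    stratum <- profile$strata[[match(paste(row$platform, row$human_label),
                                     strata_key)]]
    pool <- draw_pool_instances(stratum$alpha, profile$pool_size,
                                profile$seed, session$message_id)
    pool[[session$instance_index + 1L]]
  }
}
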