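# Domain containers and CSV readers/writers.
#
# Interchange formats (all CSV, UTF-8, header row mandatory):
#   messages.csv  : message_id, platform, human_label[, text]
#   responses.csv : message_id, instance_index (0-based), label   (long format)
#   summary.csv   : platform, category, m, n, k_m, se, ratio_to_ref
#   confusion.csv : platform, human_label, machine_label, count

PLATFORMS <- c("facebook", "twitter")

#' Construct a response pool
#'
#' A response pool holds the N response instances (label decisions) collected
#' for one message in independent sessions. Counts are always derived from the
#' instance vector, never stored independently.
#'
#' @param message_id Opaque unique message identifier.
#' @param instances Ordered character vector of sentiment labels, length N >= 1.
#' @return An object of class `response_pool` with elements `message_id`,
#'   `instances`, `counts` (named integer over [sentiment_labels()]) and `n`.
#' @export
response_pool <- function(message_id, instances) {
  stopifnot(is.character(message_id), length(message_id) == 1L)
  if (length(instances) < 1L) {
    stop_pluralvote("a response pool needs at least one instance",
                    class = "pluralvote_integrity_error")
  }
  assert_label(instances, "response instance")
  structure(list(message_id = message_id,
                 instances = instances,
                 counts = label_counts(instances),
                 n = length(instances)),
            class = "response_pool")
}

#' @export
print.response_pool <- function(x, ...) {
  cat(sprintf("<response_pool %s: N=%d; %s>\n", x$message_id, x$n,
              paste(sprintf("%s=%d", names(x$counts)[x$counts > 0],
                            x$counts[x$counts > 0]), collapse = " ")))
  invisible(x)
}

#' Bundle a message table with its response pools
#'
#' @param messages Data frame with columns `message_id`, `platform`,
#'   `human_label` and optionally `text`.
#' @param pools Named list of [response_pool()] objects, one per message
#'   (names are message ids). A plain list is matched by `message_id`.
#' @return An object of class `corpus_bundle`.
#' @export
corpus_bundle <- function(messages, pools) {
  req <- c("message_id", "platform", "human_label")
  missing_cols <- setdiff(req, names(messages))
  if (length(missing_cols)) {
    stop_pluralvote(paste("messages table lacks columns:",
                          paste(missing_cols, collapse = ", ")),
                    class = "pluralvote_schema_error")
  }
  messages$message_id <- as.character(messages$message_id)
  if (anyDuplicated(messages$message_id)) {
    stop_pluralvote("duplicate message_id in messages table",
                    class = "pluralvote_integrity_error")
  }
  if (!all(messages$platform %in% PLATFORMS)) {
    stop_pluralvote(paste("platform must be one of:",
                          paste(PLATFORMS, collapse = ", ")),
                    class = "pluralvote_schema_error")
  }
  assert_label(messages$human_label, "human_label")
  if (is.null(names(pools))) {
    names(pools) <- vapply(pools, function(p) p$message_id, character(1))
  }
  if (!setequal(names(pools), messages$message_id) ||
      length(pools) != nrow(messages)) {
    stop_pluralvote("messages and pools do not match one-to-one",
                    class = "pluralvote_integrity_error")
  }
  pools <- pools[messages$message_id]
  structure(list(messages = messages, pools = pools), class = "corpus_bundle")
}

#' @export
print.corpus_bundle <- function(x, ...) {
  cat(sprintf("<corpus_bundle: %d messages, pool size N=%s>\n",
              nrow(x$messages),
              paste(unique(vapply(x$pools, `[[`, 0L, "n")), collapse = "/")))
  invisible(x)
}

#' Read a corpus (messages + response pools) from CSV files
#'
#' Validates the schema of both files, re-tallies every pool from its long
#' format rows, and checks referential integrity: every message must have
#' exactly one pool and every pool exactly `n` instances. Row order in either
#' file never affects downstream results.
#'
#' @param messages_path Path to `messages.csv`.
#' @param pools_path Path to `responses.csv` (long format: one row per
#'   response instance).
#' @param n Declared pool size. Default 20. Use `NULL` to accept whatever
#'   common size the file contains.
#' @return A [corpus_bundle()].
#' @export
read_corpus <- function(messages_path, pools_path, n = 20L) {
  messages <- utils::read.csv(messages_path, stringsAsFactors = FALSE,
                              colClasses = "character")
  responses <- utils::read.csv(pools_path, stringsAsFactors = FALSE,
                               colClasses = "character")
  for (col in c("message_id", "instance_index", "label")) {
    if (!col %in% names(responses)) {
      stop_pluralvote(sprintf("%s lacks column '%s'", pools_path, col),
                      class = "pluralvote_schema_error")
    }
  }
  responses$instance_index <- as.integer(responses$instance_index)
  responses$label <- parse_label(responses$label)
  if ("human_label" %in% names(messages)) {
    messages$human_label <- parse_label(messages$human_label)
  }
  split_idx <- split(seq_len(nrow(responses)), responses$message_id)
  pools <- lapply(split_idx, function(idx) {
    rows <- responses[idx, ]
    rows <- rows[order(rows$instance_index), ]
    id <- rows$message_id[[1]]
    if (!is.null(n) && nrow(rows) != n) {
      stop_pluralvote(sprintf("pool for message '%s' has %d instances, expected %d",
                              id, nrow(rows), n),
                      class = "pluralvote_integrity_error")
    }
    response_pool(id, rows$label)
  })
  corpus_bundle(messages, pools)
}

#' Write a corpus to CSV files
#'
#' Inverse of [read_corpus()]: emits `messages.csv` and a long-format
#' `responses.csv` with 0-based `instance_index` so instance identity is
#' preserved for auditing.
#'
#' @param bundle A [corpus_bundle()].
#' @param messages_path,pools_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_corpus <- function(bundle, messages_path, pools_path) {
  stopifnot(inherits(bundle, "corpus_bundle"))
  utils::write.csv(bundle$messages, messages_path, row.names = FALSE)
  long <- do.call(rbind, lapply(bundle$pools, function(p) {
    data.frame(message_id = p$message_id,
               instance_index = seq_along(p$instances) - 1L,
               label = p$instances, stringsAsFactors = FALSE)
  }))
  rownames(long) <- NULL
  utils::write.csv(long, pools_path, row.names = FALSE)
  invisible(c(messages_path, pools_path))
}

#' Write / read category-level accuracy summaries
#'
#' One row per (platform, category, m) with the mean accuracy `k_m`, its
#' standard error across messages `se`, and the percentage ratio to the
#' reference (largest-m) accuracy. Reals survive a round trip to at least 12
#' significant digits.
#'
#' @param summaries Data frame as produced by [aggregate_K()] rows; must be
#'   non-empty.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_summary <- function(summaries, path) {
  req <- c("platform", "category", "m", "n", "k_m", "se", "ratio_to_ref")
  if (is.null(summaries) || !is.data.frame(summaries) || nrow(summaries) == 0L) {
    stop_pluralvote("summaries must be a non-empty data frame",
                    class = "pluralvote_schema_error")
  }
  missing_cols <- setdiff(req, names(summaries))
  if (length(missing_cols)) {
    stop_pluralvote(paste("summary lacks columns:",
                          paste(missing_cols, collapse = ", ")),
                    class = "pluralvote_schema_error")
  }
  out <- summaries[, req]
  for (col in c("k_m", "se", "ratio_to_ref")) {
    out[[col]] <- vapply(out[[col]], function(v) {
      if (is.na(v)) "" else format(v, digits = 15, scientific = FALSE)
    }, character(1))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_summary
#' @export
read_summary <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("k_m", "se", "ratio_to_ref")) df[[col]] <- as.numeric(df[[col]])
  df$m <- as.integer(df$m)
  df$n <- as.integer(df$n)
  df
}

#' Write a confusion table to CSV (long format)
#'
#' @param table A `confusion_table` from [confusion_table()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_confusion <- function(table, path) {
  stopifnot(inherits(table, "confusion_table"))
  grid <- expand.grid(human_label = sentiment_labels(),
                      machine_label = sentiment_labels(),
                      stringsAsFactors = FALSE)
  grid$platform <- table$platform
  grid$count <- mapply(function(h, g) table$counts[h, g],
                       grid$human_label, grid$machine_label)
  utils::write.csv(grid[, c("platform", "human_label", "machine_label", "count")],
                   path, row.names = FALSE)
  invisible(path)
}
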