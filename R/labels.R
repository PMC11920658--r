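# Closed five-category sentiment vocabulary and strict parsing.

#' The five admissible sentiment labels
#'
#' The coding scheme for heated-tobacco-product (HTP) messages uses a closed
#' vocabulary of five categories: `ANTI` (against HTPs), `PRO` (favorable to
#' HTPs), `NEU` (neutral), `MIX` (mixed positive and negative), and `IR`
#' (irrelevant to HTPs). All label vectors in the package use this order.
#'
#' @return Character vector of the five label names, in canonical order.
#' @export
#' @examples
#' sentiment_labels()
sentiment_labels <- function() {
  c("ANTI", "PRO", "NEU", "MIX", "IR")
}

#' Parse a raw token into a sentiment label
#'
#' Normalizes a free-text token (as emitted by a model or found in a file) by
#' stripping leading/trailing whitespace and punctuation and upcasing, then
#' requires an exact match against [sentiment_labels()]. There is deliberately
#' no fuzzy matching: anything else is a hard error of condition class
#' `pluralvote_unparseable_label`.
#'
#' @param raw Character vector of raw tokens (non-empty strings).
#' @return Character vector of validated labels.
#' @export
#' @examples
#' parse_label("ANTI")
#' parse_label(" pro.")
parse_label <- function(raw) {
  if (length(raw) == 0L || !is.character(raw)) {
    stop_pluralvote("raw must be a non-empty character vector",
                    class = "pluralvote_unparseable_label")
  }
  norm <- toupper(gsub("^[[:space:][:punct:]]+|[[:space:][:punct:]]+$", "", raw))
  bad <- is.na(norm) | !(norm %in% sentiment_labels())
  if (any(bad)) {
    stop_pluralvote(
      sprintf("unparseable label(s): %s",
              paste(unique(raw[bad]), collapse = ", ")),
      class = "pluralvote_unparseable_label")
  }
  norm
}

assert_label <- function(x, what = "label") {
  if (!all(x %in% sentiment_labels())) {
    stop_pluralvote(sprintf("invalid %s: %s", what,
                            paste(setdiff(x, sentiment_labels()), collapse = ", ")),
                    class = "pluralvote_unparseable_label")
  }
  invisible(x)
}

# Tally a vector of labels into a named count vector over the full vocabulary.
label_counts <- function(labels) {
  tab <- table(factor(labels, levels = sentiment_labels()))
  stats::setNames(as.integer(tab), sentiment_labels())
}

stop_pluralvote <- function(message, class, call = sys.call(-1)) {
  stop(structure(class = c(class, "pluralvote_error", "error", "condition"),
                 list(message = message, call = call)))
}
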