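.freq_count_cols <- function() {
  c("n_correct", "n_distractor_error", "n_prime_response_error",
    "n_other_error")
}

.freq_table_cols <- function() {
  c("condition", "trial_type", "context_relation", "saliency",
    .freq_count_cols())
}

#' Frequency table of probe-response categories
#'
#' The unit of inference: observed counts in the four response categories
#' (correct, probe-distractor error, prime-response error, other error) for
#' every design cell — trial type (ignored_repetition, control) by context
#' relation (repeated, changed) by saliency level. The `condition` label is
#' derived as `trial_type/context_relation/saliency` if absent.
#'
#' @param x Data.frame with columns `trial_type`, `context_relation`,
#'   `saliency` and the four count columns `n_correct`,
#'   `n_distractor_error`, `n_prime_response_error`, `n_other_error`.
#' @return Validated data.frame of class `mpt_freq_table`.
#' @export
freq_table <- function(x) {
  stopifnot(is.data.frame(x))
  if (!"condition" %in% names(x)) {
    x$condition <- paste(x$trial_type, x$context_relation, x$saliency,
                         sep = "/")
  }
  .validate_freq_table(x)
}

.validate_freq_table <- function(x, where = "frequency table") {
  if (!is.data.frame(x)) stop(where, " must be a data.frame")
  if (!"condition" %in% names(x)) return(freq_table(x))
  miss <- setdiff(.freq_table_cols(), names(x))
  if (length(miss)) {
    stop(where, " lacks column(s): ", paste(miss, collapse = ", "))
  }
  x <- x[, .freq_table_cols()]
  for (col in .freq_count_cols()) {
    v <- x[[col]]
    if (anyNA(v) || !is.numeric(v)) {
      stop(where, ": column ", col, " must be numeric with no missing values")
    }
    bad <- which(v < 0 | abs(v - round(v)) > 1e-9)
    if (length(bad)) {
      stop(where, ": column ", col, " has negative or non-integer count ",
           "in row(s) ", paste(bad, collapse = ", "))
    }
    x[[col]] <- as.integer(round(v))
  }
  key <- paste(x$trial_type, x$context_relation, x$saliency)
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop(where, ": duplicated design cell(s) in row(s) ",
         paste(dup, collapse = ", "), " (",
         paste(unique(key[dup]), collapse = "; "), ")")
  }
  class(x) <- unique(c("mpt_freq_table", class(x)))
  x
}

#' Read a frequency table from a CSV file
#'
#' Expects the comma-delimited schema written by
#' [write_frequency_table()]: header
#' `condition, trial_type, context_relation, saliency, n_correct,
#' n_distractor_error, n_prime_response_error, n_other_error`, one row per
#' design cell. Malformed headers, negative or non-integer counts, and
#' duplicated cells are rejected with the offending column or row named.
#'
#' @param path Path to the CSV file.
#' @return An `mpt_freq_table`.
#' @export
read_frequency_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.freq_table_cols(), names(x))
  if (length(miss)) {
    stop("malformed header in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  }
  for (col in .freq_count_cols()) {
    if (!is.numeric(x[[col]])) {
      stop("column ", col, " in ", path, " is not numeric")
    }
  }
  .validate_freq_table(x, where = path)
}

#' Write a frequency table to a CSV file
#'
#' @param x An `mpt_freq_table` (or coercible data.frame, see
#'   [freq_table()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frequency_table <- function(x, path) {
  x <- .validate_freq_table(if ("condition" %in% names(x)) x else freq_table(x))
  utils::write.csv(as.data.frame(x)[, .freq_table_cols()], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
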