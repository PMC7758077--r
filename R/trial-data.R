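#' Trial data container
#'
#' Pairs a sequence of stimuli with a sequence of discrete responses for
#' `N` trials.  Stimuli may be a numeric vector (one value per trial), a
#' matrix or data frame (one row per trial, columns `s1...sk`), or a list
#' of arbitrary per-trial records.  Responses may be an atomic vector
#' (one value per trial) or a matrix/data frame for multi-part responses;
#' they must support exact equality comparison, which the engine performs
#' on a canonical serialization of each record.
#'
#' @param stimuli stimuli, one record per trial.
#' @param responses discrete responses, one record per trial.
#' @return a `trial_data` object with fields `stimuli` (list of records),
#'   `responses` (list of records), `n_trials`, and precomputed canonical
#'   `response_keys`.
#' @seealso [read_trials()], [write_trials()]
#' @export
trial_data <- function(stimuli, responses) {
  stim <- as_record_list(stimuli)
  resp <- as_record_list(responses)
  n <- length(stim)
  if (n < 1L || length(resp) != n) {
    stop("`stimuli` and `responses` must be non-empty and of equal length",
      call. = FALSE
    )
  }
  structure(
    list(
      stimuli = stim,
      responses = resp,
      n_trials = n,
      response_keys = vapply(resp, canonical_key, character(1))
    ),
    class = "trial_data"
  )
}

#' @export
print.trial_data <- function(x, ...) {
  cat(sprintf(
    "<trial_data> %d trials; stimulus record length %d; response record length %d\n",
    x$n_trials, length(x$stimuli[[1]]), length(x$responses[[1]])
  ))
  invisible(x)
}

# normalize the accepted input shapes to a list of per-trial records
as_record_list <- function(x) {
  if (inherits(x, "data.frame")) {
    lapply(seq_len(nrow(x)), function(i) {
      r <- as.list(x[i, , drop = FALSE])
      unlist_record(r)
    })
  } else if (is.matrix(x)) {
    lapply(seq_len(nrow(x)), function(i) x[i, ])
  } else if (is.atomic(x)) {
    as.list(x)
  } else if (is.list(x)) {
    x
  } else {
    stop("unsupported stimuli/responses type", call. = FALSE)
  }
}

unlist_record <- function(r) {
  if (all(vapply(r, is.numeric, logical(1)))) {
    unlist(r, use.names = TRUE)
  } else {
    r
  }
}

#' Canonical serialization of a response record
#'
#' Exact-match testing between a simulator draw and an observed response
#' requires an unambiguous hit test.  Records are serialized field by
#' field: doubles with 17 significant digits (lossless round trip),
#' integers and tokens verbatim.  Two records match iff their keys are
#' identical strings.
#'
#' @param r a response record (scalar, vector, or list of scalars).
#' @return a single character key.
#' @keywords internal
canonical_key <- function(r) {
  if (is.list(r)) r <- unlist(r, use.names = FALSE)
  parts <- if (is.double(r)) {
    sprintf("%.17g", r)
  } else {
    as.character(r)
  }
  paste(parts, collapse = "\x1f")
}
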