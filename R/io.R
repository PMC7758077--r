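#' Read and write trial tables
#'
#' Trial data are stored as UTF-8 CSV with a header, comma separator and
#' `.` decimal: stimulus columns `s1...sk` (numeric or token), response
#' columns `r1...rm`, and an optional leading `trial` index column.
#' Doubles are written with 17 significant digits so a write/read cycle
#' reproduces the `trial_data` object exactly.  Ragged rows and missing
#' response columns raise a format error naming the offending lines or
#' columns.
#'
#' @param path CSV file path.
#' @return `read_trials()`: a [trial_data()] object.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) {
    stop("no such file: ", path, call. = FALSE)
  }
  fields <- count.fields(path, sep = ",", quote = "\"")
  if (length(unique(fields)) > 1L) {
    bad <- which(fields != fields[1]) # includes header as line 1
    stop(
      "format-error: ragged rows at line(s) ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  df <- read.csv(path, stringsAsFactors = FALSE)
  s_cols <- grep("^s[0-9]+$", names(df), value = TRUE)
  r_cols <- grep("^r[0-9]+$", names(df), value = TRUE)
  if (length(s_cols) == 0L || length(r_cols) == 0L) {
    stop(
      "format-error: need stimulus columns s1...sk and response columns ",
      "r1...rm; found: ", paste(names(df), collapse = ", "),
      call. = FALSE
    )
  }
  s_cols <- s_cols[order(as.integer(sub("^s", "", s_cols)))]
  r_cols <- r_cols[order(as.integer(sub("^r", "", r_cols)))]
  stim <- df[s_cols]
  resp <- df[r_cols]
  if (length(s_cols) == 1L) stim <- stim[[1]]
  if (length(r_cols) == 1L) resp <- resp[[1]]
  trial_data(stim, resp)
}

#' @rdname read_trials
#' @param data a [trial_data()] object.
#' @return `write_trials()`: the path, invisibly.
#' @export
write_trials <- function(data, path) {
  stopifnot(inherits(data, "trial_data"))
  stim <- record_columns(data$stimuli, "s")
  resp <- record_columns(data$responses, "r")
  df <- cbind(
    data.frame(trial = seq_len(data$n_trials)),
    stim, resp
  )
  # serialize doubles losslessly
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

record_columns <- function(records, prefix) {
  k <- length(records[[1]])
  cols <- lapply(seq_len(k), function(j) {
    vapply(records, function(r) r[[j]], records[[1]][[j]])
  })
  names(cols) <- paste0(prefix, seq_len(k))
  as.data.frame(cols)
}

#' Read and validate a run configuration
#'
#' Run configurations are JSON objects.  The schema is strict: unknown
#' keys are rejected with an error listing them, so typos cannot silently
#' change a run.
#'
#' @param path JSON file path (or a pre-parsed list).
#' @param allowed character vector of permitted top-level keys.
#' @return the validated configuration list.
#' @export
read_run_config <- function(path,
                            allowed = c(
                              "model", "params", "settings", "n_settings",
                              "datasets_per_setting", "arms", "task",
                              "opts", "seed", "n_trials"
                            )) {
  cfg <- if (is.character(path)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  } else {
    path
  }
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) {
    stop(
      "config schema error: unknown key(s): ",
      paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  cfg
}
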