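#' Trial-indexed single-channel voltage epochs
#'
#' Container for a set of equally long single-channel voltage traces with a
#' shared time axis relative to a lock event, plus the linked rows of the
#' events table.
#'
#' @param data Numeric matrix, trials x samples (microvolts).
#' @param times Numeric vector of sample times (s) relative to the lock event;
#'   length must equal \code{ncol(data)}.
#' @param fs Sampling rate in Hz.
#' @param lock Lock event, \code{"stimulus"} or \code{"response"}.
#' @param events Data frame with one row per trial (see
#'   \code{\link{validate_events}} for the expected columns).
#' @return An object of class \code{epoch_set}.
#' @export
epoch_set <- function(data, times, fs, lock = c("stimulus", "response"),
                      events = NULL) {
  lock <- match.arg(lock)
  data <- as.matrix(data)
  if (length(times) != ncol(data))
    stop("length(times) must equal ncol(data)")
  if (!is.null(events) && nrow(events) != nrow(data))
    stop("events must have one row per trial")
  structure(list(data = data, times = as.numeric(times), fs = fs,
                 lock = lock, events = events),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat("<epoch_set> ", nrow(x$data), " trials x ", ncol(x$data),
      " samples @ ", x$fs, " Hz, ", sprintf("%.2f", x$times[1]), "..",
      sprintf("%.2f", x$times[length(x$times)]), " s (", x$lock,
      "-locked)\n", sep = "")
  invisible(x)
}

#' Subset an epoch_set by trial
#' @param x An \code{epoch_set}.
#' @param i Trial indices (integer or logical).
#' @param ... Ignored.
#' @export
`[.epoch_set` <- function(x, i, ...) {
  epoch_set(x$data[i, , drop = FALSE], x$times, x$fs, x$lock,
            if (!is.null(x$events)) x$events[i, , drop = FALSE])
}

.conditions_old <- c("AR", "IR", "M")

#' Validate an events table
#'
#' Checks the per-trial events table contract: required columns, unique
#' (participant, trial, phase) keys, condition/phase consistency (AR/IR/M only
#' for old retrieval or encoding items, CR only for new retrieval items) and
#' response latencies in (0, 5] s or missing.
#'
#' @param events Data frame with columns \code{participant}, \code{trial},
#'   \code{phase} (\code{encoding}/\code{retrieval}), \code{condition}
#'   (\code{AR}/\code{IR}/\code{M}/\code{CR}), \code{association},
#'   \code{block_type} (\code{colour}/\code{scene}), \code{rt_s},
#'   \code{old_new} and \code{is_artifact}.
#' @param rt_max Upper response-latency limit in seconds.
#' @return The validated data frame, invisibly usable downstream.
#' @export
validate_events <- function(events, rt_max = 5) {
  req <- c("participant", "trial", "phase", "condition", "association",
           "block_type", "rt_s", "old_new", "is_artifact")
  miss <- setdiff(req, names(events))
  if (length(miss)) stop("events table missing columns: ",
                         paste(miss, collapse = ", "))
  if (!all(events$phase %in% c("encoding", "retrieval")))
    stop("phase must be 'encoding' or 'retrieval'")
  key <- paste(events$participant, events$trial, events$phase)
  if (anyDuplicated(key)) stop("(participant, trial, phase) must be unique")
  if (!all(events$condition %in% c(.conditions_old, "CR")))
    stop("unknown condition label")
  if (any(events$condition == "CR" & events$old_new != "new"))
    stop("CR trials must be new items")
  if (any(events$condition %in% .conditions_old & events$old_new != "old"))
    stop("AR/IR/M trials must be old items")
  if (any(events$condition == "CR" & events$phase == "encoding"))
    stop("new items cannot appear at encoding")
  rt <- events$rt_s[!is.na(events$rt_s)]
  if (any(rt <= 0 | rt > rt_max))
    stop("response latencies must lie in (0, ", rt_max, "] s")
  events
}

#' Write / read an events table as CSV
#'
#' @param events Events data frame (see \code{\link{validate_events}}).
#' @param path File path.
#' @return \code{read_events_csv} returns the validated data frame.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(validate_events(events), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  validate_events(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Save / load a generated dataset
#'
#' Persists the list returned by \code{\link{generate_dataset}} (epoch sets,
#' events table and ground truth) using R serialization. The events table can
#' additionally be exported as CSV via \code{\link{write_events_csv}}.
#'
#' @param dataset A dataset list.
#' @param path File path (.rds).
#' @export
save_dataset <- function(dataset, path) {
  saveRDS(dataset, path)
  invisible(path)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(path) readRDS(path)
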