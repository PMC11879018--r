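# Events, trace and config file formats shared across modules.

#' Lay out a behaviour record on a scanner timeline
#'
#' Converts a `behavior_record` into a BIDS-style events table. Each
#' trial runs fixation (0.5 s), decision (the recorded response time,
#' up to 3 s), feedback, and a jittered inter-trial interval (mean
#' 2 s, stored in the record). The event `onset` is the bag drop (at
#' the response), with 1 s duration; missing trials (no response
#' within 3 s) span the whole trial. Onsets are run-relative seconds.
#'
#' @param record A `behavior_record`.
#' @param fixation Fixation duration, seconds.
#' @param decision_max Maximum decision period, seconds.
#' @param feedback Feedback duration, seconds.
#' @return Data frame of class `events` with columns `onset`,
#'   `duration`, `trial`, `run`, `prediction`, `outcome`, `pe`,
#'   `update`, `reward`, `caught`, `missing`, `trial_start`,
#'   `trial_duration`.
#' @export
build_events <- function(record, fixation = 0.5, decision_max = 3,
                         feedback = 1) {
  n <- nrow(record)
  onset <- duration <- trial_start <- trial_duration <- numeric(n)
  for (r in unique(record$run)) {
    i <- which(record$run == r)
    t0 <- 0
    for (k in i) {
      rt <- if (record$missing[k]) decision_max else record$rt[k]
      trial_start[k] <- t0
      trial_duration[k] <- fixation + rt + feedback + record$iti[k]
      if (record$missing[k]) {
        onset[k] <- t0
        duration[k] <- trial_duration[k]
      } else {
        onset[k] <- t0 + fixation + rt
        duration[k] <- feedback
      }
      t0 <- t0 + trial_duration[k]
    }
  }
  structure(
    data.frame(onset = onset, duration = duration,
               trial = record$trial, run = record$run,
               prediction = record$prediction, outcome = record$outcome,
               pe = record$pe, update = record$update,
               reward = record$reward, caught = record$caught,
               missing = record$missing,
               trial_start = trial_start, trial_duration = trial_duration),
    class = c("events", "data.frame")
  )
}

#' Write / read events as tab-separated text
#'
#' @param events An events table from [build_events()].
#' @param path File path.
#' @return `read_events_tsv` returns the events data frame.
#' @export
write_events_tsv <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "n/a")
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  ev <- utils::read.delim(path, na.strings = "n/a")
  class(ev) <- c("events", "data.frame")
  ev
}

#' Write / read observer traces as tidy CSV
#'
#' Tidy per-trial trace keyed by subject/run/trial with columns `cpp`,
#' `ru`, `lr_model`, `belief`, `pe`.
#'
#' @param trace An `observer_trace` (or a data frame of stacked traces).
#' @param path File path.
#' @param subject Optional subject id column to prepend.
#' @return `read_trace_csv` returns the trace data frame.
#' @export
write_trace_csv <- function(trace, path, subject = NULL) {
  df <- as.data.frame(trace)
  if (!is.null(subject)) df <- cbind(subject = subject, df)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  utils::read.csv(path)
}
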