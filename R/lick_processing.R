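#' Detection parameters for the capacitance delta rule
#'
#' A touch is registered when the current sensor reading is at least
#' `delta` counts above the previous reading, and a release when it is at
#' least `delta` counts below. The default of 12 counts matches the
#' acquisition firmware this package targets.
#'
#' @param delta positive integer threshold in raw sensor counts.
#' @param sample_period seconds per sample (metadata carried for
#'   round-trip checks; the rule itself only compares consecutive readings).
#' @return a `detection_params` object.
#' @export
detection_params <- function(delta = 12L, sample_period = NULL) {
  delta <- as.integer(delta)
  if (is.na(delta) || delta < 1L) stop("delta must be >= 1", call. = FALSE)
  structure(list(delta = delta, sample_period = sample_period),
            class = "detection_params")
}

#' Convert sampled sensor readings to touch/release events
#'
#' Applies the per-sample delta rule: comparing each reading to the
#' previous one (never to a running baseline), a step of `+delta` or more
#' emits a touch, a step of `-delta` or more emits a release. Emissions are
#' forced to alternate starting from the untouched state, so consecutive
#' same-polarity crossings collapse to the first. A slow ramp whose
#' individual steps all stay below `delta` emits nothing. The event
#' timestamp is that of the triggering sample.
#'
#' @param samples data frame with columns `t` (nondecreasing seconds) and
#'   `value` (integer readings), single channel.
#' @param params a [detection_params()] object.
#' @param channel channel id stamped onto the returned events.
#' @return data frame of events: `t`, `channel`, `polarity`,
#'   `sensor_value` (the triggering reading).
#' @export
detect_transitions <- function(samples, params = detection_params(),
                               channel = 0L) {
  stopifnot(inherits(params, "detection_params"))
  t <- samples$t
  v <- samples$value
  if (length(t) && is.unsorted(t))
    stop("sample timestamps must be time-ordered", call. = FALSE)
  empty <- data.frame(t = numeric(0), channel = integer(0),
                      polarity = character(0), sensor_value = integer(0))
  if (length(v) < 2L) return(empty)
  d <- diff(v)
  cand <- which(abs(d) >= params$delta)
  if (!length(cand)) return(empty)
  pol <- d[cand] > 0  # TRUE = touch crossing
  keep <- logical(length(cand))
  touched <- FALSE
  for (k in seq_along(cand)) {
    if (pol[k] != touched) {  # only transitions out of the current state
      keep[k] <- TRUE
      touched <- pol[k]
    }
  }
  idx <- cand[keep] + 1L  # triggering sample
  data.frame(t = t[idx], channel = rep(as.integer(channel), length(idx)),
             polarity = ifelse(pol[keep], "touch", "release"),
             sensor_value = as.integer(v[idx]), stringsAsFactors = FALSE)
}

#' Pair touch/release events into licks
#'
#' Each touch followed by the next release on the same channel becomes one
#' lick with onset at the touch time and duration `release - touch`.
#' Orphans are handled conservatively (contact time is never invented):
#' a release before any touch is dropped; a second touch before a release
#' drops the earlier touch and keeps the later one (the one closest to the
#' eventual release); a touch with no release before the log ends is
#' dropped. Every drop is reported in a single warning.
#'
#' @param events time-ordered single-channel event data frame (columns `t`,
#'   `polarity`, optionally `channel`).
#' @param session_id session label stamped onto the licks.
#' @return lick data frame: `session_id`, `channel`, `onset`, `duration`,
#'   `bout_id` (`NA`, assigned later), sorted by onset.
#' @export
build_licks <- function(events, session_id = "session") {
  t <- events$t
  pol <- events$polarity
  if (length(t) && is.unsorted(t))
    stop("events must be time-ordered", call. = FALSE)
  channel <- if (!is.null(events$channel) && nrow(events) > 0L)
    events$channel[1L] else 0L
  if (!is.null(events$channel) && length(unique(events$channel)) > 1L)
    stop("build_licks expects single-channel events; split by channel first",
         call. = FALSE)
  onset <- numeric(0); duration <- numeric(0)
  pending <- NA_real_
  n_orphan_release <- 0L; n_double_touch <- 0L; n_unclosed <- 0L
  for (i in seq_along(t)) {
    if (pol[i] == "touch") {
      if (!is.na(pending)) n_double_touch <- n_double_touch + 1L
      pending <- t[i]
    } else {
      if (is.na(pending)) {
        n_orphan_release <- n_orphan_release + 1L
      } else {
        dur <- t[i] - pending
        if (dur > 0) {
          onset <- c(onset, pending)
          duration <- c(duration, dur)
        } else {
          n_orphan_release <- n_orphan_release + 1L  # zero-length contact
        }
        pending <- NA_real_
      }
    }
  }
  if (!is.na(pending)) n_unclosed <- 1L
  if (n_orphan_release + n_double_touch + n_unclosed > 0L)
    warning(sprintf(paste0("dropped events while pairing licks: %d orphan ",
                           "release(s), %d superseded touch(es), %d unclosed ",
                           "touch(es)"),
                    n_orphan_release, n_double_touch, n_unclosed),
            call. = FALSE)
  data.frame(session_id = rep(session_id, length(onset)),
             channel = rep(as.integer(channel), length(onset)),
             onset = onset, duration = duration,
             bout_id = rep(NA_integer_, length(onset)),
             stringsAsFactors = FALSE)
}

#' Filter licks by contact duration
#'
#' Retains licks with `min_duration <= duration <= max_duration`. The
#' defaults (5 ms to 10 s) are deliberately permissive: the upper bound must
#' not truncate the long non-bout contacts seen in ADH1-deficient animals.
#'
#' @param licks lick data frame from [build_licks()].
#' @param min_duration,max_duration inclusive duration bounds in seconds,
#'   `0 <= min_duration < max_duration`.
#' @return the retained licks; the number removed is attached as attribute
#'   `n_removed` and reported via `message()`.
#' @export
filter_licks <- function(licks, min_duration = 0.005, max_duration = 10) {
  if (!(min_duration >= 0 && min_duration < max_duration))
    stop("need 0 <= min_duration < max_duration", call. = FALSE)
  keep <- licks$duration >= min_duration & licks$duration <= max_duration
  n_removed <- sum(!keep)
  if (n_removed > 0L)
    message(sprintf("filter_licks: removed %d of %d lick(s) outside [%g, %g] s",
                    n_removed, nrow(licks), min_duration, max_duration))
  out <- licks[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- n_removed
  out
}
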