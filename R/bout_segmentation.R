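#' Bout segmentation parameters
#'
#' A bout initiates at the first lick of a run of `init_n` licks whose
#' consecutive inter-lick intervals are all at most `init_ili_max`
#' ("at least 3 licks within 1 second of each other"); once initiated it
#' extends to every subsequent lick arriving within `term_gap` of the
#' previous one, and terminates when the quiet gap exceeds `term_gap`
#' ("no licking for at least 3 seconds"). Boundary comparisons are
#' inclusive: an interval equal to `init_ili_max` still initiates and a gap
#' equal to `term_gap` still continues the bout.
#'
#' @param init_n minimum licks in the initiating run (>= 2).
#' @param init_ili_max maximum inter-lick interval within the initiating
#'   run, seconds.
#' @param term_gap quiet gap that terminates a bout, seconds; must be at
#'   least `init_ili_max`.
#' @return a `segmentation_params` object.
#' @export
segmentation_params <- function(init_n = 3L, init_ili_max = 1.0,
                                term_gap = 3.0) {
  init_n <- as.integer(init_n)
  if (is.na(init_n) || init_n < 2L) stop("init_n must be >= 2", call. = FALSE)
  if (!(init_ili_max > 0 && init_ili_max <= term_gap))
    stop("need 0 < init_ili_max <= term_gap", call. = FALSE)
  structure(list(init_n = init_n, init_ili_max = init_ili_max,
                 term_gap = term_gap), class = "segmentation_params")
}

#' Partition lick onsets into bouts and non-bout licks
#'
#' Single forward scan: at each lick, test whether it starts an initiating
#' run (`init_n` licks with every consecutive interval <= `init_ili_max`);
#' if so, open a bout there and extend it greedily while gaps stay within
#' `term_gap`, then resume scanning after the bout. Licks immediately
#' preceding an initiating run do not retro-join the bout even if their gap
#' to it is within `term_gap`: a bout's first lick is the first lick of its
#' initiating run. Licks belonging to no bout are non-bout licks; the bout
#' memberships and the non-bout set partition the input.
#'
#' @param onsets strictly increasing lick onset times, seconds (see
#'   [make_strictly_increasing()] for tie handling upstream).
#' @param params a [segmentation_params()] object.
#' @return object of class `bout_segmentation`: list with `bouts` (data
#'   frame `bout_id, start, end, n_licks, first_idx, last_idx`),
#'   `assignment` (integer vector over the input licks, `NA` = non-bout),
#'   `nonbout_idx`, and `params`.
#' @export
segment_bouts <- function(onsets, params = segmentation_params()) {
  stopifnot(inherits(params, "segmentation_params"))
  n <- length(onsets)
  if (n > 1L && any(diff(onsets) <= 0))
    stop("onsets must be strictly increasing", call. = FALSE)
  assignment <- rep(NA_integer_, n)
  first_idx <- integer(0); last_idx <- integer(0)
  k <- params$init_n
  if (n >= k) {
    d <- diff(onsets)
    i <- 1L
    while (i <= n - k + 1L) {
      if (all(d[i:(i + k - 2L)] <= params$init_ili_max)) {
        j <- i + k - 1L
        while (j < n && d[j] <= params$term_gap) j <- j + 1L
        first_idx <- c(first_idx, i)
        last_idx <- c(last_idx, j)
        assignment[i:j] <- length(first_idx)
        i <- j + 1L
      } else {
        i <- i + 1L
      }
    }
  }
  bouts <- data.frame(bout_id = seq_along(first_idx),
                      start = onsets[first_idx], end = onsets[last_idx],
                      n_licks = last_idx - first_idx + 1L,
                      first_idx = first_idx, last_idx = last_idx)
  structure(list(bouts = bouts, assignment = assignment,
                 nonbout_idx = which(is.na(assignment)), params = params),
            class = "bout_segmentation")
}

#' Per-lick bout membership labels
#'
#' @param licks lick data frame the segmentation was computed from.
#' @param seg a `bout_segmentation` from [segment_bouts()].
#' @return character vector, one label per lick: the bout id as a string or
#'   `"none"` for non-bout licks.
#' @export
label_licks <- function(licks, seg) {
  stopifnot(inherits(seg, "bout_segmentation"))
  n <- nrow(licks)
  if (length(seg$assignment) != n)
    stop("internal-consistency error: segmentation covers ",
         length(seg$assignment), " licks but ", n, " were supplied",
         call. = FALSE)
  if (nrow(seg$bouts) &&
      (max(seg$bouts$last_idx) > n || min(seg$bouts$first_idx) < 1L))
    stop("internal-consistency error: bout lick index out of range",
         call. = FALSE)
  if (n == 0L) return(character(0))
  ifelse(is.na(seg$assignment), "none", as.character(seg$assignment))
}

#' Segment a session's licks and attach bout identities
#'
#' Convenience wrapper: enforces strictly increasing onsets (nudging
#' duplicate timestamps by one millisecond quantum, with a warning), runs
#' [segment_bouts()], writes `bout_id` onto the lick table and builds the
#' bout table including per-bout total contact time.
#'
#' @param licks lick data frame (`session_id, channel, onset, duration`),
#'   sorted by onset.
#' @param params a [segmentation_params()] object.
#' @return list with `licks` (input plus `bout_id`), `bouts` (data frame
#'   `session_id, bout_id, start, end, n_licks, total_lick_duration`),
#'   `labels` (from [label_licks()]) and `seg`.
#' @export
assign_bouts <- function(licks, params = segmentation_params()) {
  onsets <- make_strictly_increasing(licks$onset)
  licks$onset <- onsets
  seg <- segment_bouts(onsets, params)
  licks$bout_id <- seg$assignment
  session_id <- if (nrow(licks)) licks$session_id[1L] else character(0)
  total_dur <- if (nrow(seg$bouts)) {
    vapply(seq_len(nrow(seg$bouts)), function(b)
      sum(licks$duration[seg$bouts$first_idx[b]:seg$bouts$last_idx[b]]),
      numeric(1))
  } else numeric(0)
  bouts <- data.frame(
    session_id = rep(session_id, nrow(seg$bouts)),
    bout_id = seg$bouts$bout_id, start = seg$bouts$start,
    end = seg$bouts$end, n_licks = seg$bouts$n_licks,
    total_lick_duration = total_dur, stringsAsFactors = FALSE)
  list(licks = licks, bouts = bouts, labels = label_licks(licks, seg),
       seg = seg)
}
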