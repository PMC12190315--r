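#' Temporal analysis parameters
#'
#' @param frontload_window end of the frontloading window in seconds from
#'   session start (default 1800 s = first 30 min). The window is half-open
#'   `[0, frontload_window)`: a lick at exactly the boundary counts as
#'   post-frontload.
#' @param kde_grid_points grid size for kernel-density estimates.
#' @param kde_bandwidth_rule `"scott"`, `"silverman"`, or a fixed numeric
#'   bandwidth.
#' @return a `temporal_params` object.
#' @export
temporal_params <- function(frontload_window = 1800, kde_grid_points = 512L,
                            kde_bandwidth_rule = "scott") {
  if (!(frontload_window > 0))
    stop("frontload_window must be positive", call. = FALSE)
  structure(list(frontload_window = frontload_window,
                 kde_grid_points = as.integer(kde_grid_points),
                 kde_bandwidth_rule = kde_bandwidth_rule),
            class = "temporal_params")
}

#' Split lick onsets at the frontloading boundary
#'
#' @param onsets lick onset times, seconds.
#' @param params a [temporal_params()] object.
#' @return named integer vector `c(frontload, postfrontload)`; the two
#'   counts always sum to the total.
#' @export
frontload_split <- function(onsets, params = temporal_params()) {
  w <- params$frontload_window
  c(frontload = sum(onsets < w), postfrontload = sum(onsets >= w))
}

#' Cumulative lick counts at grid points
#'
#' @param onsets lick onset times, seconds.
#' @param grid sorted evaluation time points.
#' @return integer vector: at each grid point, the number of lick onsets
#'   less than or equal to it (non-decreasing; final value is the total
#'   when the grid covers the session).
#' @export
cumulative_curve <- function(onsets, grid) {
  if (length(grid) > 1L && is.unsorted(grid))
    stop("grid must be sorted", call. = FALSE)
  findInterval(grid, sort(onsets))
}

#' Summarize one session's drinking microstructure
#'
#' Computes the per-session metrics reported for limited-access drinking:
#' total licks and total contact time, bout count, mean licks per bout,
#' mean total contact time per bout ("lick duration per bout"), the
#' percentage of licks occurring inside bouts, non-bout lick count, mean
#' single-lick durations inside and outside bouts, and the
#' frontload/post-frontload lick counts. Means over empty sets are `NA`
#' sentinels, never zero; with no bouts the in-bout percentage is 0.
#'
#' @param licks session lick data frame (`onset`, `duration`).
#' @param bouts bout table from [assign_bouts()].
#' @param labels per-lick labels from [label_licks()].
#' @param session one-row session record (needs `session_id` and
#'   `session_length`).
#' @param params a [temporal_params()] object.
#' @return one-row data frame (`microstructure_summary`).
#' @export
summarize_session <- function(licks, bouts, labels, session,
                              params = temporal_params()) {
  if (nrow(licks) != length(labels))
    stop("labels and licks disagree in length", call. = FALSE)
  len <- session$session_length
  if (nrow(licks) && (any(licks$onset < 0) || any(licks$onset > len)))
    stop("lick onset outside [0, session_length] for session ",
         session$session_id, call. = FALSE)
  total <- nrow(licks)
  in_bout <- labels != "none"
  n_bouts <- nrow(bouts)
  fl <- frontload_split(licks$onset, params)
  data.frame(
    session_id = session$session_id,
    total_licks = total,
    total_lick_duration = sum(licks$duration),
    n_bouts = n_bouts,
    licks_per_bout = if (n_bouts) mean(bouts$n_licks) else NA_real_,
    lick_duration_per_bout = if (n_bouts) mean(bouts$total_lick_duration)
                             else NA_real_,
    pct_licks_in_bouts = if (total) 100 * sum(in_bout) / total else 0,
    n_nonbout_licks = sum(!in_bout),
    mean_lick_duration_bout = if (any(in_bout)) mean(licks$duration[in_bout])
                              else NA_real_,
    mean_lick_duration_nonbout = if (any(!in_bout))
      mean(licks$duration[!in_bout]) else NA_real_,
    licks_frontload = unname(fl["frontload"]),
    licks_postfrontload = unname(fl["postfrontload"]),
    intake = NA_real_,
    stringsAsFactors = FALSE)
}

#' Pool lick-time and cumulative-count distributions by group
#'
#' For each group, pools across its sessions (a) every lick onset time and
#' (b) every within-session cumulative lick index (1, 2, ... per session),
#' the two samples compared across groups with [ks_two_sample()] and
#' visualized with [kde()].
#'
#' @param onsets_by_session list of numeric onset vectors, one per session.
#' @param groups character/factor vector of group labels, one per session;
#'   every group level must have at least one session.
#' @return named list per group: `list(times, cumulative)`.
#' @export
pooled_time_distribution <- function(onsets_by_session, groups) {
  if (length(onsets_by_session) != length(groups))
    stop("one group label per session required", call. = FALSE)
  groups <- as.factor(groups)
  if (any(table(groups) == 0L))
    stop("every group must contain at least one session", call. = FALSE)
  out <- lapply(levels(groups), function(g) {
    sess <- onsets_by_session[groups == g]
    list(times = unlist(lapply(sess, as.numeric), use.names = FALSE),
         cumulative = unlist(lapply(sess, seq_along), use.names = FALSE))
  })
  names(out) <- levels(groups)
  out
}
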