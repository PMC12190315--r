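#' Genotype phenotype presets for the session generator
#'
#' Parameters of the generative model of a drinking session: bout anchors
#' from a piecewise-constant-intensity Poisson process over the session
#' segments 0-30, 30-120, 120-150 and 150-240 min; bout sizes from a
#' shifted geometric (minimum 1 lick); within-bout inter-lick intervals
#' from a gamma truncated at the bout-initiation interval (about 7 Hz
#' licking, so generated bouts of size >= 3 are detectable by
#' construction); isolated licks from a homogeneous Poisson process, placed
#' farther than the termination gap from every other lick; lognormal
#' contact durations attached by bout membership; and a linear
#' intake-to-blood-ethanol relation.
#'
#' The `adh1_ko` preset differs from `wild_type` by a lower bout rate
#' overall (with an elevated 120-150 min segment), fewer licks per bout,
#' doubled non-bout contact-duration median, and a doubled blood-ethanol
#' accumulation slope; the isolated-lick rate is identical across presets.
#' The `saccharin` preset is a single parameter set used for both genotypes
#' (no genotype differences when drinking saccharin). All absolute values
#' are declared package defaults; only the ratios just listed are anchored
#' to the phenotype contrasts the generator emulates.
#'
#' @param preset `"wild_type"`, `"adh1_ko"` or `"saccharin"`.
#' @return a `phenotype_params` list; see Details for fields.
#' @export
make_phenotype <- function(preset = c("wild_type", "adh1_ko", "saccharin")) {
  preset <- match.arg(preset)
  base <- list(
    preset = preset,
    segment_bounds = c(0, 1800, 7200, 9000, 14400),  # seconds
    bout_rate = c(14, 5, 4, 3),                      # bouts/hour per segment
    bout_size_mean = 30,                             # licks (shifted geometric)
    within_ili_mean = 0.15, within_ili_shape = 4,    # gamma, seconds
    bout_lick_duration_median = 0.05,
    bout_lick_duration_sigma = 0.3,                  # lognormal, seconds
    isolated_lick_rate = 20,                         # licks/hour
    nonbout_lick_duration_median = 0.05,
    nonbout_lick_duration_sigma = 0.4,
    volume_per_lick_ul = 1.5, volume_per_lick_sd_ul = 0.3,
    bec_slope = 40,                                  # conc per g/kg
    bec_noise_sd = 10, intake_noise_sd = 0.15)
  if (preset == "adh1_ko") {
    base$bout_rate <- c(7, 4.3, 8, 2)
    base$bout_size_mean <- 20
    base$nonbout_lick_duration_median <- 0.10
    base$bec_slope <- 80
  }
  structure(base, class = "phenotype_params")
}

#' Simulate one session's lick train
#'
#' Draws bout anchors from the piecewise Poisson process, populates each
#' bout (size ~ shifted geometric, inter-lick intervals ~ truncated gamma,
#' durations ~ lognormal), drops bouts that would start within the
#' termination gap of the previous bout (so generated bouts stay disjoint
#' and recoverable), then places isolated licks uniformly, rejecting
#' positions within the termination gap of any existing lick. All licks lie
#' inside `[0, session_length]`; output is deterministic under `seed`.
#'
#' @param params a [make_phenotype()] parameter set.
#' @param session_length seconds (7200 for 2 h, 14400 for 4 h sessions).
#' @param seed integer seed, or `NULL` to draw from the current RNG state.
#' @param session_id label stamped onto the licks.
#' @param seg [segmentation_params()] the generated structure must respect.
#' @return lick data frame (`session_id, channel, onset, duration,
#'   bout_id`) sorted by onset, with `bout_id` the generated (true)
#'   membership (`NA` = isolated). Attribute `truth` records the generated
#'   bout count and sizes.
#' @export
simulate_session <- function(params, session_length = 7200, seed = NULL,
                             session_id = "sim", seg = segmentation_params()) {
  stopifnot(inherits(params, "phenotype_params"))
  if (!is.null(seed)) set.seed(seed)
  bounds <- params$segment_bounds
  # bout anchors, piecewise-constant intensity
  anchors <- numeric(0)
  for (s in seq_len(length(bounds) - 1L)) {
    lo <- min(bounds[s], session_length)
    hi <- min(bounds[s + 1L], session_length)
    if (hi <= lo) next
    nb <- rpois(1L, params$bout_rate[s] * (hi - lo) / 3600)
    if (nb > 0L) anchors <- c(anchors, runif(nb, lo, hi))
  }
  anchors <- sort(anchors)
  cap <- pgamma(seg$init_ili_max, shape = params$within_ili_shape,
                rate = params$within_ili_shape / params$within_ili_mean)
  onset <- numeric(0); duration <- numeric(0); bout_id <- integer(0)
  truth_sizes <- integer(0)
  prev_end <- -Inf
  n_kept <- 0L
  for (a in anchors) {
    size <- 1L + rgeom(1L, 1 / params$bout_size_mean)
    ili <- if (size > 1L) {
      qgamma(runif(size - 1L, 0, cap), shape = params$within_ili_shape,
             rate = params$within_ili_shape / params$within_ili_mean)
    } else numeric(0)
    on <- a + c(0, cumsum(ili))
    dur <- rlnorm(size, log(params$bout_lick_duration_median),
                  params$bout_lick_duration_sigma)
    # contacts cannot overlap the next lick: cap each duration at 90% of
    # the interval to the next onset
    if (size > 1L) dur[-size] <- pmin(dur[-size], 0.9 * ili)
    ok <- on + dur <= session_length
    on <- on[ok]; dur <- dur[ok]
    if (!length(on)) next
    if (on[1L] <= prev_end + seg$term_gap + 0.5) next  # keep bouts disjoint
    n_kept <- n_kept + 1L
    onset <- c(onset, on); duration <- c(duration, dur)
    bout_id <- c(bout_id, rep(n_kept, length(on)))
    truth_sizes <- c(truth_sizes, length(on))
    prev_end <- on[length(on)]
  }
  # isolated licks, rejected if within term_gap of any existing lick
  n_iso <- rpois(1L, params$isolated_lick_rate * session_length / 3600)
  budget <- 100L * n_iso + 1000L
  placed <- 0L
  if (n_iso > 0L) {
    while (placed < n_iso) {
      if (budget <= 0L)
        stop("isolated-lick rejection budget exhausted; lower the rates",
             call. = FALSE)
      budget <- budget - 1L
      dur <- rlnorm(1L, log(params$nonbout_lick_duration_median),
                    params$nonbout_lick_duration_sigma)
      if (dur >= session_length) next
      cand <- runif(1L, 0, session_length - dur)
      if (length(onset) == 0L || min(abs(cand - onset)) > seg$term_gap) {
        onset <- c(onset, cand); duration <- c(duration, dur)
        bout_id <- c(bout_id, NA_integer_)
        placed <- placed + 1L
      }
    }
  }
  ord <- order(onset)
  licks <- data.frame(session_id = rep(session_id, length(onset)),
                      channel = rep(0L, length(onset)),
                      onset = onset[ord], duration = duration[ord],
                      bout_id = bout_id[ord], stringsAsFactors = FALSE)
  attr(licks, "truth") <- list(n_bouts = n_kept, bout_sizes = truth_sizes,
                               n_isolated = placed, preset = params$preset)
  licks
}

#' Synthesize a raw capacitance trace from known licks
#'
#' A baseline-valued series sampled at `sample_period`, stepped up by
#' `amplitude` counts over each lick's `[onset, onset + duration)`
#' interval, with optional integer jitter (rounded Gaussian, clamped to
#' +/- 5 counts so that consecutive-sample steps always stay below the
#' default detection delta of 12). Running [detect_transitions()] then
#' [build_licks()] on the output recovers every lick's onset and duration
#' to within one sample period; with `amplitude >= delta + 10` this holds
#' under jitter as well.
#'
#' @param licks non-overlapping lick data frame (`onset`, `duration`).
#' @param sample_period seconds per sample.
#' @param baseline resting sensor reading, integer counts.
#' @param amplitude added counts during contact; must be at least the
#'   detection delta.
#' @param jitter_sd standard deviation of the sub-delta jitter (0 = none).
#' @param seed integer seed, or `NULL`.
#' @param span trace length in seconds; default covers the last lick plus
#'   one second.
#' @return data frame with `t`, `channel`, `value`.
#' @export
simulate_raw_signal <- function(licks, sample_period = 0.001,
                                baseline = 100L, amplitude = 30L,
                                jitter_sd = 0, seed = NULL, span = NULL) {
  if (!is.null(seed)) set.seed(seed)
  onset <- licks$onset; duration <- licks$duration
  if (length(onset)) {
    ord <- order(onset)
    onset <- onset[ord]; duration <- duration[ord]
    if (length(onset) > 1L &&
        any(onset[-1L] < (onset + duration)[-length(onset)]))
      stop("licks overlap; cannot synthesize a single-channel trace",
           call. = FALSE)
  }
  if (is.null(span))
    span <- if (length(onset)) max(onset + duration) + 1 else 1
  t <- seq(0, span, by = sample_period)
  value <- rep(as.integer(baseline), length(t))
  for (i in seq_along(onset)) {
    idx <- which(t >= onset[i] & t < onset[i] + duration[i])
    value[idx] <- value[idx] + as.integer(amplitude)
  }
  if (jitter_sd > 0) {
    j <- pmin(pmax(round(rnorm(length(t), 0, jitter_sd)), -5L), 5L)
    value <- value + as.integer(j)
  }
  data.frame(t = t, channel = rep(0L, length(t)), value = value)
}

#' Cohort specification for the generator
#'
#' @param n_per_group animals per group.
#' @param session_length seconds.
#' @param groups named list mapping group label (used as the genotype) to a
#'   [make_phenotype()] parameter set.
#' @param seed integer; identical specs yield identical cohorts.
#' @param body_mass_mean,body_mass_sd grams.
#' @param fluid manifest fluid label (see [fluid_spec_for()]).
#' @param bottle_mass_pre pre-session bottle mass, grams.
#' @param n_days sessions per animal (repeated-measures designs need
#'   `n_days >= 2` for an identified per-animal random intercept).
#' @return a `cohort_spec` object.
#' @export
cohort_spec <- function(n_per_group = 12L, session_length = 7200,
                        groups = list(wild_type = make_phenotype("wild_type"),
                                      adh1_ko = make_phenotype("adh1_ko")),
                        seed = 1L, body_mass_mean = 25, body_mass_sd = 2.5,
                        fluid = "ethanol20", bottle_mass_pre = 45,
                        n_days = 1L) {
  if (n_per_group < 1L) stop("n_per_group must be >= 1", call. = FALSE)
  if (n_days < 1L) stop("n_days must be >= 1", call. = FALSE)
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop("groups must be a named list", call. = FALSE)
  structure(list(n_per_group = as.integer(n_per_group),
                 session_length = session_length, groups = groups,
                 seed = as.integer(seed), body_mass_mean = body_mass_mean,
                 body_mass_sd = body_mass_sd, fluid = fluid,
                 bottle_mass_pre = bottle_mass_pre,
                 n_days = as.integer(n_days)), class = "cohort_spec")
}

#' Simulate a full cohort: lick trains, manifest and blood ethanol
#'
#' Per animal: a session lick train from [simulate_session()]; consumed
#' volume as the sum of per-lick volumes (Gaussian, truncated at 0);
#' ethanol intake in g/kg with Gaussian noise added; bottle masses obtained
#' by inverting the [compute_intake()] conversion, so the manifest
#' reproduces the intake exactly; and blood ethanol
#' `bec = bec_slope * intake + noise`. For fluids without ethanol the
#' bottle-mass difference is taken from the consumed volume directly and
#' `bec` is `NA`. Fully deterministic under the spec seed.
#'
#' @param spec a [cohort_spec()].
#' @return object of class `lick_cohort`: list with `manifest` (session
#'   records including `bec`), `licks` (named list of per-session lick data
#'   frames), `truth` (per-session generator ground truth) and `spec`.
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  fluid <- fluid_spec_for(spec$fluid)
  rows <- list(); lick_list <- list(); truth <- list()
  for (g in names(spec$groups)) {
    params <- spec$groups[[g]]
    for (a in seq_len(spec$n_per_group)) {
      aid <- sprintf("%s_%02d", g, a)
      repeat {
        body <- rnorm(1L, spec$body_mass_mean, spec$body_mass_sd)
        if (body > 5) break
      }
      for (day in seq_len(spec$n_days)) {
        sid <- if (spec$n_days == 1L) aid else sprintf("%s_d%d", aid, day)
        licks <- simulate_session(params, spec$session_length, seed = NULL,
                                  session_id = sid)
        vol_ml <- sum(pmax(rnorm(nrow(licks), params$volume_per_lick_ul,
                                 params$volume_per_lick_sd_ul), 0)) / 1000
        if (fluid$ethanol_vol_fraction > 0) {
          base_intake <- vol_ml * fluid$ethanol_vol_fraction *
            fluid$ethanol_density / (body / 1000)
          intake <- max(base_intake + rnorm(1L, 0, params$intake_noise_sd), 0)
          mass_diff <- intake * (body / 1000) /
            (fluid$ethanol_vol_fraction * fluid$ethanol_density) *
            fluid$solution_density
          bec <- params$bec_slope * intake + rnorm(1L, 0, params$bec_noise_sd)
        } else {
          mass_diff <- vol_ml * fluid$solution_density
          bec <- NA_real_
        }
        rows[[sid]] <- data.frame(
          session_id = sid, animal_id = aid, genotype = g,
          sex = if (a %% 2L) "F" else "M", fluid = spec$fluid,
          session_length = spec$session_length,
          bottle_mass_pre = spec$bottle_mass_pre,
          bottle_mass_post = spec$bottle_mass_pre - mass_diff,
          body_mass = body, day_index = day, bec = bec,
          stringsAsFactors = FALSE)
        lick_list[[sid]] <- licks
        truth[[sid]] <- attr(licks, "truth")
      }
    }
  }
  structure(list(manifest = do.call(rbind, c(rows, make.row.names = FALSE)),
                 licks = lick_list, truth = truth, spec = spec),
            class = "lick_cohort")
}

#' Expand licks into touch/release events
#'
#' The inverse of [build_licks()]: each lick yields a touch at its onset
#' and a release at `onset + duration`. Used when writing event-dialect
#' logs for synthetic cohorts.
#'
#' @param licks lick data frame.
#' @return event data frame (`t, channel, polarity, sensor_value`).
#' @export
licks_to_events <- function(licks) {
  n <- nrow(licks)
  if (n == 0L)
    return(data.frame(t = numeric(0), channel = integer(0),
                      polarity = character(0), sensor_value = integer(0)))
  ev <- data.frame(
    t = c(rbind(licks$onset, licks$onset + licks$duration)),
    channel = rep(licks$channel, each = 2L),
    polarity = rep(c("touch", "release"), n),
    sensor_value = NA_integer_, stringsAsFactors = FALSE)
  ev[order(ev$t), , drop = FALSE]
}

#' Write a synthetic cohort to disk
#'
#' Writes `manifest.csv`, one event-dialect log per session
#' (`logs/<session_id>.csv`, columns `t, channel, polarity, sensor_value`
#' with header) and `truth.json` carrying the generator ground truth.
#'
#' @param cohort a `lick_cohort` from [simulate_cohort()].
#' @param out_dir output directory, created if needed.
#' @return named list of written paths, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "lick_cohort"))
  log_dir <- file.path(out_dir, "logs")
  dir.create(log_dir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(out_dir, "manifest.csv")
  write.csv(cohort$manifest, manifest_path, row.names = FALSE)
  log_paths <- vapply(names(cohort$licks), function(sid) {
    p <- file.path(log_dir, paste0(sid, ".csv"))
    write.csv(licks_to_events(cohort$licks[[sid]]), p, row.names = FALSE)
    p
  }, character(1))
  truth_path <- file.path(out_dir, "truth.json")
  jsonlite::write_json(cohort$truth, truth_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(list(manifest = manifest_path, logs = log_paths,
                 truth = truth_path))
}
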