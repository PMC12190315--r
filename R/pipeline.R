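#' Process an in-memory cohort into a per-session summary table
#'
#' Runs the full processing chain (duration filter, bout segmentation,
#' microstructure summary, intake conversion) on a simulated or loaded
#' cohort and returns one row per session, joined with the session
#' metadata. This is the in-memory counterpart of [run_process()].
#'
#' @param cohort a `lick_cohort` from [simulate_cohort()], or any list with
#'   `manifest` and a named list `licks` keyed by `session_id`.
#' @param seg [segmentation_params()].
#' @param temporal [temporal_params()].
#' @param min_duration,max_duration lick duration filter bounds, seconds.
#' @return list with `summaries` (one row per session: microstructure
#'   metrics, intake, metadata), `licks` (processed lick table with bout
#'   labels, all sessions), `bouts` (bout table, all sessions).
#' @export
process_cohort <- function(cohort, seg = segmentation_params(),
                           temporal = temporal_params(),
                           min_duration = 0.005, max_duration = 10) {
  manifest <- cohort$manifest
  sum_rows <- list(); lick_tabs <- list(); bout_tabs <- list()
  for (i in seq_len(nrow(manifest))) {
    sess <- manifest[i, , drop = FALSE]
    sid <- sess$session_id
    licks <- cohort$licks[[sid]]
    if (is.null(licks))
      stop("no licks for session_id ", sid, call. = FALSE)
    licks <- filter_licks(licks, min_duration, max_duration)
    ab <- assign_bouts(licks, seg)
    sm <- summarize_session(ab$licks, ab$bouts, ab$labels, sess, temporal)
    fl <- fluid_spec_for(sess$fluid)
    # ethanol sessions: ethanol dose in g/kg; saccharin/water sessions:
    # consumed solution mass in grams (no per-kg dosing is involved), so
    # intake-vs-behavior models remain meaningful for any fluid
    sm$intake <- if (fl$ethanol_vol_fraction > 0) {
      compute_intake(sess, fl)
    } else {
      sess$bottle_mass_pre - sess$bottle_mass_post
    }
    sm$animal_id <- sess$animal_id
    sm$genotype <- sess$genotype
    sm$sex <- sess$sex
    sm$fluid <- sess$fluid
    sm$day_index <- sess$day_index
    sm$bec <- sess$bec
    sum_rows[[sid]] <- sm
    lick_tabs[[sid]] <- ab$licks
    bout_tabs[[sid]] <- ab$bouts
  }
  list(summaries = do.call(rbind, c(sum_rows, make.row.names = FALSE)),
       licks = do.call(rbind, c(lick_tabs, make.row.names = FALSE)),
       bouts = do.call(rbind, c(bout_tabs, make.row.names = FALSE)))
}

.CONFIG_KEYS <- c("paths", "detection", "licks", "bout", "temporal", "fluid",
                  "pk", "stats", "simulate", "seed", "log_level")

#' Read and validate a pipeline configuration
#'
#' JSON key-value file with sections mirroring the module parameters
#' (`paths`, `detection`, `licks`, `bout`, `temporal`, `fluid`, `pk`,
#' `stats`, `simulate`) plus `seed` and `log_level`. Unknown top-level keys
#' are rejected, and parameter invariants (for example
#' `bout.init_ili_max_s <= bout.term_gap_s`) are validated here, before any
#' processing starts.
#'
#' @param path path to the JSON config.
#' @return validated config list of class `pipeline_config`, with parameter
#'   objects attached (`$seg`, `$temporal`, `$detection`).
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("cannot read config '", path, "'",
                               call. = FALSE)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(cfg), .CONFIG_KEYS)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  bout <- cfg$bout %||% list()
  cfg$seg <- segmentation_params(
    init_n = bout$init_n %||% 3L,
    init_ili_max = bout$init_ili_max_s %||% 1.0,
    term_gap = bout$term_gap_s %||% 3.0)
  tmp <- cfg$temporal %||% list()
  cfg$temporal_params <- temporal_params(
    frontload_window = tmp$frontload_window_s %||% 1800,
    kde_grid_points = tmp$kde_grid_points %||% 512L,
    kde_bandwidth_rule = tmp$kde_bandwidth_rule %||% "scott")
  det <- cfg$detection %||% list()
  cfg$detection_params <- detection_params(delta = det$delta %||% 12L)
  lk <- cfg$licks %||% list()
  cfg$min_duration <- lk$min_duration_s %||% 0.005
  cfg$max_duration <- lk$max_duration_s %||% 10
  if (!(cfg$min_duration >= 0 && cfg$min_duration < cfg$max_duration))
    stop("config: need 0 <= licks.min_duration_s < licks.max_duration_s",
         call. = FALSE)
  cfg$config_path <- path
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Process on-disk logs into lick, bout and summary tables
#'
#' Reads the manifest and one log per session
#' (`<paths$log_dir>/<session_id>.csv`), applies the detection rule when
#' the dialect is `"samples"`, builds and filters licks, segments bouts,
#' summarizes each session and converts intake; writes the three tables
#' via [write_tables()] to `paths$out_dir` along with a run-manifest JSON
#' recording the config hash, package version and per-stage record counts.
#' Any stage error is annotated with the stage and session id.
#'
#' @param config a `pipeline_config` from [read_pipeline_config()], or a
#'   path to one. Requires `paths$manifest`, `paths$log_dir`,
#'   `paths$out_dir` and optionally `paths$dialect` (`"events"`, default,
#'   or `"samples"`).
#' @return the [process_cohort()] result, invisibly, with `$paths` of the
#'   written files attached.
#' @export
run_process <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  paths <- config$paths
  if (is.null(paths$manifest) || is.null(paths$log_dir) ||
      is.null(paths$out_dir))
    stop("config paths must include manifest, log_dir, out_dir",
         call. = FALSE)
  manifest <- read_session_manifest(paths$manifest)
  fmt <- paths$dialect %||% "events"
  dialect <- event_dialect(format = fmt)
  lick_list <- list()
  counts <- list()
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$session_id[i]
    log_path <- file.path(paths$log_dir, paste0(sid, ".csv"))
    res <- tryCatch({
      if (fmt == "samples") {
        samples <- read_sample_log(log_path, dialect)
        ev <- detect_transitions(samples, config$detection_params,
                                 channel = samples$channel[1] %||% 0L)
      } else {
        ev <- read_event_log(log_path, dialect)
      }
      ch0 <- ev[ev$channel == (config$channel %||% 0L), , drop = FALSE]
      licks <- build_licks(ch0, session_id = sid)
      list(events = nrow(ev), licks = licks)
    }, error = function(e)
      stop("stage 'lick_processing', session_id ", sid, ": ",
           conditionMessage(e), call. = FALSE))
    lick_list[[sid]] <- res$licks
    counts[[sid]] <- list(n_events = res$events, n_licks_raw = nrow(res$licks))
  }
  cohort <- list(manifest = manifest, licks = lick_list)
  out <- process_cohort(cohort, seg = config$seg,
                        temporal = config$temporal_params,
                        min_duration = config$min_duration,
                        max_duration = config$max_duration)
  written <- write_tables(out$licks, out$bouts, out$summaries, paths$out_dir)
  for (sid in names(counts)) {
    kept <- sum(out$licks$session_id == sid)
    counts[[sid]]$n_licks_kept <- kept
    counts[[sid]]$n_licks_filtered <- counts[[sid]]$n_licks_raw - kept
    counts[[sid]]$n_bouts <- sum(out$bouts$session_id == sid)
  }
  run_manifest <- list(
    package_version = as.character(packageVersion("lickometry")),
    config_hash = if (!is.null(config$config_path))
      unname(tools::md5sum(config$config_path)) else NA_character_,
    n_sessions = nrow(manifest), counts = counts)
  rm_path <- file.path(paths$out_dir, "run_manifest.json")
  jsonlite::write_json(run_manifest, rm_path, auto_unbox = TRUE, digits = NA)
  out$paths <- c(written, run_manifest = rm_path)
  invisible(out)
}

.analysis_block <- function(expr, skip_msg = NULL) {
  tryCatch(expr, error = function(e) {
    warning(skip_msg %||% conditionMessage(e), call. = FALSE)
    list(skipped = TRUE, reason = skip_msg %||% conditionMessage(e))
  })
}

.mixed_fit_report <- function(fit) {
  list(coefficients = as.list(fit$coefficients),
       interaction = fit$interaction_test,
       random_effect_variance = fit$random_effect_variance,
       residual_variance = fit$residual_variance,
       n_obs = fit$n_obs, n_groups = fit$n_groups, df_method = fit$df_method)
}

#' Group-level statistical report for a processed cohort
#'
#' Produces the six analysis blocks of the standard report:
#' `intake_models` (linear mixed models of intake against total licks,
#' total lick duration and bout number, each crossed with genotype, random
#' intercept per animal), `ks_time` and `ks_cumulative` (two-sample KS
#' comparisons of the pooled lick-time and within-session cumulative-count
#' distributions by genotype), `frontloading` (group location tests of
#' frontload and post-frontload lick counts), `bout_duration_anova`
#' (genotype x bout-type mixed ANOVA of mean single-lick durations) and
#' `accumulation` (per-genotype blood-ethanol-vs-intake slopes and their
#' ratio). Blocks whose requirements are unmet (single genotype, missing
#' `bec`, missing bout/non-bout cells) are skipped with a warning rather
#' than failing the report.
#'
#' @param summaries per-session summary table from [process_cohort()] /
#'   [run_process()] (needs `genotype`, `animal_id`, `intake`, the
#'   microstructure columns, optionally `bec`).
#' @param licks processed lick table with `bout_id` labels (for the KS and
#'   duration blocks); may be `NULL`, skipping those blocks.
#' @param ratio_groups length-2 character vector
#'   `c(numerator, denominator)` for the slope ratio.
#' @param out optional path for the JSON report.
#' @return report list of class `lick_report`, invisibly when written.
#' @export
run_analyze <- function(summaries, licks = NULL,
                        ratio_groups = c("adh1_ko", "wild_type"),
                        out = NULL) {
  genos <- unique(summaries$genotype)
  two_groups <- length(genos) >= 2L
  report <- list()

  report$intake_models <- if (!two_groups) {
    warning("single genotype: intake models skipped", call. = FALSE)
    list(skipped = TRUE, reason = "single genotype")
  } else {
    preds <- c(licks = "total_licks", lick_duration = "total_lick_duration",
               bouts = "n_bouts")
    lapply(preds, function(p) .analysis_block({
      fit <- fit_mixed_model(summaries, "intake",
                             c(p, "genotype", paste0(p, ":genotype")),
                             grouping = "animal_id")
      .mixed_fit_report(fit)
    }))
  }

  if (!is.null(licks) && two_groups) {
    sess_split <- split(licks$onset, licks$session_id)
    sess_geno <- summaries$genotype[match(names(sess_split),
                                          summaries$session_id)]
    pooled <- pooled_time_distribution(sess_split, sess_geno)
    report$ks_time <- .analysis_block(
      ks_two_sample(pooled[[genos[1]]]$times, pooled[[genos[2]]]$times))
    report$ks_cumulative <- .analysis_block(
      ks_two_sample(pooled[[genos[1]]]$cumulative,
                    pooled[[genos[2]]]$cumulative))
  } else {
    if (two_groups)
      warning("no lick table: KS blocks skipped", call. = FALSE)
    report$ks_time <- report$ks_cumulative <-
      list(skipped = TRUE,
           reason = if (two_groups) "no lick table" else "single genotype")
  }

  report$frontloading <- if (!two_groups) {
    list(skipped = TRUE, reason = "single genotype")
  } else .analysis_block({
    a <- summaries[summaries$genotype == ratio_groups[2], ]
    b <- summaries[summaries$genotype == ratio_groups[1], ]
    list(frontload = location_test(a$licks_frontload, b$licks_frontload),
         postfrontload = location_test(a$licks_postfrontload,
                                       b$licks_postfrontload))
  })

  report$bout_duration_anova <- if (!two_groups || is.null(licks)) {
    list(skipped = TRUE,
         reason = if (two_groups) "no lick table" else "single genotype")
  } else .analysis_block({
    lk <- licks
    lk$bout_type <- ifelse(is.na(lk$bout_id), "nonbout", "bout")
    lk$animal_id <- summaries$animal_id[match(lk$session_id,
                                              summaries$session_id)]
    lk$genotype <- summaries$genotype[match(lk$session_id,
                                            summaries$session_id)]
    per <- aggregate(duration ~ animal_id + genotype + bout_type, data = lk,
                     FUN = mean)
    mixed_anova(per, dv = "duration", within = "bout_type",
                between = "genotype", subject = "animal_id")
  }, skip_msg = "bout-duration ANOVA skipped (incomplete bout/non-bout cells)")

  has_bec <- "bec" %in% names(summaries) && any(!is.na(summaries$bec))
  report$accumulation <- if (!has_bec) {
    warning("missing bec values: accumulation block skipped", call. = FALSE)
    list(skipped = TRUE, reason = "missing bec")
  } else if (!two_groups) {
    list(skipped = TRUE, reason = "single genotype")
  } else .analysis_block({
    ok <- !is.na(summaries$bec)
    fits <- fit_accumulation(summaries$intake[ok], summaries$bec[ok],
                             summaries$genotype[ok])
    sr <- slope_ratio(fits, ratio_groups[1], ratio_groups[2],
                      data = data.frame(intake = summaries$intake[ok],
                                        bec = summaries$bec[ok],
                                        group = summaries$genotype[ok]),
                      seed = 1L)
    list(fits = fits, slope_ratio = sr)
  })

  report <- structure(report, class = c("lick_report", "list"))
  if (!is.null(out)) {
    jsonlite::write_json(lapply(report, unclass), out, auto_unbox = TRUE,
                         digits = NA, na = "null", force = TRUE)
    return(invisible(report))
  }
  report
}

#' Render a human-readable summary of an analysis report
#'
#' @param report a `lick_report` from [run_analyze()].
#' @param file connection or path for [cat()]; default stdout.
#' @return the report, invisibly.
#' @export
run_report <- function(report, file = "") {
  line <- function(...) cat(sprintf(...), "\n", sep = "", file = file,
                            append = TRUE)
  fmt_p <- function(p) format(p, digits = 4)
  line("== Drinking microstructure report ==")
  for (nm in names(report$intake_models %||% list())) {
    blk <- report$intake_models[[nm]]
    if (isTRUE(blk$skipped)) { line("intake ~ %s: skipped", nm); next }
    it <- blk$interaction
    line("intake ~ %s * genotype: %s F(%d,%d) = %.3f, p = %s", nm, it$term,
         it$df1, it$df2, it$F, fmt_p(it$p_value))
  }
  for (nm in c("ks_time", "ks_cumulative")) {
    blk <- report[[nm]]
    if (is.null(blk) || isTRUE(blk$skipped)) next
    line("%s: KS = %.4f, p = %s", nm, blk$statistic, fmt_p(blk$p_value))
  }
  fl <- report$frontloading
  if (!is.null(fl) && !isTRUE(fl$skipped)) {
    line("frontload licks: %s = %.3f, p = %s", fl$frontload$method,
         fl$frontload$statistic, fmt_p(fl$frontload$p_value))
    line("post-frontload licks: %s = %.3f, p = %s", fl$postfrontload$method,
         fl$postfrontload$statistic, fmt_p(fl$postfrontload$p_value))
  }
  ba <- report$bout_duration_anova
  if (!is.null(ba) && !isTRUE(ba$skipped)) {
    i <- ba$anova[3, ]
    line("genotype x bout-type ANOVA: F(%d,%d) = %.3f, p = %s", i$df1, i$df2,
         i$F, fmt_p(i$p_value))
  }
  ac <- report$accumulation
  if (!is.null(ac) && !isTRUE(ac$skipped)) {
    for (i in seq_len(nrow(ac$fits)))
      line("accumulation slope [%s]: %.3f (r^2 = %.3f, n = %d)",
           ac$fits$group[i], ac$fits$slope[i], ac$fits$r_squared[i],
           ac$fits$n[i])
    line("slope ratio: %.3f [%.3f, %.3f]", ac$slope_ratio$ratio,
         ac$slope_ratio$ci[1], ac$slope_ratio$ci[2])
  }
  invisible(report)
}
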