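#' Describe the on-disk layout of a lickometer log
#'
#' Two dialects are supported. `"events"` logs hold pre-digested
#' touch/release rows, the form the acquisition firmware writes after
#' applying its capacitance delta rule. `"samples"` logs hold raw sensor
#' readings at a fixed rate; they are consumed by [detect_transitions()],
#' which applies the delta rule in software.
#'
#' Timestamps on disk are either numeric seconds from the session start or
#' ISO datetimes; internally everything is seconds from the session start
#' (millisecond resolution), with the session epoch supplied here rather
#' than inferred from the first event.
#'
#' @param format `"events"` or `"samples"`.
#' @param delimiter field separator, default comma.
#' @param time_format `"seconds"` (numeric) or `"iso"` (datetime strings).
#' @param epoch session start, required for `"iso"` timestamps; a
#'   `POSIXct` or an ISO string parsed as UTC.
#' @param header does the file carry a header row?
#' @param columns column order; defaults to `t, channel, polarity,
#'   sensor_value` for events and `t, channel, value` for samples.
#' @return an `event_dialect` object.
#' @export
event_dialect <- function(format = c("events", "samples"), delimiter = ",",
                          time_format = c("seconds", "iso"), epoch = NULL,
                          header = TRUE, columns = NULL) {
  format <- match.arg(format)
  time_format <- match.arg(time_format)
  if (time_format == "iso") {
    if (is.null(epoch)) stop("ISO timestamps need an `epoch`", call. = FALSE)
    epoch <- .parse_iso(epoch)
    if (is.na(epoch)) stop("unparseable `epoch`", call. = FALSE)
  }
  if (is.null(columns)) {
    columns <- if (format == "events") {
      c("t", "channel", "polarity", "sensor_value")
    } else {
      c("t", "channel", "value")
    }
  }
  structure(list(format = format, delimiter = delimiter,
                 time_format = time_format, epoch = epoch,
                 header = header, columns = columns),
            class = "event_dialect")
}

.parse_iso <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  for (fmt in c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS")) {
    out <- as.POSIXct(x, format = fmt, tz = "UTC")
    if (!anyNA(out)) return(out)
  }
  as.POSIXct(rep(NA_character_, length(x)), tz = "UTC")
}

.read_raw_rows <- function(path, dialect) {
  if (!file.exists(path)) stop("cannot read '", path, "'", call. = FALSE)
  if (length(readLines(path, n = 1L, warn = FALSE)) == 0L)
    return(data.frame())
  dat <- tryCatch(
    read.csv(path, header = dialect$header, sep = dialect$delimiter,
             colClasses = "character", strip.white = TRUE,
             blank.lines.skip = FALSE),
    error = function(e) stop("cannot read '", path, "': ", conditionMessage(e),
                             call. = FALSE))
  if (nrow(dat) == 0L) return(dat)
  # drop fully blank lines but remember original line numbers
  line0 <- seq_len(nrow(dat)) + as.integer(dialect$header)
  blank <- apply(dat == "" | is.na(dat), 1L, all)
  dat <- dat[!blank, , drop = FALSE]
  attr(dat, "line") <- line0[!blank]
  dat
}

.times_to_seconds <- function(tt, dialect) {
  if (dialect$time_format == "seconds") {
    suppressWarnings(as.numeric(tt))
  } else {
    ts <- .parse_iso(tt)
    # POSIXct doubles carry ~1e-4 s noise at current epochs; the device
    # logs at millisecond precision, so round to the quantum
    round(as.numeric(ts) - as.numeric(dialect$epoch), 3L)
  }
}

.report_bad_rows <- function(bad, reason, lines, strict, what) {
  if (!any(bad)) return(invisible(NULL))
  first <- which(bad)[1L]
  msg <- sprintf("malformed %s row at line %d (%s)", what, lines[first],
                 reason[first])
  if (strict) stop(msg, call. = FALSE)
  warning(sprintf("%d malformed %s row(s) skipped; first: %s",
                  sum(bad), what, msg), call. = FALSE)
}

#' Read an event-dialect lickometer log
#'
#' Returns touch/release events in file order with timestamps converted to
#' seconds from the session start. In strict mode (default) the first
#' malformed row aborts with its line number; in lenient mode malformed rows
#' are skipped with a warning.
#'
#' @param path path to a delimited log file.
#' @param dialect an [event_dialect()] with `format = "events"`.
#' @param strict abort on the first malformed row?
#' @return data frame with columns `t` (seconds), `channel` (integer),
#'   `polarity` (`"touch"`/`"release"`) and `sensor_value` (integer, `NA`
#'   when absent), in file order.
#' @export
read_event_log <- function(path, dialect = event_dialect(), strict = TRUE) {
  stopifnot(inherits(dialect, "event_dialect"))
  if (dialect$format != "events")
    stop("dialect format must be 'events'; use read_sample_log() for samples",
         call. = FALSE)
  dat <- .read_raw_rows(path, dialect)
  empty <- data.frame(t = numeric(0), channel = integer(0),
                      polarity = character(0), sensor_value = integer(0))
  if (nrow(dat) == 0L) return(empty)
  lines <- attr(dat, "line")
  cols <- dialect$columns
  have_sensor <- length(cols) >= 4L && ncol(dat) >= 4L
  if (ncol(dat) < 3L)
    stop("event log needs at least 3 columns (t, channel, polarity)",
         call. = FALSE)
  names(dat)[seq_along(cols)[seq_len(min(ncol(dat), length(cols)))]] <-
    cols[seq_len(min(ncol(dat), length(cols)))]
  t <- .times_to_seconds(dat$t, dialect)
  channel <- suppressWarnings(as.integer(dat$channel))
  polarity <- tolower(dat$polarity)
  sensor <- if (have_sensor) suppressWarnings(as.integer(dat$sensor_value))
            else rep(NA_integer_, nrow(dat))
  bad <- is.na(t) | t < 0 | is.na(channel) | channel < 0L |
    !(polarity %in% c("touch", "release"))
  reason <- character(nrow(dat))
  reason[is.na(t)] <- "unparseable timestamp"
  reason[!is.na(t) & t < 0] <- "negative timestamp"
  reason[is.na(channel) | channel < 0L] <- "bad channel"
  reason[!(polarity %in% c("touch", "release"))] <-
    paste0("bad polarity '", dat$polarity[!(polarity %in% c("touch", "release"))], "'")
  .report_bad_rows(bad, reason, lines, strict, "event")
  keep <- !bad
  data.frame(t = t[keep], channel = channel[keep],
             polarity = polarity[keep], sensor_value = sensor[keep],
             stringsAsFactors = FALSE)
}

#' Read a samples-dialect lickometer log
#'
#' Raw sensor readings at (nominally) fixed rate, one channel per row group;
#' feed the result to [detect_transitions()].
#'
#' @inheritParams read_event_log
#' @param dialect an [event_dialect()] with `format = "samples"`.
#' @return data frame with columns `t` (seconds), `channel`, `value`
#'   (integer sensor reading), in file order.
#' @export
read_sample_log <- function(path, dialect = event_dialect(format = "samples"),
                            strict = TRUE) {
  stopifnot(inherits(dialect, "event_dialect"))
  if (dialect$format != "samples")
    stop("dialect format must be 'samples'", call. = FALSE)
  dat <- .read_raw_rows(path, dialect)
  if (nrow(dat) == 0L)
    return(data.frame(t = numeric(0), channel = integer(0), value = integer(0)))
  lines <- attr(dat, "line")
  if (ncol(dat) < 3L)
    stop("sample log needs 3 columns (t, channel, value)", call. = FALSE)
  names(dat)[1:3] <- c("t", "channel", "value")
  t <- .times_to_seconds(dat$t, dialect)
  channel <- suppressWarnings(as.integer(dat$channel))
  value <- suppressWarnings(as.integer(dat$value))
  bad <- is.na(t) | t < 0 | is.na(channel) | is.na(value)
  reason <- ifelse(is.na(t), "unparseable timestamp",
                   ifelse(!is.na(t) & t < 0, "negative timestamp", "bad field"))
  .report_bad_rows(bad, reason, lines, strict, "sample")
  keep <- !bad
  data.frame(t = t[keep], channel = channel[keep], value = value[keep])
}

.GENOTYPES <- c("wild_type", "adh1_ko")
.SEXES <- c("F", "M")
.FLUIDS <- c("ethanol20", "ethanol20_saccharin03", "saccharin01", "water")

.MANIFEST_REQUIRED <- c("session_id", "animal_id", "genotype", "sex", "fluid",
                        "session_length", "bottle_mass_pre",
                        "bottle_mass_post", "body_mass", "day_index")

#' Read a session manifest
#'
#' One row per drinking session: animal and condition metadata plus the
#' bottle and body masses needed for intake conversion, and an optional
#' blood-ethanol concentration (`bec`, blank when not assayed).
#'
#' @param path path to a CSV manifest with a header row naming all required
#'   fields (`session_id, animal_id, genotype, sex, fluid, session_length,
#'   bottle_mass_pre, bottle_mass_post, body_mass, day_index`; optional
#'   `bec`).
#' @return data frame of validated session records.
#' @export
read_session_manifest <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "'", call. = FALSE)
  # read everything as character first: "F" in the sex column must not be
  # coerced to logical FALSE
  dat <- read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE,
                  colClasses = "character")
  missing_cols <- setdiff(.MANIFEST_REQUIRED, names(dat))
  if (length(missing_cols))
    stop("manifest schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!"bec" %in% names(dat)) dat$bec <- NA_real_
  dat$bec <- suppressWarnings(as.numeric(dat$bec))
  for (col in c("session_length", "bottle_mass_pre", "bottle_mass_post",
                "body_mass")) {
    dat[[col]] <- suppressWarnings(as.numeric(dat[[col]]))
    if (anyNA(dat[[col]]))
      stop("manifest column '", col, "' has non-numeric entries", call. = FALSE)
  }
  dat$day_index <- suppressWarnings(as.integer(dat$day_index))
  .check_enum <- function(col, allowed) {
    bad <- !(dat[[col]] %in% allowed)
    if (any(bad))
      stop("manifest validation error: bad ", col, " '",
           dat[[col]][which(bad)[1L]], "' for session_id ",
           dat$session_id[which(bad)[1L]], call. = FALSE)
  }
  .check_enum("genotype", .GENOTYPES)
  .check_enum("sex", .SEXES)
  .check_enum("fluid", .FLUIDS)
  bad_mass <- dat$bottle_mass_post > dat$bottle_mass_pre
  if (any(bad_mass))
    stop("manifest validation error: bottle_mass_post > bottle_mass_pre for ",
         "session_id ", dat$session_id[which(bad_mass)[1L]], call. = FALSE)
  if (any(dat$session_length <= 0))
    stop("manifest validation error: non-positive session_length for ",
         "session_id ", dat$session_id[which(dat$session_length <= 0)[1L]],
         call. = FALSE)
  if (any(dat$body_mass <= 0))
    stop("manifest validation error: non-positive body_mass for session_id ",
         dat$session_id[which(dat$body_mass <= 0)[1L]], call. = FALSE)
  dat
}

.NONBOUT_SENTINEL <- "none"

#' Write processed lick/bout tables and a JSON summary
#'
#' Writes `licks.csv` (`session_id, channel, onset_s, duration_s, bout_id`
#' with the literal sentinel `"none"` for non-bout licks), `bouts.csv`
#' (`session_id, bout_id, start_s, end_s, n_licks, total_lick_duration_s`)
#' and `summary.json`. Re-reading with [read_lick_table()] /
#' [read_bout_table()] / [read_summary_json()] reproduces values bit-exact
#' for integers and to at least 6 decimal places for reals.
#'
#' @param licks lick table: `session_id, channel, onset, duration, bout_id`
#'   (`bout_id` integer or `NA` for non-bout).
#' @param bouts bout table: `session_id, bout_id, start, end, n_licks,
#'   total_lick_duration`.
#' @param summaries per-session summary data frame (see
#'   [summarize_session()]).
#' @param out_dir output directory, created if needed.
#' @return named character vector of written paths, invisibly.
#' @export
write_tables <- function(licks, bouts, summaries, out_dir) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2L) != 0L)
    stop("cannot write to directory '", out_dir, "'", call. = FALSE)
  lick_out <- data.frame(
    session_id = as.character(licks$session_id %||% character(0)),
    channel = as.integer(licks$channel %||% integer(0)),
    onset_s = as.numeric(licks$onset %||% numeric(0)),
    duration_s = as.numeric(licks$duration %||% numeric(0)),
    bout_id = if (nrow(licks) == 0L) character(0) else
      ifelse(is.na(licks$bout_id), .NONBOUT_SENTINEL,
             as.character(licks$bout_id)),
    stringsAsFactors = FALSE)
  bout_out <- data.frame(
    session_id = as.character(bouts$session_id %||% character(0)),
    bout_id = as.integer(bouts$bout_id %||% integer(0)),
    start_s = as.numeric(bouts$start %||% numeric(0)),
    end_s = as.numeric(bouts$end %||% numeric(0)),
    n_licks = as.integer(bouts$n_licks %||% integer(0)),
    total_lick_duration_s = as.numeric(bouts$total_lick_duration %||% numeric(0)),
    stringsAsFactors = FALSE)
  paths <- c(licks = file.path(out_dir, "licks.csv"),
             bouts = file.path(out_dir, "bouts.csv"),
             summary = file.path(out_dir, "summary.json"))
  write.csv(lick_out, paths[["licks"]], row.names = FALSE)
  write.csv(bout_out, paths[["bouts"]], row.names = FALSE)
  jsonlite::write_json(summaries, paths[["summary"]], dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(paths)
}

#' @rdname write_tables
#' @param path path to a table written by `write_tables()`.
#' @export
read_lick_table <- function(path) {
  dat <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(session_id = "character", bout_id = "character"))
  data.frame(session_id = dat$session_id, channel = as.integer(dat$channel),
             onset = dat$onset_s, duration = dat$duration_s,
             bout_id = suppressWarnings(
               as.integer(ifelse(dat$bout_id == .NONBOUT_SENTINEL,
                                 NA_character_, dat$bout_id))),
             stringsAsFactors = FALSE)
}

#' @rdname write_tables
#' @export
read_bout_table <- function(path) {
  dat <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(session_id = "character"))
  data.frame(session_id = dat$session_id, bout_id = as.integer(dat$bout_id),
             start = dat$start_s, end = dat$end_s,
             n_licks = as.integer(dat$n_licks),
             total_lick_duration = dat$total_lick_duration_s,
             stringsAsFactors = FALSE)
}

#' @rdname write_tables
#' @export
read_summary_json <- function(path) {
  as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
}
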