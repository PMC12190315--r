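test_that("event logs parse in file order with seconds timestamps", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0.000,0,touch,140", "0.045,0,release,120"), p)
  ev <- read_event_log(p, event_dialect(header = FALSE))
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$t, c(0.000, 0.045))
  expect_equal(ev$polarity, c("touch", "release"))
  expect_equal(ev$sensor_value, c(140L, 120L))

  # header dialect
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,channel,polarity,sensor_value", "1.5,0,touch,130"), p2)
  expect_equal(read_event_log(p2)$t, 1.5)

  # empty file -> empty collection
  p3 <- withr::local_tempfile(fileext = ".csv")
  file.create(p3)
  expect_equal(nrow(read_event_log(p3, event_dialect(header = FALSE))), 0L)

  expect_error(read_event_log(file.path(tempdir(), "no-such-file.csv")),
               "cannot read")
})

test_that("malformed rows error in strict mode and skip in lenient mode", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0.000,0,t0uch,140", "0.045,0,release,120"), p)
  d <- event_dialect(header = FALSE)
  expect_error(read_event_log(p, d, strict = TRUE), "line 1")
  expect_warning(ev <- read_event_log(p, d, strict = FALSE), "skipped")
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$polarity, "release")
})

test_that("ISO timestamps convert to seconds from the manifest epoch", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("2024-03-01T21:00:00.000,0,touch,140",
               "2024-03-01T21:00:00.045,0,release,120"), p)
  d <- event_dialect(header = FALSE, time_format = "iso",
                     epoch = "2024-03-01T21:00:00")
  ev <- read_event_log(p, d)
  expect_equal(ev$t, c(0, 0.045), tolerance = 1e-9)
})

test_that("equal timestamps keep file order", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1.000,0,touch,140", "1.000,0,release,120",
               "1.000,0,touch,150"), p)
  ev <- read_event_log(p, event_dialect(header = FALSE))
  expect_equal(ev$polarity, c("touch", "release", "touch"))
  expect_equal(ev$sensor_value, c(140L, 120L, 150L))
})

make_manifest_df <- function(...) {
  base <- data.frame(session_id = "s1", animal_id = "m1",
                     genotype = "wild_type", sex = "F", fluid = "ethanol20",
                     session_length = 7200, bottle_mass_pre = 45,
                     bottle_mass_post = 44, body_mass = 25, day_index = 1,
                     bec = 80, stringsAsFactors = FALSE)
  mods <- list(...)
  for (nm in names(mods)) base[[nm]] <- mods[[nm]]
  base
}

test_that("session manifests validate schema, enums and masses", {
  p <- withr::local_tempfile(fileext = ".csv")
  write.csv(make_manifest_df(), p, row.names = FALSE)
  m <- read_session_manifest(p)
  expect_equal(nrow(m), 1L)
  expect_equal(m$bec, 80)

  write.csv(make_manifest_df(bottle_mass_pre = 40, bottle_mass_post = 41),
            p, row.names = FALSE)
  expect_error(read_session_manifest(p), "bottle_mass_post.*s1")

  df <- make_manifest_df()
  df$genotype <- NULL
  write.csv(df, p, row.names = FALSE)
  expect_error(read_session_manifest(p), "schema error.*genotype")

  write.csv(make_manifest_df(genotype = "mutant"), p, row.names = FALSE)
  expect_error(read_session_manifest(p), "bad genotype")

  write.csv(make_manifest_df(bec = NA), p, row.names = FALSE)
  expect_true(is.na(read_session_manifest(p)$bec))
})

test_that("table round trips reproduce values under declared precision", {
  licks <- data.frame(session_id = "s1", channel = 0L,
                      onset = c(1.000001, 2.5, 6.123456),
                      duration = c(0.045, 0.05, 0.123456),
                      bout_id = c(1L, 1L, NA))
  bouts <- data.frame(session_id = "s1", bout_id = 1L, start = 1.000001,
                      end = 2.55, n_licks = 2L, total_lick_duration = 0.095)
  summaries <- data.frame(session_id = "s1", total_licks = 3L,
                          intake = 4.567890123)
  out <- withr::local_tempdir()
  paths <- write_tables(licks, bouts, summaries, out)
  expect_equal(read_lick_table(paths[["licks"]]), licks, tolerance = 1e-7)
  expect_equal(read_bout_table(paths[["bouts"]]), bouts, tolerance = 1e-7)
  rt <- read_summary_json(paths[["summary"]])
  expect_equal(rt$intake, summaries$intake, tolerance = 1e-7)
  expect_identical(rt$total_licks, summaries$total_licks)

  # non-bout sentinel is the literal string "none"
  raw <- read.csv(paths[["licks"]], colClasses = "character")
  expect_equal(raw$bout_id[3], "none")
})

test_that("empty inputs produce header-only tables", {
  empty_licks <- data.frame(session_id = character(0), channel = integer(0),
                            onset = numeric(0), duration = numeric(0),
                            bout_id = integer(0))
  empty_bouts <- data.frame(session_id = character(0), bout_id = integer(0),
                            start = numeric(0), end = numeric(0),
                            n_licks = integer(0),
                            total_lick_duration = numeric(0))
  out <- withr::local_tempdir()
  paths <- write_tables(empty_licks, empty_bouts, data.frame(), out)
  expect_equal(length(readLines(paths[["licks"]])), 1L)
  expect_equal(nrow(read_lick_table(paths[["licks"]])), 0L)
  expect_equal(nrow(read_bout_table(paths[["bouts"]])), 0L)
})
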