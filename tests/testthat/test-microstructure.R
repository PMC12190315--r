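make_session <- function(onsets, durations = rep(0.05, length(onsets)),
                         session_length = 7200, session_id = "s1") {
  n <- length(onsets)
  licks <- data.frame(session_id = rep(session_id, n),
                      channel = rep(0L, n), onset = onsets,
                      duration = durations,
                      bout_id = rep(NA_integer_, n), stringsAsFactors = FALSE)
  ab <- assign_bouts(licks)
  sess <- data.frame(session_id = session_id,
                     session_length = session_length)
  list(ab = ab, sess = sess)
}

test_that("session summary matches hand computation", {
  x <- make_session(c(0.0, 0.4, 0.8, 2.0, 6.0))
  sm <- summarize_session(x$ab$licks, x$ab$bouts, x$ab$labels, x$sess)
  expect_equal(sm$total_licks, 5L)
  expect_equal(sm$n_bouts, 1L)
  expect_equal(sm$licks_per_bout, 4)
  expect_equal(sm$pct_licks_in_bouts, 80.0)
  expect_equal(sm$n_nonbout_licks, 1L)
  expect_equal(sm$total_lick_duration, 0.25, tolerance = 1e-12)
  expect_equal(sm$lick_duration_per_bout, 0.20, tolerance = 1e-12)
  expect_equal(sm$mean_lick_duration_bout, 0.05, tolerance = 1e-12)
  expect_equal(sm$mean_lick_duration_nonbout, 0.05, tolerance = 1e-12)
  expect_equal(sm$licks_frontload, 5L)
  expect_equal(sm$licks_postfrontload, 0L)
})

test_that("empty sessions give zero counts and NA sentinels, never zeros", {
  x <- make_session(numeric(0))
  sm <- summarize_session(x$ab$licks, x$ab$bouts, x$ab$labels, x$sess)
  expect_equal(sm$total_licks, 0L)
  expect_equal(sm$total_lick_duration, 0)
  expect_equal(sm$n_bouts, 0L)
  expect_true(is.na(sm$licks_per_bout))
  expect_true(is.na(sm$mean_lick_duration_bout))
  expect_true(is.na(sm$mean_lick_duration_nonbout))
  expect_equal(sm$pct_licks_in_bouts, 0)

  y <- make_session(c(0, 0.3, 0.6))
  sm2 <- summarize_session(y$ab$licks, y$ab$bouts, y$ab$labels, y$sess)
  expect_equal(sm2$pct_licks_in_bouts, 100.0)
  expect_true(is.na(sm2$mean_lick_duration_nonbout))

  z <- make_session(c(10, 8000))
  expect_error(summarize_session(z$ab$licks, z$ab$bouts, z$ab$labels,
                                 data.frame(session_id = "s",
                                            session_length = 7200)),
               "outside")
})

test_that("cumulative curves count onsets at or before each grid point", {
  expect_equal(cumulative_curve(c(10, 100, 1900), c(0, 60, 1800, 7200)),
               c(0L, 1L, 2L, 3L))
  expect_equal(cumulative_curve(numeric(0), c(0, 100)), c(0L, 0L))
  on <- c(1.5, 2.5, 9)
  expect_equal(cumulative_curve(on, on), 1:3)
  expect_error(cumulative_curve(1:3, c(5, 1)), "sorted")
  set.seed(3)
  for (i in 1:20) {
    on <- sort(runif(50, 0, 100))
    g <- sort(runif(30, 0, 100))
    cc <- cumulative_curve(on, g)
    expect_true(all(diff(cc) >= 0))
    expect_equal(cumulative_curve(on, 100), 50L)
  }
})

test_that("frontload split is half-open at the window boundary", {
  p <- temporal_params(frontload_window = 1800)
  expect_equal(frontload_split(c(10, 100, 1900, 2000), p),
               c(frontload = 2L, postfrontload = 2L))
  expect_equal(frontload_split(c(10, 20), p),
               c(frontload = 2L, postfrontload = 0L))
  expect_equal(frontload_split(numeric(0), p),
               c(frontload = 0L, postfrontload = 0L))
  expect_equal(unname(frontload_split(1800, p)), c(0L, 1L))  # boundary lick
  set.seed(4)
  for (i in 1:20) {
    on <- runif(sample(0:100, 1), 0, 7200)
    expect_equal(sum(frontload_split(on, p)), length(on))
  }
})

test_that("pooled distributions stack times and within-session indices", {
  pooled <- pooled_time_distribution(list(c(1, 2)), "wt")
  expect_equal(pooled$wt$times, c(1, 2))
  expect_equal(pooled$wt$cumulative, c(1L, 2L))

  pooled2 <- pooled_time_distribution(list(c(1, 2), c(5, 6)), c("wt", "wt"))
  expect_equal(length(pooled2$wt$times), 4L)
  expect_equal(pooled2$wt$cumulative, c(1L, 2L, 1L, 2L))

  expect_error(pooled_time_distribution(list(c(1, 2)),
                                        factor("wt", levels = c("wt", "ko"))),
               "at least one session")
})

test_that("in-bout percentage agrees between labels and bout sums", {
  set.seed(12)
  for (i in 1:40) {
    onsets <- random_lick_train()
    x <- make_session(onsets, durations = runif(length(onsets), 0.02, 0.2))
    sm <- summarize_session(x$ab$licks, x$ab$bouts, x$ab$labels, x$sess)
    pct_from_bouts <- if (sm$total_licks)
      100 * sum(x$ab$bouts$n_licks) / sm$total_licks else 0
    expect_identical(sm$pct_licks_in_bouts, pct_from_bouts)
    expect_equal(sm$licks_frontload + sm$licks_postfrontload, sm$total_licks)
  }
})
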