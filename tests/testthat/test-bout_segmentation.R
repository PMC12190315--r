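test_that("parameter invariants are enforced", {
  expect_error(segmentation_params(init_n = 1), "init_n")
  expect_error(segmentation_params(init_ili_max = 4, term_gap = 3),
               "init_ili_max")
  expect_error(segment_bouts(c(1, 1, 2)), "strictly increasing")
})

test_that("segmentation matches hand-traced sessions", {
  p <- segmentation_params()

  empty <- segment_bouts(numeric(0), p)
  expect_equal(nrow(empty$bouts), 0L)
  expect_equal(length(empty$nonbout_idx), 0L)

  # initiating triple extends through a 1.2 s gap; 4 s gap terminates
  s1 <- segment_bouts(c(0.0, 0.4, 0.8, 2.0, 6.0), p)
  expect_equal(nrow(s1$bouts), 1L)
  expect_equal(s1$bouts$n_licks, 4L)
  expect_equal(s1$bouts$start, 0.0)
  expect_equal(s1$bouts$end, 2.0)
  expect_equal(s1$nonbout_idx, 5L)

  # no triple with inter-lick intervals <= 1 s: everything non-bout
  s2 <- segment_bouts(c(0.0, 2.0, 4.0), p)
  expect_equal(nrow(s2$bouts), 0L)
  expect_equal(s2$nonbout_idx, 1:3)

  # a close pair cannot initiate and does not retro-join the later bout
  s3 <- segment_bouts(c(0.0, 0.5, 2.0, 2.4, 2.8, 3.0), p)
  expect_equal(nrow(s3$bouts), 1L)
  expect_equal(s3$bouts$start, 2.0)
  expect_equal(s3$bouts$n_licks, 4L)
  expect_equal(s3$nonbout_idx, 1:2)

  # inclusive boundaries: interval == 1.0 initiates, gap == 3.0 continues
  s4 <- segment_bouts(c(0, 1, 2, 5), p)
  expect_equal(s4$bouts$n_licks, 4L)
})

test_that("lick labels are consistent with bout membership", {
  licks <- data.frame(session_id = "s", channel = 0L,
                      onset = c(0.0, 0.4, 0.8, 2.0, 6.0),
                      duration = rep(0.05, 5), bout_id = NA_integer_)
  seg <- segment_bouts(licks$onset)
  expect_equal(label_licks(licks, seg), c("1", "1", "1", "1", "none"))
  expect_equal(label_licks(licks[0, ], segment_bouts(numeric(0))),
               character(0))
  all_in <- segment_bouts(c(0, 0.3, 0.6, 0.9))
  expect_false(any(label_licks(data.frame(onset = 1:4), all_in) == "none"))
  expect_error(label_licks(licks[1:3, ], seg), "internal-consistency")
})

test_that("segmentation equals the brute-force oracle on random trains", {
  set.seed(2024)
  for (i in 1:300) expect_same_segmentation(random_lick_train())
  # and under perturbed parameters
  p2 <- segmentation_params(init_n = 4L, init_ili_max = 0.5, term_gap = 2)
  for (i in 1:100) expect_same_segmentation(random_lick_train(), p2)
})

test_that("bout sets and the non-bout set partition every input", {
  set.seed(99)
  for (i in 1:100) {
    onsets <- random_lick_train()
    seg <- segment_bouts(onsets)
    expect_equal(sum(seg$bouts$n_licks) + length(seg$nonbout_idx),
                 length(onsets))
    if (nrow(seg$bouts)) {
      members <- unlist(lapply(seq_len(nrow(seg$bouts)), function(b)
        seg$bouts$first_idx[b]:seg$bouts$last_idx[b]))
      expect_equal(sort(c(members, seg$nonbout_idx)), seq_along(onsets))
      # within-bout gaps never exceed the termination gap; bouts disjoint
      for (b in seq_len(nrow(seg$bouts))) {
        idx <- seg$bouts$first_idx[b]:seg$bouts$last_idx[b]
        if (length(idx) > 1L)
          expect_true(all(diff(onsets[idx]) <= seg$params$term_gap))
      }
      if (nrow(seg$bouts) > 1L)
        expect_true(all(seg$bouts$start[-1] - seg$bouts$end[-nrow(seg$bouts)] >
                          seg$params$term_gap))
    }
  }
})

test_that("raising term_gap grows bouts; raising init_ili_max adds bouts", {
  set.seed(5)
  for (i in 1:60) {
    onsets <- random_lick_train()
    base <- segment_bouts(onsets, segmentation_params())
    wide_gap <- segment_bouts(onsets, segmentation_params(term_gap = 6))
    # each original bout is contained in a bout at least as large
    for (b in seq_len(nrow(base$bouts))) {
      host <- wide_gap$assignment[base$bouts$first_idx[b]]
      expect_false(is.na(host))
      expect_gte(wide_gap$bouts$n_licks[host], base$bouts$n_licks[b])
    }
    wide_ili <- segment_bouts(onsets, segmentation_params(init_ili_max = 2,
                                                          term_gap = 3))
    expect_gte(nrow(wide_ili$bouts), nrow(base$bouts))
  }
})

test_that("assign_bouts handles ties and computes per-bout contact time", {
  licks <- data.frame(session_id = "s", channel = 0L,
                      onset = c(0.0, 0.4, 0.4, 0.8),
                      duration = c(0.05, 0.06, 0.07, 0.08),
                      bout_id = NA_integer_)
  expect_warning(ab <- assign_bouts(licks), "duplicate")
  expect_true(all(diff(ab$licks$onset) > 0))
  expect_equal(nrow(ab$bouts), 1L)
  expect_equal(ab$bouts$n_licks, 4L)
  expect_equal(ab$bouts$total_lick_duration, 0.26, tolerance = 1e-12)
})
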