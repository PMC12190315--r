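# Independent reference implementations used as oracles. These share the
# declared segmentation decisions (consecutive-interval initiation,
# inclusive boundaries, no retro-joining) but are written as enumeration
# over candidate initiation points rather than a single state scan.

brute_force_segment <- function(onsets, init_n = 3L, init_ili_max = 1.0,
                                term_gap = 3.0) {
  n <- length(onsets)
  if (n < init_n) return(list(bouts = list(), nonbout = seq_len(n)))
  d <- diff(onsets)
  # every index at which an initiating run of init_n licks begins
  candidates <- Filter(function(i)
    all(d[i:(i + init_n - 2L)] <= init_ili_max),
    seq_len(n - init_n + 1L))
  bouts <- list()
  consumed <- 0L
  for (i in candidates) {
    if (i <= consumed) next
    members <- i:(i + init_n - 1L)
    j <- i + init_n - 1L
    while (j < n && onsets[j + 1L] - onsets[j] <= term_gap) {
      j <- j + 1L
      members <- c(members, j)
    }
    bouts[[length(bouts) + 1L]] <- members
    consumed <- j
  }
  list(bouts = bouts,
       nonbout = setdiff(seq_len(n), unlist(bouts)))
}

brute_force_ks <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(vapply(pts, function(p) abs(mean(a <= p) - mean(b <= p)), numeric(1)))
}

# random lick trains with inter-lick intervals from a mixture spanning
# 0.05-10 s, so initiation/termination boundaries are all exercised
random_lick_train <- function(n_max = 50L) {
  n <- sample(0:n_max, 1L)
  if (n == 0L) return(numeric(0))
  comp <- sample(1:3, n, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  ili <- ifelse(comp == 1L, runif(n, 0.05, 0.3),
                ifelse(comp == 2L, runif(n, 0.3, 2), runif(n, 2, 10)))
  cumsum(ili)
}

expect_same_segmentation <- function(onsets, params = segmentation_params()) {
  got <- segment_bouts(onsets, params)
  ref <- brute_force_segment(onsets, params$init_n, params$init_ili_max,
                             params$term_gap)
  expect_equal(nrow(got$bouts), length(ref$bouts))
  for (b in seq_along(ref$bouts)) {
    expect_identical(got$bouts$first_idx[b]:got$bouts$last_idx[b],
                     ref$bouts[[b]])
  }
  expect_identical(got$nonbout_idx, as.integer(ref$nonbout))
}
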