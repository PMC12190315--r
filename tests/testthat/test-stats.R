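test_that("KS statistic equals the maximum pooled ECDF difference", {
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_equal(ks_two_sample(c(1, 2, 3), c(4, 5, 6))$statistic, 1.0)
  expect_equal(ks_two_sample(c(1, 2), 1.5)$statistic, 0.5)
  expect_error(ks_two_sample(numeric(0), 1), "non-empty")

  set.seed(31)
  for (i in 1:100) {
    a <- round(rnorm(sample(2:30, 1)), sample(0:2, 1))  # ties included
    b <- round(rnorm(sample(2:30, 1), mean = runif(1, -1, 1)), sample(0:2, 1))
    expect_equal(ks_two_sample(a, b)$statistic, brute_force_ks(a, b),
                 tolerance = 1e-12)
  }
})

test_that("kernel density estimates integrate to one and peak at the mode", {
  trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  set.seed(8)
  for (i in 1:20) {
    v <- rnorm(sample(10:200, 1), sd = runif(1, 0.5, 3))
    d <- kde(v)
    expect_equal(trapz(d$x, d$y), 1, tolerance = 1e-3)
  }
  # Monte-Carlo mode check: single-sample KDE modes wander ~0.08 at this
  # bandwidth, so the 0.05 tolerance applies to the replicate average
  modes <- replicate(20, {
    d <- kde(rnorm(10000))
    d$x[which.max(d$y)]
  })
  expect_lt(abs(mean(modes)), 0.05)
  big <- rnorm(10000)

  two <- kde(c(0, 1))
  expect_equal(trapz(two$x, two$y), 1, tolerance = 1e-3)

  expect_error(kde(rep(2, 5)), "distinct")
  # silverman and fixed bandwidth rules
  expect_equal(kde(big, bandwidth = "silverman")$bw, stats::bw.nrd0(big))
  expect_equal(kde(big, bandwidth = 0.25)$bw, 0.25)
})

test_that("location tests report z for ranks and Welch t otherwise", {
  a <- c(1, 2, 3, 4, 5)
  r <- location_test(a, a, method = "rank")
  expect_lt(abs(r$statistic), 0.01)

  r2 <- location_test(c(1, 2, 3), c(10, 20, 30), method = "rank")
  expect_equal(r2$U, 0)
  expect_lt(r2$statistic, 0)

  t0 <- location_test(a, a, method = "t")
  expect_equal(t0$statistic, 0)

  # rank test is invariant under strictly monotone transforms
  set.seed(21)
  for (i in 1:25) {
    x <- rnorm(12); y <- rnorm(10, 0.5)
    f <- function(v) exp(v) + v^3   # strictly increasing
    r_raw <- location_test(x, y, method = "rank")
    r_tr <- location_test(f(x), f(y), method = "rank")
    expect_equal(r_raw$statistic, r_tr$statistic, tolerance = 1e-12)
  }

  # auto selection: heavy-tailed data routes to the rank test
  set.seed(22)
  expect_equal(location_test(rcauchy(30)^3, rcauchy(30)^3)$method, "rank")
  expect_equal(location_test(rnorm(30), rnorm(30))$method, "t")
  expect_error(location_test(1, c(1, 2), method = "t"), "at least 2")
})

test_that("mixed model recovers a constructed interaction exactly", {
  d <- data.frame(x = rep(seq(0.5, 5, by = 0.5), 4),
                  g = rep(c("A", "B"), each = 20),
                  id = rep(c("a1", "a2", "b1", "b2"), each = 10))
  d$y <- ifelse(d$g == "A", 2 * d$x, 1 * d$x)
  fit <- fit_mixed_model(d, "y", c("x", "g", "x:g"), "id")
  expect_equal(abs(unname(fit$coefficients["x:gB"])), 1.0, tolerance = 1e-6)
  expect_lt(fit$interaction_test$p_value, 1e-6)
  expect_equal(fit$n_obs, 40L)
  expect_equal(fit$n_groups, 4L)

  expect_error(fit_mixed_model(within(d, id <- "one"), "y",
                               c("x", "g", "x:g"), "id"),
               "at least 2 levels")
  d$x2 <- 2 * d$x
  expect_error(fit_mixed_model(d, "y", c("x", "x2"), "id"), "collinear")
  expect_error(fit_mixed_model(d, "y", c("x", "nope"), "id"), "not in data")
})

test_that("interaction test holds its size under the null", {
  set.seed(77)
  pvals <- replicate(100, {
    n_mice <- 10L
    d <- data.frame(x = rnorm(n_mice * 4),
                    g = rep(c("A", "B"), each = n_mice * 2),
                    id = rep(sprintf("m%02d", 1:n_mice), each = 4))
    d$y <- rnorm(nrow(d)) + rnorm(n_mice)[match(d$id, unique(d$id))]
    fit_mixed_model(d, "y", c("x", "g", "x:g"), "id")$interaction_test$p_value
  })
  expect_gte(sum(pvals > 0.01), 95)
})

test_that("mixed ANOVA separates between, within and interaction effects", {
  subj <- sprintf("s%02d", 1:20)
  grp <- rep(c("wt", "ko"), each = 10)
  d <- data.frame(subject = rep(subj, 2), genotype = rep(grp, 2),
                  bout_type = rep(c("bout", "nonbout"), each = 20))

  # identical dv everywhere: no effect carries any signal
  d$dur <- 0.05
  flat <- mixed_anova(d, "dur", "bout_type", "genotype", "subject")
  expect_true(all(flat$anova$F == 0))

  # pure interaction: +d / -d pattern, no noise
  d$dur <- 0.05 + 0.01 * ifelse((d$genotype == "wt") ==
                                  (d$bout_type == "bout"), 1, -1)
  pure <- mixed_anova(d, "dur", "bout_type", "genotype", "subject")
  expect_lt(pure$anova$p_value[3], 1e-6)
  expect_equal(pure$anova$F[1], 0)
  expect_equal(pure$anova$F[2], 0)

  # realistic noisy case has finite stats and contrasts per level
  set.seed(5)
  d$dur <- d$dur + rnorm(nrow(d), 0, 0.005)
  noisy <- mixed_anova(d, "dur", "bout_type", "genotype", "subject")
  expect_true(all(is.finite(noisy$anova$F)))
  expect_equal(noisy$contrasts$level, c("bout", "nonbout"))
  expect_true(all(is.finite(noisy$contrasts$p_value)))

  expect_error(mixed_anova(d[-1, ], "dur", "bout_type", "genotype", "subject"),
               "missing cell")
})

test_that("mixed model estimates cover known parameters", {
  # known per-group slopes, random-intercept sd 0.5, residual sd 1
  set.seed(404)
  n_mice <- 12L; per <- 4L
  truth <- c(`(Intercept)` = 1, x = 2, gB = -0.5, `x:gB` = 1.5)
  checks <- 0L; hits <- 0L
  for (r in 1:50) {
    id <- rep(sprintf("m%02d", 1:n_mice), each = per)
    g <- rep(rep(c("A", "B"), each = n_mice / 2), each = per)
    x <- rnorm(n_mice * per)
    b0 <- rnorm(n_mice, 0, 0.5)[match(id, unique(id))]
    y <- 1 + 2 * x + (-0.5) * (g == "B") + 1.5 * x * (g == "B") + b0 +
      rnorm(n_mice * per)
    d <- data.frame(x = x, g = g, id = id, y = y)
    fit <- fit_mixed_model(d, "y", c("x", "g", "x:g"), "id")
    se <- sqrt(diag(as.matrix(vcov(fit$model))))
    within3 <- abs(fit$coefficients - truth) <= 3 * se
    checks <- checks + length(within3)
    hits <- hits + sum(within3)
  }
  expect_gte(hits / checks, 0.98)
})
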