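#' Fluid composition for intake conversion
#'
#' Defaults describe 20% (vol/vol) ethanol: pure-ethanol density
#' 0.789 g/mL and a bulk solution density of 0.97 g/mL (standard
#' ethanol-water density tables for a 20% v/v mixture). Saccharin-only and
#' water fluids carry an ethanol volume fraction of 0.
#'
#' @param ethanol_vol_fraction ethanol volume fraction in \[0, 1\].
#' @param ethanol_density g/mL of pure ethanol.
#' @param solution_density g/mL of the drinking solution.
#' @param additive `"none"`, `"saccharin03"` or `"saccharin01"`.
#' @return a `fluid_spec` object.
#' @export
fluid_spec <- function(ethanol_vol_fraction = 0.20, ethanol_density = 0.789,
                       solution_density = 0.97,
                       additive = c("none", "saccharin03", "saccharin01")) {
  additive <- match.arg(additive)
  if (!(ethanol_vol_fraction >= 0 && ethanol_vol_fraction <= 1))
    stop("ethanol_vol_fraction must be in [0, 1]", call. = FALSE)
  if (ethanol_density <= 0 || solution_density <= 0)
    stop("densities must be positive", call. = FALSE)
  structure(list(ethanol_vol_fraction = ethanol_vol_fraction,
                 ethanol_density = ethanol_density,
                 solution_density = solution_density, additive = additive),
            class = "fluid_spec")
}

#' Map a manifest fluid label to its composition
#'
#' @param fluid one of `"ethanol20"`, `"ethanol20_saccharin03"`,
#'   `"saccharin01"`, `"water"`.
#' @return a [fluid_spec()].
#' @export
fluid_spec_for <- function(fluid) {
  switch(fluid,
         ethanol20 = fluid_spec(),
         ethanol20_saccharin03 = fluid_spec(additive = "saccharin03"),
         saccharin01 = fluid_spec(ethanol_vol_fraction = 0,
                                  solution_density = 1.0,
                                  additive = "saccharin01"),
         water = fluid_spec(ethanol_vol_fraction = 0, solution_density = 1.0),
         stop("unknown fluid '", fluid, "'", call. = FALSE))
}

#' Ethanol intake (g/kg) from bottle masses
#'
#' Standard drinking-in-the-dark conversion: the consumed solution mass is
#' turned into a volume via the solution density, the ethanol volume
#' fraction and pure-ethanol density give grams of ethanol, and the result
#' is normalized by body mass in kg:
#' `intake = (pre - post) / solution_density * vol_fraction *
#' ethanol_density / (body_mass / 1000)`.
#'
#' Vectorized over sessions.
#'
#' @param session session record(s): data frame (or one-row list) with
#'   `bottle_mass_pre`, `bottle_mass_post`, `body_mass` in grams.
#' @param fluid a [fluid_spec()].
#' @return ethanol intake in g per kg body mass.
#' @export
compute_intake <- function(session, fluid = fluid_spec()) {
  stopifnot(inherits(fluid, "fluid_spec"))
  pre <- session$bottle_mass_pre
  post <- session$bottle_mass_post
  body <- session$body_mass
  if (any(body <= 0)) stop("body_mass must be positive", call. = FALSE)
  if (any(post > pre))
    stop("bottle_mass_post exceeds bottle_mass_pre", call. = FALSE)
  (pre - post) / fluid$solution_density * fluid$ethanol_vol_fraction *
    fluid$ethanol_density / (body / 1000)
}

#' Per-group blood-ethanol accumulation fits
#'
#' Ordinary least squares of blood-ethanol concentration on ethanol intake
#' (g/kg), fit separately per group, with a free intercept by default.
#' Units of the concentration axis are carried opaquely: slopes are
#' reported in concentration units per g/kg and all downstream ratios are
#' unit-free.
#'
#' @param intake intake values, g/kg.
#' @param bec blood-ethanol concentrations, same length.
#' @param group group labels, same length; each group needs at least 3
#'   points and non-constant intake.
#' @param include_intercept fit an intercept (default) or force the line
#'   through the origin.
#' @return data frame of class `accumulation_fit`: one row per group with
#'   `group, slope, intercept, r_squared, n`.
#' @export
fit_accumulation <- function(intake, bec, group, include_intercept = TRUE) {
  if (length(intake) != length(bec) || length(intake) != length(group))
    stop("intake, bec and group must have equal length", call. = FALSE)
  keep <- !(is.na(intake) | is.na(bec))
  intake <- intake[keep]; bec <- bec[keep]; group <- group[keep]
  groups <- unique(as.character(group))
  rows <- lapply(groups, function(g) {
    x <- intake[group == g]; y <- bec[group == g]
    if (length(x) < 3L)
      stop("group '", g, "' has fewer than 3 points", call. = FALSE)
    if (var(x) == 0)
      stop("group '", g, "' has zero intake variance", call. = FALSE)
    fit <- if (include_intercept) lm(y ~ x) else lm(y ~ x + 0)
    cf <- coef(fit)
    slope <- unname(cf[["x"]])
    intercept <- if (include_intercept) unname(cf[["(Intercept)"]]) else 0
    r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits warn
    data.frame(group = g, slope = slope, intercept = intercept,
               r_squared = r2, n = length(x), stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("accumulation_fit", "data.frame"))
}

.ols_slope <- function(x, y, include_intercept = TRUE) {
  if (include_intercept) {
    mx <- mean(x); my <- mean(y)
    sum((x - mx) * (y - my)) / sum((x - mx)^2)
  } else {
    sum(x * y) / sum(x^2)
  }
}

#' Ratio of accumulation slopes with a bootstrap interval
#'
#' Slope ratio `numerator group / denominator group`. When the underlying
#' per-animal points are supplied, animals are resampled with replacement
#' within each group (default 2000 replicates, seeded) and a percentile
#' interval for the ratio is attached.
#'
#' @param fits an `accumulation_fit` from [fit_accumulation()].
#' @param num_group,den_group group labels; the denominator slope must be
#'   nonzero.
#' @param data optional data frame with `intake`, `bec`, `group` (one row
#'   per animal) to bootstrap from.
#' @param n_boot bootstrap replicates.
#' @param seed RNG seed for the bootstrap.
#' @param conf confidence level for the percentile interval.
#' @param include_intercept passed through to the per-replicate fits.
#' @return list with `ratio`, and when `data` is given `ci` (percentile
#'   bounds) and `n_boot`.
#' @export
slope_ratio <- function(fits, num_group, den_group, data = NULL,
                        n_boot = 2000L, seed = NULL, conf = 0.95,
                        include_intercept = TRUE) {
  stopifnot(inherits(fits, "accumulation_fit"))
  s_num <- fits$slope[fits$group == num_group]
  s_den <- fits$slope[fits$group == den_group]
  if (!length(s_num) || !length(s_den))
    stop("group not present in fits", call. = FALSE)
  if (s_den == 0) stop("denominator slope is zero", call. = FALSE)
  out <- list(ratio = s_num / s_den)
  if (!is.null(data)) {
    if (!is.null(seed)) set.seed(seed)
    xi_n <- data$intake[data$group == num_group]
    yi_n <- data$bec[data$group == num_group]
    xi_d <- data$intake[data$group == den_group]
    yi_d <- data$bec[data$group == den_group]
    ratios <- vapply(seq_len(n_boot), function(i) {
      repeat {
        bn <- sample.int(length(xi_n), replace = TRUE)
        bd <- sample.int(length(xi_d), replace = TRUE)
        if (var(xi_n[bn]) > 0 && var(xi_d[bd]) > 0) break
      }
      den <- .ols_slope(xi_d[bd], yi_d[bd], include_intercept)
      .ols_slope(xi_n[bn], yi_n[bn], include_intercept) / den
    }, numeric(1))
    alpha <- (1 - conf) / 2
    out$ci <- unname(quantile(ratios, c(alpha, 1 - alpha), na.rm = TRUE))
    out$n_boot <- n_boot
  }
  out
}
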