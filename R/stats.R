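#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Statistic is the supremum over x of the absolute difference between the
#' two empirical CDFs (equivalently, the maximum over the pooled sample
#' points); the p-value comes from the asymptotic two-sample distribution.
#'
#' @param a,b non-empty numeric samples.
#' @return list with `statistic` (in \[0, 1\]) and `p_value`.
#' @export
ks_two_sample <- function(a, b) {
  if (!length(a) || !length(b))
    stop("both samples must be non-empty", call. = FALSE)
  res <- suppressWarnings(ks.test(a, b, exact = FALSE))
  list(statistic = unname(res$statistic), p_value = unname(res$p.value))
}

#' Gaussian kernel density estimate
#'
#' @param values numeric sample with at least two distinct values.
#' @param bandwidth `"scott"` (default), `"silverman"`, or a positive
#'   number used as a fixed bandwidth.
#' @param n_grid number of grid points.
#' @return list with `x` (grid spanning the data +/- 3 bandwidths), `y`
#'   (density values; numerically integrates to 1 within 1e-3) and `bw`.
#' @export
kde <- function(values, bandwidth = "scott", n_grid = 512L) {
  values <- values[!is.na(values)]
  if (length(unique(values)) < 2L)
    stop("kde needs at least 2 distinct values", call. = FALSE)
  bw <- if (is.numeric(bandwidth)) {
    if (bandwidth <= 0) stop("fixed bandwidth must be positive", call. = FALSE)
    bandwidth
  } else {
    switch(match.arg(bandwidth, c("scott", "silverman")),
           scott = stats::bw.nrd(values),
           silverman = stats::bw.nrd0(values))
  }
  # the grid must resolve the kernel: spacing <= bw/4, else sharp peaks
  # (heavy-tailed samples) break the unit-integral contract
  span <- diff(range(values)) + 6 * bw
  n_use <- min(max(n_grid, ceiling(span / (bw / 4))), 2^16)
  d <- density(values, bw = bw, kernel = "gaussian", n = n_use,
               from = min(values) - 3 * bw, to = max(values) + 3 * bw)
  # renormalize over the reported support: kernel tail mass beyond the
  # 3-bandwidth margin (up to ~1.3e-3 for edge-clustered data) would
  # otherwise break the unit-integral contract
  z <- sum(diff(d$x) * (d$y[-length(d$y)] + d$y[-1]) / 2)
  list(x = d$x, y = d$y / z, bw = d$bw)
}

#' Two-group location test
#'
#' `method = "rank"` runs a Mann-Whitney U test reported as a z score
#' (normal approximation with tie correction and continuity correction);
#' `"t"` runs a Welch two-sample t test; `"auto"` applies Shapiro-Wilk
#' normality screening at alpha = 0.05 to each group and uses the rank test
#' if either group rejects (or is too small to test), the t test otherwise.
#'
#' @param a,b non-empty numeric samples.
#' @param method `"auto"`, `"rank"` or `"t"`.
#' @return list with `method`, `statistic` (z or t), `p_value`, and for the
#'   rank test `U` (of the first sample), for the t test `df`.
#' @export
location_test <- function(a, b, method = c("auto", "rank", "t")) {
  method <- match.arg(method)
  if (!length(a) || !length(b))
    stop("both samples must be non-empty", call. = FALSE)
  if (method == "auto") {
    normal <- function(x) {
      if (length(unique(x)) < 3L || length(x) < 3L) return(FALSE)
      shapiro.test(x)$p.value >= 0.05
    }
    method <- if (normal(a) && normal(b)) "t" else "rank"
  }
  if (method == "t") {
    if (length(a) < 2L || length(b) < 2L)
      stop("t test needs at least 2 observations per group", call. = FALSE)
    res <- t.test(a, b)
    list(method = "t", statistic = unname(res$statistic),
         p_value = res$p.value, df = unname(res$parameter))
  } else {
    n1 <- length(a); n2 <- length(b); n <- n1 + n2
    r <- rank(c(a, b))
    U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - tie_term))
    z <- if (sigma == 0 || U == mu) 0 else
      (U - mu - 0.5 * sign(U - mu)) / sigma
    list(method = "rank", statistic = z, p_value = 2 * pnorm(-abs(z)), U = U)
  }
}

.check_fixed_rank <- function(fixed, data) {
  X <- model.matrix(reformulate(fixed), data)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("singular fixed-effect design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(X)
}

#' Linear mixed-effects model with a random intercept
#'
#' Fits `response ~ fixed effects + (1 | grouping)` by REML (lme4) and
#' reports a Wald F test for one fixed-effect term (by default the last
#' interaction term). The denominator degrees of freedom use a
#' between-within approximation, `ddf = n_obs - n_groups - (p - 1)` with
#' `p` the number of fixed-effect coefficients; the convention is recorded
#' in the returned `df_method`.
#'
#' @param data model data frame (one row per session/observation).
#' @param response response column name.
#' @param fixed character vector of fixed-effect terms, e.g.
#'   `c("total_licks", "genotype", "total_licks:genotype")`.
#' @param grouping column name for the random-intercept grouping factor
#'   (typically the animal id); needs at least 2 levels.
#' @param interaction term to test; default: last term containing `:`.
#' @return object of class `mixed_fit`: list with `coefficients`,
#'   `interaction_test` (`term, F, df1, df2, p_value`),
#'   `random_effect_variance`, `residual_variance`, `n_obs`, `n_groups`,
#'   `df_method` and the underlying `model`.
#' @export
fit_mixed_model <- function(data, response, fixed, grouping,
                            interaction = NULL) {
  needed <- unique(c(response, unlist(strsplit(fixed, ":", fixed = TRUE)),
                     grouping))
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols))
    stop("column(s) not in data: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  g <- as.factor(data[[grouping]])
  if (nlevels(droplevels(g)) < 2L)
    stop("grouping factor needs at least 2 levels", call. = FALSE)
  .check_fixed_rank(fixed, data)
  fml <- as.formula(paste(response, "~", paste(fixed, collapse = " + "),
                          "+ (1 |", grouping, ")"))
  ctrl <- lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                            check.nobs.vs.nRE = "ignore")
  fit <- tryCatch(
    suppressMessages(suppressWarnings(lme4::lmer(fml, data = data,
                                                 REML = TRUE,
                                                 control = ctrl))),
    error = function(e) stop("mixed model failed to converge: ",
                             conditionMessage(e), call. = FALSE))
  tl <- attr(terms(fit, fixed.only = TRUE), "term.labels")
  if (is.null(interaction)) {
    inter <- tl[grepl(":", tl, fixed = TRUE)]
    interaction <- if (length(inter)) inter[length(inter)] else tl[length(tl)]
  }
  tno <- match(interaction, tl)
  if (is.na(tno)) {
    # allow reversed factor order, e.g. "genotype:licks" vs "licks:genotype"
    canon <- vapply(strsplit(tl, ":", fixed = TRUE),
                    function(p) paste(sort(p), collapse = ":"), character(1))
    tno <- match(paste(sort(strsplit(interaction, ":", fixed = TRUE)[[1]]),
                       collapse = ":"), canon)
  }
  if (is.na(tno))
    stop("term '", interaction, "' not in the fixed-effect terms",
         call. = FALSE)
  X <- lme4::getME(fit, "X")
  asgn <- attr(X, "assign")
  cols <- which(asgn == tno)
  beta <- lme4::fixef(fit)[cols]
  V <- tryCatch(suppressWarnings(as.matrix(vcov(fit))[cols, cols,
                                                      drop = FALSE]),
                error = function(e) NULL)
  if (is.null(V) || anyNA(V)) {
    # vcov.merMod can fail on degenerate (zero-residual) fits; fall back to
    # sigma^2 (RX'RX)^-1 from the fitted Cholesky factor
    RXi <- solve(lme4::getME(fit, "RX"))
    V <- (stats::sigma(fit)^2 * tcrossprod(RXi))[cols, cols, drop = FALSE]
  }
  Fstat <- tryCatch(drop(crossprod(beta, solve(V, beta))) / length(cols),
                    error = function(e) Inf)
  if (is.nan(Fstat)) Fstat <- Inf  # exact fit: unboundedly large evidence
  n_obs <- nrow(X)
  n_groups <- nlevels(droplevels(g))
  p <- ncol(X)
  ddf <- max(n_obs - n_groups - (p - 1L), 1L)
  vc <- as.data.frame(lme4::VarCorr(fit))
  re_var <- vc$vcov[vc$grp == grouping][1L]
  res_var <- vc$vcov[vc$grp == "Residual"][1L]
  structure(list(
    coefficients = lme4::fixef(fit),
    interaction_test = list(term = tl[tno], F = Fstat, df1 = length(cols),
                            df2 = ddf,
                            p_value = pf(Fstat, length(cols), ddf,
                                         lower.tail = FALSE)),
    random_effect_variance = re_var, residual_variance = res_var,
    n_obs = n_obs, n_groups = n_groups,
    df_method = "Wald F; between-within ddf = n_obs - n_groups - (p_fixed - 1)",
    model = fit), class = "mixed_fit")
}

#' Two-way mixed-design ANOVA
#'
#' One between-subjects factor (e.g. genotype), one within-subjects factor
#' (e.g. bout vs non-bout), subjects crossed with the within factor.
#' Multiple observations per subject-within cell are averaged first; a
#' subject missing any within level is a validation error listing the
#' missing cells. Sums of squares come from the classical
#' subject-stratified decomposition (`aov` with `Error(subject/within)`),
#' and per-within-level between-group Welch t contrasts are attached.
#'
#' @param data data frame in long format.
#' @param dv,within,between,subject column names.
#' @return list with `anova` (data frame `effect, df1, df2, F, p_value`)
#'   and `contrasts` (per within level: `t`, `p_value`).
#' @export
mixed_anova <- function(data, dv, within, between, subject) {
  missing_cols <- setdiff(c(dv, within, between, subject), names(data))
  if (length(missing_cols))
    stop("column(s) not in data: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  d <- data.frame(y = data[[dv]], W = factor(data[[within]]),
                  B = factor(data[[between]]), S = factor(data[[subject]]))
  d <- d[stats::complete.cases(d), , drop = FALSE]
  bt <- table(d$S, d$B)
  if (any(rowSums(bt > 0) > 1L))
    stop("each subject must belong to exactly one between-group level",
         call. = FALSE)
  cell <- table(d$S, d$W)
  if (any(cell == 0L)) {
    miss <- which(cell == 0L, arr.ind = TRUE)
    stop("unbalanced within-structure; missing cell(s): ",
         paste(sprintf("%s:%s", rownames(cell)[miss[, 1]],
                       colnames(cell)[miss[, 2]]), collapse = ", "),
         call. = FALSE)
  }
  agg <- aggregate(y ~ B + W + S, data = d, FUN = mean)
  fit <- aov(y ~ B * W + Error(S / W), data = agg)
  s <- summary(fit)
  btw <- as.data.frame(s[["Error: S"]][[1]])
  wth <- as.data.frame(s[["Error: S:W"]][[1]])
  rn_b <- trimws(rownames(btw)); rn_w <- trimws(rownames(wth))
  res_b <- btw[rn_b == "Residuals", ]; res_w <- wth[rn_w == "Residuals", ]
  row_of <- function(tab, rn, name) tab[rn == name, , drop = FALSE]
  b_row <- row_of(btw, rn_b, "B")
  w_row <- row_of(wth, rn_w, "W")
  i_row <- row_of(wth, rn_w, "B:W")
  anova_tab <- data.frame(
    effect = c(between, within, paste(between, within, sep = ":")),
    df1 = c(b_row$Df, w_row$Df, i_row$Df),
    df2 = c(res_b$Df, res_w$Df, res_w$Df),
    F = c(b_row$`F value`, w_row$`F value`, i_row$`F value`),
    p_value = c(b_row$`Pr(>F)`, w_row$`Pr(>F)`, i_row$`Pr(>F)`),
    stringsAsFactors = FALSE)
  # an effect whose sum of squares is zero at the response scale carries no
  # signal: F = 0, even when the error stratum is also degenerate
  ss <- c(b_row$`Sum Sq`, w_row$`Sum Sq`, i_row$`Sum Sq`)
  zero <- !is.na(ss) & ss <= 1e-12 * (sum(agg$y^2) + 1)
  anova_tab$F[zero] <- 0
  anova_tab$p_value[zero] <- 1
  # a real effect over a zero-variance error stratum is unboundedly large
  inf <- is.infinite(anova_tab$F)
  anova_tab$p_value[inf] <- 0
  contrasts <- do.call(rbind, lapply(levels(agg$W), function(w) {
    sub <- agg[agg$W == w, ]
    if (nlevels(droplevels(sub$B)) < 2L ||
        min(table(droplevels(sub$B))) < 2L)
      return(data.frame(level = w, t = NA_real_, p_value = NA_real_))
    tt <- tryCatch(t.test(y ~ B, data = sub), error = function(e) NULL)
    if (is.null(tt))  # e.g. zero variance in both groups
      return(data.frame(level = w, t = NA_real_, p_value = NA_real_))
    data.frame(level = w, t = unname(tt$statistic), p_value = tt$p.value,
               stringsAsFactors = FALSE)
  }))
  list(anova = anova_tab, contrasts = contrasts)
}
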