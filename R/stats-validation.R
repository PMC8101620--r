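#' Accuracy calibration of CT measures against a reference modality
#'
#' Pearson correlation and the simple-regression calibration line mapping
#' CT-derived values onto the reference (gold-standard) scale: ordinary
#' least squares of the reference on the CT values, so
#' `reference ~ intercept + slope * ct`.
#'
#' @param data a data frame of paired values, or a numeric vector of CT
#'   values (then `ct` supplies the reference vector).
#' @param ct,reference column names (unquoted) when `data` is a data
#'   frame.
#' @return An `accuracy_calibration` object with `slope`, `intercept`,
#'   `r`, `n`; supports [generics::tidy()], [generics::glance()],
#'   `predict()` and [ggplot2::autoplot()].
#' @export
accuracy_calibration <- function(data, ct, reference) {
  if (is.numeric(data)) {
    x <- data
    y <- ct
  } else {
    x <- dplyr::pull(data, {{ ct }})
    y <- dplyr::pull(data, {{ reference }})
  }
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort_bad("need at least 3 complete pairs", "config")
  if (var(x) == 0 || var(y) == 0)
    abort_bad("zero variance: degenerate calibration", "degenerate")
  fit <- lm(y ~ x)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r = cor(x, y), n = length(x), fit = fit,
                 data = tibble::tibble(ct = x, reference = y)),
            class = "accuracy_calibration")
}

#' @export
print.accuracy_calibration <- function(x, ...) {
  cat(sprintf(
    "<accuracy_calibration> reference = %.3f + %.3f * CT  (r = %.3f, n = %d)\n",
    x$intercept, x$slope, x$r, x$n))
  invisible(x)
}

#' @export
predict.accuracy_calibration <- function(object, newdata, ...) {
  object$intercept + object$slope * newdata
}

#' One-way random-effects intraclass correlation
#'
#' Single-rater ICC from repeat scans treated as exchangeable replicates:
#' `ICC = (MSB - MSW) / (MSB + (k - 1) MSW)` from the one-way
#' between/within mean squares, with the classical F-distribution 95%
#' confidence bounds.
#'
#' @param data long data frame with one row per (unit, replicate), or a
#'   numeric matrix of units by replicates.
#' @param unit,value column names (unquoted) for the long format.
#' @param conf_level confidence level for the interval.
#' @return An `icc_result`: `icc`, `ci_low`, `ci_high`, `n_units`,
#'   `n_replicates`, `model = "oneway_random"`.
#' @export
icc_oneway <- function(data, unit, value, conf_level = 0.95) {
  if (is.matrix(data)) {
    vals <- as.vector(data)
    units <- factor(rep(seq_len(nrow(data)), times = ncol(data)))
  } else {
    units <- factor(dplyr::pull(data, {{ unit }}))
    vals <- dplyr::pull(data, {{ value }})
  }
  tab <- table(units)
  n <- length(tab)
  if (n < 3 || any(tab < 2))
    abort_bad("need >= 3 units with >= 2 replicates each", "config")
  if (var(vals) == 0)
    abort_bad("constant data: ICC undefined", "degenerate")
  N <- length(vals)
  k <- N / n   # replicates per unit (k0 for unbalanced designs)
  fit <- aov(vals ~ units)
  ms <- summary(fit)[[1]][["Mean Sq"]]
  msb <- ms[1]; msw <- ms[2]
  icc <- (msb - msw) / (msb + (k - 1) * msw)
  alpha <- 1 - conf_level
  f0 <- msb / msw
  fl <- f0 / qf(1 - alpha / 2, n - 1, N - n)
  fu <- f0 * qf(1 - alpha / 2, N - n, n - 1)
  structure(list(icc = icc,
                 ci_low = (fl - 1) / (fl + k - 1),
                 ci_high = (fu - 1) / (fu + k - 1),
                 n_units = n, n_replicates = k, model = "oneway_random"),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result> ICC = %.3f (95%% CI %.3f, %.3f), n = %d x %g\n",
              x$icc, x$ci_low, x$ci_high, x$n_units, x$n_replicates))
  invisible(x)
}

#' Unadjusted two-group comparison of bone measures
#'
#' Pooled-variance two-sample t-tests per measure, with Cohen's d as the
#' mean difference divided by the pooled standard deviation. The
#' difference is group level 1 minus group level 2 in factor order.
#'
#' @param data long data frame with one value per unit and measure.
#' @param value,group,measure column names (unquoted); `measure` may be
#'   omitted for a single-measure table.
#' @return A `group_comparison` tibble: group means and SDs, mean
#'   difference, pooled SD, t-test p-value, effect size.
#' @export
unadjusted_group_compare <- function(data, value, group, measure = NULL) {
  g <- factor(dplyr::pull(data, {{ group }}))
  if (nlevels(g) != 2) abort_bad("exactly two groups are required", "config")
  v <- dplyr::pull(data, {{ value }})
  mq <- rlang::enquo(measure)
  meas <- if (rlang::quo_is_null(mq)) rep("value", length(v))
          else as.character(dplyr::pull(data, !!mq))
  df <- tibble::tibble(measure = meas, value = v, group = g)
  res <- df |>
    dplyr::group_by(.data$measure) |>
    dplyr::group_modify(function(d, key) {
      g1 <- d$value[d$group == levels(g)[1]]
      g2 <- d$value[d$group == levels(g)[2]]
      if (length(g1) < 2 || length(g2) < 2)
        abort_bad("each group needs at least 2 observations", "config")
      sp <- sqrt(((length(g1) - 1) * var(g1) + (length(g2) - 1) * var(g2)) /
                   (length(g1) + length(g2) - 2))
      tt <- t.test(g1, g2, var.equal = TRUE)
      tibble::tibble(
        mean_1 = mean(g1), sd_1 = sd(g1),
        mean_2 = mean(g2), sd_2 = sd(g2),
        mean_difference = mean(g1) - mean(g2), pooled_sd = sp,
        t_p_value = tt$p.value,
        effect_size = (mean(g1) - mean(g2)) / sp,
        n_1 = length(g1), n_2 = length(g2))
    }) |>
    dplyr::ungroup()
  class(res) <- c("group_comparison", class(res))
  res
}

#' Covariate-adjusted (least-squares means) group comparison
#'
#' Fits the general linear model `value ~ group + covariates` per measure
#' and compares least-squares group means computed at equally weighted
#' covariate levels (factor covariates) or covariate means (numeric
#' covariates). The adjusted effect size is the LS-mean difference
#' divided by the root mean square error of the model.
#'
#' @param data long data frame.
#' @param value,group column names (unquoted).
#' @param covariates character vector of covariate column names.
#' @param measure optional measure column (unquoted).
#' @return An `adjusted_comparison` tibble: LS means, difference, SE,
#'   p-value, MSE, effect size.
#' @export
adjusted_lsmeans <- function(data, value, group, covariates,
                             measure = NULL) {
  g <- factor(dplyr::pull(data, {{ group }}))
  if (nlevels(g) != 2) abort_bad("exactly two groups are required", "config")
  v <- dplyr::pull(data, {{ value }})
  mq <- rlang::enquo(measure)
  meas <- if (rlang::quo_is_null(mq)) rep("value", length(v))
          else as.character(dplyr::pull(data, !!mq))
  covdf <- data[, covariates, drop = FALSE]
  for (cc in covariates) {
    if (length(unique(covdf[[cc]])) < 2)
      abort_bad(sprintf("covariate '%s' does not vary", cc), "rank_deficient")
    if (!is.numeric(covdf[[cc]])) covdf[[cc]] <- factor(covdf[[cc]])
  }
  df <- tibble::as_tibble(cbind(tibble::tibble(.value = v, .group = g,
                                               .measure = meas), covdf))
  res <- df |>
    dplyr::group_by(.data$.measure) |>
    dplyr::group_modify(function(d, key) {
      fml <- stats::as.formula(paste(".value ~ .group +",
                                     paste(covariates, collapse = " + ")))
      fit <- lm(fml, data = d)
      if (anyNA(coef(fit)))
        abort_bad("collinear group/covariate design", "rank_deficient")
      emm <- emmeans::emmeans(fit, ".group", weights = "equal")
      es <- as.data.frame(emm)
      ctr <- as.data.frame(emmeans::contrast(emm, method = "pairwise"))
      mse <- sigma(fit)^2
      tibble::tibble(
        ls_mean_1 = es$emmean[1], ls_mean_2 = es$emmean[2],
        ls_mean_difference = ctr$estimate[1], se = ctr$SE[1],
        t_p_value = ctr$p.value[1], mse = mse,
        effect_size = ctr$estimate[1] / sqrt(mse))
    }) |>
    dplyr::ungroup() |>
    dplyr::rename(measure = ".measure")
  class(res) <- c("adjusted_comparison", class(res))
  res
}

#' Exact power of the two-sample pooled t-test
#'
#' Noncentral-t power for effect size `d` (Cohen's d) with group sizes
#' `n1`, `n2`: noncentrality `d * sqrt(n1 n2 / (n1 + n2))` on
#' `n1 + n2 - 2` degrees of freedom.
#'
#' @param d effect size (Cohen's d).
#' @param n1,n2 group sizes (>= 2).
#' @param alpha significance level.
#' @param sides 1 or 2.
#' @return Power in `[0, 1]`.
#' @export
ttest_power <- function(d, n1, n2, alpha = 0.05, sides = 2) {
  if (n1 < 2 || n2 < 2) abort_bad("group sizes must be >= 2", "config")
  if (alpha <= 0 || alpha >= 1) abort_bad("alpha must be in (0,1)", "config")
  if (!sides %in% c(1, 2)) abort_bad("sides must be 1 or 2", "config")
  df <- n1 + n2 - 2
  ncp <- abs(d) * sqrt(n1 * n2 / (n1 + n2))
  tc <- qt(1 - alpha / sides, df)
  if (sides == 2) 1 - pt(tc, df, ncp) + pt(-tc, df, ncp)
  else 1 - pt(tc, df, ncp)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties, plus the two-sided
#' asymptotic p-value.
#'
#' @param data data frame or numeric x vector.
#' @param x,y columns (unquoted) or, when `data` is numeric, `x` is the
#'   second vector.
#' @return tibble with `rho`, `p_value`, `n`.
#' @export
spearman_assoc <- function(data, x, y) {
  if (is.numeric(data)) {
    xv <- data; yv <- x
  } else {
    xv <- dplyr::pull(data, {{ x }})
    yv <- dplyr::pull(data, {{ y }})
  }
  ok <- complete.cases(xv, yv)
  xv <- xv[ok]; yv <- yv[ok]
  if (length(xv) < 3) abort_bad("need at least 3 pairs", "config")
  if (var(xv) == 0 || var(yv) == 0)
    abort_bad("constant vector: rank correlation undefined", "degenerate")
  ct <- suppressWarnings(cor.test(xv, yv, method = "spearman",
                                  exact = FALSE))
  tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value,
                 n = length(xv))
}
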