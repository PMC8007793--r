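#' Natural cubic spline basis for training utilization
#'
#' Thin wrapper over [splines::ns()]: boundary knots at the range of the
#' observed doses, interior knots at quantiles (for df = 3 the 33rd/66th
#' percentiles), linear beyond the boundary knots.
#'
#' @param x module counts in \[0, 9\].
#' @param df basis dimension (default 3, minimum 2).
#' @return Basis matrix with `df` columns and knot attributes.
#' @export
ncs_basis <- function(x, df = 3) {
  if (df < 2) stop("df must be >= 2")
  if (length(unique(x)) < df + 1)
    stop("need more than df distinct dose values to place knots")
  splines::ns(x, df = df)
}

#' Spline dose-response regression of index change on utilization
#'
#' Least-squares fit of the index change on a natural cubic spline basis of
#' the cumulative training modules completed (plus intercept), giving the
#' conditional mean gain as a smooth function of dose.
#'
#' By default the `df - 1` interior knots sit at quantiles of the observed
#' dose (the usual natural-spline convention). Fixed knots — for example at
#' 4 and 7 modules, the boundaries between the cognitive-training,
#' stress-training and informational module groups — can be supplied
#' instead via `knots`.
#'
#' @param deltas a [delta_table()] data frame (columns `dbhi` and
#'   `modules_completed`), or a data frame with those columns.
#' @param df spline degrees of freedom when `knots = NULL` (default 3).
#' @param knots optional interior knot locations in module units; `NULL`
#'   (the default) places `df - 1` knots at dose quantiles.
#' @param min_n minimum observations required.
#' @return A `bhi_dose_fit`: list with the `lm` fit, `df`, knots, residual
#'   sd and the observed dose range.
#' @export
fit_dose_response <- function(deltas, df = 3, knots = NULL, min_n = 20) {
  dat <- data.frame(dbhi = deltas$dbhi, dose = deltas$modules_completed)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (nrow(dat) < min_n)
    stop("dose-response fit requires at least ", min_n, " observations")
  if (!is.null(knots)) df <- length(knots) + 1
  if (length(unique(dat$dose)) < df + 1)
    stop("degenerate design: fewer than df + 1 distinct doses")
  fit <- if (is.null(knots)) {
    stats::lm(dbhi ~ splines::ns(dose, df = df), data = dat)
  } else {
    stats::lm(dbhi ~ splines::ns(dose, knots = knots), data = dat)
  }
  basis <- if (is.null(knots)) splines::ns(dat$dose, df = df)
           else splines::ns(dat$dose, knots = knots)
  structure(list(fit = fit, df = df, data = dat,
                 knots = attr(basis, "knots"),
                 boundary = attr(basis, "Boundary.knots"),
                 sigma = summary(fit)$sigma,
                 dose_range = range(dat$dose)),
            class = "bhi_dose_fit")
}

#' @export
print.bhi_dose_fit <- function(x, ...) {
  cat("<bhi_dose_fit> df =", x$df, ", n =", nrow(x$data), "\n")
  cat("  knots:", paste(signif(x$knots, 3), collapse = ", "),
      " boundary:", paste(signif(x$boundary, 3), collapse = ", "), "\n")
  cat("  residual sd:", signif(x$sigma, 4), "\n")
  invisible(x)
}

#' Conditional mean gain at given doses
#'
#' @param fit a `bhi_dose_fit`.
#' @param dose numeric vector of module counts.
#' @param conf_level confidence level for the mean curve.
#' @return Data frame: `dose`, `mean`, `se`, `lower`, `upper`.
#' @export
predict_dose <- function(fit, dose, conf_level = 0.95) {
  pr <- stats::predict(fit$fit, newdata = data.frame(dose = dose),
                       se.fit = TRUE)
  z <- stats::qt(1 - (1 - conf_level) / 2, df = fit$fit$df.residual)
  data.frame(dose = dose, mean = as.numeric(pr$fit),
             se = as.numeric(pr$se.fit),
             lower = as.numeric(pr$fit - z * pr$se.fit),
             upper = as.numeric(pr$fit + z * pr$se.fit))
}

#' Dose contrast with delta-method confidence interval
#'
#' Estimated difference in conditional mean gain between two doses,
#' its standard error from the coefficient covariance, a t-based interval
#' and p-value, and an effect size standardizing the contrast by the
#' residual sd.
#'
#' @param fit a `bhi_dose_fit`.
#' @param dose_a,dose_b doses to compare (a minus b).
#' @param conf_level confidence level.
#' @return List: `estimate`, `se`, `ci`, `t`, `p`, `d`.
#' @export
dose_contrast <- function(fit, dose_a, dose_b, conf_level = 0.95) {
  mm <- stats::model.matrix(stats::delete.response(stats::terms(fit$fit)),
                            data.frame(dose = c(dose_a, dose_b)))
  cvec <- mm[1, ] - mm[2, ]
  beta <- stats::coef(fit$fit)
  V <- stats::vcov(fit$fit)
  est <- sum(cvec * beta)
  se <- sqrt(drop(t(cvec) %*% V %*% cvec))
  dfres <- fit$fit$df.residual
  tstat <- est / se
  z <- stats::qt(1 - (1 - conf_level) / 2, dfres)
  list(estimate = est, se = se,
       ci = c(lower = est - z * se, upper = est + z * se),
       t = tstat, p = 2 * stats::pt(-abs(tstat), dfres),
       d = est / fit$sigma, dose_a = dose_a, dose_b = dose_b)
}

#' Average slope of the fitted curve beyond a dose
#'
#' Average derivative of the conditional mean over \[dose_0, upper\]
#' (the secant contrast divided by the interval length), with a
#' delta-method interval. A flat tail is declared when the interval
#' contains zero.
#'
#' @param fit a `bhi_dose_fit`.
#' @param dose_0 start of the interval (default 7 modules, the end of the
#'   interventional training).
#' @param upper end of the interval (default the maximum observed dose).
#' @param conf_level confidence level.
#' @return List: `slope`, `se`, `ci`, `flat`.
#' @export
flatness_beyond <- function(fit, dose_0 = 7, upper = NULL,
                            conf_level = 0.95) {
  if (is.null(upper)) upper <- fit$dose_range[2]
  width <- upper - dose_0
  if (width <= 0) stop("upper must exceed dose_0")
  ct <- dose_contrast(fit, upper, dose_0, conf_level)
  list(slope = ct$estimate / width, se = ct$se / width,
       ci = ct$ci / width, flat = ct$ci[1] <= 0 && ct$ci[2] >= 0,
       from = dose_0, to = upper)
}

#' Demographic independence of index change
#'
#' Tests whether the index change depends on age (linear regression),
#' gender and education (one-way ANOVA), reporting both the regression
#' coefficient route and the ANOVA route where applicable. Covariates with
#' a single observed level are skipped with a notice.
#'
#' @param deltas a [delta_table()] data frame with `dbhi` and any of
#'   `age`, `gender`, `education`.
#' @return Data frame: `covariate`, `test`, `statistic`, `df1`, `df2`,
#'   `p`, `note`.
#' @export
demographic_independence <- function(deltas) {
  out <- list()
  y <- deltas$dbhi
  if (stats::sd(y, na.rm = TRUE) == 0) {
    return(data.frame(covariate = "all", test = "none",
                      statistic = NA_real_, df1 = NA_real_, df2 = NA_real_,
                      p = NA_real_,
                      note = "index change is constant; tests degenerate"))
  }
  if ("age" %in% names(deltas)) {
    fit <- stats::lm(dbhi ~ age, data = deltas)
    sm <- summary(fit)
    out[[length(out) + 1]] <- data.frame(
      covariate = "age", test = "lm_slope_t",
      statistic = sm$coefficients["age", "t value"],
      df1 = 1, df2 = fit$df.residual,
      p = sm$coefficients["age", "Pr(>|t|)"], note = "")
  }
  for (cv in c("gender", "education")) {
    if (!cv %in% names(deltas)) next
    f <- factor(deltas[[cv]])
    if (nlevels(droplevels(f[!is.na(y)])) < 2) {
      out[[length(out) + 1]] <- data.frame(
        covariate = cv, test = "anova_F", statistic = NA_real_,
        df1 = NA_real_, df2 = NA_real_, p = NA_real_,
        note = "single level observed; test skipped")
      next
    }
    av <- stats::anova(stats::lm(y ~ f))
    out[[length(out) + 1]] <- data.frame(
      covariate = cv, test = "anova_F", statistic = av$`F value`[1],
      df1 = av$Df[1], df2 = av$Df[2], p = av$`Pr(>F)`[1], note = "")
  }
  do.call(rbind, out)
}
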