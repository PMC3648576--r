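#' Arcsine square-root transform for proportions
#'
#' The classical variance-stabilising transform for proportions,
#' `asin(sqrt(x))`, in radians: 0 maps to 0 and 1 to pi/2. T enters as a
#' proportion, never as a percentage (percentages would leave the arcsine
#' domain).
#'
#' @param values Numeric vector of proportions in \[0, 1\].
#' @return Transformed values in \[0, pi/2\].
#' @export
#' @examples
#' arcsine_sqrt(c(0, 0.25, 1))  # 0, pi/6, pi/2
arcsine_sqrt <- function(values) {
  bad <- !is.na(values) & (values < 0 | values > 1)
  if (any(bad)) {
    abort_validation(sprintf(
      "proportions must lie in [0, 1]; found %s",
      paste(format(values[bad][seq_len(min(3, sum(bad)))]), collapse = ", ")
    ))
  }
  asin(sqrt(values))
}

#' Compare mean T between threat classes
#'
#' Two-sample t-test of arcsine-square-root transformed T between the two
#' threat statuses, on species with a computed T (`coverage != "none"`).
#' The default is the pooled-variance test with `n1 + n2 - 2` degrees of
#' freedom; `variant = "unequal"` gives the Welch correction as a
#' sensitivity check. The t statistic is `mean(group 1) - mean(group 2)` in
#' the order given by `groups`, so swapping the order flips its sign.
#'
#' @param results Accounting results with columns `T`, `threat_status` and
#'   (optionally) `coverage`.
#' @param groups Character vector of the two group labels, in the order the
#'   difference is taken. Defaults to the sorted unique statuses present.
#' @param variant `"pooled"` (default) or `"unequal"` (Welch).
#' @return An object of class `tourism_group_comparison`: per-group n, mean
#'   and variance of the transformed values, `t_statistic`,
#'   `degrees_freedom`, two-tailed `p_value`, and the variant used. Has
#'   [tidy()] and [glance()] methods.
#' @export
#' @examples
#' cmp <- compare_groups(fixture_results())
#' glance(cmp)
compare_groups <- function(results, groups = NULL,
                           variant = c("pooled", "unequal")) {
  variant <- match.arg(variant)
  d <- results
  if ("coverage" %in% names(d)) {
    d <- dplyr::filter(d, .data$coverage != "none")
  }
  if (is.null(groups)) {
    groups <- sort(unique(d$threat_status))
    if (length(groups) < 2) {
      abort("fewer than two threat statuses present",
            class = "tourishare_insufficient_data_error")
    }
  }
  if (length(groups) != 2) {
    abort_validation("compare_groups needs exactly two group labels")
  }
  x <- arcsine_sqrt(d$T[d$threat_status == groups[1]])
  y <- arcsine_sqrt(d$T[d$threat_status == groups[2]])
  if (length(x) < 2 || length(y) < 2) {
    abort(sprintf(
      "each group needs at least 2 species (found %d '%s', %d '%s')",
      length(x), groups[1], length(y), groups[2]
    ), class = "tourishare_insufficient_data_error")
  }
  ht <- stats::t.test(x, y, var.equal = (variant == "pooled"))
  structure(
    list(
      groups = tibble::tibble(
        group = groups,
        n = c(length(x), length(y)),
        mean_transformed = c(mean(x), mean(y)),
        var_transformed = c(var(x), var(y))
      ),
      t_statistic = unname(ht$statistic),
      degrees_freedom = unname(ht$parameter),
      p_value = unname(ht$p.value),
      variant = variant
    ),
    class = "tourism_group_comparison"
  )
}

#' @export
print.tourism_group_comparison <- function(x, ...) {
  cat(sprintf("Two-sample t-test on arcsine-sqrt(T) (%s variance)\n", x$variant))
  print(x$groups)
  cat(sprintf("t = %.4g, d.f. = %.4g, two-tailed p = %.4g\n",
              x$t_statistic, x$degrees_freedom, x$p_value))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.tourism_group_comparison <- function(x, ...) {
  x$groups
}

#' @exportS3Method generics::glance
glance.tourism_group_comparison <- function(x, ...) {
  tibble::tibble(
    t_statistic = x$t_statistic,
    degrees_freedom = x$degrees_freedom,
    p_value = x$p_value,
    mean_diff_transformed = diff(rev(x$groups$mean_transformed)),
    variant = x$variant
  )
}

#' Regress T against global population size
#'
#' Ordinary least squares of a transform of T on `ln(G)`, over species with a
#' computed T, to ask whether small populations rely more on tourism than
#' large ones. Transforms:
#'
#' * `"arcsine"` (default): `asin(sqrt(T)) ~ ln(G)` — keeps the T = 0 species
#'   in the fit, since the arcsine transform is defined at zero.
#' * `"loglog"`: `ln(T) ~ ln(G)` on the T > 0 subset, as a sensitivity check
#'   (zeros must be dropped).
#' * `"log1p_percent"`: `ln(T_percent + 1) ~ ln(G)` on the rounded one-decimal
#'   percentages, the convention that reproduces the published fit.
#'
#' @param results Accounting results.
#' @param variant Which transform of T to regress (see above).
#' @return An object of class `tourism_regression` carrying `slope`,
#'   `intercept`, `r_squared`, `degrees_freedom` (n - 2), the two-sided
#'   `p_value` for slope = 0, `n`, `variant`, and the underlying `lm` fit.
#'   Has [tidy()] and [glance()] methods.
#' @export
#' @examples
#' fit <- regress_T_on_G(fixture_results())
#' glance(fit)
regress_T_on_G <- function(results,
                           variant = c("arcsine", "loglog", "log1p_percent")) {
  variant <- match.arg(variant)
  d <- results
  if ("coverage" %in% names(d)) {
    d <- dplyr::filter(d, .data$coverage != "none")
  }
  if (variant == "loglog") {
    d <- dplyr::filter(d, .data$T > 0)
  }
  if (nrow(d) < 3) {
    abort("regression needs at least 3 species",
          class = "tourishare_insufficient_data_error")
  }
  if (length(unique(d$global_population)) < 2) {
    abort("all global populations are equal: the predictor is degenerate",
          class = "tourishare_singular_fit_error")
  }
  y <- switch(variant,
    arcsine = arcsine_sqrt(d$T),
    loglog = log(d$T),
    log1p_percent = log(d$T_percent + 1)
  )
  fit <- lm(y ~ x, data = data.frame(y = y, x = log(d$global_population)))
  s <- suppressWarnings(summary(fit))  # perfect / constant fits warn in summary.lm
  # a constant response has zero total and residual sums of squares: no
  # variance is explained, so report 0 rather than summary.lm's NaN
  r_squared <- if (is.nan(s$r.squared)) 0 else s$r.squared
  structure(
    list(
      slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]),
      r_squared = r_squared,
      degrees_freedom = fit$df.residual,
      p_value = unname(coef(s)[2, 4]),
      n = nrow(d),
      variant = variant,
      fit = fit
    ),
    class = "tourism_regression"
  )
}

#' @export
print.tourism_regression <- function(x, ...) {
  cat(sprintf(
    "OLS of %s(T) on ln(G): slope = %.4g, intercept = %.4g\nR^2 = %.4g, d.f. = %d, p = %.4g (n = %d)\n",
    x$variant, x$slope, x$intercept, x$r_squared, x$degrees_freedom,
    x$p_value, x$n
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.tourism_regression <- function(x, ...) {
  s <- summary(x$fit)
  co <- coef(s)
  tibble::tibble(
    term = c("intercept", "ln_G"),
    estimate = co[, 1],
    std_error = co[, 2],
    statistic = co[, 3],
    p_value = co[, 4]
  )
}

#' @exportS3Method generics::glance
glance.tourism_regression <- function(x, ...) {
  tibble::tibble(
    r_squared = x$r_squared,
    degrees_freedom = x$degrees_freedom,
    p_value = x$p_value,
    n = x$n,
    variant = x$variant
  )
}
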