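#' Simple linear regression of a donor metric on BMI (or any predictor)
#'
#' Ordinary least squares with two-sided slope p-value, R-squared, and
#' pointwise 95% confidence band, the per-panel statistic used for
#' donor-level metric-vs-BMI plots.
#'
#' @param data Tibble of donor-level values.
#' @param outcome,predictor Column names (strings). `predictor` defaults to
#'   `"bmi"`.
#' @return A `cohort_fit` object wrapping the [stats::lm()] fit. Use
#'   [tidy()] / [glance()] for coefficient and fit summaries and
#'   [augment.cohort_fit()] for the confidence band.
#' @export
simple_linreg <- function(data, outcome, predictor = "bmi") {
  data <- as_tibble(data)
  for (cl in c(outcome, predictor)) {
    if (!cl %in% names(data)) abort(paste0("column not found: ", cl))
  }
  data <- data[complete.cases(data[, c(outcome, predictor)]), ]
  if (nrow(data) < 3L) abort("need at least 3 donors")
  if (var(data[[predictor]]) == 0) abort("predictor is constant")
  fit <- lm(as.formula(paste0("`", outcome, "` ~ `", predictor, "`")),
            data = data)
  out <- list(fit = fit, outcome = outcome, predictor = predictor,
              covariates = predictor, retained_covariates = predictor,
              n_donors = nrow(data), data = data, mode = "simple")
  class(out) <- "cohort_fit"
  out
}

#' Multivariable regression with covariate screening
#'
#' Two-stage fit: a full model with all covariates, then a final model
#' retaining only covariates whose full-model p-value (term-wise F test)
#' falls below `p_enter` (default 0.3). The focal predictor (BMI by
#' default) is always retained and reported, so spatial metrics can be
#' batch-corrected by keeping the TMA batch term in the model.
#'
#' @param data Donor-level tibble.
#' @param outcome Outcome column name.
#' @param covariates Candidate covariate columns (default BMI, age, sex,
#'   diabetes, alcohol, smoking, batch).
#' @param p_enter Screening threshold on full-model term p-values.
#' @param always_keep Covariates reported regardless of screening.
#' @return A `cohort_fit` with `retained_covariates`; `tidy()` reports the
#'   final-model terms.
#' @export
multivariable_select <- function(data, outcome,
                                 covariates = c("bmi", "age", "sex",
                                                "diabetes", "alcohol",
                                                "smoking", "batch"),
                                 p_enter = 0.3, always_keep = "bmi") {
  data <- as_tibble(data)
  for (cl in c(outcome, covariates)) {
    if (!cl %in% names(data)) abort(paste0("column not found: ", cl))
  }
  covariates <- sort(unique(covariates))  # order-invariant result
  data <- data[complete.cases(data[, c(outcome, covariates)]), ]
  # drop covariates with a single observed level (unestimable terms)
  usable <- covariates[purrr::map_lgl(covariates, function(cl) {
    length(unique(data[[cl]])) > 1L
  })]
  dropped <- setdiff(covariates, usable)
  if (length(dropped) > 0) {
    inform(paste0("dropping constant covariate(s): ",
                  paste(dropped, collapse = ", ")))
  }
  if (nrow(data) <= length(usable) + 1L) {
    abort("need more donors than covariates")
  }
  form <- function(cv) as.formula(paste0("`", outcome, "` ~ ",
                                         paste0("`", cv, "`",
                                                collapse = " + ")))
  full <- lm(form(usable), data = data)
  mm <- stats::model.matrix(full)
  if (kappa(mm, exact = TRUE) > 1e8) {
    abort(paste0("collinear design among covariates: ",
                 paste(usable, collapse = ", ")))
  }
  # term-wise p-values from the full model (F tests handle factor terms)
  dr <- drop1(full, test = "F")
  termp <- setNames(dr[["Pr(>F)"]], gsub("`", "", rownames(dr)))
  termp <- termp[!is.na(termp)]
  retained <- union(intersect(always_keep, usable),
                    names(termp)[termp < p_enter])
  retained <- usable[usable %in% retained]  # stable order
  final <- lm(form(retained), data = data)
  out <- list(fit = final, outcome = outcome, predictor = always_keep[1],
              covariates = usable, retained_covariates = retained,
              screening_p = termp, p_enter = p_enter,
              n_donors = nrow(data), data = data, mode = "multivariable")
  class(out) <- "cohort_fit"
  out
}

#' @export
print.cohort_fit <- function(x, ...) {
  cat(sprintf("%s regression of '%s' (%d donors)\n", x$mode, x$outcome,
              x$n_donors))
  cat("  retained covariates:", paste(x$retained_covariates,
                                      collapse = ", "), "\n")
  print(tidy(x))
  invisible(x)
}

#' @method tidy cohort_fit
#' @export
tidy.cohort_fit <- function(x, ...) {
  broom::tidy(x$fit, ...) %>%
    mutate(term = gsub("`", "", .data$term))
}

#' @method glance cohort_fit
#' @export
glance.cohort_fit <- function(x, ...) {
  broom::glance(x$fit, ...) %>%
    # a constant outcome has no variance to explain: report 0, not 0/0
    mutate(r.squared = ifelse(is.nan(.data$r.squared), 0, .data$r.squared),
           outcome = x$outcome, n_donors = x$n_donors, .before = 1)
}

#' Fitted values with pointwise 95% confidence band
#'
#' @param x A `cohort_fit`.
#' @param level Confidence level.
#' @param ... Unused.
#' @return The model data with `.fitted`, `.lower`, `.upper` columns.
#' @method augment cohort_fit
#' @export
augment.cohort_fit <- function(x, level = 0.95, ...) {
  pr <- predict(x$fit, interval = "confidence", level = level)
  x$data %>%
    mutate(.fitted = pr[, "fit"], .lower = pr[, "lwr"], .upper = pr[, "upr"])
}

#' Confidence interval for the focal predictor's slope
#'
#' @param fit A `cohort_fit`.
#' @param level Confidence level.
#' @return Tibble `term`, `estimate`, `conf_low`, `conf_high`.
#' @export
slope_ci <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "cohort_fit"))
  ci <- stats::confint(fit$fit, level = level)
  rn <- gsub("`", "", rownames(ci))
  sel <- which(rn == fit$predictor)
  if (length(sel) != 1L) abort("focal predictor not in the fitted model")
  est <- coef(fit$fit)
  names(est) <- gsub("`", "", names(est))
  tibble(term = fit$predictor,
         estimate = unname(est[fit$predictor]),
         conf_low = ci[sel, 1], conf_high = ci[sel, 2])
}

#' Scatter plot with fit line and confidence band
#'
#' @param object A `cohort_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cohort_fit
#' @importFrom ggplot2 autoplot
#' @export
autoplot.cohort_fit <- function(object, ...) {
  aug <- augment.cohort_fit(object)
  ggplot2::ggplot(aug, ggplot2::aes(.data[[object$predictor]],
                                    .data[[object$outcome]])) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$.lower,
                                      ymax = .data$.upper), alpha = 0.2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$.fitted)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = object$predictor, y = object$outcome) +
    ggplot2::theme_minimal()
}

#' Pearson correlation with two-sided p-value
#'
#' @param x,y Numeric vectors (>= 3 complete pairs, both non-constant).
#' @return Tibble `estimate` (r), `p_value`, `n`.
#' @export
pearson_corr <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) abort("need at least 3 complete pairs")
  if (var(x) == 0 || var(y) == 0) abort("constant input")
  ct <- cor.test(x, y, method = "pearson")
  tibble(estimate = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Chao1 richness estimator
#'
#' Bias-corrected form (default) `S_obs + f1 (f1 - 1) / (2 (f2 + 1))`, with
#' `f1` singletons and `f2` doubletons; the classic form
#' `S_obs + f1^2 / (2 f2)` is available when `f2 > 0`. Used as a clonal
#' diversity metric on TCR clone count tables.
#'
#' @param clone_counts Positive integer counts (one per observed clone /
#'   species), optionally named.
#' @param bias_corrected Use the bias-corrected form (default `TRUE`).
#' @return The richness estimate (>= observed richness).
#' @export
chao1 <- function(clone_counts, bias_corrected = TRUE) {
  counts <- as.numeric(clone_counts)
  if (length(counts) == 0L) abort("empty clone table")
  if (any(counts < 1) || any(counts != round(counts))) {
    abort("clone counts must be positive integers")
  }
  s_obs <- length(counts)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (bias_corrected) {
    s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  } else {
    if (f2 == 0) abort("classic Chao1 requires at least one doubleton")
    s_obs + f1^2 / (2 * f2)
  }
}

#' Regress donor metrics on BMI across a cohort
#'
#' Joins a tidy per-donor metric table to donor covariates and fits either
#' simple or covariate-screened multivariable regressions per metric.
#'
#' @param metrics Tibble `donor_id`, `metric`, `value` (long format).
#' @param donors Donor covariate table.
#' @param mode `"simple"` or `"multivariable"`.
#' @param ... Passed to [simple_linreg()] or [multivariable_select()].
#' @return Tibble of per-metric slope estimates for the focal predictor with
#'   `metric`, `estimate`, `std_error`, `p_value`, `r_squared`, `n_donors`,
#'   `retained_covariates`; the fitted objects are attached as attribute
#'   `"fits"`.
#' @export
regress_metrics <- function(metrics, donors, mode = c("simple",
                                                      "multivariable"), ...) {
  mode <- match.arg(mode)
  metrics <- as_tibble(metrics)
  donors <- as_tibble(donors)
  missing_donors <- setdiff(unique(metrics$donor_id), donors$donor_id)
  if (length(missing_donors) > 0) {
    abort(paste0("metrics reference donor(s) absent from the donor table: ",
                 paste(missing_donors, collapse = ", ")))
  }
  fits <- purrr::map(split(metrics, metrics$metric), function(mt) {
    df <- mt %>% left_join(donors, by = "donor_id")
    if (mode == "simple") simple_linreg(df, "value", ...)
    else multivariable_select(df, "value", ...)
  })
  out <- purrr::imap(fits, function(f, nm) {
    td <- tidy(f) %>% filter(.data$term == f$predictor)
    tibble(metric = nm,
           estimate = td$estimate, std_error = td$std.error,
           p_value = td$p.value,
           r_squared = summary(f$fit)$r.squared,
           n_donors = f$n_donors,
           retained_covariates = paste(f$retained_covariates,
                                       collapse = "+"))
  }) %>% bind_rows()
  attr(out, "fits") <- fits
  out
}
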