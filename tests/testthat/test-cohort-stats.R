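test_that("simple regression reproduces exact fits and matches normal equations", {
  d <- tibble::tibble(bmi = c(20, 25, 30, 35, 40), value = 2 * c(20, 25, 30, 35, 40))
  fit <- simple_linreg(d, "value")
  td <- suppressWarnings(tidy(fit))  # perfect fit: summary warns
  expect_equal(td$estimate[td$term == "bmi"], 2, tolerance = 1e-12)
  expect_equal(suppressWarnings(glance(fit))$r.squared, 1, tolerance = 1e-12)
  # constant outcome: slope 0
  d2 <- d |> dplyr::mutate(value = 5)
  fit2 <- simple_linreg(d2, "value")
  expect_equal(suppressWarnings(tidy(fit2))$estimate[2], 0, tolerance = 1e-12)
  expect_equal(suppressWarnings(glance(fit2))$r.squared, 0)
  # normal-equation oracle on random data
  withr::with_seed(2, {
    d3 <- tibble::tibble(bmi = runif(40, 18, 45))
    d3$value <- 1 + 0.3 * d3$bmi + rnorm(40)
    f3 <- simple_linreg(d3, "value")
    X <- cbind(1, d3$bmi)
    beta <- solve(t(X) %*% X, t(X) %*% d3$value)
    expect_equal(unname(coef(f3$fit)), as.numeric(beta), tolerance = 1e-10)
  })
  expect_error(simple_linreg(d[1:2, ], "value"), "3 donors")
  expect_error(simple_linreg(d |> dplyr::mutate(bmi = 30), "value"),
               "constant")
})

test_that("confidence bands cover the fitted line and autoplot works", {
  withr::with_seed(14, {
    d <- tibble::tibble(bmi = runif(30, 18, 45))
    d$value <- 0.02 * d$bmi + rnorm(30, sd = 0.05)
    fit <- simple_linreg(d, "value")
    aug <- augment(fit)
    expect_true(all(aug$.lower <= aug$.fitted & aug$.fitted <= aug$.upper))
    p <- ggplot2::ggplot_build(autoplot(fit))
    expect_gt(length(p$data), 0)
  })
})

test_that("covariate screening retains strong terms and drops noise", {
  withr::with_seed(33, {
    n <- 60
    d <- tibble::tibble(
      bmi = runif(n, 18, 45),
      age = runif(n, 25, 70),
      sex = sample(c("M", "F"), n, TRUE),
      diabetes = rbinom(n, 1, 0.2) == 1,
      alcohol = rbinom(n, 1, 0.2) == 1,
      smoking = rbinom(n, 1, 0.3) == 1,
      batch = sample(c("b1", "b2"), n, TRUE)
    )
    d$value <- 0.02 * d$bmi + 0.5 * (d$batch == "b2") + rnorm(n, sd = 0.1)
    fit <- multivariable_select(d, "value")
    expect_true(all(c("bmi", "batch") %in% fit$retained_covariates))
    # noise covariates with large full-model p are screened out
    noisy <- names(fit$screening_p)[fit$screening_p > 0.3]
    expect_false(any(noisy %in% fit$retained_covariates))
    # covariate order must not matter
    fit_rev <- multivariable_select(d, "value",
                                    covariates = rev(c("bmi", "age", "sex",
                                                       "diabetes", "alcohol",
                                                       "smoking", "batch")))
    expect_equal(tidy(fit), tidy(fit_rev))
  })
})

test_that("everything below the entry threshold keeps the full model", {
  withr::with_seed(91, {
    n <- 80
    d <- tibble::tibble(bmi = runif(n, 18, 45), age = runif(n, 25, 70))
    d$value <- 0.05 * d$bmi + 0.05 * d$age + rnorm(n, sd = 0.3)
    fit <- multivariable_select(d, "value", covariates = c("bmi", "age"))
    expect_setequal(fit$retained_covariates, c("bmi", "age"))
  })
})

test_that("collinear designs are rejected", {
  withr::with_seed(3, {
    d <- tibble::tibble(bmi = runif(30, 18, 45))
    d$bmi2 <- d$bmi * 2
    d$value <- rnorm(30)
    expect_error(multivariable_select(d, "value",
                                      covariates = c("bmi", "bmi2")),
                 "collinear")
  })
})

test_that("pearson correlation handles exact and calibrated cases", {
  x <- c(1, 2, 3, 5, 8)
  expect_equal(pearson_corr(x, x)$estimate, 1)
  expect_equal(pearson_corr(x, -x)$estimate, -1)
  expect_error(pearson_corr(x, rep(1, 5)), "constant")
  expect_error(pearson_corr(1:2, 2:3), "3 complete")
  # type-I calibration of the t-transform p-value
  rej <- withr::with_seed(123, {
    mean(vapply(1:2000, function(i) {
      pearson_corr(rnorm(30), rnorm(30))$p_value < 0.05
    }, logical(1)))
  })
  expect_gt(rej, 0.03); expect_lt(rej, 0.07)
})

test_that("chao1 matches hand evaluations and dominates observed richness", {
  expect_equal(chao1(c(A = 5, B = 3)), 2)
  expect_equal(chao1(c(A = 1, B = 1, C = 2), bias_corrected = FALSE), 5)
  expect_equal(chao1(c(A = 1, B = 1, C = 2)), 3.5)
  expect_error(chao1(numeric(0)), "empty")
  expect_error(chao1(c(1, 0.5)), "positive integers")
  expect_error(chao1(c(1, 1, 3), bias_corrected = FALSE), "doubleton")
  withr::with_seed(6, {
    for (i in 1:20) {
      counts <- rpois(50, 2) + 1L
      expect_gte(chao1(counts), length(counts))
    }
  })
})

test_that("bias-corrected chao1 agrees with the vegan estimator", {
  skip_if_not_installed("vegan")
  withr::with_seed(10, {
    for (i in 1:10) {
      counts <- c(rep(1L, rpois(1, 8)), rep(2L, rpois(1, 5)),
                  rpois(20, 6) + 3L)
      comm <- matrix(counts, nrow = 1)
      expect_equal(chao1(counts),
                   unname(vegan::estimateR(comm)["S.chao1", 1]),
                   tolerance = 1e-8)
    }
  })
})

test_that("regress_metrics ties metric tables to donor covariates", {
  co <- generate_cohort(subset_cohort_config(n_donors = 12), seed = 44)
  metric <- subset_fraction_metric(co) |>
    dplyr::transmute(donor_id, metric = "cd11c_high_fraction", value)
  out <- regress_metrics(metric, co$donors, mode = "simple")
  expect_equal(out$metric, "cd11c_high_fraction")
  expect_true(out$estimate > 0)   # planted positive BMI slope
  bad <- metric |> dplyr::mutate(donor_id = paste0(donor_id, "X"))
  expect_error(regress_metrics(bad, co$donors), "absent")
})
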