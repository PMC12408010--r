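#' Fit a Box-Cox normalization model
#'
#' Finds the Box-Cox exponent maximizing the profile log-likelihood of the
#' transformed values under a normal model, then records the mean and sample
#' (n-1) SD of the transformed values so the model standardizes its own fit
#' population to mean 0, SD 1.
#'
#' @param values Strictly positive intensities with at least 10 distinct
#'   values.
#' @param lambda_range Search interval for the exponent.
#' @param fit_population Free-text description stored with the model.
#' @return A `boxcox_model` list with fields `lambda`, `center`, `scale`,
#'   `n`, `fit_population`.
#' @export
fit_boxcox <- function(values, lambda_range = c(-5, 5),
                       fit_population = "values") {
  values <- as.numeric(values)
  if (anyNA(values)) abort("values contain NA")
  bad <- which(values <= 0)
  if (length(bad) > 0) {
    abort(paste0("Box-Cox requires strictly positive values; offending ",
                 "element(s): ", paste(head(bad, 5), collapse = ", ")))
  }
  if (length(unique(values)) < 10L) {
    abort("need at least 10 distinct values to fit a Box-Cox exponent")
  }
  n <- length(values)
  slog <- sum(log(values))
  loglik <- function(lambda) {
    y <- boxcox_transform(values, lambda)
    s2 <- mean((y - mean(y))^2)
    -n / 2 * log(s2) + (lambda - 1) * slog
  }
  opt <- optimize(loglik, lambda_range, maximum = TRUE, tol = 1e-6)
  lambda <- opt$maximum
  y <- boxcox_transform(values, lambda)
  model <- list(lambda = lambda, center = mean(y), scale = sd(y), n = n,
                fit_population = fit_population)
  if (!is.finite(model$scale) || model$scale <= 0) {
    abort("degenerate fit: transformed values have zero dispersion")
  }
  class(model) <- "boxcox_model"
  model
}

# raw power-family transform (no standardization)
boxcox_transform <- function(x, lambda) {
  if (abs(lambda) < 1e-12) log(x) else (x^lambda - 1) / lambda
}

#' Apply a fitted Box-Cox normalization
#'
#' Computes `((x^lambda - 1)/lambda - center)/scale` (natural log in place of
#' the power term when `lambda = 0`). Strictly order-preserving; applying a
#' model to its own fit population yields sample mean 0 and SD 1.
#'
#' @param values Strictly positive intensities.
#' @param model A [fit_boxcox()] model.
#' @return Normalized values.
#' @export
apply_normalization <- function(values, model) {
  stopifnot(inherits(model, "boxcox_model"))
  values <- as.numeric(values)
  bad <- which(values <= 0)
  if (length(bad) > 0) {
    abort(paste0("cannot normalize nonpositive value(s) at element(s): ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  (boxcox_transform(values, model$lambda) - model$center) / model$scale
}

#' @export
print.boxcox_model <- function(x, ...) {
  cat(sprintf("Box-Cox normalization model (fit on %s, n = %d)\n",
              x$fit_population, x$n))
  cat(sprintf("  lambda = %.4f, center = %.4f, scale = %.4f\n",
              x$lambda, x$center, x$scale))
  invisible(x)
}

#' @method tidy boxcox_model
#' @export
tidy.boxcox_model <- function(x, ...) {
  tibble(lambda = x$lambda, center = x$center, scale = x$scale, n = x$n,
         fit_population = x$fit_population)
}

#' Classify marker-positive cells against a negative-control population
#'
#' Fits one Box-Cox model on the pooled target and control intensities,
#' normalizes both, and labels target cells `high` when their normalized
#' value exceeds `threshold` (strictly; ties are `low`). The fraction of
#' control cells above threshold is reported as a control false-positive
#' summary; a fraction above 0.2 triggers a warning that the control is not
#' behaving as a negative.
#'
#' @param target_values,control_values Strictly positive intensities.
#' @param threshold Cutoff on the normalized scale (default 0).
#' @return A `marker_classification` list: `labels` (factor high/low per
#'   target cell), `target_normalized`, `control_normalized`, `model`,
#'   `threshold`, `control_positive_fraction`.
#' @export
classify_by_negative_control <- function(target_values, control_values,
                                         threshold = 0) {
  if (length(target_values) == 0L) abort("empty target population")
  if (length(control_values) == 0L) abort("empty control population")
  model <- fit_boxcox(c(target_values, control_values),
                      fit_population = "target + negative control")
  tz <- apply_normalization(target_values, model)
  cz <- apply_normalization(control_values, model)
  ctrl_frac <- mean(cz > threshold)
  if (ctrl_frac > 0.2) {
    warn(sprintf(paste0("%.1f%% of negative-control cells exceed the ",
                        "threshold; control is not behaving as a negative"),
                 100 * ctrl_frac))
  }
  out <- list(
    labels = factor(ifelse(tz > threshold, "high", "low"),
                    levels = c("high", "low")),
    target_normalized = tz,
    control_normalized = cz,
    model = model,
    threshold = threshold,
    control_positive_fraction = ctrl_frac
  )
  class(out) <- "marker_classification"
  out
}

#' @export
print.marker_classification <- function(x, ...) {
  cat(sprintf("Negative-control marker classification (threshold %.2f)\n",
              x$threshold))
  print(table(x$labels))
  cat(sprintf("  control cells above threshold: %.2f%%\n",
              100 * x$control_positive_fraction))
  invisible(x)
}

#' Classify a marker on a cell table using a negative-control cell type
#'
#' Data-frame front end to [classify_by_negative_control()]: for each donor
#' (default) or pooled across donors, fits a Box-Cox model on the marker
#' intensities of target plus control cells and adds a
#' `<marker>_class` column (`high`/`low` for target cells, `NA` elsewhere).
#' The per-donor model report is attached as attribute
#' `"classification_models"`.
#'
#' @param cells A cell table.
#' @param marker Marker column name.
#' @param target_type Cell type to classify (e.g. macrophages).
#' @param control_type Negative-control cell type (e.g. neuroendocrine).
#' @param threshold Normalized-scale cutoff.
#' @param pooled If `TRUE`, fit one model across all donors instead of one
#'   per donor.
#' @return `cells` with the added class column; attribute
#'   `classification_models` holds a tibble of per-fit `lambda`, `center`,
#'   `scale`, and control positive fraction.
#' @export
classify_marker <- function(cells, marker, target_type, control_type,
                            threshold = 0, pooled = FALSE) {
  validate_cell_table(cells)
  if (!marker %in% marker_columns(cells)) {
    abort(paste0("marker column not found: ", marker))
  }
  for (tt in c(target_type, control_type)) {
    if (!tt %in% cells$cell_type) abort(paste0("cell type not present: ", tt))
  }
  col <- paste0(marker, "_class")
  cells[[col]] <- NA_character_
  groups <- if (pooled) list(seq_len(nrow(cells))) else
    split(seq_len(nrow(cells)), cells$donor_id)
  reports <- purrr::imap(groups, function(idx, key) {
    tgt <- idx[cells$cell_type[idx] == target_type]
    ctl <- idx[cells$cell_type[idx] == control_type]
    if (length(tgt) == 0L || length(ctl) == 0L) {
      warn(paste0("donor ", key, ": target or control population empty; ",
                  "skipped"))
      return(NULL)
    }
    cls <- classify_by_negative_control(cells[[marker]][tgt],
                                        cells[[marker]][ctl], threshold)
    cells[[col]][tgt] <<- as.character(cls$labels)
    tibble(donor_id = if (pooled) "(pooled)" else key,
           lambda = cls$model$lambda, center = cls$model$center,
           scale = cls$model$scale, n_target = length(tgt),
           n_control = length(ctl),
           control_positive_fraction = cls$control_positive_fraction)
  })
  attr(cells, "classification_models") <- bind_rows(purrr::compact(reports))
  cells
}

#' Histogram of normalized target and control intensities
#'
#' @param classification A [classify_by_negative_control()] result.
#' @return A ggplot object.
#' @export
plot_classification <- function(classification) {
  stopifnot(inherits(classification, "marker_classification"))
  df <- bind_rows(
    tibble(normalized = classification$target_normalized, population = "target"),
    tibble(normalized = classification$control_normalized,
           population = "negative control")
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$normalized, fill = .data$population)) +
    ggplot2::geom_histogram(alpha = 0.6, position = "identity", bins = 60) +
    ggplot2::geom_vline(xintercept = classification$threshold,
                        linetype = "dashed") +
    ggplot2::labs(x = "Box-Cox normalized intensity", y = "cells") +
    ggplot2::theme_minimal()
}
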