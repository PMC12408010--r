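#' Cell-type composition of k-nearest-cell windows
#'
#' For every cell, finds its `k` nearest other cells (the index cell itself
#' is excluded; use `include_center = TRUE` for the variant that counts it)
#' by Euclidean distance, ties broken by row order, and records the fraction
#' of each cell type among those `k` cells. Donors are processed
#' independently; donors with too few cells are skipped with a warning.
#'
#' @param cells Cell table (any number of donors).
#' @param k Window size (number of neighbouring cells; default 10).
#' @param types Optional fixed set of cell-type columns (default: all types
#'   present, sorted).
#' @param include_center Count the index cell as part of its own window.
#' @return A `window_matrix` tibble: `cell_id`, `donor_id`, `cell_type`,
#'   then one fraction column per type. Rows sum to 1. Attributes: `k`,
#'   `type_cols`.
#' @export
window_composition <- function(cells, k = 10, types = NULL,
                               include_center = FALSE) {
  validate_cell_table(cells)
  if (k < 1) abort("k must be >= 1")
  types <- types %||% sort(unique(cells$cell_type))
  out <- purrr::map(split(cells, cells$donor_id), function(dc) {
    need <- if (include_center) k else k + 1L
    if (nrow(dc) < need) {
      warn(paste0("donor ", dc$donor_id[1], " has ", nrow(dc),
                  " cells (<= k); skipped"))
      return(NULL)
    }
    kk <- if (include_center) k - 1L else k
    lab <- factor(dc$cell_type, levels = types)
    if (kk > 0L) {
      nn <- knn_indices(dc$x, dc$y, kk)
      counts <- matrix(0L, nrow(dc), length(types))
      for (j in seq_len(kk)) {
        lj <- as.integer(lab[nn[, j]])
        counts[cbind(seq_len(nrow(dc)), lj)] <-
          counts[cbind(seq_len(nrow(dc)), lj)] + 1L
      }
    } else {
      counts <- matrix(0L, nrow(dc), length(types))
    }
    if (include_center) {
      counts[cbind(seq_len(nrow(dc)), as.integer(lab))] <-
        counts[cbind(seq_len(nrow(dc)), as.integer(lab))] + 1L
    }
    frac <- counts / k
    colnames(frac) <- types
    bind_cols(dc %>% select("cell_id", "donor_id", "cell_type"),
              as_tibble(frac))
  }) %>% purrr::compact() %>% bind_rows()
  if (nrow(out) == 0L) abort("no donor had more than k cells")
  attr(out, "k") <- k
  attr(out, "type_cols") <- types
  class(out) <- c("window_matrix", class(out))
  out
}

window_values <- function(windows) {
  as.matrix(windows[, attr(windows, "type_cols"), drop = FALSE])
}

# ---- mini-batch k-means ----------------------------------------------------

# seeded k-means++ initialization
kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- X[idx, ]
  d2 <- rowSums(sweep(X, 2L, centers[1L, ])^2)
  for (j in seq_len(k - 1L) + 1L) {
    if (all(d2 == 0)) {
      idx <- sample.int(n, 1L)
    } else {
      idx <- sample.int(n, 1L, prob = d2)
    }
    centers[j, ] <- X[idx, ]
    d2 <- pmin(d2, rowSums(sweep(X, 2L, centers[j, ])^2))
  }
  centers
}

nearest_center <- function(X, centers) {
  # argmin_j ||x - c_j||^2 via the expansion trick
  cross <- X %*% t(centers)
  cn <- rowSums(centers^2)
  max.col(sweep(2 * cross, 2L, cn), ties.method = "first")
}

minibatch_kmeans <- function(X, k, batch_size = 1024L, n_iter = 120L) {
  n <- nrow(X)
  centers <- kmeanspp_init(X, k)
  counts <- rep(0, k)
  for (it in seq_len(n_iter)) {
    b <- X[sample.int(n, min(batch_size, n)), , drop = FALSE]
    a <- nearest_center(b, centers)
    for (j in unique(a)) {
      rows <- which(a == j)
      for (r in rows) {
        counts[j] <- counts[j] + 1
        eta <- 1 / counts[j]
        centers[j, ] <- (1 - eta) * centers[j, ] + eta * b[r, ]
      }
    }
  }
  assign <- nearest_center(X, centers)
  # final centroids = means of assigned points (empty clusters keep centers)
  for (j in seq_len(k)) {
    if (any(assign == j)) centers[j, ] <- colMeans(X[assign == j, , drop = FALSE])
  }
  assign <- nearest_center(X, centers)
  inertia <- sum((X - centers[assign, , drop = FALSE])^2)
  list(cluster = assign, centers = centers, inertia = inertia)
}

#' Cluster composition windows into cellular neighbourhoods
#'
#' Pools the windows of all donors and clusters them in composition space
#' with mini-batch k-means (full-batch Lloyd via [stats::kmeans()] with 10
#' restarts when `batch_size` covers the data). Deterministic given
#' `(data, seed)`.
#'
#' @param windows A [window_composition()] result (all donors pooled).
#' @param n_clusters Number of neighbourhoods (default 7).
#' @param seed Integer seed.
#' @param batch_size Mini-batch size; `Inf` (default) runs full-batch
#'   k-means.
#' @param n_iter Mini-batch iterations.
#' @return A `neighborhood_model` list: `n_clusters`, `centroids`
#'   (cluster x type), `labels` (tibble `cell_id`, `donor_id`, `nh` in
#'   `0:(n_clusters-1)`), `inertia`, `k` (window size), `type_cols`.
#' @export
cluster_windows <- function(windows, n_clusters = 7, seed,
                            batch_size = Inf, n_iter = 120L) {
  stopifnot(inherits(windows, "window_matrix"))
  if (missing(seed)) abort("cluster_windows() requires an explicit seed")
  X <- window_values(windows)
  if (n_clusters < 1) abort("n_clusters must be >= 1")
  if (nrow(X) < n_clusters) {
    abort("fewer window rows than requested clusters")
  }
  fit <- withr::with_seed(seed, {
    if (n_clusters == nrow(X)) {
      list(cluster = seq_len(nrow(X)), centers = X, inertia = 0)
    } else if (is.finite(batch_size) && batch_size < nrow(X)) {
      minibatch_kmeans(X, n_clusters, batch_size = batch_size, n_iter = n_iter)
    } else {
      km <- kmeans(X, centers = n_clusters, nstart = 10L, iter.max = 100L)
      list(cluster = km$cluster, centers = km$centers,
           inertia = km$tot.withinss)
    }
  })
  centroids <- fit$centers
  colnames(centroids) <- attr(windows, "type_cols")
  out <- list(
    n_clusters = as.integer(n_clusters),
    centroids = centroids,
    labels = tibble(cell_id = windows$cell_id, donor_id = windows$donor_id,
                    nh = as.integer(fit$cluster) - 1L),
    inertia = fit$inertia,
    k = attr(windows, "k"),
    type_cols = attr(windows, "type_cols")
  )
  class(out) <- "neighborhood_model"
  out
}

#' @export
print.neighborhood_model <- function(x, ...) {
  cat(sprintf("neighborhood model: %d NHs over %d windows (k = %d)\n",
              x$n_clusters, nrow(x$labels), x$k))
  invisible(x)
}

#' Merge neighbourhood labels post hoc
#'
#' Applies a merge map (old label -> new label) to a fitted model, e.g. to
#' consolidate 10 k-means clusters into a smaller set of reported
#' neighbourhood types.
#'
#' @param model A [cluster_windows()] model.
#' @param merge_map Named integer vector mapping old `nh` labels to new ones.
#' @return The model with relabelled `nh` and updated `n_clusters`.
#' @export
merge_neighborhoods <- function(model, merge_map) {
  stopifnot(inherits(model, "neighborhood_model"))
  old <- as.character(model$labels$nh)
  if (!all(old %in% names(merge_map))) {
    abort("merge_map must cover every existing NH label")
  }
  model$labels$nh <- as.integer(merge_map[old])
  model$n_clusters <- length(unique(model$labels$nh))
  model$centroids <- NULL
  model
}

#' Neighbourhood-by-type enrichment matrix
#'
#' `enrichment(NH, t) = log2((mean window fraction of t in NH + eps) /
#' (overall mean window fraction of t + eps))` with pseudo-fraction
#' `eps = 1 / total cells`. A neighbourhood whose mean composition equals
#' the global composition scores ~0 everywhere.
#'
#' @param model A [cluster_windows()] model.
#' @param windows The window matrix the model was fitted on.
#' @return Tibble `nh`, `cell_type`, `enrichment`.
#' @export
nh_enrichment <- function(model, windows) {
  stopifnot(inherits(model, "neighborhood_model"),
            inherits(windows, "window_matrix"))
  X <- window_values(windows)
  eps <- 1 / nrow(X)
  global <- colMeans(X)
  keep <- global > 0
  if (any(!keep)) {
    inform(paste0("dropping globally absent type(s): ",
                  paste(colnames(X)[!keep], collapse = ", ")))
  }
  purrr::map(sort(unique(model$labels$nh)), function(h) {
    rows <- model$labels$nh == h
    m <- colMeans(X[rows, keep, drop = FALSE])
    tibble(nh = h, cell_type = colnames(X)[keep],
           enrichment = unname(log2((m + eps) / (global[keep] + eps))))
  }) %>% bind_rows()
}

#' Per-donor neighbourhood frequencies
#'
#' @param model A [cluster_windows()] model.
#' @return Tibble `donor_id`, `nh`, `frequency`; frequencies sum to 1 per
#'   donor (over the donor's windowed cells).
#' @export
nh_frequencies <- function(model) {
  stopifnot(inherits(model, "neighborhood_model"))
  model$labels %>%
    count(.data$donor_id, nh = factor(.data$nh,
                                      levels = sort(unique(model$labels$nh)))) %>%
    tidyr::complete(.data$donor_id, .data$nh, fill = list(n = 0L)) %>%
    group_by(.data$donor_id) %>%
    mutate(frequency = .data$n / sum(.data$n)) %>%
    ungroup() %>%
    mutate(nh = as.integer(as.character(.data$nh))) %>%
    select("donor_id", "nh", "frequency")
}

#' Heatmap of an enrichment matrix
#'
#' @param enrichment Tibble from [nh_enrichment()] or
#'   [region_summary()]`$enrichment` (columns: a grouping column, `cell_type`,
#'   `enrichment`).
#' @return A ggplot object.
#' @export
plot_enrichment <- function(enrichment) {
  group_col <- setdiff(names(enrichment), c("cell_type", "enrichment"))[1]
  ggplot2::ggplot(enrichment,
                  ggplot2::aes(.data$cell_type,
                               factor(.data[[group_col]]),
                               fill = .data$enrichment)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b") +
    ggplot2::labs(x = NULL, y = group_col, fill = "log2\nenrichment") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
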