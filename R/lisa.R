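#' Multi-radius local composition (LISA-style) features
#'
#' For every cell and every radius, computes the proportion of neighbouring
#' cells (index cell excluded) of each cell type within that radius, then
#' centres each proportion by subtracting the type's global proportion
#' (pooled over all input cells). A cell with no neighbours at a radius gets
#' the zero proportion vector (centred: minus the global proportions); such
#' cells are tallied in the `coverage` attribute rather than dropped.
#' Donors are processed independently.
#'
#' @param cells Cell table (any number of donors).
#' @param radii Strictly increasing positive radii in micrometres
#'   (default 10, 20, 50).
#' @param types Optional fixed type set (default: all types present, sorted).
#' @return A `lisa_features` tibble: `cell_id`, `donor_id`, then one column
#'   `r<radius>_<type>` per (radius, type). Attributes: `radii`, `types`,
#'   `global` (global type proportions), `coverage` (tibble of the fraction
#'   of cells with zero neighbours per radius).
#' @export
lisa_features <- function(cells, radii = c(10, 20, 50), types = NULL) {
  validate_cell_table(cells)
  if (any(radii <= 0) || is.unsorted(radii, strictly = TRUE)) {
    abort("radii must be strictly increasing and positive")
  }
  types <- types %||% sort(unique(cells$cell_type))
  if (length(types) == 0L) abort("empty type set")
  global <- as.numeric(table(factor(cells$cell_type, levels = types))) /
    nrow(cells)
  names(global) <- types
  rmax <- max(radii)
  feature_cols <- paste0("r", rep(radii, each = length(types)), "_",
                         rep(types, times = length(radii)))
  out <- purrr::map(split(cells, cells$donor_id), function(dc) {
    n <- nrow(dc)
    lab <- as.integer(factor(dc$cell_type, levels = types))
    pr <- radius_pairs(dc$x, dc$y, rmax)
    feats <- matrix(0, n, length(types) * length(radii))
    zero_counts <- numeric(length(radii))
    for (ri in seq_along(radii)) {
      keep <- pr$distance <= radii[ri]
      i <- c(pr$i[keep], pr$j[keep])
      j <- c(pr$j[keep], pr$i[keep])
      # counts[cell, type] of neighbours within this radius
      counts <- matrix(0, n, length(types))
      if (length(i) > 0) {
        tab <- table(factor(i, levels = seq_len(n)), factor(lab[j],
                                                            levels = seq_along(types)))
        counts <- matrix(as.numeric(tab), n, length(types))
      }
      tot <- rowSums(counts)
      zero_counts[ri] <- sum(tot == 0)
      prop <- counts / pmax(tot, 1)   # zero-neighbour rows stay 0
      cols <- (ri - 1L) * length(types) + seq_along(types)
      feats[, cols] <- sweep(prop, 2L, global)
    }
    list(feats = bind_cols(dc %>% select("cell_id", "donor_id"),
                           as_tibble(`colnames<-`(feats, feature_cols))),
         zero = zero_counts, n = n)
  })
  feats <- bind_rows(purrr::map(out, "feats"))
  zero_tot <- Reduce(`+`, purrr::map(out, "zero"))
  coverage <- tibble(radius = radii,
                     zero_neighbour_fraction = zero_tot / nrow(cells))
  attr(feats, "radii") <- radii
  attr(feats, "types") <- types
  attr(feats, "global") <- global
  attr(feats, "coverage") <- coverage
  class(feats) <- c("lisa_features", class(feats))
  feats
}

lisa_values <- function(features) {
  cols <- setdiff(names(features), c("cell_id", "donor_id"))
  as.matrix(features[, cols, drop = FALSE])
}

#' PCA reduction of LISA features
#'
#' Mean-centred principal component analysis, components ordered by
#' decreasing variance, retained either by count or by cumulative explained
#' variance.
#'
#' @param features A [lisa_features()] matrix (or any numeric-feature
#'   tibble with `cell_id`, `donor_id` leading columns).
#' @param n_components Number of components; overrides `variance_target`.
#' @param variance_target Cumulative explained-variance target in `(0, 1]`
#'   (default 0.9).
#' @return List: `scores` (matrix), `rotation`, `explained_variance`
#'   (proportions for all components), `n_components`.
#' @export
reduce_features <- function(features, n_components = NULL,
                            variance_target = 0.9) {
  X <- lisa_values(features)
  if (nrow(X) <= 1L) abort("need more than one row")
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  varprop <- pc$sdev^2 / sum(pc$sdev^2)
  if (!any(pc$sdev > 0)) abort("degenerate input: all features constant")
  if (is.null(n_components)) {
    if (variance_target <= 0 || variance_target > 1) {
      abort("variance_target must be in (0, 1]")
    }
    n_components <- if (variance_target >= 1) sum(pc$sdev > 0) else
      which(cumsum(varprop) >= variance_target)[1]
  }
  n_components <- min(n_components, ncol(pc$x))
  list(scores = pc$x[, seq_len(n_components), drop = FALSE],
       rotation = pc$rotation[, seq_len(n_components), drop = FALSE],
       explained_variance = varprop,
       n_components = n_components)
}

#' Assign cells to spatial context regions by k-means
#'
#' Seeded k-means (10 restarts, best inertia; inertia ties resolve to the
#' first restart) on reduced LISA features.
#'
#' @param reduced A [reduce_features()] result or a numeric matrix.
#' @param k Number of regions (default 7).
#' @param seed Integer seed.
#' @param nstart Restarts.
#' @return Integer region labels in `0:(k-1)`, one per row.
#' @export
assign_regions <- function(reduced, k = 7, seed, nstart = 10L) {
  if (missing(seed)) abort("assign_regions() requires an explicit seed")
  X <- if (is.list(reduced) && !is.data.frame(reduced)) reduced$scores else
    as.matrix(reduced)
  if (nrow(X) < k) abort("fewer rows than regions requested")
  if (k == 1L) return(rep(0L, nrow(X)))
  km <- withr::with_seed(seed,
                         kmeans(X, centers = k, nstart = nstart,
                                iter.max = 100L))
  as.integer(km$cluster) - 1L
}

#' Region enrichment and per-donor region frequencies
#'
#' `enrichment(region, t) = log2((fraction of type t among region cells +
#' eps) / (global fraction of t + eps))`, `eps = 1 / total cells`;
#' frequencies are per-donor fractions of cells per region.
#'
#' @param region_labels Integer labels aligned with `cells` rows.
#' @param cells The cell table the labels refer to.
#' @return List of tibbles: `enrichment` (`region`, `cell_type`,
#'   `enrichment`) and `frequencies` (`donor_id`, `region`, `frequency`,
#'   summing to 1 per donor).
#' @export
region_summary <- function(region_labels, cells) {
  if (length(region_labels) != nrow(cells)) {
    abort("labels and cells are not aligned")
  }
  n <- nrow(cells)
  eps <- 1 / n
  types <- sort(unique(cells$cell_type))
  global <- as.numeric(table(factor(cells$cell_type, levels = types))) / n
  enrichment <- purrr::map(sort(unique(region_labels)), function(rg) {
    sel <- region_labels == rg
    frac <- as.numeric(table(factor(cells$cell_type[sel], levels = types))) /
      sum(sel)
    tibble(region = rg, cell_type = types,
           enrichment = log2((frac + eps) / (global + eps)))
  }) %>% bind_rows()
  regions <- sort(unique(region_labels))
  frequencies <- tibble(donor_id = cells$donor_id,
                        region = factor(region_labels, levels = regions)) %>%
    count(.data$donor_id, .data$region) %>%
    tidyr::complete(.data$donor_id, .data$region, fill = list(n = 0L)) %>%
    group_by(.data$donor_id) %>%
    mutate(frequency = .data$n / sum(.data$n)) %>%
    ungroup() %>%
    mutate(region = as.integer(as.character(.data$region))) %>%
    select("donor_id", "region", "frequency")
  list(enrichment = enrichment, frequencies = frequencies)
}

#' End-to-end LISA region assignment
#'
#' Chains [lisa_features()], [reduce_features()], [assign_regions()], and
#' [region_summary()].
#'
#' @param cells Cell table.
#' @param radii LISA radii (micrometres).
#' @param k Number of regions.
#' @param variance_target PCA cumulative-variance target.
#' @param seed Integer seed.
#' @return A `region_model` list: `labels` (tibble `cell_id`, `donor_id`,
#'   `region`), `pca` (reduction), `enrichment`, `frequencies`, `coverage`,
#'   `radii`, `k`.
#' @export
lisa_regions <- function(cells, radii = c(10, 20, 50), k = 7,
                         variance_target = 0.9, seed) {
  if (missing(seed)) abort("lisa_regions() requires an explicit seed")
  feats <- lisa_features(cells, radii)
  red <- reduce_features(feats, variance_target = variance_target)
  labels <- assign_regions(red, k = k, seed = seed)
  summ <- region_summary(labels, cells)
  out <- list(labels = tibble(cell_id = cells$cell_id,
                              donor_id = cells$donor_id,
                              region = labels),
              pca = red[c("rotation", "explained_variance", "n_components")],
              enrichment = summ$enrichment,
              frequencies = summ$frequencies,
              coverage = attr(feats, "coverage"),
              radii = radii, k = k)
  class(out) <- "region_model"
  out
}

#' @export
print.region_model <- function(x, ...) {
  cat(sprintf("LISA region model: %d regions, radii %s um, %d cells, %d PCs\n",
              x$k, paste(x$radii, collapse = "/"), nrow(x$labels),
              x$pca$n_components))
  invisible(x)
}
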