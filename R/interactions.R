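#' Observed neighbour-pair count between two cell types
#'
#' Number of unordered proximity-graph edges with one endpoint of each type
#' (for `type_a == type_b`, edges with both endpoints that type; each edge
#' counted once).
#'
#' @param graph A [build_proximity_graph()] result.
#' @param type_a,type_b Cell-type labels.
#' @return Integer count.
#' @export
observed_pair_count <- function(graph, type_a, type_b) {
  stopifnot(inherits(graph, "proximity_graph"))
  for (t in unique(c(type_a, type_b))) {
    if (!t %in% graph$cell_type) abort(paste0("unknown cell type: ", t))
  }
  la <- graph$cell_type[graph$edges$ia]
  lb <- graph$cell_type[graph$edges$ib]
  if (type_a == type_b) {
    sum(la == type_a & lb == type_a)
  } else {
    sum((la == type_a & lb == type_b) | (la == type_b & lb == type_a))
  }
}

#' Expected neighbour-pair count under random label assignment
#'
#' Closed form for the mean pair count when labels are uniformly permuted
#' over the nodes of a fixed graph with `M` edges and `n` nodes:
#' `M * 2 * n_a * n_b / (n (n-1))` for distinct types and
#' `M * n_a (n_a - 1) / (n (n-1))` for a type with itself.
#'
#' @param graph A proximity graph.
#' @param type_counts Named vector of per-type node counts; must sum to the
#'   number of nodes. Defaults to the counts of the graph's own labels.
#' @param type_a,type_b Cell-type labels.
#' @return Expected count (numeric).
#' @export
expected_pair_count <- function(graph, type_a, type_b, type_counts = NULL) {
  stopifnot(inherits(graph, "proximity_graph"))
  n <- length(graph$cell_id)
  if (n < 2L) abort("need at least two nodes")
  type_counts <- type_counts %||% table(graph$cell_type)
  if (sum(type_counts) != n) abort("type_counts must sum to the node count")
  M <- nrow(graph$edges)
  na <- as.numeric(type_counts[type_a] %||% 0)
  nb <- as.numeric(type_counts[type_b] %||% 0)
  if (is.na(na) || is.na(nb)) abort("type absent from type_counts")
  if (type_a == type_b) {
    M * na * (na - 1) / (n * (n - 1))
  } else {
    M * 2 * na * nb / (n * (n - 1))
  }
}

#' Standardized-residual interaction score
#'
#' `(observed - expected) / sqrt(expected)`: 0 indicates no spatial
#' preference, positive values attraction, negative values avoidance.
#' `expected = 0` with `observed = 0` yields 0; `expected = 0` with positive
#' `observed` is undefined and returns `NA` with a warning.
#'
#' @param observed,expected Nonnegative pair counts (vectorized).
#' @return Score(s).
#' @export
interaction_score <- function(observed, expected) {
  if (any(observed < 0) || any(expected < 0)) {
    abort("observed and expected counts must be nonnegative")
  }
  out <- numeric(length(observed))
  zero <- expected == 0
  bad <- zero & observed > 0
  if (any(bad)) {
    warn("expected count 0 with positive observed count: score undefined")
    out[bad] <- NA_real_
  }
  ok <- !zero
  out[ok] <- (observed[ok] - expected[ok]) / sqrt(expected[ok])
  out[zero & observed == 0] <- 0
  out
}

all_type_pairs <- function(types) {
  types <- sort(unique(types))
  tidyr::expand_grid(type_a = types, type_b = types) %>%
    filter(.data$type_a <= .data$type_b)
}

#' Permutation test of pairwise interaction counts
#'
#' Uniformly permutes the full cell-type label vector over the fixed graph
#' `n_perm` times. For each requested pair the two-sided p-value around the
#' closed-form expectation is
#' `p = (1 + #permutations with |O_perm - E| >= |O_obs - E|) / (n_perm + 1)`.
#'
#' @param graph A proximity graph.
#' @param pairs Tibble with columns `type_a`, `type_b`; default all unordered
#'   pairs of types present.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return Tibble `type_a`, `type_b`, `observed`, `expected`, `score`,
#'   `p_value`, `null_mean`, `null_sd`, `n_perm`. Pairs involving a type
#'   with no cells are skipped with a message.
#' @export
permutation_test <- function(graph, pairs = NULL, n_perm = 1000, seed) {
  stopifnot(inherits(graph, "proximity_graph"))
  if (missing(seed)) abort("permutation_test() requires an explicit seed")
  if (n_perm < 1) abort("n_perm must be >= 1")
  types <- sort(unique(graph$cell_type))
  pairs <- pairs %||% all_type_pairs(types)
  pairs <- as_tibble(pairs)
  present <- pairs$type_a %in% types & pairs$type_b %in% types
  if (any(!present)) {
    inform(paste0("skipping pair(s) with absent type: ",
                  paste(paste(pairs$type_a[!present], pairs$type_b[!present],
                              sep = "-"), collapse = ", ")))
    pairs <- pairs[present, ]
  }
  if (nrow(pairs) == 0L) abort("no testable pairs")

  K <- length(types)
  lab <- as.integer(factor(graph$cell_type, levels = types))
  ia <- graph$edges$ia; ib <- graph$edges$ib
  n <- length(lab)
  code <- function(l) {  # symmetric pair code for edge endpoint labels
    la <- l[ia]; lb <- l[ib]
    a <- pmin(la, lb); b <- pmax(la, lb)
    (a - 1L) * K + b
  }
  pair_idx <- {
    a <- match(pmin(pairs$type_a, pairs$type_b), types)
    b <- match(pmax(pairs$type_a, pairs$type_b), types)
    (a - 1L) * K + b
  }
  obs <- tabulate(code(lab), K * K)[pair_idx]
  expd <- purrr::map2_dbl(pairs$type_a, pairs$type_b,
                          ~ expected_pair_count(graph, .x, .y))
  null_counts <- withr::with_seed(seed, {
    out <- matrix(0L, n_perm, length(pair_idx))
    for (p in seq_len(n_perm)) {
      out[p, ] <- tabulate(code(lab[sample.int(n)]), K * K)[pair_idx]
    }
    out
  })
  stat_obs <- abs(obs - expd)
  stat_null <- abs(sweep(null_counts, 2L, expd))
  pvals <- (1 + colSums(stat_null >= rep(stat_obs, each = n_perm))) /
    (n_perm + 1)
  pairs %>%
    mutate(observed = obs,
           expected = expd,
           score = interaction_score(obs, expd),
           p_value = pvals,
           null_mean = colMeans(null_counts),
           null_sd = apply(null_counts, 2L, sd),
           n_perm = as.integer(n_perm))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Validating wrapper over `stats::p.adjust(method = "BH")`: step-up
#' adjustment with monotonicity enforcement, input order preserved.
#'
#' @param p_values P-values in `(0, 1]`.
#' @return Adjusted q-values, same order.
#' @export
adjust_fdr <- function(p_values) {
  if (anyNA(p_values) || any(p_values <= 0) || any(p_values > 1)) {
    abort("p-values must lie in (0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Per-donor pairwise interaction analysis
#'
#' Builds one proximity graph per donor, runs the permutation test over all
#' (or the given) type pairs, and BH-adjusts p-values jointly within each
#' donor.
#'
#' @param cells Cell table (any number of donors).
#' @param radius Neighbour radius, micrometres.
#' @param pairs Optional pair table (`type_a`, `type_b`).
#' @param n_perm Permutations per donor.
#' @param seed Master seed; per-donor sub-seeds are derived from it so donor
#'   results are reproducible independently of processing order.
#' @param class_column Optional classification column appended to cell types
#'   (see [proximity_fractions()]).
#' @return An `interaction_result` tibble: `donor_id`, `type_a`, `type_b`,
#'   `observed`, `expected`, `score`, `p_value`, `q_value`, `null_mean`,
#'   `null_sd`, `n_perm`; attribute `radius`.
#' @export
interaction_analysis <- function(cells, radius = 20, pairs = NULL,
                                 n_perm = 1000, seed, class_column = NULL) {
  validate_cell_table(cells)
  if (missing(seed)) abort("interaction_analysis() requires an explicit seed")
  if (!is.null(class_column)) {
    cells <- cells %>%
      mutate(cell_type = ifelse(is.na(.data[[class_column]]),
                                .data$cell_type,
                                paste(.data$cell_type,
                                      .data[[class_column]], sep = "_")))
  }
  donors <- sort(unique(cells$donor_id))
  seeds <- derive_seeds(seed, length(donors))
  out <- purrr::map2(donors, seeds, function(d, s) {
    g <- build_proximity_graph(cells[cells$donor_id == d, ], radius)
    permutation_test(g, pairs = pairs, n_perm = n_perm, seed = s) %>%
      mutate(donor_id = d, .before = 1) %>%
      mutate(q_value = adjust_fdr(.data$p_value), .after = "p_value")
  }) %>% bind_rows()
  attr(out, "radius") <- radius
  class(out) <- c("interaction_result", class(out))
  out
}

#' Aggregate per-donor interaction records across a cohort
#'
#' @param result An [interaction_analysis()] result (or any tibble with
#'   `donor_id`, `type_a`, `type_b`, `score`, `q_value`).
#' @param alpha Significance level on the adjusted p-value.
#' @return Tibble `type_a`, `type_b`, `mean_score`, `n_donors`,
#'   `n_significant`; donors lacking a pair (or with undefined score) are
#'   excluded from that pair's mean.
#' @export
aggregate_interactions <- function(result, alpha = 0.05) {
  if (nrow(result) == 0L) abort("empty interaction table")
  result %>%
    filter(!is.na(.data$score)) %>%
    group_by(.data$type_a, .data$type_b) %>%
    summarise(mean_score = mean(.data$score),
              n_donors = dplyr::n_distinct(.data$donor_id),
              n_significant = sum(.data$q_value < alpha),
              .groups = "drop")
}

#' Heatmap of aggregated interaction scores
#'
#' @param object An `interaction_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot interaction_result
#' @export
autoplot.interaction_result <- function(object, ...) {
  agg <- aggregate_interactions(object)
  full <- bind_rows(agg,
                    agg %>% filter(.data$type_a != .data$type_b) %>%
                      rename(type_a = "type_b", type_b = "type_a"))
  ggplot2::ggplot(full, ggplot2::aes(.data$type_a, .data$type_b,
                                     fill = .data$mean_score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b") +
    ggplot2::labs(x = NULL, y = NULL, fill = "mean\nscore") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
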