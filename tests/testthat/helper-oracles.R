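# Independent brute-force oracles and small fixture builders used across the
# suite. Oracles deliberately avoid the package's own search code paths.

# O(n^2) radius neighbour oracle via the full distance matrix
bf_radius_pairs <- function(x, y, radius) {
  d <- as.matrix(dist(cbind(x, y)))
  idx <- which(upper.tri(d) & d <= radius, arr.ind = TRUE)
  tibble::tibble(i = unname(idx[, 1]), j = unname(idx[, 2]),
                 distance = unname(d[idx])) |>
    dplyr::arrange(i, j)
}

# O(n^2) k-nearest-neighbour oracle (self excluded, ties by index)
bf_knn <- function(x, y, k) {
  d <- as.matrix(dist(cbind(x, y)))
  diag(d) <- Inf
  t(apply(d, 1, function(row) order(row)[seq_len(k)]))
}

# brute-force pair count on an explicit edge list
bf_pair_count <- function(edges, labels, a, b) {
  la <- labels[edges$ia]; lb <- labels[edges$ib]
  if (a == b) sum(la == a & lb == a)
  else sum((la == a & lb == b) | (la == b & lb == a))
}

# exhaustive-permutation expectation of the pair count on a small graph
bf_expected_count <- function(edges, labels, a, b, max_n = 8) {
  n <- length(labels)
  stopifnot(n <= max_n)
  perms <- gtools_permutations(n)
  mean(apply(perms, 1, function(p) bf_pair_count(edges, labels[p], a, b)))
}

# all permutations of 1:n (tiny n), no external dependency
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- gtools_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# hand-built single-donor cell table from coordinate/type vectors
make_cells <- function(x, y, type, donor = "D1",
                       compartment = "acinar", ...) {
  tibble::tibble(
    cell_id = sprintf("%s_c%03d", donor, seq_along(x)),
    donor_id = donor, x = x, y = y,
    compartment = compartment, cell_type = type, ...
  )
}

# three-zone configuration: each compartment dominated by its own cell type,
# with a little of everything everywhere, used for NH / region recovery
zone_config <- function(n_donors = 1, density = 2500, mix_density = 0) {
  mix <- function(type, main) {
    comps <- c("acinar", "ductal", "islet")
    tibble::tibble(cell_type = type, compartment = comps,
                   density = ifelse(comps == main, density, mix_density))
  }
  tissue_config(
    field_width = 900, field_height = 900,
    n_islets = 2, islet_radius_mean = 230, islet_radius_sd = 10,
    duct_width = 200,
    celltype_spec = dplyr::bind_rows(mix("zoneA", "acinar"),
                                     mix("zoneB", "ductal"),
                                     mix("zoneC", "islet")),
    marker_spec = default_marker_spec()[0, ],
    bmi_subset_slope = 0,
    n_donors = n_donors
  )
}

# minimal single-compartment cohort config carrying only macrophages with the
# CD11c mixture, for regression-recovery simulations
subset_cohort_config <- function(n_donors = 16, density = 600, field = 500,
                                 slope = 0.01, n_batches = 1,
                                 batch_frac_shift = 0, batch_bmi_assoc = 0) {
  tissue_config(
    field_width = field, field_height = field,
    n_islets = 0, duct_width = 0,
    celltype_spec = tibble::tibble(cell_type = "macrophage",
                                   compartment = "acinar",
                                   density = density),
    marker_spec = default_marker_spec()[1, ],
    bmi_subset_slope = slope,
    n_donors = n_donors,
    n_batches = n_batches,
    batch_frac_shift = batch_frac_shift,
    batch_bmi_assoc = batch_bmi_assoc
  )
}

# per-donor fraction of truly CD11c-high macrophages joined to covariates
subset_fraction_metric <- function(cohort) {
  cohort$cells |>
    dplyr::filter(cell_type == "macrophage") |>
    dplyr::group_by(donor_id) |>
    dplyr::summarise(value = mean(true_cd11c_class == "high"),
                     .groups = "drop") |>
    dplyr::left_join(cohort$donors, by = "donor_id")
}

# strip custom classes for plain-tibble joins
as_tibble_plain <- function(x) {
  out <- tibble::as_tibble(x)
  class(out) <- class(tibble::tibble())
  out
}

# build a window_matrix by hand (tests of downstream ops)
make_window_matrix <- function(df, k, types) {
  attr(df, "k") <- k
  attr(df, "type_cols") <- types
  class(df) <- c("window_matrix", class(tibble::tibble()))
  df
}

# numeric feature block of a lisa_features tibble
lisa_values_oracle <- function(f) {
  as.matrix(f[, setdiff(names(f), c("cell_id", "donor_id"))])
}
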