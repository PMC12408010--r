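#' Build a radius-based proximity graph for one donor
#'
#' Connects every pair of cells whose centroid Euclidean distance is at most
#' `radius` (closed ball). The search is exact: no approximate misses.
#' Isolated cells remain as nodes.
#'
#' @param cells Cell table restricted to a single donor.
#' @param radius Neighbour radius in micrometres (default 20, the
#'   conventional cell-contact distance for this assay).
#' @return A `proximity_graph` list: `donor_id`, `radius`, `cell_id` (all
#'   nodes, in input order), `cell_type` (aligned labels), and `edges`
#'   (tibble `a`, `b` of cell ids with `ia`, `ib` node indices and
#'   `distance`, each unordered pair stored once with `ia < ib`).
#' @export
build_proximity_graph <- function(cells, radius = 20) {
  validate_cell_table(cells)
  if (nrow(cells) < 1L) abort("need at least one cell")
  if (radius <= 0) abort("radius must be > 0")
  donor <- single_donor_id(cells)
  pr <- radius_pairs(cells$x, cells$y, radius)
  out <- list(
    donor_id = donor,
    radius = radius,
    cell_id = cells$cell_id,
    cell_type = cells$cell_type,
    edges = tibble(ia = pr$i, ib = pr$j,
                   a = cells$cell_id[pr$i], b = cells$cell_id[pr$j],
                   distance = pr$distance)
  )
  class(out) <- "proximity_graph"
  out
}

#' @export
print.proximity_graph <- function(x, ...) {
  cat(sprintf("proximity graph: donor %s, radius %g um, %d cells, %d edges\n",
              x$donor_id, x$radius, length(x$cell_id), nrow(x$edges)))
  invisible(x)
}

#' @method tidy proximity_graph
#' @export
tidy.proximity_graph <- function(x, ...) {
  x$edges %>% mutate(donor_id = x$donor_id, .before = 1) %>%
    select("donor_id", "a", "b", "distance")
}

#' Fraction of source cells with at least one target-type neighbour
#'
#' Computes `100 * #(source cells with >= 1 target neighbour) / #(source
#' cells)` on a proximity graph — the per-donor "percentage of type X within
#' 20 um of type Y" statistic.
#'
#' @param graph A [build_proximity_graph()] result.
#' @param source_type,target_type Cell-type labels.
#' @return A percentage in `[0, 100]`, or `NA` (with a warning) when the
#'   donor has no source cells.
#' @export
proximity_fraction <- function(graph, source_type, target_type) {
  stopifnot(inherits(graph, "proximity_graph"))
  lab <- graph$cell_type
  src <- which(lab == source_type)
  if (length(src) == 0L) {
    warn(paste0("no cells of source type '", source_type, "' in donor ",
                graph$donor_id))
    return(NA_real_)
  }
  e <- graph$edges
  # neighbours of each endpoint, both directions
  hit <- unique(c(e$ia[lab[e$ib] == target_type],
                  e$ib[lab[e$ia] == target_type]))
  100 * sum(src %in% hit) / length(src)
}

#' Per-donor proximity fractions for a cohort
#'
#' Builds one proximity graph per donor and evaluates
#' [proximity_fraction()] for each source/target combination, yielding a
#' tidy per-donor table ready for regression against donor covariates.
#'
#' @param cells Cell table (any number of donors).
#' @param source_types,target_types Character vectors of cell-type labels.
#' @param radius Neighbour radius in micrometres.
#' @param class_column Optional classification column (e.g. `"CD11c_class"`)
#'   whose values are appended to the cell type as `type_class` labels before
#'   matching, so subset labels like `"macrophage_high"` can be used.
#' @return Tibble `donor_id`, `source`, `target`, `fraction`.
#' @export
proximity_fractions <- function(cells, source_types, target_types,
                                radius = 20, class_column = NULL) {
  validate_cell_table(cells)
  if (!is.null(class_column)) {
    cells <- cells %>%
      mutate(cell_type = ifelse(is.na(.data[[class_column]]),
                                .data$cell_type,
                                paste(.data$cell_type,
                                      .data[[class_column]], sep = "_")))
  }
  purrr::map(split(cells, cells$donor_id), function(dc) {
    g <- build_proximity_graph(dc, radius)
    tidyr::expand_grid(source = source_types, target = target_types) %>%
      mutate(donor_id = dc$donor_id[1], .before = 1) %>%
      mutate(fraction = purrr::map2_dbl(.data$source, .data$target,
                                        ~ proximity_fraction(g, .x, .y)))
  }) %>% bind_rows()
}

#' Cell densities per compartment
#'
#' @param cells Cell table (any number of donors).
#' @param areas Tibble `donor_id`, `compartment`, `area_mm2` (as returned by
#'   [generate_cohort()]), giving the measured area of each compartment.
#' @return Tibble `donor_id`, `compartment`, `cell_type`, `n`, `area_mm2`,
#'   `density` (cells/mm^2). Compartments present in `areas` but empty of a
#'   type get density 0 for that type.
#' @export
compartment_density <- function(cells, areas) {
  validate_cell_table(cells)
  areas <- as_tibble(areas)
  populated <- cells %>% distinct(.data$donor_id, .data$compartment)
  missing <- dplyr::anti_join(populated,
                              areas %>% filter(.data$area_mm2 > 0),
                              by = c("donor_id", "compartment"))
  if (nrow(missing) > 0) {
    abort(paste0("missing area for populated compartment(s): ",
                 paste(paste(missing$donor_id, missing$compartment),
                       collapse = "; ")))
  }
  counts <- cells %>%
    count(.data$donor_id, .data$compartment, .data$cell_type)
  areas %>%
    filter(.data$area_mm2 > 0) %>%
    tidyr::expand_grid(cell_type = sort(unique(cells$cell_type))) %>%
    left_join(counts, by = c("donor_id", "compartment", "cell_type")) %>%
    mutate(n = dplyr::coalesce(.data$n, 0L),
           density = .data$n / .data$area_mm2) %>%
    select("donor_id", "compartment", "cell_type", "n", "area_mm2", "density")
}
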