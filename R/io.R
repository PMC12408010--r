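# CSV dialect: cell tables are written with columns
# cell_id, donor_id, x_um, y_um, compartment, cell_type, <markers...>;
# internally coordinates are held as x, y (micrometres).

#' Read a segmented-cell CSV table
#'
#' Reads and validates the canonical cell-table dialect (one header row;
#' `cell_id`, `donor_id`, `x_um`, `y_um`, `compartment`, `cell_type`, then
#' marker columns). Duplicate `cell_id` within a donor, unknown compartment
#' labels, non-finite coordinates, and negative marker intensities are
#' rejected with informative errors.
#'
#' @param path CSV file path.
#' @return A validated cell table (coordinates renamed to `x`, `y`).
#' @export
read_cell_table <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("cell_id", "donor_id", "x_um", "y_um", "compartment", "cell_type")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    abort(paste0("missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  df <- df %>% rename(x = "x_um", y = "y_um") %>%
    mutate(cell_id = as.character(.data$cell_id),
           donor_id = as.character(.data$donor_id))
  validate_cell_table(df)
  df
}

#' Write a cell table to the canonical CSV dialect
#'
#' @param cells A cell table (internal `x`, `y` columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(cells, path) {
  validate_cell_table(cells)
  cells %>%
    rename(x_um = "x", y_um = "y") %>%
    readr::write_csv(path)
  invisible(path)
}

#' Read a donor metadata CSV
#'
#' @param path CSV with columns `donor_id`, `bmi` and optionally `age`,
#'   `sex`, `diabetes`, `alcohol`, `smoking`, `batch`.
#' @return Validated tibble.
#' @export
read_donor_table <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE) %>%
    mutate(donor_id = as.character(.data$donor_id))
  if (!all(c("donor_id", "bmi") %in% names(df))) {
    abort("donor table requires columns donor_id and bmi")
  }
  if (anyDuplicated(df$donor_id)) abort("duplicate donor_id in donor table")
  if (any(!is.finite(df$bmi)) || any(df$bmi <= 0)) {
    abort("bmi must be positive and finite")
  }
  df
}

#' Write a donor table
#' @param donors Donor tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_donor_table <- function(donors, path) {
  readr::write_csv(donors, path)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles the parameters of the full analysis chain. All numeric
#' parameters must be positive; a master seed is mandatory because several
#' stages are stochastic.
#'
#' @param cells Cell table or path to one.
#' @param donors Donor table or path to one.
#' @param out_dir Output directory (created if needed).
#' @param marker,target_type,control_type Marker classification designations
#'   (set `marker = NULL` to skip classification).
#' @param radius Proximity radius (micrometres).
#' @param window_k Neighbourhood window size.
#' @param nh_clusters Number of cellular neighbourhoods.
#' @param lisa_radii LISA radii (micrometres).
#' @param lisa_k Number of LISA regions.
#' @param n_perm Permutations for interaction testing.
#' @param seed Master seed.
#' @param stages Character subset of
#'   `c("classify", "graph", "proximity", "neighborhoods", "interactions",
#'   "lisa", "regress")`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cells, donors, out_dir,
                            marker = "CD11c",
                            target_type = "macrophage",
                            control_type = "neuroendocrine",
                            radius = 20, window_k = 10, nh_clusters = 7,
                            lisa_radii = c(10, 20, 50), lisa_k = 7,
                            n_perm = 1000, seed,
                            stages = c("classify", "graph", "proximity",
                                       "neighborhoods", "interactions",
                                       "lisa", "regress")) {
  if (missing(seed)) abort("pipeline_config() requires a master seed")
  num <- c(radius = radius, window_k = window_k, nh_clusters = nh_clusters,
           lisa_k = lisa_k, n_perm = n_perm)
  bad <- names(num)[num <= 0]
  if (any(lisa_radii <= 0)) bad <- c(bad, "lisa_radii")
  if (length(bad) > 0) {
    abort(paste0("pipeline parameters must be positive: ",
                 paste(bad, collapse = ", ")))
  }
  cfg <- list(cells = cells, donors = donors, out_dir = out_dir,
              marker = marker, target_type = target_type,
              control_type = control_type, radius = radius,
              window_k = window_k, nh_clusters = nh_clusters,
              lisa_radii = lisa_radii, lisa_k = lisa_k, n_perm = n_perm,
              seed = as.integer(seed), stages = stages)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full spatial analysis pipeline
#'
#' Executes classify, graph, proximity, neighbourhoods, interactions, LISA,
#' and regression stages on a cell/donor table pair, writing one CSV per
#' stage output plus a `manifest.txt` recording package version, seed,
#' parameters, and per-stage row counts. Reruns with identical config and
#' inputs are bit-identical.
#'
#' @param config A [pipeline_config()].
#' @return A report list: `outputs` (named file paths), `counts` (per-stage
#'   row counts), `manifest` (manifest lines).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cells <- if (is.character(config$cells)) read_cell_table(config$cells) else
    validate_cell_table(config$cells)
  donors <- if (is.character(config$donors)) read_donor_table(config$donors) else
    as_tibble(config$donors)
  orphan <- setdiff(unique(cells$donor_id), donors$donor_id)
  if (length(orphan) > 0) {
    abort(paste0("cells reference donor(s) missing from donor table: ",
                 paste(orphan, collapse = ", ")))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_seeds(config$seed, 4L)
  outputs <- list(); counts <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }
  path <- function(f) file.path(config$out_dir, f)
  class_col <- NULL

  if ("classify" %in% config$stages && !is.null(config$marker)) {
    cells <- stage("classify", classify_marker(cells, config$marker,
                                               config$target_type,
                                               config$control_type))
    class_col <- paste0(config$marker, "_class")
    readr::write_csv(attr(cells, "classification_models"),
                     path("classification_models.csv"))
    outputs$classification_models <- path("classification_models.csv")
    counts$classified_cells <- sum(!is.na(cells[[class_col]]))
  }

  graphs <- NULL
  if (any(c("graph", "proximity") %in% config$stages)) {
    graphs <- stage("graph", purrr::map(split(cells, cells$donor_id),
                                        build_proximity_graph,
                                        radius = config$radius))
    edges <- bind_rows(purrr::map(graphs, tidy))
    readr::write_csv(edges, path("edges.csv"))
    outputs$edges <- path("edges.csv")
    counts$edges <- nrow(edges)
  }

  if ("proximity" %in% config$stages) {
    prox <- stage("proximity", {
      labels <- if (is.null(class_col)) unique(cells$cell_type) else
        c(setdiff(unique(cells$cell_type), config$target_type),
          paste(config$target_type,
                unique(stats::na.omit(cells[[class_col]])), sep = "_"))
      proximity_fractions(cells,
                          source_types = sort(labels),
                          target_types = sort(labels),
                          radius = config$radius, class_column = class_col)
    })
    readr::write_csv(prox, path("proximity_fractions.csv"))
    outputs$proximity_fractions <- path("proximity_fractions.csv")
    counts$proximity_rows <- nrow(prox)
  }

  nhfreq <- NULL
  if ("neighborhoods" %in% config$stages) {
    nh <- stage("neighborhoods", {
      win <- window_composition(cells, k = config$window_k)
      model <- cluster_windows(win, n_clusters = config$nh_clusters,
                               seed = seeds[1])
      list(labels = model$labels, enrich = nh_enrichment(model, win),
           freq = nh_frequencies(model))
    })
    readr::write_csv(nh$labels, path("nh_labels.csv"))
    readr::write_csv(nh$enrich, path("nh_enrichment.csv"))
    readr::write_csv(nh$freq, path("nh_frequencies.csv"))
    outputs$nh_labels <- path("nh_labels.csv")
    counts$nh_windows <- nrow(nh$labels)
    nhfreq <- nh$freq
  }

  interactions <- NULL
  if ("interactions" %in% config$stages) {
    interactions <- stage("interactions",
                          interaction_analysis(cells, radius = config$radius,
                                               n_perm = config$n_perm,
                                               seed = seeds[2],
                                               class_column = class_col))
    readr::write_csv(interactions, path("interactions.csv"))
    readr::write_csv(aggregate_interactions(interactions),
                     path("interactions_aggregated.csv"))
    outputs$interactions <- path("interactions.csv")
    counts$interaction_records <- nrow(interactions)
  }

  regionfreq <- NULL
  if ("lisa" %in% config$stages) {
    lisa <- stage("lisa", lisa_regions(cells, radii = config$lisa_radii,
                                       k = config$lisa_k, seed = seeds[3]))
    readr::write_csv(lisa$labels, path("region_labels.csv"))
    readr::write_csv(lisa$enrichment, path("region_enrichment.csv"))
    readr::write_csv(lisa$frequencies, path("region_frequencies.csv"))
    outputs$region_labels <- path("region_labels.csv")
    counts$region_cells <- nrow(lisa$labels)
    regionfreq <- lisa$frequencies
  }

  if ("regress" %in% config$stages) {
    metrics <- list()
    if (!is.null(class_col)) {
      metrics$subset <- cells %>%
        filter(!is.na(.data[[class_col]])) %>%
        group_by(.data$donor_id) %>%
        summarise(value = mean(.data[[class_col]] == "high"),
                  .groups = "drop") %>%
        mutate(metric = paste0(config$marker, "_high_fraction"))
    }
    if (!is.null(nhfreq)) {
      metrics$nh <- nhfreq %>%
        mutate(metric = paste0("nh", .data$nh, "_frequency")) %>%
        select("donor_id", "metric", value = "frequency")
    }
    if (!is.null(regionfreq)) {
      metrics$region <- regionfreq %>%
        mutate(metric = paste0("region", .data$region, "_frequency")) %>%
        select("donor_id", "metric", value = "frequency")
    }
    if (length(metrics) > 0) {
      metrics <- bind_rows(metrics) %>%
        select("donor_id", "metric", "value")
      reg <- stage("regress", regress_metrics(metrics, donors,
                                              mode = "simple"))
      readr::write_csv(reg, path("regression_simple.csv"))
      outputs$regression <- path("regression_simple.csv")
      counts$regressions <- nrow(reg)
    }
  }

  manifest <- c(
    paste0("spatialmx version: ",
           as.character(utils::packageVersion("spatialmx"))),
    paste0("seed: ", config$seed),
    paste0("radius_um: ", config$radius),
    paste0("window_k: ", config$window_k),
    paste0("nh_clusters: ", config$nh_clusters),
    paste0("lisa_radii_um: ", paste(config$lisa_radii, collapse = ",")),
    paste0("lisa_k: ", config$lisa_k),
    paste0("n_perm: ", config$n_perm),
    paste0("stages: ", paste(config$stages, collapse = ",")),
    paste0("n_cells: ", nrow(cells)),
    paste0("n_donors: ", nrow(donors)),
    purrr::imap_chr(counts, ~ paste0("rows_", .y, ": ", .x))
  )
  writeLines(manifest, path("manifest.txt"))
  outputs$manifest <- path("manifest.txt")
  list(outputs = outputs, counts = counts, manifest = manifest)
}
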