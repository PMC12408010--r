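#' Configuration for the synthetic tissue generator
#'
#' Builds a validated configuration describing a cohort of synthetic
#' multiplexed-imaging fields: one rectangular field per donor, partitioned
#' into acinar, ductal, and islet compartments (islets are random disks,
#' the duct a buffered random polyline, acinar the remainder), with cell
#' counts drawn Poisson around per-type per-compartment densities, log-normal
#' marker intensities (optionally two-component mixtures for bimodal markers
#' such as CD11c on macrophages), configurable cross-type spatial attraction,
#' and donor-level BMI effects on marker-defined subset fractions.
#'
#' @param field_width,field_height Field dimensions in micrometres.
#' @param n_islets Number of islet disks per field.
#' @param islet_radius_mean,islet_radius_sd Islet disk radius distribution
#'   (micrometres, normal truncated at 30).
#' @param duct_width Full width of the buffered duct polyline (micrometres);
#'   0 disables the duct.
#' @param celltype_spec Tibble with columns `cell_type`, `compartment`,
#'   `density` (cells/mm^2). Zero-density combinations may be omitted.
#' @param marker_spec Tibble with columns `cell_type`, `marker`, `meanlog`,
#'   `sdlog` and optionally `meanlog_high`, `sdlog_high`, `prop_high` for
#'   bimodal markers (`prop_high` is the high-mode mixture weight).
#' @param background_meanlog,background_sdlog Log-normal parameters used for
#'   any (cell type, marker) combination absent from `marker_spec`.
#' @param attraction_spec Tibble with columns `source`, `target`, `strength`
#'   (>= 0), `range` (micrometres): after independent placement, target cells
#'   are pulled toward their nearest source cell (see [plant_interaction()]).
#' @param bmi_subset_slope Linear change, per BMI unit, in the high-mode
#'   mixture weight of each bimodal marker (the planted "subset fraction
#'   increases with BMI" effect). Applied relative to `bmi_ref`.
#' @param density_bmi_slope Tibble with columns `cell_type`, `slope`: relative
#'   density multiplier `1 + slope * (bmi - bmi_ref)` applied to that type in
#'   all compartments (floored at 0).
#' @param bmi_ref Reference BMI (kg/m^2) at which planted effects vanish.
#' @param n_donors Number of donors.
#' @param bmi_range Donor BMI drawn uniformly from this (min, max) interval.
#' @param n_batches Number of staining batches (TMA identifiers).
#' @param batch_frac_shift Additive shift in bimodal high-mode weight for
#'   donors in batches after the first (a planted batch artefact).
#' @param batch_bmi_assoc Logistic coefficient linking BMI to the probability
#'   of assignment to the later batch (confounds batch with BMI when > 0);
#'   only used when `n_batches == 2`.
#' @param cores If `TRUE`, cells are restricted to three disk-shaped TMA
#'   cores per donor instead of the full rectangle.
#' @return A `tissue_config` list.
#' @export
tissue_config <- function(field_width = 1000,
                          field_height = 1000,
                          n_islets = 2,
                          islet_radius_mean = 60,
                          islet_radius_sd = 8,
                          duct_width = 100,
                          celltype_spec = default_celltype_spec(),
                          marker_spec = default_marker_spec(),
                          background_meanlog = 2.2,
                          background_sdlog = 0.4,
                          attraction_spec = NULL,
                          bmi_subset_slope = 0.01,
                          density_bmi_slope = NULL,
                          bmi_ref = 25,
                          n_donors = 12,
                          bmi_range = c(18, 45),
                          n_batches = 1,
                          batch_frac_shift = 0,
                          batch_bmi_assoc = 0,
                          cores = FALSE) {
  cfg <- list(
    field_width = field_width, field_height = field_height,
    n_islets = n_islets, islet_radius_mean = islet_radius_mean,
    islet_radius_sd = islet_radius_sd, duct_width = duct_width,
    celltype_spec = as_tibble(celltype_spec),
    marker_spec = as_tibble(marker_spec),
    background_meanlog = background_meanlog,
    background_sdlog = background_sdlog,
    attraction_spec = if (is.null(attraction_spec)) {
      tibble(source = character(), target = character(),
             strength = numeric(), range = numeric())
    } else as_tibble(attraction_spec),
    bmi_subset_slope = bmi_subset_slope,
    density_bmi_slope = if (is.null(density_bmi_slope)) {
      tibble(cell_type = character(), slope = numeric())
    } else as_tibble(density_bmi_slope),
    bmi_ref = bmi_ref,
    n_donors = as.integer(n_donors), bmi_range = bmi_range,
    n_batches = as.integer(n_batches),
    batch_frac_shift = batch_frac_shift,
    batch_bmi_assoc = batch_bmi_assoc,
    cores = isTRUE(cores)
  )
  class(cfg) <- "tissue_config"
  validate_tissue_config(cfg)
  cfg
}

#' Default per-type densities (cells/mm^2) for a compact pancreas-like panel
#' @return Tibble with columns `cell_type`, `compartment`, `density`.
#' @export
default_celltype_spec <- function() {
  tribble_long <- function(type, acinar, ductal, islet) {
    tibble(cell_type = type,
           compartment = COMPARTMENTS,
           density = c(acinar, ductal, islet))
  }
  bind_rows(
    tribble_long("acinar_cell",    900,   0,   0),
    tribble_long("ductal_cell",      0, 900,   0),
    tribble_long("neuroendocrine",   0,   0, 900),
    tribble_long("macrophage",      80,  60,  40),
    tribble_long("t_cell_cd8",      40,  30,  10),
    tribble_long("t_cell_cd4",      30,  20,  10),
    tribble_long("endothelial",     50,  50,  50)
  ) %>% filter(.data$density > 0)
}

#' Default marker intensity distributions
#'
#' CD11c on macrophages is a two-component log-normal mixture (low and high
#' modes separated by 6 component SDs on the log scale); CD11c on
#' neuroendocrine cells is a single low mode, emulating a marker the control
#' population does not express.
#' @return Tibble usable as `marker_spec` in [tissue_config()].
#' @export
default_marker_spec <- function() {
  tibble(
    cell_type    = c("macrophage", "neuroendocrine"),
    marker       = c("CD11c", "CD11c"),
    meanlog      = c(2.8, 2.0),
    sdlog        = c(0.3, 0.35),
    meanlog_high = c(4.6, NA),
    sdlog_high   = c(0.3, NA),
    prop_high    = c(0.55, NA)
  )
}

#' A homogeneous configuration with no spatial structure
#'
#' All listed cell types are placed uniformly over a single-compartment
#' (acinar) field at equal density with no attraction and no BMI effects:
#' the fully random tissue used for null calibration of the interaction
#' statistics.
#'
#' @param types Cell type labels.
#' @param density Per-type density (cells/mm^2).
#' @param field Side length of the square field (micrometres).
#' @param n_donors Number of donors.
#' @return A `tissue_config`.
#' @export
tissue_config_random <- function(types = c("A", "B", "C"),
                                 density = 300,
                                 field = 500,
                                 n_donors = 1) {
  tissue_config(
    field_width = field, field_height = field,
    n_islets = 0, duct_width = 0,
    celltype_spec = tibble(cell_type = rep(types, each = 1),
                           compartment = "acinar",
                           density = density),
    marker_spec = tibble(cell_type = character(), marker = character(),
                         meanlog = numeric(), sdlog = numeric(),
                         meanlog_high = numeric(), sdlog_high = numeric(),
                         prop_high = numeric()),
    bmi_subset_slope = 0,
    n_donors = n_donors
  )
}

validate_tissue_config <- function(cfg) {
  bad <- character()
  if (!is.numeric(cfg$field_width) || cfg$field_width <= 0) bad <- c(bad, "field_width")
  if (!is.numeric(cfg$field_height) || cfg$field_height <= 0) bad <- c(bad, "field_height")
  if (cfg$n_islets < 0) bad <- c(bad, "n_islets")
  if (cfg$duct_width < 0) bad <- c(bad, "duct_width")
  cs <- cfg$celltype_spec
  if (!all(c("cell_type", "compartment", "density") %in% names(cs)) ||
      any(cs$density < 0) || !all(cs$compartment %in% COMPARTMENTS)) {
    bad <- c(bad, "celltype_spec")
  }
  ms <- cfg$marker_spec
  if (nrow(ms) > 0) {
    if (any(!is.na(ms$prop_high) & (ms$prop_high < 0 | ms$prop_high > 1)) ||
        any(ms$sdlog <= 0)) {
      bad <- c(bad, "marker_spec")
    }
  }
  at <- cfg$attraction_spec
  if (nrow(at) > 0 && (any(at$strength < 0) || any(at$range <= 0))) {
    bad <- c(bad, "attraction_spec")
  }
  if (cfg$n_donors < 1) bad <- c(bad, "n_donors")
  if (length(cfg$bmi_range) != 2 || cfg$bmi_range[1] <= 0 ||
      diff(cfg$bmi_range) < 0) {
    bad <- c(bad, "bmi_range")
  }
  if (cfg$n_batches < 1) bad <- c(bad, "n_batches")
  if (length(bad) > 0) {
    abort(paste0("invalid tissue_config field(s): ", paste(bad, collapse = ", ")))
  }
  invisible(cfg)
}

# ---- compartment geometry --------------------------------------------------

# geometry = list(islets = tibble(cx, cy, r), duct = tibble(x0, y0, x1, y1),
#                 duct_halfwidth, cores = tibble(cx, cy, r) or NULL)
make_field_geometry <- function(cfg) {
  W <- cfg$field_width; H <- cfg$field_height
  cores <- NULL
  if (cfg$cores) {
    r <- min(W, H) / 6.5
    cores <- tibble(cx = W * c(0.2, 0.5, 0.8), cy = H / 2, r = r)
  }
  inside <- function(x, y) {
    ok <- x >= 0 & x <= W & y >= 0 & y <= H
    if (!is.null(cores)) {
      inc <- rep(FALSE, length(x))
      for (i in seq_len(nrow(cores))) {
        inc <- inc | ((x - cores$cx[i])^2 + (y - cores$cy[i])^2 <= cores$r[i]^2)
      }
      ok <- ok & inc
    }
    ok
  }
  islets <- tibble(cx = numeric(), cy = numeric(), r = numeric())
  if (cfg$n_islets > 0) {
    tries <- 0L
    while (nrow(islets) < cfg$n_islets && tries < 500L) {
      tries <- tries + 1L
      r <- max(30, rnorm(1, cfg$islet_radius_mean, cfg$islet_radius_sd))
      cx <- runif(1, r, W - r); cy <- runif(1, r, H - r)
      if (!inside(cx, cy)) next
      if (nrow(islets) > 0 &&
          any(sqrt((islets$cx - cx)^2 + (islets$cy - cy)^2) < islets$r + r + 10)) next
      islets <- bind_rows(islets, tibble(cx = cx, cy = cy, r = r))
    }
  }
  duct <- tibble(x0 = numeric(), y0 = numeric(), x1 = numeric(), y1 = numeric())
  if (cfg$duct_width > 0) {
    nseg <- 4L
    xs <- seq(0, W, length.out = nseg + 1L)
    ys <- runif(nseg + 1L, 0.25 * H, 0.75 * H)
    duct <- tibble(x0 = xs[-(nseg + 1L)], y0 = ys[-(nseg + 1L)],
                   x1 = xs[-1L], y1 = ys[-1L])
  }
  list(islets = islets, duct = duct, duct_halfwidth = cfg$duct_width / 2,
       cores = cores, inside = inside, W = W, H = H)
}

point_segment_dist2 <- function(px, py, x0, y0, x1, y1) {
  vx <- x1 - x0; vy <- y1 - y0
  len2 <- vx * vx + vy * vy
  t <- if (len2 == 0) rep(0, length(px)) else
    pmin(1, pmax(0, ((px - x0) * vx + (py - y0) * vy) / len2))
  (px - (x0 + t * vx))^2 + (py - (y0 + t * vy))^2
}

# vectorized compartment lookup; islet wins over duct
compartment_of <- function(geom, x, y) {
  out <- rep("acinar", length(x))
  if (nrow(geom$duct) > 0) {
    near <- rep(FALSE, length(x))
    for (i in seq_len(nrow(geom$duct))) {
      near <- near | point_segment_dist2(x, y, geom$duct$x0[i], geom$duct$y0[i],
                                         geom$duct$x1[i], geom$duct$y1[i]) <=
        geom$duct_halfwidth^2
    }
    out[near] <- "ductal"
  }
  if (nrow(geom$islets) > 0) {
    for (i in seq_len(nrow(geom$islets))) {
      inside <- (x - geom$islets$cx[i])^2 + (y - geom$islets$cy[i])^2 <=
        geom$islets$r[i]^2
      out[inside] <- "islet"
    }
  }
  out
}

# deterministic grid integration of compartment areas (mm^2)
geometry_areas <- function(geom, grid = 201L) {
  if (nrow(geom$islets) == 0L && nrow(geom$duct) == 0L &&
      is.null(geom$cores)) {
    # bare rectangle: all acinar, no integration needed
    return(tibble(compartment = COMPARTMENTS,
                  area_mm2 = c(geom$W * geom$H / 1e6, 0, 0)))
  }
  gx <- seq(geom$W / (2 * grid), geom$W - geom$W / (2 * grid), length.out = grid)
  gy <- seq(geom$H / (2 * grid), geom$H - geom$H / (2 * grid), length.out = grid)
  pts <- expand.grid(x = gx, y = gy)
  ok <- geom$inside(pts$x, pts$y)
  comp <- compartment_of(geom, pts$x, pts$y)
  cell_area <- (geom$W / grid) * (geom$H / grid) / 1e6  # mm^2
  counts <- table(factor(comp[ok], levels = COMPARTMENTS))
  tibble(compartment = COMPARTMENTS,
         area_mm2 = as.numeric(counts) * cell_area)
}

# rejection-sample n points uniformly within one compartment
sample_in_compartment <- function(geom, compartment, n) {
  if (n == 0L) return(tibble(x = numeric(), y = numeric()))
  xs <- numeric(0); ys <- numeric(0)
  guard <- 0L
  while (length(xs) < n && guard < 200L) {
    guard <- guard + 1L
    m <- max(200L, 3L * (n - length(xs)))
    if (compartment == "islet" && nrow(geom$islets) > 0 && is.null(geom$cores)) {
      # direct sampling in the (disjoint) islet disks
      w <- geom$islets$r^2
      k <- sample.int(nrow(geom$islets), m, replace = TRUE, prob = w)
      rad <- geom$islets$r[k] * sqrt(runif(m))
      th <- runif(m, 0, 2 * pi)
      px <- geom$islets$cx[k] + rad * cos(th)
      py <- geom$islets$cy[k] + rad * sin(th)
      keep <- geom$inside(px, py)
    } else {
      px <- runif(m, 0, geom$W); py <- runif(m, 0, geom$H)
      keep <- geom$inside(px, py) & compartment_of(geom, px, py) == compartment
    }
    xs <- c(xs, px[keep]); ys <- c(ys, py[keep])
  }
  if (length(xs) < n) {
    abort(paste0("could not place cells in compartment '", compartment,
                 "' (empty or vanishing area)"))
  }
  tibble(x = xs[seq_len(n)], y = ys[seq_len(n)])
}

# ---- field & cohort generation ---------------------------------------------

generate_field <- function(cfg, donor, seed) {
  withr::with_seed(seed, {
    geom <- make_field_geometry(cfg)
    areas <- geometry_areas(geom)
    spec <- cfg$celltype_spec
    if (nrow(cfg$density_bmi_slope) > 0) {
      spec <- spec %>%
        left_join(cfg$density_bmi_slope, by = "cell_type") %>%
        mutate(mult = pmax(0, 1 + dplyr::coalesce(.data$slope, 0) *
                             (donor$bmi - cfg$bmi_ref)),
               density = .data$density * .data$mult) %>%
        select(-"slope", -"mult")
    }
    spec <- spec %>% left_join(areas, by = "compartment")
    cells <- purrr::pmap(spec, function(cell_type, compartment, density, area_mm2) {
      ncell <- rpois(1, density * area_mm2)
      if (ncell == 0L) return(NULL)
      pos <- sample_in_compartment(geom, compartment, ncell)
      tibble(cell_type = cell_type, compartment = compartment,
             x = pos$x, y = pos$y)
    }) %>% purrr::compact() %>% bind_rows()
    if (nrow(cells) == 0L) {
      abort("configuration produced a field with zero cells")
    }
    cells <- cells %>%
      mutate(donor_id = donor$donor_id,
             cell_id = sprintf("%s_c%05d", donor$donor_id, seq_len(nrow(cells)))) %>%
      select("cell_id", "donor_id", "x", "y", "compartment", "cell_type")

    cells <- add_marker_intensities(cells, cfg, donor)

    if (nrow(cfg$attraction_spec) > 0) {
      at_seeds <- sample.int(.Machine$integer.max - 1L, nrow(cfg$attraction_spec))
      for (i in seq_len(nrow(cfg$attraction_spec))) {
        a <- cfg$attraction_spec[i, ]
        if (all(c(a$source, a$target) %in% cells$cell_type)) {
          cells <- plant_interaction(cells, a$source, a$target,
                                     a$strength, a$range, seed = at_seeds[i])
        }
      }
    }
    list(cells = cells, areas = areas %>% mutate(donor_id = donor$donor_id,
                                                 .before = 1))
  })
}

add_marker_intensities <- function(cells, cfg, donor) {
  ms <- cfg$marker_spec
  markers <- unique(ms$marker)
  if (length(markers) == 0L) return(cells)
  for (m in markers) {
    vals <- numeric(nrow(cells))
    truth <- rep(NA_character_, nrow(cells))
    has_truth <- FALSE
    for (t in unique(cells$cell_type)) {
      idx <- which(cells$cell_type == t)
      row <- ms %>% filter(.data$marker == m, .data$cell_type == t)
      if (nrow(row) == 0L) {
        vals[idx] <- rlnorm(length(idx), cfg$background_meanlog,
                            cfg$background_sdlog)
      } else if (is.na(row$prop_high)) {
        vals[idx] <- rlnorm(length(idx), row$meanlog, row$sdlog)
      } else {
        has_truth <- TRUE
        p <- row$prop_high +
          cfg$bmi_subset_slope * (donor$bmi - cfg$bmi_ref) +
          if (donor$batch != "batch1") cfg$batch_frac_shift else 0
        p <- min(0.98, max(0.02, p))
        hi <- rbinom(length(idx), 1L, p) == 1L
        vals[idx[hi]] <- rlnorm(sum(hi), row$meanlog_high, row$sdlog_high)
        vals[idx[!hi]] <- rlnorm(sum(!hi), row$meanlog, row$sdlog)
        truth[idx] <- ifelse(hi, "high", "low")
      }
    }
    cells[[m]] <- vals
    if (has_truth) cells[[paste0("true_", tolower(m), "_class")]] <- truth
  }
  cells
}

#' Generate a synthetic donor cohort
#'
#' Draws one field per donor under `config`, with donor BMI uniform on
#' `config$bmi_range`, Poisson cell counts around the configured densities,
#' marker intensities per the marker spec (including any planted BMI effect
#' on bimodal subset fractions), and any configured cross-type attraction.
#' Identical `(config, seed)` pairs produce identical output.
#'
#' @param config A [tissue_config()].
#' @param seed Integer seed controlling all randomness.
#' @return A list with elements `cells` (cell table: `cell_id`, `donor_id`,
#'   `x`, `y`, `compartment`, `cell_type`, marker columns, and hidden
#'   `true_*_class` columns for bimodal markers), `donors` (donor covariates:
#'   `donor_id`, `bmi`, `age`, `sex`, `diabetes`, `alcohol`, `smoking`,
#'   `batch`), and `areas` (per-donor compartment areas, mm^2).
#' @export
generate_cohort <- function(config, seed) {
  validate_tissue_config(config)
  if (missing(seed)) abort("generate_cohort() requires an explicit seed")
  info <- withr::with_seed(seed, {
    n <- config$n_donors
    bmi <- runif(n, config$bmi_range[1], config$bmi_range[2])
    batch <- if (config$n_batches == 2 && config$batch_bmi_assoc > 0) {
      mid <- mean(config$bmi_range)
      paste0("batch", 1L + rbinom(n, 1L, plogis(config$batch_bmi_assoc *
                                                  (bmi - mid))))
    } else {
      paste0("batch", rep_len(seq_len(config$n_batches), n))
    }
    list(
      donors = tibble(
        donor_id = sprintf("D%03d", seq_len(n)),
        bmi = bmi,
        age = round(runif(n, 25, 70)),
        sex = sample(c("M", "F"), n, replace = TRUE),
        diabetes = rbinom(n, 1L, 0.15) == 1L,
        alcohol = rbinom(n, 1L, 0.2) == 1L,
        smoking = rbinom(n, 1L, 0.25) == 1L,
        batch = batch
      ),
      donor_seeds = sample.int(.Machine$integer.max - 1L, n)
    )
  })
  fields <- purrr::map(seq_len(config$n_donors), function(i) {
    generate_field(config, info$donors[i, ], info$donor_seeds[i])
  })
  list(
    cells = bind_rows(purrr::map(fields, "cells")),
    donors = info$donors,
    areas = bind_rows(purrr::map(fields, "areas"))
  )
}

#' Plant a spatial attraction between two cell types
#'
#' Repositions each target-type cell toward its nearest source-type cell:
#' the cell is pulled a fraction `min(strength, 1)` of the way toward a
#' point at random distance `U(0, range)` from the source. `strength = 0`
#' returns the table unchanged; cell count and all non-coordinate columns
#' are conserved.
#'
#' @param cells A cell table (any number of donors; donors are processed
#'   independently).
#' @param source_type,target_type Cell-type labels present in `cells`.
#' @param strength Attraction strength in `[0, Inf)`; values above 1 act as 1.
#' @param range Interaction range in micrometres.
#' @param seed Integer seed.
#' @return The cell table with target coordinates updated.
#' @export
plant_interaction <- function(cells, source_type, target_type, strength,
                              range, seed) {
  if (!source_type %in% cells$cell_type) {
    abort(paste0("unknown source type: ", source_type))
  }
  if (!target_type %in% cells$cell_type) {
    abort(paste0("unknown target type: ", target_type))
  }
  if (strength < 0) abort("strength must be >= 0")
  if (range <= 0) abort("range must be > 0")
  if (strength == 0) return(cells)
  s <- min(strength, 1)
  withr::with_seed(seed, {
    for (d in unique(cells$donor_id)) {
      drows <- which(cells$donor_id == d)
      src <- drows[cells$cell_type[drows] == source_type]
      tgt <- drows[cells$cell_type[drows] == target_type]
      if (length(src) == 0L || length(tgt) == 0L) next
      # nearest source per target (brute force; sources are typically few)
      dx <- outer(cells$x[tgt], cells$x[src], "-")
      dy <- outer(cells$y[tgt], cells$y[src], "-")
      d2 <- dx * dx + dy * dy
      nn <- max.col(-d2, ties.method = "first")
      sx <- cells$x[src][nn]; sy <- cells$y[src][nn]
      dist <- sqrt(d2[cbind(seq_along(tgt), nn)])
      want <- runif(length(tgt), 0, range)
      move <- dist > want
      frac <- ifelse(move, s * (1 - want / pmax(dist, 1e-12)), 0)
      cells$x[tgt] <- cells$x[tgt] + frac * (sx - cells$x[tgt])
      cells$y[tgt] <- cells$y[tgt] + frac * (sy - cells$y[tgt])
    }
  })
  cells
}

#' Plot a synthetic or real field
#'
#' @param cells A cell table (one or more donors; facets by donor).
#' @param colour_by Column name used for point colour.
#' @return A ggplot object.
#' @export
plot_tissue <- function(cells, colour_by = "cell_type") {
  ggplot2::ggplot(cells, ggplot2::aes(.data$x, .data$y,
                                      colour = .data[[colour_by]])) +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::coord_equal() +
    ggplot2::facet_wrap(~donor_id) +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", colour = colour_by) +
    ggplot2::theme_minimal()
}
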