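# internal helpers shared across modules

COMPARTMENTS <- c("acinar", "ductal", "islet")

# columns every cell table must carry; marker columns are everything else
CELL_TABLE_COLS <- c("cell_id", "donor_id", "x", "y", "compartment", "cell_type")

#' Validate a cell table
#'
#' Checks the invariants every downstream stage relies on: required columns,
#' unique `cell_id` within donor, finite coordinates, known compartment
#' labels, and nonnegative marker intensities.
#'
#' @param cells A data frame with columns `cell_id`, `donor_id`, `x`, `y`
#'   (micrometres), `compartment`, `cell_type`, plus optional numeric marker
#'   columns.
#' @param require_markers_positive If `TRUE`, marker intensities must be
#'   strictly positive (needed before Box-Cox transformation).
#' @return The input, invisibly, as a tibble.
#' @export
validate_cell_table <- function(cells, require_markers_positive = FALSE) {
  cells <- as_tibble(cells)
  missing <- setdiff(CELL_TABLE_COLS, names(cells))
  if (length(missing) > 0) {
    abort(paste0("cell table is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  dup <- cells %>%
    dplyr::mutate(.row = dplyr::row_number()) %>%
    group_by(.data$donor_id, .data$cell_id) %>%
    filter(n() > 1L) %>%
    ungroup()
  if (nrow(dup) > 0) {
    abort(paste0("duplicate cell_id within donor at row(s): ",
                 paste(head(dup$.row, 10), collapse = ", ")))
  }
  if (!all(is.finite(cells$x)) || !all(is.finite(cells$y))) {
    abort("cell coordinates must be finite")
  }
  bad_comp <- setdiff(unique(cells$compartment), COMPARTMENTS)
  if (length(bad_comp) > 0) {
    abort(paste0("unknown compartment value(s): ",
                 paste(bad_comp, collapse = ", ")))
  }
  for (m in marker_columns(cells)) {
    v <- cells[[m]]
    if (!is.numeric(v)) abort(paste0("marker column '", m, "' is not numeric"))
    if (anyNA(v) || any(v < 0)) {
      abort(paste0("marker column '", m, "' contains NA or negative values"))
    }
    if (require_markers_positive && any(v <= 0)) {
      abort(paste0("marker column '", m, "' contains nonpositive values"))
    }
  }
  invisible(cells)
}

#' Marker columns of a cell table
#'
#' Every column that is not part of the core schema and not a hidden truth
#' column (prefix `true_`) is treated as a marker intensity.
#'
#' @param cells A cell table.
#' @return Character vector of marker column names.
#' @export
marker_columns <- function(cells) {
  extra <- setdiff(names(cells), CELL_TABLE_COLS)
  extra[!grepl("^(true_|\\.)", extra) & !grepl("_class$", extra)]
}

# one donor only, returning its id
single_donor_id <- function(cells) {
  ids <- unique(cells$donor_id)
  if (length(ids) != 1L) {
    abort(paste0("expected cells from a single donor, got ",
                 length(ids), " donors"))
  }
  ids
}

# deterministic child seeds for per-donor / per-stage substreams
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# exact all-pairs neighbour search within `radius`, chunked so the distance
# matrix never materializes whole; returns i < j index pairs with distances
radius_pairs <- function(x, y, radius, chunk = 512L) {
  n <- length(x)
  if (n < 2L) {
    return(tibble(i = integer(), j = integer(), distance = numeric()))
  }
  r2 <- radius^2
  out_i <- list(); out_j <- list(); out_d <- list(); b <- 0L
  for (start in seq(1L, n - 1L, by = chunk)) {
    end <- min(start + chunk - 1L, n - 1L)
    rows <- start:end
    # only columns j > i are needed; compute block vs tail of the field
    cols <- (start + 1L):n
    dx <- outer(x[rows], x[cols], "-")
    dy <- outer(y[rows], y[cols], "-")
    d2 <- dx * dx + dy * dy
    keep <- which(d2 <= r2, arr.ind = TRUE)
    if (nrow(keep) > 0) {
      ii <- rows[keep[, 1L]]
      jj <- cols[keep[, 2L]]
      ok <- jj > ii
      if (any(ok)) {
        b <- b + 1L
        out_i[[b]] <- ii[ok]
        out_j[[b]] <- jj[ok]
        out_d[[b]] <- sqrt(d2[keep][ok])
      }
    }
  }
  if (b == 0L) {
    return(tibble(i = integer(), j = integer(), distance = numeric()))
  }
  tibble(i = unlist(out_i), j = unlist(out_j), distance = unlist(out_d)) %>%
    arrange(.data$i, .data$j)
}

# exact k-nearest-neighbour indices (self excluded), ties broken by row
# order; returns an n x k integer matrix
knn_indices <- function(x, y, k, chunk = 512L) {
  n <- length(x)
  if (k >= n) abort("k must be smaller than the number of cells")
  out <- matrix(NA_integer_, nrow = n, ncol = k)
  for (start in seq(1L, n, by = chunk)) {
    end <- min(start + chunk - 1L, n)
    rows <- start:end
    dx <- outer(x[rows], x, "-")
    dy <- outer(y[rows], y, "-")
    d2 <- dx * dx + dy * dy
    for (r in seq_along(rows)) {
      d <- d2[r, ]
      d[rows[r]] <- Inf
      # order() is stable: equal distances resolve by index (row) order
      out[rows[r], ] <- order(d)[seq_len(k)]
    }
  }
  out
}
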