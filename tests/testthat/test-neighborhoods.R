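test_that("window composition matches a hand-worked collinear field", {
  cells <- make_cells(c(0, 1, 2, 3, 100), rep(0, 5),
                      c("A", "A", "A", "B", "A"))
  win <- window_composition(cells, k = 2)
  row <- win[win$cell_id == "D1_c003", ]  # cell at x = 2: nearest are 1 and 3
  expect_equal(row$A, 0.5)
  expect_equal(row$B, 0.5)
  # far cell at x = 100: nearest two are x = 3 (B) and x = 2 (A)
  far <- win[win$cell_id == "D1_c005", ]
  expect_equal(far$A, 0.5); expect_equal(far$B, 0.5)
})

test_that("window rows are unit compositions; single-type fields give unit vectors", {
  withr::with_seed(7, {
    cells <- make_cells(runif(80, 0, 100), runif(80, 0, 100),
                        sample(c("A", "B", "C"), 80, TRUE))
    win <- window_composition(cells, k = 10)
    expect_equal(rowSums(as.matrix(win[, c("A", "B", "C")])), rep(1, 80))
    one <- make_cells(runif(30), runif(30), "A")
    w1 <- window_composition(one, k = 5)
    expect_true(all(w1$A == 1))
  })
})

test_that("windows agree with the brute-force kNN oracle", {
  withr::with_seed(12, {
    cells <- make_cells(runif(300, 0, 250), runif(300, 0, 250),
                        sample(c("A", "B", "C"), 300, TRUE))
    win <- window_composition(cells, k = 10)
    nn <- bf_knn(cells$x, cells$y, 10)
    for (i in c(1, 57, 300)) {
      comp <- table(factor(cells$cell_type[nn[i, ]],
                           levels = c("A", "B", "C"))) / 10
      expect_equal(as.numeric(win[i, c("A", "B", "C")]), as.numeric(comp))
    }
  })
})

test_that("donors with too few cells are skipped with a warning", {
  cells <- dplyr::bind_rows(
    make_cells(runif(30), runif(30), "A", donor = "D1"),
    make_cells(runif(5), runif(5), "A", donor = "D2"))
  expect_warning(win <- window_composition(cells, k = 10), "skipped")
  expect_setequal(unique(win$donor_id), "D1")
})

test_that("include_center counts the index cell as part of its window", {
  cells <- make_cells(c(0, 1, 2), rep(0, 3), c("A", "B", "B"))
  win <- window_composition(cells, k = 2, include_center = TRUE)
  # window of the first cell = itself (A) + nearest other (B at x = 1)
  expect_equal(win$A[1], 0.5)
  expect_equal(win$B[1], 0.5)
})

test_that("window clustering is deterministic and respects degenerate cases", {
  withr::with_seed(23, {
    cells <- make_cells(runif(120, 0, 120), runif(120, 0, 120),
                        sample(c("A", "B"), 120, TRUE))
    win <- window_composition(cells, k = 6)
    m1 <- cluster_windows(win, n_clusters = 4, seed = 99)
    m2 <- cluster_windows(win, n_clusters = 4, seed = 99)
    expect_identical(m1$labels, m2$labels)
    expect_error(cluster_windows(win[1:3, ], n_clusters = 5, seed = 1),
                 "fewer")
  })
})

test_that("n_clusters equal to the number of windows gives singleton clusters", {
  win <- make_window_matrix(
    tibble::tibble(cell_id = sprintf("c%d", 1:4), donor_id = "D1",
                   cell_type = "A",
                   A = c(1, 0.75, 0.5, 0), B = c(0, 0.25, 0.5, 1)),
    k = 4, types = c("A", "B"))
  m <- cluster_windows(win, n_clusters = 4, seed = 1)
  expect_equal(m$inertia, 0)
  expect_equal(length(unique(m$labels$nh)), 4)
})

test_that("mini-batch clustering recovers three disjoint composition zones", {
  aris <- vapply(1:10, function(s) {
    co <- generate_cohort(zone_config(), seed = 700 + s)
    win <- window_composition(co$cells, k = 10)
    m <- cluster_windows(win, n_clusters = 3, seed = 41,
                         batch_size = 512, n_iter = 80)
    truth <- co$cells$compartment[match(m$labels$cell_id, co$cells$cell_id)]
    ari(m$labels$nh, truth)
  }, numeric(1))
  expect_gte(mean(aris), 0.9)
})

test_that("enrichment is zero for globally-average neighbourhoods and signed correctly", {
  withr::with_seed(31, {
    cells <- make_cells(runif(400, 0, 200), runif(400, 0, 200),
                        sample(c("A", "B"), 400, TRUE))
    win <- window_composition(cells, k = 8)
    m <- cluster_windows(win, n_clusters = 3, seed = 5)
    enr <- nh_enrichment(m, win)
    # weighted (by NH size) mean enrichment per type is ~0 on the ratio scale
    sizes <- table(m$labels$nh)
    wmean <- enr |>
      dplyr::group_by(cell_type) |>
      dplyr::summarise(v = sum(2^enrichment * as.numeric(sizes)) /
                         sum(as.numeric(sizes)))
    expect_true(all(abs(wmean$v - 1) < 0.05))
    # an NH overrepresenting A must have positive A enrichment and vice versa
    mA <- vapply(split(win$A, m$labels$nh), mean, numeric(1))
    top <- names(which.max(mA))
    if (mA[top] > mean(win$A)) {
      expect_gt(enr$enrichment[enr$nh == as.integer(top) &
                                 enr$cell_type == "A"], 0)
    }
  })
})

test_that("a pure neighbourhood in a balanced two-type field has enrichment ~1", {
  # NH mean composition 1 vs global 0.5: log2(1/0.5) = 1 (up to the epsilon)
  win <- make_window_matrix(
    tibble::tibble(cell_id = sprintf("c%02d", 1:40), donor_id = "D1",
                   cell_type = rep(c("A", "B"), each = 20),
                   A = rep(c(1, 0), each = 20), B = rep(c(0, 1), each = 20)),
    k = 5, types = c("A", "B"))
  m <- cluster_windows(win, n_clusters = 2, seed = 3)
  enr <- nh_enrichment(m, win)
  pureA <- m$labels$nh[1]
  expect_equal(enr$enrichment[enr$nh == pureA & enr$cell_type == "A"], 1,
               tolerance = 0.1)
})

test_that("NH frequencies are per-donor compositions", {
  co <- generate_cohort(tissue_config(n_donors = 3), seed = 13)
  win <- window_composition(co$cells, k = 10)
  m <- cluster_windows(win, n_clusters = 5, seed = 2)
  fr <- nh_frequencies(m)
  sums <- fr |> dplyr::group_by(donor_id) |>
    dplyr::summarise(s = sum(frequency))
  expect_equal(sums$s, rep(1, 3), tolerance = 1e-9)
  # single NH: every donor frequency 1
  m1 <- cluster_windows(win, n_clusters = 1, seed = 2)
  fr1 <- nh_frequencies(m1)
  expect_true(all(fr1$frequency == 1))
})

test_that("row order does not affect window compositions on tie-free data", {
  withr::with_seed(3, {
    cells <- make_cells(runif(100, 0, 100), runif(100, 0, 100),
                        sample(c("A", "B"), 100, TRUE))
    win <- window_composition(cells, k = 5)
    perm <- sample(nrow(cells))
    win2 <- window_composition(cells[perm, ], k = 5)
    merged <- dplyr::left_join(as_tibble_plain(win), as_tibble_plain(win2),
                               by = "cell_id", suffix = c("", ".p"))
    expect_equal(merged$A, merged$A.p)
    expect_equal(merged$B, merged$B.p)
  })
})

test_that("a planted BMI effect on a zone type shows up in NH frequencies", {
  cfg <- zone_config(n_donors = 12, density = 900)
  cfg$density_bmi_slope <- tibble::tibble(cell_type = "zoneA", slope = 0.03)
  co <- generate_cohort(cfg, seed = 246)
  win <- window_composition(co$cells, k = 10)
  m <- cluster_windows(win, n_clusters = 3, seed = 11)
  fr <- nh_frequencies(m)
  # the NH whose centroid is dominated by zoneA carries the planted effect
  nhA <- which.max(m$centroids[, "zoneA"]) - 1L
  d <- fr |> dplyr::filter(nh == nhA) |>
    dplyr::left_join(co$donors, by = "donor_id")
  fit <- simple_linreg(d |> dplyr::rename(value = frequency), "value")
  td <- tidy(fit)
  expect_gt(td$estimate[td$term == "bmi"], 0)
  expect_lt(td$p.value[td$term == "bmi"], 0.05)
})
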