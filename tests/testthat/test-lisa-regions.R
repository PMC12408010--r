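test_that("LISA features reproduce the four-cell hand computation", {
  cells <- make_cells(c(0, 0, 0, 0), c(0, 5, 12, 100),
                      c("A", "A", "B", "B"))
  f <- lisa_features(cells, radii = 10)
  # cell 1 sees only the A at y = 5: local A = 1, B = 0; global 0.5/0.5
  expect_equal(f$r10_A[1], 0.5)
  expect_equal(f$r10_B[1], -0.5)
  # cell 4 has no neighbours: centred feature is minus the global fractions
  expect_equal(f$r10_A[4], -0.5)
  expect_equal(f$r10_B[4], -0.5)
  cov <- attr(f, "coverage")
  expect_equal(cov$zero_neighbour_fraction, 0.25)
})

test_that("single-type dense fields give identically-zero centred features", {
  cells <- make_cells(rep(seq(0, 45, 5), 2),
                      rep(c(0, 5), each = 10), "A")
  f <- lisa_features(cells, radii = c(10, 20))
  expect_true(all(abs(lisa_values_oracle(f)) < 1e-12))
})

test_that("features match a brute-force neighbour scan on random fields", {
  withr::with_seed(44, {
    cells <- make_cells(runif(250, 0, 200), runif(250, 0, 200),
                        sample(c("A", "B", "C"), 250, TRUE))
    f <- lisa_features(cells, radii = c(10, 20, 50))
    d <- as.matrix(dist(cbind(cells$x, cells$y))); diag(d) <- Inf
    global <- table(factor(cells$cell_type, levels = c("A", "B", "C"))) / 250
    for (i in c(3, 99, 250)) {
      for (r in c(10, 20, 50)) {
        nb <- which(d[i, ] <= r)
        prop <- if (length(nb) == 0) c(A = 0, B = 0, C = 0) else
          table(factor(cells$cell_type[nb], levels = c("A", "B", "C"))) /
          length(nb)
        got <- as.numeric(f[i, paste0("r", r, "_", c("A", "B", "C"))])
        expect_equal(got, as.numeric(prop - global), tolerance = 1e-12)
      }
    }
  })
})

test_that("radii must be strictly increasing and positive", {
  cells <- make_cells(runif(20), runif(20), "A")
  expect_error(lisa_features(cells, radii = c(20, 10)), "increasing")
  expect_error(lisa_features(cells, radii = c(0, 10)), "increasing|positive")
})

test_that("single-radius local proportions agree with proximity-graph neighbour counts", {
  withr::with_seed(70, {
    cells <- make_cells(runif(150, 0, 150), runif(150, 0, 150),
                        sample(c("A", "B"), 150, TRUE))
    f <- lisa_features(cells, radii = 20)
    g <- build_proximity_graph(cells, 20)
    adj <- matrix(0, 150, 150)
    adj[cbind(g$edges$ia, g$edges$ib)] <- 1
    adj <- adj + t(adj)
    nA <- adj %*% (cells$cell_type == "A")
    tot <- rowSums(adj)
    propA <- ifelse(tot == 0, 0, nA / tot)
    globalA <- mean(cells$cell_type == "A")
    expect_equal(f$r20_A, as.numeric(propA - globalA), tolerance = 1e-12)
  })
})

test_that("PCA reduction preserves variance structure", {
  withr::with_seed(5, {
    base <- matrix(rnorm(200), 100, 2)
    X <- cbind(base[, 1], base[, 1] * 2, base[, 2] * 1e-8)
    f <- tibble::tibble(cell_id = as.character(1:100), donor_id = "D1") |>
      dplyr::bind_cols(tibble::as_tibble(`colnames<-`(X, c("f1", "f2", "f3"))))
    red <- reduce_features(f, variance_target = 0.9)
    expect_equal(red$n_components, 1)
    expect_gt(red$explained_variance[1], 0.999)
    red_all <- reduce_features(f, variance_target = 1.0)
    expect_equal(red_all$n_components, 3)
    # full reconstruction
    recon <- red_all$scores %*% t(red_all$rotation)
    centred <- scale(X, scale = FALSE)
    expect_lt(max(abs(recon - centred)), 1e-8)
    degenerate <- f |> dplyr::mutate(f1 = 1, f2 = 1, f3 = 1)
    expect_error(reduce_features(degenerate), "degenerate")
  })
})

test_that("region assignment is deterministic and handles edge cases", {
  withr::with_seed(88, {
    X <- matrix(rnorm(300), 100, 3)
    a <- assign_regions(X, k = 4, seed = 10)
    b <- assign_regions(X, k = 4, seed = 10)
    expect_identical(a, b)
    expect_true(all(a %in% 0:3))
    expect_equal(assign_regions(X, k = 1, seed = 1), rep(0L, 100))
    expect_error(assign_regions(X[1:3, ], k = 7, seed = 1), "fewer rows")
  })
})

test_that("region summary behaves at the boundaries", {
  cells <- make_cells(runif(60), runif(60),
                      sample(c("A", "B"), 60, TRUE))
  # single region: every donor frequency 1, enrichment ~0 everywhere
  s <- region_summary(rep(0L, 60), cells)
  expect_true(all(s$frequencies$frequency == 1))
  expect_true(all(abs(s$enrichment$enrichment) < 0.05))
  sums <- region_summary(rep(c(0L, 1L), 30), cells)$frequencies |>
    dplyr::group_by(donor_id) |> dplyr::summarise(s = sum(frequency))
  expect_equal(sums$s, 1, tolerance = 1e-9)
})

test_that("end-to-end LISA recovers planted spatial niches", {
  aris <- vapply(1:8, function(s) {
    co <- generate_cohort(zone_config(), seed = 400 + s)
    lr <- lisa_regions(co$cells, radii = c(10, 20, 50), k = 3, seed = 77)
    truth <- co$cells$compartment[match(lr$labels$cell_id, co$cells$cell_id)]
    ari(lr$labels$region, truth)
  }, numeric(1))
  expect_gte(mean(aris), 0.8)
})

test_that("a planted BMI effect on a zone type shows up in region frequencies", {
  cfg <- zone_config(n_donors = 12, density = 900)
  cfg$density_bmi_slope <- tibble::tibble(cell_type = "zoneA", slope = 0.03)
  co <- generate_cohort(cfg, seed = 357)
  lr <- lisa_regions(co$cells, radii = c(10, 20, 50), k = 3, seed = 5)
  # find the zoneA-enriched region
  enrA <- lr$enrichment |> dplyr::filter(cell_type == "zoneA")
  regA <- enrA$region[which.max(enrA$enrichment)]
  d <- lr$frequencies |> dplyr::filter(region == regA) |>
    dplyr::left_join(co$donors, by = "donor_id") |>
    dplyr::rename(value = frequency)
  td <- tidy(simple_linreg(d, "value"))
  expect_gt(td$estimate[td$term == "bmi"], 0)
  expect_lt(td$p.value[td$term == "bmi"], 0.05)
})
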