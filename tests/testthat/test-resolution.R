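# hand-built grid for threshold logic
fake_grid <- function(radii, classes, fraction = 50) {
  structure(data.frame(radius = radii, fraction = fraction,
                       median_R_hat = radii, error = 0,
                       class = classes, stringsAsFactors = FALSE),
            class = c("resolution_grid", "data.frame"))
}

test_that("substrates follow the scenario mixing rules", {
  s <- make_substrate("intra", 8, 100)
  expect_length(s$components, 1)
  expect_equal(s$components[[1]]$kind, "sphere")
  s2 <- make_substrate("intra", 8, 40)
  expect_equal(vapply(s2$components, `[[`, numeric(1), "fraction"),
               c(0.4, 0.6))
  # boundary: intra_extra at 50% has no tensor left
  s3 <- make_substrate("intra_extra", 8, 50)
  expect_equal(vapply(s3$components, `[[`, character(1), "kind"),
               c("sphere", "stick"))
  # 1:1 sphere:stick with tensor remainder
  s4 <- make_substrate("intra_extra", 8, 40)
  expect_equal(vapply(s4$components, `[[`, numeric(1), "fraction"),
               c(0.4, 0.4, 0.2))
  expect_equal(s4$components[[3]]$eigenvalues, c(2.4, 0.8))
  expect_error(make_substrate("intra_extra", 8, 60), "50")
})

test_that("noiseless dictionary-radius cells recover almost exactly", {
  sch <- connectom_like_protocol()
  cfg <- resolution_config(radii = c(6.75, 8.0625), fractions = c(100),
                           scenario = "intra", n_reps = 10, snr = Inf,
                           seed = 3)
  grid <- run_scenario(sch, cfg)
  expect_true(all(abs(grid$error) < 0.5))
  expect_true(all(grid$class == "acceptable"))
})

test_that("scenario runs are deterministic given the seed", {
  sch <- prisma_protocol()
  cfg <- resolution_config(radii = c(4, 8), fractions = c(50, 100),
                           scenario = "intra", n_reps = 10, seed = 17)
  g1 <- run_scenario(sch, cfg)
  g2 <- run_scenario(sch, cfg)
  expect_identical(as.data.frame(g1), as.data.frame(g2))
  g3 <- run_scenario(sch, resolution_config(radii = c(4, 8),
                                            fractions = c(50, 100),
                                            scenario = "intra",
                                            n_reps = 10, seed = 18))
  expect_false(identical(g1$median_R_hat, g3$median_R_hat))
})

test_that("small spheres are overestimated on the clinical protocol", {
  sch <- prisma_protocol()
  cfg <- resolution_config(radii = c(2), fractions = c(50),
                           scenario = "intra", n_reps = 20, seed = 4)
  grid <- run_scenario(sch, cfg)
  expect_equal(grid$class, "over")
})

test_that("grid classification is consistent with the tolerance", {
  sch <- prisma_protocol()
  cfg <- resolution_config(radii = c(2, 8, 12), fractions = c(50, 100),
                           scenario = "intra", n_reps = 10, seed = 6)
  grid <- run_scenario(sch, cfg)
  tau <- attr(grid, "config")$tau
  expect_equal(grid$class == "acceptable",
               abs(grid$error) <= tau)
  expect_equal(grid$class == "over", grid$error > tau)
})

test_that("radius threshold scans the acceptable tail", {
  g <- fake_grid(1:5, c("over", "over", "acceptable", "acceptable",
                        "acceptable"))
  expect_equal(recovery_threshold_radius(g, 50), 3)
  expect_equal(recovery_threshold_radius(
    fake_grid(1:5, rep("acceptable", 5)), 50), 1)
  expect_equal(recovery_threshold_radius(
    fake_grid(1:5, rep("over", 5)), 50), Inf)
  # a hole resets the threshold above it
  g2 <- fake_grid(1:10, c(rep("acceptable", 5), "over",
                          rep("acceptable", 4)))
  expect_equal(recovery_threshold_radius(g2, 50), 7)
  # brute-force scan oracle on random classifications
  set.seed(2)
  for (i in 1:20) {
    cl <- sample(c("over", "under", "acceptable"), 8, replace = TRUE)
    g3 <- fake_grid(1:8, cl)
    got <- recovery_threshold_radius(g3, 50)
    ok <- cl == "acceptable"
    brute <- Inf
    for (r in 8:1) {
      if (all(ok[r:8])) brute <- r else break
    }
    expect_equal(got, brute)
  }
  expect_error(recovery_threshold_radius(g, 99), "not on the grid")
})

test_that("fraction threshold mirrors the radius scan", {
  g <- structure(data.frame(radius = 8, fraction = seq(10, 50, 10),
                            median_R_hat = 8, error = 0,
                            class = c("over", "over", "acceptable",
                                      "acceptable", "acceptable")),
                 class = c("resolution_grid", "data.frame"))
  expect_equal(recovery_threshold_fraction(g, 8), 30)
  g$class <- rep("acceptable", 5)
  expect_equal(recovery_threshold_fraction(g, 8), 10)
  g$class <- rep("under", 5)
  expect_equal(recovery_threshold_fraction(g, 8), Inf)
  expect_error(recovery_threshold_fraction(g, 5), "not on the grid")
})

test_that("the radius scan is bounded by the dictionary's range", {
  sch <- prisma_protocol()
  cfg <- resolution_config(radii = c(11, 12, 15), fractions = c(100),
                           scenario = "intra", n_reps = 10, seed = 9)
  grid <- run_scenario(sch, cfg)
  expect_equal(attr(grid, "r_scan_max"), 12)
  # a 15-um sphere cannot be represented by a 12-um-capped dictionary
  expect_lt(grid$error[grid$radius == 15], -2)
  # the scan therefore ignores it by default but not when forced
  expect_lte(recovery_threshold_radius(grid, 100), 12)
  expect_equal(recovery_threshold_radius(grid, 100, r_max = 15), Inf)
})

test_that("grids export, render and round-trip", {
  g <- fake_grid(1:4, c("over", "acceptable", "acceptable", "acceptable"))
  f <- tempfile(fileext = ".csv")
  png <- tempfile(fileext = ".png")
  export_grid(g, f, heatmap_path = if (requireNamespace("ggplot2",
                                                        quietly = TRUE))
    png else NULL)
  g2 <- read_grid_csv(f)
  expect_equal(as.data.frame(g2), as.data.frame(g))
  expect_equal(nrow(g2), 4)
  if (requireNamespace("ggplot2", quietly = TRUE)) {
    expect_true(file.exists(png))
  }
})

test_that("resolution config validates its grids", {
  expect_error(resolution_config(radii = c(3, 2, 1), scenario = "intra"),
               "ascending")
  expect_error(resolution_config(n_reps = 5, scenario = "intra"),
               "n_reps")
  expect_error(resolution_config(tau = -1, scenario = "intra"), "tau")
})
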