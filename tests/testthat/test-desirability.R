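test_that("individual desirability ramps behave at boundaries and mirror", {
  g <- desirability_goal("y", "maximize", y_min = 10, y_max = 20)
  expect_equal(individual_desirability(10, g), 0)
  expect_equal(individual_desirability(15, g), 0.5)
  expect_equal(individual_desirability(20, g), 1)
  expect_equal(individual_desirability(c(5, 25), g), c(0, 1))  # clamped

  gm <- desirability_goal("y", "minimize", y_min = 10, y_max = 20)
  expect_equal(individual_desirability(c(10, 15, 20), gm), c(1, 0.5, 0))

  gt <- desirability_goal("y", "target", y_min = 0, y_max = 10, target = 4)
  expect_equal(individual_desirability(c(0, 2, 4, 7, 10), gt),
               c(0, 0.5, 1, 0.5, 0))
  expect_error(desirability_goal("y", "maximize", 5, 5), "y_min < y_max")
  expect_error(desirability_goal("y", "target", 0, 1, target = 2), "target")
})

test_that("composite desirability is the geometric mean with an absorbing zero", {
  expect_equal(composite_desirability(c(1, 1, 1)), 1)
  expect_equal(composite_desirability(c(0.08, 0, 0.15)), 0)
  expect_equal(composite_desirability(c(0.5, 0.5, 0.5)), 0.5)
  expect_equal(composite_desirability(c(1, 0.87, 0.84)), (0.87 * 0.84)^(1 / 3))
  expect_error(composite_desirability(numeric(0)), "empty")
  expect_error(composite_desirability(c(0.5, 1.2)), "\\[0, 1\\]")
  # weighted form reduces to unweighted at equal weights
  set.seed(9)
  d <- stats::runif(3)
  expect_equal(composite_desirability(d, weights = c(2, 2, 2)),
               composite_desirability(d))
})

test_that("desirability obeys range, AM-GM and scale invariance", {
  set.seed(13)
  for (i in 1:50) {
    d <- stats::runif(3)
    D <- composite_desirability(d)
    expect_gte(D, 0); expect_lte(D, 1)
    expect_lte(D, mean(d) + 1e-12)  # AM-GM
  }
  # affine rescaling of a response and its bounds leaves d unchanged
  g <- desirability_goal("y", "maximize", 10, 20)
  y <- stats::runif(20, 5, 25)
  for (i in 1:10) {
    a <- stats::runif(1, 0.1, 5); b <- stats::rnorm(1, sd = 10)
    g2 <- desirability_goal("y", "maximize", a * 10 + b, a * 20 + b)
    expect_equal(individual_desirability(a * y + b, g2),
                 individual_desirability(y, g), tolerance = 1e-10)
  }
})

test_that("the study desirability table selects run 11 at (60, 20, 70)", {
  ff <- fixture_fits()
  rep <- desirability_table(list(pigment = ff$pigment, abts = ff$abts,
                                 tpc = ff$tpc), ff$fx$design)
  tab <- rep$table
  expect_equal(rep$optimum$run_id, 11L)
  expect_equal(unname(rep$optimum$natural), c(60, 20, 70))
  expect_equal(round(tab$D[c(5, 6)], 2), c(0, 0))
  expect_equal(round(tab$D[10], 2), 0.58)
  expect_equal(round(tab$D[11], 2), 0.90)
  # bounds are attained at design runs: exactly one d = 1 and one d = 0
  for (col in c("d_pigment", "d_abts", "d_tpc")) {
    expect_equal(sum(tab[[col]] == 1), 1L)
    expect_equal(sum(tab[[col]] == 0), 1L)
  }
})

test_that("degenerate constant predictions are surfaced as an error", {
  d <- build_bbd(uae_factors(), 3)
  flat <- fit_quadratic(d, rep(5, 15) + 1e-13 * stats::rnorm(15), "intercept-only")
  ok <- fit_quadratic(d, stats::rnorm(15), "full")
  expect_error(desirability_table(list(a = flat, b = ok), d), "degenerate")
})

test_that("grid optimization agrees with brute force and refines monotonically", {
  ff <- fixture_fits()
  models <- list(pigment = ff$pigment, abts = ff$abts, tpc = ff$tpc)
  d <- ff$fx$design
  g3 <- grid_optimize(models, d, resolution = 3)
  # brute-force oracle over the 27 coded-level points with the same bounds
  rep0 <- desirability_table(models, d)
  pts <- as.matrix(expand.grid(x1 = c(-1, 0, 1), x2 = c(-1, 0, 1),
                               x3 = c(-1, 0, 1)))
  Dbf <- apply(pts, 1, function(z) {
    ds <- vapply(names(models), function(nm) {
      individual_desirability(predict(models[[nm]], z), rep0$goals[[nm]])
    }, numeric(1))
    composite_desirability(ds)
  })
  expect_equal(g3$D, max(Dbf), tolerance = 1e-12)
  expect_equal(unname(g3$coded), unname(pts[which.max(Dbf), ]))
  expect_equal(unname(g3$coded), c(0, -1, 1))  # the study optimum
  # nested refinement never loses the best point
  g5 <- grid_optimize(models, d, resolution = 5)
  expect_gte(g5$D, g3$D - 1e-12)

  # single monotone surface: optimum sits at the +1 face
  X <- build_model_matrix(d, "full")
  m1 <- fit_quadratic(d, drop(X %*% c(0, 1, rep(0, 8))), "full")
  m2 <- fit_quadratic(d, drop(X %*% c(5, 1, rep(0, 8))), "full")
  g1 <- grid_optimize(list(a = m1, b = m2), d, resolution = 5)
  expect_equal(unname(g1$coded["x1"]), 1)
})

test_that("factor profiles peak where the optimum sits", {
  ff <- fixture_fits()
  models <- list(pigment = ff$pigment, abts = ff$abts, tpc = ff$tpc)
  d <- ff$fx$design
  prof_time <- desirability_profiles(models, d, 2, resolution = 5)
  expect_equal(prof_time$level_coded[which.max(prof_time$D)], -1)  # 20 min
  expect_equal(prof_time$level_natural[which.max(prof_time$D)], 20)
  # the profile maximum over any factor equals the grid optimum D
  g <- grid_optimize(models, d, resolution = 5)
  for (k in 1:3) {
    pk <- desirability_profiles(models, d, k, resolution = 5)
    expect_equal(max(pk$D), g$D, tolerance = 1e-12)
  }
  expect_error(desirability_profiles(models, d, 4), "factor_index")
})

test_that("flat models give a flat profile", {
  d <- build_bbd(uae_factors(), 3)
  X <- build_model_matrix(d, "full")
  m <- fit_quadratic(d, drop(X %*% c(0, 1, rep(0, 8))), "full")
  goals <- list(a = desirability_goal("a", "maximize", -2, 2),
                b = desirability_goal("b", "maximize", -2, 2))
  # profile factor 3, on which neither model depends
  flat <- desirability_profiles(list(a = m, b = m), d, 3, resolution = 5,
                                goals = goals)
  expect_equal(diff(range(flat$D)), 0, tolerance = 1e-12)
})

test_that("confirmation runs validate against predictions", {
  v <- validate_optimum(156.31, experimental_mean = 165.19, response_name = "pigment")
  expect_equal(round(v$relative_error, 2), 0.06)
  v2 <- validate_optimum(38.62, replicates = c(37.40, 37.98, 38.56))
  expect_equal(v2$experimental_mean, 37.98)
  expect_equal(round(v2$relative_error, 2), 0.02)
  v3 <- validate_optimum(10, replicates = c(10, 10))
  expect_equal(v3$relative_error, 0)
  expect_error(validate_optimum(0, experimental_mean = 1), "non-zero")
})
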