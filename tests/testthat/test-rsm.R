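test_that("the model matrix has canonical columns", {
  d <- build_bbd(uae_factors(), 3)
  X <- build_model_matrix(d, "full")
  expect_equal(dim(X), c(15L, 10L))
  expect_equal(colnames(X),
               c("(Intercept)", "x1", "x2", "x3", "x1:x2", "x1:x3", "x2:x3",
                 "x1^2", "x2^2", "x3^2"))
  expect_true(all(X[, "(Intercept)"] == 1))
  expect_equal(unname(X[11, "x2:x3"]), -1)  # run 11 is (0, -1, 1)
  expect_equal(ncol(build_model_matrix(d, "linear")), 4L)
  expect_equal(ncol(build_model_matrix(d, "no-interactions")), 7L)
  expect_error(build_model_matrix(d[0, ], "full"), "empty")
})

test_that("OLS equals the brute-force normal equations and BBD contrasts", {
  d <- build_bbd(uae_factors(), 3)
  X <- build_model_matrix(d, "full")
  set.seed(21)
  for (i in 1:20) {
    y <- stats::rnorm(15, mean = 50, sd = 20)
    fit <- fit_quadratic(d, y, "full")
    beta_ne <- unname(drop(solve(t(X) %*% X, t(X) %*% y)))
    expect_equal(unname(fit$coefficients), unname(beta_ne), tolerance = 1e-10)
    # closed-form contrasts from orthogonality:
    # linear coefficient = (sum y at +1 - sum y at -1)/8
    for (k in 1:3) {
      z <- X[, paste0("x", k)]
      expect_equal(unname(fit$coefficients[paste0("x", k)]),
                   (sum(y[z == 1]) - sum(y[z == -1])) / 8, tolerance = 1e-10)
    }
    # interaction coefficient = 4-point contrast / 4
    w <- X[, "x2:x3"]
    expect_equal(unname(fit$coefficients["x2:x3"]),
                 sum(y[w == 1]) / 4 - sum(y[w == -1]) / 4, tolerance = 1e-10)
  }
})

test_that("noiseless quadratic data are recovered exactly", {
  d <- build_bbd(uae_factors(), 3)
  X <- build_model_matrix(d, "full")
  set.seed(5)
  beta <- stats::rnorm(10, sd = 10)
  y <- drop(X %*% beta)
  fit <- fit_quadratic(d, y, "full")
  expect_equal(unname(fit$coefficients), beta, tolerance = 1e-10)
  an <- anova(fit)
  expect_equal(an$r_squared, 1, tolerance = 1e-10)
  expect_lt(an$sse, 1e-18)
  expect_lt(abs(an$ss_lack_of_fit), 1e-18)
})

test_that("prediction at the centre returns the intercept, and the centre-mean identity holds", {
  d <- build_bbd(uae_factors(), 3)
  set.seed(31)
  for (terms in list("full", "no-interactions")) {
    y <- stats::rnorm(15, 30, 10)
    fit <- fit_quadratic(d, y, terms)
    expect_equal(predict(fit, c(0, 0, 0)),
                 unname(fit$coefficients["(Intercept)"]), tolerance = 1e-12)
    # with intercept + quadratics present the centre group is saturated:
    # the fitted centre value equals the centre-replicate mean exactly
    expect_equal(unname(fit$coefficients["(Intercept)"]), mean(y[13:15]),
                 tolerance = 1e-10)
  }
})

test_that("fitting guards rank, sample size and alignment", {
  d <- build_bbd(uae_factors(), 3)
  y <- stats::rnorm(15)
  expect_error(fit_quadratic(d, y[1:10], "full"), "length")
  expect_error(fit_quadratic(d[1:9, ], y[1:9], "full"), "observations")
  dup <- d
  dup$x3 <- dup$x2  # collinear columns
  expect_error(fit_quadratic(dup, y, "full"), "singular")
})

test_that("ANOVA partitions residual variation into pure error and lack of fit", {
  d <- build_bbd(uae_factors(), 3)
  set.seed(41)
  y <- stats::rnorm(15, 10, 3)
  fit <- fit_quadratic(d, y, "linear")
  an <- anova(fit)
  expect_equal(an$pure_error_df, 2L)
  expect_equal(an$lof_df, an$residual_df - 2L)
  expect_equal(an$ss_pure_error, sum((y[13:15] - mean(y[13:15]))^2))
  expect_equal(an$ss_lack_of_fit + an$ss_pure_error, an$sse, tolerance = 1e-10)
  expect_true(all(an$p_values >= 0 & an$p_values <= 1))
  expect_lte(an$adj_r_squared, an$r_squared)
  # a single centre point leaves lack of fit undefined
  d1 <- build_bbd(uae_factors(), 1)
  an1 <- anova(fit_quadratic(d1, stats::rnorm(13), "linear"))
  expect_true(is.na(an1$lack_of_fit_p))
})

test_that("model selection ranks by adjusted R^2, lack of fit, then parsimony", {
  fx <- spirulina_fixture()
  sel <- select_model(fx$design, fx$responses$abts_mg_TRE_per_g,
                      response_name = "abts")
  expect_equal(sel$scores$candidate[1], "no-interactions")
  expect_length(sel$model$coefficients, 7L)

  one <- select_model(fx$design, fx$responses$abts_mg_TRE_per_g,
                      candidates = list(full = term_set("full")))
  expect_length(one$model$coefficients, 10L)

  # with an explicit first-order candidate the ranking transparently
  # follows adjusted R^2: the ABTS response is dominated by linear terms
  sel_lin <- select_model(fx$design, fx$responses$abts_mg_TRE_per_g,
                          candidates = list(
                            "full" = term_set("full"),
                            "no-interactions" = term_set("no-interactions"),
                            "linear" = term_set("linear")))
  expect_equal(sel_lin$scores$candidate,
               sel_lin$scores$candidate[order(-sel_lin$scores$adj_r_squared)])

  # noiseless truth with non-zero interactions: only the full model is exact
  d <- build_bbd(uae_factors(), 3)
  X <- build_model_matrix(d, "full")
  beta <- c(10, 1, 2, 3, 4, 5, 6, -1, -2, -3)
  sel2 <- select_model(d, drop(X %*% beta))
  expect_equal(sel2$scores$candidate[1], "full")

  # zero interactions: ties on fit quality resolve to the smaller model
  beta0 <- c(10, 1, 2, 3, 0, 0, 0, -1, -2, -3)
  sel3 <- select_model(d, drop(X %*% beta0))
  expect_equal(sel3$scores$candidate[1], "no-interactions")
})

test_that("Pearson correlation matches the covariance formula and guards input", {
  a <- c(1, 2, 3, 5)
  expect_equal(pearson_cor(a, a)$r, 1)
  expect_equal(pearson_cor(c(1, 1, -1, -1), c(1, -1, 1, -1))$r, 0)
  expect_error(pearson_cor(rep(1, 5), 1:5), "constant")

  fx <- spirulina_fixture()
  p <- fx$responses$pigment_mg_per_g; t <- fx$responses$tpc_mg_GAE_per_g
  ct <- pearson_cor(p, t)
  r_brute <- sum((p - mean(p)) * (t - mean(t))) /
    sqrt(sum((p - mean(p))^2) * sum((t - mean(t))^2))
  expect_equal(ct$r, r_brute, tolerance = 1e-12)
  tstat <- r_brute * sqrt((15 - 2) / (1 - r_brute^2))
  expect_equal(ct$p, 2 * stats::pt(abs(tstat), 13, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("Monte-Carlo parameter recovery at sigma > 0 is unbiased", {
  truth <- reference_truth()
  beta <- truth$coefficients$pigment
  n_rep <- 500
  est <- matrix(NA_real_, n_rep, 10)
  for (r in seq_len(n_rep)) {
    sim <- simulate_experiment(truth, seed = 1000 + r)
    fit <- fit_quadratic(sim$design, sim$responses$pigment, "full")
    est[r, ] <- fit$coefficients
  }
  bias <- colMeans(est) - beta
  mcse <- apply(est, 2, stats::sd) / sqrt(n_rep)
  expect_true(all(abs(bias) <= 3 * mcse),
              label = sprintf("max |bias|/MCSE = %.2f", max(abs(bias) / mcse)))
})
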