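test_that("single predictor, one component reduces to simple regression", {
  set.seed(2)
  z <- rnorm(30); y <- 2 + 0.8 * z + rnorm(30, 0, 0.3)
  fit <- rankpls(matrix(z, ncol = 1), y, measure = "standard", ncomp = 1,
                 scale = FALSE)
  b <- cov(z, y) / var(z) * (29 / 29)  # closed-form slope
  expect_equal(unname(coef(fit)), sum((z - mean(z)) * (y - mean(y))) /
                 sum((z - mean(z))^2), tolerance = 1e-10)
  expect_equal(fitted(fit), mean(y) + b * 0 + unname(coef(fit)) *
                 (z - mean(z)) + (mean(y) - mean(y)), tolerance = 1e-10)
})

test_that("standard weights at full rank recover the OLS solution", {
  set.seed(7)
  Z <- matrix(rnorm(20 * 5), 20, 5)
  y <- drop(Z %*% c(1, -0.5, 0, 2, 0.3)) + rnorm(20)
  fit <- rankpls(Z, y, measure = "standard", ncomp = 5, scale = FALSE)
  ols <- oracle_ols(Z, y)
  expect_equal(unname(coef(fit, intercept = TRUE)), ols, tolerance = 1e-8)
  expect_equal(predict(fit, Z), drop(cbind(1, Z) %*% ols),
               tolerance = 1e-8)
  # scaling must not change full-rank predictions
  fit_s <- rankpls(Z, y, measure = "standard", ncomp = 5, scale = TRUE)
  expect_equal(predict(fit_s, Z), drop(cbind(1, Z) %*% ols),
               tolerance = 1e-8)
})

test_that("standard fit matches an independently coded NIPALS reference", {
  set.seed(19)
  Z <- matrix(rnorm(40 * 6), 40, 6)
  y <- drop(Z %*% rnorm(6)) + rnorm(40)
  for (C in c(1, 3, 6)) {
    fit <- rankpls(Z, y, measure = "standard", ncomp = C, scale = TRUE)
    ref <- oracle_nipals(Z, y, C)
    expect_equal(unname(fit$weights), ref$W, tolerance = 1e-8)
    expect_equal(unname(fit$scores), ref$T, tolerance = 1e-8)
    expect_equal(unname(fit$loadings), ref$P, tolerance = 1e-8)
    expect_equal(unname(fit$yloadings), ref$q, tolerance = 1e-8)
    expect_equal(unname(fit$coef_std), ref$beta_std, tolerance = 1e-8)
  }
})

test_that("scores are orthogonal and deflation reconstructs Z", {
  d <- simulate_ranked_data(n = 120, p = 10, n_informative = 3, seed = 31)
  for (m in c("standard", "rho_s", "tau_b", "theil_u", "gk_gamma")) {
    fit <- rankpls(d, measure = m, ncomp = 4)
    G <- crossprod(fit$scores)
    expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
    # T q + mean reproduces the fitted values via beta as well
    expect_equal(drop(fit$scores %*% fit$yloadings) + fit$y_mean,
                 fitted(fit), tolerance = 1e-8)
    # residual identity on training data
    expect_equal(residuals(fit),
                 d$y - drop(fit$scores %*% fit$yloadings) - fit$y_mean,
                 tolerance = 1e-8)
    # deflation conservation: Z0 = T P' + Z_C
    Zc <- sweep(sweep(d$Z, 2, fit$centers, "-"), 2, fit$scales, "/")
    ZC <- Zc - tcrossprod(fit$scores, fit$loadings)
    recon <- tcrossprod(fit$scores, fit$loadings) + ZC
    expect_equal(recon, Zc, tolerance = 1e-8)
    # and the final deflated matrix is orthogonal to all scores
    expect_lt(max(abs(crossprod(fit$scores, ZC))), 1e-6)
  }
})

test_that("adding components never increases the training RSS", {
  d <- simulate_ranked_data(n = 100, p = 10, n_informative = 3, seed = 57)
  for (m in c("standard", "rho_s", "somers_d")) {
    rss <- vapply(1:8, function(C)
      suppressMessages(rankpls(d, measure = m, ncomp = C))$RSS, numeric(1))
    expect_true(all(diff(rss) <= 1e-10))
  }
})

test_that("permuting predictor columns permutes the coefficients", {
  d <- simulate_ranked_data(n = 80, p = 7, n_informative = 2, seed = 71)
  perm <- c(4, 1, 7, 3, 6, 2, 5)
  f1 <- rankpls(d, measure = "tau_a", ncomp = 3)
  f2 <- rankpls(d$Z[, perm], d$y, measure = "tau_a", ncomp = 3)
  expect_equal(unname(coef(f2)), unname(coef(f1)[perm]), tolerance = 1e-10)
  expect_equal(f1$RSS, f2$RSS, tolerance = 1e-10)
})

test_that("prediction honors centering and projection identities", {
  d <- simulate_ranked_data(n = 90, p = 8, n_informative = 3, seed = 83)
  fit <- rankpls(d, measure = "rho_s", ncomp = 3)
  # the row of column means predicts the mean response
  expect_equal(predict(fit, matrix(fit$centers, nrow = 1)),
               fit$y_mean, tolerance = 1e-10)
  # training rows reproduce the training scores
  expect_equal(unname(predict(fit, d$Z, type = "scores")),
               unname(fit$scores), tolerance = 1e-8)
  # the score of the mean row is the zero vector
  expect_equal(as.numeric(predict(fit, matrix(fit$centers, nrow = 1),
                                  type = "scores")),
               rep(0, 3), tolerance = 1e-10)
  # duplicated rows give identical scores
  s <- predict(fit, d$Z[rep(5, 4), ], type = "scores")
  expect_equal(s, s[rep(1, 4), ], ignore_attr = TRUE)
  expect_error(predict(fit, d$Z[, 1:3]), "columns")
})

test_that("degenerate inputs fail loudly or truncate with a message", {
  Z <- matrix(sample.int(3, 60, TRUE), 20, 3)
  expect_error(rankpls(Z, rep(2, 20), ncomp = 2), "constant")
  expect_error(rankpls(Z, sample.int(3, 20, TRUE), ncomp = 10), "ncomp")
  Zc <- matrix(rep(1, 40), 20, 2)  # all columns constant
  expect_error(suppressWarnings(
    rankpls(Zc, sample.int(3, 20, TRUE), measure = "rho_s", ncomp = 1)),
    "degenerate")
  # requesting more structure than the data holds truncates with a message
  set.seed(5)
  Zr <- cbind(a = rnorm(20))
  Zr <- cbind(Zr, b = Zr[, 1], c = Zr[, 1])  # rank 1
  y <- Zr[, 1] + rnorm(20, 0, 0.1)
  expect_message(fit <- rankpls(Zr, y, measure = "standard", ncomp = 3),
                 "truncated")
  expect_lt(fit$ncomp, 3)
})

test_that("the formula interface matches the matrix interface", {
  d <- simulate_ranked_data(n = 60, p = 4, n_informative = 2, seed = 5)
  df <- as.data.frame(d$Z); df$y <- d$y
  f1 <- rankpls(y ~ ., data = df, measure = "tau_b", ncomp = 2)
  f2 <- rankpls(d$Z, d$y, measure = "tau_b", ncomp = 2)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-12)
})

test_that("JSON serialization round-trips the model exactly", {
  d <- simulate_ranked_data(n = 50, p = 6, n_informative = 2, seed = 9)
  fit <- rankpls(d, measure = "somers_d", ncomp = 3)
  path <- tempfile(fileext = ".json")
  write_rankpls(fit, path)
  back <- read_rankpls(path)
  for (nm in c("weights", "scores", "loadings", "yloadings", "projection",
               "coefficients", "intercept", "coef_std", "centers",
               "scales", "RSS", "fitted.values", "residuals", "measure",
               "ncomp", "n", "p", "K")) {
    expect_equal(back[[nm]], fit[[nm]], tolerance = 0, label = nm)
  }
  expect_equal(predict(back, d$Z), predict(fit, d$Z), tolerance = 0)
})

test_that("print, summary, plot and simulate run cleanly", {
  d <- simulate_ranked_data(n = 60, p = 5, n_informative = 2, seed = 3)
  fit <- rankpls(d, measure = "rho_s", ncomp = 2)
  expect_output(print(fit), "rho_s")
  expect_output(print(summary(fit)), "R-squared")
  expect_s3_class(summary(fit)$coef_table, "data.frame")
  grDevices::pdf(NULL)
  expect_invisible(plot(fit, type = "scores"))
  expect_invisible(plot(fit, type = "weights"))
  grDevices::dev.off()
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(60L, 3L))
  expect_equal(simulate(fit, nsim = 2, seed = 4),
               simulate(fit, nsim = 2, seed = 4))
})
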