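x_tied <- c(1, 2, 2, 3)
y_tied <- c(1, 2, 3, 3)

test_that("worked micro-examples reproduce their hand-derived values", {
  expect_equal(spearman_rho(1:4, 1:4), 1.0)
  expect_equal(spearman_rho(1:4, 4:1), -1.0)
  expect_equal(spearman_rho(1:3, c(2, 1, 3)), 0.5)

  expect_equal(kendall_tau_a(1:4, 1:4), 1.0)
  expect_equal(kendall_tau_a(1:4, c(1, 3, 2, 4)), 4 / 6)
  expect_equal(kendall_tau_a(x_tied, y_tied), 4 / 6)

  expect_equal(kendall_tau_b(x_tied, y_tied), 0.8)
  expect_equal(stuart_tau_c(x_tied, y_tied), 0.75)
  expect_equal(somers_d(x_tied, y_tied), 0.8)
  expect_equal(gk_tau(x_tied, y_tied), 8 / 6)
  expect_equal(gk_gamma(x_tied, y_tied), 1.0)
  expect_equal(gk_gamma(1:4, 4:1), -1.0)

  # Theil's U on the 2x2 table [[2,1],[0,1]]
  x <- c(1, 1, 1, 2); y <- c(1, 1, 2, 2)
  hx <- -(0.75 * log(0.75) + 0.25 * log(0.25))
  expect_equal(theil_u(x, y), (hx - 0.5 * log(2)) / hx)
  expect_equal(theil_u(x, y), 0.3837, tolerance = 1e-4)
  expect_equal(theil_u(1:3, 1:3), 1.0)            # bijective association
  expect_equal(theil_u(c(1, 1, 2, 2), c(1, 2, 1, 2)), 0.0)  # independence
})

test_that("every coefficient matches its exhaustive-enumeration oracle", {
  set.seed(101)
  measures <- c("rho_s", "tau_a", "tau_b", "tau_c", "somers_d",
                "gk_tau", "gk_gamma", "theil_u")
  for (rep in 1:200) {
    n <- sample(2:30, 1)
    x <- random_ordinal(n); y <- random_ordinal(n)
    for (m in measures) {
      expected <- oracle_measure(x, y, m)
      got <- rank_assoc(x, y, m)
      if (is.na(expected)) {
        expect_true(is_degenerate(got))
      } else {
        expect_equal(as.numeric(got), expected, tolerance = 1e-12)
      }
    }
  }
})

test_that("tau_b and rho_s agree with the stats package implementations", {
  set.seed(20)
  for (rep in 1:25) {
    n <- sample(5:40, 1)
    x <- random_ordinal(n); y <- random_ordinal(n)
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(as.numeric(kendall_tau_b(x, y)),
                 suppressWarnings(cor(x, y, method = "kendall")),
                 tolerance = 1e-12)
    expect_equal(as.numeric(spearman_rho(x, y)),
                 cor(x, y, method = "spearman"), tolerance = 1e-12)
  }
})

test_that("spearman on tie-free data equals the classical d^2 formula", {
  set.seed(3)
  for (rep in 1:25) {
    n <- sample(3:30, 1)
    x <- sample(n); y <- sample(n)
    d2 <- sum((rank(x) - rank(y))^2)
    expect_equal(spearman_rho(x, y), 1 - 6 * d2 / (n * (n^2 - 1)),
                 tolerance = 1e-12)
  }
})

test_that("symmetry and asymmetry behave as documented", {
  set.seed(9)
  for (rep in 1:20) {
    n <- sample(4:25, 1)
    x <- random_ordinal(n); y <- random_ordinal(n)
    for (m in c("rho_s", "tau_a", "tau_b", "tau_c", "gk_gamma")) {
      a <- rank_assoc(x, y, m); b <- rank_assoc(y, x, m)
      if (!is_degenerate(a) && !is_degenerate(b))
        expect_equal(as.numeric(a), as.numeric(b), tolerance = 1e-12)
    }
  }
  # asymmetry witness: ties only in the first argument
  x <- c(1, 1, 2, 3); y <- c(1, 2, 3, 4)
  expect_false(isTRUE(all.equal(somers_d(x, y), somers_d(y, x))))
  xt <- c(1, 1, 1, 2, 2, 3); yt <- c(1, 2, 3, 1, 2, 3)
  expect_false(isTRUE(all.equal(as.numeric(theil_u(xt, yt)),
                                as.numeric(theil_u(yt, xt)))))
})

test_that("negating the order of y negates signed coefficients only", {
  set.seed(13)
  for (rep in 1:20) {
    n <- sample(4:25, 1)
    x <- random_ordinal(n); y <- random_ordinal(n)
    yr <- max(y) + 1 - y  # strictly decreasing relabeling
    for (m in c("rho_s", "tau_a", "tau_b", "tau_c", "somers_d",
                "gk_tau", "gk_gamma")) {
      a <- rank_assoc(x, y, m); b <- rank_assoc(x, yr, m)
      if (!is_degenerate(a))
        expect_equal(as.numeric(b), -as.numeric(a), tolerance = 1e-12)
    }
    expect_equal(as.numeric(theil_u(x, yr)), as.numeric(theil_u(x, y)),
                 tolerance = 1e-12)
  }
})

test_that("coefficients are invariant to strictly monotone relabeling", {
  set.seed(17)
  mono <- function(v) (2 * v + 1)^2  # strictly increasing on positive codes
  for (rep in 1:20) {
    n <- sample(4:25, 1)
    x <- random_ordinal(n); y <- random_ordinal(n)
    for (m in c("rho_s", "tau_a", "tau_b", "tau_c", "somers_d",
                "gk_tau", "gk_gamma", "theil_u")) {
      a <- rank_assoc(x, y, m)
      b <- rank_assoc(mono(x), mono(y), m)
      expect_equal(as.numeric(a), as.numeric(b), tolerance = 1e-12)
    }
  }
})

test_that("tie-free reductions hold within the Kendall family", {
  set.seed(23)
  for (rep in 1:15) {
    n <- sample(4:20, 1)
    x <- sample(n); y <- sample(n)
    ta <- kendall_tau_a(x, y)
    expect_equal(kendall_tau_b(x, y), ta, tolerance = 1e-12)
    expect_equal(somers_d(x, y), ta, tolerance = 1e-12)
    expect_equal(as.numeric(gk_gamma(x, y)), ta, tolerance = 1e-12)
    expect_equal(gk_tau(x, y), 2 * ta, tolerance = 1e-12)
  }
})

test_that("degenerate inputs return flagged zeros, not errors", {
  expect_true(is_degenerate(spearman_rho(c(2, 2, 2), 1:3)))
  expect_true(is_degenerate(kendall_tau_b(c(2, 2, 2), 1:3)))
  expect_true(is_degenerate(somers_d(c(2, 2, 2), 1:3)))
  expect_true(is_degenerate(stuart_tau_c(c(2, 2, 2), 1:3)))
  expect_true(is_degenerate(gk_gamma(c(1, 1), c(2, 2))))
  expect_true(is_degenerate(gk_gamma(c(1, 1, 2), c(3, 3, 3))))
  expect_true(is_degenerate(theil_u(c(3, 3, 3), 1:3)))
  expect_equal(as.numeric(kendall_tau_b(c(2, 2, 2), 1:3)), 0)
})

test_that("classical Goodman-Kruskal tau is a PRE measure in [0, 1]", {
  set.seed(31)
  for (rep in 1:30) {
    n <- sample(5:30, 1)
    x <- random_ordinal(n); y <- random_ordinal(n)
    v <- gk_tau(x, y, mode = "classical")
    if (!is_degenerate(v)) {
      expect_gte(as.numeric(v), -1e-12)
      expect_lte(as.numeric(v), 1 + 1e-12)
    }
  }
  # perfect prediction of y from x
  expect_equal(as.numeric(gk_tau(c(1, 1, 2, 2), c(3, 3, 7, 7),
                                 mode = "classical")), 1.0)
})

test_that("loading weight vectors are unit-norm with signs restored", {
  set.seed(41)
  Z <- matrix(sample.int(4, 60 * 6, replace = TRUE), 60, 6)
  y <- sample.int(3, 60, replace = TRUE)
  Z[, 3] <- y  # column identical to the response
  for (m in MEASURES) {
    w <- loading_weights(Z, y, measure = m)
    expect_equal(sqrt(sum(w^2)), 1, tolerance = 1e-12)
    if (m != "standard") expect_equal(which.max(abs(w)), 3L)
  }
  # sign restoration: theil_u weights carry the spearman sign
  yneg <- max(y) + 1 - y
  Zn <- Z; Zn[, 3] <- yneg
  w <- loading_weights(Zn, y, measure = "theil_u")
  expect_lt(w[3], 0)
  # standard weights are proportional to Z'y on centered data
  Zc <- scale(Z, scale = FALSE)
  w_std <- loading_weights(Zc, y, measure = "standard")
  ref <- drop(crossprod(Zc, y - mean(y)))
  expect_equal(w_std, ref / sqrt(sum(ref^2)), tolerance = 1e-12)
  # p = 1 reduces to a unit scalar
  expect_equal(abs(loading_weights(Z[, 1, drop = FALSE], y, "tau_b")), 1,
               ignore_attr = TRUE)
})

test_that("degenerate columns get zero weight with a warning", {
  Z <- cbind(a = rep(2, 30), b = sample.int(3, 30, replace = TRUE))
  y <- sample.int(3, 30, replace = TRUE)
  expect_warning(w <- loading_weights(Z, y, measure = "tau_b"),
                 "degenerate")
  expect_equal(w[1], 0)
  # all columns degenerate: flagged zero vector
  Zc <- cbind(rep(1, 10), rep(2, 10))
  wc <- suppressWarnings(loading_weights(Zc, rep(1:2, 5), "rho_s"))
  expect_true(isTRUE(attr(wc, "degenerate")))
  expect_equal(as.numeric(wc), c(0, 0))
})

test_that("unknown measure names are rejected", {
  expect_error(loading_weights(matrix(1:10, 5), 1:5, measure = "pearson"))
  expect_error(rank_assoc(1:4, 1:4, "standard"))
})
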