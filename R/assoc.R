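#' @useDynLib rankpls, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Canonical names of the loading-weight association measures
#'
#' `"standard"` is the covariance weight of ordinary NIPALS PLS; the other
#' eight replace it with a rank-association measure between each predictor
#' and the response.
#'
#' @export
MEASURES <- c("standard", "rho_s", "tau_a", "tau_b", "tau_c",
              "somers_d", "gk_tau", "gk_gamma", "theil_u")

#' Concordant/discordant/tie pair counts
#'
#' Tallies all n(n-1)/2 observation pairs of two ordinal vectors. A pair
#' (i, j) is concordant when `(x_i - x_j)(y_i - y_j) > 0`, discordant when
#' `< 0`; pairs tied on `x` are counted into `n_1`, pairs tied on `y` into
#' `n_2` (a pair tied on both counts in each). These tallies are the shared
#' core of the Kendall-family coefficients.
#'
#' @param x,y numeric vectors of equal length (ordinal codes or midranks).
#' @return An object of class `"pair_counts"`: a list with elements `n_c`,
#'   `n_d`, `n_0` (= n(n-1)/2), `n_1`, `n_2`, `n_xy` (tied on both) and `n`.
#' @examples
#' pair_counts(c(1, 2, 2, 3), c(1, 2, 3, 3))
#' @export
pair_counts <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y))
    stop("'x' and 'y' must have the same length", call. = FALSE)
  if (length(x) < 2L)
    stop("pair counting needs at least 2 observations", call. = FALSE)
  if (anyNA(x) || anyNA(y))
    stop("missing values are not allowed in pair counting", call. = FALSE)
  structure(.pair_counts_cpp(x, y), class = "pair_counts")
}

#' @export
print.pair_counts <- function(x, ...) {
  cat("Pair counts (n =", x$n, "):\n")
  cat("  concordant n_c =", x$n_c, " discordant n_d =", x$n_d,
      " total n_0 =", x$n_0, "\n")
  cat("  tied in x  n_1 =", x$n_1, " tied in y  n_2 =", x$n_2,
      " tied in both =", x$n_xy, "\n")
  invisible(x)
}

# value 0 carrying a flag that the statistic was undefined on this input
.degenerate <- function() structure(0, degenerate = TRUE)

#' Is a coefficient flagged as degenerate?
#'
#' Association measures return 0 with a `degenerate` attribute when their
#' denominator is undefined (e.g. a constant variable); this predicate tests
#' the flag.
#'
#' @param x a value returned by one of the association measures.
#' @export
is_degenerate <- function(x) isTRUE(attr(x, "degenerate"))

#' Spearman's rank correlation
#'
#' Pearson correlation of the midranks of `x` and `y` — the standard
#' generalization of the classical `1 - 6 sum(d^2) / (n(n^2-1))` formula,
#' with which it coincides on tie-free data. Heavily tied ordinal codes make
#' the tie-free shortcut biased, hence the midrank form is used throughout.
#'
#' @inheritParams pair_counts
#' @return Coefficient in `[-1, 1]`; 0 with a `degenerate` attribute when a
#'   variable is constant.
#' @export
spearman_rho <- function(x, y) {
  .check_pair(x, y)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(.degenerate())
  stats::cor(rx, ry)
}

.check_pair <- function(x, y) {
  if (length(x) != length(y))
    stop("'x' and 'y' must have the same length", call. = FALSE)
  if (length(x) < 2L) stop("need at least 2 observations", call. = FALSE)
  invisible(NULL)
}

#' Kendall's tau-A
#'
#' `(n_c - n_d) / n_0`: no adjustment for ties, so heavily tied data shrink
#' the coefficient toward zero.
#'
#' @inheritParams pair_counts
#' @export
kendall_tau_a <- function(x, y) {
  pc <- pair_counts(x, y)
  (pc$n_c - pc$n_d) / pc$n_0
}

#' Kendall's tau-B
#'
#' `(n_c - n_d) / sqrt((n_0 - n_1)(n_0 - n_2))`: the tie-adjusted tau, with
#' `n_1`, `n_2` the tied-pair counts of each variable, so that `|tau_B| <= 1`
#' even under ties.
#'
#' @inheritParams pair_counts
#' @export
kendall_tau_b <- function(x, y) {
  pc <- pair_counts(x, y)
  den <- sqrt((pc$n_0 - pc$n_1) * (pc$n_0 - pc$n_2))
  if (den == 0) return(.degenerate())
  (pc$n_c - pc$n_d) / den
}

#' Stuart-Kendall tau-C
#'
#' `2 m (n_c - n_d) / (n^2 (m - 1))` with `m = min(r, k)` the smaller
#' dimension of the two variables' contingency table; suited to non-square
#' tables.
#'
#' @inheritParams pair_counts
#' @export
stuart_tau_c <- function(x, y) {
  pc <- pair_counts(x, y)
  m <- min(length(unique(.bin_levels(x))), length(unique(.bin_levels(y))))
  if (m < 2L) return(.degenerate())
  2 * m * (pc$n_c - pc$n_d) / (pc$n^2 * (m - 1))
}

#' Somers' D
#'
#' Asymmetric Kendall-type measure of `y` given predictor `x`:
#' `(n_c - n_d) / (n_0 - n_1)`, i.e. pairs tied on the predictor are removed
#' from the denominator. Equivalently the ratio tau_A(x, y) / tau_A(x, x).
#'
#' @inheritParams pair_counts
#' @export
somers_d <- function(x, y) {
  pc <- pair_counts(x, y)
  if (pc$n_0 == pc$n_1) return(.degenerate())
  (pc$n_c - pc$n_d) / (pc$n_0 - pc$n_1)
}

#' Goodman-Kruskal's tau (loading-weight form)
#'
#' Default mode `"printed"` computes `2 (n_c - n_d) / n_0` — twice tau-A —
#' which is the form this PLS family uses as a loading weight; note it can
#' exceed 1 in magnitude. Mode `"classical"` gives the classical
#' proportional-reduction-in-error Goodman-Kruskal tau of `y` given `x`
#' (nonnegative, in `[0, 1]`).
#'
#' @inheritParams pair_counts
#' @param mode `"printed"` (default) or `"classical"`.
#' @export
gk_tau <- function(x, y, mode = c("printed", "classical")) {
  mode <- match.arg(mode)
  if (mode == "printed") {
    pc <- pair_counts(x, y)
    return(2 * (pc$n_c - pc$n_d) / pc$n_0)
  }
  .check_pair(x, y)
  tab <- table(.bin_levels(x), .bin_levels(y))
  n <- sum(tab)
  py <- colSums(tab) / n
  vy <- 1 - sum(py^2)
  if (vy == 0) return(.degenerate())
  rs <- rowSums(tab)
  cond <- 0
  for (i in seq_len(nrow(tab))) {
    if (rs[i] > 0) cond <- cond + (rs[i] / n) * (1 - sum((tab[i, ] / rs[i])^2))
  }
  (vy - cond) / vy
}

#' Goodman-Kruskal's gamma
#'
#' `(n_c - n_d) / (n_c + n_d)`: all tied pairs are dropped entirely.
#'
#' @inheritParams pair_counts
#' @export
gk_gamma <- function(x, y) {
  pc <- pair_counts(x, y)
  if (pc$n_c + pc$n_d == 0) return(.degenerate())
  (pc$n_c - pc$n_d) / (pc$n_c + pc$n_d)
}

#' Theil's U (uncertainty coefficient)
#'
#' `U(x | y) = (H(x) - H(x | y)) / H(x)`: the fraction of the entropy of `x`
#' explained by conditioning on `y`. Nonnegative, in `[0, 1]`, asymmetric,
#' and invariant to the logarithm base (natural log used).
#'
#' @inheritParams pair_counts
#' @export
theil_u <- function(x, y) {
  .check_pair(x, y)
  tab <- table(.bin_levels(x), .bin_levels(y))
  n <- sum(tab)
  hx <- .entropy(rowSums(tab) / n)
  if (hx == 0) return(.degenerate())
  cs <- colSums(tab)
  hxy <- 0
  for (j in seq_len(ncol(tab))) {
    if (cs[j] > 0) hxy <- hxy + (cs[j] / n) * .entropy(tab[, j] / cs[j])
  }
  unname((hx - hxy) / hx)
}

.entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

# Contingency-table measures need discrete levels: use the values themselves
# when there are at most 20 distinct ones, else quintile bins.
.bin_levels <- function(x, max_levels = 20L) {
  ux <- unique(x)
  if (length(ux) <= max_levels) return(match(x, sort(ux)))
  br <- unique(stats::quantile(x, probs = seq(0, 1, 0.2), names = FALSE))
  if (length(br) < 3L) return(match(x, sort(ux)))
  as.integer(cut(x, breaks = br, include.lowest = TRUE))
}

#' Compute one association measure by name
#'
#' Dispatcher over the eight rank-association measures (see [MEASURES];
#' `"standard"` is not an association coefficient and is rejected here).
#'
#' @inheritParams pair_counts
#' @param measure one of `"rho_s"`, `"tau_a"`, `"tau_b"`, `"tau_c"`,
#'   `"somers_d"`, `"gk_tau"`, `"gk_gamma"`, `"theil_u"`.
#' @param gk_mode mode passed to [gk_tau()].
#' @export
rank_assoc <- function(x, y, measure, gk_mode = c("printed", "classical")) {
  gk_mode <- match.arg(gk_mode)
  switch(match.arg(measure, MEASURES[-1L]),
    rho_s    = spearman_rho(x, y),
    tau_a    = kendall_tau_a(x, y),
    tau_b    = kendall_tau_b(x, y),
    tau_c    = stuart_tau_c(x, y),
    somers_d = somers_d(x, y),
    gk_tau   = gk_tau(x, y, mode = gk_mode),
    gk_gamma = gk_gamma(x, y),
    theil_u  = theil_u(x, y))
}

#' Loading-weight vector for a predictor matrix
#'
#' Computes, for each column of `Z`, the chosen association with `y`, and
#' scales the resulting vector to unit Euclidean norm. For the `"standard"`
#' measure the weight is the covariance direction `Z'y` of ordinary NIPALS
#' PLS. Sign-free measures (`theil_u`, and `gk_tau` in classical mode) carry
#' no direction, so each entry's magnitude is given the sign of the Spearman
#' correlation of that column with `y` — PLS scores need signed weights.
#' Degenerate columns (constant/fully tied) get weight 0 with a warning. An
#' all-zero vector is returned un-normalized with attribute
#' `degenerate = TRUE`.
#'
#' @param Z numeric matrix, n rows by p columns.
#' @param y numeric response vector of length n.
#' @param measure one of [MEASURES].
#' @param gk_mode mode for [gk_tau()].
#' @param warn warn about degenerate columns (default `TRUE`).
#' @return Numeric p-vector of unit norm (or all zeros, flagged).
#' @export
loading_weights <- function(Z, y, measure = MEASURES,
                            gk_mode = c("printed", "classical"),
                            warn = TRUE) {
  measure <- match.arg(measure)
  gk_mode <- match.arg(gk_mode)
  Z <- as.matrix(Z)
  if (measure == "standard") {
    w <- as.numeric(crossprod(Z, y - mean(y)))
  } else {
    signfree <- measure == "theil_u" ||
      (measure == "gk_tau" && gk_mode == "classical")
    w <- numeric(ncol(Z))
    ndeg <- 0L
    for (j in seq_len(ncol(Z))) {
      v <- rank_assoc(Z[, j], y, measure, gk_mode = gk_mode)
      if (is_degenerate(v)) { ndeg <- ndeg + 1L; v <- 0 }
      else if (signfree) {
        s <- spearman_rho(Z[, j], y)
        v <- abs(v) * sign(as.numeric(s))
      }
      w[j] <- v
    }
    if (ndeg > 0L && warn)
      warning(ndeg, " degenerate column(s) received zero loading weight",
              call. = FALSE)
  }
  nrm <- sqrt(sum(w^2))
  if (nrm == 0 || !is.finite(nrm)) {
    attr(w, "degenerate") <- TRUE
    return(w)
  }
  w / nrm
}
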