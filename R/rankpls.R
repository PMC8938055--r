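#' Construct a ranked dataset
#'
#' The modeling input: an n x p predictor matrix of ordinal integer codes
#' (or continuous values) together with an ordinal response recoded to
#' consecutive integer ranks 1..K. Rows with missing entries are dropped
#' with a message.
#'
#' @param Z numeric matrix or data frame of predictors.
#' @param y response vector: integer ranks, or a factor/character whose
#'   levels define the rank order (factors use their level order).
#' @param level_labels optional character labels for the K response ranks.
#' @param quiet suppress the dropped-rows message.
#' @return An object of class `"ranked_dataset"`: list with elements `Z`
#'   (numeric matrix with column names), `y` (integer codes 1..K), `K`,
#'   `level_labels`, `n`, `p`.
#' @examples
#' d <- ranked_dataset(matrix(sample(1:3, 40, TRUE), 10), sample(1:3, 10, TRUE))
#' d
#' @export
ranked_dataset <- function(Z, y, level_labels = NULL, quiet = FALSE) {
  Z <- as.matrix(Z)
  storage.mode(Z) <- "double"
  if (is.null(colnames(Z))) colnames(Z) <- paste0("z", seq_len(ncol(Z)))
  if (nrow(Z) != length(y))
    stop("nrow(Z) must equal length(y)", call. = FALSE)
  if (is.character(y)) y <- factor(y, levels = unique(y))
  if (is.factor(y)) {
    if (is.null(level_labels)) level_labels <- levels(y)
    y <- as.integer(y)
  }
  y <- as.numeric(y)
  keep <- stats::complete.cases(Z) & !is.na(y)
  if (any(!keep)) {
    if (!quiet) message("dropped ", sum(!keep), " row(s) with missing values")
    Z <- Z[keep, , drop = FALSE]; y <- y[keep]
  }
  lev <- sort(unique(y))
  if (length(lev) < 2L)
    stop("response must take at least 2 distinct levels", call. = FALSE)
  ycode <- match(y, lev)
  if (is.null(level_labels)) level_labels <- as.character(lev)
  if (length(level_labels) != length(lev))
    level_labels <- as.character(lev)
  structure(list(Z = Z, y = ycode, K = length(lev),
                 level_labels = level_labels,
                 n = nrow(Z), p = ncol(Z)),
            class = "ranked_dataset")
}

#' @export
print.ranked_dataset <- function(x, ...) {
  cat("Ranked dataset: ", x$n, " observations, ", x$p, " predictors, ",
      x$K, " response ranks (", paste(x$level_labels, collapse = " < "),
      ")\n", sep = "")
  invisible(x)
}

#' @export
dim.ranked_dataset <- function(x) c(x$n, x$p)

#' Subset the predictor columns of a ranked dataset
#'
#' @param data a [ranked_dataset()].
#' @param j column indices or names to keep.
#' @export
subset_predictors <- function(data, j) {
  stopifnot(inherits(data, "ranked_dataset"))
  Z <- data$Z[, j, drop = FALSE]
  if (ncol(Z) == 0L) stop("no predictors retained", call. = FALSE)
  out <- data
  out$Z <- Z
  out$p <- ncol(Z)
  out
}

#' Rank-weighted partial least squares regression
#'
#' Fits a PLS1 regression of an ordinal response on a predictor matrix by
#' the NIPALS algorithm, with the loading weight of each component given by
#' a pluggable association measure: the covariance weight `Z'y` of standard
#' PLS, or one of eight rank-association measures (Spearman's rho, Kendall's
#' tau-A/B/C, Somers' D, Goodman-Kruskal's tau and gamma, Theil's U) suited
#' to rank-scale data. Per component c: `w_c` from the chosen measure on the
#' deflated data, scores `t_c = Z_{c-1} w_c`, loadings
#' `p_c = Z'_{c-1} t_c / t'_c t_c`, `q_c = y'_{c-1} t_c / t'_c t_c`, then
#' deflation `Z_c = Z_{c-1} - t_c p'_c`, `y_c = y_{c-1} - t_c q_c`.
#' Regression coefficients are recovered as `beta = W (P'W)^{-1} q` with
#' intercept `mean(y) - colMeans(Z) . beta`.
#'
#' Predictors are always mean-centered; unit-variance scaling is on by
#' default so that covariance weights and the scale-free rank weights act on
#' comparable columns. The response ranks are coded 1..K and centered. Each
#' weight vector is normalized to unit length with its sign fixed so the
#' largest-magnitude entry is positive. Components whose weight norm or
#' score sum-of-squares falls below `tol` stop the fit early; the truncation
#' is recorded in the object and messaged.
#'
#' @param x a [ranked_dataset()], a formula, or a predictor matrix.
#' @param ... further arguments passed to methods.
#' @return An object of class `"rankpls"`; see Details for components.
#'   Supports `print`, `summary`, `coef`, `predict`, `fitted`, `residuals`,
#'   `AIC`, `plot` and `simulate`.
#' @examples
#' d <- simulate_ranked_data(n = 120, p = 8, n_informative = 3, seed = 7)
#' fit <- rankpls(d, measure = "rho_s", ncomp = 3)
#' fit
#' head(predict(fit, d$Z))
#' @export
rankpls <- function(x, ...) UseMethod("rankpls")

#' @rdname rankpls
#' @param data a data frame holding the variables of `formula` (response on
#'   the left, predictors on the right).
#' @export
rankpls.formula <- function(x, data, ...) {
  mf <- stats::model.frame(x, data)
  y <- stats::model.response(mf)
  Z <- stats::model.matrix(attr(mf, "terms"), mf)
  Z <- Z[, colnames(Z) != "(Intercept)", drop = FALSE]
  fit <- rankpls.default(Z, y, ...)
  fit$call <- match.call()
  fit
}

#' @rdname rankpls
#' @export
rankpls.ranked_dataset <- function(x, ...) {
  fit <- rankpls.default(x$Z, x$y, ..., .K = x$K,
                         .level_labels = x$level_labels)
  fit$call <- match.call()
  fit
}

#' @rdname rankpls
#' @param y response vector of ordinal ranks (default method).
#' @param measure loading-weight variant, one of [MEASURES].
#' @param ncomp number of components C, `1 <= ncomp <= min(p, n - 1)`.
#' @param scale logical: scale predictor columns to unit variance
#'   (default `TRUE`).
#' @param gk_mode Goodman-Kruskal tau mode, see [gk_tau()].
#' @param tol early-stopping tolerance on the weight norm and score
#'   sum-of-squares.
#' @param .K,.level_labels internal: response metadata forwarded by the
#'   `ranked_dataset` method.
#' @export
rankpls.default <- function(x, y, measure = MEASURES,
                            ncomp = min(5L, ncol(as.matrix(x))),
                            scale = TRUE,
                            gk_mode = c("printed", "classical"),
                            tol = 1e-12, ...,
                            .K = NULL, .level_labels = NULL) {
  measure <- match.arg(measure)
  gk_mode <- match.arg(gk_mode)
  Z <- as.matrix(x)
  storage.mode(Z) <- "double"
  if (is.null(colnames(Z))) colnames(Z) <- paste0("z", seq_len(ncol(Z)))
  y <- as.numeric(y)
  n <- nrow(Z); p <- ncol(Z)
  if (length(y) != n) stop("length(y) must equal nrow(x)", call. = FALSE)
  if (ncomp < 1L || ncomp > p || ncomp > n - 1L)
    stop("'ncomp' must lie in 1..min(p, n-1)", call. = FALSE)
  if (stats::sd(y) == 0)
    stop("response is constant; nothing to fit", call. = FALSE)

  centers <- colMeans(Z)
  scales <- if (scale) apply(Z, 2L, stats::sd) else rep(1, p)
  const_cols <- which(scales == 0 | !is.finite(scales))
  scales[const_cols] <- 1
  Zc <- sweep(sweep(Z, 2L, centers, "-"), 2L, scales, "/")
  y_mean <- mean(y)
  yc <- y - y_mean

  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp); q <- numeric(ncomp)
  Zd <- Zc; yd <- yc
  C <- 0L; truncated <- FALSE
  for (c in seq_len(ncomp)) {
    w <- loading_weights(Zd, yd, measure = measure, gk_mode = gk_mode,
                         warn = (c == 1L))
    if (is_degenerate(w) || sqrt(sum(w^2)) < tol) {
      if (c == 1L)
        stop("all loading weights degenerate at the first component; ",
             "fit failed", call. = FALSE)
      truncated <- TRUE; break
    }
    imax <- which.max(abs(w))
    if (w[imax] < 0) w <- -w
    tc <- as.numeric(Zd %*% w)
    tt <- sum(tc^2)
    if (tt < tol) { truncated <- TRUE; break }
    pc <- as.numeric(crossprod(Zd, tc)) / tt
    qc <- sum(yd * tc) / tt
    Zd <- Zd - tcrossprod(tc, pc)
    yd <- yd - tc * qc
    C <- C + 1L
    W[, C] <- w; P[, C] <- pc; Tm[, C] <- tc; q[C] <- qc
  }
  if (truncated) {
    message("fit truncated at ", C, " of ", ncomp,
            " requested components (degenerate direction)")
    W <- W[, seq_len(C), drop = FALSE]; P <- P[, seq_len(C), drop = FALSE]
    Tm <- Tm[, seq_len(C), drop = FALSE]; q <- q[seq_len(C)]
  }
  rownames(W) <- rownames(P) <- colnames(Z)

  PW <- crossprod(P, W)
  R <- tryCatch(W %*% solve(PW),
                error = function(e) {
                  warning("P'W singular; using pseudo-inverse", call. = FALSE)
                  W %*% .ginv(PW)
                })
  beta_std <- as.numeric(R %*% q)
  beta <- beta_std / scales
  alpha <- y_mean - sum(centers * beta)
  names(beta) <- names(beta_std) <- colnames(Z)
  fitted <- alpha + as.numeric(Z %*% beta)
  res <- y - fitted

  structure(list(
    weights = W, scores = Tm, loadings = P, yloadings = q,
    projection = R,
    coefficients = beta, intercept = alpha, coef_std = beta_std,
    centers = centers, scales = scales, scaled = scale,
    y = y, y_mean = y_mean,
    K = if (is.null(.K)) length(unique(y)) else .K,
    level_labels = if (is.null(.level_labels))
      as.character(sort(unique(y))) else .level_labels,
    fitted.values = fitted, residuals = res, RSS = sum(res^2),
    ncomp = C, ncomp_requested = ncomp, truncated = truncated,
    measure = measure, gk_mode = gk_mode,
    n = n, p = p, call = match.call()),
    class = "rankpls")
}

# Moore-Penrose pseudo-inverse via SVD (fallback for singular P'W)
.ginv <- function(A, rtol = 1e-10) {
  s <- svd(A)
  keep <- s$d > rtol * max(s$d)
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}
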