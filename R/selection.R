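#' Filter-based variable importance
#'
#' Computes a per-variable importance score from a fitted PLS model by one
#' of three filter methods, and applies a retention cut:
#'
#' * `"lw"` — loading weights: within each component the absolute weights
#'   are divided by the largest, and a variable's importance is the maximum
#'   of these normalized values across components (`aggregate = "mean"`
#'   averages instead). Scores lie in `[0, 1]` with the per-component
#'   leader at 1.
#' * `"rc"` — regression coefficients: `|beta_j|` on the standardized
#'   predictor scale, with `beta = W (P'W)^{-1} q`.
#' * `"smc"` — significance multivariate correlation: each (centered,
#'   scaled) predictor column is split into its projection on the model's
#'   regression direction in sample space — the centered fitted-value
#'   vector `Z beta`, normalized to unit length — and the orthogonal
#'   remainder. The importance is the mean-square ratio
#'   `(z'b)^2 / (||z - (z'b) b||^2 / (n - 2))`. For a pure-noise column
#'   this ratio follows approximately F(1, n - 2), which motivates the
#'   default threshold.
#'
#' Default thresholds: 0.5 for LW (on the normalized scale), the median
#' `|beta|` for RC, and the 0.95 quantile of F(1, n - 2) for SMC. A fixed
#' `top_k` may be used instead of a threshold.
#'
#' @param model a fitted [rankpls()] model.
#' @param method `"lw"`, `"rc"` or `"smc"`.
#' @param data the [ranked_dataset()] the model was fitted to (required for
#'   `"smc"`, which needs the predictor columns).
#' @param threshold retention cut; `NULL` uses the method default.
#' @param top_k retain the k highest-scoring variables instead of applying
#'   a threshold.
#' @param aggregate LW aggregation across components, `"max"` or `"mean"`.
#' @return An object of class `"selection_scores"`: list with `method`,
#'   `importance` (named nonnegative p-vector), `threshold`, `retained`
#'   (integer indices), and `empty` flag.
#' @examples
#' d <- simulate_ranked_data(n = 150, p = 10, n_informative = 3, seed = 1)
#' fit <- rankpls(d, measure = "rho_s", ncomp = 3)
#' variable_importance(fit, "rc")
#' @export
variable_importance <- function(model, method = c("lw", "rc", "smc"),
                                data = NULL, threshold = NULL, top_k = NULL,
                                aggregate = c("max", "mean")) {
  method <- match.arg(method)
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(model, "rankpls"))
  p <- model$p

  if (method == "lw") {
    Wn <- abs(model$weights)
    for (c in seq_len(ncol(Wn))) {
      mx <- max(Wn[, c])
      if (mx > 0) Wn[, c] <- Wn[, c] / mx
    }
    imp <- if (aggregate == "max") apply(Wn, 1L, max)
           else rowMeans(Wn)
    default_thr <- 0.5
  } else if (method == "rc") {
    imp <- abs(model$coef_std)
    default_thr <- stats::median(imp)
  } else {
    if (is.null(data))
      stop("'data' is required for SMC importance", call. = FALSE)
    stopifnot(inherits(data, "ranked_dataset"))
    if (ncol(data$Z) != p)
      stop("'data' column count does not match the model", call. = FALSE)
    n <- data$n
    Zc <- sweep(sweep(data$Z, 2L, model$centers, "-"), 2L,
                model$scales, "/")
    # regression direction in sample space: the (centered) fitted-value
    # vector Zc beta, normalized to unit length
    b <- as.numeric(Zc %*% model$coef_std)
    nb <- sqrt(sum(b^2))
    if (nb == 0) {
      imp <- rep(0, p); names(imp) <- names(model$coefficients)
      return(structure(list(method = "smc", importance = imp,
                            threshold = Inf, retained = integer(0),
                            empty = TRUE),
                       class = "selection_scores"))
    }
    b <- b / nb
    proj <- as.numeric(crossprod(Zc, b))          # z_j' b, per column
    ss_tot <- colSums(Zc^2)
    ss_reg <- proj^2
    ss_res <- pmax(ss_tot - ss_reg, 0)
    ms_res <- ss_res / (n - 2)
    imp <- ifelse(ms_res > 0, ss_reg / ms_res, Inf)
    if (any(!is.finite(imp))) {
      warning("column(s) perfectly aligned with the coefficient direction; ",
              "importance capped", call. = FALSE)
      imp[!is.finite(imp)] <- .Machine$double.xmax
    }
    default_thr <- stats::qf(0.95, 1, n - 2)
  }
  names(imp) <- names(model$coefficients)

  if (!is.null(top_k)) {
    top_k <- min(as.integer(top_k), p)
    retained <- sort(order(imp, decreasing = TRUE)[seq_len(top_k)])
    thr <- min(imp[retained])
  } else {
    thr <- if (is.null(threshold)) default_thr else threshold
    retained <- unname(which(imp >= thr))
  }
  structure(list(method = method, importance = imp, threshold = thr,
                 retained = retained, empty = length(retained) == 0L),
            class = "selection_scores")
}

#' @export
print.selection_scores <- function(x, ...) {
  cat("Variable importance (", toupper(x$method), "): ",
      length(x$retained), " of ", length(x$importance),
      " variables retained at threshold ",
      format(x$threshold, digits = 4L), "\n", sep = "")
  if (x$empty) cat("  ** empty selection **\n")
  top <- utils::head(sort(x$importance, decreasing = TRUE), 5L)
  cat("  top scores: ",
      paste(names(top), format(top, digits = 3L), sep = "=",
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Restrict a dataset to the retained variables
#'
#' @param data the [ranked_dataset()] the scores were computed on.
#' @param scores a [variable_importance()] result.
#' @return The dataset restricted to the retained columns, order and names
#'   preserved.
#' @export
apply_selection <- function(data, scores) {
  stopifnot(inherits(data, "ranked_dataset"),
            inherits(scores, "selection_scores"))
  if (length(scores$importance) != data$p)
    stop("selection scores were computed on a different column set",
         call. = FALSE)
  if (scores$empty)
    stop("empty selection: no variable meets the threshold", call. = FALSE)
  subset_predictors(data, scores$retained)
}

#' Write an importance table as CSV
#'
#' Columns: variable, method, importance, retained.
#'
#' @param scores a [variable_importance()] result.
#' @param path output CSV path.
#' @export
write_importance <- function(scores, path) {
  df <- data.frame(variable = names(scores$importance),
                   method = scores$method,
                   importance = unname(scores$importance),
                   retained = seq_along(scores$importance) %in%
                     scores$retained)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
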