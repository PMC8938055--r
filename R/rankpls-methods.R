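#' @export
print.rankpls <- function(x, digits = max(3L, getOption("digits") - 3L), ...) {
  cat("Rank-weighted partial least squares regression\n")
  cat("  measure: ", x$measure,
      if (x$measure == "gk_tau") paste0(" (", x$gk_mode, ")"), "\n", sep = "")
  cat("  components: ", x$ncomp,
      if (x$truncated) paste0(" (truncated from ", x$ncomp_requested, ")"),
      "   n = ", x$n, "   p = ", x$p, "\n", sep = "")
  cat("  RSS: ", format(x$RSS, digits = digits),
      "   AIC: ", format(AIC(x), digits = digits), "\n", sep = "")
  invisible(x)
}

#' @export
summary.rankpls <- function(object, ...) {
  tss <- sum((object$y - object$y_mean)^2)
  expl <- numeric(object$ncomp)
  for (c in seq_len(object$ncomp)) {
    tt <- sum(object$scores[, c]^2)
    expl[c] <- object$yloadings[c]^2 * tt / tss
  }
  structure(list(fit = object,
                 r_squared = 1 - object$RSS / tss,
                 y_variance_explained = expl,
                 aic = AIC(object),
                 coef_table = data.frame(
                   variable = names(object$coefficients),
                   coefficient = unname(object$coefficients),
                   coefficient_std = unname(object$coef_std))),
            class = "summary.rankpls")
}

#' @export
print.summary.rankpls <- function(x, digits = 4L, ...) {
  print(x$fit)
  cat("  R-squared (continuous scale): ",
      format(x$r_squared, digits = digits), "\n", sep = "")
  cat("  per-component share of response variance: ",
      paste(format(x$y_variance_explained, digits = 3L), collapse = ", "),
      "\n", sep = "")
  cat("\nCoefficients:\n")
  ord <- order(-abs(x$coef_table$coefficient_std))
  print(utils::head(x$coef_table[ord, ], 10L), row.names = FALSE,
        digits = digits)
  if (nrow(x$coef_table) > 10L)
    cat("  ... (", nrow(x$coef_table) - 10L, " more)\n", sep = "")
  invisible(x)
}

#' @export
coef.rankpls <- function(object, standardized = FALSE, intercept = FALSE, ...) {
  b <- if (standardized) object$coef_std else object$coefficients
  if (intercept) c("(Intercept)" = object$intercept, b) else b
}

#' Predict from a rank-weighted PLS fit
#'
#' `type = "response"` returns the continuous prediction
#' `alpha + Z_new beta` on the original response scale; `"scores"` projects
#' new rows into the component space via `T_new = Z_c W (P'W)^{-1}` (training
#' rows reproduce the fitted scores); `"class"` classifies the projected
#' scores with a linear discriminant trained on the training scores and
#' response ranks.
#'
#' @param object a fitted [rankpls()] model.
#' @param newdata matrix (or data frame) with the same p columns as the
#'   training predictors. Defaults to returning in-sample quantities.
#' @param type `"response"`, `"scores"` or `"class"`.
#' @param ... unused.
#' @export
predict.rankpls <- function(object, newdata = NULL,
                            type = c("response", "scores", "class"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    if (type == "response") return(object$fitted.values)
    if (type == "scores") return(object$scores)
    lda <- lda_train(object$scores, object$y)
    return(lda_classify(lda, object$scores))
  }
  Z <- as.matrix(newdata)
  storage.mode(Z) <- "double"
  if (ncol(Z) != object$p)
    stop("'newdata' has ", ncol(Z), " columns; model expects ", object$p,
         call. = FALSE)
  if (type == "response")
    return(object$intercept + as.numeric(Z %*% object$coefficients))
  Zc <- sweep(sweep(Z, 2L, object$centers, "-"), 2L, object$scales, "/")
  Tn <- Zc %*% object$projection
  colnames(Tn) <- paste0("comp", seq_len(object$ncomp))
  if (type == "scores") return(Tn)
  lda <- lda_train(object$scores, object$y)
  lda_classify(lda, Tn)
}

#' @export
fitted.rankpls <- function(object, ...) object$fitted.values

#' @export
residuals.rankpls <- function(object, ...) object$residuals

#' Akaike information criterion for a PLS fit
#'
#' Gaussian least-squares form `n log(RSS / n) + k (C + 1)` with C + 1
#' effective parameters (one per component plus the intercept). A perfect
#' fit (RSS = 0) returns `-Inf` with attribute `perfect_fit = TRUE`.
#'
#' @param object a fitted [rankpls()] model.
#' @param ... unused.
#' @param k penalty per parameter (default 2).
#' @export
AIC.rankpls <- function(object, ..., k = 2) {
  if (object$RSS <= 0)
    return(structure(-Inf, perfect_fit = TRUE))
  object$n * log(object$RSS / object$n) + k * (object$ncomp + 1)
}

#' @export
plot.rankpls <- function(x, type = c("scores", "weights"),
                         comps = c(1L, 2L), ...) {
  type <- match.arg(type)
  if (type == "scores") {
    if (x$ncomp == 1L) {
      graphics::stripchart(x$scores[, 1L] ~ factor(x$level_labels[x$y]),
                           vertical = TRUE, method = "jitter", pch = 19,
                           col = grDevices::adjustcolor(seq_len(x$K), 0.6),
                           xlab = "response rank", ylab = "component 1", ...)
    } else {
      graphics::plot(x$scores[, comps[1L]], x$scores[, comps[2L]],
                     col = x$y, pch = 19,
                     xlab = paste("component", comps[1L]),
                     ylab = paste("component", comps[2L]), ...)
      graphics::legend("topright", legend = x$level_labels,
                       col = seq_len(x$K), pch = 19, bty = "n")
    }
  } else {
    graphics::barplot(x$weights[, comps[1L]],
                      names.arg = rownames(x$weights), las = 2L,
                      ylab = paste0("loading weight (component ", comps[1L],
                                    ", ", x$measure, ")"), ...)
  }
  invisible(x)
}

#' Simulate responses from a fitted PLS model
#'
#' Draws Gaussian responses around the fitted values with residual standard
#' deviation `sqrt(RSS / (n - C - 1))` — the continuous-scale noise model
#' underlying the least-squares fit.
#'
#' @param object a fitted [rankpls()] model.
#' @param nsim number of simulated response vectors.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @export
simulate.rankpls <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sdr <- sqrt(object$RSS / max(1L, object$n - object$ncomp - 1L))
  out <- as.data.frame(replicate(
    nsim, object$fitted.values + stats::rnorm(object$n, 0, sdr)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Serialize / restore a fitted model as JSON
#'
#' Writes every field of the fit to a structured text file at full double
#' precision, so that `read_rankpls(write_rankpls(fit, path))` reproduces
#' the model exactly.
#'
#' @param object a fitted [rankpls()] model.
#' @param path file path for the JSON document.
#' @export
write_rankpls <- function(object, path) {
  stopifnot(inherits(object, "rankpls"))
  x <- unclass(object)
  x$call <- deparse(x$call)
  for (nm in c("weights", "scores", "loadings", "projection")) {
    x[[nm]] <- list(data = as.numeric(x[[nm]]), nrow = nrow(x[[nm]]),
                    rownames = rownames(x[[nm]]))
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_rankpls
#' @export
read_rankpls <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("weights", "scores", "loadings", "projection")) {
    m <- matrix(x[[nm]]$data, nrow = x[[nm]]$nrow)
    rn <- x[[nm]]$rownames
    if (!is.null(rn) && length(rn) == nrow(m)) rownames(m) <- rn
    x[[nm]] <- m
  }
  x$call <- str2lang(paste(x$call, collapse = " "))
  for (nm in c("coefficients", "coef_std", "centers", "scales"))
    names(x[[nm]]) <- rownames(x$weights)
  x$ncomp <- as.integer(x$ncomp)
  x$ncomp_requested <- as.integer(x$ncomp_requested)
  x$n <- as.integer(x$n); x$p <- as.integer(x$p); x$K <- as.integer(x$K)
  structure(x, class = "rankpls")
}
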