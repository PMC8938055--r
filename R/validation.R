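#' Random 70:30 train/test split
#'
#' Uniformly random partition without replacement, training size
#' `floor(frac * n)`. By default the split is re-drawn (at most
#' `max_redraws` times) until both parts contain every response level, so
#' that discriminant analysis stays well-posed; `require_all_levels = FALSE`
#' gives plain random splits.
#'
#' @param data a [ranked_dataset()].
#' @param seed integer seed; recorded in the result.
#' @param frac training fraction (default 0.7).
#' @param require_all_levels re-draw until both parts hold all K levels.
#' @param max_redraws maximum re-draws before an error.
#' @return List with `train` and `test` (ranked datasets), `train_idx`,
#'   and `seed`.
#' @export
split_train_test <- function(data, seed, frac = 0.7,
                             require_all_levels = TRUE, max_redraws = 100L) {
  stopifnot(inherits(data, "ranked_dataset"))
  if (data$n < 10L) stop("need at least 10 observations", call. = FALSE)
  set.seed(as.integer(seed))
  n_train <- floor(frac * data$n)
  for (attempt in seq_len(max_redraws)) {
    idx <- sample.int(data$n, n_train)
    ytr <- data$y[idx]; yte <- data$y[-idx]
    ok <- !require_all_levels ||
      (length(unique(ytr)) == data$K && length(unique(yte)) == data$K)
    if (ok) {
      mk <- function(i) {
        out <- data
        out$Z <- data$Z[i, , drop = FALSE]; out$y <- data$y[i]
        out$n <- length(i)
        out
      }
      return(list(train = mk(idx), test = mk(setdiff(seq_len(data$n), idx)),
                  train_idx = sort(idx), seed = as.integer(seed)))
    }
  }
  stop("could not produce a split with all response levels in both parts",
       call. = FALSE)
}

# -- Fisher linear discriminant analysis on score matrices ------------------
# Pooled within-class covariance, proportional priors. Singular pooled
# covariance gets a small ridge (1e-6 * trace / C on the diagonal).

lda_train <- function(X, labels, ridge_factor = 1e-6) {
  X <- as.matrix(X)
  cl <- sort(unique(labels))
  K <- length(cl); n <- nrow(X); C <- ncol(X)
  if (K < 2L) stop("LDA needs at least 2 classes", call. = FALSE)
  means <- matrix(0, K, C)
  Sw <- matrix(0, C, C)
  nk <- numeric(K)
  for (k in seq_len(K)) {
    Xi <- X[labels == cl[k], , drop = FALSE]
    nk[k] <- nrow(Xi)
    means[k, ] <- colMeans(Xi)
    Xi <- sweep(Xi, 2L, means[k, ], "-")
    Sw <- Sw + crossprod(Xi)
  }
  Sw <- Sw / max(1L, n - K)
  Sinv <- tryCatch(solve(Sw), error = function(e) NULL)
  if (is.null(Sinv) || !all(is.finite(Sinv))) {
    warning("singular pooled covariance; ridge-regularized", call. = FALSE)
    Sw <- Sw + diag(ridge_factor * sum(diag(Sw)) / C + 1e-12, C)
    Sinv <- solve(Sw)
  }
  list(classes = cl, means = means, Sinv = Sinv, log_priors = log(nk / n))
}

lda_classify <- function(fit, X) {
  X <- as.matrix(X)
  A <- fit$means %*% fit$Sinv                 # K x C
  delta <- X %*% t(A)                         # n x K
  delta <- sweep(delta, 2L, 0.5 * rowSums(A * fit$means), "-")
  delta <- sweep(delta, 2L, fit$log_priors, "+")
  fit$classes[max.col(delta, ties.method = "first")]
}

#' Leave-one-out cross-validated LDA accuracy
#'
#' For each observation in turn, fits a Fisher linear discriminant (pooled
#' within-class covariance, proportional priors) on the remaining rows of
#' the score matrix and classifies the held-out row; returns the fraction
#' classified correctly.
#'
#' @param scores n x C numeric score matrix.
#' @param labels n-vector of response ranks (at least 2 classes, each with
#'   at least 2 members).
#' @return Accuracy in `[0, 1]`.
#' @export
loocv_lda_accuracy <- function(scores, labels) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (n != length(labels)) stop("dimension mismatch", call. = FALSE)
  tab <- table(labels)
  if (length(tab) < 2L || any(tab < 2L))
    stop("need at least 2 classes with at least 2 members each",
         call. = FALSE)
  correct <- 0L
  for (i in seq_len(n)) {
    fit <- suppressWarnings(lda_train(scores[-i, , drop = FALSE], labels[-i]))
    pred <- lda_classify(fit, scores[i, , drop = FALSE])
    if (pred == labels[i]) correct <- correct + 1L
  }
  correct / n
}

# Deterministic per-cell child seed: a polynomial string hash folded into
# the master seed, mod 2^31 - 1, so adding a grid cell never perturbs the
# seeds of the others.
child_seed <- function(master, key) {
  h <- as.double(master) %% 2147483647
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h %% 2147483646) + 1L
}

#' Monte-Carlo 70:30 validation of one model pipeline
#'
#' Repeats `iterations` times: split the data 70:30; fit the PLS variant on
#' the training part; if a selection method is given, apply its retention
#' cut and refit on the retained variables; project the test rows into the
#' component space of the final fit; classify the projected test scores with
#' an LDA trained on the training scores; record the test accuracy. The
#' leave-one-out LDA accuracy on the training scores and the training AIC
#' are recorded alongside. Iterations whose fit fails are marked and
#' excluded from the means.
#'
#' @param data a [ranked_dataset()].
#' @param measure loading-weight variant, one of [MEASURES].
#' @param selection `"none"`, `"lw"`, `"rc"` or `"smc"`.
#' @param ncomp number of PLS components per fit.
#' @param iterations number of Monte-Carlo repetitions (default 10).
#' @param seed master seed; each iteration derives its own child seed.
#' @param compute_loocv also compute LOOCV-LDA on the training scores.
#' @param ... further arguments passed to [rankpls()] (e.g. `gk_mode`,
#'   `scale`) and selection thresholds via `threshold`/`top_k`.
#' @return List (one grid-cell row): per-iteration `accuracy`, `loocv`,
#'   `aic`, `n_retained`, their means, and a `failed` count.
#' @export
monte_carlo_evaluate <- function(data, measure, selection = "none",
                                 ncomp = 5L, iterations = 10L, seed = 1L,
                                 compute_loocv = TRUE, threshold = NULL,
                                 top_k = NULL, ...) {
  stopifnot(inherits(data, "ranked_dataset"))
  selection <- match.arg(selection, c("none", "lw", "rc", "smc"))
  measure <- match.arg(measure, MEASURES)
  acc <- loo <- aicv <- nret <- rep(NA_real_, iterations)
  for (it in seq_len(iterations)) {
    s <- child_seed(seed, paste(measure, selection, it, sep = "|"))
    res <- tryCatch({
      sp <- split_train_test(data, seed = s)
      nc <- min(ncomp, sp$train$p, sp$train$n - 1L)
      fit <- suppressMessages(suppressWarnings(
        rankpls(sp$train, measure = measure, ncomp = nc, ...)))
      train <- sp$train
      if (selection != "none") {
        sc <- variable_importance(fit, selection, data = sp$train,
                                  threshold = threshold, top_k = top_k)
        train <- apply_selection(sp$train, sc)
        nc <- min(ncomp, train$p, train$n - 1L)
        fit <- suppressMessages(suppressWarnings(
          rankpls(train, measure = measure, ncomp = nc, ...)))
      }
      Zte <- sp$test$Z[, colnames(train$Z), drop = FALSE]
      te_scores <- predict(fit, Zte, type = "scores")
      lda <- suppressWarnings(lda_train(fit$scores, train$y))
      pred <- lda_classify(lda, te_scores)
      list(acc = mean(pred == sp$test$y),
           loo = if (compute_loocv)
             suppressWarnings(loocv_lda_accuracy(fit$scores, train$y))
           else NA_real_,
           aic = as.numeric(AIC(fit)),
           nret = train$p)
    }, error = function(e) NULL)
    if (!is.null(res)) {
      acc[it] <- res$acc; loo[it] <- res$loo
      aicv[it] <- res$aic; nret[it] <- res$nret
    }
  }
  ok <- !is.na(acc)
  list(measure = measure, selection = selection, ncomp = ncomp,
       seed = as.integer(seed), iterations = iterations,
       accuracy = acc, loocv = loo, aic = aicv, n_retained = nret,
       mean_accuracy = if (any(ok)) mean(acc[ok]) else NA_real_,
       mean_loocv = if (any(ok) && compute_loocv) mean(loo[ok]) else NA_real_,
       mean_aic = if (any(ok)) mean(aicv[ok]) else NA_real_,
       mean_retained = if (any(ok)) mean(nret[ok]) else NA_real_,
       failed = sum(!ok))
}

#' Evaluate the full measure-by-selection grid
#'
#' Runs [monte_carlo_evaluate()] for every combination of loading-weight
#' variant and selection method (default: all nine measures by
#' none/LW/RC/SMC, 36 cells; the three paper-style selection methods alone
#' give 27). All cells share one master seed from which each cell and
#' iteration derives its own child seed, so the grid is reproducible and
#' cells do not interact. The winner is the cell with the highest mean test
#' accuracy, ties broken by fewer retained variables, then lower mean AIC.
#'
#' @param data a [ranked_dataset()].
#' @param measures character vector of weight variants (default all nine).
#' @param selections character vector from `"none"`, `"lw"`, `"rc"`,
#'   `"smc"`.
#' @param ncomp components per fit.
#' @param iterations Monte-Carlo repetitions per cell.
#' @param seed master seed.
#' @param ... passed to [monte_carlo_evaluate()].
#' @return An object of class `"validation_report"`: list with `cells`
#'   (summary data frame), `details` (per-iteration long data frame),
#'   `winner`, `seed`.
#' @export
run_grid <- function(data, measures = MEASURES,
                     selections = c("none", "lw", "rc", "smc"),
                     ncomp = 5L, iterations = 10L, seed = 1L, ...) {
  measures <- match.arg(measures, MEASURES, several.ok = TRUE)
  selections <- match.arg(selections, c("none", "lw", "rc", "smc"),
                          several.ok = TRUE)
  rows <- list()
  details <- list()
  for (m in measures) for (s in selections) {
    cell <- monte_carlo_evaluate(data, m, s, ncomp = ncomp,
                                 iterations = iterations, seed = seed, ...)
    rows[[paste(m, s)]] <- data.frame(
      measure = m, selection = s,
      mean_accuracy = cell$mean_accuracy, mean_loocv = cell$mean_loocv,
      mean_aic = cell$mean_aic, mean_retained = cell$mean_retained,
      failed = cell$failed)
    details[[paste(m, s)]] <- data.frame(
      measure = m, selection = s, iteration = seq_len(iterations),
      accuracy = cell$accuracy, loocv = cell$loocv, aic = cell$aic,
      n_retained = cell$n_retained)
  }
  cells <- do.call(rbind, c(rows, make.row.names = FALSE))
  details <- do.call(rbind, c(details, make.row.names = FALSE))
  ok <- which(!is.na(cells$mean_accuracy))
  winner <- NULL
  if (length(ok)) {
    o <- ok[order(-cells$mean_accuracy[ok], cells$mean_retained[ok],
                  cells$mean_aic[ok])]
    winner <- cells[o[1L], , drop = FALSE]
  }
  structure(list(cells = cells, details = details, winner = winner,
                 seed = as.integer(seed), ncomp = ncomp,
                 iterations = iterations),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Monte-Carlo validation grid: ", nrow(x$cells), " cells, ",
      x$iterations, " iterations each (master seed ", x$seed, ")\n",
      sep = "")
  df <- x$cells[order(-x$cells$mean_accuracy), ]
  print(utils::head(df, 10L), row.names = FALSE, digits = 4L)
  if (!is.null(x$winner))
    cat("winner: ", x$winner$measure, " + ", x$winner$selection,
        " (mean accuracy ", format(x$winner$mean_accuracy, digits = 4L),
        ")\n", sep = "")
  invisible(x)
}

#' @export
plot.validation_report <- function(x, metric = c("accuracy", "aic"), ...) {
  metric <- match.arg(metric)
  val <- if (metric == "accuracy") x$cells$mean_accuracy else x$cells$mean_aic
  lab <- paste(x$cells$measure, x$cells$selection, sep = "+")
  o <- order(val, decreasing = (metric == "accuracy"))
  graphics::par(mar = c(8, 4, 2, 1))
  graphics::barplot(val[o], names.arg = lab[o], las = 2L,
                    ylab = paste("mean", metric), cex.names = 0.7, ...)
  invisible(x)
}

#' Write a validation report to disk
#'
#' Writes `report.csv` (one row per cell per iteration plus summary rows)
#' and `summary.json` under `dir`.
#'
#' @param report a [run_grid()] result.
#' @param dir output directory (created if missing).
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "validation_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  det <- report$details
  det$row_type <- "iteration"
  summ <- data.frame(measure = report$cells$measure,
                     selection = report$cells$selection,
                     iteration = NA_integer_,
                     accuracy = report$cells$mean_accuracy,
                     loocv = report$cells$mean_loocv,
                     aic = report$cells$mean_aic,
                     n_retained = report$cells$mean_retained,
                     row_type = "summary")
  utils::write.csv(rbind(det, summ), file.path(dir, "report.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(seed = report$seed, ncomp = report$ncomp,
         iterations = report$iterations,
         cells = report$cells, winner = report$winner),
    file.path(dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows", na = "null")
  invisible(dir)
}
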