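#' Simulation-study conditions: ranked data that separates the variants
#'
#' A preset of [simulate_ranked_data()] holding the conditions of the
#' package's simulation study: n = 1000 observations, p = 100 ordinal
#' predictors (the first 50 on 3 levels, the rest on 4), a 3-rank response
#' with the skewed 12/36/52 marginal typical of care-utilization outcomes,
#' and a planted signal in the first 10 predictors.
#'
#' Marginals are deliberately heterogeneous, as in survey data: the signal
#' predictors have near-balanced level frequencies, the remaining 3-level
#' columns are skewed (60/30/10), and the 4-level noise columns concentrate
#' mass on their extreme levels (40/10/10/40). This heterogeneity is what
#' gives the rank-weighted PLS variants their edge over covariance loading
#' weights: on unstandardized ordinal codes a covariance weight conflates a
#' column's marginal spread with its relevance, while every rank-association
#' weight is invariant to the coding scale. Under equal-probability
#' marginals (the [simulate_ranked_data()] default) the covariance and
#' correlation weights coincide up to a constant and standard PLS is not at
#' a disadvantage.
#'
#' @param seed RNG seed.
#' @param n,p,n_informative,effect_size,noise_sd,block_corr see
#'   [simulate_ranked_data()].
#' @return A [ranked_dataset()] with a `"truth"` attribute.
#' @seealso [compare_weight_variants()] for the AIC comparison run on these
#'   conditions.
#' @export
simulation_study_data <- function(seed = 1L, n = 1000L, p = 100L,
                                  n_informative = 10L, effect_size = 0.5,
                                  noise_sd = 2, block_corr = 0.5) {
  p3 <- ceiling(p / 2); p4 <- floor(p / 2)
  stopifnot(n_informative <= p3)
  lp <- c(rep(list(rep(1 / 3, 3)), n_informative),
          rep(list(c(0.6, 0.3, 0.1)), p3 - n_informative),
          rep(list(c(0.4, 0.1, 0.1, 0.4)), p4))
  simulate_ranked_data(
    n = n, p = p,
    levels_per_predictor = c(rep(3L, p3), rep(4L, p4)),
    response_levels = 3L,
    n_informative = n_informative,
    effect_size = effect_size,
    block_corr = block_corr,
    noise_sd = noise_sd,
    level_probs = lp,
    response_probs = c(0.12, 0.36, 0.52),
    seed = seed)
}

#' Compare loading-weight variants by AIC over replicated simulations
#'
#' Draws `replicates` datasets from a generator (default:
#' [simulation_study_data()]), fits every requested weight variant to each,
#' and records the least-squares AIC. The comparison uses a single
#' component and centering only (no unit-variance scaling): the algorithm
#' exactly as written, which isolates the loading-weight definition —
#' with more components, deflation progressively washes out the difference
#' between weight choices, and scaling turns the covariance weight into the
#' Pearson correlation, a different estimator from the one under study.
#'
#' @param replicates number of simulated datasets.
#' @param seed base seed; replicate r uses `seed + r - 1`.
#' @param measures weight variants to fit (default all nine).
#' @param ncomp components per fit (default 1, see Details).
#' @param scale passed to [rankpls()] (default `FALSE`, see Details).
#' @param generator function(seed, ...) returning a [ranked_dataset()].
#' @param ... passed on to `generator`.
#' @return An object of class `"aic_comparison"`: list with `aic`
#'   (replicates x measures matrix), `wins` (for each non-standard
#'   variant, the number of replicates with AIC below standard PLS),
#'   `mean_aic`, `replicates`.
#' @examples
#' \donttest{
#' cmp <- compare_weight_variants(replicates = 3, seed = 1)
#' cmp$wins
#' }
#' @export
compare_weight_variants <- function(replicates = 10L, seed = 1L,
                                    measures = MEASURES, ncomp = 1L,
                                    scale = FALSE,
                                    generator = simulation_study_data,
                                    ...) {
  measures <- match.arg(measures, MEASURES, several.ok = TRUE)
  aic <- matrix(NA_real_, replicates, length(measures),
                dimnames = list(NULL, measures))
  for (r in seq_len(replicates)) {
    d <- generator(seed = seed + r - 1L, ...)
    for (m in measures) {
      fit <- suppressMessages(suppressWarnings(
        rankpls(d, measure = m, ncomp = ncomp, scale = scale)))
      aic[r, m] <- as.numeric(AIC(fit))
    }
  }
  wins <- NULL
  if ("standard" %in% measures && length(measures) > 1L) {
    others <- setdiff(measures, "standard")
    wins <- colSums(aic[, others, drop = FALSE] <
                      aic[, "standard"])
  }
  structure(list(aic = aic, wins = wins, mean_aic = colMeans(aic),
                 replicates = replicates, ncomp = ncomp, seed = seed),
            class = "aic_comparison")
}

#' @export
print.aic_comparison <- function(x, ...) {
  cat("AIC comparison over", x$replicates, "replicated simulations",
      "(ncomp =", x$ncomp, ")\n")
  print(round(sort(x$mean_aic), 2))
  if (!is.null(x$wins)) {
    cat("replicates with AIC below standard PLS:\n")
    print(x$wins)
  }
  invisible(x)
}
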