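#' Simulate a ranked dataset with multicollinear ordinal predictors
#'
#' Latent-Gaussian generator of ordinal data: p standard-normal latent
#' predictors with block-exchangeable correlation (`block_corr` within each
#' block, 0 between blocks) are each discretized into its assigned number
#' of levels by equal-probability thresholds (or by `level_probs` for
#' skewed marginals). The latent response is
#' `effect_size * rowSums(latent informative columns) + N(0, noise_sd)`,
#' discretized into K ranks by its empirical quantiles (equal rank
#' frequencies) or by `response_probs`.
#'
#' The defaults reproduce a common simulation design for ranked-response
#' regression: n = 1000 observations, p = 100 predictors of which the first
#' 50 take 3 levels and the rest 4 levels, a 3-level response, the first
#' `n_informative = 10` predictors carrying the signal.
#'
#' @param n sample size.
#' @param p number of predictors.
#' @param levels_per_predictor integer vector of length p: levels per
#'   column (default: 3 for the first half, 4 for the second).
#' @param response_levels number of response ranks K.
#' @param n_informative number of signal predictors (the first
#'   `n_informative` columns); default 10, capped at p.
#' @param effect_size latent coefficient of each informative predictor.
#' @param block_corr within-block latent correlation; scalar or one value
#'   per block.
#' @param block_sizes sizes of the correlated blocks (must sum to p;
#'   default: blocks of 10).
#' @param noise_sd standard deviation of the latent response noise.
#' @param level_probs optional list of per-column level probabilities for
#'   skewed predictor marginals (recycled; `NULL` = equal probabilities).
#' @param response_probs optional K rank probabilities for a skewed
#'   response (e.g. `c(0.12, 0.36, 0.52)`); `NULL` = equal.
#' @param level_labels optional response rank labels.
#' @param seed RNG seed.
#' @return A [ranked_dataset()] with attribute `"truth"`: list holding
#'   `informative` (column indices), `effect_size`, `block_sizes`,
#'   `block_corr`, `noise_sd`, `seed` — the ground truth for recovery
#'   studies.
#' @examples
#' d <- simulate_ranked_data(n = 200, p = 12, n_informative = 3, seed = 42)
#' attr(d, "truth")$informative
#' @export
simulate_ranked_data <- function(n = 1000L, p = 100L,
                                 levels_per_predictor = NULL,
                                 response_levels = 3L,
                                 n_informative = min(10L, p),
                                 effect_size = 0.5,
                                 block_corr = 0.5,
                                 block_sizes = NULL,
                                 noise_sd = 2,
                                 level_probs = NULL,
                                 response_probs = NULL,
                                 level_labels = NULL,
                                 seed = 1L) {
  if (is.null(levels_per_predictor))
    levels_per_predictor <- c(rep(3L, ceiling(p / 2)),
                              rep(4L, floor(p / 2)))
  if (length(levels_per_predictor) != p)
    stop("'levels_per_predictor' must have length p", call. = FALSE)
  if (any(levels_per_predictor < 2L))
    stop("every predictor needs at least 2 levels", call. = FALSE)
  if (is.null(block_sizes)) {
    bs <- min(10L, p)
    block_sizes <- c(rep(bs, p %/% bs), if (p %% bs) p %% bs)
  }
  if (sum(block_sizes) != p)
    stop("'block_sizes' must sum to p", call. = FALSE)
  block_corr <- rep_len(block_corr, length(block_sizes))
  if (any(block_corr < 0 | block_corr >= 1))
    stop("'block_corr' must lie in [0, 1)", call. = FALSE)
  if (n_informative > p)
    stop("'n_informative' cannot exceed p", call. = FALSE)
  if (response_levels < 2L) stop("need K >= 2 response ranks", call. = FALSE)

  set.seed(as.integer(seed))
  # block-exchangeable latent Gaussians: sqrt(rho) shared + sqrt(1-rho) own
  L <- matrix(0, n, p)
  col0 <- 0L
  for (b in seq_along(block_sizes)) {
    sz <- block_sizes[b]; rho <- block_corr[b]
    g <- stats::rnorm(n)
    E <- matrix(stats::rnorm(n * sz), n, sz)
    L[, col0 + seq_len(sz)] <- sqrt(rho) * g + sqrt(1 - rho) * E
    col0 <- col0 + sz
  }

  Z <- matrix(0L, n, p)
  for (j in seq_len(p)) {
    lv <- levels_per_predictor[j]
    probs <- if (is.null(level_probs)) rep(1 / lv, lv)
             else rep_len(level_probs, p)[[j]]
    if (length(probs) != lv || abs(sum(probs) - 1) > 1e-8)
      stop("level probabilities of column ", j, " are invalid",
           call. = FALSE)
    cuts <- stats::qnorm(cumsum(probs)[-lv])
    Z[, j] <- findInterval(L[, j], cuts) + 1L
  }
  colnames(Z) <- paste0("z", seq_len(p))

  informative <- seq_len(n_informative)
  eta <- if (n_informative > 0L)
    effect_size * rowSums(L[, informative, drop = FALSE]) +
      stats::rnorm(n, 0, noise_sd)
  else stats::rnorm(n, 0, noise_sd)
  K <- response_levels
  rp <- if (is.null(response_probs)) rep(1 / K, K) else response_probs
  if (length(rp) != K || abs(sum(rp) - 1) > 1e-8)
    stop("'response_probs' must be K probabilities summing to 1",
         call. = FALSE)
  ycuts <- stats::quantile(eta, probs = cumsum(rp)[-K], names = FALSE)
  y <- findInterval(eta, ycuts) + 1L

  if (length(unique(y)) < 2L)
    stop("degenerate response draw; change the seed or noise level",
         call. = FALSE)
  d <- ranked_dataset(Z, y, level_labels = level_labels, quiet = TRUE)
  attr(d, "truth") <- list(informative = informative,
                           effect_size = effect_size,
                           block_sizes = block_sizes,
                           block_corr = block_corr,
                           noise_sd = noise_sd,
                           seed = as.integer(seed))
  d
}

#' Simulate an antenatal-care-style ranked dataset
#'
#' A synthetic stand-in for a demographic-survey extract on antenatal care
#' (ANC) visits: n = 943 women, p = 43 ordinal factors with 2 to 5 levels,
#' one strongly inter-correlated block of 16 covariates (latent correlation
#' 0.8) plus weaker blocks, and a 3-rank response labeled
#' inadequate/intermediate/adequate with a skewed marginal. Entirely
#' simulated — no survey microdata is included or required.
#'
#' @param seed RNG seed.
#' @param n,p sample size and predictor count.
#' @return A [ranked_dataset()] with a `"truth"` attribute as in
#'   [simulate_ranked_data()].
#' @export
simulate_anc_data <- function(seed = 1L, n = 943L, p = 43L) {
  block_sizes <- c(16L, 9L, 9L, 9L)
  if (sum(block_sizes) != p) {
    block_sizes <- c(16L, rep(9L, (p - 16L) %/% 9L),
                     if ((p - 16L) %% 9L) (p - 16L) %% 9L)
  }
  levels <- rep_len(c(3L, 2L, 4L, 5L, 3L, 2L, 4L, 3L, 5L, 2L), p)
  simulate_ranked_data(
    n = n, p = p,
    levels_per_predictor = levels,
    response_levels = 3L,
    n_informative = 8L,
    effect_size = 0.5,
    block_corr = c(0.8, 0.3, 0.3, rep(0.1, length(block_sizes) - 3L)),
    block_sizes = block_sizes,
    noise_sd = 2,
    response_probs = c(0.12, 0.36, 0.52),
    level_labels = c("inadequate", "intermediate", "adequate"),
    seed = seed)
}

#' Write / read a ranked dataset as CSV
#'
#' The CSV has a header row, the predictor columns, and the response in a
#' column named `y` (integer rank codes). `read_ranked()` drops rows with
#' missing cells (with a message) and errors on a missing response column
#' or non-numeric cells, naming the offending column.
#'
#' @param data a [ranked_dataset()].
#' @param path CSV file path.
#' @param response name of the response column (default `"y"`).
#' @return `write_ranked()` returns `path` invisibly; `read_ranked()`
#'   returns a [ranked_dataset()].
#' @export
write_ranked <- function(data, path, response = "y") {
  stopifnot(inherits(data, "ranked_dataset"))
  df <- as.data.frame(data$Z)
  df[[response]] <- data$y
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ranked
#' @param level_labels optional response rank labels for the read dataset.
#' @export
read_ranked <- function(path, response = "y", level_labels = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!response %in% names(df))
    stop("response column '", response, "' not found in ", path,
         call. = FALSE)
  for (nm in names(df)) {
    if (!is.numeric(df[[nm]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[nm]]))) &
                     !is.na(df[[nm]]))
      stop("non-numeric cells in column '", nm, "'",
           if (length(bad)) paste0(" (first at row ", bad[1L], ")"),
           call. = FALSE)
    }
  }
  y <- df[[response]]
  Z <- as.matrix(df[setdiff(names(df), response)])
  ranked_dataset(Z, y, level_labels = level_labels)
}
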