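#' Configuration for a full validation run
#'
#' Bundles everything [run_pipeline()] needs; fully serializable, and a
#' copy is always written next to the run's outputs.
#'
#' @param input path to a CSV dataset (see [read_ranked()]), or `NULL` to
#'   simulate.
#' @param simulation named list of arguments for [simulate_ranked_data()]
#'   (used when `input` is `NULL`); `list(anc = TRUE)` selects
#'   [simulate_anc_data()].
#' @param measures weight variants to evaluate.
#' @param selections selection methods to evaluate.
#' @param ncomp fixed component count, or `"cv"` to choose by Monte-Carlo
#'   accuracy over 1..15 with the first measure/selection cell.
#' @param iterations Monte-Carlo repetitions per cell.
#' @param seed master seed.
#' @param gk_mode Goodman-Kruskal tau mode.
#' @param scale unit-variance scaling of predictors.
#' @return A `"run_config"` list.
#' @export
run_config <- function(input = NULL, simulation = list(),
                       measures = MEASURES,
                       selections = c("none", "lw", "rc", "smc"),
                       ncomp = 5L, iterations = 10L, seed = 1L,
                       gk_mode = "printed", scale = TRUE) {
  structure(list(input = input, simulation = simulation,
                 measures = measures, selections = selections,
                 ncomp = ncomp, iterations = iterations,
                 seed = as.integer(seed), gk_mode = gk_mode,
                 scale = scale),
            class = "run_config")
}

#' Choose the component count by Monte-Carlo validation accuracy
#'
#' Evaluates C = 1..`cmax` with [monte_carlo_evaluate()] (no selection) and
#' returns the C with the highest mean test accuracy, ties to the smaller C.
#'
#' @param data a [ranked_dataset()].
#' @param measure weight variant used for the search.
#' @param cmax largest C tried (default `min(p, 15)`).
#' @param iterations,seed,... passed to [monte_carlo_evaluate()].
#' @export
choose_ncomp <- function(data, measure = "standard",
                         cmax = min(data$p, 15L), iterations = 10L,
                         seed = 1L, ...) {
  accs <- vapply(seq_len(cmax), function(C) {
    monte_carlo_evaluate(data, measure, "none", ncomp = C,
                         iterations = iterations, seed = seed,
                         compute_loocv = FALSE, ...)$mean_accuracy
  }, numeric(1L))
  which.max(accs)
}

#' Run the full workflow: data, grid, selection, winner
#'
#' Loads or simulates the dataset, evaluates the measure-by-selection grid,
#' refits the winning pipeline on the full data, and writes a
#' self-documenting run directory: `report.csv`, `summary.json`,
#' `importance_<method>.csv` for each requested selection method,
#' `model_winner.json`, `coefficients_winner.csv`, `config.json` and
#' `run.log`.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created).
#' @return Invisibly, a list with the report, the winning model and the
#'   output paths; `status` is 0 when every grid cell completed.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "run.log")
  logline <- function(...) cat(..., "\n", sep = "", file = logf,
                               append = TRUE)
  cat("", file = logf)
  logline("master seed: ", config$seed)

  data <- if (!is.null(config$input)) {
    logline("input: ", config$input)
    read_ranked(config$input)
  } else if (isTRUE(config$simulation$anc)) {
    logline("input: simulated ANC-like dataset")
    do.call(simulate_anc_data,
            c(list(seed = config$seed),
              config$simulation[setdiff(names(config$simulation), "anc")]))
  } else {
    logline("input: simulated dataset")
    do.call(simulate_ranked_data,
            c(config$simulation,
              if (!"seed" %in% names(config$simulation))
                list(seed = config$seed)))
  }
  logline("data: n = ", data$n, ", p = ", data$p, ", K = ", data$K)

  ncomp <- config$ncomp
  if (identical(ncomp, "cv")) {
    ncomp <- choose_ncomp(data, config$measures[1L],
                          iterations = config$iterations,
                          seed = config$seed, scale = config$scale)
    logline("ncomp chosen by Monte-Carlo accuracy: ", ncomp)
  }
  ncomp <- as.integer(ncomp)

  report <- run_grid(data, measures = config$measures,
                     selections = config$selections, ncomp = ncomp,
                     iterations = config$iterations, seed = config$seed,
                     gk_mode = config$gk_mode, scale = config$scale)
  write_report(report, out_dir)
  failed_cells <- report$cells[report$cells$failed > 0, , drop = FALSE]
  if (nrow(failed_cells))
    logline("cells with failed iterations: ",
            paste(failed_cells$measure, failed_cells$selection,
                  collapse = "; "))

  win <- report$winner
  status <- 1L
  model <- NULL
  if (!is.null(win)) {
    logline("winner: ", win$measure, " + ", win$selection)
    model <- suppressMessages(suppressWarnings(
      rankpls(data, measure = win$measure, ncomp = min(ncomp, data$p),
              gk_mode = config$gk_mode, scale = config$scale)))
    fitdat <- data
    for (sel in setdiff(config$selections, "none")) {
      sc <- variable_importance(model, sel, data = data)
      write_importance(sc, file.path(out_dir,
                                     paste0("importance_", sel, ".csv")))
      logline("selection ", sel, ": ", length(sc$retained), " of ",
              data$p, " variables retained")
    }
    if (win$selection != "none") {
      sc <- variable_importance(model, win$selection, data = data)
      fitdat <- apply_selection(data, sc)
      model <- suppressMessages(suppressWarnings(
        rankpls(fitdat, measure = win$measure,
                ncomp = min(ncomp, fitdat$p),
                gk_mode = config$gk_mode, scale = config$scale)))
    }
    write_rankpls(model, file.path(out_dir, "model_winner.json"))
    utils::write.csv(
      data.frame(factor = names(coef(model)),
                 coefficient = unname(coef(model))),
      file.path(out_dir, "coefficients_winner.csv"), row.names = FALSE)
    if (model$truncated) logline("winner fit truncated at ", model$ncomp,
                                 " components")
    status <- if (sum(report$cells$failed) == 0) 0L else 1L
  } else {
    logline("no grid cell completed; no winner")
  }
  jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  logline("status: ", status)
  invisible(list(status = status, report = report, model = model,
                 out_dir = out_dir))
}
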