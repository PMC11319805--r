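#' Pipeline configuration
#'
#' Validated bundle of everything one end-to-end analysis needs: data source
#' (built-in generator or an external dataset directory), model subset,
#' sampler settings, stacking threshold, output directory and the master
#' seed from which every stage derives its own stream. `paper_settings =
#' TRUE` restores the full sampler budget (4 chains, 2000 iterations, 1000
#' warmup); the default is a desk-scale half budget.
#'
#' @param out_dir output directory (`NULL` to skip writing files).
#' @param seed master seed.
#' @param responses responses to analyse.
#' @param model_ids subset of 1..21.
#' @param chains,iter,warmup sampler settings.
#' @param stack_threshold re-stack retention threshold (default 0.001; the
#'   "non-zero weight" reading corresponds to a tiny positive value).
#' @param data_path optional external dataset directory (from
#'   [write_dataset()]); when `NULL` a synthetic dataset is generated.
#' @param n_individuals,n_days,focals_per_day,grid_n synthetic-data sizes.
#' @param true_frequency,true_duration generative configs for the two
#'   responses (defaults: [default_true_config()]).
#' @param paper_settings use the full sampler budget.
#' @return list of class `look_config`.
#' @export
pipeline_config <- function(out_dir = NULL, seed = 1L,
                            responses = c("frequency", "duration"),
                            model_ids = 1:21,
                            chains = 2, iter = 1000, warmup = 500,
                            stack_threshold = 0.001,
                            data_path = NULL,
                            n_individuals = 65L, n_days = 78L,
                            focals_per_day = 0.725, grid_n = 24L,
                            true_frequency = NULL, true_duration = NULL,
                            paper_settings = FALSE) {
  responses <- match.arg(responses, several.ok = TRUE)
  if (paper_settings) { chains <- 4; iter <- 2000; warmup <- 1000 }
  stopifnot(all(model_ids %in% 1:21), chains >= 1, iter > warmup,
            stack_threshold > 0, stack_threshold < 1)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 responses = responses, model_ids = sort(unique(model_ids)),
                 chains = chains, iter = iter, warmup = warmup,
                 stack_threshold = stack_threshold, data_path = data_path,
                 n_individuals = as.integer(n_individuals),
                 n_days = as.integer(n_days),
                 focals_per_day = focals_per_day, grid_n = as.integer(grid_n),
                 true_frequency = true_frequency,
                 true_duration = true_duration),
            class = "look_config")
}

#' Run the full looking-analysis pipeline
#'
#' Simulate (or ingest) -> derive predictors -> fit the model subset for
#' each response -> PSIS-LOO -> stack -> re-stack -> LOO R-squared ->
#' report. A model whose fit fails is recorded and excluded from the stack
#' with a warning rather than aborting the run. Identical configuration and
#' seed give identical reports.
#'
#' @param config a [pipeline_config()].
#' @return object of class `look_report`: per response a results table,
#'   the stack, the LOO objects, plus the analysis table and provenance.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "look_config"))

  if (is.null(config$data_path)) {
    roster <- simulate_roster(config$n_individuals, seed = config$seed)
    landscape <- simulate_landscape(config$grid_n, seed = config$seed)
    base_cfg <- look_true_config(n_individuals = config$n_individuals,
                                 n_days = config$n_days,
                                 focals_per_day = config$focals_per_day,
                                 seed = config$seed)
    focals <- simulate_focals(roster, landscape, base_cfg)
    agon <- simulate_agonistic_matrix(roster, seed = config$seed)
    groom <- simulate_grooming(roster, seed = config$seed)
    table <- derive_analysis_table(focals, roster, agon, groom, landscape)
    truths <- list(
      frequency = config$true_frequency %||%
        default_true_config("frequency", n_individuals = config$n_individuals,
                            n_days = config$n_days,
                            focals_per_day = config$focals_per_day,
                            seed = config$seed),
      duration = config$true_duration %||%
        default_true_config("duration", n_individuals = config$n_individuals,
                            n_days = config$n_days,
                            focals_per_day = config$focals_per_day,
                            seed = derive_seed(config$seed, 9L)))
    for (resp in config$responses) {
      tc <- truths[[resp]]
      spec <- look_model_set(resp)[[tc$model_id]]
      table <- generate_looking(table, spec, tc)
    }
  } else {
    ds <- read_dataset(config$data_path)
    table <- derive_analysis_table(ds$focals, ds$roster, ds$agonistic,
                                   ds$grooming, ds$layers)
  }

  results <- list()
  for (resp in config$responses) {
    models <- look_model_set(resp)[config$model_ids]
    fits <- list(); loos <- list(); r2s <- list(); failed <- integer(0)
    for (m in models) {
      key <- as.character(m$model_id)
      res <- tryCatch({
        f <- fit_looking(m, table, chains = config$chains,
                         iter = config$iter, warmup = config$warmup,
                         seed = derive_seed(config$seed,
                                            1000L + m$model_id +
                                              100L * (resp == "duration")))
        list(fit = f, loo = psis_loo(f), r2 = loo_r2(f))
      }, error = function(e) {
        warning(sprintf("model %d (%s) failed and is excluded: %s",
                        m$model_id, resp, conditionMessage(e)))
        NULL
      })
      if (is.null(res)) { failed <- c(failed, m$model_id); next }
      fits[[key]] <- res$fit; loos[[key]] <- res$loo; r2s[[key]] <- res$r2
    }
    if (!length(loos)) stop(sprintf("run_pipeline: no %s model fitted", resp))
    E <- elpd_matrix(loos)
    colnames(E) <- names(loos)
    stack <- stacking_weights(E, threshold = config$stack_threshold)
    stack <- restack(stack, E)
    fitted_ids <- as.integer(names(loos))
    tab <- data.frame(
      model = fitted_ids,
      label = vapply(models[match(fitted_ids, vapply(models, `[[`, 0L,
                                                     "model_id"))],
                     `[[`, "", "label"),
      weight = as.numeric(stack$weights),
      shared_weight = as.numeric(stack$restacked_weights),
      marginal_r2 = vapply(r2s, function(r) r$estimate[r$variant == "marginal"], 0),
      marginal_low = vapply(r2s, function(r) r$low[r$variant == "marginal"], 0),
      marginal_high = vapply(r2s, function(r) r$high[r$variant == "marginal"], 0),
      conditional_r2 = vapply(r2s, function(r) r$estimate[r$variant == "conditional"], 0),
      conditional_low = vapply(r2s, function(r) r$low[r$variant == "conditional"], 0),
      conditional_high = vapply(r2s, function(r) r$high[r$variant == "conditional"], 0),
      max_pareto_k = vapply(loos, function(l) max(l$pareto_k, na.rm = TRUE), 0),
      row.names = NULL)
    results[[resp]] <- list(table = tab, stack = stack, loos = loos,
                            fits = fits, failed = failed)
  }

  report <- structure(list(results = results, config = config,
                           analysis_table = table),
                      class = "look_report")
  if (!is.null(config$out_dir)) render_report(report, config$out_dir)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Render a pipeline report to files
#'
#' Writes, per response, a stacking/R-squared table as CSV and markdown
#' (identical numbers: weights to 3 decimals, R-squared as
#' "estimate (low, high)", an `accurate` flag for weights of at least 0.1),
#' plus the provenance block (configuration and seed) as JSON.
#'
#' @param report a [run_pipeline()] result.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
render_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (resp in names(report$results)) {
    tab <- report$results[[resp]]$table
    fmt <- data.frame(
      model = tab$model, label = tab$label,
      weight = sprintf("%.3f", tab$weight),
      shared_weight = sprintf("%.3f", tab$shared_weight),
      marginal_r2 = sprintf("%.3f (%.3f, %.3f)", tab$marginal_r2,
                            tab$marginal_low, tab$marginal_high),
      conditional_r2 = sprintf("%.3f (%.3f, %.3f)", tab$conditional_r2,
                               tab$conditional_low, tab$conditional_high),
      accurate = tab$weight >= 0.1)
    csv <- file.path(dir, sprintf("stack_%s.csv", resp))
    utils::write.csv(fmt, csv, row.names = FALSE)
    md <- file.path(dir, sprintf("stack_%s.md", resp))
    writeLines(c(
      sprintf("| %s |", paste(names(fmt), collapse = " | ")),
      sprintf("|%s|", paste(rep("---", ncol(fmt)), collapse = "|")),
      apply(fmt, 1, function(r) sprintf("| %s |", paste(r, collapse = " | ")))),
      md)
    paths <- c(paths, csv, md)
  }
  prov <- file.path(dir, "provenance.json")
  cfg <- unclass(report$config)
  cfg$true_frequency <- if (!is.null(cfg$true_frequency)) unclass(cfg$true_frequency)
  cfg$true_duration <- if (!is.null(cfg$true_duration)) unclass(cfg$true_duration)
  writeLines(jsonlite::toJSON(list(config = cfg), auto_unbox = TRUE,
                              pretty = TRUE, digits = NA, null = "null"), prov)
  invisible(c(paths, prov))
}

#' @export
print.look_report <- function(x, ...) {
  cat("<look_report>\n")
  for (resp in names(x$results)) {
    cat(sprintf("\n== %s ==\n", resp))
    tab <- x$results[[resp]]$table
    show <- data.frame(model = tab$model,
                       weight = sprintf("%.3f", tab$weight),
                       shared = sprintf("%.3f", tab$shared_weight),
                       marg_R2 = sprintf("%.3f", tab$marginal_r2),
                       cond_R2 = sprintf("%.3f", tab$conditional_r2))
    print(show, row.names = FALSE)
  }
  invisible(x)
}
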