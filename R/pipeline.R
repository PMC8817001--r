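#' Pipeline configuration
#'
#' Settings for the end-to-end analysis run: either simulate a synthetic
#' population (\code{mode = "synthetic"}) or load boards and responses from
#' files (\code{mode = "files"}).
#'
#' @param mode "synthetic" or "files".
#' @param seed master seed for the training population (synthetic mode);
#'   the validation population uses \code{seed + 1}.
#' @param n_agents agents per population (synthetic mode).
#' @param board_paths character vector of board JSON paths (file mode).
#' @param response_path response CSV path (file mode).
#' @param t_predef number of predefined boards (file mode; synthetic mode
#'   always uses the 10 built-in predefined boards).
#' @param bins,rss_tol,k_range distribution-fit settings (see
#'   [select_k()]).
#' @param n_boot dip-test bootstrap size.
#' @param out_dir output directory, or \code{NULL} to skip writing files.
#' @return an object of class \code{run_config}.
#' @export
run_config <- function(mode = c("synthetic", "files"), seed = 1L,
                       n_agents = 93, board_paths = NULL,
                       response_path = NULL, t_predef = NULL,
                       bins = 20, rss_tol = 1.5, k_range = 1:10,
                       n_boot = 500, out_dir = NULL) {
  mode <- match.arg(mode)
  if (mode == "files") {
    if (is.null(board_paths) || is.null(response_path))
      stop_("file mode needs board_paths and response_path")
    for (p in c(board_paths, response_path))
      if (!file.exists(p)) stop_("input file not found: %s", p)
  }
  structure(list(mode = mode, seed = as.integer(seed), n_agents = n_agents,
                 board_paths = board_paths, response_path = response_path,
                 t_predef = t_predef, bins = bins,
                 rss_tol = rss_tol, k_range = k_range,
                 n_boot = n_boot, out_dir = out_dir),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop_("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full analysis pipeline
#'
#' Sequences the whole analysis: obtain responses (simulate or load),
#' profile each board under the selection rules, compute per-game CI and
#' per-player iCA/SR scores, characterize the iCA distribution (dip test
#' and mixture fit with k-selection), fit the PCA-compressed ability model
#' on the training population, and validate its predictions on an
#' independently simulated validation population (synthetic mode) or on the
#' training data itself (file mode, with a note in the report).
#'
#' With a fixed configuration and seed the run is fully reproducible.
#'
#' @param config a [run_config()].
#' @return an object of class \code{pipeline_result}: list with
#'   \code{scores} (per-player data frame), \code{games} (per-game data
#'   frame), \code{distribution} (dip + k-selection + mixture),
#'   \code{pca}, \code{model}, \code{validation}, \code{config},
#'   \code{versions}. If \code{config$out_dir} is set, CSV/JSON reports and
#'   a run log are written there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (config$mode == "synthetic") {
    train_spec <- stage("simulate",
                        study_population_spec(seed = config$seed,
                                              n_agents = config$n_agents))
    rm_train <- stage("simulate", simulate_population(train_spec))
    valid_spec <- stage("simulate",
                        study_population_spec(seed = config$seed + 1L,
                                              n_agents = config$n_agents))
    rm_valid <- stage("simulate", simulate_population(valid_spec))
  } else {
    boards <- stage("load_boards", lapply(config$board_paths, read_board))
    t_predef <- if (is.null(config$t_predef)) length(boards) else config$t_predef
    rm_train <- stage("load_responses",
                      read_responses(config$response_path, boards,
                                     t_predef = t_predef))
    rm_valid <- NULL
  }

  games <- stage("rules", game_summary(rm_train))
  ica_scores <- stage("score", ica(rm_train))
  sr <- stage("score", strategy_rates(rm_train))
  scores <- data.frame(player = rm_train$players, ica = unname(ica_scores),
                       sr[, sr_cols], stringsAsFactors = FALSE)

  seeds <- split_seed(config$seed, 4)
  if (nrow(scores) >= 10) {
    dip <- stage("distribution",
                 dip_statistic(scores$ica, n_boot = config$n_boot,
                               seed = seeds[1]))
    ksel <- stage("distribution",
                  select_k(scores$ica, k_range = config$k_range,
                           bins = config$bins, rss_tol = config$rss_tol,
                           seed = seeds[2]))
    distribution <- list(dip = dip$dip, dip_p_value = dip$p_value,
                         k = ksel$k, k_silhouette = ksel$k_silhouette,
                         rss = ksel$rss, silhouette = ksel$silhouette,
                         components = ksel$best_fit$components,
                         fit_rss = ksel$best_fit$rss)
  } else {
    distribution <- list(note = "too few players to characterize the iCA distribution")
  }

  if (nrow(scores) >= 4) {
    pca <- stage("model", fit_pca(sr))
    s <- stage("model", compress_profiles(sr, pca))
    model <- stage("model", fit_ability_model(s, scores$ica))
  } else {
    pca <- NULL
    model <- NULL
  }

  if (is.null(model)) {
    pred <- NULL
    valid <- NULL
    valid_note <- "too few players to fit the ability model"
  } else if (!is.null(rm_valid)) {
    ica_v <- stage("validate", ica(rm_valid))
    sr_v <- stage("validate", strategy_rates(rm_valid))
    pred <- stage("validate", predict_ica(sr_v, pca, model))
    valid <- stage("validate", validate_predictions(pred, unname(ica_v)))
    valid_note <- "independent validation population"
  } else {
    pred <- stage("validate", predict_ica(sr, pca, model))
    valid <- stage("validate", validate_predictions(pred, scores$ica))
    valid_note <- "in-sample validation (file mode)"
  }

  result <- structure(
    list(scores = scores, games = games, distribution = distribution,
         pca = pca, model = model, validation = valid,
         validation_note = valid_note, config = config,
         versions = list(package = as.character(utils::packageVersion("tacitcoord")),
                         r = R.version.string)),
    class = "pipeline_result")

  if (!is.null(config$out_dir)) write_pipeline_reports(result, config$out_dir)
  result
}

write_pipeline_reports <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$scores, file.path(out_dir, "scores.csv"),
                   row.names = FALSE)
  utils::write.csv(result$games, file.path(out_dir, "games.csv"),
                   row.names = FALSE)
  jsonlite::write_json(result$distribution,
                       file.path(out_dir, "distribution.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  model_json <- if (is.null(result$model)) {
    list(note = result$validation_note)
  } else {
    list(center = result$pca$center, scale = result$pca$scale,
         components = result$pca$components,
         eigenvalues = result$pca$eigenvalues,
         intercept = result$model$intercept,
         coef_s1 = result$model$coef_s1, coef_s2 = result$model$coef_s2,
         r_squared = result$model$r_squared, f_stat = result$model$f_stat,
         var_error = result$model$var_error)
  }
  jsonlite::write_json(model_json, file.path(out_dir, "model.json"),
                       auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  valid_json <- if (is.null(result$validation)) {
    list(note = result$validation_note)
  } else {
    list(note = result$validation_note,
         percentiles = as.list(result$validation$percentiles),
         n = result$validation$n)
  }
  jsonlite::write_json(valid_json, file.path(out_dir, "validation.json"),
                       auto_unbox = TRUE, digits = NA)
  log_lines <- c(
    sprintf("tacitcoord %s / %s", result$versions$package, result$versions$r),
    sprintf("mode=%s seed=%d agents=%d", result$config$mode,
            result$config$seed,
            if (is.null(result$config$n_agents)) NA_integer_
            else result$config$n_agents),
    sprintf("run completed: %d players, %d games", nrow(result$scores),
            nrow(result$games)))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d players, %d games (%s mode, seed %d)\n",
              nrow(x$scores), nrow(x$games), x$config$mode, x$config$seed))
  if (!is.null(x$distribution$dip)) {
    cat(sprintf("  iCA: dip = %.4f (p = %.3f), mixture k = %d (silhouette k = %d)\n",
                x$distribution$dip, x$distribution$dip_p_value,
                x$distribution$k, x$distribution$k_silhouette))
  }
  if (!is.null(x$model)) {
    cat(sprintf("  model: R^2 = %.4f; validation median |error| = %.2f%% (%s)\n",
                x$model$r_squared, x$validation$percentiles["p50"],
                x$validation_note))
  } else {
    cat(sprintf("  %s\n", x$validation_note))
  }
  invisible(x)
}
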