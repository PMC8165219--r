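# Cross-validated grid search over model hyperparameters.

#' Declare a hyperparameter grid
#'
#' Candidate lists are crossed into a grid of [model_config()]s.
#'
#' @param architecture,k,d_r,d_a,d_o,d_g,scheme,use_positions,loss_id
#'   Candidate values for the corresponding [model_config()] fields; `scheme`
#'   candidates are `"+"`-separated strings.
#' @return A tibble of configurations with a `config_id` column.
#' @export
grid_spec <- function(architecture = "convm", k = 1L, d_r = 16L, d_a = 8L,
                      d_o = 4L, d_g = 8L, scheme = "blosum+onehot+deep",
                      use_positions = TRUE, loss_id = "hv") {
  cand <- list(architecture = architecture, k = k, d_r = d_r, d_a = d_a,
               d_o = d_o, d_g = d_g, scheme = scheme,
               use_positions = use_positions, loss_id = loss_id)
  if (any(lengths(cand) == 0)) {
    abort("all candidate lists must be non-empty.", class = "peprank_config_error")
  }
  g <- tibble::as_tibble(expand.grid(cand, stringsAsFactors = FALSE))
  dplyr::mutate(g, config_id = dplyr::row_number(), .before = 1)
}

# Fold assignment by peptide: a partition into `folds` groups whose sizes
# differ by at most one.
.assign_folds <- function(n, folds) {
  sample(rep_len(seq_len(folds), n))
}

#' Cross-validated grid search
#'
#' For every configuration in the grid and every fold, trains on the
#' remaining folds (with an inner validation split driving the schedule) and
#' evaluates the seven ranking metrics on the held-out fold. Folds partition
#' peptides, so no peptide is shared between a training and a test portion.
#' Per-configuration metrics are averaged over folds and combined with
#' [hybrid_metric()]; the configuration minimizing the hybrid score wins.
#'
#' @param data Consolidated entries for one allele (columns `peptide`,
#'   `kind`, `ic50`, `b`, `level`).
#' @param grid A [grid_spec()] tibble.
#' @param control A [train_control()]; its `folds` field sets the number of
#'   folds.
#' @param loss_cfg A [loss_config()].
#' @param seed Integer seed (fold assignment and training).
#' @return A list of class `peprank_cv`: `best_config` (a [model_config()]),
#'   `summary` (per-config mean metrics with the hybrid score) and
#'   `fold_metrics` (one row per config x fold).
#' @export
cross_validate_grid <- function(data, grid, control = train_control(),
                                loss_cfg = loss_config(), seed = 1L) {
  folds <- control$folds
  if (nrow(data) < 2 * folds) {
    abort("not enough entries for the requested folds.", class = "peprank_config_error")
  }
  withr::with_seed(seed, {
    fold_of <- .assign_folds(nrow(data), folds)
    rows <- list()
    for (ci in seq_len(nrow(grid))) {
      gr <- grid[ci, ]
      config <- model_config(architecture = gr$architecture, k = gr$k,
                             d_r = gr$d_r, d_a = gr$d_a, d_o = gr$d_o,
                             d_g = gr$d_g, scheme = gr$scheme,
                             use_positions = gr$use_positions,
                             loss_id = gr$loss_id)
      for (f in seq_len(folds)) {
        train_dat <- data[fold_of != f, , drop = FALSE]
        test_dat <- data[fold_of == f, , drop = FALSE]
        fit <- train_model(train_dat, config, control, loss_cfg,
                           seed = sample.int(2^30, 1))
        preds <- score_peptides(test_dat$peptide, fit)
        preds$ic50 <- ifelse(is.na(test_dat$ic50),
                             level_threshold_ic50(test_dat$level),
                             test_dat$ic50)
        met <- suppressWarnings(evaluate_ranking(preds))
        rows[[length(rows) + 1L]] <- dplyr::bind_cols(
          tibble::tibble(config_id = gr$config_id, fold = f), met)
      }
    }
    fold_metrics <- dplyr::bind_rows(rows)
    summary <- dplyr::summarise(
      dplyr::group_by(fold_metrics, .data$config_id),
      dplyr::across(dplyr::all_of(names(.metric_smaller_better)),
                    ~ mean(.x, na.rm = TRUE)),
      .groups = "drop")
    summary <- hybrid_metric(summary)
    best_id <- summary$config_id[which.min(summary$hybrid)]
    gr <- grid[grid$config_id == best_id, ]
    best_config <- model_config(architecture = gr$architecture, k = gr$k,
                                d_r = gr$d_r, d_a = gr$d_a, d_o = gr$d_o,
                                d_g = gr$d_g, scheme = gr$scheme,
                                use_positions = gr$use_positions,
                                loss_id = gr$loss_id)
    structure(list(best_config = best_config, best_id = best_id,
                   summary = summary, fold_metrics = fold_metrics),
              class = "peprank_cv")
  })
}

#' @export
print.peprank_cv <- function(x, ...) {
  cat(sprintf("<peprank_cv> %d configurations x %d folds; best config_id = %d\n",
              nrow(x$summary), max(x$fold_metrics$fold), x$best_id))
  print(x$best_config)
  invisible(x)
}

#' @export
tidy.peprank_cv <- function(x, ...) x$fold_metrics

#' @export
glance.peprank_cv <- function(x, ...) {
  dplyr::filter(x$summary, .data$config_id == x$best_id)
}
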