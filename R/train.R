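# SGD training with validation-driven learning-rate decay and early stopping.

#' Training control parameters
#'
#' @param initial_lr Initial SGD learning rate.
#' @param lr_decay_patience Consecutive epochs without validation improvement
#'   before the learning rate is multiplied by `lr_decay_factor` (the decay
#'   repeats every further `lr_decay_patience` stale epochs).
#' @param lr_decay_factor Multiplicative decay (0.9 = "decrease by 10%").
#' @param early_stop_patience Consecutive stale epochs before training stops.
#' @param validation_fraction Fraction of training peptides held out as the
#'   validation set driving the schedule.
#' @param folds Number of cross-validation folds for [cross_validate_grid()].
#' @param batch_size Peptides sampled per training batch.
#' @param pairs_per_batch Peptide pairs drawn per batch for the hinge losses;
#'   defaults to `batch_size`.
#' @param max_epochs Hard cap on training epochs.
#' @param rel_tol Relative improvement below which a validation loss does not
#'   count as a decrease.
#' @param val_pair_cap Maximum number of validation pairs enumerated for the
#'   hinge validation loss.
#' @return A list of class `peprank_train_control`.
#' @export
train_control <- function(initial_lr = 0.05, lr_decay_patience = 5L,
                          lr_decay_factor = 0.9, early_stop_patience = 20L,
                          validation_fraction = 0.10, folds = 5L,
                          batch_size = 64L, pairs_per_batch = NULL,
                          max_epochs = 200L, rel_tol = 1e-4,
                          val_pair_cap = 50000L) {
  if (lr_decay_patience < 1 || early_stop_patience < 1) {
    abort("patiences must be >= 1.", class = "peprank_config_error")
  }
  if (validation_fraction <= 0 || validation_fraction >= 1) {
    abort("validation_fraction must be in (0, 1).", class = "peprank_config_error")
  }
  if (folds < 2) abort("folds must be >= 2.", class = "peprank_config_error")
  structure(list(initial_lr = initial_lr, lr_decay_patience = as.integer(lr_decay_patience),
                 lr_decay_factor = lr_decay_factor,
                 early_stop_patience = as.integer(early_stop_patience),
                 validation_fraction = validation_fraction, folds = as.integer(folds),
                 batch_size = as.integer(batch_size),
                 pairs_per_batch = as.integer(pairs_per_batch %||% batch_size),
                 max_epochs = as.integer(max_epochs), rel_tol = rel_tol,
                 val_pair_cap = as.integer(val_pair_cap)),
            class = "peprank_train_control")
}

#' Validation-driven learning-rate schedule
#'
#' A small state machine consumed once per epoch with the current validation
#' loss. An improvement is a drop of more than `rel_tol * |best|` below the
#' running best. After `lr_decay_patience` consecutive stale epochs the
#' learning rate is multiplied by `lr_decay_factor` (and again every further
#' `lr_decay_patience` stale epochs); after `early_stop_patience` consecutive
#' stale epochs `stop` is set.
#'
#' @param control A [train_control()].
#' @return A schedule state list; advance it with [schedule_step()].
#' @export
schedule_init <- function(control = train_control()) {
  list(lr = control$initial_lr, best = Inf, stale = 0L, stop = FALSE,
       improved = FALSE, control = control)
}

#' @rdname schedule_init
#' @param state A schedule state from [schedule_init()] or a previous
#'   [schedule_step()].
#' @param val_loss The epoch's validation loss.
#' @export
schedule_step <- function(state, val_loss) {
  ctl <- state$control
  improved <- (state$best - val_loss) > ctl$rel_tol * abs(state$best)
  if (is.infinite(state$best) && is.finite(val_loss)) improved <- TRUE
  if (improved) {
    state$best <- val_loss
    state$stale <- 0L
  } else {
    state$stale <- state$stale + 1L
    if (state$stale %% ctl$lr_decay_patience == 0L) {
      state$lr <- state$lr * ctl$lr_decay_factor
    }
    if (state$stale >= ctl$early_stop_patience) state$stop <- TRUE
  }
  state$improved <- improved
  state
}

#' Sample a batch of peptide pairs for the hinge losses
#'
#' Draws pairs uniformly from the valid pairs within a batch of entries: for
#' the value- and level-based hinge losses only cross-level pairs are valid;
#' for the constrained loss same-level pairs are allowed too. Pairs are
#' ordered so the first member has the (weakly) higher level. Uses the
#' current RNG state, so results are reproducible under a fixed seed.
#'
#' @param entries Tibble of consolidated entries with columns `b` and `level`
#'   (typically a batch of [preprocess_affinities()] rows).
#' @param loss_id `"hv"`, `"hl"` or `"hi"`.
#' @param n_pairs Number of pairs to draw (with replacement).
#' @return Tibble with index columns `i`, `j` (rows of `entries`) and the
#'   pair fields `b_i`, `b_j`, `l_i`, `l_j`.
#' @export
sample_pair_batch <- function(entries, loss_id, n_pairs) {
  n <- nrow(entries)
  lv <- entries$level
  idx <- expand.grid(i = seq_len(n), j = seq_len(n))
  idx <- idx[idx$i < idx$j, , drop = FALSE]
  valid <- if (loss_id == "hi") {
    rep(TRUE, nrow(idx))
  } else {
    lv[idx$i] != lv[idx$j]
  }
  idx <- idx[valid, , drop = FALSE]
  if (nrow(idx) == 0) {
    abort("no valid pairs: data spans a single binding level.",
          class = "peprank_no_valid_pairs")
  }
  take <- idx[sample.int(nrow(idx), n_pairs, replace = TRUE), , drop = FALSE]
  # order each pair so the higher level comes first
  swap <- lv[take$i] < lv[take$j]
  i <- ifelse(swap, take$j, take$i)
  j <- ifelse(swap, take$i, take$j)
  tibble::tibble(i = i, j = j,
                 b_i = entries$b[i], b_j = entries$b[j],
                 l_i = lv[i], l_j = lv[j])
}

# Deterministic enumeration of validation pairs (capped).
.enumerate_pairs <- function(entries, loss_id, cap) {
  n <- nrow(entries)
  idx <- expand.grid(i = seq_len(n), j = seq_len(n))
  idx <- idx[idx$i < idx$j, , drop = FALSE]
  lv <- entries$level
  if (loss_id != "hi") idx <- idx[lv[idx$i] != lv[idx$j], , drop = FALSE]
  if (nrow(idx) == 0) return(NULL)
  if (nrow(idx) > cap) idx <- idx[seq_len(cap), , drop = FALSE]
  swap <- lv[idx$i] < lv[idx$j]
  i <- ifelse(swap, idx$j, idx$i)
  j <- ifelse(swap, idx$i, idx$j)
  tibble::tibble(i = i, j = j, b_i = entries$b[i], b_j = entries$b[j],
                 l_i = lv[i], l_j = lv[j])
}

# Validation loss in evaluation mode given scored entries.
.validation_loss <- function(entries, scores, loss_id, cfg, cap) {
  if (loss_id == "ms") {
    s <- pmin(pmax(scores, 1e-12), 1 - 1e-12)
    return(mean(mean_square_loss(dplyr::mutate(entries, score = s))))
  }
  pairs <- .enumerate_pairs(entries, loss_id, cap)
  if (is.null(pairs)) {
    abort("validation set spans a single binding level.", class = "peprank_no_valid_pairs")
  }
  pairs$s_i <- scores[pairs$i]
  pairs$s_j <- scores[pairs$j]
  lf <- switch(loss_id, hv = hinge_value_loss, hl = hinge_level_loss,
               hi = hinge_constrained_loss)
  mean(lf(pairs, cfg))
}

#' Train a scoring model
#'
#' Stochastic gradient descent on one allele's consolidated entries. A
#' fraction of the peptides is held out as a validation set; the validation
#' loss drives learning-rate decay and early stopping, and the returned model
#' carries the parameters of the best-validation epoch.
#'
#' @param data Consolidated entries for one allele (see
#'   [preprocess_affinities()]): columns `peptide`, `kind`, `b`, `level`.
#' @param config A [model_config()].
#' @param control A [train_control()].
#' @param loss_cfg A [loss_config()] with the margin constants.
#' @param seed Integer seed controlling the split, batching and
#'   initialization.
#' @return An object of classes `peprank_fit` and `peprank_model` with the
#'   trained parameters, per-epoch `log` (tibble: epoch, train_loss,
#'   val_loss, lr, improved) and `best_epoch`.
#' @export
train_model <- function(data, config, control = train_control(),
                        loss_cfg = loss_config(), seed = 1L) {
  stopifnot(inherits(config, "peprank_config"))
  need <- c("peptide", "kind", "b", "level")
  if (!all(need %in% names(data))) {
    abort(paste0("`data` needs columns: ", paste(need, collapse = ", ")),
          class = "peprank_io_error")
  }
  if (anyDuplicated(data$peptide)) {
    abort("`data` must have one consolidated entry per peptide.",
          class = "peprank_io_error")
  }
  withr::with_seed(seed, {
    model <- init_model(config, seed = sample.int(.Machine$integer.max, 1))
    n <- nrow(data)
    n_val <- max(1L, round(control$validation_fraction * n))
    val_idx <- sample.int(n, n_val)
    val <- data[val_idx, , drop = FALSE]
    train <- data[-val_idx, , drop = FALSE]
    hinge <- config$loss_id != "ms"
    if (hinge && length(unique(train$level)) < 2) {
      abort("hinge losses need at least two binding levels in the training data.",
            class = "peprank_no_valid_pairs")
    }
    params <- model$params
    run_stats <- model$run_stats
    sched <- schedule_init(control)
    best_params <- params
    best_run <- run_stats
    best_epoch <- 0L
    log <- vector("list", control$max_epochs)
    steps <- max(1L, ceiling(nrow(train) / control$batch_size))
    for (epoch in seq_len(control$max_epochs)) {
      perm <- sample.int(nrow(train))
      epoch_loss <- 0
      for (s in seq_len(steps)) {
        lo <- (s - 1L) * control$batch_size + 1L
        hi <- min(s * control$batch_size, nrow(train))
        batch <- train[perm[lo:hi], , drop = FALSE]
        pairs <- NULL
        if (hinge) {
          if (length(unique(batch$level)) < 2 &&
              !(config$loss_id == "hi" && nrow(batch) >= 2)) next
          pairs <- sample_pair_batch(batch, config$loss_id, control$pairs_per_batch)
        }
        fw <- .forward(batch$peptide, config, params, run_stats, mode = "train")
        run_stats <- fw$run_stats
        lg <- .batch_loss_grad(fw$score, config$loss_id, pairs = pairs,
                               entries = batch, cfg = loss_cfg)
        if (!is.finite(lg$loss)) {
          abort(sprintf("training diverged at epoch %d (non-finite loss).", epoch),
                class = "peprank_divergence")
        }
        grads <- .backward(lg$dscore, config, params, fw$cache)
        params <- .sgd_step(params, grads, sched$lr)
        epoch_loss <- epoch_loss + lg$loss
      }
      val_scores <- .forward(val$peptide, config, params, run_stats, mode = "eval")$score
      vloss <- .validation_loss(val, val_scores, config$loss_id, loss_cfg,
                                control$val_pair_cap)
      lr_used <- sched$lr
      sched <- schedule_step(sched, vloss)
      if (sched$improved) {
        best_params <- params
        best_run <- run_stats
        best_epoch <- epoch
      }
      log[[epoch]] <- tibble::tibble(epoch = epoch,
                                     train_loss = epoch_loss / steps,
                                     val_loss = vloss, lr = lr_used,
                                     improved = sched$improved)
      if (sched$stop) break
    }
    model$params <- best_params
    model$run_stats <- best_run
    model$trained <- TRUE
    model$log <- dplyr::bind_rows(log)
    model$best_epoch <- best_epoch
    model$early_stopped <- sched$stop
    model$seed <- seed
    model$loss_cfg <- loss_cfg
    class(model) <- c("peprank_fit", "peprank_model")
    model
  })
}

#' @export
print.peprank_fit <- function(x, ...) {
  NextMethod()
  cat(sprintf("  epochs: %d | best epoch: %d | best val loss: %.6g | final lr: %.4g\n",
              nrow(x$log), x$best_epoch, min(x$log$val_loss), x$log$lr[nrow(x$log)]))
  invisible(x)
}

#' Tidy the training log of a fitted model
#'
#' @param x A `peprank_fit`.
#' @param ... Unused.
#' @return The per-epoch log as a tibble (epoch, train_loss, val_loss, lr,
#'   improved).
#' @export
tidy.peprank_fit <- function(x, ...) x$log

#' One-row summary of a fitted model
#'
#' @param x A `peprank_fit`.
#' @param ... Unused.
#' @return A one-row tibble: architecture, loss, epochs run, best epoch,
#'   best validation loss, final learning rate, whether early stopping fired.
#' @export
glance.peprank_fit <- function(x, ...) {
  tibble::tibble(architecture = x$config$architecture,
                 loss = x$config$loss_id,
                 epochs = nrow(x$log),
                 best_epoch = x$best_epoch,
                 best_val_loss = min(x$log$val_loss),
                 final_lr = x$log$lr[nrow(x$log)],
                 early_stopped = isTRUE(x$early_stopped))
}
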