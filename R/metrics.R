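# Ranking evaluation: average rank, hit rate, AUC with a strict indicator,
# truncated ROC, and the hybrid model-selection score.

.undefined_metric <- function(msg) {
  warn(msg, class = "peprank_undefined_metric")
  NA_real_
}

# Ranks by decreasing score, rank 1 = highest. Ties broken by stable input
# order, with a warning (the metrics presume a total order).
.score_ranks <- function(score, warn_ties = TRUE) {
  if (warn_ties && anyDuplicated(score)) {
    warn("tied scores: ranks broken by input order.", class = "peprank_tied_scores")
  }
  ord <- order(-score)
  rnk <- integer(length(score))
  rnk[ord] <- seq_along(score)
  rnk
}

.promising <- function(preds, h) {
  if (!all(c("score", "ic50") %in% names(preds))) {
    abort("predictions need columns `score` and `ic50`.", class = "peprank_io_error")
  }
  preds$ic50 < h
}

#' Average rank of promising peptides
#'
#' Mean rank (1 = highest score) over the promising set, the peptides with
#' IC50 below `h` nM. Lower is better.
#'
#' @param preds Tibble with columns `score` and `ic50` (nM).
#' @param h Promising threshold in nM (e.g. 100 or 500).
#' @return The mean rank, or `NA` with a warning if no peptide is promising.
#' @export
average_rank <- function(preds, h = 500) {
  pos <- .promising(preds, h)
  if (!any(pos)) return(.undefined_metric(sprintf("no peptides under %g nM.", h)))
  mean(.score_ranks(preds$score)[pos])
}

#' Hit rate of promising peptides
#'
#' Fraction of the promising set (IC50 < `h` nM) retrieved in the top `t`
#' ranked predictions, with `t` equal to the size of the promising set.
#'
#' @inheritParams average_rank
#' @return A value in `[0, 1]`, or `NA` with a warning if no peptide is
#'   promising.
#' @export
hit_rate <- function(preds, h = 500) {
  pos <- .promising(preds, h)
  t <- sum(pos)
  if (t == 0) return(.undefined_metric(sprintf("no peptides under %g nM.", h)))
  rnk <- .score_ranks(preds$score)
  sum(pos & rnk <= t) / t
}

#' Ranking AUC with a strict indicator
#'
#' Fraction of (positive, negative) peptide pairs in which the positive
#' scores strictly higher, positives being peptides with IC50 < 500 nM.
#' Ties earn no credit.
#'
#' @param preds Tibble with columns `score` and `ic50` (nM).
#' @param h Positive-class threshold in nM (500 by convention).
#' @return A value in `[0, 1]`, or `NA` with a warning for single-class input.
#' @export
ranking_auc <- function(preds, h = 500) {
  pos <- .promising(preds, h)
  if (!any(pos) || all(pos)) {
    return(.undefined_metric("AUC needs at least one positive and one negative."))
  }
  sp <- preds$score[pos]
  sn <- preds$score[!pos]
  mean(outer(sp, sn, ">"))
}

#' Truncated ROC score
#'
#' Area under the ROC curve up to the first `t` false positives: the fraction
#' of (positive, top-negative) pairs in which the positive strictly outscores
#' one of the `t` highest-scoring negatives. With `t` equal to the number of
#' negatives this is exactly [ranking_auc()].
#'
#' @inheritParams ranking_auc
#' @param t Number of top-scoring negatives to compare against.
#' @return A value in `[0, 1]`, or `NA` with a warning when there are fewer
#'   than `t` negatives or no positives.
#' @export
roc_top <- function(preds, t = 5, h = 500) {
  pos <- .promising(preds, h)
  sp <- preds$score[pos]
  sn <- preds$score[!pos]
  if (length(sp) == 0) return(.undefined_metric("no positive peptides."))
  if (length(sn) < t) return(.undefined_metric(sprintf("fewer than t = %d negatives.", t)))
  negtop <- sort(sn, decreasing = TRUE)[seq_len(t)]
  mean(outer(sp, negtop, ">"))
}

#' Evaluate the seven ranking metrics
#'
#' Computes AR100, HR100, AR500, HR500, AUC, ROC5 and ROC10 for one set of
#' scored peptides.
#'
#' @inheritParams ranking_auc
#' @return A one-row tibble with the seven metrics.
#' @export
evaluate_ranking <- function(preds) {
  tibble::tibble(
    ar100 = average_rank(preds, 100),
    hr100 = hit_rate(preds, 100),
    ar500 = average_rank(preds, 500),
    hr500 = hit_rate(preds, 500),
    auc = ranking_auc(preds),
    roc5 = roc_top(preds, 5),
    roc10 = roc_top(preds, 10)
  )
}

.metric_smaller_better <- c(ar100 = TRUE, hr100 = FALSE, ar500 = TRUE,
                            hr500 = FALSE, auc = FALSE, roc5 = FALSE,
                            roc10 = FALSE)

#' Hybrid model-selection score
#'
#' Combines the seven ranking metrics of a set of candidate configurations
#' into one non-negative score per configuration: for each metric, the
#' relative regret against the best-performing value over all candidates
#' (minimum for the average-rank metrics, where smaller is better; maximum
#' otherwise), signed so every term is non-negative. A configuration that is
#' best on every metric scores 0; selection minimizes the hybrid score.
#'
#' @param metrics Tibble with one row per configuration and columns `ar100`,
#'   `hr100`, `ar500`, `hr500`, `auc`, `roc5`, `roc10` (additional columns are
#'   carried through).
#' @return `metrics` with an added column `hybrid`.
#' @export
hybrid_metric <- function(metrics) {
  nm <- names(.metric_smaller_better)
  if (!all(nm %in% names(metrics))) {
    abort(paste0("metrics must include: ", paste(nm, collapse = ", ")),
          class = "peprank_io_error")
  }
  H <- numeric(nrow(metrics))
  for (mtrc in nm) {
    v <- metrics[[mtrc]]
    if (any(!is.finite(v))) {
      abort(sprintf("metric %s has non-finite values.", mtrc), class = "peprank_io_error")
    }
    smaller <- .metric_smaller_better[[mtrc]]
    best <- if (smaller) min(v) else max(v)
    if (best == 0) {
      warn(sprintf("metric %s has best value 0; skipped in the hybrid score.", mtrc))
      next
    }
    sgn <- if (smaller) 1 else -1
    H <- H + sgn * (v - best) / best
  }
  dplyr::mutate(metrics, hybrid = H)
}
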