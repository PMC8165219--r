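# Pairwise hinge ranking objectives and the piecewise mean-square objective.
#
# All loss functions are vectorized over tibbles: pair losses take a tibble of
# peptide pairs (columns b_i, b_j, l_i, l_j, s_i, s_j, ordered so that i is
# the higher-level peptide where required), the mean-square loss takes a
# tibble of entries. Batch aggregation is the arithmetic mean.

#' Loss margin configuration
#'
#' @param c Margin constant added to the affinity gap in the value-based
#'   hinge loss (> 0, default 0.2).
#' @param r Margin unit per level difference in the level-based losses
#'   (> 0, default 0.2).
#' @return A list with elements `c` and `r`.
#' @export
loss_config <- function(c = 0.2, r = 0.2) {
  if (c <= 0 || r <= 0) abort("margin constants must be > 0.", class = "peprank_config_error")
  list(c = c, r = r)
}

.check_pairs <- function(pairs, strict = TRUE) {
  need <- c("l_i", "l_j", "s_i", "s_j")
  if (!all(need %in% names(pairs))) {
    abort(paste0("pairs need columns: ", paste(need, collapse = ", ")),
          class = "peprank_pair_error")
  }
  if (strict && any(pairs$l_i <= pairs$l_j)) {
    abort("pairs must be ordered with l_i > l_j.", class = "peprank_pair_error")
  }
  if (!strict && any(pairs$l_i < pairs$l_j)) {
    abort("pairs must be ordered with l_i >= l_j.", class = "peprank_pair_error")
  }
}

#' Value-based pairwise hinge loss
#'
#' For a pair with the higher binding level first, penalizes a predicted
#' score gap smaller than the ground-truth affinity gap plus a margin:
#' `max(0, c + (b_i - b_j) - (s_i - s_j))`. Only defined across binding
#' levels.
#'
#' @param pairs Tibble of pairs with columns `b_i`, `b_j`, `l_i`, `l_j`,
#'   `s_i`, `s_j` and `l_i > l_j`.
#' @param cfg A [loss_config()].
#' @return Numeric vector of per-pair losses (>= 0).
#' @export
hinge_value_loss <- function(pairs, cfg = loss_config()) {
  .check_pairs(pairs, strict = TRUE)
  if (!all(c("b_i", "b_j") %in% names(pairs))) {
    abort("value-based hinge needs b_i and b_j.", class = "peprank_pair_error")
  }
  pmax(0, cfg$c + (pairs$b_i - pairs$b_j) - (pairs$s_i - pairs$s_j))
}

#' Level-based pairwise hinge loss
#'
#' Margin proportional to the level gap: `max(0, r * (l_i - l_j) - (s_i -
#' s_j))`. Independent of the numeric affinities.
#'
#' @inheritParams hinge_value_loss
#' @return Numeric vector of per-pair losses (>= 0).
#' @export
hinge_level_loss <- function(pairs, cfg = loss_config()) {
  .check_pairs(pairs, strict = TRUE)
  pmax(0, cfg$r * (pairs$l_i - pairs$l_j) - (pairs$s_i - pairs$s_j))
}

#' Constrained level-based pairwise hinge loss
#'
#' Extends the level-based hinge with a same-level constraint: across levels
#' it equals [hinge_level_loss()]; within a level it penalizes score gaps
#' larger than the margin, `max(0, |s_i - s_j| - r)`.
#'
#' @param pairs Tibble of pairs with `l_i >= l_j`.
#' @inheritParams hinge_value_loss
#' @return Numeric vector of per-pair losses (>= 0).
#' @export
hinge_constrained_loss <- function(pairs, cfg = loss_config()) {
  .check_pairs(pairs, strict = FALSE)
  ifelse(pairs$l_i > pairs$l_j,
         pmax(0, cfg$r * (pairs$l_i - pairs$l_j) - (pairs$s_i - pairs$s_j)),
         pmax(0, abs(pairs$s_i - pairs$s_j) - cfg$r))
}

#' Piecewise mean-square loss
#'
#' For quantitative entries, the squared error `(s - b)^2` between the
#' sigmoid-normalized score and the normalized affinity. For qualitative
#' entries the error is one-sided against the level's threshold affinity
#' (see [level_threshold_affinity()]): negative entries (level 1) are only
#' penalized for scoring above it, positive entries (level > 1) only for
#' scoring below it.
#'
#' @param entries Tibble with columns `kind` (`"quantitative"` /
#'   `"qualitative"`), `b` (used for quantitative entries), `level` and
#'   `score` in (0, 1).
#' @return Numeric vector of per-entry losses (>= 0).
#' @export
mean_square_loss <- function(entries) {
  need <- c("kind", "b", "level", "score")
  if (!all(need %in% names(entries))) {
    abort(paste0("entries need columns: ", paste(need, collapse = ", ")),
          class = "peprank_pair_error")
  }
  s <- entries$score
  if (any(s <= 0 | s >= 1)) {
    abort("scores must lie in (0, 1) (sigmoid-normalized).", class = "peprank_pair_error")
  }
  quant <- entries$kind == "quantitative"
  bq <- ifelse(quant, entries$b, level_threshold_affinity(entries$level))
  out <- numeric(length(s))
  out[quant] <- (s[quant] - bq[quant])^2
  neg <- !quant & entries$level == 1
  pos <- !quant & entries$level > 1
  out[neg] <- pmax(0, s[neg] - bq[neg])^2
  out[pos] <- pmax(0, bq[pos] - s[pos])^2
  out
}

# Mean batch loss and its gradient with respect to each peptide's score.
# `pairs` carries integer indices (i, j) into `scores`; `entries` is used for
# the ms loss. Returns list(loss, dscore).
.batch_loss_grad <- function(scores, loss_id, pairs = NULL, entries = NULL,
                             cfg = loss_config()) {
  n_out <- length(scores)
  dsc <- numeric(n_out)
  if (loss_id == "ms") {
    s <- scores
    quant <- entries$kind == "quantitative"
    b <- ifelse(quant, entries$b, level_threshold_affinity(entries$level))
    loss_vec <- numeric(n_out)
    grad <- numeric(n_out)
    loss_vec[quant] <- (s[quant] - b[quant])^2
    grad[quant] <- 2 * (s[quant] - b[quant])
    neg <- !quant & entries$level == 1
    pos <- !quant & entries$level > 1
    loss_vec[neg] <- pmax(0, s[neg] - b[neg])^2
    grad[neg] <- 2 * pmax(0, s[neg] - b[neg])
    loss_vec[pos] <- pmax(0, b[pos] - s[pos])^2
    grad[pos] <- -2 * pmax(0, b[pos] - s[pos])
    return(list(loss = mean(loss_vec), dscore = grad / n_out))
  }
  np <- nrow(pairs)
  s_i <- scores[pairs$i]
  s_j <- scores[pairs$j]
  gap <- s_i - s_j
  if (loss_id == "hv") {
    margin <- cfg$c + (pairs$b_i - pairs$b_j)
    lv <- pmax(0, margin - gap)
    act <- lv > 0
    di <- ifelse(act, -1, 0)
  } else if (loss_id == "hl") {
    margin <- cfg$r * (pairs$l_i - pairs$l_j)
    lv <- pmax(0, margin - gap)
    act <- lv > 0
    di <- ifelse(act, -1, 0)
  } else { # hi
    cross <- pairs$l_i > pairs$l_j
    margin <- cfg$r * (pairs$l_i - pairs$l_j)
    lv <- ifelse(cross, pmax(0, margin - gap), pmax(0, abs(gap) - cfg$r))
    di <- numeric(np)
    di[cross & lv > 0] <- -1
    same_act <- !cross & lv > 0
    di[same_act] <- sign(gap[same_act])
  }
  dj <- -di
  for (p in which(di != 0)) {
    dsc[pairs$i[p]] <- dsc[pairs$i[p]] + di[p] / np
    dsc[pairs$j[p]] <- dsc[pairs$j[p]] + dj[p] / np
  }
  list(loss = mean(lv), dscore = dsc)
}
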