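# ConvM / SpConvM scoring models: configuration, initialization, forward pass.
#
# The forward pass is written over a batch of peptides at once: feature
# columns of all peptides are concatenated into one wide matrix so the
# convolution, batch normalization, attention and head reduce to a handful of
# dense matrix products. A `group` index maps columns back to peptides.

#' Configure a scoring model
#'
#' @param architecture `"convm"` (local kernels + attention) or `"spconvm"`
#'   (adds global kernels over the middle-padded 15-mer).
#' @param k Local kernel size (1..8; must not exceed the shortest peptide).
#' @param d_r Number of local convolution filters; also the width of the
#'   fully-connected hidden layer.
#' @param d_a Attention hidden units.
#' @param d_o Position-embedding dimension.
#' @param d_g Number of global kernels (spconvm only).
#' @param scheme Residue [encoding_scheme()] or a string accepted by it.
#' @param use_positions Include the dual-end position embeddings in the local
#'   feature matrix (`FALSE` reproduces the ablation).
#' @param loss_id One of `"hv"`, `"hl"`, `"hi"` (pairwise hinge ranking
#'   losses) or `"ms"` (piecewise mean-square; scores pass through a sigmoid).
#' @return An object of class `peprank_config`.
#' @export
model_config <- function(architecture = c("convm", "spconvm"),
                         k = 1L, d_r = 16L, d_a = 8L, d_o = 4L, d_g = 8L,
                         scheme = "blosum+onehot+deep",
                         use_positions = TRUE,
                         loss_id = c("hv", "hl", "hi", "ms")) {
  architecture <- match.arg(architecture)
  loss_id <- match.arg(loss_id)
  if (!inherits(scheme, "peprank_scheme")) scheme <- encoding_scheme(scheme)
  if (k < 1 || k > 8) abort("k must be in 1..8.", class = "peprank_config_error")
  if (d_r < 1 || d_a < 1) abort("d_r and d_a must be >= 1.", class = "peprank_config_error")
  if (architecture == "spconvm" && d_g < 1) {
    abort("d_g must be >= 1 for spconvm.", class = "peprank_config_error")
  }
  if (use_positions && d_o < 1) abort("d_o must be >= 1.", class = "peprank_config_error")
  structure(list(architecture = architecture, k = as.integer(k),
                 d_r = as.integer(d_r), d_a = as.integer(d_a),
                 d_o = as.integer(d_o), d_g = as.integer(d_g),
                 scheme = scheme, use_positions = use_positions,
                 loss_id = loss_id),
            class = "peprank_config")
}

.d_in <- function(config) {
  config$scheme$d_e + if (config$use_positions) 2L * config$d_o else 0L
}

.glorot <- function(nrow, ncol) {
  s <- sqrt(6 / (nrow + ncol))
  matrix(runif(nrow * ncol, -s, s), nrow, ncol)
}

#' Initialize a scoring model
#'
#' Creates a `peprank_model`: a [model_config()] plus all learnable
#' parameters (local kernels, batch-norm affine parameters and running
#' statistics, attention parameters, optional global kernels, fully-connected
#' head, learned residue-encoding table, dual-end position tables).
#'
#' @param config A [model_config()].
#' @param seed Integer seed for the parameter initializer.
#' @return An object of class `peprank_model`.
#' @export
init_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "peprank_config"))
  withr::with_seed(seed, {
    d_in <- .d_in(config)
    p <- list(
      Wc = .glorot(config$d_r, d_in * config$k),
      bc = numeric(config$d_r),
      gamma = rep(1, config$d_r),
      beta = numeric(config$d_r),
      Wa = .glorot(config$d_a, config$d_r),
      ba = numeric(config$d_a),
      va = drop(.glorot(config$d_a, 1L)),
      Wh = NULL, bh = numeric(config$d_r),
      w_out = drop(.glorot(config$d_r, 1L)),
      b_out = 0
    )
    d_u <- config$d_r + if (config$architecture == "spconvm") config$d_g else 0L
    p$Wh <- .glorot(config$d_r, d_u)
    if (config$architecture == "spconvm") {
      p$Wg <- .glorot(config$d_g, config$scheme$d_e * 15L)
      p$bg <- numeric(config$d_g)
    }
    if ("deep" %in% config$scheme$components) {
      p$deep <- matrix(rnorm(400, 0, 0.1), 20, 20,
                       dimnames = list(NULL, aa_alphabet()))
    }
    if (config$use_positions) {
      pos <- position_tables(config$d_o)
      p$c_pos <- pos$c_table
      p$n_pos <- pos$n_table
    }
    run <- list(mean = numeric(config$d_r), var = rep(1, config$d_r))
    structure(list(config = config, params = p, run_stats = run,
                   trained = FALSE),
              class = "peprank_model")
  })
}

#' @export
print.peprank_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<peprank_model> %s | k=%d d_r=%d d_a=%d%s | scheme=%s%s | loss=%s | %s\n",
              toupper(cfg$architecture), cfg$k, cfg$d_r, cfg$d_a,
              if (cfg$architecture == "spconvm") sprintf(" d_g=%d", cfg$d_g) else "",
              paste(cfg$scheme$components, collapse = "+"),
              if (cfg$use_positions) sprintf(" | d_o=%d", cfg$d_o) else " | no positions",
              cfg$loss_id,
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

.bn_eps <- 1e-5
.bn_momentum <- 0.1

# Full forward pass over a character vector of peptides.
# mode "train" uses batch statistics in batch norm (and returns updated
# running statistics); mode "eval" uses the stored running statistics.
# Returns list(score, w, group, L, cache, run_stats).
.forward <- function(peptides, config, params, run_stats, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  k <- config$k
  idx <- .peptide_indices(peptides)
  nvec <- lengths(idx)
  if (any(nvec < 8 | nvec > 15)) {
    abort("peptide length must be 8-15.", class = "peprank_encoding_error")
  }
  if (any(nvec < k)) {
    abort("peptide shorter than the local kernel size.", class = "peprank_config_error")
  }
  m <- length(peptides)
  enc <- .encoding_table(config$scheme, params$deep)
  res_idx <- unlist(idx, use.names = FALSE)
  F_all <- enc[, res_idx, drop = FALSE]
  cpos_idx <- npos_idx <- NULL
  if (config$use_positions) {
    cpos_idx <- unlist(lapply(nvec, seq_len), use.names = FALSE)
    npos_idx <- unlist(lapply(nvec, function(n) n - seq_len(n) + 1L), use.names = FALSE)
    F_all <- rbind(F_all,
                   params$c_pos[, cpos_idx, drop = FALSE],
                   params$n_pos[, npos_idx, drop = FALSE])
  }
  # im2col over k-mer windows: X column i of peptide p stacks F columns
  # i..i+k-1; base_idx holds the global F column of each window start.
  Lvec <- nvec - k + 1L
  starts <- cumsum(c(0L, nvec[-m]))
  base_idx <- unlist(lapply(seq_len(m), function(p) starts[p] + seq_len(Lvec[p])),
                     use.names = FALSE)
  X <- if (k == 1L) F_all else {
    do.call(rbind, lapply(seq_len(k), function(t) F_all[, base_idx + t - 1L, drop = FALSE]))
  }
  Z <- params$Wc %*% X + params$bc
  M <- ncol(Z)
  if (mode == "train") {
    mu <- rowMeans(Z)
    va_ <- rowMeans((Z - mu)^2)
    run_stats <- list(mean = (1 - .bn_momentum) * run_stats$mean + .bn_momentum * mu,
                      var  = (1 - .bn_momentum) * run_stats$var + .bn_momentum * va_)
  } else {
    mu <- run_stats$mean
    va_ <- run_stats$var
  }
  istd <- 1 / sqrt(va_ + .bn_eps)
  Zhat <- (Z - mu) * istd
  ZB <- params$gamma * Zhat + params$beta
  Rm <- pmax(ZB, 0)
  # attention pooling
  Hm <- tanh(params$Wa %*% Rm + params$ba)
  a <- drop(crossprod(params$va, Hm))
  group <- rep.int(seq_len(m), Lvec)
  amax <- vapply(split(a, group), max, numeric(1), USE.NAMES = FALSE)
  ew <- exp(a - amax[group])
  esum <- unname(drop(rowsum(ew, group, reorder = FALSE)))
  w <- unname(ew / esum[group])
  Cmat <- t(rowsum(t(Rm) * w, group, reorder = FALSE))  # d_r x m
  cache <- list(peptides = peptides, idx = idx, nvec = nvec, Lvec = Lvec,
                group = group, res_idx = res_idx, cpos_idx = cpos_idx,
                npos_idx = npos_idx, base_idx = base_idx,
                X = X, Zhat = Zhat, istd = istd, ZB = ZB, Rm = Rm, Hm = Hm,
                w = w, Cmat = Cmat, mode = mode, M = M)
  if (config$architecture == "spconvm") {
    d_e <- config$scheme$d_e
    VG <- matrix(0, d_e * 15L, m)
    slot_of <- lapply(nvec, .pad_slots)
    for (p in seq_len(m)) {
      sl <- slot_of[[p]]
      rows <- rep((sl - 1L) * d_e, each = d_e) + seq_len(d_e)
      VG[rows, p] <- enc[, idx[[p]]]
    }
    gpre <- params$Wg %*% VG + params$bg
    g <- pmax(gpre, 0)
    U <- rbind(Cmat, g)
    cache$VG <- VG
    cache$gpre <- gpre
    cache$slot_of <- slot_of
  } else {
    U <- Cmat
  }
  hpre <- params$Wh %*% U + params$bh
  h <- pmax(hpre, 0)
  s_lin <- unname(drop(crossprod(params$w_out, h))) + params$b_out
  score <- if (config$loss_id == "ms") plogis(s_lin) else s_lin
  cache$U <- U
  cache$hpre <- hpre
  cache$h <- h
  cache$s_lin <- s_lin
  cache$score <- score
  list(score = score, w = w, group = group, L = Lvec, cache = cache,
       run_stats = run_stats)
}

#' Score peptides with a model
#'
#' Runs the forward pass in evaluation mode (batch normalization uses the
#' stored running statistics, so a peptide's score does not depend on what
#' else is in the batch). Models configured for the mean-square loss return
#' sigmoid-normalized scores in (0, 1); ranking-loss models return unbounded
#' scores.
#'
#' @param peptides Character vector of peptides, or a data frame with a
#'   `peptide` column.
#' @param model A `peprank_model`.
#' @return A tibble with columns `peptide` and `score`.
#' @export
score_peptides <- function(peptides, model) {
  stopifnot(inherits(model, "peprank_model"))
  if (is.data.frame(peptides)) peptides <- peptides$peptide
  fw <- .forward(peptides, model$config, model$params, model$run_stats, mode = "eval")
  tibble::tibble(peptide = peptides, score = fw$score)
}

#' @rdname score_peptides
#' @param object A `peprank_model`.
#' @param newdata Peptides as in `score_peptides()`.
#' @param ... Unused.
#' @export
predict.peprank_model <- function(object, newdata, ...) {
  score_peptides(newdata, object)
}

#' Attention pooling of a k-mer embedding matrix
#'
#' Computes the self-attention weights `w_i = softmax(v tanh(W r_i + b))`
#' over the columns of an embedding matrix and the pooled embedding
#' `c = sum_i w_i r_i`. This is the reference single-peptide form of the
#' pooling layer; the model's batched forward pass computes the same
#' quantities.
#'
#' @param R A `d_r x L` embedding matrix (columns = k-mer embeddings, L >= 1).
#' @param W A `d_a x d_r` weight matrix.
#' @param b Bias vector of length `d_a`.
#' @param v Scoring vector of length `d_a`.
#' @return A list with `c` (pooled embedding, length `d_r`) and `w`
#'   (attention weights, length `L`, positive, summing to 1).
#' @export
attention_pool <- function(R, W, b, v) {
  if (ncol(R) < 1) abort("R needs at least one column.", class = "peprank_config_error")
  a <- unname(drop(crossprod(v, tanh(W %*% R + b))))
  e <- exp(a - max(a))
  w <- e / sum(e)
  list(c = unname(drop(R %*% w)), w = w)
}
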