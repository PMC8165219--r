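# Shared fixtures: small consolidated tables and tiny model configs.

# A small consolidated training table spanning several binding levels,
# generated from the synthetic allele so affinities carry real structure.
toy_consolidated <- function(n = 120, seed = 1, noise_sd = 0.05) {
  al <- synthetic_allele(noise_sd = noise_sd, qualitative_fraction = 0.1,
                         conflict_rate = 0, seed = 1)
  gen <- generate_dataset(al, n, seed = seed)
  suppressWarnings(preprocess_affinities(gen$data))
}

tiny_config <- function(architecture = "convm", loss_id = "hv", k = 1L,
                        scheme = "onehot", ...) {
  model_config(architecture = architecture, k = k, d_r = 6L, d_a = 4L,
               d_o = 2L, d_g = 3L, scheme = scheme, loss_id = loss_id, ...)
}

fast_control <- function(max_epochs = 8L, ...) {
  train_control(batch_size = 32L, max_epochs = max_epochs, ...)
}

# Brute-force metric oracles, written directly from the definitions and kept
# independent of the package implementations.
oracle_ranks <- function(score) {
  ord <- order(-score)
  r <- integer(length(score)); r[ord] <- seq_along(score); r
}
oracle_ar <- function(score, ic50, h) {
  pos <- which(ic50 < h)
  if (length(pos) == 0) return(NA_real_)
  mean(oracle_ranks(score)[pos])
}
oracle_hr <- function(score, ic50, h) {
  pos <- which(ic50 < h)
  t <- length(pos)
  if (t == 0) return(NA_real_)
  top <- which(oracle_ranks(score) <= t)
  length(intersect(top, pos)) / t
}
oracle_auc <- function(score, ic50, h = 500) {
  pos <- score[ic50 < h]; neg <- score[ic50 >= h]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q)
  tot / (length(pos) * length(neg))
}
oracle_roc_t <- function(score, ic50, t, h = 500) {
  pos <- score[ic50 < h]; neg <- score[ic50 >= h]
  if (length(pos) == 0 || length(neg) < t) return(NA_real_)
  negtop <- sort(neg, decreasing = TRUE)[seq_len(t)]
  tot <- 0
  for (p in pos) for (q in negtop) tot <- tot + (p > q)
  tot / (length(pos) * t)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
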