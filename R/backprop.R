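# Analytic gradients of the scoring models.
#
# .backward() consumes the cache of a training-mode .forward() call and the
# gradient of the loss with respect to each peptide's final score, and returns
# gradients for every learnable parameter. Batch normalization is
# differentiated through the batch statistics (the training-time path).

.backward <- function(dscore, config, params, cache) {
  m <- length(dscore)
  d_r <- config$d_r
  k <- config$k

  # output head (and sigmoid when the model squashes scores)
  ds <- if (config$loss_id == "ms") {
    dscore * cache$score * (1 - cache$score)
  } else dscore
  g <- list()
  g$w_out <- drop(cache$h %*% ds)
  g$b_out <- sum(ds)
  dh <- (params$w_out %o% ds) * (cache$hpre > 0)
  g$Wh <- dh %*% t(cache$U)
  g$bh <- rowSums(dh)
  dU <- crossprod(params$Wh, dh)

  dC <- dU[seq_len(d_r), , drop = FALSE]
  if (config$architecture == "spconvm") {
    dg <- dU[d_r + seq_len(config$d_g), , drop = FALSE] * (cache$gpre > 0)
    g$Wg <- dg %*% t(cache$VG)
    g$bg <- rowSums(dg)
    if (!is.null(params$deep)) {
      dVG <- crossprod(params$Wg, dg)  # (d_e*15) x m
      g$deep <- matrix(0, 20, 20)
      d_e <- config$scheme$d_e
      deep_off <- 20L * (match("deep", config$scheme$components) - 1L)
      for (p in seq_len(m)) {
        sl <- cache$slot_of[[p]]
        for (t in seq_along(sl)) {
          rows <- (sl[t] - 1L) * d_e + deep_off + seq_len(20L)
          aa <- cache$idx[[p]][t]
          g$deep[, aa] <- g$deep[, aa] + dVG[rows, p]
        }
      }
    }
  }

  # attention pooling: C_g = sum_i w_i r_i
  w <- cache$w
  group <- cache$group
  dR_pool <- dC[, group, drop = FALSE] * rep(w, each = d_r)
  dw <- colSums(cache$Rm * dC[, group, drop = FALSE])
  # softmax backward within each peptide
  wdw_sum <- drop(rowsum(w * dw, group, reorder = FALSE))
  da <- w * (dw - wdw_sum[group])
  g$va <- drop(cache$Hm %*% da)
  dHm <- (params$va %o% da) * (1 - cache$Hm^2)
  g$Wa <- dHm %*% t(cache$Rm)
  g$ba <- rowSums(dHm)
  dR <- dR_pool + crossprod(params$Wa, dHm)

  # ReLU and batch normalization (batch-statistics path)
  dZB <- dR * (cache$ZB > 0)
  g$gamma <- rowSums(dZB * cache$Zhat)
  g$beta <- rowSums(dZB)
  dZhat <- dZB * params$gamma
  M <- cache$M
  dZ <- (cache$istd / M) *
    (M * dZhat - rowSums(dZhat) - cache$Zhat * rowSums(dZhat * cache$Zhat))

  # local convolution
  g$Wc <- dZ %*% t(cache$X)
  g$bc <- rowSums(dZ)
  dX <- crossprod(params$Wc, dZ)

  # col2im: scatter window gradients back onto feature columns
  d_in <- nrow(dX) / k
  dF <- matrix(0, d_in, sum(cache$nvec))
  for (t in seq_len(k)) {
    cols <- cache$base_idx + t - 1L
    dF[, cols] <- dF[, cols] + dX[(t - 1L) * d_in + seq_len(d_in), , drop = FALSE]
  }

  # feature columns -> learnable tables
  if (!is.null(params$deep)) {
    deep_rows <- 20L * (match("deep", config$scheme$components) - 1L) + seq_len(20L)
    acc <- rowsum(t(dF[deep_rows, , drop = FALSE]), cache$res_idx, reorder = FALSE)
    gdeep <- matrix(0, 20, 20)
    gdeep[, as.integer(rownames(acc))] <- t(acc)
    g$deep <- if (is.null(g$deep)) gdeep else g$deep + gdeep
  }
  if (config$use_positions) {
    d_e <- config$scheme$d_e
    crows <- d_e + seq_len(config$d_o)
    nrows <- d_e + config$d_o + seq_len(config$d_o)
    cacc <- rowsum(t(dF[crows, , drop = FALSE]), cache$cpos_idx, reorder = FALSE)
    nacc <- rowsum(t(dF[nrows, , drop = FALSE]), cache$npos_idx, reorder = FALSE)
    g$c_pos <- matrix(0, config$d_o, 15)
    g$n_pos <- matrix(0, config$d_o, 15)
    g$c_pos[, as.integer(rownames(cacc))] <- t(cacc)
    g$n_pos[, as.integer(rownames(nacc))] <- t(nacc)
  }
  g
}

# One SGD step: params <- params - lr * grads, over the parameters present in
# the gradient list.
.sgd_step <- function(params, grads, lr) {
  for (nm in names(grads)) {
    params[[nm]] <- params[[nm]] - lr * grads[[nm]]
  }
  params
}
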