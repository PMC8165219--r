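test_that("local convolution yields one embedding per k-mer and zero kernels give zeros", {
  for (k in c(1L, 3L)) {
    cfg <- tiny_config(k = k)
    m <- init_model(cfg, seed = 1)
    fw <- peprank:::.forward("SLYNTVATL", cfg, m$params, m$run_stats, mode = "eval")
    expect_identical(ncol(fw$cache$Rm), 9L - k + 1L)
  }
  cfg <- tiny_config(k = 2)
  m <- init_model(cfg, seed = 1)
  m$params$Wc[] <- 0
  m$params$bc[] <- 0
  m$params$beta[] <- 0
  m$run_stats$mean[] <- 0
  m$run_stats$var[] <- 1
  fw <- peprank:::.forward("SLYNTVATL", cfg, m$params, m$run_stats, mode = "eval")
  expect_true(all(fw$cache$Rm == 0))
  expect_error(
    peprank:::.forward("ACDEFGHI", model_config(k = 8), init_model(model_config(k = 8))$params,
                       init_model(model_config(k = 8))$run_stats),
    NA)
})

test_that("attention weights form a proper distribution and match the reference pooling", {
  withr::with_seed(11, {
    for (i in 1:10) {
      arch <- sample(c("convm", "spconvm"), 1)
      cfg <- tiny_config(architecture = arch, k = sample(1:3, 1),
                         scheme = sample(c("onehot", "blosum+deep"), 1))
      m <- init_model(cfg, seed = i)
      peps <- vapply(sample(8:15, 4, replace = TRUE), function(n) {
        paste(sample(aa_alphabet(), n, replace = TRUE), collapse = "")
      }, character(1))
      fw <- peprank:::.forward(peps, cfg, m$params, m$run_stats, mode = "eval")
      sums <- tapply(fw$w, fw$group, sum)
      expect_equal(as.numeric(sums), rep(1, 4), tolerance = 1e-12)
      expect_true(all(fw$w > 0 & fw$w < 1 + 1e-12))
      # dual route: the batched pass equals per-peptide reference pooling
      cols <- split(seq_along(fw$group), fw$group)
      for (p in seq_along(peps)) {
        ref <- attention_pool(fw$cache$Rm[, cols[[p]], drop = FALSE],
                              m$params$Wa, m$params$ba, m$params$va)
        expect_equal(fw$w[cols[[p]]], ref$w, tolerance = 1e-12)
        expect_equal(unname(fw$cache$Cmat[, p]), unname(ref$c), tolerance = 1e-12)
      }
    }
  })
})

test_that("reference attention pooling reproduces hand-computed softmax cases", {
  # logits (0, ln 3) -> weights (0.25, 0.75): d_a = 1, tanh bypassed via large
  # saturation is avoided by choosing R so that W R + b stays in linear range
  R <- matrix(c(0, log(3)), nrow = 1)       # d_r = 1, two k-mers
  out <- attention_pool(R, W = matrix(1e-8, 1, 1), b = 0, v = 1)
  expect_equal(out$w, c(0.5, 0.5), tolerance = 1e-6)  # equal logits -> uniform
  # direct logits via tanh-linear region: v * tanh(W r + b) ~ a for small a
  out2 <- attention_pool(R, W = matrix(0, 1, 1), b = 0, v = 1)
  expect_equal(out2$w, c(0.5, 0.5))
  expect_equal(out2$c, mean(R))
  # exact (0.25, 0.75) with an explicit construction: atanh recovers logits
  W <- matrix(1, 1, 1)
  Rx <- matrix(atanh(c(0, tanh(log(3)))), nrow = 1)
  out3 <- attention_pool(Rx, W = W, b = 0, v = log(3) / tanh(log(3)))
  expect_equal(out3$w, c(0.25, 0.75), tolerance = 1e-12)
  # single column -> weight 1 and c = r_1
  out4 <- attention_pool(matrix(c(1, 2)), W = matrix(0, 1, 2), b = 0, v = 1)
  expect_equal(out4$w, 1)
  expect_equal(out4$c, c(1, 2))
})

test_that("evaluation-mode scores are invariant to batch composition", {
  for (arch in c("convm", "spconvm")) {
    cfg <- tiny_config(architecture = arch, scheme = "blosum+onehot+deep")
    m <- init_model(cfg, seed = 3)
    peps <- c("SLYNTVATL", "GILGFVFTLQ", "ACDEFGHI", "WWYYHHKKRRAML")
    alone <- vapply(peps, function(p) score_peptides(p, m)$score, numeric(1))
    together <- score_peptides(peps, m)$score
    expect_equal(unname(alone), together, tolerance = 1e-6)
    shuffled <- score_peptides(rev(peps), m)$score
    expect_equal(rev(together), shuffled, tolerance = 1e-6)
  }
})

test_that("the pooled embedding of spconvm concatenates local and global parts", {
  cfg <- tiny_config(architecture = "spconvm")
  m <- init_model(cfg, seed = 2)
  fw <- peprank:::.forward("SLYNTVATL", cfg, m$params, m$run_stats, mode = "eval")
  expect_identical(nrow(fw$cache$U), cfg$d_r + cfg$d_g)
})

test_that("disabling position embeddings removes all positional influence", {
  cfg <- tiny_config(use_positions = FALSE)
  m <- init_model(cfg, seed = 5)
  s1 <- score_peptides("SLYNTVATL", m)$score
  # injected position tables must be dead parameters
  m$params$c_pos <- matrix(100, 2, 15)
  m$params$n_pos <- matrix(-100, 2, 15)
  expect_equal(score_peptides("SLYNTVATL", m)$score, s1)
})

test_that("mean-square-configured models emit sigmoid scores in (0,1)", {
  cfg <- tiny_config(loss_id = "ms")
  m <- init_model(cfg, seed = 4)
  s <- score_peptides(c("SLYNTVATL", "ACDEFGHI"), m)$score
  expect_true(all(s > 0 & s < 1))
})

test_that("backpropagated gradients match finite differences", {
  fd_check <- function(arch, loss_id, seed) {
    cfg <- model_config(arch, k = 2, d_r = 5, d_a = 4, d_o = 3, d_g = 3,
                        scheme = "blosum+deep", loss_id = loss_id)
    m <- init_model(cfg, seed = seed)
    peps <- c("SLYNTVATL", "GILGFVFTLQ", "ACDEFGHI", "WWYYHHKKRRA")
    entries <- tibble::tibble(peptide = peps,
                              kind = c("quantitative", "qualitative",
                                       "quantitative", "qualitative"),
                              b = c(0.8, 0.6, 0.3, 0.1),
                              level = c(5L, 4L, 2L, 1L))
    pairs <- tibble::tibble(i = c(1L, 2L, 1L), j = c(3L, 4L, 4L),
                            b_i = entries$b[c(1, 2, 1)], b_j = entries$b[c(3, 4, 4)],
                            l_i = entries$level[c(1, 2, 1)], l_j = entries$level[c(3, 4, 4)])
    loss_of <- function(params) {
      fw <- peprank:::.forward(peps, cfg, params, m$run_stats, mode = "train")
      peprank:::.batch_loss_grad(fw$score, loss_id, pairs = pairs, entries = entries)$loss
    }
    fw <- peprank:::.forward(peps, cfg, m$params, m$run_stats, mode = "train")
    lg <- peprank:::.batch_loss_grad(fw$score, loss_id, pairs = pairs, entries = entries)
    gr <- peprank:::.backward(lg$dscore, cfg, m$params, fw$cache)
    eps <- 1e-6
    for (nm in names(gr)) {
      sel <- if (length(gr[[nm]]) > 4) sample.int(length(gr[[nm]]), 4) else seq_along(gr[[nm]])
      for (ii in sel) {
        p2 <- m$params
        p2[[nm]][ii] <- p2[[nm]][ii] + eps
        lp <- loss_of(p2)
        p2[[nm]][ii] <- p2[[nm]][ii] - 2 * eps
        lm <- loss_of(p2)
        num <- (lp - lm) / (2 * eps)
        ana <- gr[[nm]][ii]
        denom <- max(abs(num), abs(ana))
        if (denom > 1e-10) {
          expect_lt(abs(num - ana) / denom, 1e-4)
        }
      }
    }
  }
  withr::with_seed(21, {
    fd_check("convm", "hv", seed = 7)
    fd_check("spconvm", "ms", seed = 8)
    fd_check("convm", "hi", seed = 9)
  })
})
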