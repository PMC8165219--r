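test_that("the schedule decays by 10% per stale patience window and stops at 20", {
  ctl <- train_control()
  st <- schedule_init(ctl)
  st <- schedule_step(st, 1.0)           # first loss always improves
  expect_equal(st$lr, 0.05)
  # frozen validation loss: decay at stale 5, 10, 15, 20; stop at 20
  lrs <- numeric(20)
  for (i in 1:20) {
    st <- schedule_step(st, 1.0)
    lrs[i] <- st$lr
    if (i < 20) expect_false(st$stop)
  }
  expect_equal(lrs[4], 0.05)
  expect_equal(lrs[5], 0.045)
  expect_equal(lrs[10], 0.05 * 0.9^2)    # 0.0405 after two decay events
  expect_equal(lrs[10], 0.0405)
  expect_true(st$stop)                   # fires exactly at patience 20
  # an improvement resets the stale counter
  st2 <- schedule_init(ctl)
  st2 <- schedule_step(st2, 1.0)
  for (i in 1:4) st2 <- schedule_step(st2, 1.0)
  st2 <- schedule_step(st2, 0.5)
  expect_equal(st2$stale, 0L)
  expect_equal(st2$lr, 0.05)
  # sub-tolerance wiggle does not count as improvement
  st3 <- schedule_step(st2, 0.5 - 1e-8)
  expect_equal(st3$stale, 1L)
})

test_that("pair batches respect the loss-specific level constraints", {
  entries <- tibble::tibble(peptide = paste0("P", 1:6),
                            b = c(0.9, 0.85, 0.8, 0.1, 0.15, 0.2),
                            level = c(5L, 5L, 5L, 1L, 1L, 1L))
  withr::with_seed(3, {
    pv <- sample_pair_batch(entries, "hv", 50)
    expect_true(all(pv$l_i > pv$l_j))
    expect_true(all(pv$l_i == 5L & pv$l_j == 1L))
    pi_ <- sample_pair_batch(entries, "hi", 200)
    expect_true(all(pi_$l_i >= pi_$l_j))
    expect_true(any(pi_$l_i == pi_$l_j))   # same-level pairs permitted
  })
  single <- dplyr::filter(entries, level == 5L)
  expect_error(sample_pair_batch(single, "hv", 10), class = "peprank_no_valid_pairs")
  # determinism under a fixed seed
  p1 <- withr::with_seed(7, sample_pair_batch(entries, "hl", 30))
  p2 <- withr::with_seed(7, sample_pair_batch(entries, "hl", 30))
  expect_identical(p1, p2)
})

test_that("training is reproducible and improves the validation loss on separable data", {
  dat <- toy_consolidated(n = 400, seed = 2, noise_sd = 0)
  cfg <- model_config("convm", k = 1, d_r = 8L, d_a = 4L, scheme = "onehot",
                      loss_id = "hv")
  ctl <- fast_control(max_epochs = 30L)
  fit1 <- train_model(dat, cfg, ctl, seed = 11)
  fit2 <- train_model(dat, cfg, ctl, seed = 11)
  expect_equal(fit1$params, fit2$params)
  expect_identical(fit1$log, fit2$log)
  # separable fixture: validation loss drops below its starting value
  expect_lt(min(fit1$log$val_loss), fit1$log$val_loss[1])
  expect_identical(fit1$best_epoch, which.min(fit1$log$val_loss))
  expect_s3_class(tidy(fit1), "tbl_df")
  expect_identical(nrow(glance(fit1)), 1L)
})

test_that("hinge training requires two levels and ms training does not", {
  dat <- toy_consolidated(n = 60, seed = 5)
  flat <- dplyr::mutate(dat, level = 3L)
  expect_error(train_model(flat, tiny_config(loss_id = "hv"), fast_control(max_epochs = 2L)),
               class = "peprank_no_valid_pairs")
  fit <- train_model(flat, tiny_config(loss_id = "ms"), fast_control(max_epochs = 2L))
  expect_s3_class(fit, "peprank_fit")
})

test_that("ranking training tolerates within-level affinity perturbation at least as well as regression", {
  # perturb 20% of training b values within their level band; compare held-out
  # AUC of hinge- vs mean-square-trained models over seeds
  deltas <- numeric(3)
  for (s in 1:3) {
    al <- synthetic_allele(noise_sd = 0.05, qualitative_fraction = 0,
                           conflict_rate = 0, seed = 1)
    gen <- generate_dataset(al, 600, seed = 400 + s)
    cons <- suppressWarnings(preprocess_affinities(gen$data))
    test_pep <- withr::with_seed(s, sample(cons$peptide, 120))
    train_dat <- dplyr::filter(cons, !.data$peptide %in% test_pep)
    train_dat <- withr::with_seed(s, {
      hit <- runif(nrow(train_dat)) < 0.2
      lo <- c(5000, 1000, 500, 100, 1)[train_dat$level]
      hi <- c(50000, 5000, 1000, 500, 100)[train_dat$level]
      x <- runif(nrow(train_dat), lo, hi)
      dplyr::mutate(train_dat,
                    ic50 = ifelse(hit, x, .data$ic50),
                    b = ifelse(hit, normalize_affinity(x), .data$b))
    })
    ctl <- train_control(batch_size = 32L, max_epochs = 40L)
    truth <- gen$truth[match(test_pep, gen$truth$peptide), ]
    auc_of <- function(loss) {
      fit <- train_model(train_dat, model_config("convm", k = 1, d_r = 8L, d_a = 4L,
                                                 scheme = "onehot", loss_id = loss),
                         ctl, seed = s)
      preds <- score_peptides(test_pep, fit)
      preds$ic50 <- truth$ic50
      ranking_auc(preds)
    }
    deltas[s] <- auc_of("hv") - auc_of("ms")
  }
  expect_true(all(deltas >= -0.02))
})
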