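test_that("cross-entropy losses match closed forms", {
  y <- rbind(c(1, 0), c(0, 1))
  expect_equal(bce_loss(matrix(0.5, 2, 2), y), log(2), tolerance = 1e-12)
  expect_lte(bce_loss(y, y), 1e-6)
  expect_equal(bce_loss(rbind(c(0.8, 0.2)), rbind(c(1, 0))),
               -(log(0.8) + log(0.8)) / 2, tolerance = 1e-6)
  expect_equal(round(bce_loss(rbind(c(0.8, 0.2)), rbind(c(1, 0))), 4), 0.2231)
  expect_error(bce_loss(c(0.5, 0.5), c(1)), "shapes")
  expect_equal(categorical_ce(rbind(c(0.7, 0.2, 0.1)), rbind(c(1, 0, 0))),
               -log(0.7), tolerance = 1e-12)
})

test_that("learning rate warms up linearly then decays to zero", {
  ctl <- lncloc_control(lr_peak = 3e-4, warmup_epochs = 4, max_epochs = 20)
  spe <- 10
  expect_equal(lr_at(0, spe, ctl), 0)
  expect_equal(lr_at(40, spe, ctl), 3e-4)            # end of warm-up
  expect_equal(lr_at(200, spe, ctl), 0)              # final step
  steps <- 0:200
  lrs <- lr_at(steps, spe, ctl)
  expect_equal(max(lrs), 3e-4)
  expect_equal(sum(lrs == max(lrs)), 1L)             # single peak
  expect_true(all(diff(lrs[1:41]) > 0))
  expect_true(all(diff(lrs[41:201]) < 0))
  # continuity at the junction
  expect_lt(abs(lr_at(40, spe, ctl) - lr_at(39, spe, ctl)), 3e-4 / 39)
})

test_that("control validation rejects impossible settings", {
  expect_error(lncloc_control(max_epochs = 0), "nothing to train")
  expect_error(lncloc_control(warmup_epochs = 10, max_epochs = 5), "warmup")
  expect_error(lncloc_control(batch_size = 0), "batch_size")
})

test_that("strict 0.5 call rule", {
  p <- rbind(c(0.6, 0.5, 0.4, 0.51))
  expect_equal(unname(lncloc:::calls_from_probs(p)), rbind(c(1L, 0L, 0L, 1L)))
})

make_tiny_dataset <- function(n = 10, seed = 1) {
  lncloc_simulate(synthetic_config(n_samples = n, length_range = c(200, 400),
                                   seed = seed))
}

tiny_fit <- function(ds, seed = 3, epochs = 3, ...) {
  cfg <- lncloc_config(n_blocks = 1L, n_heads = 2L, hidden = 8L,
                       head_dim = 4L, ffn_dim = 16L, n_max = 16L,
                       max_rel_dist = 5L, k = 2L, ...)
  ctl <- lncloc_control(max_epochs = epochs, warmup_epochs = 1L,
                        batch_size = 8L, val_fraction = 0, seed = seed,
                        lr_peak = 1e-3)
  emb <- train_kmer_embeddings(ds$records, k = 2, d = 8, epochs = 1,
                               seed = seed)
  lncloc(ds$records, ds$labels, cfg, ctl, embeddings = emb)
}

test_that("training is reproducible given the master seed", {
  ds <- make_tiny_dataset()
  f1 <- tiny_fit(ds)
  f2 <- tiny_fit(ds)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
  expect_identical(fitted(f1), fitted(f2))
  f3 <- tiny_fit(ds, seed = 4)
  expect_false(identical(fitted(f1), fitted(f3)))
})

test_that("fit objects expose the standard modelling methods", {
  ds <- make_tiny_dataset(12)
  fit <- tiny_fit(ds)
  expect_s3_class(fit, "lncloc_fit")
  expect_equal(nrow(fit$history), 3)
  expect_output(print(fit), "Localization Transformer")
  expect_output(summary(fit), "parameters")
  expect_named(coef(fit), c("blocks", "head", "embed"))
  r <- residuals(fit)
  expect_equal(dim(r), dim(ds$labels))
  expect_equal(unname(r), unname(ds$labels - fitted(fit)))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("prediction is batch-independent, ordered, and repeatable", {
  ds <- make_tiny_dataset(8, seed = 2)
  fit <- tiny_fit(ds)
  all8 <- predict(fit, ds$records)
  again <- predict(fit, ds$records)
  expect_identical(all8$probabilities, again$probabilities)
  singles <- do.call(rbind, lapply(ds$records, function(r)
    predict(fit, list(r))$probabilities))
  expect_identical(unname(all8$probabilities), unname(singles))
  expect_equal(all8$ids, vapply(ds$records, `[[`, character(1), "id"))
  expect_equal(unname(all8$calls),
               unname(matrix(as.integer(all8$probabilities > 0.5), 8, 4)))
  empty <- predict(fit, list())
  expect_length(empty$ids, 0)
})

test_that("checkpoints round-trip and reject foreign content", {
  ds <- make_tiny_dataset(8, seed = 5)
  fit <- tiny_fit(ds)
  f <- withr::local_tempfile(fileext = ".rds")
  save_lncloc(fit, f)
  back <- load_lncloc(f)
  expect_identical(back$params, fit$params)
  expect_identical(predict(back, ds$records[1:2])$probabilities,
                   predict(fit, ds$records[1:2])$probabilities)
  saveRDS(list(a = 1), f)
  expect_error(load_lncloc(f), "incompatible")
  expect_error(load_lncloc(tempfile()), "not found")
})

test_that("training rejects empty input and label mismatches", {
  ds <- make_tiny_dataset(6, seed = 6)
  cfg <- lncloc_config(n_blocks = 1L, n_heads = 1L, hidden = 8L,
                       head_dim = 4L, ffn_dim = 8L, n_max = 8L, k = 2L)
  ctl <- lncloc_control(max_epochs = 1, warmup_epochs = 0, val_fraction = 0)
  expect_error(lncloc(list(), ds$labels, cfg, ctl), "empty")
  bad <- ds$labels[1:3, ]
  expect_error(lncloc(ds$records, bad, cfg, ctl), "no labels for")
  zero <- ds$labels; zero[1, ] <- 0L
  expect_error(lncloc(ds$records, zero, cfg, ctl), "without any positive")
})
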