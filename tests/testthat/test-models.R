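test_that("convolve1d matches its definition and the brute-force oracle", {
  expect_equal(convolve1d(c(1, 2, 3, 4), 1), c(1, 2, 3, 4))
  expect_equal(convolve1d(c(1, 2, 3), c(1, 1)), c(3, 5))
  expect_equal(convolve1d(numeric(5), c(2, 3)), numeric(4))
  withr::with_seed(1, {
    for (i in 1:20) {
      n <- sample(3:20, 1)
      m <- sample(seq_len(n), 1)
      f <- rnorm(n)
      g <- rnorm(m)
      brute <- vapply(seq_len(n - m + 1), function(i) {
        s <- 0
        for (j in seq_len(m)) s <- s + g[j] * f[i + j - 1]
        s
      }, numeric(1))
      expect_equal(convolve1d(f, g), brute, tolerance = 1e-12)
    }
  })
  expect_error(convolve1d(1:2, 1:3), "longer than")
})

test_that("architecture shape arithmetic admits N=7 and rejects N=3", {
  m <- build_cnn(cnn_config(), n = 7)
  expect_equal(m$arch$flatten_dim, 16L)  # 16 filters x length 1
  expect_error(build_cnn(cnn_config(), n = 3), "convolution block 2")
  # parameter count is deterministic given the config
  np <- sum(vapply(m$weights, length, numeric(1)))
  expect_equal(np, 8 * 8 + 8 + 2 * 8 * 16 + 16 + 16 * 16 + 16 + 16 * 2 + 2)
})

test_that("weight initialization is reproducible from the seed", {
  a <- build_cnn(cnn_config(seed = 42), n = 7)
  b <- build_cnn(cnn_config(seed = 42), n = 7)
  expect_identical(a$weights, b$weights)
  c <- build_cnn(cnn_config(seed = 43), n = 7)
  expect_false(identical(a$weights, c$weights))
})

test_that("gradient reversal is identity forward and -lambda backward", {
  g <- c(0.3, -1.2, 4)
  expect_equal(grl_backward(g, 1), -g)
  expect_equal(grl_backward(g, 0), c(0, 0, 0))
  expect_equal(grl_backward(g, 2.5), -2.5 * g)
  expect_error(grl_backward(g, -1), "lambda")
})

test_that("analytic gradients match finite differences of the full adversarial objective", {
  wd <- separable_windows(12, seed = 3)
  wd$domain <- rep(c("target", "source"), 6)
  model <- build_cnn(cnn_config(seed = 7), n = 7, domain_head_units = 8)
  lambda <- 0.7
  gr <- model_gradients(model, wd, lambda = lambda)
  eps <- 1e-6
  loss_at <- function(m) model_losses(m, wd, lambda = lambda)
  # extractor params follow label - lambda * domain (through the GRL);
  # the label head follows the label loss, the domain head the domain loss
  objective <- function(nm, losses) {
    if (nm %in% c("Wdm", "bdm", "Wdo", "bdo")) return(losses$domain_loss)
    if (nm %in% c("Wd", "bd", "Wo", "bo")) return(losses$label_loss)
    losses$label_loss - lambda * losses$domain_loss
  }
  withr::with_seed(11, {
    for (nm in names(model$weights)) {
      idx <- sample(length(model$weights[[nm]]), min(4, length(model$weights[[nm]])))
      for (i in idx) {
        up <- model
        up$weights[[nm]][i] <- up$weights[[nm]][i] + eps
        dn <- model
        dn$weights[[nm]][i] <- dn$weights[[nm]][i] - eps
        num <- (objective(nm, loss_at(up)) - objective(nm, loss_at(dn))) / (2 * eps)
        expect_equal(gr[[nm]][i], num, tolerance = 1e-5)
      }
    }
  })
})

test_that("training separates separable windows quickly", {
  wd <- separable_windows(60, mu = 1, seed = 11)
  m <- train_baseline(wd, cnn_config(epochs = 50, seed = 2))
  acc <- mean(predict_adherence(m, wd)$.pred == wd$y)
  expect_gte(acc, 0.95)
  expect_lte(nrow(tidy(m)), 50)
})

test_that("single-class training degrades to a constant predictor with a warning", {
  wd <- separable_windows(20, seed = 4)
  wd$y <- rep(1L, 20)
  expect_warning(m <- train_baseline(wd, cnn_config(epochs = 10, seed = 1)),
                 "class")
  preds <- predict_adherence(m, wd)
  expect_equal(mean(preds$.pred == 1), 1)
})

test_that("training is bit-deterministic under a fixed seed", {
  wd <- persistent_windows(50, seed = 6)
  cfg <- cnn_config(epochs = 25, seed = 9)
  a <- train_baseline(wd, cfg)
  b <- train_baseline(wd, cfg)
  expect_identical(a$weights, b$weights)
  expect_identical(tidy(a), tidy(b))
})

test_that("an empty source pool reduces pooled training to the baseline", {
  wd <- persistent_windows(50, seed = 8)
  cfg <- cnn_config(epochs = 15, seed = 3)
  base <- train_baseline(wd, cfg)
  expect_warning(pooled <- train_pooled(wd, NULL, cfg), "Empty source pool")
  expect_identical(base$weights, pooled$weights)
  expect_warning(da <- train_dann(wd, NULL, dann_config(base = cfg)), "Empty source pool")
  expect_identical(base$weights, da$weights)
})

test_that("same-distribution sources help and adversarial sources hurt", {
  cfg_seeds <- 1:10
  accs <- vapply(cfg_seeds, function(s) {
    tgt <- persistent_windows(45, seed = s)
    good <- persistent_windows(80, seed = s + 100, domain = "source")
    bad <- good
    bad$y <- 1L - bad$y  # inverted label function
    test <- persistent_windows(60, seed = s + 200)
    cfg <- cnn_config(epochs = 40, seed = s)
    m0 <- train_baseline(tgt, cfg)
    mg <- train_pooled(tgt, good, cfg)
    mb <- train_pooled(tgt, bad, cfg)
    c(
      base = mean(predict_adherence(m0, test)$.pred == test$y),
      good = mean(predict_adherence(mg, test)$.pred == test$y),
      bad = mean(predict_adherence(mb, test)$.pred == test$y)
    )
  }, numeric(3))
  means <- rowMeans(accs)
  expect_gte(means["good"], means["base"])
  expect_gte(means["good"], means["bad"])
})

test_that("lambda = 0 reproduces pooled training exactly, lambda > 0 departs", {
  tgt <- persistent_windows(45, seed = 21)
  src <- persistent_windows(60, seed = 22, domain = "source")
  cfg <- cnn_config(epochs = 20, seed = 5)
  pooled <- train_pooled(tgt, src, cfg)
  da0 <- train_dann(tgt, src, dann_config(base = cfg, lambda = 0))
  expect_identical(tidy(pooled)$train_label_loss, tidy(da0)$train_label_loss)
  expect_identical(tidy(pooled)$val_loss, tidy(da0)$val_loss)
  da1 <- train_dann(tgt, src, dann_config(base = cfg, lambda = 1))
  expect_false(identical(tidy(pooled)$train_label_loss, tidy(da1)$train_label_loss))
})

test_that("adversarial training reduces domain separability of frozen features", {
  probe_acc <- function(model, tgt, src) {
    f <- rbind(model_features(model, tgt), model_features(model, src))
    d <- c(rep(0L, n_t <- nrow(model_features(model, tgt))),
           rep(1L, nrow(model_features(model, src))))
    fit <- suppressWarnings(stats::glm(d ~ ., data = data.frame(f), family = binomial))
    pr <- as.integer(stats::fitted(fit) > 0.5)
    (mean(pr[d == 0] == 0) + mean(pr[d == 1] == 1)) / 2
  }
  gaps <- vapply(1:5, function(s) {
    tgt <- persistent_windows(40, seed = s)
    src <- persistent_windows(60, seed = s + 50, domain = "source",
                              mean_shift = 0.75)
    cfg <- cnn_config(epochs = 150, seed = s)
    mp <- train_pooled(tgt, src, cfg)
    md <- train_dann(tgt, src, dann_config(base = cfg, lambda = 1))
    c(pooled = probe_acc(mp, tgt, src), dann = probe_acc(md, tgt, src))
  }, numeric(2))
  expect_lt(mean(abs(gaps["dann", ] - 0.5)), mean(abs(gaps["pooled", ] - 0.5)))
})

test_that("predictions are the argmax of the scores with shape checking", {
  wd <- separable_windows(30, seed = 14)
  m <- train_baseline(wd, cnn_config(epochs = 10, seed = 1))
  preds <- predict_adherence(m, wd)
  expect_equal(preds$.pred,
               as.integer(preds$.score_adherent > preds$.score_nonadherent))
  expect_equal(preds$.truth, wd$y)
  bad <- separable_windows(5, seed = 15)
  bad$x <- bad$x[, 1:5, , drop = FALSE]
  expect_error(predict_adherence(m, bad), "does not match")
})
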