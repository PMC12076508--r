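# two well-separated Gaussian blobs in 10 dimensions
make_blobs <- function(n = 200, seed = 1) {
  set.seed(seed)
  half <- n / 2
  x <- rbind(matrix(rnorm(half * 10, -2, 0.5), half),
             matrix(rnorm(half * 10, 2, 0.5), half))
  colnames(x) <- paste0("f", 1:10)
  list(x = x, y = factor(rep(c("a", "b"), each = half)))
}

test_that("all three families separate linearly separable blobs", {
  d <- make_blobs(200, seed = 1)
  for (fam in c("rf", "gbdt", "ann")) {
    cfg <- model_config(fam, seed = 5, epochs = 150)
    fit <- train_model(d$x, d$y, cfg)
    pred <- predict(fit, d$x)
    expect_equal(mean(pred == d$y), 1.0)
    prob <- predict(fit, d$x, type = "prob")
    expect_equal(unname(rowSums(prob)), rep(1, nrow(d$x)),
                 tolerance = 1e-9)
  }
})

test_that("training is deterministic under a fixed seed", {
  d <- make_blobs(120, seed = 2)
  idx <- 1:80
  for (fam in c("rf", "gbdt", "ann")) {
    cfg <- model_config(fam, seed = 9, epochs = 60)
    p1 <- predict(train_model(d$x[idx, ], d$y[idx], cfg), d$x[-idx, ],
                  type = "prob")
    p2 <- predict(train_model(d$x[idx, ], d$y[idx], cfg), d$x[-idx, ],
                  type = "prob")
    expect_identical(p1, p2)
  }
})

test_that("permuted labels bring accuracy to chance", {
  recs <- make_dataset(c(`1` = 500), seed = 60, noise_sd = 0)
  y <- factor(vapply(recs, function(r) r$labels[[1]], character(1)))
  x <- t(vapply(recs, function(r) flatten_ohecc(encode_ohecc(r$molecule)),
                numeric(216)))
  set.seed(61)
  y_perm <- sample(y)
  idx <- sample(500, 400)
  fit <- train_model(x[idx, ], y_perm[idx], model_config("rf", seed = 8))
  acc <- mean(predict(fit, x[-idx, ]) == y_perm[-idx])
  expect_gte(acc, 0.35)
  expect_lte(acc, 0.65)
})

test_that("random forest prediction equals the majority vote of its trees", {
  d <- make_blobs(300, seed = 3)
  # overlap the blobs a bit so votes are not unanimous
  x <- d$x + matrix(rnorm(length(d$x), 0, 2), nrow(d$x))
  fit <- train_model(x, d$y, model_config("rf", n_estimators = 51, seed = 4))
  votes <- predict_votes(fit, x[1:100, ])
  pred <- predict(fit, x[1:100, ])
  tallied <- apply(votes, 2, function(v) {
    fit$classes[which.max(tabulate(v, nbins = length(fit$classes)))]
  })
  expect_identical(as.character(pred), tallied)
  expect_gt(length(unique(as.vector(votes))), 1L)
})

test_that("memorizing forest reproduces its training labels", {
  d <- make_blobs(60, seed = 6)
  x <- d$x + matrix(rnorm(length(d$x), 0, 3), nrow(d$x))
  fit <- train_model(x, d$y,
                     model_config("rf", n_estimators = 500,
                                  min_samples_leaf = 1, seed = 7))
  expect_gte(mean(predict(fit, x) == d$y), 0.98)
})

test_that("deeper forests do at least as well on the handedness task", {
  recs <- make_dataset(c(`1` = 600), seed = 62, noise_sd = 0)
  y <- factor(vapply(recs, function(r) if (r$rotations[["589.3"]] > 0) "+"
                     else "-", character(1)))
  x <- t(vapply(recs, function(r) flatten_ohecc(encode_ohecc(r$molecule)),
                numeric(216)))
  set.seed(63)
  idx <- sample(600, 480)
  acc <- vapply(c(5L, 50L), function(depth) {
    fit <- train_model(x[idx, ], y[idx],
                       model_config("rf", max_depth = depth, seed = 3))
    mean(predict(fit, x[-idx, ]) == y[-idx])
  }, numeric(1))
  expect_gte(acc[2], acc[1])
})

test_that("invalid training input is rejected", {
  d <- make_blobs(40, seed = 5)
  expect_error(train_model(d$x, rep("a", 40), model_config("rf")),
               "single class")
  xx <- d$x; xx[1, 1] <- NA
  expect_error(train_model(xx, d$y, model_config("rf")), "finite")
  fit <- train_model(d$x, d$y, model_config("rf", seed = 2))
  expect_error(predict(fit, d$x[, 1:5]), "width")
})

test_that("multiclass probabilities cover the declared classes", {
  set.seed(30)
  x <- rbind(matrix(rnorm(150, -3), 50), matrix(rnorm(150, 0), 50),
             matrix(rnorm(150, 3), 50))
  colnames(x) <- paste0("f", 1:3)
  y <- factor(rep(c("lo", "mid", "hi"), each = 50),
              levels = c("lo", "mid", "hi"))
  for (fam in c("rf", "gbdt", "ann")) {
    fit <- train_model(x, y, model_config(fam, seed = 11, epochs = 120))
    prob <- predict(fit, x, type = "prob")
    expect_identical(colnames(prob), c("lo", "mid", "hi"))
    # xgboost softprob normalizes in single precision
    expect_equal(unname(rowSums(prob)), rep(1, 150), tolerance = 1e-6)
    expect_gte(mean(predict(fit, x) == y), 0.9)
  }
})

test_that("shipped study-scale configs parse into valid configurations", {
  for (f in c("rf", "rf_study", "xgboost", "xgboost_study", "ann",
              "ann_study")) {
    cfg <- read_model_config(system.file("configs", paste0(f, ".yaml"),
                                         package = "ohecc"))
    expect_s3_class(cfg, "model_config")
  }
  study <- read_model_config(system.file("configs", "rf_study.yaml",
                                         package = "ohecc"))
  expect_equal(study$n_estimators, 1800L)
  expect_equal(study$max_depth, 100L)
  ann <- read_model_config(system.file("configs", "ann_study.yaml",
                                       package = "ohecc"))
  expect_equal(ann$hidden, c(500L, 200L))
  expect_equal(ann$dropout, 0.05)
  expect_gte(ann$epochs, 10000L)
})
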