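test_that("normalizer statistics are the training mean and n-1 SD", {
  x <- matrix(c(0, 2, 0, 2), nrow = 2)
  colnames(x) <- c("f1", "f2")
  st <- fit_normalizer(x)
  expect_equal(unname(st$mean), c(1, 1))
  expect_equal(unname(st$sd), c(sqrt(2), sqrt(2)))
  z <- apply_normalizer(st, x)
  expect_equal(unname(colMeans(z)), c(0, 0))
  expect_equal(unname(apply(z, 2, stats::sd)), c(1, 1))
  xc <- x
  xc[, 2] <- 5
  expect_error(fit_normalizer(xc), "zero-variance.*f2")
  expect_error(fit_normalizer(x[1, , drop = FALSE]), "at least 2")
})

test_that("test data is normalized with TRAIN statistics, not its own", {
  fm <- toy_features(n_per_class = 10, sep = 0)
  st <- fit_normalizer(fm)
  shifted <- fm$x + 5 # a test set with a different mean
  z <- apply_normalizer(st, shifted)
  # had test statistics been used the columns would be re-centered to 0
  expect_true(all(abs(colMeans(z) - 5 / st$sd) < 1e-9))
})

test_that("linear SVM separates separable data and is class-symmetric", {
  fm <- toy_features(n_per_class = 5, sep = 6, noise_sd = 0.5)
  clf <- train_classifier(fm, C = 1)
  p <- predict(clf, fm)
  expect_equal(p$label, fm$labels)
  # label flip negates the decision rule
  fm_flip <- fm
  fm_flip$labels <- ifelse(fm$labels == "relax", "nback", "relax")
  clf_flip <- train_classifier(fm_flip, C = 1)
  expect_equal(
    predict(clf_flip, fm)$score, -predict(clf, fm)$score,
    tolerance = 1e-6
  )
  single <- fm
  single$labels <- rep("relax", length(fm$labels))
  expect_error(train_classifier(single), "single class")
})

test_that("hard-margin width 2/||w|| equals the convex-hull distance oracle", {
  # four normalized points; bypass z-scoring by supplying identity stats
  x <- rbind(c(-1, -1), c(-1, 1), c(1.5, -0.5), c(1.5, 0.7))
  colnames(x) <- c("f1", "f2")
  fm <- structure(
    list(x = x, labels = c("relax", "relax", "nback", "nback")),
    class = "feature_matrix"
  )
  ident <- structure(
    list(mean = c(f1 = 0, f2 = 0), sd = c(f1 = 1, f2 = 1)),
    class = "normalization_stats"
  )
  clf <- train_classifier(fm, stats = ident, C = 1e6)
  width <- 2 / sqrt(sum(clf$w^2))
  oracle <- hull_distance_2d(x[1:2, ], x[3:4, ])
  expect_equal(width, oracle, tolerance = 1e-3)
})

test_that("cross-validation partitions epochs, is deterministic, and nails informative features", {
  labels <- rep(c("relax", "nback"), 10)
  x <- cbind(
    as.numeric(labels == "nback"),
    as.numeric(labels == "nback") + stats::rnorm(20, sd = 1e-3)
  )
  colnames(x) <- c("f1", "f2")
  fm <- structure(list(x = x, labels = labels), class = "feature_matrix")
  cv <- crossvalidate(fm, k = 5, seed = 3)
  expect_equal(cv$mean_accuracy, 100)
  expect_equal(sort(unique(cv$fold_assignment)), 1:5)
  expect_equal(as.vector(table(cv$fold_assignment)), rep(4L, 5)) # 4 test epochs per fold
  expect_false(anyNA(cv$predictions$predicted)) # each epoch predicted once
  expect_equal(cv$mean_accuracy, mean(cv$fold_accuracies) * 100)
  # determinism and seed-reproducible fold assignment
  cv2 <- crossvalidate(fm, k = 5, seed = 3)
  expect_identical(cv$fold_assignment, cv2$fold_assignment)
  expect_equal(cv$fold_accuracies, cv2$fold_accuracies)
  expect_error(crossvalidate(fm, k = 21), "more folds|at least")
})

test_that("pure-noise features stay inside the chance interval", {
  bound <- chance_upper_bound(20, 2, 0.05)
  inside <- vapply(1:50, function(s) {
    fm <- toy_features(n_per_class = 10, n_feat = 8, sep = 0, seed = 1000 + s)
    acc <- crossvalidate(fm, k = 5, seed = s)$mean_accuracy
    acc >= bound$lower && acc <= bound$upper
  }, logical(1))
  expect_gte(mean(inside), 0.9)
})

test_that("online replay applies the frozen calibration rule in order", {
  fm <- toy_features(n_per_class = 10, sep = 3)
  # online = copy of calibration: accuracy equals resubstitution accuracy
  rep1 <- replay_online(fm, fm)
  clf <- train_classifier(fm)
  resub <- 100 * mean(predict(clf, fm)$label == fm$labels)
  expect_equal(rep1$accuracy, resub)
  expect_equal(rep1$predictions$epoch, seq_along(fm$labels))
  # high-SNR online draws from the calibration distribution beat chance
  bound <- chance_upper_bound(20, 2, 0.05)
  ok <- vapply(1:20, function(s) {
    cal <- toy_features(n_per_class = 10, sep = 3, seed = 200 + s)
    onl <- toy_features(n_per_class = 10, sep = 3, seed = 400 + s)
    replay_online(cal, onl)$accuracy >= bound$upper
  }, logical(1))
  expect_gte(mean(ok), 0.9)
  # label-shuffled online sits near 50%
  set.seed(7)
  accs <- vapply(1:20, function(s) {
    onl <- toy_features(n_per_class = 10, sep = 3, seed = 600 + s)
    onl$labels <- sample(onl$labels)
    replay_online(fm, onl)$accuracy
  }, numeric(1))
  ci <- 100 * stats::qbinom(c(0.005, 0.995), 20 * 20, 0.5) / (20 * 20)
  expect_gt(mean(accs), ci[1])
  expect_lt(mean(accs), ci[2])
  # column mismatch is an error
  bad <- fm
  colnames(bad$x) <- paste0("g", seq_len(ncol(bad$x)))
  expect_error(replay_online(fm, bad), "mismatch")
})

test_that("corrupting test-fold values never changes that fold's fitted rule", {
  fm <- toy_features(n_per_class = 10, n_feat = 6, sep = 1.5, seed = 5)
  k <- 5
  fold <- nirstate:::stratified_folds(fm$labels, k, seed = 11)
  for (f in seq_len(k)) {
    tr <- which(fold != f)
    te <- which(fold == f)
    train_fm <- structure(
      list(x = fm$x[tr, , drop = FALSE], labels = fm$labels[tr]),
      class = "feature_matrix"
    )
    clf_clean <- train_classifier(train_fm)
    # corrupt the test fold wildly; the training-side artifacts must not move
    fm_bad <- fm
    fm_bad$x[te, ] <- fm_bad$x[te, ] * 1e6 + 1e3
    train_bad <- structure(
      list(x = fm_bad$x[tr, , drop = FALSE], labels = fm_bad$labels[tr]),
      class = "feature_matrix"
    )
    clf_bad <- train_classifier(train_bad)
    expect_identical(clf_bad$stats, clf_clean$stats)
    expect_identical(clf_bad$w, clf_clean$w)
    expect_identical(clf_bad$b, clf_clean$b)
  }
})
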