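test_that("accuracy and pairwise rates account for every misclassification", {
  conf <- matrix(c(3, 2, 1, 4), 2, 2, dimnames = list(c("a", "b"),
                                                      c("a", "b")))
  expect_equal(classification_accuracy(conf), 0.7)
  pw <- pairwise_misclassification(conf)
  expect_equal(pw$rate, 3 / 10)
  expect_equal(classification_accuracy(diag(c(5, 5, 5))), 1)
  zero_diag <- matrix(1, 3, 3) - diag(3)
  expect_equal(classification_accuracy(zero_diag), 0)
  expect_true(all(pairwise_misclassification(diag(c(2, 3))) $rate == 0))
  expect_error(classification_accuracy(matrix(0, 2, 2)), "no counts")

  # identity: accuracy + sum of pairwise rates is exactly 1
  for (seed in 1:10) {
    set.seed(seed)
    cf <- matrix(rpois(25, 4), 5, 5)
    expect_identical(classification_accuracy(cf) +
                       sum(pairwise_misclassification(cf)$rate), 1)
  }
})

test_that("k-fold partitions cover every sample once with balanced sizes", {
  fold <- kfold_partition(405, 10, seed = 3)
  expect_equal(length(fold), 405)
  expect_setequal(unique(fold), 1:10)
  expect_setequal(as.integer(table(fold)), c(40L, 41L))
  expect_equal(sum(table(fold) == 41), 5)
  expect_identical(fold, kfold_partition(405, 10, seed = 3))
  expect_false(identical(fold, kfold_partition(405, 10, seed = 4)))
  expect_error(kfold_partition(5, 10, seed = 1), "exceeds")
})

test_that("stratified folds balance every class to within one sample", {
  labels <- factor(rep(c("A0", "A1", "A2", "A3", "A4"), each = 81))
  fold <- kfold_partition(405, 10, seed = 5, stratify = TRUE,
                          labels = labels)
  tab <- table(labels, fold)
  expect_true(all(tab %in% c(8, 9)))
  sizes <- as.integer(table(fold))
  expect_lte(max(sizes) - min(sizes), 1)
})

test_that("both classifiers separate distant Gaussian blobs perfectly", {
  set.seed(51)
  x <- rbind(matrix(rnorm(40, mean = 0), 20, 2),
             matrix(rnorm(40, mean = 10), 20, 2))
  colnames(x) <- c("f1", "f2")
  y <- factor(rep(c("a", "b"), each = 20))
  for (clf in c("rf", "svm")) {
    cfg <- cv_config(n_folds = 5, repeats = 2, seed = 8, classifier = clf,
                     rf_trees = 100)
    cv <- run_cv(list(features = x, labels = y), cfg)
    expect_equal(cv$mean_accuracy, 1.0)
  }
})

test_that("permuted labels drive accuracy to the five-class chance level", {
  d <- make_dataset(seed = 52, h = 16, w = 16)
  snap <- assemble_snapshots(d)
  ft <- build_feature_table(pod(snap, 10), snap, 10)
  ft$labels <- with_seed_shuffle(ft$labels, 99)
  cfg <- cv_config(repeats = 20, seed = 60, classifier = "rf",
                   rf_trees = 200)
  cv <- run_cv(ft, cfg)
  expect_gt(cv$mean_accuracy, 0.12)
  expect_lt(cv$mean_accuracy, 0.28)
})

test_that("identical seeds reproduce per-repeat accuracies exactly", {
  d <- make_dataset(seed = 53, h = 16, w = 16)
  snap <- assemble_snapshots(d)
  ft <- build_feature_table(pod(snap, 5), snap, 5)
  for (clf in c("rf", "svm")) {
    cfg <- cv_config(repeats = 2, seed = 17, classifier = clf,
                     rf_trees = 100)
    cv1 <- run_cv(ft, cfg)
    cv2 <- run_cv(ft, cfg)
    expect_identical(cv1$accuracy_per_repeat, cv2$accuracy_per_repeat)
    expect_identical(cv1$confusion, cv2$confusion)
  }
})

test_that("SVM feature scaling uses training statistics only", {
  set.seed(54)
  x_train <- matrix(rnorm(100), 20, 5)
  colnames(x_train) <- paste0("f", 1:5)
  y <- factor(rep(c("a", "b"), 10))
  cfg <- cv_config(repeats = 1, seed = 2, classifier = "svm")
  model <- train_classifier(x_train, y, cfg)
  expect_equal(model$scaling$center, colMeans(x_train))
  expect_equal(model$scaling$scale, apply(x_train, 2, sd))
  # predicting on a wild test-fold outlier leaves the stored training
  # statistics untouched
  outlier <- matrix(1e6, 1, 5, dimnames = list(NULL, paste0("f", 1:5)))
  invisible(predict_classifier(model, outlier))
  expect_equal(model$scaling$center, colMeans(x_train))
})

test_that("cross-validation bookkeeping matches the accuracy identity", {
  set.seed(55)
  x <- matrix(rnorm(200), 40, 5)
  colnames(x) <- paste0("f", 1:5)
  y <- factor(rep(c("a", "b", "c", "d"), 10))
  cfg <- cv_config(n_folds = 10, repeats = 3, seed = 21,
                   classifier = "rf", rf_trees = 50)
  cv <- run_cv(list(features = x, labels = y), cfg)
  expect_equal(sum(cv$confusion), 3 * 40)
  expect_true(all(cv$accuracy_per_repeat >= 0 &
                    cv$accuracy_per_repeat <= 1))
  # equal-sized folds: pooled accuracy is the mean of per-repeat ones
  expect_equal(classification_accuracy(cv$confusion),
               mean(cv$accuracy_per_repeat), tolerance = 1e-12)
  expect_identical(classification_accuracy(cv$confusion) +
                     sum(cv$pairwise$rate), 1)
})

test_that("perfect one-hot features classify without error", {
  y <- factor(rep(c("A0", "A1", "A2", "A3", "A4"), each = 8))
  x <- model.matrix(~ y - 1)
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  cfg <- cv_config(n_folds = 10, repeats = 1, seed = 31,
                   classifier = "rf", rf_trees = 100)
  cv <- run_cv(list(features = x, labels = y), cfg)
  expect_equal(cv$mean_accuracy, 1.0)
})

test_that("the retained-mode sweep covers its factorial grid deterministically", {
  d <- make_dataset(seed = 56, h = 16, w = 16)
  cfg <- cv_config(repeats = 2, seed = 41, rf_trees = 50)
  sw <- mode_sweep(d, methods = c("pod", "dmd"), classifiers = c("rf"),
                   r_list = c(3, 5), config = cfg)
  expect_equal(nrow(sw), 4)
  expect_setequal(paste(sw$method, sw$r), c("pod 3", "pod 5",
                                            "dmd 3", "dmd 5"))
  sw2 <- mode_sweep(d, methods = c("pod", "dmd"), classifiers = c("rf"),
                    r_list = c(3, 5), config = cfg)
  expect_equal(sw, sw2)
  expect_true(all(sw$q1 <= sw$median & sw$median <= sw$q3))
})

test_that("single-class training sets and non-finite features are rejected", {
  x <- matrix(rnorm(20), 10, 2)
  colnames(x) <- c("f1", "f2")
  cfg <- cv_config(repeats = 1, seed = 1, classifier = "rf")
  expect_error(train_classifier(x, factor(rep("a", 10)), cfg),
               "fewer than two classes")
  x[1, 1] <- NA
  expect_error(train_classifier(x, factor(rep(c("a", "b"), 5)), cfg),
               "finite")
})

test_that("one-way ANOVA matches its sum-of-squares definition", {
  groups <- list(c(6, 8, 4, 5, 3, 4), c(8, 12, 9, 11, 6, 8),
                 c(13, 9, 11, 8, 7, 12))
  res <- one_way_anova(groups)
  # brute-force oracle from the sum-of-squares definitions
  all_v <- unlist(groups)
  grand <- mean(all_v)
  ss_between <- sum(lengths(groups) *
                      (sapply(groups, mean) - grand)^2)
  ss_within <- sum(unlist(lapply(groups, function(g) (g - mean(g))^2)))
  df_b <- length(groups) - 1
  df_w <- length(all_v) - length(groups)
  f_oracle <- (ss_between / df_b) / (ss_within / df_w)
  expect_equal(res$statistic, f_oracle, tolerance = 1e-6)
  expect_equal(res$p.value, stats::pf(f_oracle, df_b, df_w,
                                      lower.tail = FALSE),
               tolerance = 1e-8)

  # identical groups: no between-group variability
  same <- list(c(1, 2, 3), c(1, 2, 3))
  res0 <- one_way_anova(same)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p.value, 1)

  # two groups: F is the square of the pooled two-sample t statistic
  g2 <- list(rnorm(8, 0), rnorm(9, 1))
  tt <- stats::t.test(g2[[1]], g2[[2]], var.equal = TRUE)
  expect_equal(one_way_anova(g2)$statistic, unname(tt$statistic)^2,
               tolerance = 1e-10)

  expect_error(one_way_anova(list(1:3)), "two groups")
  expect_error(one_way_anova(list(1, 1:3)), "at least two observations")
})
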