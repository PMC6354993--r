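# Supervised classification of eigenmode feature tables with random
# forests and support vector machines under repeated k-fold
# cross-validation, plus the accuracy bookkeeping and the retained-mode
# sweep.

#' Cross-validation configuration
#'
#' @param n_folds number of folds (default 10).
#' @param repeats number of re-randomized repetitions of the whole
#'   cross-validation (default 100).
#' @param seed master RNG seed; fans out into per-repeat partition seeds
#'   and per-fit classifier seeds, so any cell is independently
#'   reproducible.
#' @param classifier `"rf"` (random forest, 1000 trees by default,
#'   majority voting, feature-subset size `floor(sqrt(p))` per split) or
#'   `"svm"` (radial-kernel one-vs-one multiclass SVM, cost 1, kernel
#'   width `1/p`, features z-scored with training-fold statistics only).
#' @param rf_trees trees per forest.
#' @param svm_cost,svm_gamma SVM cost and kernel width (`NULL` gamma
#'   means `1/n_features`).
#' @param stratified stratify folds by class (default `TRUE`; with 81
#'   images per class, unstratified folds are occasionally class-poor).
#' @return a validated list of class `cv_config`.
#' @export
cv_config <- function(n_folds = 10, repeats = 100, seed,
                      classifier = c("rf", "svm"), rf_trees = 1000,
                      svm_cost = 1, svm_gamma = NULL, stratified = TRUE) {
  abort_if(missing(seed) || !is_number(seed), "seed must be supplied")
  classifier <- match.arg(classifier)
  abort_if(!is_number(n_folds) || n_folds < 2, "n_folds must be >= 2")
  abort_if(!is_number(repeats) || repeats < 1, "repeats must be >= 1")
  abort_if(!is_number(rf_trees) || rf_trees < 1, "rf_trees must be >= 1")
  abort_if(!is_number(svm_cost) || svm_cost <= 0, "svm_cost must be > 0")
  structure(list(n_folds = as.integer(n_folds),
                 repeats = as.integer(repeats),
                 seed = as.integer(seed), classifier = classifier,
                 rf_trees = as.integer(rf_trees), svm_cost = svm_cost,
                 svm_gamma = svm_gamma,
                 stratified = isTRUE(stratified)),
            class = "cv_config")
}

#' Classification accuracy from a confusion matrix
#'
#' `1 - misclassified/total`: one minus the off-diagonal fraction of the
#' confusion counts (rows = truth, columns = prediction).
#'
#' @param confusion square matrix of nonnegative counts.
#' @return accuracy fraction in \[0, 1\].
#' @export
classification_accuracy <- function(confusion) {
  abort_if(!is.matrix(confusion) || nrow(confusion) != ncol(confusion) ||
             length(confusion) == 0,
           "confusion must be a nonempty square matrix")
  abort_if(any(confusion < 0), "confusion counts must be nonnegative")
  total <- sum(confusion)
  abort_if(total <= 0, "confusion matrix has no counts")
  1 - (total - sum(diag(confusion))) / total
}

#' Pairwise misclassification rates from a confusion matrix
#'
#' For every unordered class pair (i, j) the rate
#' `(count(i -> j) + count(j -> i)) / total`. The rates sum exactly to
#' one minus the accuracy, so the misclassification budget is fully
#' accounted for pair by pair.
#'
#' @param confusion square count matrix with class dimnames
#'   (rows = truth).
#' @return data frame with columns `class_a`, `class_b`, `rate`.
#' @export
pairwise_misclassification <- function(confusion) {
  classification_accuracy(confusion) # validates
  k <- nrow(confusion)
  labels <- rownames(confusion)
  if (is.null(labels)) labels <- as.character(seq_len(k))
  total <- sum(confusion)
  pairs <- utils::combn(k, 2)
  data.frame(
    class_a = labels[pairs[1, ]],
    class_b = labels[pairs[2, ]],
    rate = apply(pairs, 2, function(ij) {
      (confusion[ij[1], ij[2]] + confusion[ij[2], ij[1]]) / total
    }),
    stringsAsFactors = FALSE
  )
}

#' Deterministic k-fold partition
#'
#' Partitions `1:n` into `k` folds whose sizes differ by at most one;
#' the stratified variant additionally balances every class across folds
#' to within one sample per fold. Identical seeds give identical
#' assignments.
#'
#' @param n number of samples.
#' @param k number of folds (`k <= n`).
#' @param seed RNG seed.
#' @param stratify balance class proportions per fold?
#' @param labels class labels (required when `stratify = TRUE`).
#' @return integer vector of fold ids (1..k) of length `n`.
#' @export
kfold_partition <- function(n, k, seed, stratify = FALSE, labels = NULL) {
  abort_if(!is_number(n) || !is_number(k) || k < 1, "invalid n or k")
  abort_if(k > n, "k = %d exceeds n = %d", k, n)
  abort_if(!is_number(seed), "seed must be supplied")
  n <- as.integer(n)
  k <- as.integer(k)
  with_seed(seed, {
    fold <- integer(n)
    if (stratify) {
      abort_if(is.null(labels) || length(labels) != n,
               "labels of length n are required for stratification")
      load <- integer(k)
      for (cl in unique(labels)) {
        idx <- sample(which(labels == cl))
        for (i in idx) {
          target <- which.min(load) # ties -> lowest fold id
          fold[i] <- target
          load[target] <- load[target] + 1L
        }
      }
    } else {
      sizes <- rep(n %/% k, k)
      extra <- n %% k
      if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
      fold[sample.int(n)] <- rep(seq_len(k), sizes)
    }
    fold
  })
}

#' @noRd
standardize_fit <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  list(center = ctr, scale = scl)
}

#' @noRd
standardize_apply <- function(x, fit) {
  scale(x, center = fit$center, scale = fit$scale)[, , drop = FALSE]
}

#' Train a classifier on a feature matrix
#'
#' Random forests are `ranger` ensembles (`rf_trees` trees, feature
#' subset `floor(sqrt(p))` per split, single-threaded, seeded). SVMs are
#' `e1071::svm` radial-kernel one-vs-one multiclass machines; features
#' are z-scored using the statistics of the training set only, and the
#' same transform is applied at prediction time, so no test-fold
#' information leaks into preprocessing.
#'
#' @param x numeric feature matrix (rows = samples).
#' @param y factor of class labels (at least two classes present).
#' @param config a [cv_config()] naming the classifier and its settings.
#' @param seed RNG seed for the fit.
#' @return a `trained_classifier` (list with the fitted model, type,
#'   scaling and training levels).
#' @export
train_classifier <- function(x, y, config, seed = config$seed) {
  abort_if(!is.matrix(x) || any(!is.finite(x)),
           "features must be a finite numeric matrix")
  y <- as.factor(y)
  abort_if(length(unique(y[!is.na(y)])) < 2,
           "training labels contain fewer than two classes")
  abort_if(length(y) != nrow(x), "labels do not match feature rows")
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (config$classifier == "rf") {
    # probability forests return the vote fractions, which are exactly
    # reproducible for a fixed seed; majority voting with ties broken by
    # the lowest class index is then an explicit argmax
    fit <- ranger::ranger(x = x, y = y,
                          num.trees = config$rf_trees,
                          mtry = max(1L, floor(sqrt(ncol(x)))),
                          num.threads = 1L, seed = seed,
                          probability = TRUE)
    structure(list(type = "rf", model = fit, levels = levels(y)),
              class = "trained_classifier")
  } else {
    scaling <- standardize_fit(x)
    gamma <- if (is.null(config$svm_gamma)) 1 / ncol(x) else config$svm_gamma
    fit <- with_seed(seed, {
      e1071::svm(x = standardize_apply(x, scaling), y = y,
                 kernel = "radial", cost = config$svm_cost,
                 gamma = gamma, scale = FALSE)
    })
    structure(list(type = "svm", model = fit, scaling = scaling,
                   levels = levels(y)),
              class = "trained_classifier")
  }
}

#' Predict class labels with a trained classifier
#'
#' @param model a `trained_classifier` from [train_classifier()].
#' @param x feature matrix with the training columns.
#' @return factor of predicted labels with the training levels.
#' @export
predict_classifier <- function(model, x) {
  abort_if(!inherits(model, "trained_classifier"),
           "model must come from train_classifier()")
  abort_if(!is.matrix(x) || any(!is.finite(x)),
           "features must be a finite numeric matrix")
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (model$type == "rf") {
    votes <- stats::predict(model$model, data = x,
                            num.threads = 1L)$predictions
    pred <- colnames(votes)[max.col(votes, ties.method = "first")]
  } else {
    pred <- stats::predict(model$model, standardize_apply(x, model$scaling))
  }
  factor(as.character(pred), levels = model$levels)
}

#' Repeated k-fold cross-validation of a feature table
#'
#' Runs `repeats` re-randomized k-fold cycles; in every repeat each
#' sample is tested exactly once. Per-repeat accuracies are retained for
#' dispersion statistics and the confusion counts are pooled over all
#' repeats (counts sum to `repeats * n`).
#'
#' @param features a `feature_table` (or list with `features` matrix and
#'   `labels` factor).
#' @param config a [cv_config()].
#' @return An object of class `cv_result`: list with
#'   `accuracy_per_repeat`, `mean_accuracy`, pooled `confusion`,
#'   `pairwise` misclassification rates and the `config`.
#' @export
run_cv <- function(features, config) {
  abort_if(!inherits(config, "cv_config"), "config must be a cv_config")
  x <- features$features
  y <- as.factor(features$labels)
  abort_if(!is.matrix(x) || nrow(x) != length(y),
           "features and labels are misaligned")
  n <- nrow(x)
  k <- config$n_folds
  classes <- levels(y)
  confusion <- matrix(0L, length(classes), length(classes),
                      dimnames = list(truth = classes,
                                      prediction = classes))
  acc <- numeric(config$repeats)
  seeds <- spawn_seeds(config$seed, config$repeats * (1L + k))
  si <- 0L
  for (rep_i in seq_len(config$repeats)) {
    si <- si + 1L
    fold <- kfold_partition(n, k, seeds[si],
                            stratify = config$stratified, labels = y)
    rep_conf <- matrix(0L, length(classes), length(classes),
                       dimnames = dimnames(confusion))
    for (f in seq_len(k)) {
      si <- si + 1L
      test <- fold == f
      model <- train_classifier(x[!test, , drop = FALSE], y[!test],
                                config, seed = seeds[si])
      pred <- predict_classifier(model, x[test, , drop = FALSE])
      rep_conf <- rep_conf + table(factor(y[test], levels = classes),
                                   factor(pred, levels = classes))
    }
    acc[rep_i] <- classification_accuracy(rep_conf)
    confusion <- confusion + rep_conf
  }
  structure(list(accuracy_per_repeat = acc,
                 mean_accuracy = mean(acc),
                 confusion = confusion,
                 pairwise = pairwise_misclassification(confusion),
                 config = config),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: %s, %d-fold x %d repeats, mean accuracy %.3f (sd %.3f)\n",
              x$config$classifier, x$config$n_folds, x$config$repeats,
              x$mean_accuracy, stats::sd(x$accuracy_per_repeat)))
  invisible(x)
}

#' Sweep classification accuracy over feature methods and retained modes
#'
#' For every combination of eigenmode method, classifier and retained
#' mode count `r`, builds the feature table and runs repeated k-fold
#' cross-validation. Decompositions are computed once per method at the
#' largest requested rank; smaller feature sets take the leading modes
#' of that basis (sigma-ranked for POD/PCA, amplitude-ranked for
#' DMD/DMDC). Cells whose `r` exceeds the available rank are skipped
#' with a message. Cell seeds are drawn up front from the master seed,
#' so any cell is reproducible independently of which cells run.
#'
#' @param dataset an `aerosol_dataset`.
#' @param methods subset of `c("pod", "pca", "dmd", "dmdc")`.
#' @param classifiers subset of `c("rf", "svm")`.
#' @param r_list retained mode counts (default the standard sweep set
#'   `c(3, 5, 10, 25, 50, 75, 100)`).
#' @param config a [cv_config()]; its `classifier` field is overridden
#'   per cell.
#' @return An object of class `sweep_report`: data frame with one row
#'   per cell (`method`, `classifier`, `r`, `mean_acc`, `sd`, `q1`,
#'   `median`, `q3`, `n_repeats`) and the per-cell `cv_result`s in
#'   `attr(, "results")` keyed `method_classifier_r`.
#' @export
mode_sweep <- function(dataset,
                       methods = c("pod", "pca", "dmd", "dmdc"),
                       classifiers = c("rf", "svm"),
                       r_list = c(3, 5, 10, 25, 50, 75, 100),
                       config) {
  abort_if(!inherits(config, "cv_config"), "config must be a cv_config")
  methods <- match.arg(methods, c("pod", "pca", "dmd", "dmdc"),
                       several.ok = TRUE)
  classifiers <- match.arg(classifiers, c("rf", "svm"), several.ok = TRUE)
  r_list <- sort(unique(as.integer(r_list)))
  r_max <- max(r_list)

  snap <- if (inherits(dataset, "snapshot_matrix")) dataset
          else assemble_snapshots(dataset)
  split <- split_transitions(snap)
  y <- build_control_matrix(split)

  bases <- list()
  for (mth in methods) {
    bases[[mth]] <- switch(
      mth,
      pod = pod(snap, r_max),
      pca = pca(snap, r_max),
      dmd = dmd(split$x_prime, split$x_dprime, r_max),
      dmdc = dmdc(split$x_prime, split$x_dprime, y, r = r_max)$basis
    )
  }

  grid <- expand.grid(r = r_list, classifier = classifiers,
                      method = methods, stringsAsFactors = FALSE)
  grid <- grid[, c("method", "classifier", "r")]
  cell_seeds <- spawn_seeds(config$seed, nrow(grid))

  rows <- list()
  results <- list()
  for (i in seq_len(nrow(grid))) {
    mth <- grid$method[i]
    clf <- grid$classifier[i]
    r <- grid$r[i]
    basis <- bases[[mth]]
    if (r > basis$rank_used) {
      message(sprintf("skipping %s/%s at r=%d: only %d modes available",
                      mth, clf, r, basis$rank_used))
      next
    }
    ft <- build_feature_table(basis, snap, r)
    cell_cfg <- config
    cell_cfg$classifier <- clf
    cell_cfg$seed <- cell_seeds[i]
    cv <- run_cv(ft, cell_cfg)
    qs <- stats::quantile(cv$accuracy_per_repeat, c(0.25, 0.5, 0.75),
                          names = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      method = mth, classifier = clf, r = r,
      mean_acc = cv$mean_accuracy,
      sd = stats::sd(cv$accuracy_per_repeat),
      q1 = qs[1], median = qs[2], q3 = qs[3],
      n_repeats = cell_cfg$repeats, stringsAsFactors = FALSE)
    results[[paste(mth, clf, r, sep = "_")]] <- cv
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  attr(report, "results") <- results
  class(report) <- c("sweep_report", "data.frame")
  report
}

#' One-way analysis of variance across accuracy groups
#'
#' Classical between/within mean-square F ratio and its F-distribution
#' tail probability, used to judge whether classification accuracies
#' differ across methods or classifiers beyond repeat-to-repeat
#' variability.
#'
#' @param groups a named list of numeric vectors (one per group), each
#'   with at least two observations.
#' @return list with `statistic` (F), `p.value`, and the degrees of
#'   freedom `df_between`, `df_within`.
#' @export
one_way_anova <- function(groups) {
  abort_if(!is.list(groups) || length(groups) < 2,
           "at least two groups are required")
  sizes <- lengths(groups)
  abort_if(any(sizes < 2), "every group needs at least two observations")
  values <- unlist(groups, use.names = FALSE)
  abort_if(any(!is.finite(values)), "group values must be finite")
  grp <- factor(rep(seq_along(groups), sizes))
  ht <- stats::oneway.test(values ~ grp, var.equal = TRUE)
  list(statistic = unname(ht$statistic), p.value = unname(ht$p.value),
       df_between = unname(ht$parameter[1]),
       df_within = unname(ht$parameter[2]))
}
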