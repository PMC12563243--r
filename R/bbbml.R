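#' Descriptor columns used by the BBB classifier
#' @return Character vector of the five descriptor names.
#' @export
bbb_features <- function() c("mw", "logp", "psa", "hbd", "hba")

#' Stratified train/test split
#'
#' Samples `round(class_n * test_frac)` compounds per class into the
#' test set so the class ratio is preserved within rounding; the split
#' is a partition and deterministic under the seed.
#'
#' @param data Data frame with a binary `cns_label` column (1 penetrant,
#'   0 non-penetrant).
#' @param test_frac Test fraction in (0, 1); default 0.2.
#' @param seed Integer seed; default 42.
#' @return A list with `train` and `test` data frames.
#' @export
stratified_split <- function(data, test_frac = 0.2, seed = 42) {
  if (test_frac <= 0 || test_frac >= 1) {
    abort_input("test_frac must lie in (0, 1)")
  }
  labels <- data$cns_label
  if (length(unique(labels)) < 2) abort_input("both classes must be present")
  if (any(table(labels) < 2)) {
    abort_input("each class needs at least two members")
  }
  set.seed(seed)
  test_idx <- integer(0)
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    n_test <- round(length(idx) * test_frac)
    test_idx <- c(test_idx, sample(idx, n_test))
  }
  list(
    train = data[-test_idx, , drop = FALSE],
    test = data[test_idx, , drop = FALSE]
  )
}

#' Z-score standardization with train-derived parameters
#'
#' Means and population (divide-by-n) standard deviations are computed
#' on the training rows only and applied unchanged to any other matrix,
#' preventing information leakage from test data.
#'
#' @param train Numeric matrix or data frame of training descriptors.
#' @param apply_to Optional matrix/data frame scaled with the training
#'   parameters.
#' @return A list with `train_scaled`, `apply_scaled` (or NULL) and
#'   `params` (`mean`, `sd` per feature).
#' @export
standardize <- function(train, apply_to = NULL) {
  train <- as.matrix(train)
  mu <- colMeans(train)
  sigma <- sqrt(colMeans(sweep(train, 2, mu)^2))
  if (any(sigma <= 0)) {
    abort_input(sprintf("constant training feature: %s",
                        paste(colnames(train)[sigma <= 0], collapse = ", ")))
  }
  scale_with <- function(m) {
    m <- as.matrix(m)
    sweep(sweep(m, 2, mu[colnames(m)]), 2, sigma[colnames(m)], "/")
  }
  list(
    train_scaled = scale_with(train),
    apply_scaled = if (!is.null(apply_to)) scale_with(apply_to),
    params = list(mean = mu, sd = sigma)
  )
}

#' Default classifier configurations
#'
#' Random forest: 200 trees, maximum depth 10. Gradient boosting: 100
#' rounds, depth 5, learning rate 0.1 (regularization off, classical
#' sequential boosting). XGBoost: same boosting size with the library's
#' default L1/L2 regularization. SVM: radial kernel, C = 1, gamma
#' 1/n_features (equals "scale" on standardized inputs), Platt-calibrated
#' probabilities.
#'
#' @param families Character subset of
#'   `c("random_forest", "gradient_boosting", "xgboost", "svm_rbf")`.
#' @param seed Integer seed applied to every family.
#' @return Named list of per-family configuration lists.
#' @export
classifier_configs <- function(families = c("random_forest",
                                            "gradient_boosting",
                                            "xgboost", "svm_rbf"),
                               seed = 42) {
  all <- list(
    random_forest = list(trees = 200, max_depth = 10),
    gradient_boosting = list(estimators = 100, max_depth = 5,
                             learning_rate = 0.1),
    xgboost = list(estimators = 100, max_depth = 5, learning_rate = 0.1),
    svm_rbf = list(C = 1.0)
  )
  cfgs <- all[families]
  for (f in names(cfgs)) cfgs[[f]]$seed <- seed
  cfgs
}

# Internal: fit one family on standardized x / binary y.
.fit_family <- function(family, x, y, cfg) {
  if (family == "random_forest") {
    fit <- ranger::ranger(
      x = as.data.frame(x), y = factor(y, levels = c(0, 1)),
      num.trees = cfg$trees, max.depth = cfg$max_depth,
      probability = TRUE, seed = cfg$seed
    )
    predictor <- function(newx) {
      predict(fit, data = as.data.frame(newx))$predictions[, "1"]
    }
  } else if (family %in% c("gradient_boosting", "xgboost")) {
    reg <- if (family == "gradient_boosting") list(reg_lambda = 0,
                                                  reg_alpha = 0) else list()
    args <- c(
      list(
        x = as.matrix(x), y = factor(y, levels = c(0, 1)),
        objective = "binary:logistic",
        nrounds = cfg$estimators, max_depth = cfg$max_depth,
        learning_rate = cfg$learning_rate,
        nthreads = 1, seed = cfg$seed, verbosity = 0
      ),
      reg
    )
    fit <- do.call(xgboost::xgboost, args)
    predictor <- function(newx) as.numeric(predict(fit, as.matrix(newx)))
  } else if (family == "svm_rbf") {
    set.seed(cfg$seed)
    fit <- e1071::svm(
      x = as.matrix(x), y = factor(y, levels = c(0, 1)),
      kernel = "radial", cost = cfg$C, probability = TRUE
    )
    predictor <- function(newx) {
      pr <- predict(fit, as.matrix(newx), probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    }
  } else {
    abort_input(sprintf("unknown model family: %s", family))
  }
  list(family = family, fit = fit, predict_prob = predictor, config = cfg)
}

#' Train the BBB classifier ensemble
#'
#' Fits every configured family on standardized training descriptors and
#' binary labels; each fitted model exposes a probability predictor.
#'
#' @param train_x Standardized training descriptor matrix.
#' @param train_y Binary labels (0/1).
#' @param configs Configurations from [classifier_configs()].
#' @return Named list of fitted models.
#' @export
train_models <- function(train_x, train_y, configs = classifier_configs()) {
  if (length(unique(train_y)) < 2) {
    abort_input("training set contains a single class")
  }
  out <- lapply(names(configs), function(f) {
    .fit_family(f, train_x, train_y, configs[[f]])
  })
  setNames(out, names(configs))
}

#' Confusion matrix from binary predictions
#'
#' @param predicted,actual Binary vectors (1 positive).
#' @return A list with `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_matrix <- function(predicted, actual) {
  list(
    tp = sum(predicted == 1 & actual == 1),
    tn = sum(predicted == 0 & actual == 0),
    fp = sum(predicted == 1 & actual == 0),
    fn = sum(predicted == 0 & actual == 1)
  )
}

#' Rank-statistic area under the ROC curve
#'
#' Mann-Whitney formulation: ties receive half credit; invariant under
#' strictly monotone score transformations.
#'
#' @param scores Numeric scores (higher means more positive).
#' @param labels Binary labels.
#' @return AUC in \[0, 1\] (NA when a class is absent).
#' @export
auc_rank <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy, sensitivity, specificity, PPV, NPV, balanced accuracy, and
#' (when scores are supplied) the rank-statistic AUC. Metrics whose
#' denominator is zero are reported NA with a warning.
#'
#' @param cm Confusion matrix from [confusion_matrix()].
#' @param scores,labels Optional score/label pairs for the AUC.
#' @return A one-row data frame of metrics plus the confusion counts.
#' @export
evaluate <- function(cm, scores = NULL, labels = NULL) {
  total <- cm$tp + cm$tn + cm$fp + cm$fn
  if (total == 0) abort_input("empty confusion matrix")
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined (zero denominator)", what))
      return(NA_real_)
    }
    num / den
  }
  sens <- safe_div(cm$tp, cm$tp + cm$fn, "sensitivity")
  spec <- safe_div(cm$tn, cm$tn + cm$fp, "specificity")
  data.frame(
    tp = cm$tp, tn = cm$tn, fp = cm$fp, fn = cm$fn,
    accuracy = (cm$tp + cm$tn) / total,
    sensitivity = sens,
    specificity = spec,
    ppv = safe_div(cm$tp, cm$tp + cm$fp, "PPV"),
    npv = safe_div(cm$tn, cm$tn + cm$fn, "NPV"),
    balanced_accuracy = (sens + spec) / 2,
    auc_roc = if (!is.null(scores)) auc_rank(scores, labels) else NA_real_
  )
}

#' Best-model selection by balanced accuracy
#'
#' Argmax of balanced accuracy; ties break by higher AUC, then by the
#' fixed family order random forest > gradient boosting > xgboost > SVM.
#'
#' @param reports Named list (or row-bound data frame with a `model`
#'   column) of [evaluate()] outputs per family.
#' @return The winning model id.
#' @export
select_best <- function(reports) {
  if (is.data.frame(reports)) {
    ids <- reports$model
    ba <- reports$balanced_accuracy
    auc <- reports$auc_roc
  } else {
    ids <- names(reports)
    ba <- vapply(reports, function(r) r$balanced_accuracy, numeric(1))
    auc <- vapply(reports, function(r) r$auc_roc, numeric(1))
  }
  if (length(ids) == 0) abort_input("no model reports supplied")
  fam_order <- c("random_forest", "gradient_boosting", "xgboost", "svm_rbf")
  pref <- match(ids, fam_order)
  pref[is.na(pref)] <- length(fam_order) + 1
  auc[is.na(auc)] <- -Inf
  ids[order(-ba, -auc, pref)][1]
}

#' Probabilistic BBB prediction for candidate compounds
#'
#' Standardizes the descriptors with the training parameters, predicts
#' the penetration probability, thresholds at 0.5 (inclusive) for the
#' binary call, and assigns the five-band probability class.
#'
#' @param model A fitted model from [train_models()].
#' @param params Standardization parameters (`$params` of
#'   [standardize()]).
#' @param profiles Data frame with a `drug` column and the five
#'   descriptor columns.
#' @return Data frame `drug, probability, binary, ml_class`.
#' @export
predict_bbb <- function(model, params, profiles) {
  feats <- bbb_features()
  for (f in feats) {
    bad <- is.null(profiles[[f]]) | is.na(profiles[[f]])
    if (any(bad)) {
      abort_input(sprintf("missing descriptor %s for drug %s", f,
                          paste(profiles$drug[bad], collapse = ", ")))
    }
  }
  x <- as.matrix(profiles[, feats])
  xs <- sweep(sweep(x, 2, params$mean[feats]), 2, params$sd[feats], "/")
  prob <- model$predict_prob(xs)
  data.frame(
    drug = profiles$drug,
    probability = as.numeric(prob),
    binary = as.integer(prob >= 0.5),
    ml_class = bbb_class_from_probability(as.numeric(prob)),
    stringsAsFactors = FALSE
  )
}

#' End-to-end BBB validation harness
#'
#' Splits the labeled set, standardizes on the training rows, trains the
#' four families, evaluates each on the held-out test set, and selects
#' the best model by balanced accuracy.
#'
#' @param data Labeled compound table (`drug`, five descriptors,
#'   `cns_label`).
#' @param test_frac Held-out fraction; default 0.2.
#' @param seed Integer seed; default 42.
#' @param families Model families to train.
#' @return A list with `models`, `params`, `metrics` (one row per
#'   family), `best`, and the `split`.
#' @export
run_bbb_validation <- function(data, test_frac = 0.2, seed = 42,
                               families = c("random_forest",
                                            "gradient_boosting",
                                            "xgboost", "svm_rbf")) {
  split <- stratified_split(data, test_frac, seed)
  feats <- bbb_features()
  std <- standardize(split$train[, feats], split$test[, feats])
  models <- train_models(std$train_scaled, split$train$cns_label,
                         classifier_configs(families, seed))
  y_test <- split$test$cns_label
  metrics <- do.call(rbind, lapply(names(models), function(f) {
    prob <- models[[f]]$predict_prob(std$apply_scaled)
    cm <- confusion_matrix(as.integer(prob >= 0.5), y_test)
    rep <- evaluate(cm, scores = prob, labels = y_test)
    cbind(model = f, rep)
  }))
  list(
    models = models,
    params = std$params,
    metrics = metrics,
    best = select_best(metrics),
    split = split
  )
}
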