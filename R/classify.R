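# Class-weighted classification over the 15 regional activity indices:
# six model families, nested cross-validated permutation feature
# importance, iterative feature elimination, and pooled k-fold evaluation
# with Wilson and Hanley-McNeil intervals.

#' Cross-validation protocol
#'
#' @param outer_folds Outer folds of the nested importance stage.
#' @param inner_folds Inner folds for hyperparameter selection.
#' @param eval_folds Folds of the final evaluation stage.
#' @param pfi_repeats Permutations per feature when scoring importance.
#' @param seed Shuffling seed (42 by default, used for every fold split
#'   and permutation).
#' @param models Model families to run; any subset of
#'   `c("random_forest", "extra_trees", "gradient_boosting", "adaboost",
#'   "svm", "knn")`.
#' @return A list of class `cv_protocol`.
#' @export
cv_protocol <- function(outer_folds = 5L, inner_folds = 3L, eval_folds = 5L,
                        pfi_repeats = 10L, seed = 42L,
                        models = model_families()) {
  stopifnot(outer_folds >= 2, inner_folds >= 2, eval_folds >= 2,
            pfi_repeats >= 1, all(models %in% model_families()))
  structure(list(outer_folds = as.integer(outer_folds),
                 inner_folds = as.integer(inner_folds),
                 eval_folds = as.integer(eval_folds),
                 pfi_repeats = as.integer(pfi_repeats),
                 seed = as.integer(seed), models = models),
            class = "cv_protocol")
}

#' Names of the supported model families
#' @return Character vector.
#' @export
model_families <- function() {
  c("random_forest", "extra_trees", "gradient_boosting", "adaboost",
    "svm", "knn")
}

#' Inverse-frequency class weights
#'
#' `w_c = n_total / (k_classes * n_c)`: minority classes receive higher
#' weights so their misclassification carries a greater penalty.
#'
#' @param labels Factor (or vector) of class labels.
#' @return Named numeric weights, one per class.
#' @export
class_weights <- function(labels) {
  tab <- table(labels)
  if (any(tab == 0) || length(tab) < 2)
    stop("every class needs at least one sample", call. = FALSE)
  w <- sum(tab) / (length(tab) * tab)
  stats::setNames(as.numeric(w), names(tab))
}

#' The eight-region reduced feature set
#'
#' Fixed distal-dominant preset (left elbow, right wrist, both distal
#' hands, both distal feet, right knee, right ankle) for evaluating a
#' reduced model without rerunning the elimination stage.
#'
#' @return Character vector of 8 region names.
#' @export
distal8_features <- function() {
  c("left_elbow", "right_wrist", "left_hand", "right_hand",
    "left_foot", "right_foot", "right_knee", "right_ankle")
}

# Default hyperparameter grids: small, fixed, deterministic under seed.
default_grids <- function() {
  list(random_forest = list(ntree = c(50L, 100L, 200L)),
       extra_trees = list(ntree = c(50L, 100L, 200L)),
       gradient_boosting = list(nrounds = c(50L, 100L, 200L)),
       adaboost = list(depth = c(1L, 2L)),
       svm = list(cost = c(0.1, 1, 10)),
       knn = list(k = c(3L, 5L, 7L)))
}

default_params <- function(model) {
  g <- default_grids()[[model]]
  stats::setNames(list(g[[1]][ceiling(length(g[[1]]) / 2)]), names(g))
}

# Stratified fold assignment: shuffle within class under `seed`, deal
# round-robin. Returns integer fold id per sample.
make_folds <- function(y, k, seed) {
  if (min(table(y)) < k)
    stop("stratification impossible: a class has fewer samples than folds",
         call. = FALSE)
  folds <- integer(length(y))
  with_local_seed(seed, {
    for (cl in levels(factor(y))) {
      idx <- sample(which(y == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

# Per-fold feature standardization (train statistics applied to test).
standardize_fold <- function(Xtr, Xte) {
  mu <- colMeans(Xtr)
  sg <- apply(Xtr, 2, stats::sd)
  sg[sg == 0] <- 1
  list(train = sweep(sweep(Xtr, 2, mu), 2, sg, "/"),
       test = sweep(sweep(Xte, 2, mu), 2, sg, "/"))
}

# --- AdaBoost (discrete SAMME) over rpart base trees --------------------

adaboost_fit <- function(X, y, depth = 1L, n_rounds = 50L) {
  pos <- levels(y)[1]
  d <- as.data.frame(X); d$.y <- y
  w <- rep(1 / nrow(d), nrow(d))
  stumps <- list(); alphas <- numeric(0)
  ctrl <- rpart::rpart.control(maxdepth = depth, minsplit = 4, cp = 0,
                               xval = 0, maxcompete = 0, maxsurrogate = 0)
  for (m in seq_len(n_rounds)) {
    fit <- rpart::rpart(.y ~ ., data = d, weights = w / mean(w),
                        method = "class", control = ctrl)
    pred <- predict(fit, d, type = "class")
    miss <- pred != y
    err <- sum(w[miss]) / sum(w)
    if (err <= 0) { stumps[[m]] <- fit; alphas[m] <- 10; break }
    if (err >= 0.5) break
    alphas[m] <- 0.5 * log((1 - err) / err)
    stumps[[m]] <- fit
    w <- w * exp(alphas[m] * ifelse(miss, 1, -1))
    w <- w / sum(w)
  }
  if (!length(stumps)) {  # no usable weak learner: fall back to the prior
    structure(list(stumps = list(), alphas = numeric(0), pos = pos,
                   prior = mean(y == pos)), class = "adaboost")
  } else
    structure(list(stumps = stumps, alphas = alphas, pos = pos),
              class = "adaboost")
}

adaboost_score <- function(model, X) {
  d <- as.data.frame(X)
  if (!length(model$stumps)) return(rep(model$prior, nrow(d)))
  f <- rep(0, nrow(d))
  for (m in seq_along(model$stumps)) {
    pred <- predict(model$stumps[[m]], d, type = "class")
    f <- f + model$alphas[m] * ifelse(pred == model$pos, 1, -1)
  }
  1 / (1 + exp(-2 * f))  # margin -> probability-like score
}

# --- class-weighted KNN -------------------------------------------------

knn_score <- function(Xtr, ytr, Xte, k, weights) {
  pos <- levels(ytr)[1]
  sc <- numeric(nrow(Xte))
  for (i in seq_len(nrow(Xte))) {
    dist2 <- colSums((t(Xtr) - Xte[i, ])^2)
    nb <- order(dist2)[seq_len(min(k, length(dist2)))]
    wv <- weights[as.character(ytr[nb])]
    sc[i] <- sum(wv[ytr[nb] == pos]) / sum(wv)
  }
  sc
}

# --- unified fit/predict interface -------------------------------------
# A fitted fold model predicts the positive-class score (first factor
# level) for arbitrary test rows; training happens once per fold so
# permutation importance can re-score without refitting. Class weights
# are applied to SVM and KNN; features are standardized with training-
# fold statistics for SVM and KNN only.
model_fit <- function(model, Xtr, ytr, params, seed) {
  pos <- levels(ytr)[1]
  obj <- list(model = model, pos = pos)
  if (model %in% c("svm", "knn")) {
    obj$mu <- colMeans(Xtr)
    obj$sg <- apply(Xtr, 2, stats::sd)
    obj$sg[obj$sg == 0] <- 1
    Xtr <- sweep(sweep(Xtr, 2, obj$mu), 2, obj$sg, "/")
  }
  w <- class_weights(ytr)
  obj$fit <- switch(model,
    random_forest = with_local_seed(seed,
      randomForest::randomForest(x = Xtr, y = ytr,
                                 ntree = params$ntree %||% 100L)),
    extra_trees = ranger::ranger(x = Xtr, y = ytr,
                                 num.trees = params$ntree %||% 100L,
                                 splitrule = "extratrees",
                                 num.random.splits = 1,
                                 probability = TRUE, seed = seed,
                                 num.threads = 1),
    gradient_boosting = with_local_seed(seed, {
      dtr <- xgboost::xgb.DMatrix(as.matrix(Xtr),
                                  label = as.numeric(ytr == pos))
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = 3,
                      eta = 0.1, nthread = 1),
        data = dtr, nrounds = params$nrounds %||% 100L, verbose = 0)
    }),
    adaboost = with_local_seed(seed,
      adaboost_fit(Xtr, ytr, depth = params$depth %||% 1L)),
    svm = with_local_seed(seed,
      e1071::svm(x = Xtr, y = ytr, kernel = "radial",
                 cost = params$cost %||% 1,
                 class.weights = w, scale = FALSE)),
    knn = list(Ztr = Xtr, ytr = ytr, k = params$k %||% 5L, w = w),
    stop("unknown model family: ", model, call. = FALSE))
  obj
}

model_predict <- function(obj, Xte) {
  if (obj$model %in% c("svm", "knn"))
    Xte <- sweep(sweep(Xte, 2, obj$mu), 2, obj$sg, "/")
  switch(obj$model,
    random_forest = predict(obj$fit, Xte, type = "prob")[, obj$pos],
    extra_trees = predict(obj$fit, as.data.frame(Xte),
                          num.threads = 1)$predictions[, obj$pos],
    gradient_boosting = predict(obj$fit,
                                xgboost::xgb.DMatrix(as.matrix(Xte))),
    adaboost = adaboost_score(obj$fit, Xte),
    svm = {
      dv <- attr(predict(obj$fit, Xte, decision.values = TRUE),
                 "decision.values")
      # orient the decision value toward the positive class
      first <- strsplit(colnames(dv)[1], "/")[[1]][1]
      if (first == obj$pos) dv[, 1] else -dv[, 1]
    },
    knn = knn_score(obj$fit$Ztr, obj$fit$ytr, Xte, obj$fit$k, obj$fit$w))
}

fit_score <- function(model, Xtr, ytr, Xte, params, seed) {
  model_predict(model_fit(model, Xtr, ytr, params, seed), Xte)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Pooled k-fold cross-validated scores for one model + parameter set.
cv_scores <- function(model, X, y, k, seed, params = default_params(model)) {
  folds <- make_folds(y, k, seed)
  scores <- numeric(length(y))
  for (f in seq_len(k)) {
    te <- folds == f
    scores[te] <- fit_score(model, X[!te, , drop = FALSE], y[!te],
                            X[te, , drop = FALSE], params,
                            seed = seed + 131L * f)
  }
  scores
}

# SVM emits signed margins (threshold 0); all other families emit
# probability-like scores (threshold 0.5).
score_threshold <- function(model) if (model == "svm") 0 else 0.5

score_to_pred <- function(scores, y, threshold = 0.5) {
  pos <- levels(y)[1]; neg <- levels(y)[2]
  factor(ifelse(scores > threshold, pos, neg), levels = levels(y))
}

#' Rank-based AUC (Mann-Whitney identity)
#'
#' `AUC = (R_pos - n1(n1+1)/2) / (n1 n2)` with `R_pos` the rank sum of
#' positive-class scores (average ranks for ties).
#'
#' @param scores Numeric decision scores, larger = more positive.
#' @param labels Factor; first level is the positive class.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, labels) {
  pos <- labels == levels(labels)[1]
  n1 <- sum(pos); n2 <- sum(!pos)
  stopifnot(n1 >= 1, n2 >= 1)
  rk <- rank(scores)
  (sum(rk[pos]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Classification metrics from pooled confusion counts
#'
#' @param tp,fp,tn,fn Pooled confusion counts.
#' @return Named list: accuracy, precision, sensitivity, specificity, f1
#'   (fractions in `[0, 1]`).
#' @export
metrics_from_confusion <- function(tp, fp, tn, fn) {
  acc <- (tp + tn) / (tp + fp + tn + fn)
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  f1 <- if (is.na(prec) || prec + sens == 0) NA_real_
        else 2 * prec * sens / (prec + sens)
  list(accuracy = acc, precision = prec, sensitivity = sens,
       specificity = spec, f1 = f1)
}

# ROC points from pooled scores (one point per distinct threshold).
roc_points <- function(scores, labels) {
  pos <- labels == levels(labels)[1]
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[pos] >= t), 0)
  fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), 0)
  data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Evaluate models with pooled k-fold cross-validation
#'
#' Stratified `eval_folds`-fold CV; out-of-fold predictions are pooled
#' into a single confusion matrix per model, metrics are computed from the
#' pooled counts with Wilson intervals (whole-sample effective n by
#' default), and the AUC of the pooled scores carries a Hanley-McNeil
#' interval with the true class sizes.
#'
#' @param X Numeric feature matrix (rows = subjects).
#' @param y Factor labels; first level is the positive class.
#' @param protocol A [cv_protocol()].
#' @param params Optional named list of per-model parameter lists (e.g.
#'   from [tune_models()]); defaults to mid-grid values.
#' @param n_eff_mode `"total"` (whole-sample Wilson n, the reporting
#'   convention reproduced here) or `"metric"` (each metric's natural
#'   denominator).
#' @return List of per-model reports: `confusion`, `metrics` (point
#'   estimate + Wilson bounds), `auc`, `auc_ci`, `roc`, `scores`.
#' @export
evaluate_models <- function(X, y, protocol = cv_protocol(), params = NULL,
                            n_eff_mode = c("total", "metric")) {
  n_eff_mode <- match.arg(n_eff_mode)
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  stopifnot(nlevels(y) == 2)
  n <- length(y)
  n1 <- sum(y == levels(y)[1]); n2 <- n - n1
  out <- list()
  for (model in protocol$models) {
    pp <- params[[model]] %||% default_params(model)
    sc <- cv_scores(model, X, y, protocol$eval_folds, protocol$seed, pp)
    pred <- score_to_pred(sc, y, score_threshold(model))
    pos <- levels(y)[1]
    tp <- sum(pred == pos & y == pos); fp <- sum(pred == pos & y != pos)
    tn <- sum(pred != pos & y != pos); fn <- sum(pred != pos & y == pos)
    met <- metrics_from_confusion(tp, fp, tn, fn)
    denom <- list(accuracy = n, precision = tp + fp, sensitivity = n1,
                  specificity = n2, f1 = n)
    ci <- lapply(names(met), function(nm) {
      p <- met[[nm]]
      if (is.na(p)) return(c(lower = NA_real_, upper = NA_real_))
      n_eff <- if (n_eff_mode == "total") n else denom[[nm]]
      wilson_ci(p * n_eff, n_eff)
    })
    names(ci) <- names(met)
    auc <- auc_rank(sc, y)
    out[[model]] <- list(
      model = model, params = pp,
      confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
      metrics = met, metric_ci = ci,
      auc = auc, auc_ci = hanley_mcneil_ci(auc, n1, n2),
      roc = roc_points(sc, y), scores = sc, predictions = pred)
  }
  out
}

# Inner-loop grid search: mean pooled CV accuracy over the grid.
tune_one <- function(model, X, y, inner_folds, seed) {
  grid <- default_grids()[[model]]
  pname <- names(grid)[1]
  best <- NULL; best_acc <- -Inf
  for (v in grid[[1]]) {
    pp <- stats::setNames(list(v), pname)
    sc <- cv_scores(model, X, y, inner_folds, seed, pp)
    acc <- mean(score_to_pred(sc, y, score_threshold(model)) == y)
    if (acc > best_acc) { best_acc <- acc; best <- pp }
  }
  list(params = best, accuracy = best_acc)
}

#' Tune every model family on the full sample
#'
#' @param X Feature matrix.
#' @param y Factor labels.
#' @param protocol A [cv_protocol()].
#' @return Named list of selected parameter lists, one per model.
#' @export
tune_models <- function(X, y, protocol = cv_protocol()) {
  X <- as.matrix(X); y <- droplevels(as.factor(y))
  out <- lapply(protocol$models, function(m)
    tune_one(m, X, y, protocol$inner_folds, protocol$seed)$params)
  stats::setNames(out, protocol$models)
}

#' Nested cross-validated permutation feature importance
#'
#' For each outer fold, hyperparameters are selected by an inner CV on the
#' training part; the tuned model is fit on the outer-training set and its
#' validation accuracy recorded. Each feature's importance is the mean
#' drop in validation accuracy over `pfi_repeats` independent permutations
#' of that feature's column within the validation set (the model is never
#' refit). Scores are averaged over outer folds and then over model
#' families.
#'
#' @param X Feature matrix.
#' @param y Factor labels.
#' @param protocol A [cv_protocol()].
#' @return List: `importance` (named vector, aggregated over models),
#'   `per_model` (matrix features x models).
#' @export
permutation_importance_nested <- function(X, y, protocol = cv_protocol()) {
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  folds <- make_folds(y, protocol$outer_folds, protocol$seed)
  per_model <- matrix(0, ncol(X), length(protocol$models),
                      dimnames = list(colnames(X), protocol$models))
  for (mi in seq_along(protocol$models)) {
    model <- protocol$models[mi]
    imp_folds <- matrix(0, ncol(X), protocol$outer_folds)
    for (f in seq_len(protocol$outer_folds)) {
      te <- folds == f
      Xtr <- X[!te, , drop = FALSE]; ytr <- y[!te]
      Xte <- X[te, , drop = FALSE];  yte <- y[te]
      tuned <- tune_one(model, Xtr, ytr, protocol$inner_folds,
                        protocol$seed + f)
      seed_f <- protocol$seed + 977L * f + 31L * mi
      thr <- score_threshold(model)
      fitted <- model_fit(model, Xtr, ytr, tuned$params, seed_f)
      base_acc <- mean(score_to_pred(model_predict(fitted, Xte), y, thr) ==
                         yte)
      drops <- with_local_seed(seed_f, {
        vapply(seq_len(ncol(X)), function(j) {
          mean(vapply(seq_len(protocol$pfi_repeats), function(rep) {
            Xp <- Xte
            Xp[, j] <- Xp[sample(nrow(Xp)), j]
            sc <- model_predict(fitted, Xp)
            base_acc - mean(score_to_pred(sc, y, thr) == yte)
          }, 0))
        }, 0)
      })
      imp_folds[, f] <- drops
    }
    per_model[, mi] <- rowMeans(imp_folds)
  }
  list(importance = rowMeans(per_model), per_model = per_model)
}

#' Iterative importance-guided feature elimination
#'
#' Starting from the aggregated importance ranking, the least important
#' feature is dropped one at a time; after each drop the mean pooled CV
#' accuracy of the remaining set (averaged over the protocol's model
#' families) is measured. Elimination stops when the current accuracy
#' falls more than `eps` below the best seen, and the best-scoring set is
#' returned.
#'
#' @param importance Named importance scores ([permutation_importance_nested()]).
#' @param X Feature matrix.
#' @param y Factor labels.
#' @param protocol A [cv_protocol()].
#' @param eps Accuracy tolerance for "balanced simplicity and
#'   performance" (default 0.02).
#' @param min_features Smallest set size to consider.
#' @return Character vector of selected feature names.
#' @export
eliminate_features <- function(importance, X, y, protocol = cv_protocol(),
                               eps = 0.02, min_features = 2L) {
  X <- as.matrix(X); y <- droplevels(as.factor(y))
  stopifnot(ncol(X) >= 2, !is.null(names(importance)))
  order_keep <- names(sort(importance, decreasing = TRUE))
  order_keep <- order_keep[order_keep %in% colnames(X)]
  set_acc <- function(cols) {
    accs <- vapply(protocol$models, function(m) {
      sc <- cv_scores(m, X[, cols, drop = FALSE], y, protocol$eval_folds,
                      protocol$seed)
      mean(score_to_pred(sc, y, score_threshold(m)) == y)
    }, 0)
    mean(accs)
  }
  current <- order_keep
  trace_sets <- list(current)
  trace_acc <- set_acc(current)
  while (length(current) > min_features) {
    candidate <- current[-length(current)]   # drop least important
    acc <- set_acc(candidate)
    if (acc < max(trace_acc) - eps) break
    current <- candidate
    trace_sets <- c(trace_sets, list(current))
    trace_acc <- c(trace_acc, acc)
  }
  # best-scoring set; on ties prefer the smaller (later) one
  best <- max(which(trace_acc == max(trace_acc)))
  trace_sets[[best]]
}
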