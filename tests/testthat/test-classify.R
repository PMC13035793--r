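test_that("class weights are inverse to class frequency", {
  y <- rep(c("case", "control"), c(37, 29))
  w <- class_weights(y)
  expect_equal(w[["case"]], 66 / (2 * 37), tolerance = 1e-12)   # ~0.892
  expect_equal(w[["control"]], 66 / (2 * 29), tolerance = 1e-12) # ~1.138
  expect_lt(w[["case"]], w[["control"]])
  expect_equal(unname(class_weights(rep(c("a", "b"), 10))), c(1, 1))
  expect_error(class_weights(rep("a", 5)), "class")
})

test_that("rank AUC equals pair counting and the Mann-Whitney identity", {
  set.seed(21)
  for (rep in 1:10) {
    n1 <- sample(5:15, 1); n2 <- sample(5:15, 1)
    y <- factor(rep(c("case", "control"), c(n1, n2)),
                levels = c("case", "control"))
    sc <- round(c(rnorm(n1, 0.5), rnorm(n2)), 1)  # rounding induces ties
    pos <- sc[seq_len(n1)]; neg <- sc[-seq_len(n1)]
    pairs <- outer(pos, neg, function(a, b)
      (a > b) + 0.5 * (a == b))
    expect_equal(auc_rank(sc, y), mean(pairs), tolerance = 1e-12)
    # Mann-Whitney identity: AUC = U_pos / (n1 n2)
    mw_u <- sum(rank(sc)[seq_len(n1)]) - n1 * (n1 + 1) / 2
    expect_equal(auc_rank(sc, y), mw_u / (n1 * n2), tolerance = 1e-12)
  }
  # one swapped negative: AUC = 1 - 1/(n1 n2)
  y <- factor(rep(c("case", "control"), c(4, 5)), levels = c("case", "control"))
  sc <- c(rep(1, 3), 0.4, rep(0, 4), 0.5)  # one discordant pos/neg pair
  expect_equal(auc_rank(sc, y), 1 - 1 / (4 * 5), tolerance = 1e-12)
})

test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(33)
  y <- factor(rep(c("case", "control"), c(20, 25)), levels = c("case", "control"))
  sc <- c(rnorm(20, 0.4), rnorm(25))
  ref <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = sc,
                                        levels = c("control", "case"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(auc_rank(sc, y), ref, tolerance = 1e-12)
})

test_that("pooled confusion metrics match hand arithmetic", {
  m <- metrics_from_confusion(tp = 31, fp = 6, tn = 23, fn = 6)
  expect_equal(m$accuracy, 54 / 66, tolerance = 1e-12)
  expect_equal(m$sensitivity, 31 / 37, tolerance = 1e-12)
  expect_equal(m$specificity, 23 / 29, tolerance = 1e-12)
  expect_equal(m$precision, 31 / 37, tolerance = 1e-12)
  expect_equal(m$f1, 31 / 37, tolerance = 1e-12)  # precision = recall here
})

test_that("a perfectly separable problem is learned perfectly in training
           by every family and marginals are conserved", {
  set.seed(2)
  fx <- synth_feature_matrix(n1 = 20, n2 = 20, p = 5, delta = 8)
  for (m in model_families()) {
    sc <- povmotion:::fit_score(m, fx$X, fx$y, fx$X,
                                povmotion:::default_params(m), seed = 1L)
    thr <- povmotion:::score_threshold(m)
    expect_equal(mean((sc > thr) == (fx$y == "case")), 1,
                 label = paste(m, "training accuracy"))
  }
  # held-out margin points can fall on either side of a split, but pooled
  # CV performance stays near-perfect
  rep <- evaluate_models(fx$X, fx$y, cv_protocol(eval_folds = 4))
  for (r in rep) {
    expect_gte(r$metrics$accuracy, 0.95)
    expect_gte(r$auc, 0.95)
    expect_equal(r$confusion[["TP"]] + r$confusion[["FN"]], 20L)
    expect_equal(r$confusion[["TN"]] + r$confusion[["FP"]], 20L)
  }
})

test_that("the whole evaluation is a pure function of data, protocol and
           seed", {
  fx <- synth_feature_matrix(seed = 9)
  proto <- cv_protocol(models = c("random_forest", "svm", "adaboost"))
  r1 <- evaluate_models(fx$X, fx$y, proto)
  r2 <- evaluate_models(fx$X, fx$y, proto)
  expect_identical(r1, r2)
  # marginals conserved on an imperfect problem too
  for (r in r1) {
    expect_equal(r$confusion[["TP"]] + r$confusion[["FN"]], 37L)
    expect_equal(r$confusion[["TN"]] + r$confusion[["FP"]], 29L)
  }
})

test_that("label-permuted features give chance-level pooled AUC", {
  set.seed(6)
  aucs <- vapply(1:20, function(sd) {
    fx <- synth_feature_matrix(seed = sd)
    yp <- with(fx, factor(sample(as.character(y)), levels = levels(y)))
    r <- evaluate_models(fx$X, yp, cv_protocol(models = "random_forest",
                                               seed = 42L + sd))
    r$random_forest$auc
  }, 0)
  expect_gt(mean(aucs), 0.35)
  expect_lt(mean(aucs), 0.65)
})

test_that("permutation importance ranks an informative feature first and
           a pure-noise feature near zero", {
  proto <- cv_protocol(pfi_repeats = 5, models = c("random_forest", "svm"))
  top_hits <- 0; noise_scores <- numeric(0)
  for (sd in 1:20) {
    set.seed(sd)
    n <- 60
    y <- factor(rep(c("case", "control"), each = n / 2),
                levels = c("case", "control"))
    X <- cbind(label_copy = as.numeric(y == "case") + rnorm(n, 0, 0.05),
               noise1 = rnorm(n), noise2 = rnorm(n), noise3 = rnorm(n))
    imp <- permutation_importance_nested(X, y, proto)$importance
    top_hits <- top_hits + (names(which.max(imp)) == "label_copy")
    noise_scores <- c(noise_scores, imp[c("noise1", "noise2", "noise3")])
  }
  expect_gte(top_hits, 18)                 # informative feature wins
  expect_lt(abs(mean(noise_scores)), 0.05) # noise contributes nothing
})

test_that("permutation importance only permutes the validation columns,
           matching a hand-rolled single-fold oracle", {
  set.seed(14)
  n <- 40
  y <- factor(rep(c("case", "control"), each = n / 2),
              levels = c("case", "control"))
  X <- cbind(f1 = as.numeric(y == "case") + rnorm(n, 0, 0.3),
             f2 = rnorm(n), f3 = rnorm(n))
  proto <- cv_protocol(outer_folds = 2, inner_folds = 2, pfi_repeats = 3,
                       models = "knn", seed = 7)
  got <- permutation_importance_nested(X, y, proto)$importance

  # oracle: same folds (fold assignment is not under test), but KNN
  # scoring, grid search, and the permutation loop re-implemented by hand
  knn_oracle <- function(Xtr, ytr, Xte, k) {
    mu <- colMeans(Xtr); sg <- apply(Xtr, 2, sd); sg[sg == 0] <- 1
    Ztr <- sweep(sweep(Xtr, 2, mu), 2, sg, "/")
    Zte <- sweep(sweep(Xte, 2, mu), 2, sg, "/")
    wts <- length(ytr) / (2 * table(ytr))
    sapply(seq_len(nrow(Zte)), function(i) {
      d2 <- rowSums((Ztr - matrix(Zte[i, ], nrow(Ztr), ncol(Ztr),
                                  byrow = TRUE))^2)
      nb <- order(d2)[seq_len(k)]
      sum(wts[as.character(ytr[nb])][ytr[nb] == "case"]) /
        sum(wts[as.character(ytr[nb])])
    })
  }
  folds <- povmotion:::make_folds(y, 2L, 7L)
  acc_of <- function(sc, truth) mean(ifelse(sc > 0.5, "case", "control") == truth)
  imp_oracle <- matrix(0, 3, 2)
  for (f in 1:2) {
    te <- folds == f
    Xtr <- X[!te, ]; ytr <- y[!te]; Xte <- X[te, ]; yte <- y[te]
    # inner 2-fold grid search over k in {3, 5, 7}
    inner <- povmotion:::make_folds(ytr, 2L, 7L + f)
    inner_acc <- sapply(c(3, 5, 7), function(k) {
      sc <- numeric(length(ytr))
      for (g in 1:2)
        sc[inner == g] <- knn_oracle(Xtr[inner != g, ], ytr[inner != g],
                                     Xtr[inner == g, , drop = FALSE], k)
      acc_of(sc, ytr)
    })
    k_best <- c(3, 5, 7)[which.max(inner_acc)]
    base_acc <- acc_of(knn_oracle(Xtr, ytr, Xte, k_best), yte)
    seed_f <- 7L + 977L * f + 31L * 1L
    set.seed(seed_f)
    for (j in 1:3) {
      drops <- numeric(3)
      for (r in 1:3) {
        Xp <- Xte
        Xp[, j] <- Xp[sample(nrow(Xp)), j]
        drops[r] <- base_acc - acc_of(knn_oracle(Xtr, ytr, Xp, k_best), yte)
      }
      imp_oracle[j, f] <- mean(drops)
    }
  }
  expect_equal(unname(got), rowMeans(imp_oracle), tolerance = 1e-12)
})

test_that("feature elimination drops noise and keeps informative features", {
  # two features, one pure noise: the noise feature is removed
  set.seed(3)
  n <- 60
  y <- factor(rep(c("case", "control"), each = n / 2),
              levels = c("case", "control"))
  X <- cbind(signal = as.numeric(y == "case") * 4 + rnorm(n),
             noise = rnorm(n))
  sel <- eliminate_features(c(signal = 0.4, noise = 0), X, y,
                            cv_protocol(models = "random_forest"),
                            min_features = 1L)
  expect_true("signal" %in% sel)
  expect_false("noise" %in% sel)

  # 8 informative + 7 null features: most informative ones survive
  retained <- vapply(1:20, function(sd) {
    fx <- synth_feature_matrix(n1 = 33, n2 = 33, p = 15, delta = 1.2,
                               informative = 1:8, seed = sd)
    tstat <- abs(apply(fx$X, 2, function(v)
      t.test(v[fx$y == "case"], v[fx$y == "control"])$statistic))
    sel <- eliminate_features(tstat, fx$X, fx$y,
                              cv_protocol(models = "random_forest",
                                          seed = 42L + sd))
    sum(colnames(fx$X)[1:8] %in% sel)
  }, 0)
  expect_gte(mean(retained), 6)
})

test_that("tie-case elimination is deterministic under the seed", {
  set.seed(11)
  n <- 40
  y <- factor(rep(c("case", "control"), each = n / 2),
              levels = c("case", "control"))
  base <- as.numeric(y == "case") + rnorm(n, 0, 0.5)
  X <- cbind(a = base, b = base, c = base)  # identical features
  imp <- c(a = 0.1, b = 0.1, c = 0.1)
  proto <- cv_protocol(models = "knn")
  s1 <- eliminate_features(imp, X, y, proto, min_features = 1L)
  s2 <- eliminate_features(imp, X, y, proto, min_features = 1L)
  expect_identical(s1, s2)
  expect_gte(length(s1), 1L)
})

test_that("the end-to-end harness separates planted cohorts but not
           label-permuted ones", {
  best_auc <- numeric(20); perm_auc <- numeric(20)
  for (sd in 1:20) {
    sim <- simulate_cohort(cohort_spec(seed = 4000 + sd), n_frames = 600)
    ft <- feature_table(sim$sessions, sim$cohort, cfg = short_qc(600))
    X <- as.matrix(ft$features[, region_names()])
    y <- ft$features$group
    rep <- evaluate_models(X, y, cv_protocol())
    best_auc[sd] <- max(vapply(rep, function(r) r$auc, 0))
    set.seed(sd)
    yp <- factor(sample(as.character(y)), levels = levels(y))
    rp <- evaluate_models(X, yp, cv_protocol(models = "adaboost"))
    perm_auc[sd] <- rp$adaboost$auc
  }
  expect_gte(mean(best_auc > 0.70), 0.8)
  expect_lt(abs(mean(perm_auc) - 0.5), 0.12)
})
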