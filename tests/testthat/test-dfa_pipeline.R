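test_that("stub backbone extraction is deterministic, fixed-length and pixel-sensitive", {
  bb <- backbone_spec(input_size = c(16, 16), n_features = 32)
  set.seed(5)
  ims <- lapply(1:3, function(i) matrix(runif(400), 20, 20))
  fm1 <- extract_deep_features(ims, bb)
  fm2 <- extract_deep_features(ims, bb)
  expect_equal(dim(fm1$X), c(3L, 32L))
  expect_identical(fm1$X, fm2$X)
  # single-pixel change propagates to the features
  ims2 <- ims
  ims2[[1]][4, 7] <- ims2[[1]][4, 7] + 0.5
  fm3 <- extract_deep_features(ims2, bb)
  expect_false(isTRUE(all.equal(fm1$X[1, ], fm3$X[1, ])))
  expect_equal(fm1$X[2, ], fm3$X[2, ])
  expect_error(backbone_spec(layer = "conv3"), "unknown layer")
  expect_error(backbone_spec(name = "vgg19"), "unknown backbone")
})

test_that("ANOVA F scores match hand computation and the stats oracle", {
  fm <- feature_matrix(cbind(c(1, 2, 3, 4, 5, 6),
                             c(1, 2, 3, 1, 2, 3)),
                       c(0, 0, 0, 1, 1, 1))
  sc <- anova_f_scores(fm)
  expect_equal(sc$scores[1], 13.5)      # SSB 13.5, SSW/4 = 1
  expect_equal(sc$scores[2], 0)         # identical class distributions
  # dual route: stats::oneway.test with equal variances
  set.seed(8)
  x <- rnorm(20); y <- rep(c(0, 1), each = 10)
  fm2 <- feature_matrix(cbind(x), y)
  expect_equal(anova_f_scores(fm2)$scores[1],
               unname(oneway.test(x ~ factor(y), var.equal = TRUE)$statistic),
               tolerance = 1e-12)
  # location invariance
  expect_equal(anova_f_scores(feature_matrix(cbind(x + 100), y))$scores,
               anova_f_scores(fm2)$scores, tolerance = 1e-9)
  # zero within-variance with unequal means: sentinel, flagged
  fmz <- feature_matrix(cbind(c(1, 1, 2, 2)), c(0, 0, 1, 1))
  scz <- anova_f_scores(fmz)
  expect_equal(scz$scores[1], 1e12)
  expect_true(attr(scz, "sentinel")[1])
})

test_that("Kruskal-Wallis scores match the hand rank computation", {
  fm <- feature_matrix(cbind(c(1, 2, 3, 4, 5, 6), c(7, 8, 9, 7, 8, 9)),
                       c(0, 0, 0, 1, 1, 1))
  sc <- kruskal_wallis_scores(fm)
  # ranks 1..6, no ties: 12/(6*7) * (6^2/3 + 15^2/3) - 3*7 = 27/7
  expect_equal(sc$scores[1], 27 / 7, tolerance = 1e-12)
  expect_equal(round(sc$scores[1], 3), 3.857)
  expect_equal(sc$scores[2], 0)         # same values in both classes
  # invariance under strictly monotone transforms
  fm2 <- feature_matrix(cbind(exp(c(1, 2, 3, 4, 5, 6))), c(0, 0, 0, 1, 1, 1))
  expect_equal(kruskal_wallis_scores(fm2)$scores[1], sc$scores[1])
})

test_that("chi-squared scores follow the per-class-sum formula", {
  fm <- feature_matrix(cbind(c(1, 1, 3, 3), c(2, 2, 2, 2)), c(0, 0, 1, 1))
  sc <- chi2_scores(fm)
  expect_equal(sc$scores[1], 2.0)       # observed {2,6}, expected {4,4}
  expect_equal(sc$scores[2], 0)         # equal class sums, equal sizes
  # doubling all values doubles the score
  fm2 <- fm; fm2$X <- fm$X * 2
  expect_equal(chi2_scores(fm2)$scores, 2 * sc$scores)
  fm3 <- fm; fm3$X[1, 1] <- -1
  expect_error(chi2_scores(fm3), "non-negative")
})

test_that("ReliefF exhaustive mode equals the brute-force reference exactly", {
  set.seed(13)
  for (rep in 1:4) {
    n <- sample(6:10, 1)
    p <- sample(2:5, 1)
    y <- rep(c(0, 1), length.out = n)
    X <- matrix(rnorm(n * p), n, p)
    X[, 1] <- X[, 1] + 2 * y            # one relevant feature
    k <- min(2L, min(table(y)) - 1L)
    got <- relieff_scores(feature_matrix(X, y), k_neighbors = k)$scores
    want <- relieff_bruteforce(X, y, k)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("ReliefF: constant features score zero, separating feature dominates", {
  # 6-sample 1D construction: classes fully separated on feature 1; feature 2
  # constant; exhaustive iteration with k = 1
  X <- cbind(c(0, 0.1, 0.2, 1.0, 1.1, 1.2), rep(3, 6))
  y <- c(0, 0, 0, 1, 1, 1)
  sc <- relieff_scores(feature_matrix(X, y), k_neighbors = 1L)$scores
  expect_equal(sc[2], 0)
  expect_gt(sc[1], 0)
  # theoretical value for this geometry: every nearest-hit diff is 0.1/1.2 of
  # the range; nearest-miss diffs are {1.0,0.9,0.8,0.8,0.9,1.0}/1.2 (mean
  # 0.9/1.2), so W = (0.9 - 0.1)/1.2 = 2/3
  expect_equal(sc[1], 2 / 3, tolerance = 1e-12)
  # weights follow a feature permutation
  sc2 <- relieff_scores(feature_matrix(X[, 2:1], y), k_neighbors = 1L)$scores
  expect_equal(sc2, sc[2:1])
  expect_error(relieff_scores(feature_matrix(X, y), k_neighbors = 3L), "k_neighbors")
})

test_that("mRMR picks by relevance first, then penalises redundancy", {
  set.seed(17)
  n <- 120
  y <- rep(c(0, 1), each = n / 2)
  f1 <- rnorm(n) + 3 * y                # strongly relevant
  f2 <- f1                              # exact copy: redundant
  f3 <- rnorm(n) + 0.8 * y              # weakly relevant, independent
  fm <- feature_matrix(cbind(f1, f2, f3), y)
  sel <- mrmr_select(fm, n_select = 3)
  expect_equal(sel$selected_order, c(1L, 3L, 2L))
  # step 1 is always the argmax of single-feature relevance
  expect_equal(sel$selected_order[1], which.max(sel$scores))
  # MI of a feature with itself >= MI with any other feature (brute force)
  Xd <- apply(fm$X, 2, blademri:::discretize_ew, n_bins = 10)
  for (j in 1:3) {
    self <- mi_bruteforce(Xd[, j], Xd[, j])
    for (k in 1:3) expect_gte(self + 1e-12, mi_bruteforce(Xd[, j], Xd[, k]))
  }
  # package MI agrees with the brute-force contingency computation
  expect_equal(blademri:::discrete_mi(Xd[, 1], fm$y),
               mi_bruteforce(Xd[, 1], fm$y), tolerance = 1e-12)
  expect_error(mrmr_select(fm, n_select = 9), "exceeds")
})

test_that("mRMR with the redundancy weight ignored reduces to plain MI ranking", {
  set.seed(23)
  n <- 80
  y <- rep(c(0, 1), each = n / 2)
  X <- sapply(c(2, 0.5, 1.2, 0.1), function(d) rnorm(n) + d * y)
  fm <- feature_matrix(X, y)
  sel <- mrmr_select(fm, n_select = 4, redundancy_weight = 0)
  plain <- order(-sel$scores, seq_along(sel$scores))
  expect_equal(sel$selected_order, plain)
})

test_that("ROC AUC: pair counting, trapezoid equality and complement symmetry", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1.0)
  r <- roc_auc(c(0.9, 0.3, 0.4, 0.1), c(1, 1, 0, 0))
  expect_equal(r$auc, 0.75)             # 3 of 4 pairs concordant
  expect_equal(r$roc_points[1, ], data.frame(fpr = 0, tpr = 0))
  expect_equal(as.numeric(r$roc_points[nrow(r$roc_points), ]), c(1, 1))
  set.seed(31)
  for (i in 1:40) {
    n <- sample(6:30, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)   # force ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    out <- roc_auc(scores, labels)
    expect_equal(out$auc, auc_paircount(scores, labels), tolerance = 1e-12)
    expect_equal(roc_trapezoid(out$roc_points), out$auc, tolerance = 1e-12)
    expect_equal(out$auc + roc_auc(scores, 1 - labels)$auc, 1, tolerance = 1e-12)
  }
  expect_error(roc_auc(c(1, 2), c(1, 1)), "both classes")
})

test_that("ROC AUC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(37)
  scores <- rnorm(60)
  labels <- rbinom(60, 1, 0.5)
  expect_equal(roc_auc(scores, labels)$auc,
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("confusion metrics follow the standard definitions and flag undefined ratios", {
  m <- confusion_metrics(TP = 3, FP = 1, FN = 2, TN = 4)
  expect_equal(m$sensitivity, 0.6)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$precision, 0.75)
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$f1, 0.6667, tolerance = 1e-4)
  perfect <- confusion_metrics(5, 0, 0, 5)
  expect_true(all(unlist(perfect[c("accuracy", "sensitivity", "specificity",
                                   "precision", "f1")]) == 1))
  und <- confusion_metrics(0, 2, 0, 3)
  expect_true(is.nan(und$sensitivity))
  expect_true("sensitivity" %in% und$undefined)
  expect_error(confusion_metrics(-1, 0, 0, 1), "non-negative")
})

test_that("all five scorers rank a perfectly separating feature first among noise", {
  set.seed(41)
  n <- 100; p <- 20
  y <- rep(c(0, 1), each = n / 2)
  X <- matrix(rnorm(n * p), n, p)
  X[, 7] <- y * 10 + runif(n)           # perfect separation on feature 7
  fm <- feature_matrix(X, y)
  for (method in c("anova_f", "kruskal_wallis", "chi2", "relieff", "mrmr")) {
    sc <- score_features(fm, method, n_select = 5, seed = 2)
    top <- if (method == "mrmr") sc$selected_order[1] else sc$ranking[1]
    expect_equal(top, 7L)
  }
})

test_that("train/eval is reproducible, leakage-safe and separable data gives AUC 1", {
  fm_sep <- make_feature_dataset(n_samples = 60, n_features = 10,
                                 n_informative = 3, class_separation = 6, seed = 3)
  for (clf in c("svm", "decision_tree", "knn")) {
    rep1 <- train_eval(fm_sep, clf, seed = 11)
    expect_equal(rep1$auc, 1.0)
    expect_equal(rep1$accuracy, 1.0)
    rep2 <- train_eval(fm_sep, clf, seed = 11)
    expect_identical(rep1[c("auc", "accuracy", "confusion", "selected_features")],
                     rep2[c("auc", "accuracy", "confusion", "selected_features")])
  }
  # permuted labels: null behaviour
  set.seed(19)
  fm_null <- make_feature_dataset(n_samples = 200, n_features = 20,
                                  n_informative = 0, class_separation = 0, seed = 5)
  rep_null <- train_eval(fm_null, "svm", seed = 7)
  expect_gte(rep_null$auc, 0.4)
  expect_lte(rep_null$auc, 0.6)
  # feature selection sees only training folds: the features train_eval picks
  # equal the ranking computed on the training subset alone, and altering the
  # held-out rows' feature values never changes the selection
  fm_a <- make_feature_dataset(n_samples = 80, n_features = 15,
                               n_informative = 4, class_separation = 2, seed = 9)
  tr <- blademri:::stratified_holdout(fm_a$y, 0.7, seed = 13)
  te <- setdiff(seq_along(fm_a$y), tr)
  direct <- score_features(feature_matrix(fm_a$X[tr, ], fm_a$y[tr]), "anova_f")
  sel_a <- train_eval(fm_a, "knn", selection = "anova_f", k_features = 4, seed = 13)
  expect_identical(sel_a$selected_features, direct$ranking[1:4])
  fm_b <- fm_a
  set.seed(99); fm_b$X[te, ] <- matrix(rnorm(length(te) * 15), length(te), 15)
  sel_b <- train_eval(fm_b, "knn", selection = "anova_f", k_features = 4, seed = 13)
  expect_identical(sel_a$selected_features, sel_b$selected_features)
  expect_error(train_eval(fm_a, "svm", k_features = 99), "exceeds")
})
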