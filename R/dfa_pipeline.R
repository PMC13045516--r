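# Deep-feature classification path: backbone-agnostic feature extraction, five
# univariate/multivariate feature scorers, three classifiers, ROC evaluation.
# All randomness is seeded; ties break on the lowest index throughout.

#' Feature matrix container
#'
#' @param X n_samples x n_features numeric matrix (no missing entries).
#' @param y binary class labels (coerced to 0/1 integer; both classes must be
#'   present for supervised operations).
#' @param feature_names optional feature identifiers.
#' @param sample_ids optional sample identifiers.
#' @return a `feature_matrix` list.
#' @export
feature_matrix <- function(X, y, feature_names = NULL, sample_ids = NULL) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("feature_matrix: X contains missing/non-finite entries")
  y <- as.integer(as.factor(y)) - 1L
  if (length(y) != nrow(X)) stop("feature_matrix: label length mismatch")
  if (length(unique(y)) > 2L) stop("feature_matrix: only binary labels supported")
  if (is.null(feature_names)) feature_names <- paste0("f", seq_len(ncol(X)))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(X)))
  structure(list(X = X, y = y, feature_names = feature_names,
                 sample_ids = sample_ids), class = "feature_matrix")
}

check_two_class <- function(fm, min_per_class = 2L) {
  tab <- table(fm$y)
  if (length(tab) < 2L) stop("both classes must be present")
  if (any(tab < min_per_class)) stop("need >= ", min_per_class, " samples per class")
  invisible(tab)
}

#' Backbone specification for deep-feature extraction
#'
#' Declares which network and tap-point produce the features. The package
#' ships one built-in backbone, `"stub"`: a deterministic seeded random
#' projection + tanh nonlinearity standing behind the same contract a
#' pretrained convolutional network would (fixed-length vector per image,
#' deterministic for fixed input). Real pretrained backbones can be registered
#' as plug-ins via `extractor`.
#'
#' @param name backbone identifier (`"stub"` built in).
#' @param layer tap-point identifier (stub supports `"fc"`).
#' @param input_size expected image height/width, length-2 integer.
#' @param n_features output dimensionality of the tapped layer.
#' @param preprocessing normalisation recipe tag (`"minmax"` or `"zscore"`).
#' @param extractor optional function(image_matrix) -> numeric vector for
#'   plug-in backbones.
#' @return a `backbone_spec` list.
#' @export
backbone_spec <- function(name = "stub", layer = "fc", input_size = c(64, 64),
                          n_features = 128L, preprocessing = "minmax",
                          extractor = NULL) {
  if (name == "stub" && layer != "fc") {
    stop("backbone_spec: unknown layer '", layer, "' for the stub backbone")
  }
  if (name != "stub" && is.null(extractor)) {
    stop("backbone_spec: unknown backbone '", name,
         "' — register a plug-in via `extractor` or use 'stub'")
  }
  structure(list(name = name, layer = layer, input_size = as.integer(input_size),
                 n_features = as.integer(n_features),
                 preprocessing = preprocessing, extractor = extractor),
            class = "backbone_spec")
}

# Deterministic integer seed from the backbone identity (so different
# name/layer combinations give different, but reproducible, projections).
backbone_seed <- function(spec) {
  key <- paste(spec$name, spec$layer, sep = "/")
  sum(utf8ToInt(key) * seq_along(utf8ToInt(key))) %% 2147483647L
}

#' Extract deep features from 2D images
#'
#' Applies the backbone's preprocessing recipe (intensity normalisation and
#' resize to `input_size`), then the tapped layer's map. The stub backbone
#' computes `tanh(W x + b)` with a fixed seeded Gaussian projection `W`, so
#' features are deterministic, fixed-length, and sensitive to any pixel
#' change, which is the full extraction contract a pretrained network
#' fulfils.
#'
#' @param images list of 2D numeric matrices.
#' @param backbone a [backbone_spec].
#' @param labels optional labels attached to the resulting [feature_matrix]
#'   (defaults to 0).
#' @return a [feature_matrix] with one row per image.
#' @export
extract_deep_features <- function(images, backbone = backbone_spec(), labels = NULL) {
  stopifnot(inherits(backbone, "backbone_spec"))
  if (!is.list(images)) images <- list(images)
  h <- backbone$input_size[1]; w <- backbone$input_size[2]
  prep <- lapply(images, function(im) {
    im <- as.matrix(im)
    im <- tryCatch(normalize_intensity(im, backbone$preprocessing),
                   error = function(e) array(0, dim(im)))  # constant image -> all-zero
    if (!all(dim(im) == c(h, w))) im <- resize_image(im, c(h, w), "bilinear")
    as.vector(im)
  })
  if (!is.null(backbone$extractor)) {
    feats <- t(vapply(prep, function(x) backbone$extractor(matrix(x, h, w)),
                      numeric(backbone$n_features)))
  } else {
    d <- backbone$n_features
    npix <- h * w
    rs <- .Random.seed_save()
    on.exit(.Random.seed_restore(rs), add = TRUE)
    set.seed(backbone_seed(backbone))
    W <- matrix(rnorm(d * npix) / sqrt(npix), nrow = d)
    bb <- rnorm(d) * 0.1
    feats <- t(vapply(prep, function(x) tanh(as.vector(W %*% x) + bb), numeric(d)))
  }
  if (is.null(labels)) labels <- rep(0L, length(images))
  structure(list(X = feats, y = as.integer(labels),
                 feature_names = paste0(backbone$name, "_", backbone$layer,
                                        "_", seq_len(ncol(feats))),
                 sample_ids = paste0("s", seq_len(nrow(feats)))),
            class = "feature_matrix")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(rs) {
  if (is.null(rs)) {
    if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", rs, envir = globalenv())
}

feature_scores_obj <- function(method, scores, selected_order = NULL) {
  scores <- as.numeric(scores)
  ranking <- order(-scores, seq_along(scores))  # descending, lowest index first on ties
  structure(list(method = method, scores = scores, ranking = ranking,
                 selected_order = selected_order), class = "feature_scores")
}

#' ANOVA F feature scores
#'
#' Per-feature one-way F statistic (between-group mean square over
#' within-group mean square), the classical parametric univariate screen.
#' Features with zero within-group variance but unequal means get a large
#' finite sentinel score (1e12) and a flag.
#'
#' @param fm a [feature_matrix] with >= 2 samples per class.
#' @return a `feature_scores` object (`method = "anova_f"`); attribute
#'   `sentinel` marks flagged features.
#' @export
anova_f_scores <- function(fm) {
  check_two_class(fm)
  y <- fm$y
  n <- length(y)
  g <- split(seq_len(n), y)
  k <- length(g)
  sentinel <- logical(ncol(fm$X))
  scores <- vapply(seq_len(ncol(fm$X)), function(j) {
    x <- fm$X[, j]
    means <- vapply(g, function(i) mean(x[i]), numeric(1))
    ssb <- sum(vapply(seq_along(g), function(gi) length(g[[gi]]) * (means[gi] - mean(x))^2, numeric(1)))
    ssw <- sum(vapply(seq_along(g), function(gi) sum((x[g[[gi]]] - means[gi])^2), numeric(1)))
    if (ssw == 0) {
      if (ssb == 0) return(0)
      sentinel[j] <<- TRUE
      return(1e12)
    }
    (ssb / (k - 1)) / (ssw / (n - k))
  }, numeric(1))
  out <- feature_scores_obj("anova_f", scores)
  attr(out, "sentinel") <- sentinel
  out
}

#' Kruskal-Wallis H feature scores
#'
#' Per-feature rank-based H statistic with tie correction, delegated to
#' [stats::kruskal.test()]. Constant features score 0.
#'
#' @param fm a [feature_matrix] with >= 2 samples per class.
#' @return a `feature_scores` object (`method = "kruskal_wallis"`).
#' @export
kruskal_wallis_scores <- function(fm) {
  check_two_class(fm)
  grp <- factor(fm$y)
  scores <- vapply(seq_len(ncol(fm$X)), function(j) {
    x <- fm$X[, j]
    if (length(unique(x)) == 1L) return(0)
    unname(kruskal.test(x, grp)$statistic)
  }, numeric(1))
  feature_scores_obj("kruskal_wallis", scores)
}

#' Chi-squared feature scores
#'
#' Treats each non-negative feature as a frequency: the observed values are
#' the per-class sums, the expected values split the total in proportion to
#' class size, and the score is `sum((O - E)^2 / E)`. Scores scale linearly
#' with the feature (doubling values doubles the score), so features should
#' share a common non-negative scale.
#'
#' @param fm a [feature_matrix] with all values >= 0.
#' @return a `feature_scores` object (`method = "chi2"`).
#' @export
chi2_scores <- function(fm) {
  check_two_class(fm, min_per_class = 1L)
  if (any(fm$X < 0)) {
    stop("chi2_scores: negative feature values — shift/scale features to a non-negative range first")
  }
  y <- fm$y
  cls <- sort(unique(y))
  n_c <- vapply(cls, function(c) sum(y == c), numeric(1))
  prop <- n_c / length(y)
  scores <- vapply(seq_len(ncol(fm$X)), function(j) {
    obs <- vapply(cls, function(c) sum(fm$X[y == c, j]), numeric(1))
    expd <- sum(obs) * prop
    if (sum(obs) == 0) return(0)
    sum((obs - expd)^2 / expd)
  }, numeric(1))
  feature_scores_obj("chi2", scores)
}

#' ReliefF feature weights
#'
#' Standard ReliefF: for each sampled instance, find its k nearest hits (same
#' class) and k nearest misses (other class) by Manhattan distance on
#' range-normalised features; decrement each feature's weight by the hit
#' differences and increment by the miss differences, normalising by
#' iterations x k. With `n_iterations >= n_samples` every instance is visited
#' once (exhaustive, deterministic); otherwise instances are sampled with the
#' given seed.
#'
#' @param fm a [feature_matrix].
#' @param k_neighbors neighbours per class (must be < each class count).
#' @param n_iterations instances to sample; `Inf`/`>= n` means exhaustive.
#' @param seed RNG seed for the sampling path.
#' @return a `feature_scores` object (`method = "relieff"`).
#' @export
relieff_scores <- function(fm, k_neighbors = 10L, n_iterations = Inf, seed = 1L) {
  tab <- check_two_class(fm)
  if (any(tab < k_neighbors + 1L)) {
    stop("relieff_scores: each class needs > k_neighbors samples")
  }
  X <- fm$X; y <- fm$y
  n <- nrow(X); p <- ncol(X)
  rng <- apply(X, 2, function(v) diff(range(v)))
  rng[rng == 0] <- 1                      # constant features contribute 0 anyway
  Xn <- sweep(sweep(X, 2, apply(X, 2, min)), 2, rng, "/")
  if (n_iterations >= n) {
    picks <- seq_len(n)
  } else {
    rs <- .Random.seed_save(); on.exit(.Random.seed_restore(rs), add = TRUE)
    set.seed(seed)
    picks <- sample.int(n, n_iterations)
  }
  D <- as.matrix(dist(Xn, method = "manhattan"))
  w <- numeric(p)
  k <- k_neighbors
  for (i in picks) {
    same <- setdiff(which(y == y[i]), i)
    other <- which(y != y[i])
    hits <- same[order(D[i, same], same)][seq_len(k)]
    misses <- other[order(D[i, other], other)][seq_len(k)]
    dh <- abs(sweep(Xn[hits, , drop = FALSE], 2, Xn[i, ]))
    dm <- abs(sweep(Xn[misses, , drop = FALSE], 2, Xn[i, ]))
    w <- w - colSums(dh) + colSums(dm)
  }
  feature_scores_obj("relieff", w / (length(picks) * k))
}

# Equal-width discretisation into n_bins; a constant feature occupies one bin.
discretize_ew <- function(x, n_bins) {
  r <- range(x)
  if (diff(r) == 0) return(rep(1L, length(x)))
  b <- pmin(floor((x - r[1]) / diff(r) * n_bins) + 1L, n_bins)
  as.integer(b)
}

# Mutual information (nats) of two discrete vectors from their contingency table.
discrete_mi <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  p <- tab / n
  pa <- rowSums(p); pb <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(pa, pb)[nz]))
}

#' Minimum-redundancy maximum-relevance feature selection
#'
#' Greedy MID (mutual-information difference) scheme: features and the class
#' are discretised into `n_bins` equal-width bins; the first pick maximises
#' `I(feature; class)`, then each subsequent pick maximises
#' `I(f; class) - mean_s I(f; s)` over the already-selected set `s`. Ties
#' break on the lowest feature index. Features whose discretisation collapses
#' to a single bin have MI 0 by construction.
#'
#' @param fm a [feature_matrix].
#' @param n_select number of features to pick (<= n_features).
#' @param n_bins equal-width bins for discretisation (>= 2).
#' @param redundancy_weight weight of the mean-redundancy penalty; 1 is the
#'   MID criterion, 0 reduces the selection to plain relevance ranking.
#' @return a `feature_scores` object (`method = "mrmr"`): `scores` are the
#'   relevance values `I(f; class)`, `selected_order` the greedy sequence,
#'   and `ranking` puts the selected features first (in selection order).
#' @export
mrmr_select <- function(fm, n_select = 10L, n_bins = 10L, redundancy_weight = 1) {
  check_two_class(fm, min_per_class = 1L)
  p <- ncol(fm$X)
  if (n_select > p) stop("mrmr_select: n_select exceeds the number of features")
  if (n_bins < 2L) stop("mrmr_select: n_bins must be >= 2")
  Xd <- apply(fm$X, 2, discretize_ew, n_bins = n_bins)
  rel <- vapply(seq_len(p), function(j) discrete_mi(Xd[, j], fm$y), numeric(1))
  selected <- integer(0)
  red_sum <- numeric(p)                # running sum of I(f; s) over selected s
  for (step in seq_len(n_select)) {
    if (step == 1L) {
      crit <- rel
    } else {
      crit <- rel - redundancy_weight * red_sum / length(selected)
    }
    crit[selected] <- -Inf
    pick <- which.max(crit)            # which.max takes the lowest index on ties
    selected <- c(selected, pick)
    if (step < n_select && redundancy_weight != 0) {
      red_sum <- red_sum + vapply(seq_len(p), function(j) {
        if (j %in% selected) 0 else discrete_mi(Xd[, j], Xd[, pick])
      }, numeric(1))
    }
  }
  out <- feature_scores_obj("mrmr", rel, selected_order = selected)
  out$ranking <- c(selected, setdiff(order(-rel, seq_len(p)), selected))
  out
}

#' Dispatch a feature-selection scorer by name
#'
#' @param fm a [feature_matrix].
#' @param method one of `"mrmr"`, `"relieff"`, `"chi2"`, `"anova_f"`,
#'   `"kruskal_wallis"`, `"none"`.
#' @param n_select features to select (used by mrmr; others rank all).
#' @param seed seed for stochastic scorers.
#' @return a `feature_scores` object; for `"none"`, all scores are equal and
#'   the ranking is the identity.
#' @export
score_features <- function(fm, method = c("none", "mrmr", "relieff", "chi2",
                                          "anova_f", "kruskal_wallis"),
                           n_select = ncol(fm$X), seed = 1L) {
  method <- match.arg(method)
  switch(method,
         none = feature_scores_obj("none", rep(0, ncol(fm$X))),
         mrmr = mrmr_select(fm, n_select = min(n_select, ncol(fm$X))),
         relieff = relieff_scores(fm, k_neighbors = min(10L, min(table(fm$y)) - 1L),
                                  seed = seed),
         chi2 = chi2_scores(shift_nonnegative(fm)),
         anova_f = anova_f_scores(fm),
         kruskal_wallis = kruskal_wallis_scores(fm))
}

# chi2 needs non-negative values; deep features are arbitrary-signed, so the
# dispatcher min-shifts each feature (documented scale behaviour).
shift_nonnegative <- function(fm) {
  fm$X <- sweep(fm$X, 2, pmin(apply(fm$X, 2, min), 0))
  fm
}

#' ROC curve and AUC
#'
#' AUC by the Mann-Whitney pair-counting definition (concordant pairs count
#' 1, ties 1/2) computed via midranks; ROC points from a threshold sweep over
#' the unique scores, whose trapezoidal area equals the pair-count AUC.
#'
#' @param scores per-sample continuous decision values (higher = more
#'   positive).
#' @param labels binary labels (1 = positive).
#' @return list `auc`, `roc_points` (data.frame `fpr`, `tpr` from (0,0) to
#'   (1,1)).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels > 0)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("roc_auc: both classes must be present (undefined metric)")
  r <- rank(scores)                       # midranks handle ties as 1/2
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(th) sum(scores >= th & labels == 1) / n1, numeric(1))
  fpr <- vapply(thr, function(th) sum(scores >= th & labels == 0) / n0, numeric(1))
  roc <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  if (roc$fpr[nrow(roc)] != 1 || roc$tpr[nrow(roc)] != 1) {
    roc <- rbind(roc, data.frame(fpr = 1, tpr = 1))
  }
  list(auc = auc, roc_points = roc)
}

#' Classification metrics from a confusion table
#'
#' Standard definitions; ratios with zero denominators are reported as NaN
#' with an entry in `undefined`, never silently as 0.
#'
#' @param TP,FP,FN,TN non-negative counts (total > 0).
#' @return list `accuracy`, `sensitivity`, `specificity`, `precision`, `f1`,
#'   `undefined` (character vector of metrics with zero denominators).
#' @export
confusion_metrics <- function(TP, FP, FN, TN) {
  cnt <- c(TP = TP, FP = FP, FN = FN, TN = TN)
  if (any(cnt < 0)) stop("confusion_metrics: counts must be non-negative")
  if (sum(cnt) == 0) stop("confusion_metrics: empty confusion table")
  safe <- function(num, den) if (!is.finite(den) || den == 0) NaN else num / den
  sens <- safe(TP, TP + FN)
  spec <- safe(TN, TN + FP)
  prec <- safe(TP, TP + FP)
  f1 <- safe(2 * prec * sens, prec + sens)
  und <- c("sensitivity", "specificity", "precision", "f1")[
    is.nan(c(sens, spec, prec, f1))]
  list(accuracy = (TP + TN) / sum(cnt), sensitivity = sens, specificity = spec,
       precision = prec, f1 = f1, undefined = und)
}

# Fit one classifier on training data, return continuous positive-class
# scores and hard labels on the test set.
fit_predict_classifier <- function(classifier, Xtr, ytr, Xte, seed) {
  ytr_f <- factor(ytr, levels = c(0, 1))
  colnames(Xtr) <- colnames(Xte) <- paste0("V", seq_len(ncol(Xtr)))
  if (classifier == "svm") {
    rs <- .Random.seed_save(); on.exit(.Random.seed_restore(rs), add = TRUE)
    set.seed(seed)
    m <- e1071::svm(Xtr, ytr_f, kernel = "radial", cost = 1, scale = TRUE,
                    probability = FALSE)
    pr <- predict(m, Xte, decision.values = TRUE)
    dv <- attr(pr, "decision.values")[, 1]
    # decision values are oriented towards the first class named in the column
    pos_first <- startsWith(colnames(attr(pr, "decision.values"))[1], "1")
    score <- if (pos_first) dv else -dv
    list(score = score, label = as.integer(as.character(pr)))
  } else if (classifier == "decision_tree") {
    df_tr <- data.frame(Xtr, y = ytr_f)
    rs <- .Random.seed_save(); on.exit(.Random.seed_restore(rs), add = TRUE)
    set.seed(seed)
    m <- rpart::rpart(y ~ ., data = df_tr,
                      method = "class",
                      parms = list(split = "gini"),
                      control = rpart::rpart.control(minsplit = 2, cp = 0.01,
                                                     xval = 0))
    pb <- predict(m, data.frame(Xte), type = "prob")[, "1"]
    list(score = pb, label = as.integer(pb > 0.5))
  } else if (classifier == "knn") {
    k <- min(5L, nrow(Xtr))
    # scale to the training distribution, as for the SVM
    mu <- colMeans(Xtr); sdev <- apply(Xtr, 2, sd); sdev[sdev == 0] <- 1
    Ztr <- scale(Xtr, mu, sdev); Zte <- scale(Xte, mu, sdev)
    rs <- .Random.seed_save(); on.exit(.Random.seed_restore(rs), add = TRUE)
    set.seed(seed)
    pr <- class::knn(Ztr, Zte, ytr_f, k = k, prob = TRUE, use.all = TRUE)
    win <- attr(pr, "prob")
    p_pos <- ifelse(pr == "1", win, 1 - win)
    list(score = p_pos, label = as.integer(as.character(pr)))
  } else stop("unknown classifier: ", classifier)
}

stratified_holdout <- function(y, frac_train, seed) {
  rs <- .Random.seed_save(); on.exit(.Random.seed_restore(rs), add = TRUE)
  set.seed(seed)
  tr <- unlist(lapply(unique(y), function(c) {
    i <- which(y == c)
    sample(i, max(1L, round(frac_train * length(i))))
  }))
  sort(tr)
}

#' Train and evaluate a classifier with leakage-safe feature selection
#'
#' Splits the data (stratified holdout by default), computes the requested
#' feature-selection scores on the training portion only, keeps the top
#' `k_features`, fits the classifier, and scores the held-out samples with a
#' continuous decision value. Fully reproducible for a fixed seed.
#'
#' @param fm a [feature_matrix].
#' @param classifier `"svm"`, `"decision_tree"` or `"knn"`.
#' @param selection scorer name passed to [score_features()] (`"none"`
#'   disables selection).
#' @param k_features number of top-ranked features kept when selection is
#'   active.
#' @param holdout_fraction training fraction for the stratified split.
#' @param seed RNG seed controlling the split and any classifier randomness.
#' @return an `eval_report` list: `auc`, `accuracy`, `sensitivity`,
#'   `specificity`, `precision`, `f1`, `roc_points`, `confusion`
#'   (TP/FP/FN/TN), `selected_features`, `split_seed`.
#' @export
train_eval <- function(fm, classifier = c("svm", "decision_tree", "knn"),
                       selection = "none", k_features = ncol(fm$X),
                       holdout_fraction = 0.7, seed = 1L) {
  classifier <- match.arg(classifier)
  check_two_class(fm)
  if (k_features > ncol(fm$X)) stop("train_eval: k_features exceeds available features")
  tr <- stratified_holdout(fm$y, holdout_fraction, seed)
  te <- setdiff(seq_len(nrow(fm$X)), tr)
  if (length(unique(fm$y[tr])) < 2L || length(unique(fm$y[te])) < 2L) {
    stop("train_eval: split produced a single-class fold")
  }
  fm_tr <- feature_matrix(fm$X[tr, , drop = FALSE], fm$y[tr])
  if (selection == "none") {
    keep <- seq_len(ncol(fm$X))
  } else {
    sc <- score_features(fm_tr, selection, n_select = k_features, seed = seed)
    keep <- sc$ranking[seq_len(k_features)]
  }
  pred <- fit_predict_classifier(classifier,
                                 fm$X[tr, keep, drop = FALSE], fm$y[tr],
                                 fm$X[te, keep, drop = FALSE], seed)
  roc <- roc_auc(pred$score, fm$y[te])
  yte <- fm$y[te]
  TP <- sum(pred$label == 1 & yte == 1); FP <- sum(pred$label == 1 & yte == 0)
  FN <- sum(pred$label == 0 & yte == 1); TN <- sum(pred$label == 0 & yte == 0)
  met <- confusion_metrics(TP, FP, FN, TN)
  structure(list(auc = roc$auc, accuracy = met$accuracy,
                 sensitivity = met$sensitivity, specificity = met$specificity,
                 precision = met$precision, f1 = met$f1,
                 roc_points = roc$roc_points,
                 confusion = list(TP = TP, FP = FP, FN = FN, TN = TN),
                 selected_features = keep, classifier = classifier,
                 selection = selection, split_seed = seed),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> ", x$classifier, " / selection=", x$selection,
      "\n  AUC ", round(x$auc, 4), "  accuracy ", round(x$accuracy, 4),
      "  sens ", round(x$sensitivity, 4), "  spec ", round(x$specificity, 4),
      "  precision ", round(x$precision, 4), "  F1 ", round(x$f1, 4), "\n",
      sep = "")
  invisible(x)
}
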