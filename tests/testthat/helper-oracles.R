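# Shared helpers and independent oracles for the test suite.

rel_err <- function(est, truth) abs(est - truth) / abs(truth)

# Cohort-mean ground truths used as generator inputs throughout.
NGIVIM_TRUTH <- c(S0 = 1000, f = 0.24, Dstar = 25.57e-3, D = 1.21e-3, K = 0.41)
EXT_TOFTS_TRUTH <- c(Ktrans = 0.27, ve = 0.38, vp = 0.03)
T10_TRUTH <- 1.16
R1_CA <- 3.9

# Coarse grid-search oracle: minimum residual sum of squares over a bounded
# parameter box, independent of the package optimiser.
grid_search_rss <- function(resid_fn, grids) {
  combos <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
  best <- Inf
  for (i in seq_len(nrow(combos))) {
    r <- resid_fn(as.numeric(combos[i, ]))
    rss <- sum(r^2)
    if (rss < best) best <- rss
  }
  best
}

# Brute-force ReliefF reference: literal textbook loops, exhaustive over all
# instances, k nearest hits/misses by Manhattan distance on range-normalised
# features. Independent of the package implementation.
relieff_bruteforce <- function(X, y, k) {
  n <- nrow(X); p <- ncol(X)
  rng <- apply(X, 2, function(v) diff(range(v)))
  rng[rng == 0] <- 1
  Xn <- sweep(sweep(X, 2, apply(X, 2, min)), 2, rng, "/")
  w <- numeric(p)
  for (i in seq_len(n)) {
    d <- rep(Inf, n)
    for (j in seq_len(n)) if (j != i) d[j] <- sum(abs(Xn[i, ] - Xn[j, ]))
    same <- which(y == y[i]); same <- same[same != i]
    other <- which(y != y[i])
    hits <- same[order(d[same], same)][seq_len(k)]
    misses <- other[order(d[other], other)][seq_len(k)]
    for (f in seq_len(p)) {
      w[f] <- w[f] - sum(abs(Xn[hits, f] - Xn[i, f])) +
        sum(abs(Xn[misses, f] - Xn[i, f]))
    }
  }
  w / (n * k)
}

# Brute-force mutual information of two discrete vectors (plain double loop
# over the contingency table).
mi_bruteforce <- function(a, b) {
  ua <- unique(a); ub <- unique(b)
  n <- length(a)
  mi <- 0
  for (x in ua) for (y in ub) {
    pxy <- sum(a == x & b == y) / n
    if (pxy > 0) mi <- mi + pxy * log(pxy / ((sum(a == x) / n) * (sum(b == y) / n)))
  }
  mi
}

# Pair-count AUC by explicit enumeration over all positive/negative pairs.
auc_paircount <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Trapezoid area under ROC points.
roc_trapezoid <- function(roc) {
  o <- order(roc$fpr, roc$tpr)
  sum(diff(roc$fpr[o]) * (head(roc$tpr[o], -1) + roc$tpr[o][-1]) / 2)
}

make_noiseless_dwi_spec <- function(grid = c(8, 8, 2)) {
  phantom_spec(grid, default_dwi_regions(), acquisition = default_bvalues())
}
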