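# Independent oracles used across the suite. These deliberately re-derive
# quantities by the most literal route available (exhaustive enumeration,
# direct formula evaluation) so they share no code with the implementation.

# Mann-Whitney AUC by exhaustive case-control pair enumeration, ties = 1/2
auc_pairwise <- function(scores, y) {
  cases <- scores[y == 1]
  controls <- scores[y == 0]
  tot <- 0
  for (a in cases) for (b in controls)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cases) * length(controls))
}

# topological overlap by direct triple loop over the formula
tom_manual <- function(a) {
  p <- nrow(a)
  k <- colSums(a) - diag(a)
  d <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(p)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    d[i, j] <- 1 - (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  d
}

# independent binned log-log regression of the connectivity histogram
binned_rsq_oracle <- function(k, n_bins) {
  br <- seq(min(k), max(k), length.out = n_bins + 1)
  idx <- findInterval(k, br, rightmost.closed = TRUE, all.inside = TRUE)
  xs <- ys <- numeric(0)
  for (b in unique(idx)) {
    kk <- k[idx == b]
    if (mean(kk) > 0) {
      xs <- c(xs, log10(mean(kk)))
      ys <- c(ys, log10(length(kk) / length(k)))
    }
  }
  if (length(xs) < 2 || stats::sd(xs) == 0) return(0)
  stats::cor(xs, ys)^2
}

# two columns with an exact target Pearson correlation
make_cor_pair <- function(n, r, seed = 1) {
  set.seed(seed)
  z <- qr.Q(qr(cbind(1, rnorm(n), rnorm(n))))[, 2:3]  # orthonormal, mean 0
  cbind(a = z[, 1], b = r * z[, 1] + sqrt(1 - r^2) * z[, 2])
}

# small latent one-factor block generator, independent of the package's own
make_block <- function(n, size, rho, seed) {
  set.seed(seed)
  f <- rnorm(n)
  sapply(seq_len(size), function(j) sqrt(rho) * f + sqrt(1 - rho) * rnorm(n))
}

# per-tree OOB permutation importance computed by hand on a randomForest,
# with an injectable permutation (identity permutation must contribute 0)
rf_perm_importance <- function(rf, X, y, feature, perm = sample) {
  inbag <- rf$inbag
  drops <- numeric(rf$ntree)
  for (t in seq_len(rf$ntree)) {
    oob <- which(inbag[, t] == 0)
    if (!length(oob)) { drops[t] <- NA; next }
    Xo <- X[oob, , drop = FALSE]
    pred <- predict(rf, Xo, predict.all = TRUE)$individual[, t]
    acc0 <- mean(pred == as.character(y[oob]))
    Xp <- Xo
    Xp[, feature] <- Xp[perm(seq_along(oob)), feature]
    predp <- predict(rf, Xp, predict.all = TRUE)$individual[, t]
    drops[t] <- acc0 - mean(predp == as.character(y[oob]))
  }
  mean(drops, na.rm = TRUE)
}

# fast small survey config used by pipeline tests
small_sim_config <- function(...) {
  sim_config(n_train = 600L, n_test = 600L,
             modules = list(list(size = 12L, rho = 0.75),
                            list(size = 10L, rho = 0.65)),
             n_independent = 8L,
             planted = data.frame(feature = c("m1_f01", "m2_f01", "ind_01"),
                                  beta = rep(1.3, 3)),
             language = list(
               levels = c("English", "Spanish", "Korean", "Tagalog"),
               probs = c(0.80, 0.13, 0.07, 0),
               effects = c(English = 0, Spanish = -1, Korean = -0.6,
                           Tagalog = 0)),
             ...)
}
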