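#' Control parameters for the fuzzy-forest screening stage
#'
#' @param keep_fraction fraction of each module retained by the per-module
#'   recursive feature elimination ("top thirty-five percent" by default).
#' @param number_selected size of the final selected set (default 20).
#' @param drop_fraction fraction of the current feature set eliminated per
#'   RFE iteration.
#' @param ntree trees per forest. The actual count is
#'   `max(ntree, trees_per_feature * p_current)` so every feature retains a
#'   realistic chance of entering the model as the feature set shrinks.
#' @param trees_per_feature per-feature tree floor (see `ntree`).
#' @param mtry candidate split variables per node; `NULL` means
#'   `ceiling(sqrt(p))`.
#' @param min_node_size minimal terminal node size. The default (25), with
#'   the depth cap, yields screening-oriented forests: stable importance
#'   ranking is what matters here, not fully-grown individual trees.
#' @param max_depth maximal tree depth (0 = unlimited).
#' @param sample_fraction per-tree subsample fraction.
#' @param replace sample with replacement (bootstrap) or without
#'   (subsampling; the default, which avoids the selection bias bootstrap
#'   resampling can induce and keeps an out-of-bag set of ~37%).
#' @param n_permutations importance replications: when `> 1`, permutation
#'   importance is averaged over this many independently seeded forests.
#' @param scale_importance divide each importance by its standard error
#'   (off by default: raw mean accuracy decrease is more stable when the
#'   standard error is near zero).
#' @param weighted_bootstrap use survey weights as case weights when growing
#'   trees (off by default; weights belong to the confirmatory model).
#' @param num_threads threads for the forest engine.
#' @return a list of class `"ff_control"`.
#' @export
ff_control <- function(keep_fraction = 0.35, number_selected = 20L,
                       drop_fraction = 0.5, ntree = 150L,
                       trees_per_feature = 3L, mtry = NULL,
                       min_node_size = 25L, max_depth = 8L,
                       sample_fraction = 0.632, replace = FALSE,
                       n_permutations = 1L, scale_importance = FALSE,
                       weighted_bootstrap = FALSE, num_threads = 1L) {
  stopifnot(keep_fraction > 0, keep_fraction <= 1,
            number_selected >= 1L,
            drop_fraction > 0, drop_fraction < 1,
            ntree >= 1L, trees_per_feature >= 0L,
            min_node_size >= 1L, max_depth >= 0L,
            sample_fraction > 0, sample_fraction <= 1,
            n_permutations >= 1L)
  structure(list(keep_fraction = keep_fraction,
                 number_selected = as.integer(number_selected),
                 drop_fraction = drop_fraction, ntree = as.integer(ntree),
                 trees_per_feature = as.integer(trees_per_feature),
                 mtry = mtry, min_node_size = as.integer(min_node_size),
                 max_depth = as.integer(max_depth),
                 sample_fraction = sample_fraction, replace = replace,
                 n_permutations = as.integer(n_permutations),
                 scale_importance = scale_importance,
                 weighted_bootstrap = weighted_bootstrap,
                 num_threads = as.integer(num_threads)),
            class = "ff_control")
}

#' Per-module survivor count
#'
#' Every module keeps `max(1, ceiling(keep_fraction * size))` features in the
#' screening stage — the "top thirty-five percent" rule with a floor of one
#' so no module is eliminated outright.
#'
#' @param size module size(s).
#' @param keep_fraction fraction kept (default 0.35).
#' @return integer vector of survivor counts.
#' @export
module_keep_n <- function(size, keep_fraction = 0.35) {
  stopifnot(all(size >= 1L), keep_fraction > 0, keep_fraction <= 1)
  pmax(1L, as.integer(ceiling(keep_fraction * size)))
}

# number of trees actually grown for p features
n_trees_for <- function(control, p) {
  max(control$ntree, control$trees_per_feature * p)
}

fit_forest <- function(x, y, control, seed, weights = NULL,
                       probability = FALSE) {
  p <- ncol(x)
  ranger::ranger(
    x = as.data.frame(x), y = factor(y, levels = c(0L, 1L)),
    probability = probability,
    num.trees = n_trees_for(control, p),
    mtry = if (is.null(control$mtry)) ceiling(sqrt(p)) else
      min(control$mtry, p),
    importance = if (probability) "none" else "permutation",
    scale.permutation.importance = isTRUE(control$scale_importance),
    min.node.size = control$min_node_size,
    max.depth = if (control$max_depth > 0L) control$max_depth else NULL,
    sample.fraction = control$sample_fraction,
    replace = control$replace,
    case.weights = if (isTRUE(control$weighted_bootstrap)) weights else NULL,
    num.threads = control$num_threads,
    seed = seed)
}

#' Out-of-bag permutation importance
#'
#' Fits a classification random forest and reports, per feature, the mean
#' decrease in out-of-bag accuracy when that feature is permuted — averaged
#' across trees and, when `n_permutations > 1`, across independently seeded
#' replicate forests. Deterministic given the seed.
#'
#' @param x numeric feature matrix (constant columns are allowed and simply
#'   receive importance near zero).
#' @param y binary outcome (0/1, logical or two-level factor) with both
#'   classes present; at least 20 observations.
#' @param control an [ff_control()] list.
#' @param seed integer seed.
#' @param weights optional survey weights, used only when
#'   `control$weighted_bootstrap` is TRUE.
#' @return data frame of class `"importance_table"` with columns `feature`,
#'   `vim`, `rank` (1 = most important; ties broken by feature name),
#'   ordered by rank.
#' @export
oob_importance <- function(x, y, control = ff_control(), seed = 1L,
                           weights = NULL) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  y <- check_binary_outcome(y)
  if (length(y) < 20L)
    stop("need at least 20 observations for out-of-bag importance",
         call. = FALSE)
  vims <- vapply(seq_len(control$n_permutations), function(r) {
    f <- fit_forest(x, y, control, seed = derive_seed(seed, paste0("perm_", r)),
                    weights = weights)
    f$variable.importance[colnames(x)]
  }, numeric(ncol(x)))
  vim <- if (is.matrix(vims)) rowMeans(vims) else vims
  out <- data.frame(feature = colnames(x), vim = unname(vim),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$vim, out$feature), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("importance_table", "data.frame")
  out
}

#' Recursive feature elimination with a random forest
#'
#' Repeatedly fits a forest and drops the `ceiling(drop_fraction * p)`
#' least-important features, never dropping below `keep_n`; the final
#' iteration truncates to exactly `keep_n` features by importance rank.
#'
#' @param x feature matrix.
#' @param y binary outcome.
#' @param keep_n number of survivors (1 <= keep_n <= ncol(x)).
#' @param control an [ff_control()] list.
#' @param seed integer seed; each elimination round uses a seed derived from
#'   it.
#' @param weights optional survey weights (see [ff_control()]).
#' @return list with `survivors` (character vector, ordered by final-round
#'   rank) and `importance` (the last-round [oob_importance()] table
#'   restricted to the survivors).
#' @export
rfe_select <- function(x, y, keep_n, control = ff_control(), seed = 1L,
                       weights = NULL) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  keep_n <- as.integer(keep_n)
  stopifnot(keep_n >= 1L, keep_n <= ncol(x))
  current <- sort(colnames(x))
  round <- 0L
  imp <- NULL
  repeat {
    round <- round + 1L
    imp <- oob_importance(x[, current, drop = FALSE], y, control,
                          seed = derive_seed(seed, paste0("rfe_", round)),
                          weights = weights)
    if (length(current) <= keep_n) break
    n_drop <- min(ceiling(control$drop_fraction * length(current)),
                  length(current) - keep_n)
    current <- imp$feature[seq_len(length(current) - n_drop)]
  }
  surv <- imp$feature[seq_len(keep_n)]
  list(survivors = surv,
       importance = imp[imp$feature %in% surv, , drop = FALSE])
}
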