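#' Per-module screening by recursive feature elimination
#'
#' Runs [rfe_select()] within each module of the partition, including the
#' pseudo-module of unassigned features (label 0): independent predictors are
#' exactly the variables that correlation bias penalizes, so they are
#' screened rather than discarded. Each module keeps
#' `max(1, ceiling(keep_fraction * size))` features. Per-module seeds are
#' derived by name from the master seed, so screening order cannot change
#' results.
#'
#' @param x feature matrix.
#' @param y binary outcome.
#' @param partition a `"module_partition"` from [build_network()], or a named
#'   integer vector of labels covering the columns of `x`.
#' @param control an [ff_control()] list.
#' @param seed master integer seed.
#' @param weights optional survey weights (see [ff_control()]).
#' @return named list (one element per module id, as character) of character
#'   vectors of surviving features.
#' @export
screen_modules <- function(x, y, partition, control = ff_control(),
                           seed = 1L, weights = NULL) {
  labels <- if (inherits(partition, "module_partition")) partition$labels
            else partition
  x <- as.matrix(x)
  if (!all(colnames(x) %in% names(labels)))
    stop("partition does not cover all feature columns", call. = FALSE)
  labels <- labels[colnames(x)]
  ids <- sort(unique(labels))
  out <- lapply(ids, function(id) {
    memb <- names(labels)[labels == id]
    keep_n <- module_keep_n(length(memb), control$keep_fraction)
    if (keep_n >= length(memb)) return(sort(memb))
    rfe_select(x[, memb, drop = FALSE], y, keep_n, control,
               seed = derive_seed(seed, paste0("module_", id)),
               weights = weights)$survivors
  })
  names(out) <- as.character(ids)
  out
}

#' Final selection forest over the pooled survivors
#'
#' All module survivors enter a single recursive feature elimination forest;
#' the top `min(number_selected, n survivors)` features are returned, ordered
#' by final importance.
#'
#' @inheritParams screen_modules
#' @param survivors character vector of pooled surviving features (non-empty
#'   subset of `colnames(x)`).
#' @return data frame with columns `feature`, `vim`, `rank`.
#' @export
select_final <- function(x, y, survivors, control = ff_control(), seed = 1L,
                         weights = NULL) {
  stopifnot(length(survivors) >= 1L, all(survivors %in% colnames(x)))
  keep_n <- min(control$number_selected, length(survivors))
  res <- rfe_select(x[, survivors, drop = FALSE], y, keep_n, control,
                    seed = derive_seed(seed, "final"), weights = weights)
  out <- res$importance
  out <- out[match(res$survivors, out$feature), c("feature", "vim", "rank")]
  rownames(out) <- NULL
  out
}

#' Fit a fuzzy forest
#'
#' Two-stage variable screening for correlated features. Stage 1 partitions
#' the features into modules from their correlation structure alone
#' ([build_network()]; the outcome is never consulted). Stage 2 screens each
#' module by recursive feature elimination with out-of-bag permutation
#' importance and then selects a final feature set from the pooled module
#' survivors. A single master seed governs all stage-2 randomness.
#'
#' @param x numeric respondent-by-feature matrix. Must not contain the
#'   outcome or the survey-weight column (an error results if `y` matches a
#'   column of `x`).
#' @param y binary outcome (0/1, logical or two-level factor).
#' @param net_options stage-1 settings from [network_options()].
#' @param control stage-2 settings from [ff_control()].
#' @param seed master integer seed.
#' @param weights optional survey weights, only used when
#'   `control$weighted_bootstrap` is TRUE.
#' @param partition optionally, a precomputed `"module_partition"` (or named
#'   label vector) to reuse — e.g. across repeated stage-2 runs, since stage 1
#'   is deterministic.
#' @param refit refit a probability forest on the selected features (needed
#'   by [predict.fuzzy_forest()]; skipped during stability runs).
#' @return an object of class `"fuzzy_forest"`: `selected` (data frame
#'   feature/vim/rank/module), `survivors_by_module`, `partition`, a refit
#'   `final_forest` on the selected features (for [predict.fuzzy_forest()]),
#'   `params` and `seed`.
#' @seealso [stability_selection()], [module_importance_summary()]
#' @export
fuzzy_forest <- function(x, y, net_options = network_options(),
                         control = ff_control(), seed = 1L, weights = NULL,
                         partition = NULL, refit = TRUE) {
  x <- check_feature_matrix(x, min_p = 3L)
  y <- check_binary_outcome(y)
  if (nrow(x) != length(y)) stop("nrow(x) must equal length(y)")
  same <- vapply(seq_len(ncol(x)),
                 function(j) isTRUE(all.equal(unname(x[, j]), as.numeric(y))),
                 logical(1))
  if (any(same))
    stop("feature matrix appears to contain the outcome column: ",
         paste(colnames(x)[same], collapse = ", "), call. = FALSE)
  if (is.null(partition)) partition <- build_network(x, net_options)
  survivors_by_module <- screen_modules(x, y, partition, control, seed,
                                        weights)
  pooled <- unlist(survivors_by_module, use.names = FALSE)
  selected <- select_final(x, y, pooled, control, seed, weights)
  labels <- if (inherits(partition, "module_partition")) partition$labels
            else partition
  selected$module <- unname(labels[selected$feature])
  final_forest <- if (refit)
    fit_forest(x[, selected$feature, drop = FALSE], y, control,
               seed = derive_seed(seed, "refit"),
               weights = weights, probability = TRUE)
  structure(list(selected = selected,
                 survivors_by_module = survivors_by_module,
                 partition = partition, final_forest = final_forest,
                 net_options = net_options, control = control,
                 seed = as.integer(seed), call = match.call()),
            class = "fuzzy_forest")
}

#' @export
print.fuzzy_forest <- function(x, ...) {
  cat("Fuzzy forest fit (seed", x$seed, ")\n")
  labels <- if (inherits(x$partition, "module_partition")) x$partition$labels
            else x$partition
  cat(sprintf("  %d features in %d modules -> %d survivors -> %d selected\n",
              length(labels), length(x$survivors_by_module),
              sum(lengths(x$survivors_by_module)), nrow(x$selected)))
  cat("Top selected features:\n")
  print(utils::head(x$selected, 10L), row.names = FALSE)
  invisible(x)
}

#' @export
summary.fuzzy_forest <- function(object, ...) {
  out <- list(selected = object$selected,
              modplot = module_importance_summary(object),
              n_survivors = sum(lengths(object$survivors_by_module)),
              seed = object$seed)
  class(out) <- "summary.fuzzy_forest"
  out
}

#' @export
print.summary.fuzzy_forest <- function(x, ...) {
  cat("Selected features:\n")
  print(x$selected, row.names = FALSE)
  cat("\nPer-module selection (modplot):\n")
  print(x$modplot, row.names = FALSE)
  invisible(x)
}

#' Predicted class probabilities from a fuzzy forest
#'
#' Uses the probability forest refit on the selected features.
#'
#' @param object a `"fuzzy_forest"` fit.
#' @param newdata matrix or data frame containing at least the selected
#'   feature columns.
#' @param ... unused.
#' @return numeric vector of P(y = 1).
#' @export
predict.fuzzy_forest <- function(object, newdata, ...) {
  if (is.null(object$final_forest))
    stop("fit was run with refit = FALSE; no prediction forest available",
         call. = FALSE)
  nd <- as.data.frame(newdata)[, object$selected$feature, drop = FALSE]
  pr <- stats::predict(object$final_forest, data = nd,
                       num.threads = object$control$num_threads)
  p <- pr$predictions
  if (is.matrix(p)) p[, "1"] else as.numeric(as.character(p))
}

#' Per-module selection percentages ("modplot")
#'
#' For every module (including those with no selections) reports the number
#' of its features in the final selected set and that count as a percentage
#' of the module size.
#'
#' @param fit a `"fuzzy_forest"` object.
#' @return data frame with columns `module`, `module_size`, `n_selected`,
#'   `percent_important`.
#' @export
module_importance_summary <- function(fit) {
  stopifnot(inherits(fit, "fuzzy_forest"))
  labels <- if (inherits(fit$partition, "module_partition"))
    fit$partition$labels else fit$partition
  ids <- sort(unique(labels))
  n_sel <- vapply(ids, function(id)
    sum(fit$selected$module == id), integer(1))
  size <- vapply(ids, function(id) sum(labels == id), integer(1))
  data.frame(module = ids, module_size = size, n_selected = n_sel,
             percent_important = 100 * n_sel / size)
}

#' Plot method: the modplot
#'
#' Barplot of the per-module percentage of features that reached the final
#' selected set.
#'
#' @param x a `"fuzzy_forest"` object.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.fuzzy_forest <- function(x, ...) {
  m <- module_importance_summary(x)
  graphics::barplot(m$percent_important,
                    names.arg = ifelse(m$module == 0, "unassigned",
                                       paste0("M", m$module)),
                    ylab = "% of module selected", xlab = "module", ...)
  invisible(m)
}

#' Selection stability across repeated stage-2 runs
#'
#' Recomputes the supervised stage with `n_runs` distinct derived seeds
#' (stage 1 is deterministic, so the network is built once and reused) and
#' reports, per feature, the fraction of runs in which it was selected.
#'
#' @inheritParams fuzzy_forest
#' @param n_runs number of repeated runs (>= 2).
#' @param master_seed integer seed from which the per-run seeds are derived.
#' @return data frame with columns `feature` and `frequency`, sorted by
#'   decreasing frequency; attribute `"n_runs"` records the repeat count.
#' @export
stability_selection <- function(x, y, net_options = network_options(),
                                control = ff_control(), n_runs = 50L,
                                master_seed = 1L, weights = NULL,
                                partition = NULL) {
  stopifnot(n_runs >= 2L)
  x <- check_feature_matrix(x, min_p = 3L)
  if (is.null(partition)) partition <- build_network(x, net_options)
  counts <- integer(ncol(x))
  names(counts) <- colnames(x)
  for (r in seq_len(n_runs)) {
    fit <- fuzzy_forest(x, y, net_options, control,
                        seed = derive_seed(master_seed, paste0("run_", r)),
                        weights = weights, partition = partition,
                        refit = FALSE)
    counts[fit$selected$feature] <- counts[fit$selected$feature] + 1L
  }
  out <- data.frame(feature = names(counts),
                    frequency = unname(counts) / n_runs)
  out <- out[order(-out$frequency, out$feature), ]
  rownames(out) <- NULL
  attr(out, "n_runs") <- as.integer(n_runs)
  out
}

#' Write screening artifacts as plain text
#'
#' Emits `selected.csv` (rank, feature, vim, module), `survivors.csv`
#' (module, feature), `modplot.csv` and a `manifest.json` holding the
#' parameters and seed.
#'
#' @param fit a `"fuzzy_forest"` object.
#' @param dir output directory (created if needed).
#' @param stability optional data frame from [stability_selection()], written
#'   as `stability.csv`.
#' @return `dir`, invisibly.
#' @export
write_fuzzy_forest <- function(fit, dir, stability = NULL) {
  stopifnot(inherits(fit, "fuzzy_forest"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(fit$selected[, c("rank", "feature", "vim", "module")],
                   file.path(dir, "selected.csv"), row.names = FALSE)
  surv <- data.frame(
    module = rep(names(fit$survivors_by_module),
                 lengths(fit$survivors_by_module)),
    feature = unlist(fit$survivors_by_module, use.names = FALSE))
  utils::write.csv(surv, file.path(dir, "survivors.csv"), row.names = FALSE)
  utils::write.csv(module_importance_summary(fit),
                   file.path(dir, "modplot.csv"), row.names = FALSE)
  if (!is.null(stability))
    utils::write.csv(stability, file.path(dir, "stability.csv"),
                     row.names = FALSE)
  manifest <- list(seed = fit$seed,
                   net_options = unclass(fit$net_options),
                   control = unclass(fit$control),
                   package_version =
                     as.character(utils::packageVersion("fuzzyscreen")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Plain single-forest top-k selection (comparison baseline)
#'
#' Selects the `k` features with the highest out-of-bag permutation
#' importance from one random forest on all features — the approach whose
#' correlation bias motivates the two-stage screen.
#'
#' @inheritParams oob_importance
#' @param k number of features to select.
#' @return character vector of the top-`k` features.
#' @export
single_forest_topk <- function(x, y, k, control = ff_control(), seed = 1L) {
  imp <- oob_importance(x, y, control, seed)
  imp$feature[seq_len(min(k, nrow(imp)))]
}
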