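#' Options for the weighted correlation network (stage 1)
#'
#' Parameters of the unsupervised screening stage: soft-threshold power,
#' scale-free fit target, clustering cut and module-merge threshold.
#'
#' @param power soft-threshold exponent applied to absolute Pearson
#'   correlations. The default 7 targets approximate scale-free topology in
#'   survey-sized feature sets. Set to `NULL` to choose the power from
#'   `candidate_powers` via [pick_soft_power()].
#' @param candidate_powers ascending integer grid searched when `power` is
#'   `NULL`.
#' @param rsq_target scale-free model-fit threshold in `[0, 1]` used by
#'   [pick_soft_power()].
#' @param min_module_size clusters smaller than this are left unassigned
#'   (module label 0).
#' @param merge_similarity modules whose eigenfactors correlate above this
#'   value are merged ("more than 50 percent similarity" by default).
#' @param n_bins connectivity histogram bins for the scale-free fit index.
#' @param cut_height static tree-cut height as a fraction of the maximum
#'   dendrogram height. Soft-thresholding at a high power compresses
#'   topological overlap toward zero, so unrelated features join only at
#'   dissimilarity ~1; the default cuts just below that ceiling.
#' @param use_tom cluster on topological-overlap dissimilarity (default) or
#'   directly on `1 - adjacency`.
#' @return a list of class `"ff_network_options"`.
#' @export
network_options <- function(power = 7L, candidate_powers = 1:12,
                            rsq_target = 0.8, min_module_size = 5L,
                            merge_similarity = 0.5, n_bins = 10L,
                            cut_height = 0.99, use_tom = TRUE) {
  if (!is.null(power)) {
    power <- as.integer(power)
    stopifnot(length(power) == 1L, power >= 1L)
  }
  candidate_powers <- as.integer(candidate_powers)
  stopifnot(length(candidate_powers) >= 1L,
            !is.unsorted(candidate_powers, strictly = TRUE),
            all(candidate_powers >= 1L),
            rsq_target >= 0, rsq_target <= 1,
            min_module_size >= 1L,
            merge_similarity > 0, merge_similarity < 1,
            n_bins >= 2L, cut_height > 0, cut_height <= 1)
  structure(list(power = power, candidate_powers = candidate_powers,
                 rsq_target = rsq_target,
                 min_module_size = as.integer(min_module_size),
                 merge_similarity = merge_similarity,
                 n_bins = as.integer(n_bins), cut_height = cut_height,
                 use_tom = isTRUE(use_tom)),
            class = "ff_network_options")
}

#' Soft-thresholded adjacency matrix
#'
#' Unsigned weighted network: `a_ij = |cor(x_i, x_j)|^power` (Pearson), with
#' unit diagonal.
#'
#' @param x numeric respondent-by-feature matrix (at least 3 features, each
#'   with nonzero variance).
#' @param power soft-threshold exponent, `>= 1`.
#' @return symmetric `p x p` matrix in `[0, 1]` with feature names.
#' @export
soft_adjacency <- function(x, power = 7) {
  stopifnot(power >= 1)
  x <- check_feature_matrix(x, min_p = 3L)
  a <- abs(stats::cor(x))^power
  diag(a) <- 1
  a
}

#' Scale-free topology fit index
#'
#' Bins node connectivities `k_i = sum_{j != i} a_ij`, then regresses
#' `log10(bin frequency)` on `log10(mean bin connectivity)` over non-empty
#' bins; the R-squared of that fit measures how closely the connectivity
#' distribution follows a power law.
#'
#' @param adjacency symmetric adjacency matrix from [soft_adjacency()].
#' @param n_bins number of equal-width connectivity bins (`>= 2`).
#' @return list with `rsq`, `slope`, `mean_connectivity` and `degenerate`
#'   (TRUE when the log-log regression is undefined, e.g. all connectivities
#'   equal; `rsq` is then reported as 0).
#' @export
scale_free_fit <- function(adjacency, n_bins = 10L) {
  stopifnot(is.matrix(adjacency), nrow(adjacency) == ncol(adjacency),
            n_bins >= 2L)
  k <- colSums(adjacency) - diag(adjacency)
  out <- list(rsq = 0, slope = NA_real_, mean_connectivity = mean(k),
              degenerate = TRUE)
  if (diff(range(k)) < .Machine$double.eps^0.5) return(out)
  breaks <- seq(min(k), max(k), length.out = n_bins + 1L)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  kbar <- tapply(k, bin, mean)
  freq <- tapply(k, bin, length)
  keep <- !is.na(kbar) & kbar > 0
  if (sum(keep) < 2L) return(out)
  lx <- log10(kbar[keep])
  ly <- log10(freq[keep] / length(k))
  if (stats::sd(lx) == 0) return(out)
  fit <- stats::lm(ly ~ lx)
  list(rsq = summary(fit)$r.squared,
       slope = unname(stats::coef(fit)[2L]),
       mean_connectivity = mean(k),
       degenerate = FALSE)
}

#' Choose the soft-threshold power
#'
#' Returns the smallest candidate power whose scale-free fit index reaches
#' `rsq_target`; if none does, the power with the largest index is returned
#' and flagged.
#'
#' @param x feature matrix.
#' @param options a [network_options()] list; `candidate_powers`,
#'   `rsq_target` and `n_bins` are used.
#' @return list with `power`, `reached_target` flag and `path`, a data frame
#'   of per-power `rsq`, `slope` and `mean_connectivity`.
#' @export
pick_soft_power <- function(x, options = network_options()) {
  x <- check_feature_matrix(x, min_p = 3L)
  pw <- options$candidate_powers
  r <- abs(stats::cor(x))
  path <- do.call(rbind, lapply(pw, function(b) {
    a <- r^b; diag(a) <- 1
    f <- scale_free_fit(a, options$n_bins)
    data.frame(power = b, rsq = f$rsq, slope = f$slope,
               mean_connectivity = f$mean_connectivity)
  }))
  hit <- which(path$rsq >= options$rsq_target)
  if (length(hit)) {
    list(power = pw[hit[1L]], reached_target = TRUE, path = path)
  } else {
    warning("no candidate power reached the scale-free fit target; ",
            "returning the best-fitting power", call. = FALSE)
    list(power = pw[which.max(path$rsq)], reached_target = FALSE, path = path)
  }
}

#' Topological overlap dissimilarity
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`;
#' the returned dissimilarity is `1 - TOM` with zero diagonal.
#'
#' @param adjacency adjacency matrix from [soft_adjacency()].
#' @return symmetric dissimilarity matrix with entries in `[0, 1]`.
#' @export
tom_dissimilarity <- function(adjacency) {
  a <- adjacency
  stopifnot(is.matrix(a), nrow(a) == ncol(a))
  k <- colSums(a) - diag(a)
  # sum_u in the overlap excludes u = i and u = j; a %*% a includes both
  shared <- a %*% a - outer(diag(a), rep(1, ncol(a))) * a -
    a * outer(rep(1, ncol(a)), diag(a))
  num <- shared + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  d <- 1 - tom
  d[d < 0] <- 0
  (d + t(d)) / 2
}

#' Detect modules by average-linkage clustering
#'
#' Clusters the dissimilarity matrix with average linkage and cuts the tree
#' at a fixed fraction of its maximum height. Clusters smaller than
#' `min_module_size` are unassigned (label 0); the rest are labelled
#' `1..K` by decreasing size, ties broken by the lexicographically smallest
#' member feature name. Features are clustered in lexicographic name order so
#' the result is invariant to column permutation.
#'
#' @param dissimilarity symmetric matrix with zero diagonal, feature names on
#'   the dimnames.
#' @param options a [network_options()] list.
#' @return named integer vector of module labels.
#' @export
detect_modules <- function(dissimilarity, options = network_options()) {
  d <- dissimilarity
  stopifnot(is.matrix(d), nrow(d) == ncol(d),
            max(abs(diag(d))) < 1e-12,
            max(abs(d - t(d))) < 1e-8)
  nm <- colnames(d)
  if (is.null(nm)) nm <- paste0("V", seq_len(ncol(d)))
  ord <- order(nm)
  d <- d[ord, ord]
  tree <- stats::hclust(stats::as.dist(d), method = "average")
  h <- options$cut_height * max(tree$height)
  raw <- stats::cutree(tree, h = h)
  labels <- relabel_modules(raw, nm[ord], options$min_module_size)
  labels[match(nm, nm[ord])]
}

# size-ordered relabelling with the name-based tie break and the 0 label for
# undersized clusters
relabel_modules <- function(raw, feature_names, min_module_size) {
  sizes <- table(raw)
  keep_ids <- names(sizes)[sizes >= min_module_size]
  first_name <- vapply(keep_ids, function(id)
    min(feature_names[raw == as.integer(id)]), character(1))
  o <- order(-sizes[keep_ids], first_name)
  new <- integer(length(raw))
  for (i in seq_along(o)) new[raw == as.integer(keep_ids[o[i]])] <- i
  names(new) <- feature_names
  new
}

#' Module eigenfactors (eigengenes)
#'
#' The eigenfactor of a module is the first principal component of its
#' standardized member columns, scaled to unit norm and sign-fixed so its
#' correlation with the module's mean standardized feature is nonnegative.
#'
#' @param x feature matrix.
#' @param labels named integer module labels (0 = unassigned is skipped).
#' @return list with `eigengenes` (an `n x K` matrix, one column per nonzero
#'   module) and `variance_explained` (leading-eigenvalue share per module).
#' @export
module_eigengenes <- function(x, labels) {
  x <- as.matrix(x)
  if (is.null(names(labels))) names(labels) <- colnames(x)
  stopifnot(all(names(labels) %in% colnames(x)))
  ids <- sort(unique(labels[labels > 0]))
  if (!length(ids))
    return(list(eigengenes = matrix(numeric(0), nrow(x), 0),
                variance_explained = numeric(0)))
  e <- matrix(NA_real_, nrow(x), length(ids),
              dimnames = list(NULL, paste0("ME", ids)))
  ve <- numeric(length(ids))
  for (i in seq_along(ids)) {
    memb <- names(labels)[labels == ids[i]]
    z <- scale(x[, memb, drop = FALSE])
    if (length(memb) == 1L) {
      v <- z[, 1L]
      ve[i] <- 1
    } else {
      sv <- svd(z, nu = 1L, nv = 0L)
      v <- sv$u[, 1L]
      ve[i] <- sv$d[1L]^2 / sum(sv$d^2)
    }
    v <- v / sqrt(sum(v^2))
    if (stats::cor(v, rowMeans(z)) < 0) v <- -v
    e[, i] <- v
  }
  names(ve) <- colnames(e)
  list(eigengenes = e, variance_explained = ve)
}

#' Merge similar modules
#'
#' Iteratively merges the most-similar pair of modules while any pair of
#' eigenfactors correlates above `merge_similarity`, recomputing eigenfactors
#' after each merge.
#'
#' @param x feature matrix.
#' @param labels named integer module labels.
#' @param options a [network_options()] list.
#' @return object of class `"module_partition"`: `labels`, `eigengenes`,
#'   `variance_explained`, `merge_history` (data frame of merged pairs and
#'   their similarity) and `params`.
#' @export
merge_modules <- function(x, labels, options = network_options()) {
  x <- as.matrix(x)
  if (is.null(names(labels))) names(labels) <- colnames(x)
  history <- data.frame(module_a = integer(), module_b = integer(),
                        similarity = numeric())
  repeat {
    ids <- sort(unique(labels[labels > 0]))
    if (length(ids) < 2L) break
    me <- module_eigengenes(x, labels)
    cc <- stats::cor(me$eigengenes)
    diag(cc) <- -Inf
    best <- which(cc == max(cc), arr.ind = TRUE)[1L, ]
    if (max(cc) <= options$merge_similarity) break
    a <- ids[best[1L]]; b <- ids[best[2L]]
    history <- rbind(history,
                     data.frame(module_a = min(a, b), module_b = max(a, b),
                                similarity = max(cc)))
    labels[labels == max(a, b)] <- min(a, b)
  }
  # renumber surviving modules 1..K by decreasing size; unassigned stay 0
  nz <- labels > 0
  if (any(nz))
    labels[nz] <- relabel_modules(labels[nz], names(labels)[nz],
                                  min_module_size = 1L)
  me <- module_eigengenes(x, labels)
  structure(list(labels = labels, eigengenes = me$eigengenes,
                 variance_explained = me$variance_explained,
                 merge_history = history, params = options),
            class = "module_partition")
}

#' Build the full stage-1 network partition
#'
#' Pipeline: (optionally pick the soft power) -> soft adjacency ->
#' topological-overlap dissimilarity -> average-linkage module detection ->
#' eigenfactor merging. Entirely deterministic: the outcome variable plays no
#' role and no randomness is involved.
#'
#' @param x feature matrix (must not contain outcome or weight columns).
#' @param options a [network_options()] list.
#' @return a `"module_partition"` with the extra fields `power` and
#'   `power_path` (when the power was searched).
#' @export
build_network <- function(x, options = network_options()) {
  x <- check_feature_matrix(x, min_p = 3L)
  path <- NULL
  power <- options$power
  if (is.null(power)) {
    pick <- pick_soft_power(x, options)
    power <- pick$power
    path <- pick$path
  }
  a <- soft_adjacency(x, power)
  d <- if (options$use_tom) tom_dissimilarity(a) else {
    dd <- 1 - a; diag(dd) <- 0; dd
  }
  labels <- detect_modules(d, options)
  part <- merge_modules(x, labels, options)
  part$power <- power
  part$power_path <- path
  part
}

#' Write stage-1 network artifacts as plain text
#'
#' Emits `modules.csv` (feature, module_id, module_size),
#' `eigengenes.csv` (respondent by module), `merge_history.json` and, when
#' the soft power was searched, `power_path.csv`.
#'
#' @param partition a `"module_partition"` from [build_network()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_network <- function(partition, dir) {
  stopifnot(inherits(partition, "module_partition"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sizes <- table(partition$labels)
  memb <- data.frame(feature = names(partition$labels),
                     module_id = unname(partition$labels),
                     module_size =
                       as.integer(sizes[as.character(partition$labels)]))
  utils::write.csv(memb, file.path(dir, "modules.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(partition$eigengenes),
                   file.path(dir, "eigengenes.csv"), row.names = FALSE)
  jsonlite::write_json(partition$merge_history,
                       file.path(dir, "merge_history.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(partition$power_path))
    utils::write.csv(partition$power_path,
                     file.path(dir, "power_path.csv"), row.names = FALSE)
  invisible(dir)
}

#' @export
print.module_partition <- function(x, ...) {
  sizes <- table(factor(x$labels, levels = 0:max(x$labels)))
  k <- sum(as.integer(names(sizes)) > 0 & sizes > 0)
  cat("Module partition:", length(x$labels), "features,", k, "modules",
      sprintf("(%d unassigned)\n", sizes["0"]))
  if (k > 0) {
    tab <- data.frame(module = seq_len(k),
                      size = as.integer(sizes[as.character(seq_len(k))]),
                      variance_explained =
                        round(x$variance_explained[paste0("ME", seq_len(k))], 3))
    print(tab, row.names = FALSE)
  }
  if (nrow(x$merge_history))
    cat(nrow(x$merge_history), "merge(s) above similarity",
        x$params$merge_similarity, "\n")
  invisible(x)
}
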