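test_that("soft adjacency raises absolute correlations to the power", {
  x <- cbind(make_cor_pair(50, 0.5), extra = rnorm(50))
  a <- soft_adjacency(x, 7)
  expect_equal(a["a", "b"], 0.5^7, tolerance = 1e-12)
  expect_equal(diag(a), rep(1, 3), ignore_attr = TRUE)
  expect_true(isSymmetric(a))

  # perfect negative correlation saturates at 1 for any power
  y <- cbind(make_cor_pair(50, -1)[, 1:2], extra = rnorm(50))
  y[, 2] <- -y[, 1]
  for (pw in c(1, 3, 7)) {
    expect_equal(soft_adjacency(y, pw)[1, 2], 1, tolerance = 1e-12)
  }

  # identical (perfectly correlated) columns give the all-ones matrix
  z <- matrix(rep(rnorm(30), 4), ncol = 4)
  expect_equal(unname(soft_adjacency(z, 7)), matrix(1, 4, 4))
})

test_that("soft adjacency validates its input", {
  x <- cbind(a = rnorm(20), b = rep(2, 20), c = rnorm(20))
  expect_error(soft_adjacency(x, 7), "zero-variance.*b")
  expect_error(soft_adjacency(matrix(rnorm(20), ncol = 2), 7), "at least 3")
  expect_error(soft_adjacency(matrix(rnorm(30), ncol = 3), 0.5))
})

test_that("raising the power weakly shrinks every off-diagonal entry", {
  set.seed(11)
  x <- matrix(rnorm(200), ncol = 8)
  a3 <- soft_adjacency(x, 3); a5 <- soft_adjacency(x, 5)
  off <- upper.tri(a3)
  expect_true(all(a5[off] <= a3[off]))
  expect_true(all(a5[off][a3[off] < 1] < a3[off][a3[off] < 1]))
})

test_that("scale-free fit index matches an independent binned regression", {
  # two connectivity groups -> two bins -> an exactly linear log-log fit
  a <- matrix(0, 7, 7)
  a[1:4, 1:4] <- 0.1; a[5:7, 5:7] <- 0.9
  diag(a) <- 1
  f <- scale_free_fit(a, n_bins = 4)
  expect_equal(f$rsq, 1.0, tolerance = 1e-12)
  expect_false(f$degenerate)

  # near-zero adjacency: mean connectivity near zero
  set.seed(3)
  x <- matrix(rnorm(6000), ncol = 20)
  f0 <- scale_free_fit(soft_adjacency(x, 12), n_bins = 5)
  expect_lt(f0$mean_connectivity, 0.05)

  # 5-block design over a power grid agrees with the oracle regression
  x5 <- do.call(cbind, lapply(1:5, function(k) make_block(300, 6, 0.7, k)))
  colnames(x5) <- paste0("v", seq_len(ncol(x5)))
  for (pw in c(1, 2, 4, 7, 10, 12)) {
    a <- soft_adjacency(x5, pw)
    got <- scale_free_fit(a, n_bins = 8)
    k <- colSums(a) - 1
    expect_equal(got$rsq, binned_rsq_oracle(k, 8), tolerance = 1e-10)
  }
})

test_that("degenerate connectivity distributions are flagged with rsq 0", {
  a <- matrix(0.5, 6, 6); diag(a) <- 1
  f <- scale_free_fit(a, 4)
  expect_true(f$degenerate)
  expect_identical(f$rsq, 0)
})

test_that("pick_soft_power returns the first power hitting the target", {
  x <- do.call(cbind, lapply(1:4, function(k) make_block(250, 8, 0.75, k)))
  colnames(x) <- paste0("v", seq_len(ncol(x)))
  # exhaustive oracle over the same grid
  grid <- 1:12
  rsqs <- sapply(grid, function(pw)
    binned_rsq_oracle(colSums(soft_adjacency(x, pw)) - 1, 10))
  opts <- network_options(power = NULL, candidate_powers = grid,
                          rsq_target = 0.8, n_bins = 10)
  got <- suppressWarnings(pick_soft_power(x, opts))
  oracle <- if (any(rsqs >= 0.8)) grid[which(rsqs >= 0.8)[1]] else
    grid[which.max(rsqs)]
  expect_identical(got$power, oracle)
  expect_equal(got$path$rsq, rsqs, tolerance = 1e-10)

  # unreachable target falls back to the argmax with a warning
  expect_warning(
    low <- pick_soft_power(x, network_options(power = NULL,
                                              candidate_powers = grid,
                                              rsq_target = 0.999)),
    "best-fitting")
  expect_identical(low$power, grid[which.max(rsqs)])
  expect_false(low$reached_target)
})

test_that("topological overlap dissimilarity matches the direct formula", {
  a <- matrix(c(1, .8, .2,
                .8, 1, .4,
                .2, .4, 1), 3, 3)
  d <- tom_dissimilarity(a)
  expect_equal(unname(d), tom_manual(a), tolerance = 1e-12)

  # binary adjacency, i-j connected with identical neighbourhoods -> 0
  ab <- matrix(0, 5, 5); diag(ab) <- 1
  ab[1, 2] <- ab[2, 1] <- 1
  ab[1, 3:5] <- ab[3:5, 1] <- 1
  ab[2, 3:5] <- ab[3:5, 2] <- 1
  expect_equal(tom_dissimilarity(ab)[1, 2], 0, tolerance = 1e-12)

  # no edge, no shared neighbours -> dissimilarity 1
  a0 <- diag(4)
  a0[1, 2] <- a0[2, 1] <- 0
  a0[3, 4] <- a0[4, 3] <- 0.9
  expect_equal(tom_dissimilarity(a0)[1, 2], 1, tolerance = 1e-12)

  # general properties on a random adjacency
  set.seed(5)
  r <- abs(cor(matrix(rnorm(400), ncol = 10)))^4; diag(r) <- 1
  dr <- tom_dissimilarity(r)
  expect_true(all(dr >= 0 & dr <= 1))
  expect_equal(diag(dr), rep(0, 10))
  expect_true(isSymmetric(dr))
})

test_that("module detection recovers planted blocks and applies size rules", {
  # block-diagonal dissimilarity: two planted blocks
  d <- matrix(1, 10, 10)
  d[1:6, 1:6] <- 0.2; d[7:10, 7:10] <- 0.3
  diag(d) <- 0
  colnames(d) <- rownames(d) <- sprintf("f%02d", 1:10)
  lab <- detect_modules(d, network_options(min_module_size = 3,
                                           cut_height = 0.6))
  expect_identical(unname(lab), c(rep(1L, 6), rep(2L, 4)))

  # all-zero dissimilarity: one module containing everything
  dz <- matrix(0, 5, 5)
  colnames(dz) <- rownames(dz) <- paste0("v", 1:5)
  expect_identical(unname(detect_modules(dz, network_options())),
                   rep(1L, 5))

  # undersized cluster is left unassigned
  d2 <- matrix(1, 5, 5); d2[1:3, 1:3] <- 0.1; d2[4:5, 4:5] <- 0.1
  diag(d2) <- 0
  colnames(d2) <- rownames(d2) <- paste0("v", 1:5)
  lab2 <- detect_modules(d2, network_options(min_module_size = 3,
                                             cut_height = 0.5))
  expect_identical(unname(lab2), c(1L, 1L, 1L, 0L, 0L))
})

test_that("eigenfactors are unit-norm first PCs with the sign convention", {
  n <- 80
  # five identical columns: eigenfactor is the standardized column
  z <- rnorm(n)
  x <- matrix(rep(z, 5), ncol = 5,
              dimnames = list(NULL, paste0("v", 1:5)))
  lab <- setNames(rep(1L, 5), colnames(x))
  me <- module_eigengenes(x, lab)
  expect_equal(me$variance_explained[["ME1"]], 1.0, tolerance = 1e-12)
  zs <- scale(z)[, 1]; zs <- zs / sqrt(sum(zs^2))
  expect_equal(abs(cor(me$eigengenes[, 1], z)), 1, tolerance = 1e-12)
  expect_equal(sum(me$eigengenes[, 1]^2), 1, tolerance = 1e-10)

  # two-feature module: variance explained has the closed form (1+|r|)/2
  for (r in c(0.3, -0.6, 0.9)) {
    xp <- make_cor_pair(200, r)
    colnames(xp) <- c("p", "q")
    me2 <- module_eigengenes(xp, setNames(c(1L, 1L), colnames(xp)))
    expect_equal(me2$variance_explained[["ME1"]], (1 + abs(r)) / 2,
                 tolerance = 1e-8)
  }

  # sign convention survives negating every member column
  set.seed(9)
  xm <- make_block(100, 6, 0.6, 2)
  colnames(xm) <- paste0("v", 1:6)
  labm <- setNames(rep(1L, 6), colnames(xm))
  e1 <- module_eigengenes(xm, labm)$eigengenes[, 1]
  e2 <- module_eigengenes(-xm, labm)$eigengenes[, 1]
  expect_gte(cor(e1, rowMeans(scale(xm))), 0)
  expect_gte(cor(e2, rowMeans(scale(-xm))), 0)
  expect_equal(e1, -e2, tolerance = 1e-10)

  # singleton module: eigengene is the standardized column itself
  xs <- cbind(s = rnorm(50))
  mes <- module_eigengenes(xs, c(s = 1L))
  expect_equal(mes$variance_explained[["ME1"]], 1)
})

test_that("module merging joins similar eigenfactors and terminates", {
  n <- 150
  set.seed(21)
  f <- rnorm(n)
  # modules 1 and 2 share a latent factor (eigengene correlation ~0.9);
  # module 3 is independent
  m1 <- sapply(1:5, function(j) f + 0.35 * rnorm(n))
  m2 <- sapply(1:5, function(j) f + 0.35 * rnorm(n))
  m3 <- make_block(n, 5, 0.7, 99)
  x <- cbind(m1, m2, m3)
  colnames(x) <- sprintf("v%02d", 1:15)
  lab <- setNames(rep(1:3, each = 5), colnames(x))
  part <- merge_modules(x, lab, network_options(merge_similarity = 0.5))
  expect_identical(length(unique(part$labels[1:10])), 1L)
  expect_identical(length(unique(part$labels)), 2L)
  expect_equal(nrow(part$merge_history), 1L)
  expect_gt(part$merge_history$similarity[1], 0.5)

  # dissimilar modules stay untouched
  x2 <- cbind(make_block(n, 5, 0.7, 1), make_block(n, 5, 0.7, 2))
  colnames(x2) <- sprintf("w%02d", 1:10)
  lab2 <- setNames(rep(1:2, each = 5), colnames(x2))
  part2 <- merge_modules(x2, lab2, network_options())
  expect_identical(sort(unique(part2$labels)), c(1L, 2L))
  expect_equal(nrow(part2$merge_history), 0L)

  # three mutually similar modules collapse to one, and the final partition
  # has no eigengene pair above the threshold
  m <- lapply(1:3, function(k) sapply(1:4, function(j) f + 0.5 * rnorm(n)))
  x3 <- do.call(cbind, m)
  colnames(x3) <- sprintf("u%02d", 1:12)
  lab3 <- setNames(rep(1:3, each = 4), colnames(x3))
  part3 <- merge_modules(x3, lab3, network_options())
  expect_identical(length(unique(part3$labels)), 1L)
  expect_lte(nrow(part3$merge_history), 2L)
  if (ncol(part3$eigengenes) > 1) {
    cc <- cor(part3$eigengenes); diag(cc) <- 0
    expect_true(all(cc <= part3$params$merge_similarity))
  }
})

test_that("build_network is deterministic and permutation-equivariant", {
  x <- do.call(cbind, lapply(1:3, function(k) make_block(150, 6, 0.75, k)))
  colnames(x) <- sprintf("v%02d", 1:18)
  p1 <- build_network(x)
  p2 <- build_network(x)
  expect_identical(p1$labels, p2$labels)
  expect_identical(p1$eigengenes, p2$eigengenes)

  perm <- sample(ncol(x))
  p3 <- build_network(x[, perm])
  expect_identical(p3$labels[colnames(x)], p1$labels)

  # module sizes partition the feature set
  expect_identical(length(p1$labels), ncol(x))
  expect_identical(sum(table(p1$labels)), ncol(x))

  # eigengene unit norms
  expect_equal(colSums(p1$eigengenes^2), rep(1, ncol(p1$eigengenes)),
               ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("the feature block fed to the network must not contain the outcome", {
  x <- do.call(cbind, lapply(1:2, function(k) make_block(100, 5, 0.7, k)))
  colnames(x) <- paste0("v", 1:10)
  y <- rbinom(100, 1, 0.5)
  bad <- cbind(x, outcome = y)
  expect_error(fuzzy_forest(bad, y), "outcome")
})
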