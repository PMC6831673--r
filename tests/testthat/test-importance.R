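test_that("the unique informative feature earns rank 1", {
  set.seed(7)
  n <- 500
  x <- matrix(rnorm(n * 10), n, 10,
              dimnames = list(NULL, sprintf("x%02d", 1:10)))
  y <- as.integer(x[, 1] > 0)
  imp <- oob_importance(x, y, seed = 7)
  expect_identical(imp$feature[1], "x01")
  # univariate accuracy oracle: x01 is the only feature whose sign predicts y
  acc <- apply(x, 2, function(v) max(mean((v > 0) == y), mean((v < 0) == y)))
  expect_identical(names(which.max(acc)), "x01")
  expect_gt(imp$vim[1], 10 * max(abs(imp$vim[-1])))
})

test_that("importance handles constant features, ties, and bad inputs", {
  set.seed(8)
  n <- 200
  x <- cbind(sig = rnorm(n), c1 = rep(1, n), c2 = rep(5, n))
  y <- as.integer(x[, "sig"] + rnorm(n, sd = 0.5) > 0)
  imp <- oob_importance(x, y, seed = 2)
  expect_equal(imp$vim[imp$feature %in% c("c1", "c2")], c(0, 0))
  # exact tie at zero: ranks break lexicographically
  expect_identical(imp$feature[imp$vim == 0], c("c1", "c2"))
  expect_identical(imp$rank, 1:3)

  expect_error(oob_importance(x, rep(1L, n)), "single class")
  expect_error(oob_importance(x[1:10, ], y[1:10]), "at least 20")
})

test_that("importance is a pure function of (input, seed)", {
  set.seed(10)
  x <- matrix(rnorm(3000), 150, 20,
              dimnames = list(NULL, sprintf("v%02d", 1:20)))
  y <- as.integer(x[, 3] > 0)
  a <- oob_importance(x, y, seed = 123)
  b <- oob_importance(x, y, seed = 123)
  expect_identical(a, b)
  c2 <- oob_importance(x, y, seed = 124)
  expect_false(identical(a$vim, c2$vim))
  # replicate-averaged importance is deterministic too and less noisy
  m <- oob_importance(x, y, control = ff_control(n_permutations = 3),
                      seed = 123)
  expect_identical(m,
                   oob_importance(x, y,
                                  control = ff_control(n_permutations = 3),
                                  seed = 123))
})

test_that("fast-path ranking agrees with a brute-force per-tree oracle", {
  skip_if_not_installed("randomForest")
  set.seed(31)
  n <- 300
  x <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("f", 1:6)))
  y <- factor(as.integer(x[, 2] - x[, 5] + rnorm(n, sd = 0.7) > 0))
  rf <- randomForest::randomForest(x, y, ntree = 150, keep.inbag = TRUE)
  set.seed(42)
  oracle <- sapply(colnames(x), function(f) rf_perm_importance(rf, x, y, f))
  imp <- oob_importance(x, as.integer(as.character(y)), seed = 31)
  # the two strong features lead in both implementations
  expect_setequal(imp$feature[1:2], names(sort(-oracle))[1:2])
  # permuting with the identity permutation contributes exactly zero
  expect_identical(rf_perm_importance(rf, x, y, "f2", perm = identity), 0)
})

test_that("RFE keeps exactly keep_n features and retains planted signal", {
  set.seed(3)
  n <- 500
  x <- matrix(rnorm(n * 20), n, 20,
              dimnames = list(NULL, sprintf("x%02d", 1:20)))
  y <- as.integer(x[, 5] + rnorm(n, sd = 0.6) > 0)
  res <- rfe_select(x, y, keep_n = 7, seed = 3)
  expect_length(res$survivors, 7L)
  expect_true(all(res$survivors %in% colnames(x)))
  expect_identical(res$importance$feature, res$survivors)

  # keep_n = p: everything survives, nothing eliminated
  all_in <- rfe_select(x, y, keep_n = 20, seed = 1)
  expect_setequal(all_in$survivors, colnames(x))

  # the planted predictor survives in nearly every seeded run
  hits <- sum(vapply(1:25, function(s)
    "x05" %in% rfe_select(x, y, keep_n = 7, seed = s)$survivors, logical(1)))
  expect_gte(hits, 24L)
})

test_that("per-module screening applies the ceiling-with-floor rule", {
  set.seed(12)
  n <- 300
  sizes <- c(20L, 9L, 1L)
  x <- matrix(rnorm(n * sum(sizes)), n,
              dimnames = list(NULL, sprintf("v%02d", seq_len(sum(sizes)))))
  labels <- setNames(rep(1:3, sizes), colnames(x))
  y <- as.integer(x[, 1] + rnorm(n) > 0)
  surv <- screen_modules(x, y, labels, seed = 4)
  expect_identical(lengths(surv)[c("1", "2", "3")], c(`1` = 7L, `2` = 4L, `3` = 1L))

  # keep everything at keep_fraction 1
  surv_all <- screen_modules(x, y, labels,
                             control = ff_control(keep_fraction = 1), seed = 4)
  expect_identical(unname(lengths(surv_all)), sizes)

  # survivor-count arithmetic across a sweep of sizes
  expect_identical(module_keep_n(c(1, 2, 3, 10, 20, 60)),
                   c(1L, 1L, 2L, 4L, 7L, 21L))
})

test_that("a strong in-module signal survives its module screen", {
  hits <- vapply(1:20, function(s) {
    x <- cbind(make_block(400, 15, 0.7, seed = 100 + s))
    colnames(x) <- sprintf("m%02d", 1:15)
    set.seed(200 + s)
    y <- rbinom(400, 1, plogis(1.5 * x[, 1]))
    labels <- setNames(rep(1L, 15), colnames(x))
    "m01" %in% screen_modules(x, y, labels, seed = 11)[["1"]]
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("final selection truncates at number_selected and is deterministic", {
  set.seed(17)
  n <- 400
  x <- matrix(rnorm(n * 40), n, 40,
              dimnames = list(NULL, sprintf("s%02d", 1:40)))
  y <- as.integer(x[, 1] + x[, 2] + rnorm(n) > 0)
  sel <- select_final(x, y, colnames(x), seed = 5)
  expect_identical(nrow(sel), 20L)
  expect_identical(sel$rank, 1:20)
  expect_identical(sel, select_final(x, y, colnames(x), seed = 5))

  few <- select_final(x, y, colnames(x)[1:12], seed = 5)
  expect_identical(nrow(few), 12L)
})

test_that("modplot percentages are conserved and include empty modules", {
  set.seed(23)
  x <- cbind(make_block(250, 12, 0.7, 1), matrix(rnorm(250 * 6), 250, 6))
  colnames(x) <- sprintf("v%02d", 1:18)
  y <- as.integer(x[, 1] + rnorm(250, sd = .7) > 0)
  fit <- fuzzy_forest(x, y, control = ff_control(number_selected = 5),
                      net_options = network_options(min_module_size = 4),
                      seed = 2)
  m <- module_importance_summary(fit)
  expect_equal(sum(m$n_selected), nrow(fit$selected))
  expect_equal(m$percent_important, 100 * m$n_selected / m$module_size)
  expect_true(all(m$percent_important >= 0 & m$percent_important <= 100))
  expect_identical(sum(m$module_size), ncol(x))
})

test_that("fuzzy forest fits are reproducible and respect the size chain", {
  set.seed(29)
  x <- cbind(make_block(250, 10, 0.75, 3), matrix(rnorm(250 * 8), 250, 8))
  colnames(x) <- sprintf("v%02d", 1:18)
  y <- as.integer(1.2 * x[, 1] + x[, 11] + rnorm(250) > 0)
  f1 <- fuzzy_forest(x, y, control = ff_control(number_selected = 6), seed = 8)
  f2 <- fuzzy_forest(x, y, control = ff_control(number_selected = 6), seed = 8)
  expect_identical(f1$selected, f2$selected)
  expect_identical(f1$survivors_by_module, f2$survivors_by_module)

  n_surv <- sum(lengths(f1$survivors_by_module))
  expect_lte(nrow(f1$selected), n_surv)
  expect_lte(n_surv, ncol(x))
  expect_true(all(f1$selected$feature %in%
                    unlist(f1$survivors_by_module)))

  # survivor counts match the rule for the realized module sizes
  labels <- f1$partition$labels
  for (id in names(f1$survivors_by_module)) {
    size <- sum(labels == as.integer(id))
    expect_length(f1$survivors_by_module[[id]], module_keep_n(size))
  }

  # probabilities from the refit forest are valid
  p <- predict(f1, x)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("stability frequencies are valid and favour planted signal", {
  set.seed(41)
  x <- cbind(make_block(300, 10, 0.7, 5), matrix(rnorm(300 * 6), 300, 6))
  colnames(x) <- sprintf("v%02d", 1:16)
  y <- as.integer(1.5 * x[, 11] + rnorm(300, sd = .8) > 0)
  st <- stability_selection(x, y, control = ff_control(number_selected = 5),
                            n_runs = 10, master_seed = 6)
  expect_true(all(st$frequency >= 0 & st$frequency <= 1))
  # every run selects exactly 5, so total frequency mass is 5
  expect_equal(sum(st$frequency), 5)
  expect_gte(st$frequency[st$feature == "v11"], 0.9)
})
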