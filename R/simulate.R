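#' Configuration for the synthetic survey generator
#'
#' The generator emulates the structure of a large multilingual health
#' survey at desk scale: block-correlated feature modules (one latent factor
#' per module, so the population within-module correlation is exactly `rho`),
#' independent features, a handful of truly outcome-associated features (some
#' inside modules, some independent), a multi-level interview-language factor
#' with one very rare level, a binary good-health outcome generated under a
#' logistic link, and positive right-skewed survey weights.
#'
#' Defaults: 2000 train + 2000 test respondents; five modules of sizes
#' 40/36/34/30/30 with within-correlations 0.80/0.75/0.70/0.65/0.60 plus 30
#' independent features (~200 features once the 7-level language factor is
#' indicator-coded); planted coefficients of 1.2 on the first feature of
#' modules 1-3 and on two independent features; language shares mirroring a
#' mostly-English survey with a one-in-2000 rare level; log-normal(0, 0.5)
#' weights.
#'
#' @param n_train,n_test respondents per wave.
#' @param modules list of `list(size, rho)` blocks (`size >= 2`,
#'   `0 < rho < 1`).
#' @param n_independent count of uncorrelated features.
#' @param planted data frame with columns `feature`, `beta`.
#' @param language list with `levels`, `probs` (summing to 1; one rare level
#'   allowed) and `effects` (additive log-odds shifts, reference level 0).
#' @param intercept intercept of the linear predictor.
#' @param weight_meanlog,weight_sdlog log-normal weight parameters.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(n_train = 2000L, n_test = 2000L,
                       modules = list(list(size = 40L, rho = 0.80),
                                      list(size = 36L, rho = 0.75),
                                      list(size = 34L, rho = 0.70),
                                      list(size = 30L, rho = 0.65),
                                      list(size = 30L, rho = 0.60)),
                       n_independent = 30L,
                       planted = data.frame(
                         feature = c("m1_f01", "m2_f01", "m3_f01",
                                     "ind_01", "ind_02"),
                         beta = rep(1.2, 5)),
                       language = list(
                         levels = c("English", "Spanish", "Vietnamese",
                                    "Korean", "Cantonese", "Mandarin",
                                    "Tagalog"),
                         probs = c(0.9013, 0.0824, 0.0026, 0.0071, 0.0033,
                                   0.0028, 0.0005),
                         effects = c(English = 0, Spanish = -1.2,
                                     Vietnamese = -2.0, Korean = -0.9,
                                     Cantonese = -1.0, Mandarin = -1.5,
                                     Tagalog = -2.0)),
                       intercept = 0.5,
                       weight_meanlog = 0, weight_sdlog = 0.5) {
  for (m in modules) stopifnot(m$size >= 2L, m$rho > 0, m$rho < 1)
  stopifnot(abs(sum(language$probs) - 1) < 1e-8,
            length(language$levels) == length(language$probs),
            all(names(language$effects) %in% language$levels) ||
              is.null(names(language$effects)))
  cfg <- list(n_train = as.integer(n_train), n_test = as.integer(n_test),
              modules = modules, n_independent = as.integer(n_independent),
              planted = planted, language = language,
              intercept = intercept, weight_meanlog = weight_meanlog,
              weight_sdlog = weight_sdlog)
  feature_names <- sim_feature_names(cfg)
  missing_feat <- setdiff(planted$feature, feature_names)
  if (length(missing_feat))
    stop("planted feature(s) not in the design: ",
         paste(missing_feat, collapse = ", "), call. = FALSE)
  structure(cfg, class = "sim_config")
}

sim_feature_names <- function(config) {
  c(unlist(lapply(seq_along(config$modules), function(k)
    sprintf("m%d_f%02d", k, seq_len(config$modules[[k]]$size)))),
    if (config$n_independent > 0)
      sprintf("ind_%02d", seq_len(config$n_independent)))
}

#' Simulate block-correlated features
#'
#' Module `k` with correlation `rho` uses one latent factor:
#' `x_j = sqrt(rho) f_k + sqrt(1 - rho) e_j` with `f_k, e_j` iid standard
#' normal, so every within-module pair has population correlation exactly
#' `rho` and cross-module correlations are 0. Independent features are pure
#' standard normal.
#'
#' @param config a [sim_config()].
#' @param n number of respondents.
#' @param seed integer seed.
#' @return list with `x` (numeric matrix) and `labels` (named truth labels,
#'   module number or 0 for independent features).
#' @export
simulate_modular_features <- function(config, n, seed = 1L) {
  set.seed(derive_seed(seed, "features"))
  blocks <- lapply(seq_along(config$modules), function(k) {
    m <- config$modules[[k]]
    f <- stats::rnorm(n)
    sapply(seq_len(m$size), function(j)
      sqrt(m$rho) * f + sqrt(1 - m$rho) * stats::rnorm(n))
  })
  ind <- if (config$n_independent > 0)
    matrix(stats::rnorm(n * config$n_independent), n) else NULL
  x <- do.call(cbind, c(blocks, list(ind)))
  colnames(x) <- sim_feature_names(config)
  labels <- c(rep(seq_along(config$modules),
                  vapply(config$modules, `[[`, integer(1), "size")),
              rep(0L, config$n_independent))
  names(labels) <- colnames(x)
  list(x = x, labels = labels)
}

#' Simulate the outcome, interview language and weights
#'
#' Language is drawn per the configured shares; the linear predictor is
#' `intercept + sum planted beta_j x_j + language effect`; the binary outcome
#' is Bernoulli(logistic(lp)); weights are iid log-normal.
#'
#' @param x feature matrix from [simulate_modular_features()].
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list with `y`, `language` (factor), `weights`, `lp` (the true
#'   linear predictor) and `prob`.
#' @export
simulate_outcome_and_language <- function(x, config, seed = 1L) {
  set.seed(derive_seed(seed, "outcome"))
  n <- nrow(x)
  lang <- factor(sample(config$language$levels, n, replace = TRUE,
                        prob = config$language$probs),
                 levels = config$language$levels)
  eff <- config$language$effects[as.character(lang)]
  eff[is.na(eff)] <- 0
  lp <- config$intercept +
    drop(x[, config$planted$feature, drop = FALSE] %*% config$planted$beta) +
    unname(eff)
  prob <- stats::plogis(lp)
  y <- stats::rbinom(n, 1L, prob)
  w <- stats::rlnorm(n, config$weight_meanlog, config$weight_sdlog)
  list(y = y, language = lang, weights = w, lp = lp, prob = prob)
}

sim_wave <- function(config, n, seed) {
  feats <- simulate_modular_features(config, n, seed)
  out <- simulate_outcome_and_language(feats$x, config, seed)
  # five-level self-rated health consistent with the binary truth:
  # good-health respondents split over Excellent/Very Good/Good, the rest
  # over Fair/Poor, so the standard recode recovers y exactly
  set.seed(derive_seed(seed, "health_levels"))
  health <- character(n)
  good <- out$y == 1L
  health[good] <- sample(c("Excellent", "Very Good", "Good"), sum(good),
                         replace = TRUE, prob = c(0.30, 0.35, 0.35))
  health[!good] <- sample(c("Fair", "Poor"), sum(!good),
                          replace = TRUE, prob = c(0.60, 0.40))
  tab <- data.frame(id = seq_len(n),
                    general_health = factor(health, levels = health_levels),
                    language = out$language,
                    weight = out$weights,
                    stringsAsFactors = FALSE)
  tab <- cbind(tab, as.data.frame(feats$x))
  list(table = tab, labels = feats$labels, lp = out$lp, prob = out$prob,
       y = out$y)
}

#' Generate a synthetic train/test survey pair with known truth
#'
#' @param config a [sim_config()].
#' @param seed master integer seed; train and test waves use seeds derived
#'   from it, so the pair is fully reproducible.
#' @return list of class `"sim_survey"`: `train` and `test` data frames
#'   (id, five-level `general_health`, `language`, `weight`, features),
#'   `codebook` (an `"ff_codebook"`), and `truth` (module labels, planted
#'   coefficients, language effects, intercept, and the realized Bayes
#'   accuracy of the true model on the training wave). The truth is never
#'   consulted by any fitting stage.
#' @export
simulate_survey <- function(config = sim_config(), seed = 1L) {
  train <- sim_wave(config, config$n_train, derive_seed(seed, "train"))
  test <- sim_wave(config, config$n_test, derive_seed(seed, "test"))
  cb <- codebook(c(
    list(list(name = "id", role = "id"),
         list(name = "general_health", role = "outcome", kind = "ordinal",
              levels = health_levels),
         list(name = "language", role = "feature", kind = "nominal",
              levels = config$language$levels),
         list(name = "weight", role = "weight")),
    lapply(sim_feature_names(config), function(nm)
      list(name = nm, role = "feature", kind = "ordinal"))))
  truth <- list(
    module_labels = train$labels,
    planted = config$planted,
    language_effects = config$language$effects,
    intercept = config$intercept,
    bayes_accuracy = mean(pmax(train$prob, 1 - train$prob)))
  structure(list(train = train$table, test = test$table, codebook = cb,
                 truth = truth, config = config, seed = as.integer(seed)),
            class = "sim_survey")
}

#' Write a simulated survey to disk
#'
#' Emits `train.csv`, `test.csv`, `codebook.yaml` and `truth.json` (the
#' truth file is for evaluation only and is read by no fitting stage).
#'
#' @param sim a `"sim_survey"` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_survey <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_survey"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(sim$train, file.path(dir, "train.csv"), row.names = FALSE)
  utils::write.csv(sim$test, file.path(dir, "test.csv"), row.names = FALSE)
  write_codebook(sim$codebook, file.path(dir, "codebook.yaml"))
  truth <- sim$truth
  truth$module_labels <- as.list(truth$module_labels)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
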