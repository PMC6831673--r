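#' End-to-end train/test screening and validation pipeline
#'
#' Orchestrates the full workflow on a pair of survey waves sharing a
#' codebook: dichotomize the five-level health outcome, drop rare interview
#' languages, run the two-stage fuzzy-forest screen on the training wave,
#' refit a survey-weighted logistic regression with the selected predictors
#' (nominal selections aggregated to their parent factor) plus any forced
#' adjusters, and evaluate on the held-out test wave. Test rows are never
#' touched before evaluation.
#'
#' @param train,test survey data frames sharing the codebook's columns.
#' @param cb an `"ff_codebook"` declaring outcome, weight, id and features.
#' @param net_options stage-1 settings ([network_options()]).
#' @param control stage-2 settings ([ff_control()]).
#' @param seed master integer seed.
#' @param adjusters character vector of covariates forced into the logistic
#'   model whether or not the screen selects them (e.g. age, income, gender,
#'   ethnicity).
#' @param sqrt_terms columns to square-root transform before the logistic
#'   fit (the conventional variance-stabilizer for income).
#' @param min_language_n threshold for [drop_rare_language()] (applied to
#'   the training wave; test rows with a dropped level are excluded and
#'   logged).
#' @param threshold classification threshold for held-out accuracy.
#' @param language_col name of the interview-language column, if any.
#' @return object of class `"ff_pipeline"`: `selection` (selected features
#'   with parent variables), `glm_fit`, `forest_fit`, `or_table`, `metrics`
#'   (held-out accuracy/AUC for both the logistic model and the selection
#'   forest, labelled), `language_table`, `dropped_languages`,
#'   `excluded_test_languages` (test respondents whose language was never
#'   retained in training), `modplot`, and a `manifest` of all parameters
#'   and derived seeds.
#' @export
run_pipeline <- function(train, test, cb, net_options = network_options(),
                         control = ff_control(), seed = 1L,
                         adjusters = character(0),
                         sqrt_terms = character(0),
                         min_language_n = 2L, threshold = 0.5,
                         language_col = "language") {
  stopifnot(inherits(cb, "ff_codebook"))
  need <- setdiff(names(cb), character(0))
  for (tab_nm in c("train", "test")) {
    tab <- get(tab_nm)
    missing_cols <- setdiff(need, names(tab))
    if (length(missing_cols))
      stop("codebook mismatch in ", tab_nm, ": missing column(s) ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  outcome_col <- codebook_names(cb, role = "outcome")
  weight_col <- codebook_names(cb, role = "weight")
  if (length(outcome_col) != 1L)
    stop("codebook must declare exactly one outcome column", call. = FALSE)
  if (length(weight_col) != 1L)
    stop("codebook must declare exactly one weight column", call. = FALSE)

  # --- outcome recode (stage: recode) ---------------------------------------
  train$.y <- recode_good_health(train[[outcome_col]])
  language_table <- NULL
  dropped <- data.frame(level = character(0), n = integer(0))
  if (!is.null(language_col) && language_col %in% names(train)) {
    language_table <- language_summary(table(train[[language_col]]))
    train <- drop_rare_language(train, language_col, min_language_n)
    dropped <- attr(train, "dropped_languages")
  }

  # --- stage 1 + 2 on the training wave only --------------------------------
  expd <- expand_features(train, cb)
  ff <- fuzzy_forest(expd$x, train$.y, net_options, control, seed,
                     weights = train[[weight_col]])
  selection <- ff$selected
  selection$parent <- unname(expd$parent[selection$feature])

  # --- confirmatory survey-weighted logistic --------------------------------
  glm_terms <- unique(c(selection$parent, adjusters))
  glm_data <- train
  for (v in intersect(sqrt_terms, glm_terms)) glm_data[[v]] <- sqrt(glm_data[[v]])
  for (v in glm_terms)
    if (!is.numeric(glm_data[[v]]))
      glm_data[[v]] <- droplevels(factor(glm_data[[v]]))
  fml <- stats::reformulate(glm_terms, response = ".y")
  glm_fit <- weighted_logit(fml, glm_data, weights = glm_data[[weight_col]])

  # --- held-out evaluation (test rows first touched here) -------------------
  test$.y <- recode_good_health(test[[outcome_col]])
  excluded_test <- data.frame(level = character(0), n = integer(0))
  if (!is.null(language_col) && language_col %in% names(test)) {
    # a language never seen (or dropped as rare) in training cannot be
    # scored: exclude those test respondents and log them
    keep_levels <- levels(train[[language_col]])
    keep <- as.character(test[[language_col]]) %in% keep_levels
    if (any(!keep)) {
      gone <- table(as.character(test[[language_col]])[!keep])
      excluded_test <- data.frame(level = names(gone),
                                  n = as.integer(gone))
    }
    test <- test[keep, , drop = FALSE]
    test[[language_col]] <- factor(as.character(test[[language_col]]),
                                   levels = keep_levels)
  }
  test_glm <- test
  for (v in intersect(sqrt_terms, glm_terms)) test_glm[[v]] <- sqrt(test_glm[[v]])
  p_glm <- predict(glm_fit, test_glm)
  m_glm <- evaluate_predictions(p_glm, test$.y, threshold)
  expd_test <- expand_features(test, cb, factor_levels = expd$factor_levels)
  p_forest <- predict(ff, expd_test$x)
  m_forest <- evaluate_predictions(p_forest, test$.y, threshold)

  manifest <- list(seed = as.integer(seed),
                   net_options = unclass(net_options),
                   control = unclass(control),
                   adjusters = adjusters, sqrt_terms = sqrt_terms,
                   min_language_n = min_language_n, threshold = threshold,
                   n_train = nrow(train), n_test = nrow(test),
                   package_version =
                     as.character(utils::packageVersion("fuzzyscreen")))
  structure(list(selection = selection, glm_fit = glm_fit, forest_fit = ff,
                 or_table = odds_ratios(glm_fit),
                 metrics = list(logistic = m_glm, forest = m_forest),
                 language_table = language_table,
                 dropped_languages = dropped,
                 excluded_test_languages = excluded_test,
                 modplot = module_importance_summary(ff),
                 manifest = manifest),
            class = "ff_pipeline")
}

#' @export
print.ff_pipeline <- function(x, ...) {
  cat("Fuzzy-forest survey pipeline\n")
  cat(sprintf("  train n = %d, test n = %d, seed = %d\n",
              x$manifest$n_train, x$manifest$n_test, x$manifest$seed))
  if (nrow(x$dropped_languages))
    cat("  dropped rare language level(s):",
        paste(sprintf("%s (n=%d)", x$dropped_languages$level,
                      x$dropped_languages$n), collapse = ", "), "\n")
  cat("  selected predictors:",
      paste(utils::head(unique(x$selection$parent), 8), collapse = ", "),
      if (length(unique(x$selection$parent)) > 8) "..." else "", "\n")
  cat(sprintf("  held-out accuracy: logistic %.3f, forest %.3f\n",
              x$metrics$logistic$accuracy, x$metrics$forest$accuracy))
  cat(sprintf("  held-out AUC:      logistic %.3f, forest %.3f\n",
              x$metrics$logistic$auc, x$metrics$forest$auc))
  invisible(x)
}

#' Write pipeline outputs as plain-text artifacts
#'
#' Emits `selected.csv`, `modplot.csv`, `odds_ratios.csv`, `metrics.json`
#' and `manifest.json` into `dir`.
#'
#' @param report an `"ff_pipeline"` object.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_pipeline <- function(report, dir) {
  stopifnot(inherits(report, "ff_pipeline"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$selection, file.path(dir, "selected.csv"),
                   row.names = FALSE)
  utils::write.csv(report$modplot, file.path(dir, "modplot.csv"),
                   row.names = FALSE)
  utils::write.csv(report$or_table, file.path(dir, "odds_ratios.csv"),
                   row.names = FALSE)
  metrics <- lapply(report$metrics, function(m)
    list(accuracy = m$accuracy, auc = m$auc, threshold = m$threshold,
         n_test = m$n, confusion = as.list(m$confusion)))
  jsonlite::write_json(metrics, file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(report$language_table))
    utils::write.csv(report$language_table,
                     file.path(dir, "language_table.csv"), row.names = FALSE)
  invisible(dir)
}
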