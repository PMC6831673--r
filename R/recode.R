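health_levels <- c("Excellent", "Very Good", "Good", "Fair", "Poor")

#' Dichotomize a five-level self-rated health item
#'
#' "Excellent", "Very Good" or "Good" (codes 1-3) map to 1; "Fair" or "Poor"
#' (codes 4-5) map to 0.
#'
#' @param values character/factor responses or their numeric codes 1-5
#'   (1 = Excellent ... 5 = Poor).
#' @return integer 0/1 vector.
#' @export
recode_good_health <- function(values) {
  if (is.factor(values)) values <- as.character(values)
  if (is.numeric(values)) {
    bad <- unique(values[!values %in% 1:5])
    if (length(bad))
      stop("health codes outside 1-5: ", paste(bad, collapse = ", "),
           call. = FALSE)
    code <- as.integer(values)
  } else {
    bad <- unique(values[!values %in% health_levels])
    if (length(bad))
      stop("unrecognized health responses: ", paste(bad, collapse = ", "),
           call. = FALSE)
    code <- match(values, health_levels)
  }
  as.integer(code <= 3L)
}

#' Any-chronic-condition indicator
#'
#' Elementwise logical OR of the diabetes, cardiovascular-disease and
#' high-blood-pressure indicators: a respondent has a chronic condition if
#' they report any one or more of them. Missing values are an error, never
#' silently imputed.
#'
#' @param diabetes,cvd,hbp binary (0/1 or logical) vectors of equal length.
#' @return integer 0/1 vector.
#' @export
chronic_condition_indicator <- function(diabetes, cvd, hbp) {
  args <- list(diabetes = diabetes, cvd = cvd, hbp = hbp)
  n <- unique(lengths(args))
  if (length(n) != 1L) stop("inputs must have equal length", call. = FALSE)
  for (nm in names(args)) {
    v <- args[[nm]]
    if (anyNA(v)) stop("missing values in '", nm, "'", call. = FALSE)
    if (!all(v %in% c(0, 1)))
      stop("'", nm, "' must be binary 0/1", call. = FALSE)
  }
  as.integer(diabetes == 1 | cvd == 1 | hbp == 1)
}

#' Drop respondents with a rare interview language
#'
#' Removes rows whose language level occurs fewer than `min_n` times and
#' drops the level from the factor. With the default `min_n = 2` a level
#' observed once — too few to estimate anything stable — is removed without
#' naming any particular language.
#'
#' @param data data frame.
#' @param language_col name of the language column.
#' @param min_n minimum level count to retain (`0` keeps everything).
#' @return the filtered data frame; attribute `"dropped_languages"` is a
#'   data frame logging each removed level and its row count.
#' @export
drop_rare_language <- function(data, language_col = "language", min_n = 2L) {
  stopifnot(min_n >= 0L, language_col %in% names(data))
  lang <- as.factor(data[[language_col]])
  counts <- table(lang)
  rare <- names(counts)[counts < min_n]
  log <- data.frame(level = rare,
                    n = as.integer(counts[rare]),
                    stringsAsFactors = FALSE)
  keep <- !(as.character(lang) %in% rare)
  out <- data[keep, , drop = FALSE]
  out[[language_col]] <- droplevels(factor(out[[language_col]],
                                           levels = setdiff(levels(lang),
                                                            rare)))
  attr(out, "dropped_languages") <- log
  out
}

#' Interview-language summary table
#'
#' Counts and percentages per language, rounded half-away-from-zero to two
#' decimals as in published survey tables, with a total row and optional
#' aggregate rows (e.g. all Asian languages combined).
#'
#' @param counts named nonnegative counts per language, or a factor/character
#'   vector of per-respondent languages to be tabulated.
#' @param aggregates optional named list of character vectors; each entry
#'   adds a row summing the named levels (computed from counts, not from
#'   rounded percentages).
#' @return data frame with columns `language`, `n`, `percent`; the final row
#'   is `Total`. Aggregate rows carry the attribute `"aggregate_rows"`.
#' @export
language_summary <- function(counts, aggregates = NULL) {
  if (is.factor(counts) || is.character(counts))
    counts <- table(counts)
  counts <- stats::setNames(as.numeric(counts), names(counts))
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("counts must be named by language", call. = FALSE)
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  total <- sum(counts)
  if (total == 0) stop("all counts are zero", call. = FALSE)
  pct <- round_half_up(100 * counts / total, 2)
  out <- data.frame(language = names(counts), n = unname(counts),
                    percent = unname(pct), stringsAsFactors = FALSE)
  agg <- NULL
  if (!is.null(aggregates)) {
    agg <- do.call(rbind, lapply(names(aggregates), function(nm) {
      levs <- aggregates[[nm]]
      missing_lev <- setdiff(levs, names(counts))
      if (length(missing_lev))
        stop("aggregate '", nm, "' names unknown level(s): ",
             paste(missing_lev, collapse = ", "), call. = FALSE)
      n <- sum(counts[levs])
      data.frame(language = nm, n = n,
                 percent = round_half_up(100 * n / total, 2),
                 stringsAsFactors = FALSE)
    }))
    out <- rbind(out, agg)
  }
  out <- rbind(out, data.frame(language = "Total", n = total,
                               percent = round_half_up(100, 2)))
  attr(out, "aggregate_rows") <- if (is.null(agg)) character(0) else
    agg$language
  out
}

#' Conditional proportions by group
#'
#' Restricts the table to rows satisfying a filter (e.g. respondents
#' reporting not-good health), then computes within each group level the
#' proportion with a binary target attribute, alongside the cell size.
#' An empty cell yields `NA` (undefined), never 0.
#'
#' @param data data frame.
#' @param filter logical vector (length `nrow(data)`) or the name of a
#'   binary column; rows where it is 1/TRUE are kept.
#' @param target name of the binary attribute column.
#' @param group name of the grouping column (e.g. interview language).
#' @return data frame with columns `group`, `n`, `proportion`.
#' @export
conditional_proportions <- function(data, filter, target, group) {
  stopifnot(target %in% names(data), group %in% names(data))
  if (is.character(filter) && length(filter) == 1L) {
    stopifnot(filter %in% names(data))
    filter <- data[[filter]] == 1
  }
  stopifnot(is.logical(filter), length(filter) == nrow(data))
  sub <- data[filter, , drop = FALSE]
  g <- factor(sub[[group]])
  levs <- levels(factor(data[[group]]))
  out <- do.call(rbind, lapply(levs, function(l) {
    v <- sub[[target]][g == l]
    data.frame(group = l, n = length(v),
               proportion = if (length(v)) mean(v == 1) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
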