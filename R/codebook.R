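#' Construct a codebook
#'
#' A codebook declares the role of every column of a survey table: plain
#' `feature` (ordinal-numeric or nominal), the five-level health `outcome`,
#' the survey `weight`, or the respondent `id`. Nominal features are expanded
#' to reference-coded indicators before entering the correlation network or
#' any forest.
#'
#' @param entries list of lists, each with fields `name`, `role`
#'   (`"feature"`, `"outcome"`, `"weight"`, `"id"`), optional `kind`
#'   (`"ordinal"` or `"nominal"`, features only) and optional `levels`
#'   (character vector; first level is the reference).
#' @return list of class `"ff_codebook"`.
#' @export
codebook <- function(entries) {
  roles <- c("feature", "outcome", "weight", "id")
  for (e in entries) {
    stopifnot(is.list(e), !is.null(e$name))
    if (!e$role %in% roles)
      stop("unknown role '", e$role, "' for '", e$name, "'", call. = FALSE)
    if (identical(e$role, "feature") &&
        !is.null(e$kind) && !e$kind %in% c("ordinal", "nominal"))
      stop("unknown kind '", e$kind, "' for '", e$name, "'", call. = FALSE)
  }
  nm <- vapply(entries, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate codebook names", call. = FALSE)
  structure(stats::setNames(entries, nm), class = "ff_codebook")
}

codebook_names <- function(cb, role = NULL, kind = NULL) {
  keep <- vapply(cb, function(e) {
    (is.null(role) || identical(e$role, role)) &&
      (is.null(kind) || identical(e$kind %||% "ordinal", kind))
  }, logical(1))
  names(cb)[keep]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write a YAML codebook
#'
#' @param path file path.
#' @return [read_codebook()] returns an `"ff_codebook"`.
#' @export
read_codebook <- function(path) {
  codebook(yaml::read_yaml(path))
}

#' @rdname read_codebook
#' @param cb an `"ff_codebook"`.
#' @export
write_codebook <- function(cb, path) {
  yaml::write_yaml(lapply(unname(cb), function(e)
    e[!vapply(e, is.null, logical(1))]), path)
  invisible(path)
}

#' Expand survey columns into a numeric feature matrix
#'
#' Ordinal features become numeric columns; nominal features become
#' reference-coded 0/1 indicator columns named `"<name>=<level>"`, one per
#' non-reference observed level. The mapping from indicator to parent column
#' is recorded so that forest importances can later be aggregated back to
#' the parent variable.
#'
#' @param data survey data frame.
#' @param cb an `"ff_codebook"`.
#' @param factor_levels optional named list fixing the levels used for each
#'   nominal feature (e.g. the training-wave levels when expanding a test
#'   wave); defaults to the observed levels in `data`.
#' @return list with `x` (numeric matrix), `parent` (named character vector
#'   mapping each column of `x` to its source column) and `factor_levels`.
#' @export
expand_features <- function(data, cb, factor_levels = NULL) {
  feats <- codebook_names(cb, role = "feature")
  missing_cols <- setdiff(feats, names(data))
  if (length(missing_cols))
    stop("codebook mismatch: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  cols <- list(); parent <- character(0); used_levels <- list()
  for (nm in feats) {
    kind <- cb[[nm]]$kind %||% "ordinal"
    if (kind == "nominal") {
      levs <- factor_levels[[nm]] %||%
        levels(factor(data[[nm]], levels = cb[[nm]]$levels %||%
                        sort(unique(as.character(data[[nm]])))))
      levs <- levs[levs %in% unique(as.character(data[[nm]])) |
                     !is.null(factor_levels[[nm]])]
      f <- factor(as.character(data[[nm]]), levels = levs)
      if (anyNA(f))
        stop("level(s) outside the declared set in '", nm, "'",
             call. = FALSE)
      for (l in levs[-1L]) {
        cn <- paste0(nm, "=", l)
        cols[[cn]] <- as.numeric(f == l)
        parent[cn] <- nm
      }
      used_levels[[nm]] <- levs
    } else {
      v <- data[[nm]]
      if (!is.numeric(v))
        stop("ordinal feature '", nm, "' is not numeric", call. = FALSE)
      cols[[nm]] <- as.numeric(v)
      parent[nm] <- nm
    }
  }
  x <- do.call(cbind, cols)
  colnames(x) <- names(cols)
  list(x = x, parent = parent, factor_levels = used_levels)
}
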