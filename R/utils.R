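#' Derive a child seed from a master seed and a name
#'
#' Counter/name-based derivation so that per-module or per-run seeds do not
#' depend on execution order. The result is always in `[1, 2^31 - 2]`.
#'
#' @param master integer master seed.
#' @param key character tag (e.g. `"module_3"` or `"run_17"`).
#' @return a single integer seed.
#' @export
derive_seed <- function(master, key) {
  stopifnot(length(master) == 1L, is.finite(master), is.character(key),
            length(key) == 1L)
  m <- 2147483647  # 2^31 - 1, Mersenne prime; arithmetic stays exact in doubles
  h <- 0
  for (c in utf8ToInt(key)) h <- (h * 31 + c) %% m
  s <- (abs(as.numeric(master)) %% m)
  # two multiplicative mixing rounds keep distinct (master, key) pairs apart
  v <- (s * 48271) %% m
  v <- (v + h) %% m
  v <- (v * 69621 + 1) %% m
  as.integer(v %% (m - 1) + 1)
}

#' Round half away from zero
#'
#' Published survey tables round `x.xx5` upward in magnitude, unlike R's
#' banker's rounding in [round()].
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# shared argument checks ------------------------------------------------------

check_feature_matrix <- function(x, min_p = 1L) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("feature matrix must be numeric", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (ncol(x) < min_p)
    stop(sprintf("need at least %d features, got %d", min_p, ncol(x)),
         call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0 | !is.finite(sds))) {
    bad <- colnames(x)[sds == 0 | !is.finite(sds)]
    stop("zero-variance feature(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  x
}

check_binary_outcome <- function(y) {
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (is.logical(y)) y <- as.integer(y)
  u <- sort(unique(y))
  if (!all(u %in% c(0, 1)))
    stop("outcome must be binary (0/1, logical, or two-level factor)",
         call. = FALSE)
  if (length(u) < 2L)
    stop("outcome has a single class; both classes are required",
         call. = FALSE)
  as.integer(y)
}
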