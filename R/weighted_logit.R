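#' Survey-weighted logistic regression
#'
#' Maximizes the weighted pseudo-log-likelihood
#' `sum w_i [y_i log p_i + (1 - y_i) log(1 - p_i)]` by iteratively
#' reweighted least squares. The variance is a weights-only sandwich
#' estimator (with-replacement approximation), so point estimates match a
#' design-based fit while standard errors approximate — but do not
#' replicate — a full Taylor-linearization with strata and PSUs. Weights are
#' normalized to mean 1 internally; point estimates and sandwich standard
#' errors are invariant to rescaling all weights by a constant.
#'
#' Quasi-complete separation is reported, not repaired: when the algorithm
#' fails to converge and a coefficient magnitude exceeds 15 (a nonsensical
#' value on the log-odds scale for survey covariates), an error names the
#' offending term — the familiar pathology of a factor level observed only a
#' handful of times.
#'
#' @param formula model formula; factor terms use their first level as
#'   reference.
#' @param data data frame.
#' @param weights positive survey weights (one per row); defaults to equal
#'   weights, which reproduces the ordinary maximum-likelihood fit.
#' @param tol convergence tolerance on `max |delta beta|`.
#' @param max_iter maximum IRLS iterations.
#' @return object of class `"weighted_logit"` with components
#'   `coefficients`, `vcov` (sandwich), `converged`, `n_iter`,
#'   `weight_total`, `fitted`, `linear_predictors`, `y`, `terms`, `xlevels`.
#' @examples
#' d <- data.frame(y = rbinom(100, 1, 0.5), x = rnorm(100))
#' fit <- weighted_logit(y ~ x, d)
#' coef(fit)
#' @export
weighted_logit <- function(formula, data, weights = NULL, tol = 1e-8,
                           max_iter = 100L) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  tt <- attr(mf, "terms")
  y <- check_binary_outcome(stats::model.response(mf))
  X <- stats::model.matrix(tt, mf)
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient", call. = FALSE)
  n <- length(y)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(!is.finite(weights)) || any(weights <= 0))
    stop("weights must be positive, finite, one per row", call. = FALSE)
  w <- weights / mean(weights)

  beta <- numeric(ncol(X))
  converged <- FALSE
  iter <- 0L
  eps <- 1e-10
  while (iter < max_iter) {
    iter <- iter + 1L
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    p <- pmin(pmax(p, eps), 1 - eps)
    v <- p * (1 - p)
    WX <- X * (w * v)
    z <- eta + (y - p) / v
    new_beta <- tryCatch(
      drop(solve(crossprod(X, WX), crossprod(WX, z))),
      error = function(e) stop("IRLS failed: ", conditionMessage(e),
                               call. = FALSE))
    delta <- max(abs(new_beta - beta))
    beta <- new_beta
    if (delta < tol) { converged <- TRUE; break }
  }
  names(beta) <- colnames(X)
  if (!converged && max(abs(beta)) > 15) {
    worst <- names(beta)[which.max(abs(beta))]
    stop("apparent separation: coefficient for '", worst,
         "' diverged (|beta| > 15 without convergence); ",
         "consider dropping rare factor levels", call. = FALSE)
  }
  eta <- drop(X %*% beta)
  p <- stats::plogis(eta)
  # sandwich: bread = weighted Fisher information, meat = weighted scores
  A <- crossprod(X, X * (w * p * (1 - p)))
  U <- X * (w * (y - p))
  M <- crossprod(U)
  Ainv <- solve(A)
  V <- Ainv %*% M %*% Ainv
  V <- (V + t(V)) / 2
  dimnames(V) <- list(names(beta), names(beta))
  structure(list(coefficients = beta, vcov = V, converged = converged,
                 n_iter = iter, weight_total = sum(weights),
                 fitted = p, linear_predictors = eta, y = y,
                 weights = weights, terms = tt,
                 xlevels = stats::.getXlevels(tt, mf),
                 call = match.call()),
            class = "weighted_logit")
}

#' @export
coef.weighted_logit <- function(object, ...) object$coefficients

#' @export
vcov.weighted_logit <- function(object, ...) object$vcov

#' @export
print.weighted_logit <- function(x, ...) {
  cat("Survey-weighted logistic regression",
      if (!x$converged) "(NOT converged)" else "", "\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
summary.weighted_logit <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  z <- object$coefficients / se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               `z value` = z, `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  out <- list(coefficients = tab, converged = object$converged,
              n_iter = object$n_iter, n = length(object$y),
              weight_total = object$weight_total)
  class(out) <- "summary.weighted_logit"
  out
}

#' @export
print.summary.weighted_logit <- function(x, ...) {
  cat("Survey-weighted logistic regression (sandwich standard errors)\n")
  cat(sprintf("n = %d, total weight = %.1f, IRLS iterations = %d%s\n\n",
              x$n, x$weight_total, x$n_iter,
              if (!x$converged) " [not converged]" else ""))
  stats::printCoefmat(x$coefficients, digits = 4)
  invisible(x)
}

#' @export
confint.weighted_logit <- function(object, parm, level = 0.95, ...) {
  se <- sqrt(diag(object$vcov))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(object$coefficients - zq * se, object$coefficients + zq * se)
  colnames(ci) <- sprintf("%.1f %%", c((1 - level) / 2, 1 - (1 - level) / 2) * 100)
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
residuals.weighted_logit <- function(object,
                                     type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  r <- object$y - object$fitted
  if (type == "pearson")
    r <- r / sqrt(object$fitted * (1 - object$fitted))
  r
}

#' Predicted probabilities for new data
#'
#' @param object a `"weighted_logit"` fit.
#' @param newdata data frame with the model's covariates; factor columns must
#'   only use levels seen at fit time (an unseen level is an error naming the
#'   level, not a silent extrapolation).
#' @param type `"response"` (probabilities, default) or `"link"`.
#' @param ... unused.
#' @export
predict.weighted_logit <- function(object, newdata,
                                   type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (missing(newdata))
    return(if (type == "response") object$fitted else
             object$linear_predictors)
  for (v in names(object$xlevels)) {
    if (!v %in% names(newdata)) next
    new_lev <- setdiff(unique(as.character(newdata[[v]])),
                       object$xlevels[[v]])
    if (length(new_lev))
      stop("unseen level(s) in '", v, "': ",
           paste(new_lev, collapse = ", "), call. = FALSE)
    newdata[[v]] <- factor(newdata[[v]], levels = object$xlevels[[v]])
  }
  tt <- stats::delete.response(object$terms)
  mf <- stats::model.frame(tt, newdata, na.action = stats::na.fail,
                           xlev = object$xlevels)
  X <- stats::model.matrix(tt, mf)
  eta <- drop(X %*% object$coefficients[colnames(X)])
  if (type == "response") stats::plogis(eta) else eta
}

#' Odds ratios with Wald confidence limits
#'
#' `exp(beta)` with `exp(beta +/- z * se)` limits from the sandwich standard
#' errors; each factor coefficient is labelled "level vs reference".
#'
#' @param fit a converged `"weighted_logit"` fit.
#' @param level confidence level (default 0.95).
#' @return data frame with columns `term`, `label`, `point`, `lo`, `hi`.
#' @export
odds_ratios <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "weighted_logit"))
  if (!fit$converged)
    stop("odds ratios require a converged fit", call. = FALSE)
  beta <- fit$coefficients
  se <- sqrt(diag(fit$vcov))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  keep <- names(beta) != "(Intercept)"
  label <- names(beta)
  for (v in names(fit$xlevels)) {
    levs <- fit$xlevels[[v]]
    ref <- levs[1L]
    for (l in levs[-1L]) {
      idx <- label == paste0(v, l)
      label[idx] <- paste0(v, ": ", l, " vs ", ref)
    }
  }
  out <- data.frame(term = names(beta)[keep], label = label[keep],
                    point = exp(beta[keep]),
                    lo = exp(beta[keep] - zq * se[keep]),
                    hi = exp(beta[keep] + zq * se[keep]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Held-out classification metrics
#'
#' Accuracy at a probability threshold, the confusion counts, and the
#' Mann-Whitney AUC: `P(score_case > score_control) + 0.5 P(tie)` over all
#' case-control pairs, computed from midranks.
#'
#' @param probs predicted probabilities (or any scores for the AUC).
#' @param y_true binary outcomes.
#' @param threshold classification threshold for accuracy (default 0.5).
#' @return list with `accuracy`, `auc` (`NA` with `auc_defined = FALSE` when
#'   `y_true` has a single class), `confusion` (tp/fp/tn/fn), `threshold`,
#'   `n`.
#' @export
evaluate_predictions <- function(probs, y_true, threshold = 0.5) {
  stopifnot(length(probs) == length(y_true),
            all(probs >= 0 & probs <= 1))
  if (is.factor(y_true)) y_true <- as.integer(y_true) - 1L
  y <- as.integer(y_true)
  stopifnot(all(y %in% c(0L, 1L)))
  pred <- as.integer(probs >= threshold)
  conf <- c(tp = sum(pred == 1 & y == 1), fp = sum(pred == 1 & y == 0),
            tn = sum(pred == 0 & y == 0), fn = sum(pred == 0 & y == 1))
  acc <- mean(pred == y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L) {
    auc <- NA_real_; defined <- FALSE
  } else {
    r <- rank(probs)  # midranks give the half-credit tie convention
    auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    defined <- TRUE
  }
  list(accuracy = acc, auc = auc, auc_defined = defined,
       confusion = conf, threshold = threshold, n = length(y))
}
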