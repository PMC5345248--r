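# Model-error and selection metrics against a known truth.

#' Model error of a coefficient estimate
#'
#' The quadratic form \eqn{ME(\hat\theta) = (\hat\theta - \theta)' \Sigma
#' (\hat\theta - \theta)}, where \eqn{\Sigma} is the covariance matrix of the
#' regressors. With a positive-definite \eqn{\Sigma} this is 0 exactly when
#' the estimate equals the truth. The intercept is excluded: both vectors are
#' coefficient (slope) vectors of the same length as `ncol(sigma)`.
#'
#' @param beta_hat Estimated coefficient vector.
#' @param beta_true True coefficient vector.
#' @param sigma Covariance matrix of the regressors (by default the
#'   generating, population covariance; pass the empirical covariance of a
#'   realized design for the sample-based variant).
#' @return Non-negative scalar.
#' @examples
#' model_error(c(1, 1), c(0, 0), matrix(c(1, .5, .5, 1), 2))  # 3
#' @export
model_error <- function(beta_hat, beta_true, sigma) {
  beta_hat <- as.numeric(beta_hat)
  beta_true <- as.numeric(beta_true)
  if (length(beta_hat) != length(beta_true) ||
      length(beta_hat) != nrow(sigma) || nrow(sigma) != ncol(sigma)) {
    stop("dimension mismatch between coefficient vectors and `sigma`",
         call. = FALSE)
  }
  d <- beta_hat - beta_true
  as.numeric(crossprod(d, sigma %*% d))
}

#' Relative model error
#'
#' The ratio \eqn{ME(\hat\theta) / ME(\hat\theta_{LS})} of a method's model
#' error to that of the full-model least-squares estimator. The median of
#' this ratio over simulation replicates, times 100, is the MRME reported by
#' the simulation study.
#'
#' @param me_method Model error of the method under evaluation.
#' @param me_fullols Model error of the full-model OLS estimator; must be
#'   strictly positive.
#' @return The ratio (dimensionless; multiply by 100 for percent).
#' @export
relative_model_error <- function(me_method, me_fullols) {
  if (any(me_fullols <= 0)) {
    stop("full-model OLS model error must be > 0 (degenerate replicate)",
         call. = FALSE)
  }
  me_method / me_fullols
}

#' True- and false-positive selection counts
#'
#' A variable is "selected" if its estimated coefficient is nonzero. TP is
#' the number of truly nonzero coefficients selected; FP the number of truly
#' zero coefficients selected.
#'
#' @param selected Integer indices of the selected variables (1-based).
#' @param beta_true True coefficient vector defining the support.
#' @return A one-row tibble with integer columns `tp` and `fp`.
#' @examples
#' selection_metrics(c(1, 3), c(1, 0, 0, 2))  # tp = 1, fp = 1
#' @export
selection_metrics <- function(selected, beta_true) {
  selected <- as.integer(selected)
  p <- length(beta_true)
  if (length(selected) && (min(selected) < 1L || max(selected) > p)) {
    stop("`selected` indices out of 1..p", call. = FALSE)
  }
  truth <- which(beta_true != 0)
  tibble::tibble(
    tp = length(intersect(selected, truth)),
    fp = length(setdiff(selected, truth))
  )
}
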