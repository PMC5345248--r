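#' Penalty specification
#'
#' Construct and validate the specification of a coefficient penalty for
#' penalized least squares. Five families are supported:
#'
#' * `"lasso"`: \eqn{p_\lambda(\theta) = \lambda \theta},
#' * `"elastic_net"`: \eqn{p_\lambda(\theta) = \lambda[\alpha\theta +
#'   (1-\alpha)\theta^2]}, a linear combination of the L1 and L2 (ridge)
#'   penalties with L1 proportion `alpha`,
#' * `"scad"`: the smoothly clipped absolute deviation penalty, defined by its
#'   derivative \eqn{p'_\lambda(\theta) = \lambda\{I(\theta\le\lambda) +
#'   (a\lambda-\theta)_+ / ((a-1)\lambda) \, I(\theta>\lambda)\}} with
#'   \eqn{p_\lambda(0)=0} and concavity parameter `a > 2` (default 3.7),
#' * `"mcp"`: the minimax concave penalty, with derivative
#'   \eqn{p'_\lambda(\theta) = (a\lambda-\theta)_+ / a}, `a > 1` (default 3),
#'   which moves the flat part of the SCAD derivative to the origin,
#' * `"adaptive_lasso"`: the lasso with per-coordinate weights \eqn{w_j}
#'   multiplying \eqn{\lambda}; a weight of `Inf` excludes a coordinate.
#'
#' SCAD and MCP taper their derivative to zero so large coefficients are left
#' unshrunk (near-unbiasedness); together with the adaptive lasso they enjoy
#' the oracle property under BIC tuning.
#'
#' @param family Penalty family, one of `"lasso"`, `"elastic_net"`, `"scad"`,
#'   `"mcp"`, `"adaptive_lasso"`.
#' @param lambda Non-negative penalty level \eqn{\lambda}.
#' @param a Concavity parameter for SCAD (`> 2`, default 3.7, the value
#'   suggested by Bayesian risk analysis) and MCP (`> 1`, default 3).
#' @param alpha L1 proportion in `(0, 1]` for the elastic net (default 0.5).
#' @param weights Non-negative per-coordinate weights for the adaptive lasso
#'   (`Inf` allowed, meaning the coordinate is excluded). Ignored otherwise.
#' @return An object of class `"penalty_spec"`.
#' @examples
#' penalty_spec("scad", lambda = 0.1)
#' penalty_spec("elastic_net", lambda = 0.2, alpha = 0.3)
#' @export
penalty_spec <- function(family = c("lasso", "elastic_net", "scad", "mcp",
                                    "adaptive_lasso"),
                         lambda, a = NULL, alpha = 0.5, weights = NULL) {
  family <- match.arg(family)
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0) {
    stop("`lambda` must be a single non-negative number", call. = FALSE)
  }
  if (is.null(a)) a <- switch(family, scad = 3.7, mcp = 3, NA_real_)
  if (family == "scad" && (!is.finite(a) || a <= 2)) {
    stop("SCAD requires concavity parameter a > 2", call. = FALSE)
  }
  if (family == "mcp" && (!is.finite(a) || a <= 1)) {
    stop("MCP requires concavity parameter a > 1", call. = FALSE)
  }
  if (family == "elastic_net") {
    if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
        alpha <= 0 || alpha > 1) {
      stop("elastic net requires alpha in (0, 1]", call. = FALSE)
    }
  }
  if (family == "adaptive_lasso") {
    if (is.null(weights) || !is.numeric(weights) || any(is.na(weights)) ||
        any(weights < 0)) {
      stop("adaptive lasso requires non-negative `weights`", call. = FALSE)
    }
  } else {
    weights <- NULL
  }
  structure(
    list(family = family, lambda = lambda, a = a, alpha = alpha,
         weights = weights),
    class = "penalty_spec"
  )
}

#' @export
print.penalty_spec <- function(x, ...) {
  cat("<penalty_spec> family =", x$family, " lambda =", format(x$lambda))
  if (x$family %in% c("scad", "mcp")) cat("  a =", x$a)
  if (x$family == "elastic_net") cat("  alpha =", x$alpha)
  if (x$family == "adaptive_lasso") {
    cat("  weights = [", length(x$weights), "values ]")
  }
  cat("\n")
  invisible(x)
}

# effective lambda for one coordinate; `weight` multiplies lambda.
# An infinite weight excludes the coordinate even at lambda = 0.
.eff_lambda <- function(spec, weight) {
  lam <- spec$lambda * weight
  lam[is.nan(lam)] <- Inf
  lam
}

#' Penalty function value
#'
#' Evaluate the scalar penalty \eqn{p_\lambda(\theta)} at `theta >= 0`.
#' SCAD and MCP values are the integrals of their defining derivatives from 0,
#' with \eqn{p_\lambda(0) = 0}; both are constant for
#' \eqn{\theta \ge a\lambda}.
#'
#' @param theta Non-negative value(s) at which to evaluate the penalty.
#' @param spec A [penalty_spec()].
#' @param weight Non-negative multiplier of `lambda` (adaptive weight;
#'   default 1).
#' @return Numeric vector of penalty values, same length as `theta`.
#' @examples
#' penalty_value(1.5, penalty_spec("lasso", lambda = 2))  # 3
#' @export
penalty_value <- function(theta, spec, weight = 1) {
  stopifnot(inherits(spec, "penalty_spec"))
  if (any(!is.finite(theta)) || any(theta < 0)) {
    stop("`theta` must be finite and non-negative", call. = FALSE)
  }
  lam <- .eff_lambda(spec, weight)
  a <- spec$a
  switch(spec$family,
    lasso = ,
    adaptive_lasso = lam * theta,
    elastic_net = lam * (spec$alpha * theta + (1 - spec$alpha) * theta^2),
    scad = {
      out <- ifelse(theta <= lam, lam * theta,
        ifelse(theta <= a * lam,
          (2 * a * lam * theta - theta^2 - lam^2) / (2 * (a - 1)),
          (a + 1) * lam^2 / 2
        )
      )
      out
    },
    mcp = ifelse(theta <= a * lam, lam * theta - theta^2 / (2 * a),
                 a * lam^2 / 2)
  )
}

#' Penalty derivative
#'
#' Evaluate \eqn{p'_\lambda(\theta)} for `theta >= 0`. For SCAD this equals
#' \eqn{\lambda} on \eqn{[0, \lambda]}, decreases linearly on
#' \eqn{(\lambda, a\lambda]} and is 0 beyond; for MCP it is
#' \eqn{(a\lambda - \theta)_+ / a}.
#'
#' @inheritParams penalty_value
#' @return Numeric vector of derivative values.
#' @export
penalty_derivative <- function(theta, spec, weight = 1) {
  stopifnot(inherits(spec, "penalty_spec"))
  if (any(!is.finite(theta)) || any(theta < 0)) {
    stop("`theta` must be finite and non-negative", call. = FALSE)
  }
  lam <- .eff_lambda(spec, weight)
  a <- spec$a
  switch(spec$family,
    lasso = ,
    adaptive_lasso = rep_len(lam, length(theta)),
    elastic_net = lam * (spec$alpha + 2 * (1 - spec$alpha) * theta),
    scad = ifelse(theta <= lam, lam,
                  pmax(a * lam - theta, 0) / (a - 1)),
    mcp = pmax(a * lam - theta, 0) / a
  )
}

.soft <- function(z, t) sign(z) * pmax(abs(z) - t, 0)

#' Univariate thresholding operator
#'
#' The exact minimizer over \eqn{\beta} of the univariate penalized problem
#' \deqn{\tfrac12 (z - \beta)^2 + p_\lambda(|\beta|),}
#' which is the coordinate update used by the coordinate-descent solver on a
#' standardized design. Closed forms: soft thresholding for the lasso and
#' (with additional proportional shrinkage) the elastic net; the piecewise
#' SCAD rule; the firm-thresholding MCP rule. For SCAD and MCP the operator
#' is the identity for \eqn{|z| \ge a\lambda} (the unbiasedness region).
#'
#' @param z Real value(s): the unpenalized univariate least-squares solution.
#' @param spec A [penalty_spec()].
#' @param weight Non-negative multiplier of `lambda` (default 1). `Inf`
#'   forces the coordinate to 0.
#' @return Numeric vector, same length as `z`.
#' @examples
#' threshold(0.5, penalty_spec("lasso", lambda = 1))        # 0
#' threshold(10, penalty_spec("scad", lambda = 1))          # 10 (unbiased)
#' @export
threshold <- function(z, spec, weight = 1) {
  stopifnot(inherits(spec, "penalty_spec"))
  if (any(!is.finite(z))) stop("`z` must be finite", call. = FALSE)
  lam <- .eff_lambda(spec, weight)
  if (!is.finite(lam)) return(rep_len(0, length(z)))
  a <- spec$a
  switch(spec$family,
    lasso = ,
    adaptive_lasso = .soft(z, lam),
    elastic_net = .soft(z, lam * spec$alpha) /
      (1 + 2 * lam * (1 - spec$alpha)),
    scad = {
      az <- abs(z)
      ifelse(az <= 2 * lam, .soft(z, lam),
        ifelse(az <= a * lam,
          ((a - 1) * z - sign(z) * a * lam) / (a - 2),
          z
        )
      )
    },
    mcp = {
      az <- abs(z)
      ifelse(az <= a * lam, .soft(z, lam) * a / (a - 1), z)
    }
  )
}
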