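# lambda-path construction and BIC model selection.

# lambda_max on the standardized scale: the smallest lambda at which every
# coefficient is 0. For the (weighted) lasso this is max_j |x_j' yc| / (n w_j)
# over coordinates with finite positive weight; for the elastic net the L1
# part carries alpha, so divide by alpha; SCAD/MCP share the lasso value
# (their threshold is soft thresholding for |z| <= lambda... <= 2 lambda).
.lambda_max <- function(Xs, yc, family, alpha = 0.5, weights = NULL) {
  n <- nrow(Xs)
  z <- abs(crossprod(Xs, yc)) / n
  if (max(z) < 1e-14) stop("outcome has no variance", call. = FALSE)
  lmax <- switch(family,
    elastic_net = max(z) / alpha,
    adaptive_lasso = {
      if (is.null(weights)) stop("adaptive lasso needs weights", call. = FALSE)
      ok <- is.finite(weights) & weights > 0
      if (!any(ok)) stop("no finite positive adaptive weights", call. = FALSE)
      max(z[ok] / weights[ok])
    },
    max(z)
  )
  # one-ulp guard: the compiled dot product may round differently from R's
  # crossprod, so sit a hair above the analytic boundary
  lmax * (1 + 1e-10)
}

#' Construct a decreasing log-spaced lambda grid
#'
#' The grid runs from \eqn{\lambda_{max}} — the smallest penalty level at
#' which all coefficients are zero on the standardized scale — down to
#' `ratio * lambda_max`, log-spaced, with `n_lambda` points.
#'
#' @inheritParams fit_penalized
#' @param n_lambda Number of grid points (default 100).
#' @param ratio Ratio of the smallest to the largest lambda (default 0.001).
#' @param gamma Adaptive-lasso weight exponent (used when
#'   `family = "adaptive_lasso"` and `weights` is `NULL`).
#' @return Strictly decreasing numeric vector of length `n_lambda`.
#' @export
lambda_path <- function(data, outcome, family = c("lasso", "elastic_net",
                                                  "scad", "mcp",
                                                  "adaptive_lasso"),
                        n_lambda = 100L, ratio = 0.001, alpha = 0.5,
                        weights = NULL, gamma = 1) {
  family <- match.arg(family)
  if (n_lambda < 2L) stop("`n_lambda` must be >= 2", call. = FALSE)
  if (ratio <= 0 || ratio >= 1) stop("`ratio` must be in (0, 1)", call. = FALSE)
  xy <- .extract_xy(data, outcome)
  std <- .standardize(xy$X, xy$y)
  if (family == "adaptive_lasso" && is.null(weights)) {
    weights <- adaptive_weights(data, outcome, gamma = gamma)
  }
  lmax <- .lambda_max(std$Xs, std$yc, family, alpha = alpha,
                      weights = weights)
  .lambda_grid(lmax, n_lambda, ratio)
}

.lambda_grid <- function(lmax, n_lambda, ratio) {
  lams <- exp(seq(log(lmax), log(ratio * lmax), length.out = n_lambda))
  # pin the endpoints: exp(log(x)) can lose the last ulp, which would let a
  # coordinate sitting exactly at the boundary activate at lams[1]
  lams[1L] <- lmax
  lams[n_lambda] <- ratio * lmax
  lams
}

# Fit a path and compute BIC per lambda on a standardized problem.
# Returns list(lambda, beta (p x L std scale), df, bic, n_sweeps, converged).
.bic_path_core <- function(Xs, yc, family, a = NULL, alpha = 0.5,
                           weights = NULL, n_lambda = 100L, ratio = 0.001,
                           tol = 1e-7, max_sweeps = 10000L) {
  n <- nrow(Xs)
  lmax <- .lambda_max(Xs, yc, family, alpha = alpha, weights = weights)
  lams <- .lambda_grid(lmax, n_lambda, ratio)
  sol <- .cd_path(Xs, yc, lams, family, a = a, alpha = alpha,
                  weights = weights, tol = tol, max_sweeps = max_sweeps)
  B <- sol$beta
  rss <- colSums((yc - Xs %*% B)^2)
  df <- colSums(B != 0)
  rss_b <- pmax(rss, 1e-12)
  if (any(rss < 1e-12)) {
    warning("RSS numerically zero on the path; floored at 1e-12 for BIC",
            call. = FALSE)
  }
  bic <- n * log(rss_b / n) + df * log(n)
  list(lambda = lams, beta = B, df = df, bic = bic, rss = rss,
       n_sweeps = sol$n_sweeps, converged = sol$converged)
}

#' Fit a lambda path and select the tuning parameter by BIC
#'
#' Fits the whole decreasing lambda path with warm starts (each solution
#' initializes the next) and selects the model minimizing
#' \deqn{BIC(\lambda) = n \log(RSS/n) + \log(n)\,df,} with `df` the number of
#' nonzero coefficients (the always-present intercept is not counted). Ties
#' are broken toward the larger lambda, i.e. the sparser model. For the
#' elastic net the L1-proportion grid `alpha_grid` is crossed with the lambda
#' path and the global BIC minimum over both is returned. For the adaptive
#' lasso, pilot OLS weights \eqn{|\tilde\beta_j|^{-\gamma}} are computed
#' first (or supplied via `weights`).
#'
#' @inheritParams lambda_path
#' @inheritParams fit_penalized
#' @param alpha_grid Elastic-net alpha values to search (default
#'   `seq(0.1, 0.9, by = 0.1)`).
#' @param ... Passed to the solver (`tol`, `max_sweeps`).
#' @return A `pensel_path` object: the per-lambda path (see
#'   [tidy.pensel_path()]), the index of the BIC-optimal fit, and the selected
#'   fit as `$best_fit` (a `pensel_fit`).
#' @examples
#' d <- tibble::tibble(x1 = rnorm(80), x2 = rnorm(80), x3 = rnorm(80))
#' d$y <- 1.5 * d$x1 + rnorm(80)
#' path <- select_by_bic(d, "y", family = "scad", n_lambda = 40)
#' generics::glance(path)
#' @export
select_by_bic <- function(data, outcome, family = c("lasso", "elastic_net",
                                                    "scad", "mcp",
                                                    "adaptive_lasso"),
                          n_lambda = 100L, ratio = 0.001, a = NULL,
                          alpha_grid = seq(0.1, 0.9, by = 0.1), gamma = 1,
                          weights = NULL, ...) {
  family <- match.arg(family)
  if (n_lambda < 2L) stop("`n_lambda` must be >= 2", call. = FALSE)
  if (ratio <= 0 || ratio >= 1) stop("`ratio` must be in (0, 1)", call. = FALSE)
  xy <- .extract_xy(data, outcome)
  std <- .standardize(xy$X, xy$y)
  if (family == "adaptive_lasso" && is.null(weights)) {
    weights <- adaptive_weights(data, outcome, gamma = gamma)
  }

  if (family == "elastic_net") {
    paths <- lapply(alpha_grid, function(al) {
      .bic_path_core(std$Xs, std$yc, "elastic_net", alpha = al,
                     n_lambda = n_lambda, ratio = ratio, ...)
    })
    mins <- vapply(paths, function(pp) min(pp$bic), numeric(1))
    k <- which.min(mins)
    core <- paths[[k]]
    alpha_best <- alpha_grid[k]
    path_tbl <- purrr::map2_dfr(paths, alpha_grid, function(pp, al) {
      tibble::tibble(alpha = al, lambda = pp$lambda, df = as.integer(pp$df),
                     bic = pp$bic, n_selected = as.integer(pp$df))
    })
  } else {
    core <- .bic_path_core(std$Xs, std$yc, family, a = a,
                           weights = weights, n_lambda = n_lambda,
                           ratio = ratio, ...)
    alpha_best <- NA_real_
    path_tbl <- tibble::tibble(alpha = NA_real_, lambda = core$lambda,
                               df = as.integer(core$df), bic = core$bic,
                               n_selected = as.integer(core$df))
  }
  best <- which.min(core$bic)  # first minimum = largest lambda on ties
  fit <- .make_fit(core$beta[, best], std, xy$names, family,
                   core$lambda[best], a %||% switch(family, scad = 3.7,
                                                    mcp = 3, NA_real_),
                   if (family == "elastic_net") alpha_best else NA_real_,
                   weights, nrow(xy$X), core$n_sweeps[best],
                   core$converged[best] == 1L, outcome)
  structure(
    list(path = path_tbl, lambda = core$lambda, bic = core$bic,
         df = as.integer(core$df), best_index = best, best_fit = fit,
         family = family, alpha = alpha_best,
         alpha_grid = if (family == "elastic_net") alpha_grid else NULL,
         n = nrow(xy$X), outcome = outcome),
    class = "pensel_path"
  )
}

#' @export
print.pensel_path <- function(x, ...) {
  cat("<pensel_path> family =", x$family,
      if (!is.na(x$alpha)) paste0("(alpha = ", x$alpha, ")") else "",
      "\n  ", length(x$lambda), "lambda values; BIC-optimal lambda =",
      signif(x$lambda[x$best_index], 4), "selecting",
      length(x$best_fit$selected), "variable(s)\n")
  invisible(x)
}

#' Tidy a BIC-tuned path
#'
#' @param x A `pensel_path`.
#' @param ... Unused.
#' @return Tibble with one row per (alpha,) lambda: `alpha`, `lambda`, `df`,
#'   `bic`, `n_selected`.
#' @export
tidy.pensel_path <- function(x, ...) x$path

#' One-row summary of a BIC-tuned path
#'
#' @param x A `pensel_path`.
#' @param ... Unused.
#' @return One-row tibble describing the BIC-optimal fit.
#' @export
glance.pensel_path <- function(x, ...) {
  dplyr::mutate(glance(x$best_fit),
                alpha = x$alpha, best_index = x$best_index,
                n_lambda = length(x$lambda), .after = "lambda")
}

#' Plot BIC along the regularization path
#'
#' @param object A `pensel_path`.
#' @param ... Unused.
#' @return A ggplot: BIC against \eqn{\log_{10}\lambda} (one line per alpha
#'   for the elastic net), with the selected point marked.
#' @export
autoplot.pensel_path <- function(object, ...) {
  d <- object$path
  d$alpha_lab <- if (all(is.na(d$alpha))) "1" else factor(d$alpha)
  best <- tibble::tibble(lambda = object$lambda[object$best_index],
                         bic = object$bic[object$best_index])
  ggplot2::ggplot(d, ggplot2::aes(log10(.data$lambda), .data$bic,
                                  group = .data$alpha_lab,
                                  colour = .data$alpha_lab)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = best,
                        ggplot2::aes(log10(.data$lambda), .data$bic),
                        inherit.aes = FALSE, colour = "red", size = 2) +
    ggplot2::labs(x = expression(log[10](lambda)), y = "BIC",
                  colour = expression(alpha),
                  title = paste0("BIC path (", object$family, ")")) +
    ggplot2::theme_minimal()
}
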