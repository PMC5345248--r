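#' @useDynLib pensel, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
#' @importFrom stats coef lm median pt sd var predict rnorm
NULL

# ---- internal matrix plumbing -----------------------------------------------

# Extract the design matrix and outcome from a data frame. All columns other
# than `outcome` are covariates and must be numeric with no missing values.
.extract_xy <- function(data, outcome) {
  data <- as.data.frame(data)
  if (!outcome %in% names(data)) {
    stop("outcome column '", outcome, "' not found in `data`", call. = FALSE)
  }
  y <- data[[outcome]]
  xnames <- setdiff(names(data), outcome)
  if (length(xnames) == 0L) stop("no covariate columns", call. = FALSE)
  bad <- xnames[!vapply(data[xnames], is.numeric, logical(1))]
  if (length(bad)) {
    stop("non-numeric covariate column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  X <- as.matrix(data[xnames])
  if (anyNA(X) || anyNA(y)) stop("missing values in `data`", call. = FALSE)
  if (!is.numeric(y)) stop("outcome must be numeric", call. = FALSE)
  if (nrow(X) <= ncol(X)) {
    stop("this solver requires n > p (", nrow(X), " rows, ", ncol(X),
         " covariates)", call. = FALSE)
  }
  list(X = X, y = as.numeric(y), names = xnames)
}

# Standardize columns to mean 0 and 1/n-variance 1; center y.
.standardize <- function(X, y) {
  xbar <- colMeans(X)
  Xc <- sweep(X, 2L, xbar, "-")
  xsd <- sqrt(colMeans(Xc^2))
  if (any(xsd < 1e-10)) {
    stop("constant covariate column(s): ",
         paste(colnames(X)[xsd < 1e-10], collapse = ", "), call. = FALSE)
  }
  list(Xs = sweep(Xc, 2L, xsd, "/"), yc = y - mean(y),
       xbar = xbar, xsd = xsd, ybar = mean(y))
}

.family_code <- function(family) {
  switch(family, lasso = 1L, adaptive_lasso = 1L, elastic_net = 2L,
         scad = 3L, mcp = 4L,
         stop("unknown family '", family, "'", call. = FALSE))
}

# Penalized objective (standardized scale): (1/(2n))||yc - Xs b||^2 + penalty
.objective <- function(Xs, yc, beta, spec, weights = NULL) {
  n <- nrow(Xs)
  rss <- sum((yc - Xs %*% beta)^2)
  if (is.null(weights)) weights <- rep(1, length(beta))
  pen <- sum(vapply(seq_along(beta), function(j) {
    if (beta[j] == 0) return(0)
    penalty_value(abs(beta[j]), spec, weights[j])
  }, numeric(1)))
  rss / (2 * n) + pen
}

# BIC on the centered scale: n log(RSS/n) + df log(n); df = #nonzero slopes.
.bic <- function(rss, n, df) {
  if (rss < 1e-12) {
    warning("RSS numerically zero; floored at 1e-12 for BIC", call. = FALSE)
    rss <- 1e-12
  }
  n * log(rss / n) + df * log(n)
}

# Core path solver on a pre-standardized problem. Returns a list with the
# coefficient matrix (p x nlambda, standardized scale), sweeps, convergence.
.cd_path <- function(Xs, yc, lambda, family, a = NULL, alpha = 0.5,
                     weights = NULL, beta0 = NULL, tol = 1e-7,
                     max_sweeps = 10000L) {
  p <- ncol(Xs)
  if (is.null(weights)) weights <- rep(1, p)
  if (is.null(beta0)) beta0 <- rep(0, p)
  a_use <- if (is.null(a)) switch(family, scad = 3.7, mcp = 3, 0) else a
  fam <- .family_code(family)
  # arma::vec cannot hold Inf reliably across platforms? It can; but map
  # excluded coordinates explicitly to a huge finite sentinel is unnecessary:
  # the C++ threshold treats non-finite lambda*w as exclusion.
  .cd_path_cpp(Xs, yc, as.numeric(lambda), fam, a_use,
               alpha, as.numeric(weights), as.numeric(beta0),
               tol, as.integer(max_sweeps))
}

# Build a pensel_fit from a standardized-scale solution.
.make_fit <- function(beta_std, std, names, family, lambda, a, alpha,
                      weights, n, n_sweeps, converged, outcome) {
  beta <- as.numeric(beta_std) / std$xsd
  names(beta) <- names
  intercept <- std$ybar - sum(beta * std$xbar)
  selected <- which(beta_std != 0)
  rss <- sum((std$yc - std$Xs %*% beta_std)^2)
  df <- length(selected)
  structure(
    list(
      beta = beta, intercept = intercept, selected = selected,
      beta_std = as.numeric(beta_std),
      family = family, lambda = lambda, a = a, alpha = alpha,
      weights = weights, bic = .bic(rss, n, df), rss = rss, df = df,
      n = n, p = length(beta), n_sweeps = n_sweeps,
      converged = converged, outcome = outcome,
      xbar = std$xbar, xsd = std$xsd, ybar = std$ybar
    ),
    class = "pensel_fit"
  )
}

# ---- user-facing fitters ----------------------------------------------------

#' Fit a penalized linear regression at a fixed penalty level
#'
#' Minimizes \deqn{\frac{1}{2n}\|y - X\beta\|^2 +
#' \sum_{j=1}^p p_\lambda(|\beta_j|)} by cyclic coordinate descent. Covariate
#' columns are standardized internally to mean 0 and variance 1 and the
#' outcome is centered, so `lambda` always refers to the standardized scale;
#' reported coefficients are back-transformed to the original covariate scale
#' and an (unpenalized) intercept is always included. Zeros are exact: a
#' variable is selected iff its coefficient is nonzero.
#'
#' @param data A data frame: covariate columns plus one outcome column.
#' @param outcome Name of the outcome column.
#' @param family Penalty family (see [penalty_spec()]).
#' @param lambda Penalty level (standardized scale).
#' @param a Concavity parameter for SCAD/MCP (defaults 3.7 / 3).
#' @param alpha Elastic-net L1 proportion in `(0, 1]`.
#' @param weights Adaptive-lasso weights, length = number of covariates;
#'   `Inf` excludes a coordinate.
#' @param init Optional initial coefficient vector (original scale) for warm
#'   starts.
#' @param tol Convergence tolerance: maximum absolute standardized-coefficient
#'   change in a full sweep.
#' @param max_sweeps Sweep cap; exceeding it flags `converged = FALSE` rather
#'   than erroring.
#' @return A `pensel_fit` object; see [tidy.pensel_fit()] and
#'   [glance.pensel_fit()].
#' @examples
#' d <- tibble::tibble(x1 = rnorm(60), x2 = rnorm(60))
#' d$y <- 2 * d$x1 + rnorm(60, sd = 0.5)
#' fit <- fit_penalized(d, "y", family = "scad", lambda = 0.2)
#' generics::tidy(fit)
#' @export
fit_penalized <- function(data, outcome, family = c("lasso", "elastic_net",
                                                    "scad", "mcp",
                                                    "adaptive_lasso"),
                          lambda, a = NULL, alpha = 0.5, weights = NULL,
                          init = NULL, tol = 1e-7, max_sweeps = 10000L) {
  family <- match.arg(family)
  xy <- .extract_xy(data, outcome)
  spec <- penalty_spec(family, lambda = lambda, a = a, alpha = alpha,
                       weights = if (family == "adaptive_lasso") {
                         weights %||% rep(1, ncol(xy$X))
                       })
  std <- .standardize(xy$X, xy$y)
  p <- ncol(xy$X)
  w <- spec$weights %||% rep(1, p)
  if (length(w) != p) {
    stop("`weights` must have length ", p, call. = FALSE)
  }
  beta0 <- if (is.null(init)) rep(0, p) else as.numeric(init) * std$xsd
  sol <- .cd_path(std$Xs, std$yc, lambda, family, a = spec$a,
                  alpha = spec$alpha, weights = w, beta0 = beta0,
                  tol = tol, max_sweeps = max_sweeps)
  .make_fit(sol$beta[, 1L], std, xy$names, family, lambda, spec$a,
            spec$alpha, spec$weights, nrow(xy$X), sol$n_sweeps[1L],
            sol$converged[1L] == 1L, outcome)
}

#' Ordinary least squares, optionally restricted to a support
#'
#' Exact least-squares fit with an intercept. With `support` given (indices or
#' names of covariate columns), coefficients outside the support are exactly 0
#' — this is the "oracle" estimator when `support` is the true one. With
#' `support = NULL` all covariates are used (the full model).
#'
#' @inheritParams fit_penalized
#' @param support Optional integer indices or column names of the covariates
#'   to include; `integer(0)` gives the intercept-only model.
#' @return A `pensel_fit` with `family = "ols"` and `lambda = 0`.
#' @export
fit_ols <- function(data, outcome, support = NULL) {
  xy <- .extract_xy(data, outcome)
  p <- ncol(xy$X)
  if (is.null(support)) {
    support <- seq_len(p)
  } else if (is.character(support)) {
    idx <- match(support, xy$names)
    if (anyNA(idx)) {
      stop("unknown covariate(s): ",
           paste(support[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    support <- idx
  } else {
    support <- as.integer(support)
    if (length(support) && (min(support) < 1L || max(support) > p)) {
      stop("`support` indices out of range", call. = FALSE)
    }
  }
  support <- sort(unique(support))
  n <- nrow(xy$X)
  if (length(support) >= n) stop("|support| must be < n", call. = FALSE)
  beta <- rep(0, p)
  names(beta) <- xy$names
  if (length(support) == 0L) {
    intercept <- mean(xy$y)
    rss <- sum((xy$y - intercept)^2)
  } else {
    Xm <- cbind(1, xy$X[, support, drop = FALSE])
    qrx <- qr(Xm)
    if (qrx$rank < ncol(Xm)) {
      stop("rank-deficient design on the requested support", call. = FALSE)
    }
    cf <- qr.coef(qrx, xy$y)
    intercept <- cf[1L]
    beta[support] <- cf[-1L]
    rss <- sum(qr.resid(qrx, xy$y)^2)
  }
  df <- length(support)
  structure(
    list(
      beta = beta, intercept = unname(intercept), selected = support,
      beta_std = NULL, family = "ols", lambda = 0, a = NA_real_,
      alpha = NA_real_, weights = NULL, bic = .bic(rss, n, df), rss = rss,
      df = df, n = n, p = p, n_sweeps = 0L, converged = TRUE,
      outcome = outcome, xbar = colMeans(xy$X),
      xsd = sqrt(colMeans(sweep(xy$X, 2, colMeans(xy$X))^2)),
      ybar = mean(xy$y)
    ),
    class = "pensel_fit"
  )
}

#' Two-stage adaptive LASSO
#'
#' Stage 1 fits the full ordinary least squares model to obtain pilot
#' coefficients \eqn{\tilde\beta}; stage 2 solves a weighted lasso with
#' per-coordinate weights \eqn{w_j = |\tilde\beta_j|^{-\gamma}} (computed on
#' the standardized scale, so weights are unit-invariant). A pilot
#' coefficient of exactly 0 yields an infinite weight and that coordinate is
#' excluded.
#'
#' @inheritParams fit_penalized
#' @param gamma Weight exponent, `> 0` (default 1).
#' @param ... Passed on to [fit_penalized()] (e.g. `tol`, `max_sweeps`).
#' @return A `pensel_fit` with `family = "adaptive_lasso"`.
#' @export
fit_adaptive_lasso <- function(data, outcome, lambda, gamma = 1, ...) {
  if (!is.numeric(gamma) || gamma <= 0) {
    stop("`gamma` must be > 0", call. = FALSE)
  }
  w <- adaptive_weights(data, outcome, gamma = gamma)
  fit_penalized(data, outcome, family = "adaptive_lasso", lambda = lambda,
                weights = w, ...)
}

#' Adaptive-lasso weights from a full OLS pilot fit
#'
#' @inheritParams fit_adaptive_lasso
#' @return Numeric weight vector \eqn{|\tilde\beta_j|^{-\gamma}} on the
#'   standardized scale (`Inf` where the pilot coefficient is 0).
#' @export
adaptive_weights <- function(data, outcome, gamma = 1) {
  pilot <- fit_ols(data, outcome)
  b_std <- abs(pilot$beta * pilot$xsd)  # standardized-scale magnitudes
  ifelse(b_std == 0, Inf, b_std^(-gamma))
}

#' Bidirectional stepwise regression baseline
#'
#' Classic stepwise selection: repeatedly add the candidate variable that most
#' improves the criterion, then drop any included variable whose removal
#' improves it, until no move improves. Ties are broken toward the lowest
#' column index, so the procedure is deterministic given the data. The final
#' model is refit by OLS on the chosen support.
#'
#' @inheritParams fit_penalized
#' @param criterion `"bic"` (default; BIC must strictly decrease) or
#'   `"pvalue"` (enter the most significant candidate with p < `p_enter`,
#'   remove the least significant included variable with p > `p_remove`).
#' @param p_enter,p_remove Entry/removal p-value thresholds for
#'   `criterion = "pvalue"`; requires `p_enter <= p_remove`.
#' @return A `pensel_fit` with `family = "stepwise"`; the sequence of moves is
#'   attached as attribute `"steps"` (tibble with columns `action`, `term`).
#' @export
fit_stepwise <- function(data, outcome, criterion = c("bic", "pvalue"),
                         p_enter = 0.05, p_remove = 0.10) {
  criterion <- match.arg(criterion)
  if (criterion == "pvalue" && p_enter > p_remove) {
    stop("`p_enter` must be <= `p_remove`", call. = FALSE)
  }
  xy <- .extract_xy(data, outcome)
  X <- xy$X; y <- xy$y
  n <- nrow(X); p <- ncol(X)

  rss_of <- function(supp) {
    if (length(supp) == 0L) return(sum((y - mean(y))^2))
    f <- stats::.lm.fit(cbind(1, X[, supp, drop = FALSE]), y)
    sum(f$residuals^2)
  }
  # two-sided p-value of the last column's t statistic in an OLS fit
  pval_of <- function(supp, j) {
    Xm <- cbind(1, X[, c(supp, j), drop = FALSE])
    qrx <- qr(Xm)
    if (qrx$rank < ncol(Xm)) return(1)
    cf <- qr.coef(qrx, y)
    res <- qr.resid(qrx, y)
    df_res <- n - ncol(Xm)
    s2 <- sum(res^2) / df_res
    xtxinv <- chol2inv(qr.R(qrx))
    se <- sqrt(s2 * diag(xtxinv))
    tstat <- cf[length(cf)] / se[length(se)]
    2 * pt(abs(tstat), df_res, lower.tail = FALSE)
  }

  supp <- integer(0)
  steps <- list()
  if (criterion == "bic") {
    crit <- .bic(rss_of(supp), n, 0L)
    repeat {
      moved <- FALSE
      # forward
      cand <- setdiff(seq_len(p), supp)
      if (length(cand)) {
        bics <- vapply(cand, function(j) {
          .bic(rss_of(c(supp, j)), n, length(supp) + 1L)
        }, numeric(1))
        k <- which.min(bics)
        if (bics[k] < crit - 1e-10) {
          supp <- sort(c(supp, cand[k]))
          crit <- bics[k]
          steps[[length(steps) + 1L]] <- c("add", xy$names[cand[k]])
          moved <- TRUE
        }
      }
      # backward
      repeat {
        if (length(supp) == 0L) break
        bics <- vapply(seq_along(supp), function(i) {
          .bic(rss_of(supp[-i]), n, length(supp) - 1L)
        }, numeric(1))
        k <- which.min(bics)
        if (bics[k] < crit - 1e-10) {
          steps[[length(steps) + 1L]] <- c("drop", xy$names[supp[k]])
          supp <- supp[-k]
          crit <- bics[k]
          moved <- TRUE
        } else break
      }
      if (!moved) break
    }
  } else {
    repeat {
      moved <- FALSE
      cand <- setdiff(seq_len(p), supp)
      if (length(cand)) {
        pv <- vapply(cand, function(j) pval_of(supp, j), numeric(1))
        k <- which.min(pv)
        if (pv[k] < p_enter) {
          supp <- sort(c(supp, cand[k]))
          steps[[length(steps) + 1L]] <- c("add", xy$names[cand[k]])
          moved <- TRUE
        }
      }
      repeat {
        if (length(supp) == 0L) break
        # p-value of each included variable in the current model
        pv <- vapply(seq_along(supp), function(i) {
          pval_of(supp[-i], supp[i])
        }, numeric(1))
        k <- which.max(pv)
        if (pv[k] > p_remove) {
          steps[[length(steps) + 1L]] <- c("drop", xy$names[supp[k]])
          supp <- supp[-k]
          moved <- TRUE
        } else break
      }
      if (!moved) break
    }
  }
  fit <- fit_ols(data, outcome, support = supp)
  fit$family <- "stepwise"
  attr(fit, "steps") <- tibble::tibble(
    action = vapply(steps, `[`, character(1), 1L),
    term = vapply(steps, `[`, character(1), 2L)
  )
  fit
}

# ---- pensel_fit methods -----------------------------------------------------

#' @export
print.pensel_fit <- function(x, ...) {
  cat("<pensel_fit> family =", x$family,
      if (x$family %in% c("ols", "stepwise")) "" else
        paste0(" lambda = ", signif(x$lambda, 4)),
      "\n  n =", x$n, " p =", x$p,
      " selected =", length(x$selected),
      " BIC =", round(x$bic, 2),
      if (!x$converged) " [NOT CONVERGED]" else "", "\n")
  invisible(x)
}

#' Tidy a penalized fit
#'
#' @param x A `pensel_fit`.
#' @param ... Unused.
#' @return A tibble with one row per term (intercept first): `term`,
#'   `estimate` (original covariate scale), `selected`.
#' @export
tidy.pensel_fit <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", names(x$beta)),
    estimate = c(x$intercept, unname(x$beta)),
    selected = c(NA, unname(x$beta) != 0)
  )
}

#' One-row summary of a penalized fit
#'
#' @param x A `pensel_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `family`, `lambda`, `df`, `bic`, `rss`,
#'   `n_sweeps`, `converged`.
#' @export
glance.pensel_fit <- function(x, ...) {
  tibble::tibble(
    family = x$family, lambda = x$lambda, df = x$df, bic = x$bic,
    rss = x$rss, n_sweeps = as.integer(x$n_sweeps),
    converged = isTRUE(x$converged) || x$converged == 1
  )
}

#' @export
predict.pensel_fit <- function(object, newdata, ...) {
  X <- as.matrix(as.data.frame(newdata)[names(object$beta)])
  as.numeric(X %*% object$beta + object$intercept)
}

#' @export
coef.pensel_fit <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$beta)
}

#' Selected variable names of a fit
#'
#' @param fit A `pensel_fit`.
#' @return Character vector of covariate names with nonzero coefficients.
#' @export
selected_vars <- function(fit) {
  stopifnot(inherits(fit, "pensel_fit"))
  names(fit$beta)[fit$selected]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
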