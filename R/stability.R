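# Bootstrap selection-frequency analysis (selection-stability reports).

#' Fit one variable-selection method with BIC tuning
#'
#' Dispatcher used by the bootstrap and the command-line tools: penalized
#' families are tuned along a BIC lambda path, `"stepwise"` runs the
#' bidirectional baseline, `"ols"` the full least-squares model.
#'
#' @inheritParams fit_penalized
#' @param method One of `"lasso"`, `"elastic_net"`, `"scad"`, `"mcp"`,
#'   `"adaptive_lasso"`, `"stepwise"`, `"ols"`.
#' @param ... Passed to [select_by_bic()] (`n_lambda`, `ratio`, `a`,
#'   `alpha_grid`, `gamma`, `weights`, ...).
#' @return A `pensel_fit`.
#' @export
fit_method <- function(data, outcome, method = c("lasso", "elastic_net",
                                                 "scad", "mcp",
                                                 "adaptive_lasso",
                                                 "stepwise", "ols"), ...) {
  method <- match.arg(method)
  switch(method,
    stepwise = fit_stepwise(data, outcome),
    ols = fit_ols(data, outcome),
    select_by_bic(data, outcome, family = method, ...)$best_fit
  )
}

#' Bootstrap selection frequencies for one method
#'
#' Fits `method` (with BIC tuning) on the full data to obtain the selected
#' set and coefficient signs, then draws `n_boot` with-replacement resamples
#' of the rows and refits the *entire* procedure — a fresh lambda path and
#' BIC minimization per resample by default — recording which variables are
#' selected each time. The selection frequency of variable `j` is the
#' fraction of resamples selecting it; a variable consistently reselected
#' under resampling is a stable finding. Deterministic given `seed`.
#'
#' A resample containing a constant covariate column is redrawn once and, if
#' still degenerate, skipped (counted in `attr(, "n_skipped")`).
#'
#' @inheritParams fit_method
#' @param n_boot Number of bootstrap resamples (default 100).
#' @param seed RNG seed.
#' @param retune If `FALSE`, freeze the full-data tuning (`lambda`, and
#'   `alpha` for the elastic net) instead of re-tuning per resample.
#' @param ... Passed to the underlying fitter (see [fit_method()]).
#' @return A `stability_report`: a tibble with one row per covariate —
#'   `variable`, `selected_full` (selected on the full data), `sign`
#'   (`"+"`, `"-"` or `""`, from the full-data fit, falling back to the
#'   majority bootstrap sign for variables never selected on the full
#'   data), `freq` (bootstrap selection frequency) — with attributes
#'   `method`, `n_boot`, `seed`, `n_skipped`, `full_fit` and `counts`.
#' @examples
#' d <- tibble::tibble(x1 = rnorm(80), x2 = rnorm(80))
#' d$y <- 3 * d$x1 + rnorm(80, sd = 0.3)
#' bootstrap_selection(d, "y", "lasso", n_boot = 5, seed = 1, n_lambda = 30)
#' @export
bootstrap_selection <- function(data, outcome, method, n_boot = 100L,
                                seed = 1L, retune = TRUE, ...) {
  stopifnot(n_boot >= 1L)
  data <- as.data.frame(data)
  xnames <- setdiff(names(data), outcome)
  p <- length(xnames)
  n <- nrow(data)

  full <- fit_method(data, outcome, method, ...)
  frozen <- if (!retune && !method %in% c("stepwise", "ols")) {
    list(lambda = full$lambda, alpha = full$alpha, a = full$a,
         weights = full$weights)
  }

  set.seed(seed)
  counts <- integer(p)
  sign_sum <- numeric(p)
  n_skipped <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    if (any(apply(data[idx, xnames, drop = FALSE], 2L, sd) < 1e-10)) {
      idx <- sample.int(n, n, replace = TRUE)  # one redraw
      if (any(apply(data[idx, xnames, drop = FALSE], 2L, sd) < 1e-10)) {
        n_skipped <- n_skipped + 1L
        next
      }
    }
    boot <- data[idx, , drop = FALSE]
    fit <- if (is.null(frozen)) {
      fit_method(boot, outcome, method, ...)
    } else {
      fit_penalized(boot, outcome, family = method, lambda = frozen$lambda,
                    a = if (is.na(frozen$a)) NULL else frozen$a,
                    alpha = if (is.na(frozen$alpha)) 0.5 else frozen$alpha,
                    weights = frozen$weights)
    }
    counts[fit$selected] <- counts[fit$selected] + 1L
    sign_sum[fit$selected] <- sign_sum[fit$selected] +
      sign(fit$beta[fit$selected])
  }
  n_eff <- n_boot - n_skipped
  if (n_eff < 1L) stop("all bootstrap resamples degenerate", call. = FALSE)

  full_sign <- sign(full$beta)
  sgn <- ifelse(full_sign != 0, full_sign, sign(sign_sum))
  sign_chr <- c("-", "", "+")[sgn + 2]
  sign_chr[counts == 0 & full_sign == 0] <- ""

  out <- tibble::tibble(
    variable = xnames,
    selected_full = seq_len(p) %in% full$selected,
    sign = sign_chr,
    freq = counts / n_eff
  )
  structure(out, class = c("stability_report", class(out)),
            method = method, n_boot = as.integer(n_boot),
            seed = as.integer(seed), n_skipped = n_skipped,
            counts = counts, full_fit = full)
}

#' Render a cross-method selection-stability table
#'
#' Combines one [bootstrap_selection()] report per method into a single
#' table: rows are the variables selected on the full data by at least one
#' method; each method's cell shows the coefficient sign with the bootstrap
#' selection frequency in parentheses (e.g. `"+ (0.98)"`), and is empty for
#' methods that did not select the variable. The output is a plain character
#' tibble, bit-stable for regression testing.
#'
#' @param reports A single `stability_report` or a list of them (one per
#'   method, identical variable lists).
#' @return A tibble: column `variable` plus one character column per method.
#' @export
render_selection_table <- function(reports) {
  if (inherits(reports, "stability_report")) reports <- list(reports)
  vars <- reports[[1L]]$variable
  for (r in reports) {
    if (!identical(r$variable, vars)) {
      stop("all reports must share the same variable list", call. = FALSE)
    }
  }
  methods <- vapply(reports, function(r) attr(r, "method"), character(1))
  if (anyDuplicated(methods)) {
    methods <- make.unique(methods)
  }
  keep <- Reduce(`|`, lapply(reports, function(r) r$selected_full))
  out <- tibble::tibble(variable = vars[keep])
  for (i in seq_along(reports)) {
    r <- reports[[i]]
    cell <- ifelse(r$selected_full,
                   sprintf("%s (%.2f)", r$sign, r$freq), "")
    out[[methods[i]]] <- cell[keep]
  }
  out
}

#' @export
print.stability_report <- function(x, ...) {
  cat("<stability_report> method =", attr(x, "method"),
      " n_boot =", attr(x, "n_boot"),
      " skipped =", attr(x, "n_skipped"), "\n")
  NextMethod()
}

#' Plot bootstrap selection frequencies
#'
#' @param object A `stability_report`.
#' @param min_freq Only show variables with at least this frequency
#'   (default 0.05).
#' @param ... Unused.
#' @return A ggplot of selection frequency per variable, colored by
#'   coefficient sign.
#' @export
autoplot.stability_report <- function(object, min_freq = 0.05, ...) {
  d <- dplyr::filter(tibble::as_tibble(object), .data$freq >= min_freq)
  d$variable <- stats::reorder(d$variable, d$freq)
  ggplot2::ggplot(d, ggplot2::aes(.data$freq, .data$variable,
                                  fill = .data$sign)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(
      values = stats::setNames(c("firebrick", "steelblue", "grey"),
                               c("-", "+", ""))) +
    ggplot2::labs(x = paste0("bootstrap selection frequency (",
                             attr(object, "method"), ")"),
                  y = NULL, fill = "sign") +
    ggplot2::theme_minimal()
}
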