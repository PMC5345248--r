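# Reading tabular datasets and writing fits / reports with a provenance
# header.

#' Read a covariate/outcome dataset from CSV
#'
#' Header row gives the column names; all covariate columns must be numeric
#' with no missing values and the designated outcome column must be present.
#' Malformed cells are reported with their row and column.
#'
#' @param path Path to a CSV file.
#' @param outcome Name of the outcome column (checked for presence).
#' @return A tibble.
#' @export
read_dataset <- function(path, outcome) {
  raw <- utils::read.csv(path, check.names = FALSE)
  if (!outcome %in% names(raw)) {
    stop("outcome column '", outcome, "' not found in ", path, call. = FALSE)
  }
  for (cn in names(raw)) {
    col <- raw[[cn]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad)) {
        stop("non-numeric cell at row ", bad[1L], ", column '", cn, "'",
             call. = FALSE)
      }
      raw[[cn]] <- num
    }
    if (anyNA(raw[[cn]])) {
      stop("missing value at row ", which(is.na(raw[[cn]]))[1L],
           ", column '", cn, "'", call. = FALSE)
    }
  }
  tibble::as_tibble(raw)
}

# provenance header lines written as CSV comments
.provenance <- function(config_desc, seed = NULL) {
  c(paste0("# pensel ", as.character(utils::packageVersion("pensel"))),
    paste0("# config: ", config_desc),
    if (!is.null(seed)) paste0("# seed: ", seed))
}

#' Write a fitted model to CSV and/or JSON
#'
#' The CSV holds one row per covariate (`name`, `coefficient`, `selected`),
#' preceded by a provenance comment header; the JSON holds the full fit
#' record (coefficients, intercept, lambda, BIC, convergence).
#'
#' @param fit A `pensel_fit`.
#' @param csv,json Output paths (either may be `NULL` to skip).
#' @param seed Optional seed to record in the provenance header.
#' @return `fit`, invisibly.
#' @export
write_fit <- function(fit, csv = NULL, json = NULL, seed = NULL) {
  stopifnot(inherits(fit, "pensel_fit"))
  if (!is.null(csv)) {
    hdr <- .provenance(paste0("fit family=", fit$family, " lambda=",
                              signif(fit$lambda, 8), " outcome=",
                              fit$outcome), seed)
    tbl <- tibble::tibble(name = names(fit$beta),
                          coefficient = unname(fit$beta),
                          selected = unname(fit$beta) != 0)
    writeLines(c(hdr, readr::format_csv(tbl)), csv)
  }
  if (!is.null(json)) {
    rec <- list(family = fit$family, outcome = fit$outcome,
                intercept = fit$intercept, coefficients = as.list(fit$beta),
                selected = names(fit$beta)[fit$selected],
                lambda = fit$lambda, alpha = fit$alpha, a = fit$a,
                bic = fit$bic, rss = fit$rss, df = fit$df, n = fit$n,
                p = fit$p, n_sweeps = fit$n_sweeps,
                converged = isTRUE(fit$converged) || fit$converged == 1)
    jsonlite::write_json(rec, json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(fit)
}

#' Write a simulation-study summary to CSV
#'
#' Columns `rho`, `snr`, `method`, `mrme`, `tp`, `fp`, `n_fail`, preceded by
#' a provenance comment header echoing the configuration and seed.
#'
#' @param study A `pensel_study` from [run_study()].
#' @param path Output CSV path.
#' @param digits Rounding for the summary columns (default `NULL`: full
#'   precision).
#' @return `study`, invisibly.
#' @export
write_study <- function(study, path, digits = NULL) {
  stopifnot(inherits(study, "pensel_study"))
  cfg <- study$config
  hdr <- .provenance(
    paste0("simulate n=", cfg$n, " p=", cfg$p, " block=",
           cfg$corr_block_size, " rho=", paste(cfg$rho, collapse = "/"),
           " snr=", paste(cfg$snr, collapse = "/"), " reps=", cfg$n_reps,
           " methods=", paste(cfg$methods, collapse = ",")),
    cfg$seed
  )
  tbl <- study$summary
  if (!is.null(digits)) {
    tbl <- dplyr::mutate(tbl, dplyr::across(c("mrme", "tp", "fp"),
                                            ~ round(.x, digits)))
  }
  writeLines(c(hdr, readr::format_csv(tbl)), path)
  invisible(study)
}

#' Write a stability report (tidy CSV + formatted table)
#'
#' @param reports A `stability_report` or list of them.
#' @param csv Path for the tidy CSV (`method`, `variable`, `sign`, `freq`);
#'   `NULL` to skip.
#' @param table Path for the rendered selection table
#'   ([render_selection_table()]); `NULL` to skip.
#' @param seed Optional seed for the provenance header.
#' @return The rendered table, invisibly.
#' @export
write_stability <- function(reports, csv = NULL, table = NULL, seed = NULL) {
  if (inherits(reports, "stability_report")) reports <- list(reports)
  methods <- vapply(reports, function(r) attr(r, "method"), character(1))
  if (!is.null(csv)) {
    tidy_tbl <- purrr::map2_dfr(reports, methods, function(r, m) {
      tibble::tibble(method = m, variable = r$variable, sign = r$sign,
                     freq = r$freq)
    })
    hdr <- .provenance(paste0("stability methods=",
                              paste(methods, collapse = ","), " n_boot=",
                              attr(reports[[1L]], "n_boot")), seed)
    writeLines(c(hdr, readr::format_csv(tidy_tbl)), csv)
  }
  rendered <- render_selection_table(reports)
  if (!is.null(table)) {
    hdr <- .provenance(paste0("selection table methods=",
                              paste(methods, collapse = ",")), seed)
    writeLines(c(hdr, readr::format_csv(rendered)), table)
  }
  invisible(rendered)
}

#' Write a synthetic cohort to CSV
#'
#' @param cohort A tibble from [generate_cohort()].
#' @param path Output CSV path.
#' @return `cohort`, invisibly. The file has no provenance header so it can
#'   be read back directly by [read_dataset()].
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(as.data.frame(cohort), path)
  invisible(cohort)
}
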