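#' Goodness-of-fit statistics for model validation
#'
#' The formula-defined validation battery comparing experimental values
#' `x_exp` with model predictions `x_pre`:
#'
#' * `sse()` — sum of squared errors, `sum((pre - exp)^2)`.
#' * `rmse()` — root mean square error, `sqrt(sse / N)`.
#' * `chi_square()` — reduced chi-square, `sse / (N - n_constants)`.
#' * `mbe()` — mean bias error, `mean(pre - exp)` (signed).
#' * `mpe()` — mean percentage error, `100 * mean((pre - exp) / exp)`
#'   (signed, in percent).
#' * `aard()` — absolute average relative deviation,
#'   `100 * mean(abs(exp - pre) / exp)`, reported in percent.
#' * `r_squared()` — coefficient of determination,
#'   `1 - sse / sum((exp - mean(exp))^2)`.
#'
#' `n_constants` defaults to 2, the value implied by the published
#' goodness-of-fit table itself (its SSE-to-chi-square ratios equal
#' `N - 2 = 13` for the 15-run campaign).
#'
#' @param x_exp,x_pre Equal-length numeric vectors of experimental and
#'   predicted values.
#' @param n_constants The `n` subtracted from `N` in the reduced chi-square
#'   denominator.
#' @return A single numeric value.
#' @examples
#' rmse(c(1, 2, 3), c(1.1, 1.9, 3.2))
#' @name fit_statistics
NULL

check_metric_input <- function(x_exp, x_pre, relative = FALSE) {
  if (length(x_exp) != length(x_pre)) {
    abort(sprintf("length mismatch: %d experimental vs %d predicted",
                  length(x_exp), length(x_pre)))
  }
  if (length(x_exp) < 1) abort("need at least one observation")
  if (relative && any(x_exp == 0)) {
    abort(sprintf("experimental value is zero at index %d; relative metrics undefined",
                  which(x_exp == 0)[1]))
  }
  invisible(NULL)
}

#' @rdname fit_statistics
#' @export
sse <- function(x_exp, x_pre) {
  check_metric_input(x_exp, x_pre)
  sum((x_pre - x_exp)^2)
}

#' @rdname fit_statistics
#' @export
rmse <- function(x_exp, x_pre) {
  sqrt(sse(x_exp, x_pre) / length(x_exp))
}

#' @rdname fit_statistics
#' @export
chi_square <- function(x_exp, x_pre, n_constants = 2) {
  check_metric_input(x_exp, x_pre)
  if (length(x_exp) <= n_constants) {
    abort(sprintf("N = %d must exceed n_constants = %d",
                  length(x_exp), n_constants))
  }
  sse(x_exp, x_pre) / (length(x_exp) - n_constants)
}

#' @rdname fit_statistics
#' @export
mbe <- function(x_exp, x_pre) {
  check_metric_input(x_exp, x_pre)
  mean(x_pre - x_exp)
}

#' @rdname fit_statistics
#' @export
mpe <- function(x_exp, x_pre) {
  check_metric_input(x_exp, x_pre, relative = TRUE)
  100 * mean((x_pre - x_exp) / x_exp)
}

#' @rdname fit_statistics
#' @export
aard <- function(x_exp, x_pre) {
  check_metric_input(x_exp, x_pre, relative = TRUE)
  100 * mean(abs(x_exp - x_pre) / x_exp)
}

#' @rdname fit_statistics
#' @export
r_squared <- function(x_exp, x_pre) {
  check_metric_input(x_exp, x_pre)
  ss_tot <- sum((x_exp - mean(x_exp))^2)
  if (ss_tot == 0) abort("experimental values are constant; r-squared undefined")
  1 - sse(x_exp, x_pre) / ss_tot
}

#' Per-response validation report
#'
#' Applies the full validation battery (see [fit_statistics]) column by
#' column to matching experimental and predicted response tables.
#'
#' @param x_exp,x_pre Samples x responses matrices, wide data frames, or
#'   long response tibbles with matching response sets.
#' @param n_constants Passed to [chi_square()].
#' @return A tibble with one row per response and columns `response`,
#'   `n_obs`, `chi2`, `rmse`, `mbe`, `mpe`, `sse`, `aard`, `r2`.
#' @export
fit_report <- function(x_exp, x_pre, n_constants = 2) {
  me <- response_matrix(x_exp)
  mp <- response_matrix(x_pre, outputs = colnames(me))
  if (!identical(dim(me), dim(mp))) {
    abort("experimental and predicted tables have different shapes")
  }
  purrr::map_dfr(colnames(me), function(resp) {
    e <- me[, resp]; p <- mp[, resp]
    tibble(response = resp, n_obs = length(e),
           chi2 = chi_square(e, p, n_constants),
           rmse = rmse(e, p), mbe = mbe(e, p), mpe = mpe(e, p),
           sse = sse(e, p), aard = aard(e, p), r2 = r_squared(e, p))
  })
}

#' Pearson correlation with significance
#'
#' Product-moment correlation between two response vectors, with the
#' two-sided p-value from the t transform on `length - 2` degrees of
#' freedom (via [stats::cor.test()]).
#'
#' @param x,y Equal-length numeric vectors (at least 3 values).
#' @return `pearson_r()` returns the correlation; `pearson_test()` a tibble
#'   with columns `r`, `p_value`, `df`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3) abort("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0) abort("correlation undefined for constant input")
  cor(x, y)
}

#' @rdname pearson_r
#' @export
pearson_test <- function(x, y) {
  r <- pearson_r(x, y)
  ht <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble(r = unname(r), p_value = ht$p.value, df = unname(ht$parameter))
}

#' Bundled published goodness-of-fit table
#'
#' The published per-response validation statistics for the three surrogate
#' models, as printed (three decimals). Used by the self-consistency checks
#' that pin down the reduced chi-square's `n_constants = 2` reading.
#'
#' @return A tibble with columns `response`, `chi2`, `rmse`, `mbe`, `mpe`,
#'   `sse`, `aard`, `r2`.
#' @export
published_fit_table <- function() {
  readr::read_csv(path_fixture("goodness_of_fit.csv"), show_col_types = FALSE)
}
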