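#' Fit a reversible column scaler
#'
#' Records per-column scaling parameters for later application and exact
#' inversion. Two kinds are supported: `"minmax"` maps each column's observed
#' range onto a target interval, and `"zscore"` centres to mean 0 and scales
#' to unit standard deviation. Scaled values falling outside the fitted range
#' are extrapolated linearly, never clipped, so optimizers may probe the
#' edges of (and slightly beyond) the fitted box.
#'
#' Constant columns are recorded with zero spread: min-max maps them to the
#' midpoint of the target interval, z-scoring maps them to 0 (with a
#' warning), and both invert back to the constant.
#'
#' @param x Numeric matrix or data frame of numeric columns.
#' @param kind `"minmax"` or `"zscore"`.
#' @param range Target interval `c(lo, hi)` for min-max scaling.
#' @param sd_convention For z-scoring: `"sample"` (n-1 denominator, default)
#'   or `"population"`.
#' @return A `scaler_spec` object.
#' @examples
#' sc <- fit_scaler(cbind(time = c(10, 20, 30)), "minmax", c(0, 1))
#' scaler_apply(sc, cbind(time = c(10, 20, 30)))
#' @export
fit_scaler <- function(x, kind = c("minmax", "zscore"), range = c(0, 1),
                       sd_convention = c("sample", "population")) {
  kind <- match.arg(kind)
  sd_convention <- match.arg(sd_convention)
  m <- as.matrix(x)
  if (nrow(m) == 0) abort("cannot fit a scaler to an empty matrix")
  storage.mode(m) <- "double"
  if (kind == "minmax" && range[2] <= range[1]) {
    abort("target interval must satisfy hi > lo")
  }
  spec <- list(
    kind = kind,
    columns = colnames(m) %||% paste0("V", seq_len(ncol(m))),
    lo = range[1], hi = range[2],
    min = apply(m, 2, min), max = apply(m, 2, max),
    mean = colMeans(m), sd = col_sd(m, sd_convention),
    sd_convention = sd_convention)
  if (kind == "zscore" && any(spec$sd == 0)) {
    warn("constant column(s) in z-score scaler; mapped to 0")
  }
  structure(spec, class = "scaler_spec")
}

# Per-column affine coefficients: scaled = a * x + b
scaler_coef <- function(spec) {
  if (spec$kind == "minmax") {
    span <- spec$max - spec$min
    a <- ifelse(span > 0, (spec$hi - spec$lo) / span, 0)
    b <- ifelse(span > 0, spec$lo - a * spec$min, (spec$lo + spec$hi) / 2)
  } else {
    a <- ifelse(spec$sd > 0, 1 / spec$sd, 0)
    b <- ifelse(spec$sd > 0, -spec$mean / spec$sd, 0)
  }
  list(a = a, b = b)
}

check_scaler_input <- function(spec, x) {
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  if (ncol(m) != length(spec$columns)) {
    abort(sprintf("scaler expects %d column(s), got %d",
                  length(spec$columns), ncol(m)))
  }
  m
}

#' Apply or invert a fitted scaler
#'
#' @param spec A `scaler_spec` from [fit_scaler()].
#' @param x Matrix (or data frame) with the same columns the scaler was
#'   fitted on.
#' @return A numeric matrix of the same shape.
#' @export
scaler_apply <- function(spec, x) {
  m <- check_scaler_input(spec, x)
  cf <- scaler_coef(spec)
  sweep(sweep(m, 2, cf$a, "*"), 2, cf$b, "+")
}

#' @rdname scaler_apply
#' @export
scaler_invert <- function(spec, x) {
  m <- check_scaler_input(spec, x)
  cf <- scaler_coef(spec)
  out <- sweep(m, 2, cf$b, "-")
  a <- ifelse(cf$a == 0, 1, cf$a)
  out <- sweep(out, 2, a, "/")
  # constant columns carry no information in scaled space; restore the value
  const <- which(cf$a == 0)
  centre <- if (spec$kind == "minmax") spec$min else spec$mean
  for (j in const) out[, j] <- centre[j]
  out
}

#' @export
print.scaler_spec <- function(x, ...) {
  tgt <- if (x$kind == "minmax") sprintf(" -> [%g, %g]", x$lo, x$hi)
         else sprintf(" (%s SD)", x$sd_convention)
  cat(sprintf("%s scaler%s over %d column(s): %s\n", x$kind, tgt,
              length(x$columns), paste(x$columns, collapse = ", ")))
  invisible(x)
}

# Serialize for model bundles.
scaler_to_list <- function(spec) unclass(spec)
scaler_from_list <- function(l) structure(l, class = "scaler_spec")
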