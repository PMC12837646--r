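#' Quadratic response-surface specification for synthetic campaigns
#'
#' A synthetic stand-in for a real extraction campaign: each response is a
#' full quadratic in the three process factors (intercept, linear, pure
#' quadratic, and pairwise interaction terms) plus independent Gaussian
#' replicate noise. The quadratic-with-interactions family is the simplest
#' one exhibiting an interior optimum like the bundled campaign's, and a
#' single-hidden-layer perceptron can approximate it closely — which is what
#' makes end-to-end parameter-recovery tests possible.
#'
#' `surface_spec()` builds a specification from an explicit coefficient
#' table; [default_surface_spec()] calibrates one against the bundled
#' campaign by least squares, so simulated response ranges match the
#' measured ranges by construction.
#'
#' @param coefficients Tibble with columns `response`, `term`, `value`;
#'   terms are `intercept`, `time`, `temperature`, `ratio`, `time2`,
#'   `temperature2`, `ratio2`, `time:temperature`, `time:ratio`,
#'   `temperature:ratio` (missing terms default to 0).
#' @param noise_sd Named numeric vector of replicate standard deviations per
#'   response (response units); non-negative.
#' @return An object of class `surface_spec`.
#' @export
surface_spec <- function(coefficients, noise_sd) {
  responses <- unique(coefficients$response)
  if (any(noise_sd < 0)) abort("noise_sd must be non-negative")
  if (is.null(names(noise_sd))) {
    if (length(noise_sd) == 1) {
      noise_sd <- setNames(rep(noise_sd, length(responses)), responses)
    } else abort("noise_sd must be named by response")
  }
  missing <- setdiff(responses, names(noise_sd))
  if (length(missing)) {
    abort(paste0("noise_sd missing for: ", paste(missing, collapse = ", ")))
  }
  bad <- setdiff(unique(coefficients$term), surface_terms())
  if (length(bad)) {
    abort(paste0("unknown surface term(s): ", paste(bad, collapse = ", ")))
  }
  structure(list(coefficients = as_tibble(coefficients),
                 noise_sd = noise_sd[responses],
                 responses = responses),
            class = "surface_spec")
}

surface_terms <- function() {
  c("intercept", "time", "temperature", "ratio",
    "time2", "temperature2", "ratio2",
    "time:temperature", "time:ratio", "temperature:ratio")
}

surface_design_matrix <- function(design) {
  m <- factor_matrix(design)
  t_ <- m[, "time"]; te <- m[, "temperature"]; r <- m[, "ratio"]
  cbind(intercept = 1, time = t_, temperature = te, ratio = r,
        time2 = t_^2, temperature2 = te^2, ratio2 = r^2,
        `time:temperature` = t_ * te, `time:ratio` = t_ * r,
        `temperature:ratio` = te * r)
}

#' Calibrated default surface specification
#'
#' Fits the quadratic surface of [surface_spec()] to the bundled campaign's
#' response means by least squares (one fit per response) and sets each
#' response's replicate noise to the median of its printed replicate SDs.
#' The calibration is deterministic and recomputed at call time from the
#' bundled fixtures.
#'
#' @param responses Response names to include (default: all 13).
#' @return A `surface_spec`.
#' @examples
#' spec <- default_surface_spec("TPC")
#' true_optimum(spec, step = c(time = 1, temperature = 2.5, ratio = 0.5))
#' @export
default_surface_spec <- function(responses = response_names()) {
  design <- load_design("pomace")
  resp <- load_responses("pomace")
  resp <- resp[resp$response %in% responses, ]
  M <- surface_design_matrix(design)
  Y <- response_matrix(resp, outputs = responses)
  coefs <- purrr::map_dfr(responses, function(r) {
    beta <- qr.coef(qr(M), Y[, r])
    # affine recalibration: a quadratic stays quadratic under a*f + b, so
    # rescale the fitted surface to span exactly the measured range over the
    # campaign design (least squares alone flattens the best run's spike)
    v <- as.vector(M %*% beta)
    a <- (max(Y[, r]) - min(Y[, r])) / (max(v) - min(v))
    beta <- beta * a
    beta["intercept"] <- beta["intercept"] + min(Y[, r]) - a * min(v)
    tibble(response = r, term = colnames(M), value = unname(beta))
  })
  noise <- resp |>
    dplyr::group_by(.data$response) |>
    dplyr::summarise(sd = stats::median(.data$sd), .groups = "drop")
  surface_spec(coefs, setNames(noise$sd, noise$response)[responses])
}

#' Evaluate the noiseless surface
#'
#' @param spec A `surface_spec`.
#' @param design Design tibble or matrix of factor settings.
#' @return Matrix, samples x responses.
#' @export
eval_surface <- function(spec, design) {
  M <- surface_design_matrix(design)
  out <- purrr::map(spec$responses, function(r) {
    cf <- spec$coefficients[spec$coefficients$response == r, ]
    beta <- setNames(rep(0, ncol(M)), colnames(M))
    beta[cf$term] <- cf$value
    as.vector(M %*% beta)
  })
  m <- do.call(cbind, out)
  colnames(m) <- spec$responses
  m
}

#' Generate an extraction design
#'
#' Either the full-factorial enumeration of the supplied factor levels, or
#' (with `replicate_campaign = TRUE`) the bundled 15-run campaign design.
#'
#' @param levels Named list of numeric levels per factor (`time`,
#'   `temperature`, `ratio`).
#' @param replicate_campaign Return the bundled design instead.
#' @return A design tibble (`sample_id`, `time`, `temperature`, `ratio`).
#' @examples
#' nrow(generate_design(list(time = c(10, 20, 30), temperature = c(25, 50, 75),
#'                           ratio = c(10, 15, 20))))  # 27
#' @export
generate_design <- function(levels = NULL, replicate_campaign = FALSE) {
  if (replicate_campaign) return(load_design("pomace"))
  if (is.null(levels) || any(!FACTOR_NAMES %in% names(levels))) {
    abort("levels must name time, temperature and ratio")
  }
  if (any(lengths(levels[FACTOR_NAMES]) == 0)) {
    abort("each factor needs at least one level")
  }
  grid <- tidyr::expand_grid(time = sort(levels$time),
                             temperature = sort(levels$temperature),
                             ratio = sort(levels$ratio))
  dplyr::bind_cols(tibble(sample_id = seq_len(nrow(grid))), grid)
}

#' Simulate a response campaign from a surface specification
#'
#' For each design point and response, draws `n_replicates` noisy surface
#' evaluations (Gaussian, independent across responses, SD from the spec)
#' and records their mean and sample SD — the same summary that a triplicate
#' wet-lab campaign reports. A fixed seed reproduces the campaign exactly.
#'
#' @param design Design tibble from [generate_design()] / [load_design()].
#' @param spec A `surface_spec`.
#' @param n_replicates Replicates per design point (>= 1).
#' @param seed Integer seed.
#' @return A long response tibble (`sample_id`, `response`, `mean`, `sd`,
#'   `unit`) compatible with every downstream analysis.
#' @export
simulate_responses <- function(design, spec, n_replicates = 3, seed = 1) {
  if (nrow(design) == 0) abort("design is empty")
  if (n_replicates < 1) abort("n_replicates must be >= 1")
  truth <- eval_surface(spec, design)
  units <- response_units()
  with_seed(seed, {
    out <- purrr::map_dfr(seq_along(spec$responses), function(j) {
      r <- spec$responses[j]
      reps <- matrix(rnorm(nrow(truth) * n_replicates, mean = truth[, j],
                           sd = spec$noise_sd[r]),
                     nrow(truth), n_replicates)
      tibble(sample_id = design$sample_id,
             response = r,
             mean = rowMeans(reps),
             sd = if (n_replicates > 1) apply(reps, 1, sd) else 0,
             unit = unname(units[r]))
    })
    dplyr::arrange(out, .data$sample_id)
  })
}

#' True optimum of a noiseless surface
#'
#' Grid-search oracle: the argmax of the noiseless surface for one response
#' over a dense grid of the factor box. Ties are broken lexicographically by
#' lowest time, then temperature, then ratio.
#'
#' @param spec A `surface_spec`.
#' @param response Response to optimize (default: the spec's single
#'   response).
#' @param bounds Named list `c(lo, hi)` per factor; default is the bundled
#'   design box (time 10-30 min, temperature 25-75 C, ratio 10-20 mL/g).
#' @param step Grid step per factor (single value or named vector).
#' @return A one-row tibble with `time`, `temperature`, `ratio` and the
#'   response value at the optimum.
#' @export
true_optimum <- function(spec, response = NULL,
                         bounds = list(time = c(10, 30),
                                       temperature = c(25, 75),
                                       ratio = c(10, 20)),
                         step = 1) {
  response <- response %||% spec$responses[1]
  if (length(step) == 1) step <- setNames(rep(step, 3), FACTOR_NAMES)
  if (any(step[FACTOR_NAMES] <= 0)) abort("grid step must be positive")
  axes <- purrr::map(FACTOR_NAMES,
                     function(f) seq(bounds[[f]][1], bounds[[f]][2],
                                     by = step[[f]]))
  names(axes) <- FACTOR_NAMES
  grid <- tidyr::expand_grid(!!!axes)
  grid <- dplyr::arrange(grid, .data$time, .data$temperature, .data$ratio)
  vals <- eval_surface(surface_subset(spec, response), grid)[, 1]
  best <- which.max(vals)   # first max = lowest (time, temperature, ratio)
  out <- grid[best, ]
  out[[response]] <- vals[best]
  out
}

surface_subset <- function(spec, response) {
  if (!response %in% spec$responses) {
    abort(paste0("spec has no response named ", response))
  }
  surface_spec(spec$coefficients[spec$coefficients$response == response, ],
               spec$noise_sd[response])
}

#' @export
print.surface_spec <- function(x, ...) {
  cat(sprintf("quadratic surface spec for %d response(s): %s\n",
              length(x$responses), paste(x$responses, collapse = ", ")))
  invisible(x)
}
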