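#' Non-dominated (Pareto) filtering
#'
#' Exact dominance filtering of a candidate table: a candidate dominates
#' another if it is at least as good in every objective (after orienting by
#' `senses`) and strictly better in at least one. Ties (identical objective
#' vectors) do not dominate each other, so duplicated candidates leave the
#' front unchanged as a set. If the front exceeds `cap`, it is thinned by
#' crowding distance, always keeping the extremes of every objective.
#'
#' @param data Data frame of candidates (decision variables plus objectives).
#' @param objectives Names of the objective columns (default: all numeric
#'   columns not named `time`, `temperature`, `ratio`, `sample_id`).
#' @param senses Named character vector of `"max"` / `"min"` per objective;
#'   a single unnamed value recycles. Default: maximize everything.
#' @param cap Optional maximum front size.
#' @return The non-dominated rows of `data` (a tibble).
#' @examples
#' pts <- tibble::tibble(a = c(1, 2, 0.5, 0.9), b = c(1, 0.5, 2, 0.9))
#' pareto_front(pts, objectives = c("a", "b"))
#' @export
pareto_front <- function(data, objectives = NULL, senses = NULL, cap = NULL) {
  if (nrow(data) == 0) abort("candidate set is empty")
  objectives <- objectives %||%
    setdiff(names(data)[purrr::map_lgl(data, is.numeric)],
            c(FACTOR_NAMES, "sample_id"))
  obj <- as.matrix(data[objectives])
  obj <- orient_objectives(obj, senses)   # larger is better everywhere
  keep <- !purrr::map_lgl(seq_len(nrow(obj)), function(i) {
    dominated_by_any(obj[i, ], obj)
  })
  front <- data[keep, , drop = FALSE]
  if (!is.null(cap) && nrow(front) > cap) {
    cd <- crowding_distance(obj[keep, , drop = FALSE])
    front <- front[order(cd, decreasing = TRUE)[seq_len(cap)], ]
  }
  as_tibble(front)
}

orient_objectives <- function(obj, senses) {
  if (is.null(senses)) return(obj)
  if (is.null(names(senses)) && length(senses) == 1) {
    senses <- setNames(rep(senses, ncol(obj)), colnames(obj))
  }
  for (nm in names(senses)) {
    if (!nm %in% colnames(obj)) abort(paste0("no objective named ", nm))
    if (senses[[nm]] == "min") obj[, nm] <- -obj[, nm]
  }
  obj
}

# TRUE if v is strictly dominated by any row of m (maximization).
dominated_by_any <- function(v, m) {
  ge <- m >= matrix(v, nrow(m), length(v), byrow = TRUE)
  gt <- m > matrix(v, nrow(m), length(v), byrow = TRUE)
  any(rowSums(ge) == length(v) & rowSums(gt) > 0)
}

# NSGA-II crowding distance; extremes get Inf.
crowding_distance <- function(obj) {
  n <- nrow(obj)
  if (n <= 2) return(rep(Inf, n))
  d <- numeric(n)
  for (j in seq_len(ncol(obj))) {
    o <- order(obj[, j])
    span <- obj[o[n], j] - obj[o[1], j]
    d[o[c(1, n)]] <- Inf
    if (span > 0) {
      d[o[2:(n - 1)]] <- d[o[2:(n - 1)]] +
        (obj[o[3:n], j] - obj[o[1:(n - 2)], j]) / span
    }
  }
  d
}

# Fast-enough non-dominated sorting: returns integer front rank per row.
nondominated_rank <- function(obj) {
  n <- nrow(obj)
  if (ncol(obj) == 1) {           # single objective: fronts are value ties
    return(match(-obj[, 1], sort(unique(-obj[, 1]))))
  }
  rank <- integer(n)
  remaining <- seq_len(n)
  level <- 0L
  while (length(remaining)) {
    level <- level + 1L
    sub <- obj[remaining, , drop = FALSE]
    nd <- !purrr::map_lgl(seq_len(nrow(sub)), function(i) {
      dominated_by_any(sub[i, ], sub)
    })
    rank[remaining[nd]] <- level
    remaining <- remaining[!nd]
  }
  rank
}

#' Multi-objective genetic-algorithm optimization over surrogates
#'
#' NSGA-II style elitist genetic algorithm over the three process factors:
#' simulated binary crossover, polynomial mutation, binary tournament
#' selection on (front rank, crowding distance), and truncation of the
#' combined parent + offspring population. All surrogate outputs are treated
#' as objectives (oriented by `senses`). The run stops when the front's
#' objective set has not changed for `stall` consecutive generations, or at
#' `generations`; the generation counts published for this campaign (88, 69,
#' 84) are outcomes of such a convergence rule, not inputs.
#'
#' @param surrogates A fitted surrogate (`uae_mlp` / `published_mlp`) or a
#'   list of them; their outputs together form the objective set.
#' @param bounds Named list of `c(lo, hi)` per factor; default is the box the
#'   first surrogate was trained on.
#' @param senses As in [pareto_front()]; default maximizes every output.
#' @param population Population size.
#' @param front_cap Maximum number of points returned on the front.
#' @param generations Hard generation cap.
#' @param stall Generations without front change that trigger convergence.
#' @param seed Integer seed; the run is fully reproducible.
#' @return A tibble of class `uae_pareto`: factor settings plus predicted
#'   objectives for each front member, with attributes `generations`,
#'   `population`, `front_cap`.
#' @export
ga_optimize <- function(surrogates, bounds = NULL, senses = NULL,
                        population = 100, front_cap = 50,
                        generations = 200, stall = 20, seed = 1) {
  if (population < 4) abort("population must be at least 4")
  if (inherits(surrogates, c("uae_mlp", "published_mlp"))) {
    surrogates <- list(surrogates)
  }
  outputs <- unlist(purrr::map(surrogates, "outputs"))
  if (anyDuplicated(outputs)) abort("surrogates predict overlapping responses")
  if (!is.null(senses) && !is.null(names(senses))) {
    missing <- setdiff(names(senses), outputs)
    if (length(missing)) {
      abort(paste0("no surrogate predicts objective(s): ",
                   paste(missing, collapse = ", ")))
    }
  }
  sc <- surrogates[[1]]$input_scaler
  lo <- sc$min; hi <- sc$max
  if (!is.null(bounds)) {
    bounds <- bounds[sc$columns]
    lo <- purrr::map_dbl(bounds, 1); hi <- purrr::map_dbl(bounds, 2)
  }
  if (any(hi <= lo)) abort("invalid factor bounds")
  nv <- length(lo)

  evaluate <- function(X) {
    colnames(X) <- sc$columns
    grid <- as_tibble(X)
    preds <- purrr::map(surrogates, function(s) predict(s, grid))
    as.matrix(dplyr::bind_cols(preds))
  }

  with_seed(seed, {
    P <- matrix(runif(population * nv, rep(lo, each = population),
                      rep(hi, each = population)), population, nv)
    objP <- evaluate(P)
    gen <- 0L
    stalled <- 0L
    front_sig <- ""
    while (gen < generations && stalled < stall) {
      gen <- gen + 1L
      oriented <- orient_objectives(objP, senses)
      rk <- nondominated_rank(oriented)
      cd <- crowding_distance(oriented)
      # binary tournament on (rank, crowding)
      pick <- function() {
        i <- sample.int(population, 2)
        if (rk[i[1]] < rk[i[2]]) i[1]
        else if (rk[i[2]] < rk[i[1]]) i[2]
        else if (cd[i[1]] >= cd[i[2]]) i[1] else i[2]
      }
      Q <- matrix(0, population, nv)
      for (k in seq(1, population, by = 2)) {
        pair <- sbx_crossover(P[pick(), ], P[pick(), ], lo, hi)
        Q[k, ] <- poly_mutation(pair[[1]], lo, hi)
        if (k + 1 <= population) Q[k + 1, ] <- poly_mutation(pair[[2]], lo, hi)
      }
      objQ <- evaluate(Q)
      R <- rbind(P, Q); objR <- rbind(objP, objQ)
      orientedR <- orient_objectives(objR, senses)
      rkR <- nondominated_rank(orientedR)
      cdR <- crowding_distance(orientedR)
      keep <- order(rkR, -cdR)[seq_len(population)]
      P <- R[keep, , drop = FALSE]; objP <- objR[keep, , drop = FALSE]
      # convergence: front objective set stable
      fr <- orient_objectives(objP, senses)
      nd <- nondominated_rank(fr) == 1L
      sig <- paste(sort(apply(round(objP[nd, , drop = FALSE], 6), 1,
                              paste, collapse = ",")), collapse = ";")
      if (identical(sig, front_sig)) stalled <- stalled + 1L
      else { stalled <- 0L; front_sig <- sig }
    }
    colnames(P) <- sc$columns
    cand <- dplyr::bind_cols(as_tibble(P), as_tibble(objP))
    front <- pareto_front(cand, objectives = colnames(objP),
                          senses = senses, cap = front_cap)
    front <- dplyr::distinct(front)
    attr(front, "generations") <- gen
    attr(front, "population") <- population
    attr(front, "front_cap") <- front_cap
    class(front) <- c("uae_pareto", class(front))
    front
  })
}

# Simulated binary crossover (eta_c = 15, p = 0.9), per-variable.
sbx_crossover <- function(a, b, lo, hi, eta = 15, p = 0.9) {
  c1 <- a; c2 <- b
  if (runif(1) < p) {
    for (j in seq_along(a)) {
      if (runif(1) < 0.5 && abs(a[j] - b[j]) > 1e-14) {
        u <- runif(1)
        beta <- if (u <= 0.5) (2 * u)^(1 / (eta + 1))
                else (1 / (2 * (1 - u)))^(1 / (eta + 1))
        c1[j] <- 0.5 * ((1 + beta) * a[j] + (1 - beta) * b[j])
        c2[j] <- 0.5 * ((1 - beta) * a[j] + (1 + beta) * b[j])
      }
    }
  }
  list(pmin(pmax(c1, lo), hi), pmin(pmax(c2, lo), hi))
}

# Polynomial mutation (eta_m = 20, per-variable rate 1/nv).
poly_mutation <- function(x, lo, hi, eta = 20) {
  for (j in seq_along(x)) {
    if (runif(1) < 1 / length(x)) {
      u <- runif(1)
      delta <- if (u < 0.5) (2 * u)^(1 / (eta + 1)) - 1
               else 1 - (2 * (1 - u))^(1 / (eta + 1))
      x[j] <- x[j] + delta * (hi[j] - lo[j])
    }
  }
  pmin(pmax(x, lo), hi)
}

#' Standard-score ranking of extraction conditions
#'
#' Combines the thirteen responses into a single per-sample score and ranks
#' the samples. Two scoring conventions are available:
#'
#' * `method = "minmax"` (default): each response is rescaled to the unit
#'   interval over the samples (`(x - min) / (max - min)`), oriented by
#'   `senses`, and averaged — the combined "standard score" used in the
#'   original analysis of the bundled campaign.
#' * `method = "zscore"`: classic standard scores
#'   `(x - mean) / sd` per response (sample or population SD per
#'   `sd_convention`), oriented and averaged.
#'
#' Both conventions rank the bundled campaign identically, with sample 6
#' first. Responses with zero variance contribute 0 with a warning.
#'
#' @param responses Long response tibble (or wide table) of sample means.
#' @param senses Named `"max"` / `"min"` per response (default: all
#'   maximize — higher bioactivity is better).
#' @param method Scoring convention, see above.
#' @param sd_convention SD denominator for `method = "zscore"`.
#' @return A tibble of class `uae_zscore` with columns `sample_id`,
#'   `mean_score`, `rank`, and the per-response score matrix in attribute
#'   `"scores"` (long tibble).
#' @examples
#' zscore_rank(load_responses())
#' @export
zscore_rank <- function(responses, senses = NULL,
                        method = c("minmax", "zscore"),
                        sd_convention = c("sample", "population")) {
  method <- match.arg(method)
  sd_convention <- match.arg(sd_convention)
  m <- response_matrix(responses)
  if (nrow(m) < 2) abort("need at least 2 samples to rank")
  ids <- response_sample_ids(responses, m)
  spread <- if (method == "minmax") apply(m, 2, max) - apply(m, 2, min)
            else col_sd(m, sd_convention)
  if (any(spread == 0)) {
    warn(paste0("constant response(s) contribute 0 to the score: ",
                paste(colnames(m)[spread == 0], collapse = ", ")))
  }
  centre <- if (method == "minmax") apply(m, 2, min) else colMeans(m)
  z <- sweep(sweep(m, 2, centre), 2, ifelse(spread == 0, 1, spread), "/")
  z[, spread == 0] <- 0
  if (!is.null(senses)) {
    for (nm in names(senses)) {
      if (!nm %in% colnames(z)) abort(paste0("no response named ", nm))
      if (senses[[nm]] == "min") {
        z[, nm] <- if (method == "minmax") 1 - z[, nm] else -z[, nm]
      }
    }
  }
  out <- tibble(sample_id = ids, mean_score = unname(rowMeans(z)))
  out$rank <- rank(-out$mean_score, ties.method = "min")
  out <- dplyr::arrange(out, .data$rank)
  attr(out, "scores") <- tibble(
    sample_id = rep(ids, ncol(z)),
    response = rep(colnames(z), each = nrow(z)),
    score = as.vector(z))
  attr(out, "method") <- method
  class(out) <- c("uae_zscore", class(out))
  out
}

#' @describeIn zscore_rank Per-response scores in long format.
#' @param x A `uae_zscore` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.uae_zscore <- function(x, ...) attr(x, "scores")

#' Select the optimal extraction condition
#'
#' Ranks candidates by combined standard score and returns the winner with
#' its process factors and full response vector. For a measured campaign
#' pass the response table (and design); for a surrogate optimization pass
#' the [ga_optimize()] front, whose predicted objectives are scored the same
#' way.
#'
#' @param x A response table (long tibble) or a `uae_pareto` front.
#' @param ... Passed on to methods.
#' @return A one-row tibble: `sample_id` (for measured campaigns), the
#'   factor settings, `mean_score`, and the responses (wide).
#' @examples
#' select_optimum(load_responses(), design = load_design())
#' @export
select_optimum <- function(x, ...) UseMethod("select_optimum")

#' @rdname select_optimum
#' @param design Design tibble matching the response table's samples.
#' @param senses,method,sd_convention Passed to [zscore_rank()].
#' @export
select_optimum.data.frame <- function(x, design = NULL, senses = NULL,
                                      method = "minmax",
                                      sd_convention = "sample", ...) {
  if (inherits(x, "uae_pareto")) return(NextMethod())
  ranking <- zscore_rank(x, senses = senses, method = method,
                         sd_convention = sd_convention)
  top <- ranking$sample_id[ranking$rank == 1][1]
  m <- response_matrix(x)
  wide <- as_tibble(m[match(top, response_sample_ids(x, m)), , drop = FALSE])
  out <- tibble(sample_id = top,
                mean_score = unname(ranking$mean_score[ranking$sample_id == top]))
  if (!is.null(design)) {
    out <- dplyr::bind_cols(out,
      design[design$sample_id == top, FACTOR_NAMES])
  }
  dplyr::bind_cols(out, wide)
}

#' @rdname select_optimum
#' @export
select_optimum.uae_pareto <- function(x, senses = NULL, method = "minmax",
                                      sd_convention = "sample", ...) {
  if (nrow(x) == 0) abort("empty Pareto front")
  if (nrow(x) == 1) {
    return(dplyr::bind_cols(tibble(mean_score = NA_real_), as_tibble(x)))
  }
  obj_cols <- setdiff(names(x), FACTOR_NAMES)
  obj <- as_tibble(x)[c(obj_cols)]
  obj$sample_id <- seq_len(nrow(x))
  long <- tidyr::pivot_longer(obj, -"sample_id",
                              names_to = "response", values_to = "mean")
  ranking <- zscore_rank(long, senses = senses, method = method,
                         sd_convention = sd_convention)
  top <- ranking$sample_id[ranking$rank == 1][1]
  dplyr::bind_cols(
    tibble(mean_score = unname(ranking$mean_score[ranking$sample_id == top])),
    as_tibble(x)[top, ])
}
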