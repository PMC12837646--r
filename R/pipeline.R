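#' Pipeline configuration
#'
#' Resolves every knob of [run_pipeline()] into one serializable list. The
#' resolved configuration is written alongside the outputs of every run, so
#' a result directory is always self-describing.
#'
#' @param input `"pomace"` for the bundled campaign, or a list with `design`
#'   and `responses` CSV paths.
#' @param stages Character vector among `"chemometrics"`, `"fit"`,
#'   `"validate"`, `"optimize"`, `"rank"`.
#' @param seed Global seed; drives splits, restarts and the GA.
#' @param restarts Training restarts per architecture.
#' @param hidden Hidden-layer sizes for the three architectures.
#' @param population,front_cap,generations,stall GA settings.
#' @param senses Optional named `"max"` / `"min"` per response.
#' @param score_method `"minmax"` or `"zscore"` for the ranking stage.
#' @param sd_convention SD convention for z-scoring.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = "pomace",
                            stages = c("chemometrics", "rank"),
                            seed = 1,
                            restarts = 200,
                            hidden = c(ANN1 = 9, ANN2 = 10, ANN3 = 10),
                            population = 100, front_cap = 50,
                            generations = 200, stall = 20,
                            senses = NULL,
                            score_method = "minmax",
                            sd_convention = "sample") {
  known <- c("chemometrics", "fit", "validate", "optimize", "rank")
  bad <- setdiff(stages, known)
  if (length(bad)) abort(paste0("unknown stage(s): ", paste(bad, collapse = ", ")))
  structure(list(input = input, stages = stages, seed = seed,
                 restarts = restarts, hidden = hidden,
                 population = population, front_cap = front_cap,
                 generations = generations, stall = stall,
                 senses = senses, score_method = score_method,
                 sd_convention = sd_convention),
            class = "pipeline_config")
}

# The three published architectures; outputs per surrogate model.
architecture_outputs <- function() {
  list(ANN1 = list(outputs = c("TPC", "TFC"),
                   f_hidden = "tanh", f_output = "identity"),
       ANN2 = list(outputs = c("DPPH", "ABTS", "CUPRAC", "FRAP", "MC", "PM"),
                   f_hidden = "tanh", f_output = "tanh"),
       ANN3 = list(outputs = c("AChE", "BChE", "Tyrosinase",
                               "alpha-amylase", "alpha-glucosidase"),
                   f_hidden = "logistic", f_output = "identity"))
}

read_pipeline_input <- function(input) {
  if (identical(input, "pomace")) {
    list(design = load_design("pomace"), responses = load_responses("pomace"))
  } else {
    for (p in c(input$design, input$responses)) {
      if (!file.exists(p)) abort(paste0("input file not found: ", p))
    }
    list(design = load_design(input$design),
         responses = load_responses(input$responses))
  }
}

stage_log <- function(log, stage, t0, seed = NA) {
  dplyr::bind_rows(log, tibble(
    stage = stage, seconds = round(as.numeric(Sys.time()) - t0, 3),
    seed = seed))
}

#' Run the analysis pipeline
#'
#' Executes the configured stages in dependency order on one campaign:
#' chemometrics (correlation, PCA, clustering), surrogate fitting, validation
#' reporting, GA Pareto optimization, and standard-score ranking. Every
#' tabular output is written as CSV into `output_dir`, together with the
#' resolved configuration (`config.yaml`) and a stage log with timings and
#' seeds (`log.csv`).
#'
#' @param config A [pipeline_config()] or the path of a YAML file with the
#'   same fields.
#' @param output_dir Directory for outputs (created if needed).
#' @return Invisibly, a named list with the in-memory results of each stage.
#' @export
run_pipeline <- function(config, output_dir) {
  if (is.character(config)) {
    config <- do.call(pipeline_config, yaml::read_yaml(config))
  }
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  dat <- read_pipeline_input(config$input)
  out <- list(config = config)
  log <- tibble(stage = character(), seconds = numeric(), seed = numeric())
  put <- function(df, file) readr::write_csv(df, file.path(output_dir, file))

  if ("chemometrics" %in% config$stages) {
    t0 <- as.numeric(Sys.time())
    out$correlation <- correlation_matrix(dat$responses)
    out$pca <- pca_responses(dat$responses)
    out$hca <- hcluster_responses(dat$responses)
    out$clusters <- cut_dendrogram(out$hca, k = min(3, nrow(dat$design)))
    put(out$correlation, "correlation.csv")
    put(out$pca$variance, "pca_variance.csv")
    put(out$pca$loadings, "pca_loadings.csv")
    put(out$pca$scores, "pca_scores.csv")
    put(out$hca$merges, "dendrogram.csv")
    put(out$clusters, "clusters.csv")
    log <- stage_log(log, "chemometrics", t0)
  }

  fits <- NULL
  if (any(c("fit", "validate", "optimize") %in% config$stages)) {
    t0 <- as.numeric(Sys.time())
    archs <- architecture_outputs()
    present <- unique(dat$responses$response)
    fits <- purrr::imap(archs, function(a, id) {
      outs <- intersect(a$outputs, present)
      if (!length(outs)) return(NULL)
      mlp_train(dat$design, dat$responses,
                hidden = config$hidden[[id]], outputs = outs,
                f_hidden = a$f_hidden, f_output = a$f_output,
                control = train_control(restarts = config$restarts,
                                        seed = config$seed))
    })
    fits <- purrr::compact(fits)
    out$fits <- fits
    purrr::iwalk(fits, function(f, id) {
      write_model(f, file.path(output_dir, paste0("model_", tolower(id), ".json")))
      put(glance(f), paste0("performance_", tolower(id), ".csv"))
    })
    log <- stage_log(log, "fit", t0, config$seed)
  }

  if ("validate" %in% config$stages) {
    t0 <- as.numeric(Sys.time())
    obs <- response_matrix(dat$responses)
    reports <- purrr::imap_dfr(fits, function(f, id) {
      pred <- as.matrix(predict(f, dat$design))
      dplyr::mutate(fit_report(obs[, f$outputs, drop = FALSE], pred),
                    model = id, .before = 1)
    })
    out$fit_report <- reports
    put(reports, "fit_report.csv")
    log <- stage_log(log, "validate", t0)
  }

  if ("optimize" %in% config$stages) {
    t0 <- as.numeric(Sys.time())
    out$pareto <- ga_optimize(unname(fits),
                              senses = config$senses,
                              population = config$population,
                              front_cap = config$front_cap,
                              generations = config$generations,
                              stall = config$stall,
                              seed = config$seed)
    out$pareto_optimum <- select_optimum(out$pareto, senses = config$senses,
                                         method = config$score_method)
    put(as_tibble(out$pareto), "pareto_front.csv")
    put(out$pareto_optimum, "pareto_optimum.csv")
    log <- stage_log(log, "optimize", t0, config$seed)
  }

  if ("rank" %in% config$stages) {
    t0 <- as.numeric(Sys.time())
    out$ranking <- zscore_rank(dat$responses, senses = config$senses,
                               method = config$score_method,
                               sd_convention = config$sd_convention)
    out$optimum <- select_optimum(dat$responses, design = dat$design,
                                  senses = config$senses,
                                  method = config$score_method,
                                  sd_convention = config$sd_convention)
    put(as_tibble(out$ranking), "ranking.csv")
    put(out$optimum, "optimum.csv")
    log <- stage_log(log, "rank", t0)
  }

  yaml::write_yaml(unclass(config), file.path(output_dir, "config.yaml"))
  put(log, "log.csv")
  invisible(out)
}

# Published reference values the reproduction run is compared against.
published_reference <- function() {
  tibble::tribble(
    ~quantity, ~reference, ~tolerance, ~cmp,
    "r_FRAP_CUPRAC", 0.9730, 0.02, "abs",
    "r_DPPH_FRAP", 0.9572, 0.02, "abs",
    "r_TPC_PM", 0.5517, 0.02, "abs",
    "r_TFC_PM", 0.3561, 0.02, "abs",
    "pc1_percent", 46.15, 1.0, "abs",
    "pc2_percent", 15.66, 1.0, "abs",
    "pc1_plus_pc2_percent", 61.81, 1.0, "abs",
    "top_sample", 6, 0, "abs",
    "combined_score_top", 0.794, 0.02, "abs",
    "optimum_time_min", 20, 0, "abs",
    "optimum_temperature_C", 50, 0, "abs",
    "optimum_ratio_mL_per_g", 20, 0, "abs",
    "optimum_TPC", 16.494, 0, "abs",
    "optimum_TFC", 2.103, 0, "abs",
    "hca_final_merge_height", 100, NA, "ge",
    "min_train_r2", 0.99, NA, "ge")
}

#' One-command reproduction of the bundled campaign's analysis
#'
#' Runs the full reproduce path on the bundled 15-run campaign: correlation
#' matrix, standardized PCA, complete-linkage Manhattan clustering,
#' standard-score ranking with optimum readout, and (optionally) retraining
#' of the three surrogate architectures with per-response validation
#' reports. Writes every table as CSV plus `comparison.csv`, which sets the
#' recomputed quantities against the published reference values with a
#' pass/fail per tolerance.
#'
#' @param output_dir Directory for the report bundle.
#' @param seed Global seed (splits and restarts).
#' @param retrain Refit the three surrogates (the slow stage); with
#'   `FALSE` only the sub-second analyses run.
#' @param restarts Training restarts per architecture when retraining.
#' @return Invisibly, the list of results including `comparison`.
#' @examples
#' \donttest{
#' res <- reproduce_study(tempfile("repro"), retrain = FALSE)
#' res$comparison
#' }
#' @export
reproduce_study <- function(output_dir, seed = 1, retrain = TRUE,
                            restarts = 200) {
  stages <- c("chemometrics", "rank",
              if (retrain) c("fit", "validate"))
  cfg <- pipeline_config(input = "pomace", stages = stages, seed = seed,
                         restarts = restarts)
  out <- run_pipeline(cfg, output_dir)

  getr <- function(x, y) {
    out$correlation$r[out$correlation$response_x == x &
                        out$correlation$response_y == y]
  }
  computed <- c(
    r_FRAP_CUPRAC = getr("FRAP", "CUPRAC"),
    r_DPPH_FRAP = getr("DPPH", "FRAP"),
    r_TPC_PM = getr("TPC", "PM"),
    r_TFC_PM = getr("TFC", "PM"),
    pc1_percent = out$pca$variance$percent[1],
    pc2_percent = out$pca$variance$percent[2],
    pc1_plus_pc2_percent = out$pca$variance$cumulative[2],
    top_sample = out$optimum$sample_id,
    combined_score_top = out$optimum$mean_score,
    optimum_time_min = out$optimum$time,
    optimum_temperature_C = out$optimum$temperature,
    optimum_ratio_mL_per_g = out$optimum$ratio,
    optimum_TPC = out$optimum$TPC,
    optimum_TFC = out$optimum$TFC,
    hca_final_merge_height = max(out$hca$merges$height),
    min_train_r2 = if (retrain) {
      min(purrr::map_dbl(out$fits, function(f) {
        f$performance$r2[f$performance$partition == "train"]
      }))
    } else NA_real_)
  comparison <- published_reference()
  comparison$computed <- unname(computed[comparison$quantity])
  comparison$pass <- ifelse(
    comparison$cmp == "ge", comparison$computed >= comparison$reference,
    abs(comparison$computed - comparison$reference) <= comparison$tolerance)
  comparison <- comparison[c("quantity", "computed", "reference",
                             "tolerance", "cmp", "pass")]
  out$comparison <- comparison
  readr::write_csv(comparison, file.path(output_dir, "comparison.csv"))
  invisible(out)
}
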