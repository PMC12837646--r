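# Internal helpers shared across modules.

FACTOR_NAMES <- c("time", "temperature", "ratio")

#' Measured response names, in canonical order
#'
#' The thirteen bioactivity responses measured on each extract: total phenolic
#' and flavonoid content, six antioxidant assays, and five enzyme-inhibition
#' assays.
#'
#' @return Character vector of length 13.
#' @export
response_names <- function() {
  c("TPC", "TFC", "DPPH", "ABTS", "CUPRAC", "FRAP", "MC", "PM",
    "AChE", "BChE", "Tyrosinase", "alpha-amylase", "alpha-glucosidase")
}

#' Units for the measured responses
#'
#' Bundled dictionary mapping each response to the unit in which it is
#' reported (equivalents of the assay's reference standard per gram of
#' extract).
#'
#' @return Named character vector; names are response names.
#' @export
response_units <- function() {
  c(TPC = "mg GAE/g", TFC = "mg RE/g",
    DPPH = "mg TE/g", ABTS = "mg TE/g", CUPRAC = "mg TE/g", FRAP = "mg TE/g",
    MC = "mg EDTAE/g", PM = "mmol TE/g",
    AChE = "mg GALAE/g", BChE = "mg GALAE/g", Tyrosinase = "mg KAE/g",
    `alpha-amylase` = "mmol ACAE/g", `alpha-glucosidase` = "mmol ACAE/g")
}

# Coerce a design (data frame with time/temperature/ratio) to a numeric
# matrix with the three factor columns in canonical order.
factor_matrix <- function(design) {
  if (is.matrix(design)) {
    if (ncol(design) != 3L) {
      abort(sprintf("design matrix must have 3 columns, got %d", ncol(design)))
    }
    m <- design
    colnames(m) <- FACTOR_NAMES
    return(m)
  }
  missing <- setdiff(FACTOR_NAMES, names(design))
  if (length(missing)) {
    abort(paste0("design is missing column(s): ", paste(missing, collapse = ", ")))
  }
  as.matrix(design[FACTOR_NAMES])
}

# Coerce responses (long tibble with sample_id/response/mean, or a wide data
# frame / matrix of response columns) to a samples x responses numeric matrix.
# `outputs` optionally restricts and orders the columns.
response_matrix <- function(responses, outputs = NULL, value = "mean") {
  if (is.matrix(responses)) {
    m <- responses
  } else if (all(c("sample_id", "response", value) %in% names(responses))) {
    wide <- tidyr::pivot_wider(
      responses[c("sample_id", "response", value)],
      names_from = "response", values_from = dplyr::all_of(value))
    wide <- dplyr::arrange(wide, .data$sample_id)
    m <- as.matrix(wide[setdiff(names(wide), "sample_id")])
    rownames(m) <- wide$sample_id
  } else {
    df <- responses[setdiff(names(responses), c("sample_id", FACTOR_NAMES))]
    m <- as.matrix(df)
    if (!is.null(responses[["sample_id"]])) rownames(m) <- responses$sample_id
  }
  if (!is.null(outputs)) {
    missing <- setdiff(outputs, colnames(m))
    if (length(missing)) {
      abort(paste0("response(s) not found: ", paste(missing, collapse = ", ")))
    }
    m <- m[, outputs, drop = FALSE]
  }
  storage.mode(m) <- "double"
  m
}

# Sample ids associated with a response object (long or wide).
response_sample_ids <- function(responses, m) {
  if (!is.null(rownames(m))) return(as.integer(rownames(m)))
  seq_len(nrow(m))
}

# Column-wise sample or population standard deviation.
col_sd <- function(m, convention = c("sample", "population")) {
  convention <- match.arg(convention)
  s <- apply(m, 2, sd)
  if (convention == "population") s <- s * sqrt((nrow(m) - 1) / nrow(m))
  s
}

# Evaluate with a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

path_fixture <- function(file) {
  system.file("extdata", file, package = "uaeopt", mustWork = TRUE)
}
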