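#' Pairwise correlation matrix of responses
#'
#' Pearson correlation with two-sided significance for every pair of
#' responses across samples. Constant responses are kept but flagged with
#' `NA` correlations.
#'
#' @param responses Long response tibble (or wide table) of sample means.
#' @return A tibble of class `uae_corr` with columns `response_x`,
#'   `response_y`, `r`, `p_value`, symmetric and with unit diagonal.
#' @examples
#' cm <- correlation_matrix(load_responses())
#' dplyr::filter(cm, response_x == "FRAP", response_y == "CUPRAC")
#' @export
correlation_matrix <- function(responses) {
  m <- response_matrix(responses)
  if (nrow(m) < 3) abort("need at least 3 samples for correlations")
  resp <- colnames(m)
  constant <- apply(m, 2, sd) == 0
  if (any(constant)) {
    warn(paste0("constant response(s), correlations undefined: ",
                paste(resp[constant], collapse = ", ")))
  }
  grid <- tidyr::expand_grid(response_x = resp, response_y = resp)
  out <- purrr::pmap_dfr(grid, function(response_x, response_y) {
    if (constant[response_x] || constant[response_y]) {
      return(tibble(response_x = response_x, response_y = response_y,
                    r = NA_real_, p_value = NA_real_))
    }
    if (response_x == response_y) {
      return(tibble(response_x = response_x, response_y = response_y,
                    r = 1, p_value = 0))
    }
    ht <- pearson_test(m[, response_x], m[, response_y])
    tibble(response_x = response_x, response_y = response_y,
           r = ht$r, p_value = ht$p_value)
  })
  class(out) <- c("uae_corr", class(out))
  out
}

#' Principal component analysis of the response table
#'
#' PCA of the samples x responses mean table. With `standardize = TRUE`
#' (default) variables are centred and scaled to unit variance, i.e. the
#' decomposition is of the correlation matrix — appropriate here because the
#' thirteen responses carry heterogeneous units. Components are ordered by
#' decreasing explained variance, and each loading vector's sign is fixed so
#' that its largest-magnitude entry is positive.
#'
#' @param responses Long response tibble (or wide table) of sample means.
#' @param standardize Scale each response to unit variance first.
#' @return An object of class `uae_pca` with tibbles `variance` (component,
#'   eigenvalue, percent, cumulative), `loadings` (responses x components)
#'   and `scores` (samples x components).
#' @examples
#' pca <- pca_responses(load_responses())
#' glance(pca)
#' @export
pca_responses <- function(responses, standardize = TRUE) {
  m <- response_matrix(responses)
  if (nrow(m) < 2 || ncol(m) < 2) abort("need at least 2 samples and 2 responses")
  if (standardize && any(apply(m, 2, sd) == 0)) {
    bad <- colnames(m)[apply(m, 2, sd) == 0]
    abort(paste0("constant response(s) cannot be standardized: ",
                 paste(bad, collapse = ", ")))
  }
  fit <- prcomp(m, center = TRUE, scale. = standardize)
  flip <- apply(fit$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  rotation <- sweep(fit$rotation, 2, flip, "*")
  scores <- sweep(fit$x, 2, flip, "*")
  eig <- fit$sdev^2
  pct <- 100 * eig / sum(eig)
  comp <- paste0("PC", seq_along(eig))
  loadings <- as_tibble(rotation, rownames = "response")
  names(loadings) <- c("response", comp)
  scores_tbl <- as_tibble(scores, rownames = "sample_id")
  names(scores_tbl) <- c("sample_id", comp)
  scores_tbl$sample_id <- as.integer(scores_tbl$sample_id)
  structure(list(
    variance = tibble(component = comp, eigenvalue = eig,
                      percent = pct, cumulative = cumsum(pct)),
    loadings = loadings,
    scores = scores_tbl,
    standardized = standardize), class = "uae_pca")
}

#' @export
print.uae_pca <- function(x, ...) {
  v <- x$variance
  cat(sprintf("PCA of %d responses: PC1 %.2f%%, PC2 %.2f%% (cumulative %.2f%%)\n",
              nrow(x$loadings), v$percent[1], v$percent[2], v$cumulative[2]))
  invisible(x)
}

#' @describeIn pca_responses Loadings in long format.
#' @param x A `uae_pca` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.uae_pca <- function(x, ...) {
  tidyr::pivot_longer(x$loadings, -"response",
                      names_to = "component", values_to = "loading")
}

#' @describeIn pca_responses Explained-variance table.
#' @exportS3Method generics::glance
glance.uae_pca <- function(x, ...) x$variance

#' Hierarchical clustering of samples
#'
#' Agglomerative clustering of the extracts on their raw (unstandardized)
#' response means, by default with complete linkage on City-block
#' (Manhattan) distances. Raw units are used deliberately: merge heights are
#' then sums of absolute response differences and directly comparable to the
#' published linkage distances.
#'
#' @param responses Long response tibble (or wide table) of sample means.
#' @param metric Distance metric passed to [stats::dist()].
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @return An object of class `uae_hca`: `merges` (tibble with `step`,
#'   `left`, `right`, `height`; negative ids are leaves, positive ids earlier
#'   merge steps, the [stats::hclust()] convention), `labels`, and the
#'   underlying `hclust` object.
#' @export
hcluster_responses <- function(responses, metric = "manhattan",
                               linkage = "complete") {
  m <- response_matrix(responses)
  if (nrow(m) < 2) abort("need at least 2 samples to cluster")
  ids <- response_sample_ids(responses, m)
  h <- hclust(dist(m, method = metric), method = linkage)
  merges <- tibble(step = seq_len(nrow(h$merge)),
                   left = h$merge[, 1], right = h$merge[, 2],
                   height = h$height)
  structure(list(merges = merges, labels = ids, hclust = h,
                 metric = metric, linkage = linkage), class = "uae_hca")
}

#' @export
print.uae_hca <- function(x, ...) {
  cat(sprintf("%s-linkage %s clustering of %d samples; final merge height %.3f\n",
              x$linkage, x$metric, length(x$labels), max(x$merges$height)))
  invisible(x)
}

#' @describeIn hcluster_responses Merge table as a tibble.
#' @param x A `uae_hca` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.uae_hca <- function(x, ...) x$merges

#' Cut a dendrogram into k clusters
#'
#' @param hca A `uae_hca` from [hcluster_responses()].
#' @param k Number of clusters, between 1 and the number of leaves.
#' @return A tibble with columns `sample_id`, `cluster`.
#' @export
cut_dendrogram <- function(hca, k) {
  n <- length(hca$labels)
  if (k < 1 || k > n) abort(sprintf("k must be between 1 and %d", n))
  tibble(sample_id = hca$labels,
         cluster = unname(cutree(hca$hclust, k = k)))
}
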