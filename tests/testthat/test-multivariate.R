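test_that("correlation matrix is symmetric with unit diagonal and matches a pairwise oracle", {
  resp <- load_responses()
  cm <- correlation_matrix(resp)
  wide <- tidyr::pivot_wider(cm[c("response_x", "response_y", "r")],
                             names_from = "response_y", values_from = "r")
  m <- as.matrix(wide[-1])
  expect_equal(unname(diag(m)), rep(1, 13))
  expect_equal(unname(m), unname(t(m)), tolerance = 1e-12)

  # brute-force pairwise check on a small toy table
  set.seed(3)
  toy <- matrix(rnorm(15), 5, 3, dimnames = list(NULL, c("A", "B", "C")))
  cmt <- correlation_matrix(toy)
  for (i in c("A", "B", "C")) for (j in c("A", "B", "C")) {
    got <- cmt$r[cmt$response_x == i & cmt$response_y == j]
    expect_equal(got, cor(toy[, i], toy[, j]), tolerance = 1e-12)
  }
  expect_error(correlation_matrix(toy[1:2, ]), "at least 3")
})

test_that("antioxidant and phenolic responses are tightly intercorrelated", {
  cm <- correlation_matrix(load_responses())
  six <- c("TPC", "TFC", "DPPH", "ABTS", "CUPRAC", "FRAP")
  sub <- cm[cm$response_x %in% six & cm$response_y %in% six &
              cm$response_x != cm$response_y, ]
  expect_gt(min(sub$r), 0.83)
  expect_lt(max(sub$p_value), 0.001)
})

test_that("standardized PCA has the spectral properties of a correlation PCA", {
  resp <- load_responses()
  pca <- pca_responses(resp)
  expect_equal(sum(pca$variance$percent), 100, tolerance = 1e-9)
  L <- as.matrix(pca$loadings[-1])
  expect_equal(unname(crossprod(L)), diag(13), tolerance = 1e-9)
  # scores decorrelate with variances equal to the eigenvalues
  S <- as.matrix(pca$scores[-1])
  expect_equal(unname(diag(stats::cov(S))), pca$variance$eigenvalue,
               tolerance = 1e-9)
  offdiag <- stats::cov(S); diag(offdiag) <- 0
  expect_lt(max(abs(offdiag)), 1e-9)
  # sign convention: dominant entry of every loading vector is positive
  expect_true(all(apply(L, 2, function(v) v[which.max(abs(v))] > 0)))
})

test_that("two standardized variables give the closed-form eigenvalue split", {
  set.seed(8)
  x <- rnorm(40)
  y <- 0.6 * x + sqrt(1 - 0.36) * rnorm(40)
  m <- cbind(u = x, v = y)
  r <- cor(x, y)
  pca <- pca_responses(m)
  expect_equal(pca$variance$percent[1], 100 * (1 + abs(r)) / 2,
               tolerance = 1e-9)

  # a single informative variable among constants captures everything
  m2 <- cbind(flat1 = rep(2, 6), sig = rnorm(6))
  pca2 <- pca_responses(m2, standardize = FALSE)
  expect_equal(pca2$variance$percent[1], 100, tolerance = 1e-9)
  expect_error(pca_responses(m2, standardize = TRUE), "constant")
})

test_that("complete-linkage Manhattan clustering matches hand and brute-force oracles", {
  # three points on a line: {0,1} merge at 1, then join {5} at 5
  m <- cbind(x = c(0, 1, 5))
  h <- hcluster_responses(m)
  expect_equal(h$merges$height, c(1, 5))
  expect_equal(unname(sort(unlist(h$merges[1, c("left", "right")]))), c(-2, -1))

  # duplicated rows merge first at height zero
  hd <- hcluster_responses(cbind(x = c(3, 3, 9), y = c(1, 1, 4)))
  expect_equal(hd$merges$height[1], 0)

  # randomized comparison against a naive O(n^3) agglomerative oracle
  set.seed(21)
  for (trial in 1:50) {
    m <- matrix(rnorm(6 * 3), 6, 3)
    got <- hcluster_responses(m)
    want <- oracle_hclust(m)
    expect_equal(got$merges$height, want$heights, tolerance = 1e-9)
    for (k in 2:5) {
      cut <- cut_dendrogram(got, k)
      # partitions match up to label permutation
      step <- 6 - k
      expect_equal(canonical_partition(cut$cluster[order(cut$sample_id)]),
                   canonical_partition(want$partitions[[step]]))
    }
  }
})

test_that("merge heights are monotone and count n - 1 merges", {
  h <- hcluster_responses(load_responses())
  expect_equal(nrow(h$merges), 14)
  expect_true(all(diff(h$merges$height) >= 0))
})

test_that("the best-performing extract is a cluster of its own", {
  resp <- load_responses()
  h <- hcluster_responses(resp)
  # final merge joins sample 6 alone against everything else
  expect_gt(max(h$merges$height), 100)
  cl <- cut_dendrogram(h, 3)
  expect_equal(cl$sample_id[cl$cluster == cl$cluster[cl$sample_id == 6]], 6)
  # the cluster holding sample 1 keeps its published companions
  c1 <- cl$cluster[cl$sample_id == 1]
  expect_true(all(c(2, 4, 5, 13, 14) %in% cl$sample_id[cl$cluster == c1]))

  expect_equal(nrow(unique(cut_dendrogram(h, 15)["cluster"])), 15)
  expect_error(cut_dendrogram(h, 0), "between 1 and 15")
  expect_error(cut_dendrogram(h, 16), "between 1 and 15")
})
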