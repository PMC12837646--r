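test_that("dominance filtering matches exhaustive pairwise checks", {
  pts <- tibble::tibble(id = c("A", "B", "C", "D"),
                        o1 = c(1, 2, 0.5, 0.9), o2 = c(1, 0.5, 2, 0.9))
  front <- pareto_front(pts, objectives = c("o1", "o2"))
  expect_setequal(front$id, c("A", "B", "C"))

  # duplicated candidates leave the front unchanged as a set
  dup <- pareto_front(dplyr::bind_rows(pts, pts[1, ]),
                      objectives = c("o1", "o2"))
  expect_setequal(unique(dup$id), c("A", "B", "C"))

  # single objective reduces to the argmax
  one <- pareto_front(pts, objectives = "o1")
  expect_equal(one$id, "B")

  # minimization sense flips the orientation: D now dominates A
  mins <- pareto_front(pts, objectives = c("o1", "o2"),
                       senses = c(o1 = "min", o2 = "min"))
  expect_setequal(mins$id, c("B", "C", "D"))
})

test_that("pareto_front equals the brute-force oracle on random instances", {
  set.seed(14)
  for (trial in 1:20) {
    obj <- matrix(runif(50 * 3), 50, 3,
                  dimnames = list(NULL, c("f1", "f2", "f3")))
    df <- tibble::as_tibble(obj)
    df$row <- seq_len(50)
    front <- pareto_front(df, objectives = c("f1", "f2", "f3"))
    expect_setequal(front$row, which(oracle_pareto(obj)))
  }
})

test_that("front caps thin by crowding while keeping objective extremes", {
  set.seed(15)
  t_ <- seq(0, 1, length.out = 200)
  dense <- tibble::tibble(f1 = t_, f2 = sqrt(1 - t_^2))  # all non-dominated
  capped <- pareto_front(dense, objectives = c("f1", "f2"), cap = 50)
  expect_equal(nrow(capped), 50)
  expect_true(max(dense$f1) %in% capped$f1)
  expect_true(max(dense$f2) %in% capped$f2)
})

test_that("the GA is reproducible and honors its front cap", {
  fit <- monotone_surrogate()
  a <- ga_optimize(fit, population = 20, front_cap = 5, generations = 30,
                   stall = 10, seed = 3)
  b <- ga_optimize(fit, population = 20, front_cap = 5, generations = 30,
                   stall = 10, seed = 3)
  expect_equal(as.data.frame(a), as.data.frame(b))
  expect_lte(nrow(a), 5)
  expect_gt(attr(a, "generations"), 0)

  # monotone objective drives the search to the upper corner of the box
  top <- a[which.max(a$y), ]
  expect_lt(abs(top$time - 30), 2)
  expect_lt(abs(top$temperature - 75), 5)
  expect_lt(abs(top$ratio - 20), 1)
})

test_that("standard scores match hand computation and classic z properties", {
  toy <- cbind(c1 = c(1, 2, 3), c2 = c(2, 4, 9))
  zr <- zscore_rank(toy, method = "zscore")
  s3 <- zr$mean_score[zr$sample_id == 3]
  expect_equal(s3, (1 + 4 / sqrt(13)) / 2, tolerance = 1e-9)
  expect_equal(zr$rank[zr$sample_id == 3], 1L)

  # z columns have mean 0 and unit SD under the chosen convention
  scores <- tidyr::pivot_wider(tidy(zr), names_from = "response",
                               values_from = "score")
  z <- as.matrix(scores[-1])
  expect_equal(unname(colMeans(z)), c(0, 0), tolerance = 1e-9)
  expect_equal(unname(apply(z, 2, sd)), c(1, 1), tolerance = 1e-9)

  zp <- zscore_rank(toy, method = "zscore", sd_convention = "population")
  zpm <- tidyr::pivot_wider(tidy(zp), names_from = "response",
                            values_from = "score")
  expect_equal(unname(apply(as.matrix(zpm[-1]), 2,
                            function(x) sqrt(mean((x - mean(x))^2)))),
               c(1, 1), tolerance = 1e-9)

  # identical samples: all scores zero (flagged)
  expect_warning(flat <- zscore_rank(cbind(a = rep(1, 4), b = rep(2, 4))),
                 "constant")
  expect_true(all(flat$mean_score == 0))
})

test_that("rankings are invariant to positive affine response rescaling", {
  set.seed(16)
  m <- matrix(runif(30, 1, 10), 10, 3, dimnames = list(NULL, c("A", "B", "C")))
  m2 <- m
  m2[, 2] <- 100 * m2[, 2] + 7
  for (meth in c("minmax", "zscore")) {
    r1 <- zscore_rank(m, method = meth)
    r2 <- zscore_rank(m2, method = meth)
    expect_equal(r1$rank, r2$rank)
    expect_equal(r1$mean_score, r2$mean_score, tolerance = 1e-9)
  }
})

test_that("minimization senses flip a response's contribution", {
  m <- cbind(good = c(1, 2, 3), bad = c(1, 2, 3))
  r <- zscore_rank(m, senses = c(bad = "min"), method = "zscore")
  expect_true(all(r$mean_score == 0))
  rmax <- zscore_rank(m, method = "zscore")
  expect_equal(rmax$sample_id[rmax$rank == 1], 3)
})

test_that("the bundled campaign ranks sample 6 first under every convention", {
  resp <- load_responses()
  for (meth in c("minmax", "zscore")) {
    for (conv in c("sample", "population")) {
      r <- zscore_rank(resp, method = meth, sd_convention = conv)
      expect_equal(r$sample_id[r$rank == 1], 6)
    }
  }
  mm <- zscore_rank(resp, method = "minmax")
  expect_equal(mm$mean_score[mm$sample_id == 6], 0.794, tolerance = 0.02)
})

test_that("select_optimum returns the winning condition with its responses", {
  resp <- load_responses()
  opt <- select_optimum(resp, design = load_design())
  expect_equal(unlist(opt[c("time", "temperature", "ratio")]),
               c(time = 20, temperature = 50, ratio = 20))
  expect_equal(opt$TPC, 16.494)
  expect_equal(opt$TFC, 2.103)

  # a candidate ahead in every column wins
  two <- cbind(A = c(1, 2), B = c(3, 5))
  opt2 <- select_optimum(as.data.frame(two))
  expect_equal(opt2$sample_id, 2)
  expect_error(select_optimum(resp[0, ]), "at least 2|empty")
})
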