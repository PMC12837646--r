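test_that("forward pass matches hand evaluation on toy networks", {
  p <- mlp_parameters(W1 = matrix(1), B1 = 0, W2 = matrix(2), B2 = 1,
                      f_hidden = "tanh", f_output = "identity")
  expect_equal(mlp_forward(p, matrix(0.5))[[1]], 2 * tanh(0.5) + 1,
               tolerance = 1e-12)

  # zero weights collapse to the output bias for any input
  pz <- mlp_parameters(W1 = matrix(0, 4, 3), B1 = rep(0, 4),
                       W2 = matrix(0, 2, 4), B2 = c(3.5, -1),
                       f_hidden = "tanh", f_output = "identity")
  X <- matrix(rnorm(15), 5, 3)
  out <- mlp_forward(pz, X)
  expect_true(all(out[[1]] == 3.5) && all(out[[2]] == -1))

  # odd symmetry with tanh hidden, identity output, zero biases
  ps <- mlp_parameters(W1 = matrix(rnorm(6), 2, 3), B1 = c(0, 0),
                       W2 = matrix(rnorm(2), 1, 2), B2 = 0,
                       f_hidden = "tanh", f_output = "identity")
  expect_equal(as.matrix(mlp_forward(ps, -X)), -as.matrix(mlp_forward(ps, X)),
               tolerance = 1e-12)

  expect_error(mlp_forward(p, matrix(1, 2, 3)), "expects 1")
})

test_that("vectorized forward pass agrees with a loop-based oracle", {
  set.seed(42)
  for (trial in 1:100) {
    nh <- sample(1:10, 1); no <- sample(1:6, 1)
    fh <- sample(c("tanh", "logistic", "identity"), 1)
    fo <- sample(c("tanh", "logistic", "identity"), 1)
    p <- random_mlp(3, nh, no, fh, fo)
    X <- matrix(rnorm(12), 4, 3)
    expect_equal(as.matrix(mlp_forward(p, X)), unname(oracle_forward(p, X)),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("15 samples split 9/3/3, disjoint, exhaustive and seed-stable", {
  s <- split_dataset(15, seed = 7)
  expect_equal(unname(table(s)[c("train", "test", "validation")]),
               c(9L, 3L, 3L), ignore_attr = TRUE)
  expect_equal(length(s), 15)
  expect_identical(s, split_dataset(15, seed = 7))
  expect_false(identical(s, split_dataset(15, seed = 8)))
  expect_error(split_dataset(3), "too few samples")
})

test_that("parameter validation catches shape mismatches", {
  expect_error(mlp_parameters(matrix(1, 2, 3), B1 = 1, W2 = matrix(1, 1, 2),
                              B2 = 0), "bias length")
  expect_error(mlp_parameters(matrix(1, 2, 3), B1 = c(0, 0),
                              W2 = matrix(1, 1, 3), B2 = 0), "W2 columns")
  expect_error(mlp_parameters(matrix(NA_real_, 1, 1), B1 = 0,
                              W2 = matrix(1), B2 = 0), "finite")
})

test_that("a realizable linear response is fitted almost exactly", {
  design <- generate_design(paper_levels())
  lin <- tibble::tibble(
    sample_id = rep(design$sample_id, 1), response = "lin",
    mean = 0.1 * design$time + 0.04 * design$temperature + 0.2 * design$ratio,
    sd = 0)
  fit <- mlp_train(design, lin, hidden = 2, outputs = "lin",
                   control = train_control(restarts = 10, seed = 3))
  r2 <- fit$performance$r2[fit$performance$partition == "train"]
  expect_gt(r2, 0.9999)

  # one hidden unit suffices for a linear target
  sw <- sweep_hidden_sizes(design, lin, sizes = c(1, 10), outputs = "lin",
                           control = train_control(restarts = 10, seed = 3))
  expect_lt(abs(sw$r2_train[sw$hidden == 1] - sw$r2_train[sw$hidden == 10]),
            0.001)
})

test_that("adding restarts never degrades the selected training fit", {
  design <- load_design()
  resp <- load_responses()
  r2_for <- function(k) {
    fit <- mlp_train(design, resp, hidden = 4, outputs = c("TPC", "TFC"),
                     control = train_control(restarts = k, seed = 5))
    fit$performance$r2[fit$performance$partition == "train"]
  }
  r2 <- vapply(c(1, 5, 15), r2_for, numeric(1))
  expect_true(all(diff(r2) >= -1e-12))
  # and the recorded history tracks the cumulative best
  fit <- mlp_train(design, resp, hidden = 4, outputs = c("TPC", "TFC"),
                   control = train_control(restarts = 15, seed = 5))
  expect_true(all(diff(fit$history$best_r2_so_far) >= 0))
  expect_equal(max(fit$history$r2_train, na.rm = TRUE),
               fit$performance$r2[fit$performance$partition == "train"])
})

test_that("tanh-output networks emit values inside (-1, 1) before unscaling", {
  set.seed(9)
  p <- random_mlp(3, 6, 4, "tanh", "tanh")
  raw <- uaeopt:::mlp_forward_raw(p, matrix(rnorm(30, sd = 3), 10, 3))
  expect_true(all(raw > -1 & raw < 1))
})

test_that("published weights give finite, rank-consistent predictions", {
  design <- load_design()
  resp <- load_responses()
  tpc <- resp$mean[resp$response == "TPC"]
  for (id in c("ANN1", "ANN2", "ANN3")) {
    pred <- predict(load_published_model(id), design)
    expect_true(all(is.finite(as.matrix(pred))))
  }
  ann1 <- predict(load_published_model("ANN1"), design)
  expect_gt(cor(ann1$TPC, tpc, method = "spearman"), 0)
})

test_that("hidden-size sweep returns one row per size and a sane recommendation", {
  design <- load_design()
  resp <- load_responses()
  sw1 <- sweep_hidden_sizes(design, resp, sizes = 9, outputs = c("TPC", "TFC"),
                            control = train_control(restarts = 3, seed = 2))
  expect_equal(attr(sw1, "recommended"), 9)

  sw <- sweep_hidden_sizes(design, resp, sizes = c(2, 5, 9),
                           outputs = c("TPC", "TFC"),
                           control = train_control(restarts = 8, seed = 2))
  expect_equal(nrow(sw), 3)
  best <- max(sw$r2_train)
  expect_gte(best, sw$r2_train[sw$hidden == 2])
  expect_gt(best, 0.99)
})

test_that("grid prediction is consistent with forward evaluation", {
  design <- load_design()
  net <- load_published_model("ANN1")
  g <- predict_grid(net, step = c(time = 10, temperature = 25, ratio = 5))
  direct <- predict(net, g[c("time", "temperature", "ratio")])
  expect_equal(g$TPC, direct$TPC, tolerance = 1e-12)

  corners <- predict_grid(net, step = c(time = 20, temperature = 50, ratio = 10))
  expect_equal(nrow(corners), 8)

  mono <- monotone_surrogate()
  gm <- predict_grid(mono, step = c(time = 5, temperature = 12.5, ratio = 2.5))
  expect_equal(unlist(gm[which.max(gm$y), c("time", "temperature", "ratio")]),
               c(time = 30, temperature = 75, ratio = 20))

  expect_error(predict_grid(net, bounds = list(time = c(0, 200),
                                               temperature = c(25, 75),
                                               ratio = c(10, 20)),
                            step = 10), "outside the design box")
})

test_that("model bundles survive a JSON round trip", {
  design <- load_design()
  resp <- load_responses()
  fit <- mlp_train(design, resp, hidden = 3, outputs = c("TPC", "TFC"),
                   control = train_control(restarts = 2, seed = 1))
  path <- withr::local_tempfile(fileext = ".json")
  write_model(fit, path)
  back <- read_model(path)
  expect_equal(predict(back, design), predict(fit, design), tolerance = 1e-12)
  expect_equal(back$outputs, fit$outputs)
})
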