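test_that("bundled fixtures are byte-stable and match the printed tables", {
  md5 <- tools::md5sum(c(
    design = system.file("extdata", "uae_design.csv", package = "uaeopt"),
    responses = system.file("extdata", "uae_responses.csv", package = "uaeopt"),
    gof = system.file("extdata", "goodness_of_fit.csv", package = "uaeopt"),
    ann1 = system.file("extdata", "ann1.json", package = "uaeopt"),
    ann2 = system.file("extdata", "ann2.json", package = "uaeopt"),
    ann3 = system.file("extdata", "ann3.json", package = "uaeopt")))
  expect_equal(unname(md5), c(
    "21ca73330fba9069c62ad5a975639b4c",
    "63c1c5592fcb6abd2c4d92c55ab5ef70",
    "578f006a04804d3265bb2aa20cf2a039",
    "786c28463451bc1cf6343dcb9ed30ad8",
    "1334c358abf017741defa1595e400598",
    "e706587c92f49050789bdf3eff195a83"))

  design <- load_design()
  expect_equal(nrow(design), 15)
  expect_equal(unlist(design[design$sample_id == 6, c("time", "temperature", "ratio")]),
               c(time = 20, temperature = 50, ratio = 20))
  expect_true(all(design$time %in% c(10, 20, 30)))
  expect_true(all(design$temperature %in% c(25, 50, 75)))
  expect_true(all(design$ratio %in% c(10, 15, 20)))
  expect_false(anyDuplicated(design$sample_id) > 0)

  resp <- load_responses()
  expect_equal(nrow(resp), 15 * 13)
  expect_false(any(is.na(resp$mean)))
  expect_true(all(resp$sd >= 0))
  expect_equal(resp$mean[resp$sample_id == 6 & resp$response == "TPC"], 16.494)
  expect_equal(resp$mean[resp$sample_id == 15 & resp$response == "PM"], 0.740)
  expect_equal(resp$unit[resp$response == "TPC"][1], "mg GAE/g")
})

test_that("the MC cell correction is applied by default and skippable", {
  verbatim <- load_responses(corrected = FALSE)
  expect_equal(verbatim$mean[verbatim$sample_id == 15 & verbatim$response == "MC"],
               8.611)
  corrected <- load_responses()
  expect_equal(corrected$mean[corrected$sample_id == 15 & corrected$response == "MC"],
               18.611)
  # only that one cell differs
  expect_equal(sum(corrected$mean != verbatim$mean), 1)
})

test_that("design and response tables round-trip through CSV exactly", {
  design <- load_design()
  path <- withr::local_tempfile(fileext = ".csv")
  write_design(design, path)
  expect_equal(load_design(path), design)

  resp <- load_responses()
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_responses(resp, path2)
  expect_equal(load_responses(path2), resp)
})

test_that("malformed inputs are rejected with informative errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(sample_id = 1:2, time = c(10, 20),
                                  temperature = c(25, 50)), path)
  expect_error(load_design(path), "ratio")

  readr::write_csv(tibble::tibble(sample_id = c(1, 1), time = c(10, 20),
                                  temperature = c(25, 50), ratio = c(10, 15)),
                   path)
  expect_error(load_design(path), "duplicate sample_id")

  readr::write_csv(tibble::tibble(sample_id = 1:2, time = c(10, -5),
                                  temperature = c(25, 50), ratio = c(10, 15)),
                   path)
  expect_error(load_design(path), "time")

  readr::write_csv(tibble::tibble(sample_id = 1, response = "TPC",
                                  mean = 10, sd = -0.1), path)
  expect_error(load_responses(path), "negative SD")

  readr::write_csv(tibble::tibble(sample_id = 1, response = "mystery",
                                  mean = 10, sd = 0.1), path)
  expect_warning(got <- load_responses(path), "unitless")
  expect_true(is.na(got$unit[1]))

  expect_error(write_design(load_design()[0, ], path), "empty")
  expect_error(load_design("/nonexistent/file.csv"), "not found")
})

test_that("published weight bundles load with the printed values and shapes", {
  expect_error(load_published_model("ANN9"), "ANN1, ANN2, ANN3")

  ann1 <- load_published_model("ANN1")
  expect_equal(dim(ann1$parameters$W1), c(9, 3))
  expect_equal(dim(ann1$parameters$W2), c(2, 9))
  expect_equal(ann1$parameters$W1[1, 1], 1.829)  # time -> hidden neuron 1
  expect_equal(ann1$parameters$B2[1], 0.433)     # TPC output bias
  expect_equal(ann1$parameters$f_hidden, "tanh")
  expect_equal(ann1$parameters$f_output, "identity")
  expect_equal(ann1$outputs, c("TPC", "TFC"))

  ann2 <- load_published_model("ANN2")
  expect_equal(dim(ann2$parameters$W1), c(10, 3))
  expect_equal(dim(ann2$parameters$W2), c(6, 10))
  expect_equal(ann2$parameters$f_output, "tanh")

  ann3 <- load_published_model("ANN3")
  expect_equal(dim(ann3$parameters$W1), c(10, 3))
  expect_equal(dim(ann3$parameters$W2), c(5, 10))
  expect_equal(ann3$parameters$f_hidden, "logistic")
  expect_equal(ann3$parameters$f_output, "identity")
})
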