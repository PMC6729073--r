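test_that("construction validates positivity, missingness and labels", {
  expect_s3_class(dmu_data(cbind(x = 1:3), cbind(y = 0:2)), "dmu_data")
  # a negative caregiver-style count names the offending cell
  expect_error(
    dmu_data(cbind(caregivers = c(5, -3)), cbind(y = c(1, 1)),
             dmu_ids = c("a", "b")),
    "caregivers.*'b'")
  expect_error(dmu_data(cbind(x = c(1, 0)), cbind(y = c(1, 1))),
               "strictly positive")
  expect_error(dmu_data(cbind(x = c(1, NA)), cbind(y = c(1, 1))), "missing")
  expect_error(dmu_data(cbind(x = c(1, 2)), cbind(y = c(-1, 1))),
               "non-negative")
  expect_error(dmu_data(cbind(x = c(1, 2)), cbind(y = c(1, 1)),
                        dmu_ids = c("a", "a")), "duplicate")
  expect_error(dmu_data(cbind(x = c(1, 2)), cbind(y = c(1, 1)),
                        output_direction = rep("desirable", 3)),
               "every output")
})

test_that("CSV round-trip preserves numeric content exactly", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "d.csv")
  df <- data.frame(id = c("f1", "f2", "f3"),
                   assets = c(2.25, 0.5, 16), beds = c(24, 300, 80),
                   residents = c(10, 55, 7), falls = c(14.65, 0, 39.8),
                   occupancy = c(0.4, 0.9, 0.5))
  write.csv(df, f, row.names = FALSE, quote = FALSE)
  schema <- list(id = "id", inputs = c("assets", "beds"),
                 outputs = c("residents", "falls"), undesirable = "falls",
                 covariates = "occupancy")
  ds <- read_dmu_data(f, schema)
  expect_identical(ds$dmu_ids, c("f1", "f2", "f3"))
  expect_identical(unname(ds$output_direction), c("desirable", "undesirable"))
  expect_identical(ds$covariates$occupancy, df$occupancy)
  f2 <- file.path(dir, "echo.csv")
  write_dmu_data(ds, f2)
  schema2 <- schema
  schema2$id <- "dmu"       # the echo stores labels under 'dmu'
  ds2 <- read_dmu_data(f2, schema2)
  expect_identical(ds$X, ds2$X)
  expect_identical(ds$Y, ds2$Y)
})

test_that("CSV loading rejects bad files with informative errors", {
  dir <- withr::local_tempdir()
  schema <- list(inputs = "x", outputs = "y")
  expect_error(read_dmu_data(file.path(dir, "nope.csv"), schema),
               "no such file")
  f <- file.path(dir, "empty.csv")
  writeLines("x,y", f)
  expect_error(read_dmu_data(f, schema), "no data rows")
  f2 <- file.path(dir, "miss.csv")
  writeLines(c("x,z", "1,2"), f2)
  expect_error(read_dmu_data(f2, schema), "missing columns: y")
  f3 <- file.path(dir, "chr.csv")
  writeLines(c("x,y", "1,apple"), f3)
  expect_error(read_dmu_data(f3, schema), "not numeric")
})

test_that("adequacy applies the n >= 2(m+s) rule and screens correlations", {
  ds32 <- simulate_ltcf(32, seed = 3)
  a <- check_adequacy(ds32)
  expect_true(a$adequate)         # 32 >= 2 * (6 + 6)
  expect_identical(a$threshold, 24L)
  small <- dmu_data(matrix(runif(30, 1, 2), 10, 3),
                    matrix(runif(30, 1, 2), 10, 3))
  expect_false(check_adequacy(small)$adequate)   # 10 < 12
  # zero-variance input column -> NA correlation, others defined
  const <- dmu_data(cbind(a = rep(2, 5), b = 1:5), cbind(y = c(2, 4, 5, 4, 7)))
  cc <- check_adequacy(const)$correlation
  expect_true(is.na(cc["a", "y"]))
  expect_false(is.na(cc["b", "y"]))
  # purity: the dataset is untouched
  before <- unserialize(serialize(const, NULL))
  invisible(check_adequacy(const))
  expect_identical(const, before)
})

test_that("packaged published tables load with the documented shape", {
  t3 <- ltcf_table3()
  expect_identical(nrow(t3), 32L)
  expect_true(all(t3$rts %in% c("CRS", "IRS", "DRS")))
  expect_true(all(t3$te > 0 & t3$te <= 1))
  expect_setequal(t3$order, 1:32)
  # spot values from the published table
  expect_equal(t3$te[t3$dmu == 12], 0.634)
  expect_true(all(t3[t3$dmu == 1, c("te", "pte", "se", "sbm")] == 1))
  t4 <- ltcf_table4()
  expect_identical(nrow(t4), 9L)    # 8 DRS facilities + mean row
  expect_identical(sum(t4$dmu == "Mean"), 1L)
  expect_identical(nrow(ltcf_table4(include_mean = FALSE)), 8L)
  mom <- ltcf_moments()
  expect_identical(nrow(mom), 12L)
  expect_identical(sum(mom$role == "input"), 6L)
  expect_identical(sum(mom$direction == "undesirable"), 3L)
})
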