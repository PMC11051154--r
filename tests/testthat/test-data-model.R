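test_that("wide CSV round trip is lossless for values and missingness", {
  set.seed(7)
  X <- matrix(rbinom(24, 1, 0.5), 4, 6)
  RT <- matrix(round(rlnorm(24, 3, 0.5), 6), 4, 6)
  X[2, 3] <- NA; RT[2, 3] <- NA; RT[4, 1] <- NA; X[4, 1] <- NA
  ds <- test_dataset(X, RT)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  ds2 <- load_dataset(file.path(dir, "dataset_responses.csv"),
                      file.path(dir, "dataset_rts.csv"))
  expect_identical(ds2$responses, ds$responses)
  expect_identical(ds2$response_times, ds$response_times)
})

test_that("a 2x2 wide pair loads with the right shape and ids", {
  dir <- withr::local_tempdir()
  writeLines(c("person,i1,i2", "p1,1,0", "p2,0,1"), file.path(dir, "r.csv"))
  writeLines(c("person,i1,i2", "p1,10,20", "p2,30,40"), file.path(dir, "t.csv"))
  ds <- load_dataset(file.path(dir, "r.csv"), file.path(dir, "t.csv"))
  expect_equal(dim(ds), c(2L, 2L))
  expect_equal(ds$person_ids, c("p1", "p2"))
  expect_equal(ds$response_times[2, 2], 40)
})

test_that("long layout pivots and rejects duplicate records", {
  dir <- withr::local_tempdir()
  writeLines(c("person,item,response,rt", "p1,i1,1,10", "p1,i2,0,12",
               "p2,i1,1,8"), file.path(dir, "long.csv"))
  ds <- load_dataset(file.path(dir, "long.csv"), layout = "long")
  expect_equal(dim(ds), c(2L, 2L))
  expect_true(is.na(ds$responses["p2", "i2"]))
  writeLines(c("person,item,response,rt", "p1,i1,1,10", "p1,i1,0,12"),
             file.path(dir, "dup.csv"))
  expect_error(load_dataset(file.path(dir, "dup.csv"), layout = "long"),
               "duplicate")
})

test_that("validation rejects bad shapes, values and ids", {
  X <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_error(test_dataset(X, matrix(1, 3, 2)), "shape mismatch")
  expect_error(test_dataset(X, matrix(c(1, -2, 3, 4), 2, 2)), "non-positive")
  expect_error(test_dataset(matrix(2, 2, 2)), "0, 1 or NA")
  expect_error(test_dataset(X, person_covariates = data.frame(person = "zz", v = 1)),
               "unknown person")
  expect_error(
    test_dataset(X, item_covariates = data.frame(item = c("i1", "i2"),
                                                 position = c(1, 3))),
    "permutation")
})

test_that("log transform matches the published seconds conversions", {
  expect_equal(log_transform(matrix(1))[1, 1], 0)
  # mean log RTs and their second equivalents as reported for the three
  # latent classes
  expect_equal(log_transform(matrix(20.860))[1, 1], 3.038, tolerance = 1e-3)
  expect_equal(log_transform(matrix(31.375))[1, 1], 3.446, tolerance = 1e-3)
  m <- matrix(c(2.5, NA, 0.5, 4), 2, 2)
  lt <- log_transform(m)
  expect_true(is.na(lt[2, 1]))
  expect_equal(exp(unclass(lt)[!is.na(m)]), m[!is.na(m)])
  bad <- matrix(c(1, -3), 1, 2, dimnames = list("pA", c("x", "y")))
  expect_error(log_transform(bad), "pA.*y")
})
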