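test_that("window resolution follows the begin/end anchor convention", {
  expect_equal(unname(resolve_window(observation_window(0, 30), 120)),
               c(0, 30))
  expect_equal(unname(resolve_window(parse_window("-30:end"), 120)),
               c(90, 120))
  expect_equal(unname(resolve_window(parse_window("full"), 45)), c(0, 45))
  expect_error(resolve_window(parse_window("-30:end"), 20), "outside")
  expect_error(resolve_window(observation_window(30, 10), 120), "empty")
})

test_that("window string notation parses like the study notation", {
  w <- parse_window("0:30")
  expect_equal(c(w$anchor_x, w$anchor_y), c("begin", "begin"))
  expect_equal(c(w$t_x, w$t_y), c(0, 30))
  w <- parse_window("-30:end")
  expect_equal(c(w$anchor_x, w$anchor_y), c("end", "end"))
  expect_equal(c(w$t_x, w$t_y), c(-30, 0))
  expect_error(parse_window("oops"), "endpoint|a:b")
})

test_that("grid resampling bins by mean with a left-closed convention", {
  ev <- toy_events(list("s1", "p1", "hr", 0, 1),
                   list("s1", "p1", "hr", 1, 2),
                   list("s1", "p1", "hr", 2, 3),
                   list("s1", "p1", "hr", 3, 10))  # next bin
  tens <- resample_to_grid(ev, toy_surgeries("s1", 30),
                           observation_window(0, 9), 3, "hr")
  expect_equal(dim(tens$values), c(1, 1, 3))
  expect_equal(tens$values[1, 1, ], c(2, 10, NA))
  expect_equal(tens$mask[1, 1, ], c(0, 0, 1))
})

test_that("a 30-minute window at a 3-minute interval yields 10 steps", {
  ev <- toy_events(list("s1", "p1", "hr", 0, 1))
  tens <- resample_to_grid(ev, toy_surgeries("s1", 120),
                           observation_window(0, 30), 3, "hr")
  expect_equal(dim(tens$values)[3], 10)
  expect_error(resample_to_grid(ev, toy_surgeries("s1", 120),
                                observation_window(0, 2), 3, "hr"),
               "shorter")
})

test_that("composite streams concatenate member events and keep members", {
  specs <- feature_spec(c("nibp_map", "ibp_map", "map_comp"),
                        composite_of = c("", "", "nibp_map;ibp_map"))
  ev <- toy_events(list("s1", "p1", "nibp_map", 1, 80),
                   list("s1", "p1", "ibp_map", 2, 90))
  merged <- merge_composites(ev, specs)
  expect_setequal(unique(merged$feature_name),
                  c("nibp_map", "ibp_map", "map_comp"))
  tens <- resample_to_grid(merged, toy_surgeries("s1", 30),
                           observation_window(0, 3), 3,
                           c("nibp_map", "ibp_map", "map_comp"))
  expect_equal(tens$values[1, 3, 1], 85)   # concatenate then bin-mean
  expect_equal(tens$values[1, 1, 1], 80)   # members retained
  # no member observations -> composite bin missing
  ev2 <- toy_events(list("s1", "p1", "nibp_map", 20, 80))
  tens2 <- resample_to_grid(merge_composites(ev2, specs),
                            toy_surgeries("s1", 30),
                            observation_window(0, 3), 3, "map_comp")
  expect_equal(tens2$mask[1, 1, 1], 1)
})

test_that("cumulative dose channels are prefix sums starting at zero", {
  expect_equal(cumulative_doses(c(2, NA, 3)), c(2, 2, 5))
  expect_equal(cumulative_doses(c(NA, NA, NA)), c(0, 0, 0))
  expect_error(cumulative_doses(c(1, -2)), "negative")
  set.seed(4)
  doses <- ifelse(runif(20) < 0.4, NA, round(runif(20, 0, 5), 2))
  brute <- numeric(20); acc <- 0
  for (i in 1:20) {
    acc <- acc + ifelse(is.na(doses[i]), 0, doses[i]); brute[i] <- acc
  }
  expect_equal(cumulative_doses(doses), brute)
})

test_that("cumulative channels are appended from per-bin dose totals", {
  specs <- feature_spec(c("hr", "propofol"), cumulative = c(FALSE, TRUE))
  ev <- toy_events(list("s1", "p1", "propofol", 0, 2),
                   list("s1", "p1", "propofol", 1, 1),   # same bin: sum = 3
                   list("s1", "p1", "propofol", 7, 5),
                   list("s1", "p1", "hr", 0, 70))
  surg <- toy_surgeries("s1", 30)
  tens <- resample_to_grid(ev, surg, observation_window(0, 9), 3,
                           c("hr", "propofol"))
  tens <- add_cumulative_channels(tens, ev, surg, specs)
  expect_equal(tens$channel_names, c("hr", "propofol", "propofol_cum"))
  expect_equal(tens$values[1, 3, ], c(3, 3, 8))
  expect_equal(tens$mask[1, 3, ], c(0, 0, 0))  # never missing
})

test_that("missingness indicators copy the mask for flagged features only", {
  specs <- feature_spec(c("hr", "hist"), missing_indicator = c(TRUE, FALSE))
  vals <- array(NA_real_, c(1, 2, 3))
  vals[1, 1, ] <- c(NA, 5, NA)
  vals[1, 2, ] <- c(1, 1, 1)
  tens <- toy_tensor(vals[1, , ], channels = c("hr", "hist"))
  out <- add_missing_indicators(tens, specs)
  expect_equal(out$channel_names, c("hr", "hist", "hr_miss"))
  expect_equal(out$values[1, 3, ], c(1, 0, 1))
  # fully observed feature -> all-zero indicator
  tens2 <- toy_tensor(matrix(c(1, 2, 3), 1), channels = "hr")
  out2 <- add_missing_indicators(tens2, feature_spec("hr",
                                                     missing_indicator = TRUE))
  expect_equal(out2$values[1, 2, ], c(0, 0, 0))
})

test_that("imputation applies LOCF with training means for leading gaps", {
  tens <- toy_tensor(matrix(c(NA, 5, NA, 7), 1), channels = "hr")
  out <- impute(tens, list(impute_mean = c(hr = 4)))
  expect_equal(out$values[1, 1, ], c(4, 5, 5, 7))
  # fully observed series unchanged
  tens2 <- toy_tensor(matrix(1:4, 1), channels = "hr")
  expect_equal(impute(tens2, list(impute_mean = c(hr = 99)))$values[1, 1, ],
               1:4)
  # all-missing series -> training mean throughout
  tens3 <- toy_tensor(matrix(NA_real_, 1, 4), channels = "hr")
  expect_equal(impute(tens3, list(impute_mean = c(hr = 2.5)))$values[1, 1, ],
               rep(2.5, 4))
  expect_error(impute(tens, list(impute_mean = c(other = 1))), "hr")
})

test_that("imputation never alters the mask", {
  tens <- toy_tensor(matrix(c(NA, 5, NA, 7), 1), channels = "hr")
  out <- impute(tens, list(impute_mean = c(hr = 4)))
  expect_equal(out$mask, tens$mask)
})

test_that("z-scaling uses training statistics and guards zero variance", {
  set.seed(2)
  vals <- array(rnorm(5 * 2 * 6, mean = 3, sd = 2), c(5, 2, 6))
  train <- seq_tensor(vals, array(0, dim(vals)), c("a", "b"),
                      paste0("s", 1:5), 3)
  sc <- fit_scaler(train)
  scaled <- apply_scaler(impute(train, sc), sc)
  for (j in 1:2) {
    expect_equal(mean(scaled$values[, j, ]), 0, tolerance = 1e-9)
    expect_equal(stats::sd(scaled$values[, j, ]), 1, tolerance = 1e-9)
  }
  # constant channel maps to zero
  cvals <- array(7, c(2, 1, 4))
  const <- seq_tensor(cvals, array(0, dim(cvals)), "c", c("s1", "s2"), 3)
  csc <- fit_scaler(const)
  expect_true(all(apply_scaler(impute(const, csc), csc)$values == 0))
  # shifted test data standardized with train stats differs from test-fitted
  test_t <- train
  test_t$values <- train$values + 5
  by_train <- apply_scaler(impute(test_t, sc), sc)
  sc_test <- fit_scaler(test_t)
  by_test <- apply_scaler(impute(test_t, sc_test), sc_test)
  expect_gt(max(abs(by_train$values - by_test$values)), 1)
})

test_that("static features broadcast to constant-in-time channels", {
  st <- matrix(c(60, 70, 1, 0), 2, 2,
               dimnames = list(c("s1", "s2"), c("age", "asa")))
  b <- broadcast_static(st, n = 10)
  expect_equal(dim(b$values), c(2, 2, 10))
  expect_true(all(b$values[1, 1, ] == 60))
  for (t in 1:10) expect_equal(b$values[, , t], st, ignore_attr = TRUE)
})

test_that("the full pipeline is deterministic and train-fitted", {
  coh <- null_cohort()
  tr <- coh$truth$surgeries
  labels <- label_pod(coh$nudesc, tr)
  sp <- split_by_patient(labels, 0.3, seed = 1)
  specs <- feature_spec(c("hr", "nibp_map", "sef"), missing_indicator = TRUE)
  surgeries <- data.frame(surgery_id = tr$surgery_id,
                          patient_id = tr$patient_id, t_end = tr$length_min)
  run <- function() {
    prepare_sequences(coh$events, surgeries, specs, parse_window("0:30"),
                      interval_min = 3,
                      train_patient_ids = sp$train_patient_ids)
  }
  a <- run(); b <- run()
  expect_identical(a, b)
  expect_false(any(is.na(a$train$tensor$values)))
  expect_equal(dim(a$train$tensor)[2], 6)  # 3 values + 3 indicators
  # leakage guard: perturbing test-side events leaves the scaler untouched
  coh2 <- coh
  test_rows <- coh2$events$patient_id %in% sp$test_patient_ids
  coh2$events$value[test_rows] <- coh2$events$value[test_rows] + 100
  prep2 <- prepare_sequences(coh2$events, surgeries, specs,
                             parse_window("0:30"), interval_min = 3,
                             train_patient_ids = sp$train_patient_ids)
  expect_identical(prep2$scaler, a$scaler)
})

test_that("tensors round-trip through the text container", {
  dir <- withr::local_tempdir()
  set.seed(9)
  vals <- array(rnorm(3 * 2 * 4), c(3, 2, 4))
  mask <- array(rbinom(24, 1, 0.2), c(3, 2, 4))
  vals[mask == 1] <- NA
  tens <- seq_tensor(vals, mask, c("a", "b"), paste0("s", 1:3), 3)
  write_tensor(tens, file.path(dir, "t"))
  back <- read_tensor(file.path(dir, "t"))
  expect_equal(back$values, tens$values, ignore_attr = TRUE)
  expect_equal(back$mask, tens$mask, ignore_attr = TRUE)
  expect_equal(back$channel_names, tens$channel_names)
})
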