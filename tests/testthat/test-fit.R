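test_that("a perfectly explanatory regulator is found with zero error", {
  set.seed(2)
  m <- matrix(rnorm(30), 3, 10,
              dimnames = list(c("A", "B", "C"), paste0("s", 1:10)))
  act <- as_activity(m)
  fit <- fit_regulators(act, m["B", ], c(A = 1, B = 1, C = 1), size = 1)
  expect_equal(fit$selected, "B")
  expect_equal(unname(fit$beta["B"]), 1, tolerance = 1e-9)
  expect_equal(fit$beta0, 0, tolerance = 1e-9)
  expect_lt(fit$train_error, 1e-9)
})

test_that("the empty model fits the L1-optimal constant, the median", {
  set.seed(3)
  m <- matrix(rnorm(20), 2, 10,
              dimnames = list(c("A", "B"), paste0("s", 1:10)))
  y <- rexp(10)  # asymmetric so mean != median
  fit <- fit_regulators(as_activity(m), y, c(A = 1, B = 1), size = 0)
  expect_equal(length(fit$selected), 0L)
  expect_equal(fit$beta0, median(y))
  expect_equal(fit$train_error, sum(abs(y - median(y))))
})

test_that("branch and bound matches exhaustive enumeration on random instances", {
  set.seed(10)
  for (i in 1:8) {
    n <- 40; p <- 6
    X <- matrix(rnorm(n * p), n, dimnames = list(NULL, sprintf("C%d", 1:p)))
    y <- X[, 1] - 0.8 * X[, 3] + rnorm(n, sd = 0.4)
    b <- brute_best_subset(X, y, 2)
    s <- regmodule:::best_subset_lad(X, y, sizes = 2)[[1L]]
    expect_equal(s$err, b$err, tolerance = 1e-6)
  }
})

test_that("the tiny vertex-enumeration oracle agrees with the LP route", {
  set.seed(20)
  for (i in 1:5) {
    X <- matrix(rnorm(12 * 2), 12, dimnames = list(NULL, c("a", "b")))
    y <- rnorm(12)
    expect_equal(lad_oracle_err(X, y, 1:2), lad_vertex_err(X, y, 1:2),
                 tolerance = 1e-8)
  }
})

test_that("optimal training error is non-increasing in model size", {
  set.seed(4)
  n <- 50; p <- 8
  X <- matrix(rnorm(n * p), n, dimnames = list(NULL, sprintf("C%d", 1:p)))
  y <- X[, 2] + 0.5 * X[, 5] + rnorm(n)
  sols <- regmodule:::best_subset_lad(X, y, sizes = 0:5)
  errs <- vapply(sols, `[[`, numeric(1), "err")
  expect_true(all(diff(errs) <= 1e-9))
})

test_that("equally optimal subsets break ties lexicographically", {
  # duplicate column: selecting either is optimal; the alphabetically
  # earlier name must win
  set.seed(6)
  z <- rnorm(20)
  m <- rbind(zz_dup = z, aa_dup = z)
  colnames(m) <- paste0("s", 1:20)
  y <- z + rnorm(20, sd = 0.1)
  fit <- fit_regulators(as_activity(m), y, c(zz_dup = 1, aa_dup = 1), size = 1)
  expect_equal(fit$selected, "aa_dup")
})

test_that("prediction applies the edge-score-scaled linear model", {
  m <- matrix(0.5, 1, 4, dimnames = list("R", paste0("s", 1:4)))
  model <- structure(
    list(selected = "R", beta0 = 0, beta = c(R = 1), es_target = c(R = 2),
         size_limit = 1, train_error = 0, candidates = "R"),
    class = "regulator_model"
  )
  expect_equal(unname(predict(model, as_activity(m))), rep(1, 4))  # 1*2*0.5

  empty <- structure(
    list(selected = character(), beta0 = 3.2, beta = numeric(),
         es_target = numeric(), size_limit = 0, train_error = 1,
         candidates = "R"),
    class = "regulator_model"
  )
  expect_equal(unname(predict(empty, as_activity(m))), rep(3.2, 4))

  model$selected <- "MISSING"
  expect_error(predict(model, as_activity(m)), "no activity")
})

test_that("training predictions reproduce the training error", {
  set.seed(9)
  m <- matrix(rnorm(40), 4, 10,
              dimnames = list(paste0("R", 1:4), paste0("s", 1:10)))
  act <- as_activity(m)
  es <- c(R1 = 1.2, R2 = 0.7, R3 = 1, R4 = 2)
  y <- 0.5 + 1.5 * es["R2"] * m["R2", ] + rnorm(10, sd = 0.3)
  fit <- fit_regulators(act, y, es, size = 2)
  pred <- predict(fit, act)
  expect_equal(sum(abs(y - pred)), fit$train_error, tolerance = 1e-9)
})

test_that("model performance is the Pearson correlation, with guards", {
  expect_equal(model_performance(1:5, 1:5), 1)
  expect_equal(model_performance(1:5, -(1:5)), -1)
  # hand-picked 4-point vectors against the closed-form formula
  p <- c(1, 2, 4, 7); m <- c(2, 1, 5, 6)
  num <- sum((p - mean(p)) * (m - mean(m)))
  den <- sqrt(sum((p - mean(p))^2) * sum((m - mean(m))^2))
  expect_equal(model_performance(p, m), num / den)
  expect_warning(r <- model_performance(rep(1, 5), 1:5), "constant")
  expect_true(is.na(r))
  expect_error(model_performance(1:2, 1:2), "at least 3")
})

test_that("coefficients reaching big_m trigger the bound-active warning", {
  set.seed(12)
  m <- matrix(rnorm(20), 2, 10,
              dimnames = list(c("A", "B"), paste0("s", 1:10)))
  y <- 50 * m["A", ]
  expect_warning(
    fit_regulators(as_activity(m), y, c(A = 1, B = 1), size = 1, big_m = 10),
    "big_m"
  )
})

test_that("tidiers return broom-shaped tibbles", {
  set.seed(13)
  m <- matrix(rnorm(30), 3, 10,
              dimnames = list(c("A", "B", "C"), paste0("s", 1:10)))
  fit <- fit_regulators(as_activity(m), m["A", ] + rnorm(10, sd = 0.1),
                        c(A = 1, B = 1, C = 1), size = 1)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$term[1], "(Intercept)")
  expect_true("A" %in% td$term)
  gl <- glance(fit)
  expect_equal(gl$n_selected, 1L)
  expect_equal(gl$n_candidates, 3L)
})
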