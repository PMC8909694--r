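# shared toy: 4 direct + 4 indirect candidates over 40 samples
make_toy <- function(seed = 7) {
  withr::with_seed(seed, {
    n <- 40
    dir_ids <- sprintf("D%02d", 1:4)
    ind_ids <- sprintf("I%02d", 1:4)
    cands <- c(dir_ids, ind_ids)
    m <- matrix(rnorm(8 * n), 8, n, dimnames = list(cands, paste0("s", 1:n)))
    y <- m[1, ] - m[2, ] + rnorm(n, sd = 0.3)
    es <- stats::setNames(runif(4, 0.8, 1.2), dir_ids)
    W <- matrix(rnorm(64), 8)
    W <- (W + t(W)) / 2
    diag(W) <- 0
    dimnames(W) <- list(cands, cands)
  })
  list(act = as_activity(m), y = y, es = es, dir = dir_ids, ind = ind_ids,
       g = make_module_graph(W))
}

test_that("the combined objective matches exhaustive subset enumeration", {
  toy <- make_toy()
  W <- toy$g$w_mod
  brute <- function(lambda, limit) {
    best <- Inf
    Xd <- regmodule:::candidate_design(toy$act, toy$es)
    for (k in 0:limit) {
      combs <- if (k == 0) list(integer()) else asplit(utils::combn(8, k), 2L)
      for (S in combs) {
        S <- as.integer(S)
        dsel <- sort(match(intersect(rownames(W)[S], toy$dir), rownames(Xd)))
        e <- lad_oracle_err(t(Xd), toy$y, dsel)
        ms <- if (length(S) >= 2)
          sum(W[S, S][upper.tri(diag(length(S)))]) else 0
        best <- min(best, e - lambda * ms)
      }
    }
    best
  }
  for (lam in c(0, 0.5, 2)) {
    cm <- solve_combined(toy$act, toy$y, toy$es, toy$dir, toy$ind, toy$g,
                         lambda = lam, limit = 4)
    expect_equal(cm$objective, brute(lam, 4), tolerance = 1e-6)
  }
})

test_that("lambda = 0 reduces to the pure regression model", {
  for (seed in c(7, 8, 9)) {
    toy <- make_toy(seed)
    cm <- solve_combined(toy$act, toy$y, toy$es, toy$dir, toy$ind, toy$g,
                         lambda = 0, limit = 3)
    fit <- fit_regulators(toy$act, toy$y, toy$es, size = 3)
    expect_identical(cm$direct_selected, fit$selected)
    expect_length(cm$indirect_selected, 0)
    expect_equal(cm$fit_error, fit$train_error, tolerance = 1e-6)
  }
})

test_that("very large lambda reduces to the pure modularity module", {
  for (seed in c(7, 11)) {
    toy <- make_toy(seed)
    cm <- solve_combined(toy$act, toy$y, toy$es, toy$dir, toy$ind, toy$g,
                         lambda = 1e6, limit = 3)
    sm <- solve_module(toy$g, limit = 3)
    expect_setequal(c(cm$direct_selected, cm$indirect_selected), sm$selected)
    expect_equal(cm$modularity_score, sm$objective, tolerance = 1e-9)
  }
})

test_that("combined model input contracts are enforced", {
  toy <- make_toy()
  expect_error(solve_combined(toy$act, toy$y, toy$es, toy$dir, toy$ind, toy$g,
                              lambda = -1, limit = 3), "lambda")
  expect_error(solve_combined(toy$act, toy$y, toy$es, toy$dir, toy$ind, toy$g,
                              lambda = 1, limit = -2), "limit")
  expect_error(solve_combined(toy$act, toy$y, toy$es, c(toy$dir, "NEW"),
                              toy$ind, toy$g, lambda = 1, limit = 3),
               "does not span")
  raw <- structure(list(nodes = toy$g$nodes, w = toy$g$w),
                   class = "module_graph")
  expect_error(solve_combined(toy$act, toy$y, toy$es, toy$dir, toy$ind, raw,
                              lambda = 1, limit = 3), "corrected")
})

test_that("per-model selections never exceed the size budget", {
  toy <- make_toy()
  mods <- cross_validate_combined(toy$act, toy$y, toy$es, toy$dir, toy$ind,
                                  toy$g, lambda = 1, sizes = 2:4, repeats = 2,
                                  folds = 2, seed = 5)
  expect_equal(nrow(mods), 2 * 2 * 3)
  expect_true(all(mods$n_direct + mods$n_indirect <= mods$size))
})

test_that("the sweep capacity identity holds for the reference protocol", {
  expect_equal(selection_capacity(2:20, 10, 3), 6270L)
  expect_equal(selection_capacity(1, 1, 3), 3L)
})

test_that("the crossing of the count curves interpolates in log-lambda", {
  # direct 8 -> 4, indirect 6 -> 12 between lambda = 1 and 3:
  # diff goes +2 -> -8, crossing fraction 0.2, lambda* = 10^(0.2 log10 3)
  cr <- regmodule:::interpolate_crossing(c(1, 3), c(8, 4), c(6, 12))
  expect_true(cr$crossed)
  expect_equal(cr$lambda_star, 10^(0.2 * log10(3)), tolerance = 1e-12)
  expect_equal(cr$lambda_star, 1.245731, tolerance = 1e-6)

  # exact tie at a grid point is returned verbatim
  cr2 <- regmodule:::interpolate_crossing(c(1, 3, 10), c(8, 7, 2),
                                          c(6, 7, 9))
  expect_equal(cr2$lambda_star, 3)

  # no crossing: closest balance with a warning
  expect_warning(
    cr3 <- regmodule:::interpolate_crossing(c(1, 3), c(9, 8), c(2, 3)),
    "do not cross"
  )
  expect_false(cr3$crossed)
  expect_equal(cr3$lambda_star, 3)
})

test_that("the consensus module is the most frequent direct combination", {
  mk <- function(direct, indirect, perf) {
    tibble::tibble(
      repeat_id = 1L, fold = 1L, size = 4L,
      direct = list(direct), indirect = list(indirect),
      n_direct = length(direct), n_indirect = length(indirect),
      fit_error = 0, modularity_score = 0, performance = perf
    )
  }
  # {A,B} x3 beats {A,C} x2
  models <- dplyr::bind_rows(
    mk(c("A", "B"), c("X"), 0.5), mk(c("A", "B"), c("X", "Y"), 0.5),
    mk(c("B", "A"), c("Y"), 0.5),  # order must not matter
    mk(c("A", "C"), c("Z"), 0.9), mk(c("A", "C"), c("Z"), 0.9)
  )
  out <- extract_final_module(models)
  expect_setequal(out$direct, c("A", "B"))
  expect_equal(out$support, 3L)
  expect_equal(out$support_frac, 0.6)
  # indirect majority within winning models: X in 2/3 (> half), Y in 2/3
  expect_setequal(out$indirect, c("X", "Y"))

  # unanimous combination: support 100%
  uni <- dplyr::bind_rows(mk(c("A", "B"), "X", 0.5),
                          mk(c("A", "B"), "X", 0.6))
  out2 <- extract_final_module(uni)
  expect_equal(out2$support_frac, 1)
  expect_equal(out2$indirect, "X")

  # count ties break by higher mean held-out performance
  tie <- dplyr::bind_rows(mk("A", character(), 0.2),
                          mk("B", character(), 0.8))
  expect_equal(extract_final_module(tie)$direct, "B")
})
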