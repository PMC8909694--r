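test_that("pair weights average both edge directions times the correlation", {
  # identical activities (cor = 1): w = mean(es_fwd, es_bwd)
  m <- matrix(rep(c(1, 2, 3, 4), 2), 2, 4, byrow = TRUE,
              dimnames = list(c("A", "B"), paste0("s", 1:4)))
  net <- regulatory_network(tibble::tibble(
    regulator = c("A", "B"), target = c("B", "A"),
    source = "s", weight = c(0.5, 0.3)
  ))
  g <- pairwise_weights(as_activity(m), net)
  expect_equal(g$w["A", "B"], 0.4)
  expect_equal(g$w["B", "A"], 0.4)  # symmetric by construction
  expect_equal(unname(diag(g$w)), c(0, 0))

  # anti-correlated, es both 1 -> w = -1
  m2 <- rbind(A = c(1, 2, 3, 4), B = -c(1, 2, 3, 4))
  colnames(m2) <- paste0("s", 1:4)
  net2 <- regulatory_network(tibble::tibble(
    regulator = c("A", "B"), target = c("B", "A"), source = "s", weight = 1
  ))
  g2 <- pairwise_weights(as_activity(m2), net2)
  expect_equal(g2$w["A", "B"], -1)

  # no edge in either direction -> 0 even with perfect correlation
  net3 <- regulatory_network(tibble::tibble(
    regulator = "A", target = "Z", source = "s", weight = 1
  ))
  g3 <- pairwise_weights(as_activity(m), net3)
  expect_equal(g3$w["A", "B"], 0)
})

test_that("degenerate activity inputs are guarded", {
  m <- matrix(1:4, 2, 2, dimnames = list(c("A", "B"), c("s1", "s2")))
  net <- regulatory_network(tibble::tibble(
    regulator = "A", target = "B", source = "s", weight = 1
  ))
  expect_error(pairwise_weights(as_activity(m), net), "3 common samples")

  m2 <- rbind(A = c(1, 1, 1, 1), B = c(1, 2, 3, 4))
  colnames(m2) <- paste0("s", 1:4)
  expect_warning(g <- pairwise_weights(as_activity(m2), net), "constant")
  expect_equal(g$w["A", "B"], 0)
})

test_that("the Newman correction reproduces hand-computed triangle values", {
  W <- matrix(1, 3, 3) - diag(3)
  dimnames(W) <- list(c("A", "B", "C"), c("A", "B", "C"))
  g <- make_module_graph(W)
  expect_equal(unname(g$d), rep(2, 3))
  expect_equal(g$m, 3)
  expect_equal(g$w_mod["A", "B"], 1 - 4 / 6)           # 1/3
  # conservation: ordered pairs incl. self-terms sum to zero
  expect_equal(sum(g$w_mod), 0, tolerance = 1e-9)
  expect_equal(6 * (1 / 3) + 3 * (-4 / 6), 0)

  # two disconnected equal edges on 4 nodes
  W2 <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  W2["a", "b"] <- W2["b", "a"] <- 1
  W2["c", "d"] <- W2["d", "c"] <- 1
  g2 <- make_module_graph(W2)
  expect_equal(g2$m, 2)
  expect_equal(g2$w_mod["a", "b"], 1 - 1 / 4)
  expect_equal(g2$w_mod["a", "c"], -1 / 4)
  expect_equal(sum(g2$w_mod), 0, tolerance = 1e-9)

  expect_error(make_module_graph(matrix(0, 2, 2,
                                        dimnames = list(c("x", "y"),
                                                        c("x", "y")))),
               "m = 0")
})

test_that("corrected weights always conserve to zero on random graphs", {
  for (seed in 1:6) {
    g <- make_module_graph(random_weights(8, seed))
    expect_equal(sum(g$w_mod), 0, tolerance = 1e-9)
  }
})

test_that("module search matches exhaustive enumeration on random graphs", {
  for (seed in 1:10) {
    p <- sample(6:12, 1)
    g <- make_module_graph(random_weights(p, seed))
    limit <- sample(2:4, 1)
    got <- solve_module(g, limit = limit)
    want <- brute_module(g$w_mod, limit)
    expect_equal(got$objective, max(want$score, 0), tolerance = 1e-9)
  }
})

test_that("module objective is invariant under node relabeling", {
  W <- random_weights(9, 77)
  g <- make_module_graph(W)
  obj1 <- solve_module(g, limit = 4)$objective
  perm <- withr::with_seed(7, sample(9))
  W2 <- W[perm, perm]
  nd <- sprintf("Z%02d", 1:9)  # fresh names, same structure
  dimnames(W2) <- list(nd, nd)
  obj2 <- solve_module(make_module_graph(W2), limit = 4)$objective
  expect_equal(obj1, obj2, tolerance = 1e-9)
})

test_that("small-limit and structured cases behave as designed", {
  # limit 1: no pair can form, objective 0
  g <- make_module_graph(random_weights(5, 3))
  expect_equal(solve_module(g, limit = 1)$objective, 0)
  expect_error(solve_module(g, limit = -1), ">= 0")

  # two triangles joined by one negative bridge: one triangle wins
  W <- matrix(0, 6, 6, dimnames = list(LETTERS[1:6], LETTERS[1:6]))
  for (tri in list(1:3, 4:6)) {
    for (i in tri) for (j in tri) if (i != j) W[i, j] <- 1
  }
  W[3, 4] <- W[4, 3] <- -0.5
  g2 <- structure(list(nodes = LETTERS[1:6], w = W), class = "module_graph")
  g2$w_mod <- W  # uncorrected synthetic weights: score the raw structure
  out <- solve_module(g2, limit = 3)
  expect_equal(out$objective, 3)
  expect_true(setequal(out$selected, c("A", "B", "C")) ||
                setequal(out$selected, c("D", "E", "F")))
  expect_equal(nrow(out$edges), 3L)
})

test_that("module graphs export edge weights to GraphML", {
  g <- make_module_graph(random_weights(5, 8))
  path <- withr::local_tempfile(fileext = ".graphml")
  write_module_graph(g, path)
  ig <- igraph::read_graph(path, format = "graphml")
  expect_gt(igraph::ecount(ig), 0)
  expect_true(all(c("w", "w_mod") %in% igraph::edge_attr_names(ig)))
})
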