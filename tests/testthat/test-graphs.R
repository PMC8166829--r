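test_that("make_graph builds symmetric strength-correct graphs and rejects bad input", {
  expect_equal(strengths(triangle_graph()), c(2, 2, 2))
  expect_equal(strengths(path3_graph()), c(1, 3, 2))
  expect_error(make_graph(rbind(c(0, 0, 1), c(0, 1, 1))), "self-loop")
  expect_error(make_graph(rbind(c(0, 1, -2))), "non-negative")
  expect_error(make_graph(rbind(c(0, 1, 1), c(1, 0, 2))), "duplicate")
  # zero-weight edge leaves a vertex isolated
  expect_error(make_graph(rbind(c(0, 1, 1), c(1, 2, 0))), "isolated")
})

test_that("random generators emit connected graphs satisfying the invariants", {
  for (seed in 1:5) {
    for (g in list(random_graph(30, 4, seed = seed),
                   random_regular(10, 3, seed = seed),
                   scale_free(40, 6, seed = seed))) {
      expect_identical(g$w, t(g$w))
      expect_true(all(diag(g$w) == 0))
      expect_true(all(g$d > 0))
      expect_true(igraph::is_connected(
        igraph::graph_from_adjacency_matrix(g$w, mode = "undirected")))
    }
    expect_true(all(strengths(random_regular(10, 3, seed = seed)) == 3))
  }
  g <- random_graph(1000, 6, seed = 1)
  expect_lt(abs(mean(strengths(g)) - 6) / 6, 0.1)
  expect_error(random_regular(5, 3), "even")
  expect_error(random_graph(10, 9.5), "below")
})

test_that("assign_weights reweights edges without touching topology", {
  g <- random_graph(40, 5, seed = 3)
  expect_identical(assign_weights(g, "homogeneous"), g)
  gu <- assign_weights(g, "uniform_int", seed = 4)
  gz <- assign_weights(g, "zipf", seed = 5)
  for (gw in list(gu, gz)) {
    expect_identical(gw$w > 0, g$w > 0)
    expect_identical(gw$w, t(gw$w))
  }
  expect_true(all(gu$w[gu$w > 0] %in% 1:10))
  # zipf pmf ~ k^-3 is sharply decreasing: weight 1 dominates weight 5
  set.seed(6)
  draws <- sample.int(100L, 1e4, replace = TRUE,
                      prob = (1:100)^(-3) / sum((1:100)^(-3)))
  expect_gt(sum(draws == 1), 20 * sum(draws == 5))
  expect_error(assign_weights(gu, "uniform_int"), "unit-weight")
})

test_that("enumeration matches brute-force isomorphism classes for small n", {
  expect_length(enumerate_connected_graphs(2), 1)
  expect_length(enumerate_connected_graphs(3), 2)
  g4 <- enumerate_connected_graphs(4)
  expect_length(g4, 6)
  # independent oracle: pairwise-isomorphism dedup of all labeled graphs
  brute_count <- function(n) {
    pr <- which(upper.tri(diag(n)), arr.ind = TRUE)
    reps <- list()
    for (mask in seq_len(2^nrow(pr) - 1)) {
      sel <- bitwAnd(mask, bitwShiftL(1L, 0:(nrow(pr) - 1L))) != 0L
      w <- matrix(0, n, n)
      w[pr[sel, , drop = FALSE]] <- 1
      ig <- igraph::graph_from_adjacency_matrix(w + t(w), mode = "undirected")
      if (!igraph::is_connected(ig)) next
      if (!any(vapply(reps, igraph::isomorphic, TRUE, ig))) {
        reps[[length(reps) + 1L]] <- ig
      }
    }
    length(reps)
  }
  expect_equal(brute_count(3), 2)
  expect_equal(brute_count(4), 6)
  # no two members isomorphic, all unit weights, all connected
  igs <- lapply(g4, function(g)
    igraph::graph_from_adjacency_matrix(g$w, mode = "undirected"))
  for (i in 1:5) for (j in (i + 1):6) {
    expect_false(igraph::isomorphic(igs[[i]], igs[[j]]))
  }
  expect_true(all(vapply(g4, function(g) all(g$w %in% c(0, 1)), TRUE)))
  expect_error(enumerate_connected_graphs(8), "between 2 and 7")
})

test_that("edge-list files round-trip exactly and reject malformed input", {
  g <- assign_weights(random_graph(12, 3, seed = 9), "zipf", seed = 10)
  path <- withr::local_tempfile(fileext = ".edges")
  write_edgelist(g, path)
  g2 <- read_edgelist(path)
  expect_identical(g2$w, g$w)
  # header + comments tolerated; fractional weights preserved exactly
  path2 <- withr::local_tempfile()
  writeLines(c("u v w", "# triangle", "0 1 0.1", "1 2 1", "0 2 2"), path2)
  g3 <- read_edgelist(path2)
  expect_equal(strengths(g3), c(2.1, 1.1, 3))
  expect_identical(g3$w[1, 2], 0.1)
  path3 <- withr::local_tempfile()
  writeLines("0 0 1", path3)
  expect_error(read_edgelist(path3), "self-loop")
  writeLines(c("0 1 1", "0 1 2"), path3)
  expect_error(read_edgelist(path3), "duplicate")
  writeLines("0 1 x y", path3)
  expect_error(read_edgelist(path3), "malformed")
})

test_that("graph sets serialize as a directory of edge lists with an index", {
  dir <- withr::local_tempdir()
  gs <- enumerate_connected_graphs(3)
  write_graph_set(gs, dir)
  idx <- read.table(file.path(dir, "index.tsv"), header = TRUE, sep = "\t")
  expect_equal(nrow(idx), 2)
  back <- lapply(file.path(dir, idx$file), read_edgelist)
  expect_equal(lapply(back, function(g) g$w), lapply(gs, function(g) g$w))
})
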