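test_that("the aspiration chain is sparse, stochastic and neutral-correct", {
  g <- triangle_graph()
  pm <- payoff_matrix(4, 0, 5, 1)
  asp <- aspiration_scheme(2)
  fs <- builtin_update_functions()
  tm <- build_aspiration_chain(g, pm, asp, fs$g1, beta = 0.3)
  P <- as.matrix(tm$P)
  expect_equal(rowSums(P), rep(1, 8), tolerance = 1e-12)
  expect_true(all(P >= 0 & P <= 1))
  # off-diagonal mass only between states at Hamming distance one
  S <- aspiradyn:::state_matrix(3)
  for (i in 1:8) for (j in 1:8) {
    hd <- sum(S[i, ] != S[j, ])
    if (hd > 1) expect_identical(P[i, j], 0)
  }
  # neutral chain: every flip probability is g(0)/n = 1/(2n)
  P0 <- as.matrix(build_aspiration_chain(g, pm, asp, fs$g1, 0)$P)
  off <- P0[row(P0) != col(P0)]
  expect_equal(sort(unique(off[off > 0])), 1 / 6)
  # degenerate game at the aspiration point is neutral at any beta
  pm0 <- payoff_matrix(0, 0, 0, 0)
  asp0 <- aspiration_scheme(0)
  Pn <- build_aspiration_chain(two_vertex_graph(), pm0, asp0, fs$g1, 0.01)$P
  expect_equal(as.matrix(Pn),
               as.matrix(build_aspiration_chain(two_vertex_graph(), pm0,
                                                asp0, fs$g1, 0)$P))
})

test_that("neutral stationary distribution is uniform with the exact strategy moments", {
  setups <- list(
    list(g = triangle_graph(), fs = builtin_update_functions()$g5),
    list(g = random_graph(5, 2.5, seed = 8),
         fs = unname(builtin_update_functions()[c(1, 3, 6, 2, 4)])))
  for (su in setups) {
    n <- su$g$n
    tm <- build_aspiration_chain(su$g, payoff_matrix(4, 0, 5, 1),
                                 aspiration_scheme(1.3), su$fs, 0)
    st <- stationary(tm)
    expect_lt(max(abs(st$u - 2^(-n))), 1e-12)
    expect_equal(st$mean_xA, 0.5)
    expect_lt(st$residual, 1e-10)
    S <- aspiradyn:::state_matrix(n)
    first <- as.vector(st$u %*% S)
    expect_equal(first, rep(1 / 2, n))
    second <- t(S) %*% (st$u * S)
    expect_equal(as.matrix(second), (1 + diag(n)) / 4, ignore_attr = TRUE)
  }
})

test_that("closed-form c equals the resolvent oracle and the hand-solved cases", {
  fs <- builtin_update_functions()
  # with g1 (g(0) = 1/2), c counts A-players minus B-players
  cc <- c_vector_closed(fs$g1, 2)
  expect_equal(cc, c(-2, 0, 0, 2))
  # exhaustive: every connected graph on 2..4 vertices, random fs mixes
  set.seed(11)
  for (n in 2:4) {
    for (g in enumerate_connected_graphs(n)) {
      fsl <- unname(fs[sample(6, n, replace = TRUE)])
      tm0 <- build_aspiration_chain(g, payoff_matrix(3, 1, 0, 2),
                                    aspiration_scheme(runif(n, 0, 5)), fsl, 0)
      expect_equal(c_vector_oracle(tm0), c_vector_closed(fsl, n),
                   tolerance = 1e-10)
    }
  }
  # defining equation: (I - P0) c recovers (2x - 1) minus its mean
  g <- random_graph(4, 2, seed = 12)
  tm0 <- build_aspiration_chain(g, payoff_matrix(1, 0, 0, 1),
                                aspiration_scheme(1), fs$g2, 0)
  cv <- c_vector_oracle(tm0)
  x <- rowMeans(aspiradyn:::state_matrix(4))
  resid <- as.vector((Matrix::Diagonal(16) - tm0$P) %*% cv) - (2 * x - 1)
  expect_lt(max(abs(resid - mean(resid))), 1e-10)
  # precondition: u0^T (2x - 1) must vanish
  expect_error(c_vector_oracle(tm0, x = rep(1, 16)), "precondition")
})

test_that("dP/dbeta matches a finite-difference derivative of the chain", {
  su <- random_setup6(21)
  pm <- payoff_matrix(7, 0, 5, 1)
  D <- as.matrix(dP_dbeta(su$g, pm, su$asp, su$fs))
  expect_equal(rowSums(D), rep(0, 64), tolerance = 1e-12)
  # one-sided Richardson difference (beta cannot go negative), O(h^2)
  h <- 1e-5
  P0 <- as.matrix(build_aspiration_chain(su$g, pm, su$asp, su$fs, 0)$P)
  P1 <- as.matrix(build_aspiration_chain(su$g, pm, su$asp, su$fs, h)$P)
  P2 <- as.matrix(build_aspiration_chain(su$g, pm, su$asp, su$fs, 2 * h)$P)
  num <- 2 * (P1 - P0) / h - (P2 - P0) / (2 * h)
  expect_lt(max(abs(num - D)), 1e-6)
  # a game pinned to the aspiration point has zero derivative
  flat <- payoff_matrix(2, 2, 2, 2)
  D0 <- dP_dbeta(su$g, flat, aspiration_scheme(2),
                 builtin_update_functions()$g1)
  expect_equal(max(abs(D0)), 0)
})

test_that("weak-selection margin agrees with the satisfaction closed form", {
  # margin = (1/(4n)) * sum_l g_l'(0)/g_l(0) * (a + b - c - d), graph-free
  set.seed(31)
  games <- list(payoff_matrix(7.5, 0, 5, 1), payoff_matrix(1, 2, 6, 0.5),
                payoff_matrix(-1, 3, 2, 0))
  for (seed in c(101, 202)) {
    su <- random_setup6(seed)
    ratio <- sum(vapply(su$fs, function(f)
      attr(f, "gprime0") / attr(f, "g0"), 0))
    for (pm in games) {
      r <- weak_selection_margin(su$g, pm, su$asp, su$fs)
      expect_equal(r$margin, ratio * (pm$a + pm$b - pm$c - pm$d) / 24)
      expect_equal(r$h_mean, r$margin, tolerance = 1e-12)
    }
  }
  # balanced game: a + b = c + d gives a tie
  su <- random_setup6(7)
  r0 <- weak_selection_margin(su$g, payoff_matrix(4, 2, 5, 1), su$asp, su$fs)
  expect_equal(r0$margin, 0, tolerance = 1e-14)
  expect_identical(r0$winner, "tie")
  # a > 6 with b=0, c=5, d=1: A prevails on any graph and any fs
  r1 <- weak_selection_margin(su$g, payoff_matrix(8, 0, 5, 1), su$asp, su$fs)
  expect_identical(r1$winner, "A")
})

test_that("the margin is invariant to the graph and to permuting update functions", {
  fs <- mixed_fs6()
  asp <- aspiration_scheme(c(0.4, 3, 1.2, 5, 2.2, 0))
  pm <- payoff_matrix(7.1, 0, 5, 1)
  margins <- vapply(c(51, 52, 53), function(seed) {
    weak_selection_margin(random_setup6(seed)$g, pm, asp, fs)$margin
  }, 0)
  expect_lt(diff(range(margins)), 1e-14)
  set.seed(33)
  base <- weak_selection_margin(cycle6_graph(), pm, asp, fs)$margin
  for (r in 1:5) {
    perm <- sample(6)
    expect_equal(weak_selection_margin(cycle6_graph(), pm, asp,
                                       fs[perm])$margin, base)
  }
})

test_that("first-order prediction sign-matches the finite-beta exact chain", {
  set.seed(61)
  for (seed in c(71, 72, 73)) {
    su <- random_setup6(seed)
    for (a in c(4, 8)) {
      pm <- payoff_matrix(a, 0, 5, 1)
      m <- weak_selection_margin(su$g, pm, su$asp, su$fs)$margin
      for (beta in c(0.001, 0.01)) {
        xa <- exact_abundance(su$g, pm, su$asp, su$fs, beta)
        expect_equal(sign(xa - 0.5), sign(m))
      }
    }
  }
})

test_that("exact abundance is 1/2 at neutrality and under full symmetry, monotone in a", {
  su <- random_setup6(81)
  pm <- payoff_matrix(3, 0, 5, 1)
  expect_equal(exact_abundance(su$g, pm, su$asp, su$fs, 0), 0.5)
  # symmetric game with equal aspirations: A and B are relabelings
  sym <- payoff_matrix(2, 3, 3, 2)
  expect_equal(exact_abundance(su$g, sym, aspiration_scheme(1),
                               builtin_update_functions()$g1, 0.05), 0.5)
  grid <- seq(2, 10, by = 2)
  xa <- vapply(grid, function(a)
    exact_abundance(su$g, payoff_matrix(a, 0, 5, 1),
                    aspiration_scheme(2), builtin_update_functions()$g1,
                    0.01), 0)
  expect_true(all(diff(xa) > 0))
})

test_that("weak-selection reports serialize to JSON", {
  su <- random_setup6(91)
  r <- weak_selection_margin(su$g, payoff_matrix(7, 0, 5, 1), su$asp, su$fs)
  js <- jsonlite::fromJSON(report_json(r))
  expect_equal(js$margin, r$margin)
  expect_identical(js$winner, "A")
})
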