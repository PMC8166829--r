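#' Imitation-based comparison dynamics
#'
#' Specification of an imitation update rule with symmetric mutation, used
#' as the contrast class to aspiration dynamics:
#' \itemize{
#'   \item `pairwise_comparison`: the focal individual `l` (picked uniformly)
#'     samples a neighbor `j` with probability `w_lj / d_l` and adopts `j`'s
#'     strategy with probability `f_l(beta * (pi_j - pi_l))` (Fermi-type
#'     rule when `f` is the logistic function);
#'   \item `death_birth`: the focal individual dies and is replaced by a
#'     neighbor's strategy sampled proportionally to `w_lj * F_j` with
#'     fitness `F_j = exp(beta * pi_j)`.
#' }
#' With probability `mu` the updating individual instead adopts a uniformly
#' random strategy (symmetric mutation).
#'
#' @param rule `"pairwise_comparison"` or `"death_birth"`.
#' @param mu mutation probability per update event, in `[0, 1]`.
#' @param beta selection intensity.
#' @param fs comparison function(s) for the pairwise rule (defaults to the
#'   logistic `g1`); ignored by death-birth.
#' @param payoff_mode `"average"` or `"accumulated"`.
#' @return An object of class `imitation_model`.
#' @export
imitation_model <- function(rule = c("pairwise_comparison", "death_birth"),
                            mu = 0, beta = 0.01, fs = NULL,
                            payoff_mode = c("average", "accumulated")) {
  rule <- match.arg(rule)
  payoff_mode <- match.arg(payoff_mode)
  if (mu < 0 || mu > 1) stop("mu must lie in [0, 1]")
  if (beta < 0) stop("beta must be non-negative")
  if (is.null(fs) && rule == "pairwise_comparison") {
    fs <- builtin_update_functions()$g1
  }
  structure(list(rule = rule, mu = mu, beta = beta, fs = fs,
                 payoff_mode = payoff_mode),
            class = "imitation_model")
}

#' @export
print.imitation_model <- function(x, ...) {
  cat(sprintf("imitation_model: %s, mu = %g, beta = %g\n",
              x$rule, x$mu, x$beta))
  invisible(x)
}

#' Transition matrix of an imitation rule
#'
#' Full `2^n x 2^n` chain of the imitation dynamics described in
#' [imitation_model()]. Off-diagonal transitions connect states at Hamming
#' distance one; with `mu = 0` the two monomorphic states are absorbing.
#'
#' @param g a [weighted_graph()].
#' @param pm a [payoff_matrix()].
#' @param model an [imitation_model()].
#' @return A `transition_model`.
#' @export
build_imitation_chain <- function(g, pm, model) {
  stopifnot(inherits(model, "imitation_model"))
  n <- g$n
  if (n > 16) stop("state space 2^n too large for the imitation chain")
  S <- state_matrix(n)
  M <- nrow(S)
  Pi <- state_payoffs(g, pm, model$payoff_mode, S)
  flip <- matrix(0, M, n)
  if (model$rule == "pairwise_comparison") {
    fs <- as_update_list(model$fs, n)
    for (l in seq_len(n)) {
      acc <- numeric(M)
      for (j in which(g$w[l, ] > 0)) {
        differ <- S[, j] != S[, l]
        acc <- acc + (g$w[l, j] / g$d[l]) * differ *
          fs[[l]](model$beta * (Pi[, j] - Pi[, l]))
      }
      flip[, l] <- acc
    }
  } else { # death_birth
    for (l in seq_len(n)) {
      nbrs <- which(g$w[l, ] > 0)
      Fw <- sapply(nbrs, function(j) g$w[l, j] * exp(model$beta * Pi[, j]))
      tot <- rowSums(Fw)
      differ <- sapply(nbrs, function(j) as.numeric(S[, j] != S[, l]))
      flip[, l] <- rowSums(Fw * differ) / tot
    }
  }
  flip <- (model$mu / 2 + (1 - model$mu) * flip) / n
  jj <- vapply(seq_len(n), function(l) flip_index(n, l), integer(M))
  P <- Matrix::sparseMatrix(
    i = c(rep(seq_len(M), n), seq_len(M)),
    j = c(as.vector(jj), seq_len(M)),
    x = c(as.vector(flip), 1 - rowSums(flip)),
    dims = c(M, M))
  structure(list(P = P, beta = model$beta, n = n, rule = model$rule,
                 mu = model$mu, payoff_mode = model$payoff_mode),
            class = "transition_model")
}

#' Fixation probability of a single A mutant
#'
#' Absorption probability into the all-A state from a single A-player,
#' computed exactly by a linear solve on the absorbing chain (`mu` must be
#' 0). At neutrality (`beta = 0`) the vertex-averaged fixation probability
#' is exactly `1/n` for both rules (the conserved quantity of the weighted
#' voter model is the strength-weighted strategy sum).
#'
#' @param g a [weighted_graph()].
#' @param pm a [payoff_matrix()].
#' @param model an [imitation_model()] with `mu = 0`.
#' @param initial `"average"` for the vertex-averaged single-mutant
#'   probability, or a vertex index.
#' @return List with `rho_per_vertex` (length `n`) and `rho_mean` (or the
#'   requested vertex's value in `rho_mean` when `initial` is a vertex).
#' @export
fixation_probability <- function(g, pm, model, initial = "average") {
  stopifnot(inherits(model, "imitation_model"))
  if (model$mu != 0) stop("fixation probabilities require mu = 0")
  n <- g$n
  M <- 2^n
  P <- as.matrix(build_imitation_chain(g, pm, model)$P)
  allB <- 1L
  allA <- M
  if (abs(P[allA, allA] - 1) > 1e-12 || abs(P[allB, allB] - 1) > 1e-12) {
    stop("monomorphic states are not absorbing")
  }
  trans <- setdiff(seq_len(M), c(allA, allB))
  A <- diag(length(trans)) - P[trans, trans]
  h <- solve(A, P[trans, allA])
  rho <- numeric(n)
  for (l in seq_len(n)) {
    rho[l] <- h[match(2^(l - 1) + 1L, trans)]
  }
  rho_mean <- if (identical(initial, "average")) mean(rho) else rho[initial]
  list(rho_per_vertex = rho, rho_mean = rho_mean)
}

#' Critical payoff a* under an imitation rule
#'
#' Finds the `a` (at fixed `b, c, d`) where the imitation dynamics stop
#' favoring strategy B and start favoring A, by bisection with one of two
#' success criteria:
#' \itemize{
#'   \item `rare_mutation`: root of `rho_A(a) - rho_B(a)` (vertex-averaged
#'     single-mutant fixation probabilities at `mu = 0`, `rho_B` via
#'     strategy relabeling), the mu -> 0 success criterion;
#'   \item `small_mu_stationary`: root of `<x_A> - 1/2` in the stationary
#'     distribution of the chain with a small explicit mutation rate
#'     (`mu = 1e-3`).
#' }
#'
#' @param g a [weighted_graph()].
#' @param b,c,d fixed payoffs.
#' @param model an [imitation_model()].
#' @param method success criterion (see above).
#' @param bracket_half half-width of the bisection bracket around the
#'   risk-dominance value `c + d - b`.
#' @param tol bisection tolerance on `a`.
#' @param mu_small mutation rate for the `small_mu_stationary` method.
#' @return Critical `a`, or `NA` (with a warning) when the success margin
#'   has no sign change in the bracket.
#' @export
critical_a_imitation <- function(g, b, c, d, model,
                                 method = c("rare_mutation", "small_mu_stationary"),
                                 bracket_half = 8, tol = 1e-3,
                                 mu_small = 1e-3) {
  method <- match.arg(method)
  center <- c + d - b
  if (method == "rare_mutation") {
    m <- model
    m$mu <- 0
    f <- function(a) {
      rA <- fixation_probability(g, payoff_matrix(a, b, c, d), m)$rho_mean
      rB <- fixation_probability(g, payoff_matrix(d, c, b, a), m)$rho_mean
      rA - rB
    }
  } else {
    m <- model
    m$mu <- mu_small
    f <- function(a) {
      stationary(build_imitation_chain(g, payoff_matrix(a, b, c, d), m))$mean_xA - 0.5
    }
  }
  lo <- center - bracket_half
  hi <- center + bracket_half
  flo <- f(lo); fhi <- f(hi)
  if (flo >= 0 || fhi <= 0) {
    warning("no sign change of the success margin in the bracket")
    return(NA_real_)
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
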