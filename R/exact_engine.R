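#' Full transition matrix of aspiration dynamics
#'
#' Builds the `2^n x 2^n` row-stochastic transition matrix of the
#' aspiration-update Markov chain on a graph: at each step a uniformly
#' random individual `l` may flip, so the only off-diagonal transitions are
#' between states at Hamming distance one, with probability
#' `(1/n) * f_l(beta * (alpha_l - pi_l(s)))`.
#'
#' @param g a [weighted_graph()].
#' @param pm a [payoff_matrix()].
#' @param asp an [aspiration_scheme()].
#' @param fs one [update_function()] shared by all, or a list of `n`.
#' @param beta selection intensity (`beta = 0` is neutral drift).
#' @param payoff_mode `"average"` or `"accumulated"`.
#' @return An object of class `transition_model`: list with the sparse
#'   matrix `P`, `beta`, `n`, and `rule = "aspiration"`.
#' @export
build_aspiration_chain <- function(g, pm, asp, fs, beta,
                                   payoff_mode = c("average", "accumulated")) {
  payoff_mode <- match.arg(payoff_mode)
  if (beta < 0) stop("beta must be non-negative")
  n <- g$n
  fs <- as_update_list(fs, n)
  S <- state_matrix(n)
  M <- nrow(S)
  Pi <- state_payoffs(g, pm, payoff_mode, S)
  Alpha <- aspiration_levels(asp, S)
  flip <- matrix(0, M, n)
  for (l in seq_len(n)) {
    flip[, l] <- fs[[l]](beta * (Alpha[, l] - Pi[, l])) / n
  }
  if (any(flip < 0) || any(flip > 1 / n)) {
    stop("invalid update function: switching probability outside [0, 1]")
  }
  jj <- vapply(seq_len(n), function(l) flip_index(n, l), integer(M))
  P <- Matrix::sparseMatrix(
    i = c(rep(seq_len(M), n), seq_len(M)),
    j = c(as.vector(jj), seq_len(M)),
    x = c(as.vector(flip), 1 - rowSums(flip)),
    dims = c(M, M))
  structure(list(P = P, beta = beta, n = n, rule = "aspiration",
                 payoff_mode = payoff_mode),
            class = "transition_model")
}

#' @export
print.transition_model <- function(x, ...) {
  cat(sprintf("transition_model (%s): %d states, beta = %g\n",
              x$rule, nrow(x$P), x$beta))
  invisible(x)
}

#' Stationary distribution of a transition model
#'
#' Solves `u^T P = u^T`, `sum(u) = 1` exactly by replacing one equation of
#' the singular system `(P^T - I) u = 0` with the normalization row (dense
#' LU for up to 4096 states, sparse LU beyond). The chain of aspiration
#' dynamics is irreducible and aperiodic whenever every `g_l(0) > 0`, so
#' the solution is unique.
#'
#' @param tm a `transition_model` (or a bare matrix).
#' @return An object of class `stationary_result`: list with `u`,
#'   `mean_xA`, `mean_xB`, and the fixed-point `residual`
#'   `max |u^T P - u^T|`.
#' @export
stationary <- function(tm) {
  P <- if (inherits(tm, "transition_model")) tm$P else tm
  M <- nrow(P)
  n <- as.integer(round(log2(M)))
  if (M <= 4096) {
    A <- t(as.matrix(P)) - diag(M)
    A[M, ] <- 1
    u <- solve(A, c(rep(0, M - 1), 1))
  } else {
    A <- Matrix::t(P) - Matrix::Diagonal(M)
    A[M, ] <- 1
    u <- as.vector(Matrix::solve(A, c(rep(0, M - 1), 1)))
  }
  if (any(u < -1e-12)) stop("stationary solve produced negative probabilities")
  u <- pmax(u, 0)
  u <- u / sum(u)
  residual <- max(abs(as.vector(u %*% P) - u))
  if (residual > 1e-8) stop("stationary solve ill-conditioned: residual ", residual)
  xA <- rowMeans(state_matrix(n))
  mean_xA <- sum(u * xA)
  structure(list(u = u, mean_xA = mean_xA, mean_xB = 1 - mean_xA,
                 residual = residual),
            class = "stationary_result")
}

#' @export
print.stationary_result <- function(x, ...) {
  cat(sprintf("stationary_result: <x_A> = %.8g, residual = %.2g\n",
              x$mean_xA, x$residual))
  invisible(x)
}

#' Mean abundance of strategy A at finite selection intensity
#'
#' Convenience wrapper: builds the aspiration chain at `beta` and returns
#' the stationary mean frequency of A. At `beta = 0` this is exactly 1/2.
#'
#' @inheritParams build_aspiration_chain
#' @return `<x_A>` as a single number.
#' @export
exact_abundance <- function(g, pm, asp, fs, beta,
                            payoff_mode = c("average", "accumulated")) {
  stationary(build_aspiration_chain(g, pm, asp, fs, beta, payoff_mode))$mean_xA
}

#' Accumulated abundance-difference vector c
#'
#' `c_vector_closed()` evaluates the closed form
#' `c_i = sum_l (2 s_i(l) - 1) / (2 g_l(0))`, which exists because at
#' neutrality individuals update independently, so the `2^n`-state chain
#' factorizes into `n` two-state chains. `c_vector_oracle()` is its
#' brute-force twin: it sums the series `sum_k P0^k (2x - 1)` by solving
#' the resolvent system `(I - P0 + 1 u0^T) c = 2x - 1` on the full chain,
#' requiring the neutral-balance precondition `u0^T (2x - 1) = 0`.
#'
#' @param fs an [update_function()] or list of `n` of them.
#' @param n population size.
#' @param P0 neutral transition matrix (a `transition_model` built at
#'   `beta = 0`, or a bare matrix).
#' @param x frequency of A in each state (defaults to `rowMeans` of the
#'   state matrix).
#' @return Numeric vector of length `2^n`.
#' @export
c_vector_closed <- function(fs, n) {
  fs <- as_update_list(fs, n)
  g0 <- vapply(fs, g_at_zero, 0)
  S <- state_matrix(n)
  as.vector((2 * S - 1) %*% (1 / (2 * g0)))
}

#' @rdname c_vector_closed
#' @export
c_vector_oracle <- function(P0, x = NULL) {
  P <- if (inherits(P0, "transition_model")) P0$P else P0
  P <- as.matrix(P)
  M <- nrow(P)
  n <- as.integer(round(log2(M)))
  if (is.null(x)) x <- rowMeans(state_matrix(n))
  u0 <- stationary(P)$u
  b <- 2 * x - 1
  if (abs(sum(u0 * b)) > 1e-10) {
    stop("precondition violated: u0^T (2x - 1) != 0, the series diverges")
  }
  A <- diag(M) - P + outer(rep(1, M), u0)
  as.vector(solve(A, b))
}

#' Derivative of the transition matrix at beta = 0
#'
#' Analytic `P0' = dP/dbeta` at `beta = 0`: the entry for flipping
#' individual `l` in state `s` is `(1/n) * g_l'(0) * (alpha_l - pi_l(s))`
#' and the diagonal is minus the row sum (rows of a stochastic family
#' differentiate to zero-sum rows).
#'
#' @inheritParams build_aspiration_chain
#' @return Sparse `2^n x 2^n` matrix with zero row sums.
#' @export
dP_dbeta <- function(g, pm, asp, fs,
                     payoff_mode = c("average", "accumulated")) {
  payoff_mode <- match.arg(payoff_mode)
  n <- g$n
  fs <- as_update_list(fs, n)
  S <- state_matrix(n)
  M <- nrow(S)
  Pi <- state_payoffs(g, pm, payoff_mode, S)
  Alpha <- aspiration_levels(asp, S)
  gp <- vapply(fs, gprime_at_zero, 0)
  val <- matrix(0, M, n)
  for (l in seq_len(n)) {
    val[, l] <- gp[l] * (Alpha[, l] - Pi[, l]) / n
  }
  jj <- vapply(seq_len(n), function(l) flip_index(n, l), integer(M))
  Matrix::sparseMatrix(
    i = c(rep(seq_len(M), n), seq_len(M)),
    j = c(as.vector(jj), seq_len(M)),
    x = c(as.vector(val), -rowSums(val)),
    dims = c(M, M))
}

#' Weak-selection margin and predicted winner
#'
#' First-order perturbation of the stationary abundance difference around
#' neutrality: strategy A prevails over B under weak selection iff
#' `u0^T P0' c > 0`. The margin is computed twice, through independent code
#' paths that must agree to 1e-9 relative:
#' \itemize{
#'   \item matrix route: assemble `P0'` ([dP_dbeta()]) and `c`
#'     ([c_vector_closed()]) and contract with the uniform neutral
#'     distribution `u0 = 2^-n 1`;
#'   \item closed-form route: average the per-state satisfaction statistic
#'     `h(s) = (1/n) sum_l (g_l'(0)/g_l(0)) [(1 - 2 s_l) alpha_l(s) +
#'     (2 s_l - 1) pi_l(s)]` over the uniform neutral distribution.
#' }
#' For symmetric aspirations both reduce to
#' `(1/(4n)) (sum_l g_l'(0)/g_l(0)) (a + b - c - d)`, the risk-dominance
#' condition; strategy-contingent aspirations add `2(alpha_B - alpha_A)`
#' inside the bracket.
#'
#' @inheritParams build_aspiration_chain
#' @return Object of class `weak_selection_report`: list with `margin`,
#'   `h_mean`, `winner` (`"A"`, `"B"` or `"tie"`), the `c` vector, and a
#'   parameter echo.
#' @export
weak_selection_margin <- function(g, pm, asp, fs,
                                  payoff_mode = c("average", "accumulated")) {
  payoff_mode <- match.arg(payoff_mode)
  n <- g$n
  fs <- as_update_list(fs, n)
  M <- 2^n
  # route 1: u0^T P0' c by explicit matrix algebra
  P0p <- dP_dbeta(g, pm, asp, fs, payoff_mode)
  cv <- c_vector_closed(fs, n)
  u0 <- rep(1 / M, M)
  margin <- as.numeric(u0 %*% (P0p %*% cv))
  # route 2: enumeration of the closed-form h(s)
  S <- state_matrix(n)
  Pi <- state_payoffs(g, pm, payoff_mode, S)
  Alpha <- aspiration_levels(asp, S)
  gp <- vapply(fs, gprime_at_zero, 0)
  g0 <- vapply(fs, g_at_zero, 0)
  h <- as.vector(((1 - 2 * S) * Alpha + (2 * S - 1) * Pi) %*% (gp / g0)) / n
  h_mean <- mean(h)
  scale <- max(1, abs(margin), abs(h_mean))
  if (abs(margin - h_mean) > 1e-9 * scale) {
    stop("internal consistency failure: matrix route and closed-form route ",
         "disagree (", margin, " vs ", h_mean, ")")
  }
  tol <- 1e-12 * max(1, abs(margin))
  winner <- if (margin > tol) "A" else if (margin < -tol) "B" else "tie"
  structure(list(margin = margin, h_mean = h_mean, winner = winner, c = cv,
                 params = list(pm = unclass(pm), aspiration = unclass(asp),
                               n = n, payoff_mode = payoff_mode)),
            class = "weak_selection_report")
}

#' @export
print.weak_selection_report <- function(x, ...) {
  cat(sprintf("weak_selection_report: margin = %.8g -> %s\n",
              x$margin, if (x$winner == "tie") "tie" else
                paste("strategy", x$winner, "prevails")))
  invisible(x)
}

#' Serialize a weak-selection report to JSON
#'
#' @param report a `weak_selection_report`.
#' @param path optional file; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "weak_selection_report"))
  obj <- list(margin = report$margin, h_mean = report$h_mean,
              winner = report$winner, params = report$params)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
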