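condition_result <- function(winner, lhs, rhs, critical_a) {
  structure(list(winner = winner, lhs = lhs, rhs = rhs,
                 critical_a = critical_a),
            class = "condition_result")
}

#' @export
print.condition_result <- function(x, ...) {
  cat(sprintf("condition_result: %s  (lhs %.6g vs rhs %.6g, a* = %.6g)\n",
              if (x$winner == "tie") "tie" else
                paste("strategy", x$winner, "prevails"),
              x$lhs, x$rhs, x$critical_a))
  invisible(x)
}

winner_from <- function(lhs, rhs) {
  if (lhs > rhs) "A" else if (lhs < rhs) "B" else "tie"
}

#' Closed-form strategy-success conditions
#'
#' Under weak selection and symmetric (strategy-independent) aspirations,
#' strategy A prevails over B iff `a + b > c + d` — the classical
#' risk-dominance condition, independent of the weighted graph, the
#' aspiration levels and the update functions. When aspirations are
#' contingent on the strategy in use, the condition shifts to
#' `a + b > c + d - 2 (alpha_B - alpha_A)`.
#'
#' @param pm a [payoff_matrix()].
#' @param alpha_A,alpha_B aspirations of A-players and B-players.
#' @return A `condition_result` with `winner`, the two sides of the
#'   inequality, and the critical payoff `critical_a` at fixed `b, c, d`.
#' @examples
#' symmetric_condition(payoff_matrix(7, 0, 5, 1)) # A prevails, a* = 6
#' @export
symmetric_condition <- function(pm) {
  stopifnot(inherits(pm, "payoff_matrix"))
  condition_result(winner_from(pm$a + pm$b, pm$c + pm$d),
                   pm$a + pm$b, pm$c + pm$d,
                   pm$c + pm$d - pm$b)
}

#' @rdname symmetric_condition
#' @export
asymmetric_condition <- function(pm, alpha_A, alpha_B) {
  stopifnot(inherits(pm, "payoff_matrix"))
  rhs <- pm$c + pm$d - 2 * (alpha_B - alpha_A)
  condition_result(winner_from(pm$a + pm$b, rhs), pm$a + pm$b, rhs,
                   pm$c + pm$d - pm$b - 2 * (alpha_B - alpha_A))
}

#' Critical payoff a*
#'
#' The value of `a` (at fixed `b, c, d`) above which strategy A prevails:
#' `a* = c + d - b` for symmetric aspirations,
#' `a* = c + d - b - 2 (alpha_B - alpha_A)` for strategy-contingent ones.
#'
#' @param b,c,d fixed payoffs.
#' @param scheme `"symmetric"` or `"strategy_contingent"`.
#' @param alpha_A,alpha_B aspirations (contingent scheme only).
#' @return The critical payoff value.
#' @examples
#' critical_a(0, 5, 1) # 6
#' @export
critical_a <- function(b, c, d, scheme = c("symmetric", "strategy_contingent"),
                       alpha_A = NULL, alpha_B = NULL) {
  scheme <- match.arg(scheme)
  if (scheme == "symmetric") return(c + d - b)
  if (is.null(alpha_A) || is.null(alpha_B)) {
    stop("strategy_contingent scheme needs alpha_A and alpha_B")
  }
  c + d - b - 2 * (alpha_B - alpha_A)
}

#' Critical a from the weak-selection margin
#'
#' The margin is affine in `a` at fixed `b, c, d`; its root is found
#' exactly from two probes (`a = 0` and `a = 1`).
#'
#' @param g a [weighted_graph()].
#' @param b,c,d fixed payoffs.
#' @param asp an [aspiration_scheme()].
#' @param fs update function(s).
#' @param payoff_mode `"average"` or `"accumulated"`.
#' @return Critical `a` where the margin changes sign.
#' @export
critical_a_margin <- function(g, b, c, d, asp, fs,
                              payoff_mode = c("average", "accumulated")) {
  payoff_mode <- match.arg(payoff_mode)
  m0 <- weak_selection_margin(g, payoff_matrix(0, b, c, d), asp, fs,
                              payoff_mode)$margin
  m1 <- weak_selection_margin(g, payoff_matrix(1, b, c, d), asp, fs,
                              payoff_mode)$margin
  if (m1 == m0) stop("margin does not depend on a; no crossing")
  -m0 / (m1 - m0)
}

#' Critical a from finite-beta stationary crossings
#'
#' Locates the root of `<x_A>(a) - 1/2` on the exact chain at finite
#' selection intensity by bisection. `<x_A>` is monotone increasing in `a`
#' in this regime; the bracket endpoints are checked before bisecting.
#'
#' @inheritParams critical_a_margin
#' @param beta selection intensity of the exact chain.
#' @param half_width half-width of the bisection bracket around the
#'   closed-form prediction.
#' @param tol bisection tolerance on `a`.
#' @return Critical `a` at this `beta`.
#' @export
critical_a_crossing <- function(g, b, c, d, asp, fs, beta = 0.01,
                                half_width = 5, tol = 1e-4,
                                payoff_mode = c("average", "accumulated")) {
  payoff_mode <- match.arg(payoff_mode)
  center <- if (asp$mode == "personalized") {
    critical_a(b, c, d)
  } else {
    critical_a(b, c, d, "strategy_contingent",
               alpha_A = asp$alpha[["A"]], alpha_B = asp$alpha[["B"]])
  }
  f <- function(a) {
    exact_abundance(g, payoff_matrix(a, b, c, d), asp, fs, beta,
                    payoff_mode) - 0.5
  }
  lo <- center - half_width
  hi <- center + half_width
  flo <- f(lo); fhi <- f(hi)
  if (flo >= 0 || fhi <= 0) {
    stop("no sign change of <x_A> - 1/2 in the bracket; ",
         "monotonicity precondition violated")
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Extract the structure coefficient sigma
#'
#' The weak-selection success condition of any dynamics whose margin is
#' linear in the payoff entries can be written `sigma a + b > c + sigma d`.
#' The extractor probes the four basis games (1,0,0,0) ... (0,0,0,1) to
#' obtain the margin's coefficients `(lambda_a, lambda_b, lambda_c,
#' lambda_d)`, verifies the antisymmetry `lambda_a = -lambda_d`,
#' `lambda_b = -lambda_c` and linearity (residual on a fifth probe), and
#' returns `sigma = lambda_a / lambda_b`. For aspiration dynamics
#' `sigma = 1` on every admissible graph — structure induces no assortment
#' for strategy selection — whereas imitation dynamics yield
#' structure-dependent sigma.
#'
#' @param evaluator function `(a, b, c, d) -> margin`; see
#'   [aspiration_margin_evaluator()] and [imitation_margin_evaluator()].
#' @param tol relative tolerance for the antisymmetry/linearity checks.
#' @return List of class `sigma_result`: `sigma`, `lambda`, `antisym_ok`,
#'   `linearity_residual`, and `message` when sigma is undefined.
#' @export
structure_coefficient <- function(evaluator, tol = 1e-6) {
  lam <- c(a = evaluator(1, 0, 0, 0), b = evaluator(0, 1, 0, 0),
           c = evaluator(0, 0, 1, 0), d = evaluator(0, 0, 0, 1))
  scale <- max(abs(lam), 1e-300)
  probe <- evaluator(2, 3, -1, 0.5)
  lin_res <- abs(probe - sum(lam * c(2, 3, -1, 0.5))) / scale
  antisym <- abs(lam["a"] + lam["d"]) <= tol * scale &&
    abs(lam["b"] + lam["c"]) <= tol * scale
  msg <- NULL
  sigma <- NA_real_
  if (lin_res > tol) {
    msg <- "margin is not linear in the payoff entries"
  } else if (abs(lam["b"]) <= tol * scale) {
    msg <- "lambda_b ~ 0: sigma undefined"
  } else {
    sigma <- unname(lam["a"] / lam["b"])
  }
  structure(list(sigma = sigma, lambda = lam, antisym_ok = antisym,
                 linearity_residual = lin_res, message = msg),
            class = "sigma_result")
}

#' @export
print.sigma_result <- function(x, ...) {
  if (is.na(x$sigma)) {
    cat("sigma_result: undefined (", x$message, ")\n", sep = "")
  } else {
    cat(sprintf("sigma_result: sigma = %.10g (antisym %s, residual %.2g)\n",
                x$sigma, if (x$antisym_ok) "ok" else "VIOLATED",
                x$linearity_residual))
  }
  invisible(x)
}

#' Margin evaluators for sigma extraction
#'
#' `aspiration_margin_evaluator()` returns the exact first-order margin of
#' aspiration dynamics as a function of the payoffs.
#' `imitation_margin_evaluator()` returns the rare-mutation success margin
#' `(rho_A - rho_B) / beta` of an imitation rule at small `beta`
#' (vertex-averaged single-mutant fixation probabilities; `rho_B` by
#' strategy relabeling), which converges to a payoff-linear form as
#' `beta -> 0`.
#'
#' @param g a [weighted_graph()].
#' @param asp an [aspiration_scheme()].
#' @param fs update function(s).
#' @param model an [imitation_model()] (its `mu` is forced to 0).
#' @param beta probe selection intensity for the imitation margin.
#' @param payoff_mode `"average"` or `"accumulated"`.
#' @return A function `(a, b, c, d) -> margin`.
#' @export
aspiration_margin_evaluator <- function(g, asp, fs,
                                        payoff_mode = c("average", "accumulated")) {
  payoff_mode <- match.arg(payoff_mode)
  force(g); force(asp); force(fs)
  function(a, b, c, d) {
    weak_selection_margin(g, payoff_matrix(a, b, c, d), asp, fs,
                          payoff_mode)$margin
  }
}

#' @rdname aspiration_margin_evaluator
#' @export
imitation_margin_evaluator <- function(g, model, beta = 1e-4) {
  force(g); force(model); force(beta)
  function(a, b, c, d) {
    m <- model
    m$mu <- 0
    m$beta <- beta
    rA <- fixation_probability(g, payoff_matrix(a, b, c, d), m)$rho_mean
    rB <- fixation_probability(g, payoff_matrix(d, c, b, a), m)$rho_mean
    (rA - rB) / beta
  }
}
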