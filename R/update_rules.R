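#' Update functions
#'
#' An update function `g` maps the scaled aspiration-payoff difference
#' `u = beta * (alpha - pi)` to a switching probability. Admissible update
#' functions satisfy three axioms: (i) `g(u)` lies in `[0, 1]`, (ii) `g` is
#' strictly increasing (more satisfaction, less switching), and
#' (iii) `g(0) > 0` so neutral dynamics never freeze. The weak-selection
#' analysis only ever uses `g(0)` and `g'(0)`, which are stored on the
#' object: analytically for the built-ins, by central finite difference
#' (step 1e-6) for user-supplied functions.
#'
#' @param fn a function of one numeric argument, vectorized.
#' @param g0,gprime0 optional exact values of `fn(0)` and `fn'(0)`.
#' @param name display name.
#' @return A function of class `update_function` carrying attributes `g0`,
#'   `gprime0` and `name`.
#' @seealso [builtin_update_functions()], [validate_update_function()]
#' @export
update_function <- function(fn, g0 = NULL, gprime0 = NULL,
                            name = deparse(substitute(fn))) {
  stopifnot(is.function(fn))
  if (is.null(g0)) g0 <- fn(0)
  if (is.null(gprime0)) {
    h <- 1e-6
    gprime0 <- (fn(h) - fn(-h)) / (2 * h)
  }
  if (!is.finite(g0) || g0 <= 0) stop("update function needs g(0) > 0")
  if (!is.finite(gprime0) || gprime0 <= 0) {
    stop("update function needs g'(0) > 0 (strictly increasing)")
  }
  structure(fn, class = c("update_function", "function"),
            g0 = g0, gprime0 = gprime0, name = name)
}

#' @export
print.update_function <- function(x, ...) {
  cat(sprintf("update_function %s: g(0) = %.6g, g'(0) = %.6g\n",
              attr(x, "name"), attr(x, "g0"), attr(x, "gprime0")))
  invisible(x)
}

g_at_zero <- function(f) attr(f, "g0")
gprime_at_zero <- function(f) attr(f, "gprime0")

erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' The six built-in update functions
#'
#' The named family used for heterogeneous-population experiments:
#' `g1(u) = 1/(1+exp(-u))`, `g2(u) = (1+erf(u))/2`,
#' `g3(u) = (1+tanh(u))/2`, `g4(u) = 1/(1+exp(-u/2))`,
#' `g5(u) = 1/(1+10 exp(-u))`, `g6(u) = 10/(10+exp(-u))`. Each carries its
#' exact `g(0)` and `g'(0)` (for example `g5(0) = 1/11`,
#' `g5'(0) = 10/121`).
#'
#' @return Named list of six [update_function()] objects.
#' @examples
#' fs <- builtin_update_functions()
#' fs$g1(0) # 1/2
#' @export
builtin_update_functions <- function() {
  mk <- function(fn, g0, gp, name, id) {
    f <- update_function(fn, g0 = g0, gprime0 = gp, name = name)
    attr(f, "builtin_id") <- id
    f
  }
  list(
    g1 = mk(function(u) 1 / (1 + exp(-u)), 1 / 2, 1 / 4, "g1", 1L),
    g2 = mk(function(u) (1 + erf(u)) / 2, 1 / 2, 1 / sqrt(pi), "g2", 2L),
    g3 = mk(function(u) (1 + tanh(u)) / 2, 1 / 2, 1 / 2, "g3", 3L),
    g4 = mk(function(u) 1 / (1 + exp(-u / 2)), 1 / 2, 1 / 8, "g4", 4L),
    g5 = mk(function(u) 1 / (1 + 10 * exp(-u)), 1 / 11, 10 / 121, "g5", 5L),
    g6 = mk(function(u) 10 / (10 + exp(-u)), 10 / 11, 10 / 121, "g6", 6L)
  )
}

#' Validate an update function against the model axioms
#'
#' Checks, on an evaluation grid over `u` in `[-50, 50]`: (i) values within
#' `[0, 1]`, (ii) strict monotone increase, (iii) `g(0) > 0`.
#'
#' @param f a function (need not be an [update_function()] yet).
#' @param grid numeric grid of evaluation points.
#' @return List with elements `pass` (logical), `checks` (named logical
#'   vector for the three axioms) and `first_violation` (message or `NA`).
#' @export
validate_update_function <- function(f, grid = seq(-50, 50, length.out = 2001)) {
  vals <- vapply(grid, function(u) as.numeric(f(u)), 0)
  in_range <- all(is.finite(vals)) && all(vals >= 0) && all(vals <= 1)
  # strict increase is required except where the function has numerically
  # saturated at 0 or 1 (the admissible sigmoids reach the bounds of double
  # precision well inside the grid)
  d <- diff(vals)
  sat <- vals <= 1e-12 | vals >= 1 - 1e-12
  both_sat <- sat[-length(sat)] & sat[-1]
  increasing <- all(d >= 0) && all(d[!both_sat] > 0)
  g0_pos <- is.finite(f(0)) && f(0) > 0
  checks <- c(range = in_range, strictly_increasing = increasing,
              g0_positive = g0_pos)
  first <- if (all(checks)) NA_character_ else
    c("values leave [0,1]", "not strictly increasing on the grid",
      "g(0) is not positive")[which(!checks)[1]]
  list(pass = all(checks), checks = checks, first_violation = first)
}

#' Aspiration schemes
#'
#' Aspirations are either `personalized` (individual `l` carries its own
#' fixed level `alpha[l]`, independent of its strategy) or
#' `strategy_contingent` (all A-players aspire to `alpha["A"]`, all
#' B-players to `alpha["B"]`).
#'
#' @param alpha for `personalized`: numeric of length 1 (recycled) or `n`;
#'   for `strategy_contingent`: numeric of length 2 `(A, B)`.
#' @param mode aspiration mode.
#' @return An object of class `aspiration_scheme`.
#' @examples
#' aspiration_scheme(2)                       # everyone aspires to 2
#' aspiration_scheme(c(1, 3), "strategy_contingent") # alpha_A=1, alpha_B=3
#' @export
aspiration_scheme <- function(alpha,
                              mode = c("personalized", "strategy_contingent")) {
  mode <- match.arg(mode)
  alpha <- as.numeric(alpha)
  if (any(!is.finite(alpha))) stop("aspirations must be finite")
  if (mode == "strategy_contingent") {
    if (length(alpha) != 2) {
      stop("strategy-contingent aspirations need length-2 alpha (A, B)")
    }
    names(alpha) <- c("A", "B")
  }
  structure(list(mode = mode, alpha = alpha), class = "aspiration_scheme")
}

#' @export
print.aspiration_scheme <- function(x, ...) {
  cat("aspiration_scheme:", x$mode, "alpha =",
      paste(format(x$alpha), collapse = ", "), "\n")
  invisible(x)
}

# per-vertex aspiration levels of every state: M x n matrix.
# Under the contingent scheme an individual self-evaluates with the
# aspiration of the strategy it currently uses.
aspiration_levels <- function(asp, S) {
  stopifnot(inherits(asp, "aspiration_scheme"))
  n <- ncol(S)
  if (asp$mode == "personalized") {
    a <- rep_len(asp$alpha, n)
    matrix(a, nrow(S), n, byrow = TRUE)
  } else {
    S * asp$alpha[["A"]] + (1 - S) * asp$alpha[["B"]]
  }
}

# normalize fs to a per-vertex list of update functions
as_update_list <- function(fs, n) {
  if (inherits(fs, "update_function")) fs <- rep(list(fs), n)
  if (!is.list(fs) || length(fs) != n ||
      !all(vapply(fs, inherits, TRUE, "update_function"))) {
    stop("fs must be an update_function or a list of n of them")
  }
  fs
}

#' Switching probability of one individual
#'
#' The probability that individual `l`, once selected, abandons its current
#' strategy: `f(beta * (alpha - pi_l(s)))` with `alpha` its personalized
#' level or the level of its current strategy.
#'
#' @param l vertex index.
#' @param s binary strategy vector.
#' @param g a [weighted_graph()].
#' @param pm a [payoff_matrix()].
#' @param asp an [aspiration_scheme()].
#' @param f an [update_function()].
#' @param beta selection intensity, `beta >= 0`.
#' @param payoff_mode `"average"` (edge-weighted mean) or `"accumulated"`.
#' @return A probability.
#' @export
switch_probability <- function(l, s, g, pm, asp, f, beta,
                               payoff_mode = c("average", "accumulated")) {
  payoff_mode <- match.arg(payoff_mode)
  if (beta < 0) stop("beta must be non-negative")
  pay <- edge_weighted_payoff(l, s, g, pm)
  if (payoff_mode == "accumulated") pay <- pay * g$d[l]
  alpha <- if (asp$mode == "personalized") {
    rep_len(asp$alpha, g$n)[l]
  } else {
    if (s[l] == 1) asp$alpha[["A"]] else asp$alpha[["B"]]
  }
  as.numeric(f(beta * (alpha - pay)))
}
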