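#' 2x2 payoff matrix
#'
#' The symmetric two-player game: two A-players each get `a`, two B-players
#' each get `d`, and in a mixed pair the A-player gets `b` and the B-player
#' gets `c`. Any finite real entries are allowed.
#'
#' @param a,b,c,d real payoffs.
#' @return An object of class `payoff_matrix`.
#' @examples
#' payoff_matrix(7, 0, 5, 1)
#' @export
payoff_matrix <- function(a, b, c, d) {
  v <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(v))) stop("payoffs must be finite reals")
  structure(as.list(v), class = "payoff_matrix")
}

#' @export
print.payoff_matrix <- function(x, ...) {
  cat("payoff_matrix:\n")
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("A", "B"), c("A", "B")))
  print(m)
  invisible(x)
}

#' Payoff of one individual in a population state
#'
#' `edge_weighted_payoff()` is the model's default payoff: individual `l`
#' plays the game once along each incident edge and averages the payoffs
#' with weights `w[l, k] / d[l]`,
#' `pi_l(s) = sum_k w_lk [a s_l s_k + b s_l (1 - s_k) + c (1 - s_l) s_k +
#' d (1 - s_l)(1 - s_k)] / d_l`.
#' `accumulated_payoff()` is the same edge sum without the `1 / d_l`
#' normalization, i.e. `d_l * pi_l(s)`.
#'
#' @param l vertex index (1-based).
#' @param s binary strategy vector of length `n` (1 = strategy A).
#' @param g a [weighted_graph()].
#' @param pm a [payoff_matrix()].
#' @return A single payoff value.
#' @examples
#' g <- make_graph(rbind(c(0, 1, 1), c(1, 2, 2)))
#' edge_weighted_payoff(2, c(1, 0, 0), g, payoff_matrix(3, 2, 5, 1))
#' # (1*c + 2*d) / 3
#' @export
edge_weighted_payoff <- function(l, s, g, pm) {
  stopifnot(inherits(g, "weighted_graph"), inherits(pm, "payoff_matrix"))
  s <- as.numeric(s)
  if (length(s) != g$n || !all(s %in% c(0, 1))) {
    stop("s must be a binary vector of length n")
  }
  if (l < 1 || l > g$n) stop("vertex index out of range")
  wl <- g$w[l, ]
  sum(wl * (pm$a * s[l] * s + pm$b * s[l] * (1 - s) +
            pm$c * (1 - s[l]) * s + pm$d * (1 - s[l]) * (1 - s))) / g$d[l]
}

#' @rdname edge_weighted_payoff
#' @export
accumulated_payoff <- function(l, s, g, pm) {
  g$d[l] * edge_weighted_payoff(l, s, g, pm)
}

# --- vectorized state-space payoff machinery (shared by the exact engines) ---

# M x n matrix of all strategy words; row i is the state with index i under
# the decimal-plus-one rule, bit (l-1) of i-1 being individual l's strategy.
state_matrix <- function(n) {
  if (n > 20) stop("state space 2^n too large (n must be <= 20)")
  M <- 2^n
  S <- matrix(0L, M, n)
  for (l in seq_len(n)) {
    S[, l] <- bitwAnd(bitwShiftR(0:(M - 1), l - 1L), 1L)
  }
  S
}

# index of the state reached from each state by flipping individual l
flip_index <- function(n, l) {
  bitwXor(0:(2^n - 1), bitwShiftL(1L, l - 1L)) + 1L
}

#' State indexing
#'
#' States of the population are binary words `s` (element `l` is 1 when
#' individual `l` plays A) indexed `1..2^n` by their decimal value plus one,
#' with individual 1 on the least-significant bit.
#'
#' @param s binary strategy vector.
#' @param i state index in `1..2^n`.
#' @param n population size.
#' @return `state_index()` the integer index; `index_to_state()` the binary
#'   vector.
#' @examples
#' state_index(c(1, 0, 1)) # 1 + 4 -> index 6
#' index_to_state(6, 3)
#' @export
state_index <- function(s) {
  s <- as.integer(s)
  stopifnot(all(s %in% 0:1))
  sum(s * 2^(seq_along(s) - 1)) + 1L
}

#' @rdname state_index
#' @export
index_to_state <- function(i, n) {
  stopifnot(i >= 1, i <= 2^n)
  bitwAnd(bitwShiftR(i - 1L, 0:(n - 1L)), 1L)
}

# Payoff of every individual in every state: M x n matrix.
# mode "average" divides the edge sum by d_l, "accumulated" does not.
state_payoffs <- function(g, pm, mode = c("average", "accumulated"),
                          S = state_matrix(g$n)) {
  mode <- match.arg(mode)
  # nA[i, l]: weighted number of A-neighbors of l in state i
  nA <- S %*% t(g$w)
  tot <- matrix(g$d, nrow(S), g$n, byrow = TRUE)
  pay <- S * (pm$a * nA + pm$b * (tot - nA)) +
    (1 - S) * (pm$c * nA + pm$d * (tot - nA))
  if (mode == "average") pay <- pay / tot
  pay
}
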