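# Shared fixtures, built in code. The six-vertex graph catalogue is
# memoized because several files sweep over it.

triangle_graph <- function() {
  make_graph(rbind(c(0, 1, 1), c(1, 2, 1), c(0, 2, 1)))
}

path3_graph <- function() {
  make_graph(rbind(c(0, 1, 1), c(1, 2, 2)))
}

two_vertex_graph <- function() {
  make_graph(rbind(c(0, 1, 1)))
}

cycle6_graph <- function() {
  make_graph(cbind(0:5, c(1:5, 0), 1))
}

complete_graph <- function(n) {
  idx <- utils::combn(0:(n - 1), 2)
  make_graph(cbind(idx[1, ], idx[2, ], 1))
}

.g6_cache <- new.env(parent = emptyenv())
six_vertex_graphs <- function() {
  if (is.null(.g6_cache$g6)) .g6_cache$g6 <- enumerate_connected_graphs(6)
  .g6_cache$g6
}

# random weighted six-vertex graph plus random aspirations and a random
# assignment of the six built-in update functions
random_setup6 <- function(seed) {
  set.seed(seed)
  g <- assign_weights(random_graph(6, sample(2:4, 1), seed = seed + 1000L),
                      sample(c("uniform_int", "zipf"), 1), seed = seed + 2000L)
  fs <- unname(builtin_update_functions()[sample(6)])
  asp <- aspiration_scheme(runif(6, 0, 5))
  list(g = g, fs = fs, asp = asp)
}

mixed_fs6 <- function() unname(builtin_update_functions())
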