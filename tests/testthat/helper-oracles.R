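# Independent oracles, deliberately naive: closed-form combinatorial sums,
# explicit loops and union-find, never sharing code with the implementation.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Upper-tail hypergeometric by direct enumeration of overlap counts:
# P(X >= k) for k successes when drawing n from a universe of N containing m.
hyper_upper_oracle <- function(m, n_draw, N, k) {
  js <- seq(from = k, to = min(m, n_draw))
  if (k > min(m, n_draw)) return(0)
  sum(choose(m, js) * choose(N - m, n_draw - js)) / choose(N, n_draw)
}

# Activation z by explicit per-edge loop over the summation formula.
activation_z_oracle <- function(edges, directions) {
  num <- 0
  den <- 0
  for (i in seq_len(nrow(edges))) {
    g <- edges$target[i]
    if (edges$sign[i] == "unknown" || !g %in% names(directions)) next
    predicted <- if (edges$sign[i] == "activates") 1 else -1
    m <- if (predicted == directions[[g]]) 1 else -1
    num <- num + edges$weight[i] * m
    den <- den + edges$weight[i]^2
  }
  if (den == 0) return(NA_real_)
  num / sqrt(den)
}

# Connected-component sizes by union-find over an edge tibble.
component_sizes_oracle <- function(nodes, edges) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (i in seq_len(nrow(edges))) {
    ra <- find(edges$node_a[i]); rb <- find(edges$node_b[i])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(nodes, find, character(1))
  sort(as.integer(table(roots)), decreasing = TRUE)
}

# Small fixed prior network used across tests.
toy_network <- function() {
  prior_network(tibble::tibble(
    regulator = c("R1", "R1", "R1", "R1", "R2", "R2", "R3"),
    target = c("A", "B", "C", "D", "C", "E", "F"),
    sign = c("+", "+", "-", "?", "+", "-", "+"),
    weight = 1
  ))
}

random_ranking <- function(regs, condition) {
  ord <- sample(regs)
  r <- tibble::tibble(
    regulator = ord,
    n_targets_in_universe = 10L,
    n_overlap = 5L,
    n_consistent = 3L,
    n_inconsistent = 2L,
    p_overlap = sort(runif(length(ord))),
    fdr_overlap = sort(runif(length(ord))),
    z = rnorm(length(ord)),
    state = "indeterminate"
  )
  attr(r, "condition") <- condition
  class(r) <- c("itr_ranking", class(tibble::tibble()))
  r
}
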