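# Brute-force graph-statistic oracles and small fixture builders.
# These are deliberately naive (triple loops, BFS) and independent of the
# igraph-backed implementations they check.

random_digraph <- function(V, p = 0.4) {
  A <- matrix(rbinom(V * V, 1, p), V, V)
  diag(A) <- 0
  A
}

# digraph with exactly E directed edges on V labelled nodes
digraph_with_edges <- function(V, E) {
  stopifnot(E <= V * (V - 1))
  slots <- which(row(matrix(0, V, V)) != col(matrix(0, V, V)))
  A <- matrix(0L, V, V)
  A[sample(slots, E)] <- 1L
  A
}

brute_reciprocity <- function(A) {
  E <- sum(A)
  if (E == 0) return(0)
  mutual <- 0
  V <- nrow(A)
  for (i in seq_len(V)) for (j in seq_len(V))
    if (A[i, j] == 1 && A[j, i] == 1) mutual <- mutual + 1
  mutual / E
}

brute_transitivity <- function(A) {
  U <- (A + t(A)) > 0
  V <- nrow(U)
  closed <- 0; connected <- 0
  for (i in seq_len(V)) for (j in seq_len(V)) for (k in seq_len(V)) {
    if (i == j || j == k || i == k) next
    if (U[i, j] && U[j, k]) { # path through center j
      connected <- connected + 1
      if (U[i, k]) closed <- closed + 1
    }
  }
  if (connected == 0) 0 else closed / connected
}

brute_avg_distance <- function(A) {
  V <- nrow(A)
  total <- 0; count <- 0
  for (s in seq_len(V)) {
    dist <- rep(Inf, V); dist[s] <- 0
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (w in which(A[v, ] == 1))
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1
          queue <- c(queue, w)
        }
    }
    reach <- dist[-s][is.finite(dist[-s])]
    total <- total + sum(reach); count <- count + length(reach)
  }
  if (count == 0) stop("no reachable pairs")
  total / count
}

tiny_net <- function() {
  ros <- data.frame(id = c("a", "b", "c"), is_ego = c(TRUE, TRUE, FALSE))
  multiplex_network(ros, layers = c("give", "rate"))
}

# random valid parameter state matching a network's dimensions
random_state <- function(J, M, gamma_identity = FALSE) {
  K <- 2L * M
  D <- J * (J - 1L) / 2L
  rc <- function() {
    X <- matrix(rnorm(K * K), K)
    t(chol(stats::cov2cor(crossprod(X) + diag(K))))
  }
  parameter_state(
    fixed_effects(rnorm(M)),
    generalized_effects(matrix(rnorm(J * K), J, K), rexp(K) + 0.2, rc()),
    dyadic_effects(matrix(rnorm(D * K), D, K), rexp(M) + 0.2,
                   if (gamma_identity) diag(K) else rc()))
}

# Printed per-community layer descriptives (vertices, directed edges, density)
table1_cells <- function() {
  df <- read.csv(text = "
community,layer,vertices,edges,density
coastal,generosity_rating,186,1732,0.05
coastal,selfishness_rating,186,1365,0.04
coastal,giving,186,1763,0.051
coastal,exploitation,186,20362,0.592
coastal,punishment,186,387,0.011
lowland,generosity_rating,154,1347,0.057
lowland,selfishness_rating,154,1072,0.045
lowland,giving,154,1271,0.054
lowland,exploitation,154,13607,0.577
lowland,punishment,154,480,0.02
highland,generosity_rating,45,256,0.129
highland,selfishness_rating,45,115,0.058
highland,giving,45,444,0.224
highland,exploitation,45,810,0.409
highland,punishment,45,62,0.031
altiplano,generosity_rating,111,596,0.049
altiplano,selfishness_rating,111,319,0.026
altiplano,giving,111,1020,0.084
altiplano,exploitation,111,6690,0.548
altiplano,punishment,111,178,0.015
", stringsAsFactors = FALSE)
  df
}
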