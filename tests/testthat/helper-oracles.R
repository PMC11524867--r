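# Shared fixtures and independent brute-force oracles.

# Six-node hand-traceable fixture: degrees [3,2,2,1,1,1], average 10/6.
fixture_graph <- function() {
  igraph::graph_from_edgelist(
    matrix(c(1, 2, 1, 3, 1, 4, 2, 3, 5, 6), ncol = 2, byrow = TRUE),
    directed = FALSE)
}

# Local clustering by direct triangle/wedge counting on the adjacency matrix.
oracle_avg_clustering <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  n <- nrow(A)
  if (n == 0) return(0)
  cc <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] == 1)
    k <- length(nb)
    if (k < 2) next
    links <- sum(A[nb, nb]) / 2
    cc[i] <- links / (k * (k - 1) / 2)
  }
  mean(cc)
}

# All-pairs shortest paths by Floyd-Warshall.
oracle_mean_shortest_path <- function(g) {
  n <- igraph::vcount(g)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  em <- igraph::as_edgelist(g, names = FALSE)
  for (r in seq_len(nrow(em))) d[em[r, 1], em[r, 2]] <- d[em[r, 2], em[r, 1]] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  off <- d[row(d) != col(d)]
  list(mean_distance = mean(off[is.finite(off)]),
       excluded_fraction = mean(!is.finite(off)))
}

# Literal summation oracle for the passive-isolation node probability:
# unoptimized loops over the full edge-count range, the candidate-count
# mixture written out explicitly, no log-space tricks.
oracle_pdin_node_prob <- function(n, p_er, p_pcro, k1_lit = 1, k2_avg = TRUE) {
  m <- n * (n - 1) / 2
  total <- 0
  for (L in 1:m) {
    pl <- dbinom(L, m, p_er)
    if (pl < 1e-18) next
    pecp <- L / m
    k1 <- k1_lit
    k2 <- if (k2_avg) 2 * L / n else n - 1
    q <- 0
    for (k in ceiling(k1):floor(k2)) q <- q + dbinom(k, n - 1, pecp)
    inner_ki <- 0
    for (ki in 1:(n - 1)) {
      pcp1 <- if (ki >= k1 && ki <= k2) 1 - p_pcro else 1
      pcp2_base <- 0
      for (kj in ceiling(k1):floor(k2))
        pcp2_base <- pcp2_base + dbinom(kj - 1, n - 2, pecp)
      pki <- dbinom(ki - 1, n - 2, pecp)
      inner_ki <- inner_ki + pcp1 * pcp2_base^ki * p_pcro^ki * pki
    }
    mix <- 0
    for (nn in 1:n) mix <- mix + dbinom(nn, n, q) * inner_ki
    total <- total + pl * mix
  }
  total
}
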