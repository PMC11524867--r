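# Counts of the node classes for one realization, without building the
# rewired topology (classification only needs degrees). Same rules and the
# same RNG draw order as apply_pcro, so identical seeds give identical counts.
count_one_realization <- function(n, p_er, config) {
  count_fixed_graph(igraph::sample_gnp(n, p_er, directed = FALSE, loops = FALSE),
                    config)
}

#' Monte Carlo realizations of the cutting--rewiring counts
#'
#' Draws `S` independent (substrate, cut) realizations — a fresh
#' Erdos-Renyi graph each sample unless `graph` pins the substrate — and
#' records the counts of candidates and of the three isolated-node classes.
#' Counts are taken from the classification stage, before any rewiring
#' topology is needed, so realizations where too few non-isolated nodes
#' remain to host the hubs still contribute counts; they are only tallied in
#' `n_rejected`.
#'
#' @param n_nodes,p_er Substrate parameters.
#' @param config A [pcro_config()].
#' @param S Number of samples.
#' @param seed Optional integer for reproducibility.
#' @param graph Optional fixed igraph substrate reused for every sample
#'   (diagnostic mode; the analytic theory averages over the edge count and
#'   assumes redrawing).
#' @param method `"auto"` picks the fully vectorized pair-indicator sampler
#'   for small substrates (`n_nodes <= 12`) and the per-sample loop
#'   otherwise; both implement the same classification rules and are each
#'   deterministic under a seed (their RNG draw orders differ).
#' @return A `pcro_simulation`: per-sample count matrix, sample size,
#'   `n_rejected`, and the generating parameters.
#' @examples
#' sim <- simulate_counts(100, 0.05, pcro_config(p_pcro = 0.5), S = 200, seed = 1)
#' summary(sim)
#' @export
simulate_counts <- function(n_nodes, p_er, config = pcro_config(), S = 1e4,
                            seed = NULL, graph = NULL,
                            method = c("auto", "loop", "vectorized")) {
  stopifnot(S >= 1)
  method <- match.arg(method)
  if (method == "auto")
    method <- if (is.null(graph) && n_nodes <= 12) "vectorized" else "loop"
  with_seed(seed, {
    if (method == "vectorized") {
      counts <- simulate_counts_smalln(n_nodes, p_er, config, S)
    } else {
      counts <- matrix(0L, nrow = S, ncol = 6,
                       dimnames = list(NULL, c("nspccp", "nin", "adin", "pdin",
                                               "cl", "degenerate")))
      for (s in seq_len(S)) {
        counts[s, ] <- if (is.null(graph))
          count_one_realization(n_nodes, p_er, config)
        else
          count_fixed_graph(graph, config)
      }
    }
    stopifnot(all(counts[, "cl"] ==
                    counts[, "nin"] + counts[, "adin"] + counts[, "pdin"]))
    structure(list(counts = counts[, 1:5, drop = FALSE], S = S,
                   n_rejected = sum(counts[, "degenerate"]),
                   n_nodes = n_nodes, p_er = p_er, config = config,
                   seed = seed),
              class = "pcro_simulation")
  })
}

# Vectorized sampler for small substrates: all C(n,2) pair indicators for all
# S samples at once. Same classification rules as count_fixed_graph.
simulate_counts_smalln <- function(n, p_er, config, S) {
  pairs <- if (n >= 2) utils::combn(n, 2) else matrix(integer(0), nrow = 2)
  m <- ncol(pairs)
  E <- matrix(stats::runif(S * m) < p_er, S, m)
  B <- matrix(0L, m, n)
  if (m) B[cbind(seq_len(m), pairs[1, ])] <- 1L
  if (m) B[cbind(seq_len(m), pairs[2, ])] <- 1L
  deg <- E %*% B
  L <- rowSums(E)
  band_edge <- function(spec) switch(spec$kind,
    literal = rep(spec$value, S),
    avg_pre = 2 * L / n,
    max_pre = apply(deg, 1, max),
    stop("post-cut constraints cannot be resolved before the cut"))
  k1 <- band_edge(config$k1)
  k2 <- band_edge(config$k2)
  cand <- deg >= k1 & deg <= k2
  adin <- cand & matrix(stats::runif(S * n) < config$p_pcro, S, n)
  surv <- E & !adin[, pairs[1, ], drop = FALSE] & !adin[, pairs[2, ], drop = FALSE]
  deg_post <- surv %*% B
  nin <- rowSums(deg == 0)
  n_adin <- rowSums(adin)
  pdin <- rowSums(deg >= 1 & !adin & deg_post == 0)
  cbind(nspccp = rowSums(cand), nin = nin, adin = n_adin, pdin = pdin,
        cl = nin + n_adin + pdin,
        degenerate = as.integer(rowSums(deg_post >= 1) < config$n_hubs))
}

count_fixed_graph <- function(g, config) {
  n <- igraph::vcount(g)
  deg <- igraph::degree(g)
  k1 <- resolve_constraint(config$k1, g)
  k2 <- resolve_constraint(config$k2, g)
  cand <- which(deg >= k1 & deg <= k2)
  adin <- cand[stats::runif(length(cand)) < config$p_pcro]
  em <- igraph::as_edgelist(g, names = FALSE)
  if (length(adin) && nrow(em)) {
    keep <- !(em[, 1] %in% adin | em[, 2] %in% adin)
    deg_post <- tabulate(c(em[keep, 1], em[keep, 2]), nbins = n)
  } else deg_post <- deg
  is_adin <- seq_len(n) %in% adin
  n_nin <- sum(deg == 0)
  n_pdin <- sum(deg >= 1 & !is_adin & deg_post == 0)
  c(nspccp = length(cand), nin = n_nin, adin = length(adin), pdin = n_pdin,
    cl = n_nin + length(adin) + n_pdin,
    degenerate = as.integer(sum(deg_post >= 1) < config$n_hubs))
}

#' Empirical distribution of one recorded count
#'
#' @param sim A `pcro_simulation`.
#' @param what One of `"nspccp"`, `"nin"`, `"adin"`, `"pdin"`, `"cl"`.
#' @return A `count_distribution` of raw frequencies.
#' @export
simulated_dist <- function(sim, what = c("cl", "nin", "adin", "pdin", "nspccp")) {
  what <- match.arg(what)
  empirical_distribution(sim$counts[, what])
}

#' @export
print.pcro_simulation <- function(x, ...) {
  cat(sprintf("PCRO simulation: S = %d samples, N = %d, P_ER = %g, p_pcro = %g\n",
              x$S, x$n_nodes, x$p_er, x$config$p_pcro))
  cat(sprintf("  %d realization(s) degenerate for hub selection\n", x$n_rejected))
  invisible(x)
}

#' @export
summary.pcro_simulation <- function(object, ...) {
  print(object)
  mu <- colMeans(object$counts)
  se <- apply(object$counts, 2, stats::sd) / sqrt(object$S)
  cat("\nMeans (standard errors):\n")
  for (nm in colnames(object$counts))
    cat(sprintf("  %-7s %8.4f (%.4f)\n", nm, mu[[nm]], se[[nm]]))
  invisible(object)
}

#' Total variation distance between two count distributions
#'
#' Half the absolute mass difference over the union support.
#'
#' @param p,q `count_distribution` objects.
#' @return A number in `[0, 1]`.
#' @export
total_variation <- function(p, q) {
  lo <- min(p$support, q$support)
  hi <- max(p$support, q$support)
  pv <- qv <- numeric(hi - lo + 1)
  pv[p$support - lo + 1] <- p$pmf
  qv[q$support - lo + 1] <- q$pmf
  sum(abs(pv - qv)) / 2
}

#' Exhaustive enumeration of the class counts on tiny substrates
#'
#' Ground truth free of the equivalent-connection-probability
#' approximation: iterates every labeled graph on `n_nodes <= 5` nodes with
#' probability `P_ER^L (1-P_ER)^(C(n,2)-L)`, and within each graph every
#' subset of the cutting candidates with probability
#' `p^|A| (1-p)^(|cand|-|A|)`, applying the deterministic classification
#' rules and accumulating the exact joint law of the three isolated-node
#' counts.
#'
#' @param n_nodes At most 5.
#' @param p_er Connection probability.
#' @param config A [pcro_config()] (only the cutting side is used).
#' @return A `pcro_enumeration`: `joint` array indexed by
#'   `(nin, adin, pdin)` counts (offset by 1) plus marginal and common-leaf
#'   `count_distribution`s.
#' @export
enumerate_exact <- function(n_nodes, p_er, config = pcro_config()) {
  stopifnot(n_nodes >= 1, n_nodes <= 5)
  n <- as.integer(n_nodes)
  pairs <- if (n >= 2) utils::combn(n, 2) else matrix(integer(0), nrow = 2)
  m <- ncol(pairs)
  joint <- array(0, dim = c(n + 1, n + 1, n + 1))
  cl_pmf <- numeric(n + 1)
  for (gmask in 0:(2^m - 1)) {
    present <- as.logical(bitwAnd(gmask, 2^(seq_len(m) - 1)))
    L <- sum(present)
    pg <- p_er^L * (1 - p_er)^(m - L)
    if (pg == 0) next
    em <- pairs[, present, drop = FALSE]
    deg <- tabulate(as.vector(em), nbins = n)
    k1 <- if (config$k1$kind == "literal") config$k1$value else
      switch(config$k1$kind, avg_pre = 2 * L / n, max_pre = max(deg),
             stop("post-cut constraint not meaningful for candidate selection"))
    k2 <- if (config$k2$kind == "literal") config$k2$value else
      switch(config$k2$kind, avg_pre = 2 * L / n, max_pre = max(deg),
             stop("post-cut constraint not meaningful for candidate selection"))
    cand <- which(deg >= k1 & deg <= k2)
    nc <- length(cand)
    n_nin <- sum(deg == 0)
    for (amask in 0:(2^nc - 1)) {
      sel <- as.logical(bitwAnd(amask, 2^(seq_len(max(nc, 1)) - 1)))[seq_len(nc)]
      adin <- cand[sel]
      pa <- config$p_pcro^length(adin) *
        (1 - config$p_pcro)^(nc - length(adin))
      if (pa == 0) next
      if (length(adin) && ncol(em)) {
        keep <- !(em[1, ] %in% adin | em[2, ] %in% adin)
        deg_post <- tabulate(as.vector(em[, keep, drop = FALSE]), nbins = n)
      } else deg_post <- deg
      n_pdin <- sum(deg >= 1 & !(seq_len(n) %in% adin) & deg_post == 0)
      n_adin <- length(adin)
      joint[n_nin + 1, n_adin + 1, n_pdin + 1] <-
        joint[n_nin + 1, n_adin + 1, n_pdin + 1] + pg * pa
      ncl <- n_nin + n_adin + n_pdin
      cl_pmf[ncl + 1] <- cl_pmf[ncl + 1] + pg * pa
    }
  }
  marg <- function(d) count_distribution(0:n, apply(joint, d, sum))
  structure(list(joint = joint, n_nodes = n, p_er = p_er, config = config,
                 nin = marg(1), adin = marg(2), pdin = marg(3),
                 cl = count_distribution(0:n, cl_pmf)),
            class = "pcro_enumeration")
}

#' @export
print.pcro_enumeration <- function(x, ...) {
  cat(sprintf("Exact enumeration: N = %d, P_ER = %g, p_pcro = %g\n",
              x$n_nodes, x$p_er, x$config$p_pcro))
  cat(sprintf("  mean counts: NIN %.4f, ADIN %.4f, PDIN %.4f, CL %.4f\n",
              mean(x$nin), mean(x$adin), mean(x$pdin), mean(x$cl)))
  invisible(x)
}

# Joint empirical pmf of (nin, adin, pdin) from a simulation, as an array
# aligned with an enumeration's joint array.
joint_empirical <- function(sim, n_nodes) {
  joint <- array(0, dim = rep(n_nodes + 1, 3))
  idx <- cbind(sim$counts[, "nin"], sim$counts[, "adin"], sim$counts[, "pdin"]) + 1
  for (s in seq_len(nrow(idx)))
    joint[idx[s, 1], idx[s, 2], idx[s, 3]] <-
      joint[idx[s, 1], idx[s, 2], idx[s, 3]] + 1
  joint / sim$S
}

#' Total variation between a simulation and an exact enumeration, on the
#' joint law of the three isolated-node counts
#'
#' @param sim A `pcro_simulation` on the same parameters.
#' @param enum A `pcro_enumeration`.
#' @return TV distance in `[0, 1]`.
#' @export
joint_tv <- function(sim, enum) {
  emp <- joint_empirical(sim, enum$n_nodes)
  sum(abs(emp - enum$joint)) / 2
}

#' The default analytic-vs-empirical validation grid
#'
#' One row per parameter cell: the reference setting at three cut
#' probabilities, the three alternative constraint combinations, and the
#' substrate variants in connection probability and size.
#'
#' @return Data frame with columns `n`, `p_er`, `k1`, `k2`, `k3`, `p_pcro`.
#' @export
default_validation_grid <- function() {
  rbind(
    data.frame(n = 100, p_er = 0.05, k1 = "1", k2 = "avg_pre", k3 = "max_post",
               p_pcro = c(0.25, 0.5, 0.75)),
    data.frame(n = 100, p_er = 0.05,
               k1 = c("avg_pre", "1", "avg_pre"),
               k2 = c("max_pre", "avg_pre", "max_pre"),
               k3 = c("max_post", "avg_post", "avg_post"),
               p_pcro = 0.5),
    data.frame(n = c(100, 100, 50, 200), p_er = c(0.03, 0.08, 0.05, 0.05),
               k1 = "1", k2 = "avg_pre", k3 = "max_post", p_pcro = 0.5)
  )
}

parse_constraint_chr <- function(x) {
  v <- suppressWarnings(as.numeric(x))
  if (!is.na(v)) as_constraint(v) else as_constraint(x)
}

#' Analytic-vs-empirical validation over a parameter grid
#'
#' For every grid cell, simulates `S` realizations, computes the analytic
#' count distributions under the same parameters, and reports total
#' variation distances (candidate-cut class, naturally isolated class, and
#' common leaves) plus the mean common-leaf discrepancy.
#'
#' @param grid As returned by [default_validation_grid()].
#' @param S Samples per cell.
#' @param seed Optional integer; each cell derives its own sub-seed.
#' @param tv_threshold Flagging threshold for the `pass` column.
#' @return Data frame: the grid plus `tv_adin`, `tv_nin`, `tv_cl`,
#'   `tv_pdin_edge_biased`, `tv_pdin_binomial` (the two candidate focal-node
#'   degree laws for the passively deleted class, so the better-matching form
#'   is visible per cell), `mean_cl_analytic`, `mean_cl_empirical`, `pass`.
#' @export
validation_suite <- function(grid = default_validation_grid(), S = 1e4,
                             seed = NULL, tv_threshold = 0.05) {
  res <- grid
  res$tv_adin <- res$tv_nin <- res$tv_cl <- NA_real_
  res$tv_pdin_edge_biased <- res$tv_pdin_binomial <- NA_real_
  res$mean_cl_analytic <- res$mean_cl_empirical <- NA_real_
  for (i in seq_len(nrow(grid))) {
    cell <- grid[i, ]
    cfg <- pcro_config(k1 = parse_constraint_chr(cell$k1),
                       k2 = parse_constraint_chr(cell$k2),
                       k3 = parse_constraint_chr(cell$k3),
                       p_pcro = cell$p_pcro)
    cell_seed <- if (is.null(seed)) NULL else seed + i
    sim <- simulate_counts(cell$n, cell$p_er, cfg, S = S, seed = cell_seed)
    model <- pcro_model(cell$n, cell$p_er, k1 = cfg$k1, k2 = cfg$k2,
                        p_pcro = cell$p_pcro)
    alt <- model
    alt$pki_form <- "binomial"
    emp_pdin <- simulated_dist(sim, "pdin")
    res$tv_adin[i] <- total_variation(adin_count_dist(model), simulated_dist(sim, "adin"))
    res$tv_nin[i] <- total_variation(nin_count_dist(model), simulated_dist(sim, "nin"))
    res$tv_cl[i] <- total_variation(cl_count_dist(model), simulated_dist(sim, "cl"))
    res$tv_pdin_edge_biased[i] <- total_variation(pdin_count_dist(model), emp_pdin)
    res$tv_pdin_binomial[i] <- total_variation(pdin_count_dist(alt), emp_pdin)
    res$mean_cl_analytic[i] <- mean(cl_count_dist(model))
    res$mean_cl_empirical[i] <- mean(sim$counts[, "cl"])
  }
  res$pass <- res$tv_adin <= tv_threshold & res$tv_nin <= tv_threshold &
    res$tv_cl <= tv_threshold
  res
}
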