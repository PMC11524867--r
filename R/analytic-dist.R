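#' Discrete count distribution
#'
#' Light container for a probability mass function over a contiguous integer
#' support, the common currency of the analytic and empirical sides of the
#' package.
#'
#' @param support Integer vector (contiguous, ascending).
#' @param pmf Non-negative masses, same length, summing to 1 within `1e-9`
#'   (renormalized exactly to 1 on construction).
#' @return A `count_distribution`.
#' @export
count_distribution <- function(support, pmf) {
  stopifnot(length(support) == length(pmf), all(pmf >= -1e-15),
            all(diff(support) == 1))
  pmf <- pmax(pmf, 0)
  s <- sum(pmf)
  if (abs(s - 1) > 1e-9)
    stop(sprintf("pmf sums to %.12f, not 1 within 1e-9", s))
  structure(list(support = as.integer(support), pmf = pmf / s),
            class = "count_distribution")
}

#' Empirical count distribution from observed counts
#'
#' @param counts Integer vector of observed counts (raw frequencies, no
#'   smoothing).
#' @return A `count_distribution` on `0..max(counts)`.
#' @export
empirical_distribution <- function(counts) {
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  m <- max(counts, 0L)
  pmf <- tabulate(counts + 1L, nbins = m + 1L) / length(counts)
  count_distribution(0:m, pmf)
}

#' @export
mean.count_distribution <- function(x, ...) sum(x$support * x$pmf)

#' Variance of a count distribution
#' @param x A `count_distribution`.
#' @return Numeric variance.
#' @export
dist_variance <- function(x) {
  mu <- mean(x)
  sum((x$support - mu)^2 * x$pmf)
}

#' @export
print.count_distribution <- function(x, ...) {
  cat(sprintf("Count distribution on %d..%d: mean %.4f, sd %.4f\n",
              min(x$support), max(x$support), mean(x), sqrt(dist_variance(x))))
  invisible(x)
}

#' @export
plot.count_distribution <- function(x, ..., type = "h") {
  plot(x$support, x$pmf, type = type, xlab = "count", ylab = "probability", ...)
}

#' Analytic model of the operated random network
#'
#' Collects the parameters under which the closed-form count distributions
#' are evaluated: the substrate `G(N, P_ER)`, the cutting band `[k1, k2]`,
#' and the cut probability. Symbolic band edges are resolved per realized
#' edge count inside every mixture over `L` (`avg_pre` becomes `2L/N`;
#' `max_pre` becomes `N - 1`, exact for candidate membership since no degree
#' exceeds the realized maximum).
#'
#' @param n_nodes Substrate size `N`.
#' @param p_er Connection probability.
#' @param k1,k2 Cutting band, literal or `"avg_pre"`/`"max_pre"`
#'   (post-cut symbols are meaningless here and rejected).
#' @param p_pcro Cut probability.
#' @param truncation_tol Mass allowed to be dropped when the edge-count
#'   mixture support is truncated (default `1e-10`).
#' @param pki_form Degree law used for the focal node in the passively
#'   deleted class: `"edge_biased"` (the size-biased conditional form, the
#'   default) or `"binomial"` (the plain degree law restricted to degree
#'   >= 1). See the methods vignette.
#' @return A `pcro_model`.
#' @examples
#' m <- pcro_model(100, 0.05, p_pcro = 0.5)
#' mean(cl_count_dist(m))
#' @export
pcro_model <- function(n_nodes, p_er, k1 = 1, k2 = "avg_pre", p_pcro = 0.5,
                       truncation_tol = 1e-10,
                       pki_form = c("edge_biased", "binomial")) {
  stopifnot(n_nodes >= 1, n_nodes == round(n_nodes), p_er >= 0, p_er <= 1,
            p_pcro >= 0, p_pcro <= 1,
            truncation_tol > 0, truncation_tol <= 1e-6)
  k1 <- as_constraint(k1); k2 <- as_constraint(k2)
  for (k in list(k1, k2))
    if (k$kind %in% c("avg_post", "max_post"))
      stop("post-cut symbolic constraints cannot appear in the analytic cutting band")
  structure(list(n_nodes = as.integer(n_nodes), p_er = p_er, k1 = k1, k2 = k2,
                 p_pcro = p_pcro, truncation_tol = truncation_tol,
                 pki_form = match.arg(pki_form)),
            class = "pcro_model")
}

#' @export
print.pcro_model <- function(x, ...) {
  cat(sprintf("Analytic PCRO model: N = %d, P_ER = %g, band [%s, %s], p_pcro = %g\n",
              x$n_nodes, x$p_er, format(x$k1), format(x$k2), x$p_pcro))
  invisible(x)
}

# Band edges resolved for a given edge count L: c(k1, k2) numeric.
resolve_band <- function(model, L) {
  res1 <- switch(model$k1$kind, literal = model$k1$value,
                 avg_pre = 2 * L / model$n_nodes, max_pre = model$n_nodes - 1)
  res2 <- switch(model$k2$kind, literal = model$k2$value,
                 avg_pre = 2 * L / model$n_nodes, max_pre = model$n_nodes - 1)
  c(res1, res2)
}

#' Equivalent connection probability for a realized edge count
#'
#' The connection probability whose expected average degree matches an
#' observed edge count `L`: `2L / (N(N-1))`.
#'
#' @param L Edge count, `0 <= L <= N(N-1)/2`.
#' @param n_nodes Node count `N`.
#' @return Numeric probability.
#' @export
equivalent_connection_prob <- function(L, n_nodes) {
  m <- n_nodes * (n_nodes - 1) / 2
  stopifnot(all(L >= 0), all(L <= m))
  L / m
}

#' Edge-count distribution of the substrate
#'
#' The number of edges of `G(N, P_ER)` is binomial over the `N(N-1)/2` node
#' pairs. The support is truncated to the smallest contiguous range holding
#' at least `1 - truncation_tol` of the mass (grown outward from the mode),
#' then renormalized.
#'
#' @param model A [pcro_model()].
#' @return A `count_distribution` over edge counts.
#' @export
edge_count_pmf <- function(model) {
  m <- model$n_nodes * (model$n_nodes - 1) / 2
  full <- stats::dbinom(0:m, m, model$p_er)
  lo <- hi <- which.max(full)
  mass <- full[lo]
  while (mass < 1 - model$truncation_tol) {
    left <- if (lo > 1) full[lo - 1] else -1
    right <- if (hi < length(full)) full[hi + 1] else -1
    if (left >= right) { lo <- lo - 1; mass <- mass + full[lo] }
    else { hi <- hi + 1; mass <- mass + full[hi] }
  }
  count_distribution((lo - 1):(hi - 1), full[lo:hi] / mass)
}

#' Conditional candidate probability given the edge count
#'
#' Probability that an arbitrary node of a network with `L` realized edges
#' has degree inside the resolved cutting band, under the
#' equivalent-connection-probability approximation: the degree sum of
#' `Binomial(N-1, 2L/(N(N-1)))` over integers in `[ceil(k1), floor(k2)]`.
#'
#' @param model A [pcro_model()].
#' @param L Realized edge count.
#' @return Numeric probability (0 when the integer band is empty).
#' @export
nspccp_prob_given_L <- function(model, L) {
  band <- resolve_band(model, L)
  lo <- ceiling(band[1]); hi <- floor(band[2])
  if (hi < lo) return(0)
  pecp <- equivalent_connection_prob(L, model$n_nodes)
  sum(stats::dbinom(lo:hi, model$n_nodes - 1, pecp))
}

#' Count distribution of the cutting candidates
#'
#' Mixture over the edge count: given `L`, the number of in-band nodes is
#' taken binomial `(N, q_L)` with `q_L` from [nspccp_prob_given_L()];
#' averaging over the edge-count law gives the marginal.
#'
#' @param model A [pcro_model()].
#' @return A `count_distribution` on `0..N`.
#' @export
nspccp_count_dist <- function(model) {
  pl <- edge_count_pmf(model)
  n <- model$n_nodes
  pmf <- numeric(n + 1)
  for (i in seq_along(pl$support)) {
    q <- nspccp_prob_given_L(model, pl$support[i])
    pmf <- pmf + pl$pmf[i] * stats::dbinom(0:n, n, q)
  }
  count_distribution(0:n, pmf)
}

#' Count distribution of the actively deleted isolated nodes
#'
#' Binomial thinning of the candidate count: each of `m` candidates is cut
#' independently with probability `p_pcro`, so the marginal is the compound
#' `sum_m P(candidates = m) Binomial(m, p_pcro)`. The mean is exactly
#' `p_pcro` times the candidate mean.
#'
#' @param model A [pcro_model()].
#' @return A `count_distribution` on `0..N`.
#' @export
adin_count_dist <- function(model) {
  pn <- nspccp_count_dist(model)
  n <- model$n_nodes
  pmf <- numeric(n + 1)
  for (i in seq_along(pn$support)) {
    m <- pn$support[i]
    if (pn$pmf[i] > 0)
      pmf[1:(m + 1)] <- pmf[1:(m + 1)] + pn$pmf[i] * stats::dbinom(0:m, m, model$p_pcro)
  }
  count_distribution(0:n, pmf)
}

#' Node-level probability of passive isolation
#'
#' A node with degree `ki >= 1` becomes a passively deleted isolated node
#' when it survives the cut itself (probability 1 outside the band,
#' `1 - p_pcro` inside), every one of its `ki` neighbours lies in the band
#' (each with the size-biased conditional degree law of a node known to own
#' the shared edge), and every neighbour is actually cut (`p_pcro^ki`). The
#' three factors are multiplied, averaged over the focal degree law, and
#' mixed over the edge count. The per-`ki` power is taken in log space.
#'
#' @param model A [pcro_model()].
#' @return A single probability.
#' @export
pdin_node_prob <- function(model) {
  if (model$p_pcro == 0) return(0)
  n <- model$n_nodes
  if (n < 2) return(0)
  pl <- edge_count_pmf(model)
  ki <- 1:(n - 1)
  log_p <- log(model$p_pcro)
  total <- 0
  for (i in seq_along(pl$support)) {
    L <- pl$support[i]
    pecp <- equivalent_connection_prob(L, n)
    band <- resolve_band(model, L)
    lo <- ceiling(band[1]); hi <- floor(band[2])
    pcp2 <- if (hi < lo) 0 else
      sum(stats::dbinom((lo:hi) - 1, n - 2, pecp))
    if (pcp2 == 0) next
    pki <- switch(model$pki_form,
      edge_biased = stats::dbinom(ki - 1, n - 2, pecp),
      binomial = stats::dbinom(ki, n - 1, pecp))
    pcp1 <- ifelse(ki >= band[1] & ki <= band[2], 1 - model$p_pcro, 1)
    total <- total + pl$pmf[i] *
      sum(pcp1 * exp(ki * (log(pcp2) + log_p)) * pki)
  }
  if (total < 0 || total > 1)
    stop(sprintf("passive-isolation probability %.6g outside [0,1]", total))
  total
}

#' Count distribution of the passively deleted isolated nodes
#'
#' Binomial `(N, p)` with `p` the node-level probability of
#' [pdin_node_prob()].
#'
#' @param model A [pcro_model()].
#' @return A `count_distribution` on `0..N`.
#' @export
pdin_count_dist <- function(model) {
  p <- pdin_node_prob(model)
  count_distribution(0:model$n_nodes, stats::dbinom(0:model$n_nodes, model$n_nodes, p))
}

#' Count distribution of the naturally isolated nodes
#'
#' A node is isolated in `G(N, P_ER)` with probability `(1 - P_ER)^(N-1)`;
#' the count is binomial. This component involves no approximation at the
#' node level.
#'
#' @param model A [pcro_model()].
#' @return A `count_distribution` on `0..N`.
#' @export
nin_count_dist <- function(model) {
  p <- (1 - model$p_er)^(model$n_nodes - 1)
  count_distribution(0:model$n_nodes, stats::dbinom(0:model$n_nodes, model$n_nodes, p))
}

# Discrete convolution of two pmfs on supports 0..(len-1).
conv_pmf <- function(p, q) {
  out <- numeric(length(p) + length(q) - 1)
  for (i in seq_along(p))
    if (p[i] > 0) {
      idx <- i:(i + length(q) - 1)
      out[idx] <- out[idx] + p[i] * q
    }
  out
}

#' Count distribution of the common leaves
#'
#' The common-leaf count is the sum of the naturally, actively, and
#' passively isolated counts; treating the three as independent, its law is
#' their discrete convolution. The (negligible) mass the convolution places
#' above `N` is preserved and reported in the `"super_n_mass"` attribute.
#'
#' @param model A [pcro_model()].
#' @return A `count_distribution` on `0..3N`.
#' @export
cl_count_dist <- function(model) {
  pmf <- conv_pmf(conv_pmf(nin_count_dist(model)$pmf, adin_count_dist(model)$pmf),
                  pdin_count_dist(model)$pmf)
  d <- count_distribution(seq_along(pmf) - 1L, pmf)
  attr(d, "super_n_mass") <- sum(pmf[(model$n_nodes + 2):length(pmf)])
  d
}

#' Analytic mean common-leaf count as a function of the cut probability
#'
#' @param model A [pcro_model()] (its `p_pcro` is overridden point by point).
#' @param p_grid Cut probabilities in `[0, 1]`.
#' @return Data frame with columns `p_pcro` and `mean_cl`.
#' @export
mean_cl_curve <- function(model, p_grid = seq(0, 1, by = 0.1)) {
  stopifnot(all(p_grid >= 0), all(p_grid <= 1))
  mean_cl <- vapply(p_grid, function(p) {
    m <- model
    m$p_pcro <- p
    mean(cl_count_dist(m))
  }, numeric(1))
  data.frame(p_pcro = p_grid, mean_cl = mean_cl)
}
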