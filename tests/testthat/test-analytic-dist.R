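test_that("count distributions validate, normalize, and expose moments", {
  d <- count_distribution(0:3, c(0.1, 0.2, 0.3, 0.4))
  expect_equal(sum(d$pmf), 1)
  expect_equal(mean(d), 2)
  expect_equal(dist_variance(d), 1)
  expect_error(count_distribution(0:2, c(0.5, 0.4, 0.2)), "sums to")
  e <- empirical_distribution(c(0L, 0L, 1L, 3L))
  expect_equal(e$pmf, c(0.5, 0.25, 0, 0.25))
})

test_that("the edge-count law is the pair binomial with correct mean", {
  m2 <- pcro_model(2, 0.3)
  d2 <- edge_count_pmf(m2)
  expect_equal(d2$pmf[match(0:1, d2$support)], c(0.7, 0.3))
  m <- pcro_model(100, 0.05)
  expect_equal(mean(edge_count_pmf(m)), 247.5, tolerance = 1e-9)
  m0 <- pcro_model(50, 0)
  d0 <- edge_count_pmf(m0)
  expect_equal(d0$support, 0L)
  expect_equal(d0$pmf, 1)
})

test_that("equivalent connection probability interpolates the edge count", {
  expect_equal(equivalent_connection_prob(0, 100), 0)
  expect_equal(equivalent_connection_prob(4950, 100), 1)
  expect_equal(equivalent_connection_prob(247, 100), 247 / 4950)
  expect_error(equivalent_connection_prob(5000, 100))
})

test_that("the conditional candidate probability sums the in-band degree masses", {
  m <- pcro_model(100, 0.05)
  expect_equal(nspccp_prob_given_L(m, 0), 0)
  mall <- pcro_model(100, 0.05, k1 = 0, k2 = 99)
  expect_equal(nspccp_prob_given_L(mall, 247), 1)
  # direct summation oracle at L = 247: band [1, 4.94] -> degrees 1..4
  expect_equal(nspccp_prob_given_L(m, 247),
               sum(dbinom(1:4, 99, 247 / 4950)), tolerance = 1e-12)
})

test_that("the candidate count mean matches Monte Carlo to within 2 percent", {
  m <- pcro_model(100, 0.05)
  sim <- simulate_counts(100, 0.05, pcro_config(), S = 1e4, seed = 314)
  expect_lt(abs(mean(nspccp_count_dist(m)) / mean(sim$counts[, "nspccp"]) - 1),
            0.02)
})

test_that("cut-count law is the thinned candidate law", {
  m0 <- pcro_model(100, 0.05, p_pcro = 0)
  d0 <- adin_count_dist(m0)
  expect_equal(mean(d0), 0)
  expect_equal(d0$pmf[1], 1)
  m1 <- pcro_model(100, 0.05, p_pcro = 1)
  expect_lt(total_variation(adin_count_dist(m1), nspccp_count_dist(m1)), 1e-12)
  for (p in seq(0, 1, by = 0.1)) {
    mp <- pcro_model(100, 0.05, p_pcro = p)
    expect_equal(mean(adin_count_dist(mp)), p * mean(nspccp_count_dist(mp)),
                 tolerance = 1e-9)
  }
})

test_that("passive-isolation probability matches the literal summation oracle", {
  m <- pcro_model(100, 0.05, p_pcro = 0.5, truncation_tol = 1e-12)
  expect_equal(pdin_node_prob(m), oracle_pdin_node_prob(100, 0.05, 0.5),
               tolerance = 1e-10)
  expect_equal(pdin_node_prob(pcro_model(100, 0.05, p_pcro = 0)), 0)
})

test_that("passive and natural isolation counts are binomial with the stated moments", {
  m <- pcro_model(100, 0.05, p_pcro = 0.5)
  p <- pdin_node_prob(m)
  d <- pdin_count_dist(m)
  expect_equal(mean(d), 100 * p, tolerance = 1e-9)
  expect_equal(dist_variance(d), 100 * p * (1 - p), tolerance = 1e-9)
  dn <- nin_count_dist(m)
  expect_equal(mean(dn), 100 * 0.95^99, tolerance = 1e-12)
  expect_equal(mean(dn), 0.6232, tolerance = 1e-4)
  expect_equal(nin_count_dist(pcro_model(20, 0))$pmf[21], 1)
  expect_equal(nin_count_dist(pcro_model(20, 1))$pmf[1], 1)
})

test_that("natural-isolation node probability equals exhaustive enumeration", {
  # brute force over all 2^(N-1) neighbourhoods of one node at N = 12
  n <- 12; p_er <- 0.3
  p_iso <- 0
  for (mask in 0:(2^(n - 1) - 1)) {
    k <- sum(as.integer(intToBits(mask))[1:(n - 1)])
    if (k == 0) p_iso <- p_iso + p_er^k * (1 - p_er)^(n - 1 - k)
  }
  model <- pcro_model(n, p_er)
  expect_equal(mean(nin_count_dist(model)) / n, p_iso, tolerance = 1e-12)
})

test_that("the leaf-count law is the convolution of its three components", {
  delta <- function(k, n = 10) count_distribution(0:n, as.numeric(0:n == k))
  m <- pcro_model(10, 0.3, p_pcro = 0.5)
  # convolution of point masses lands on the summed count
  conv <- pcro:::conv_pmf(pcro:::conv_pmf(delta(1)$pmf, delta(2)$pmf), delta(3)$pmf)
  expect_equal(which(conv == 1) - 1, 6)
  expect_equal(sum(conv), 1)
  d <- cl_count_dist(m)
  expect_equal(mean(d),
               mean(nin_count_dist(m)) + mean(adin_count_dist(m)) +
                 mean(pdin_count_dist(m)),
               tolerance = 1e-12)
  expect_lt(attr(d, "super_n_mass"), 1e-3)  # diagnostic: tiny even at N = 10
})

test_that("the mean leaf curve starts at the natural isolates and never decreases", {
  m <- pcro_model(100, 0.05)
  curve <- mean_cl_curve(m, seq(0, 1, by = 0.1))
  expect_equal(curve$mean_cl[1], mean(nin_count_dist(m)), tolerance = 1e-9)
  expect_true(all(diff(curve$mean_cl) >= 0))
  # at full cutting the leaves include every candidate plus the natural isolates
  m1 <- pcro_model(100, 0.05, p_pcro = 1)
  expect_gte(curve$mean_cl[11] + 1e-9,
             mean(nspccp_count_dist(m1)) + mean(nin_count_dist(m1)))
})

test_that("results are insensitive to the mixture truncation tolerance", {
  base <- pcro_model(100, 0.05, p_pcro = 0.5, truncation_tol = 1e-12)
  ref <- cl_count_dist(base)
  for (tol in c(1e-8, 1e-10)) {
    m <- pcro_model(100, 0.05, p_pcro = 0.5, truncation_tol = tol)
    expect_lt(total_variation(cl_count_dist(m), ref), 1e-6)
  }
})

test_that("both focal degree-law variants are proper and differ as expected", {
  m_eb <- pcro_model(100, 0.05, p_pcro = 0.5)
  m_b <- pcro_model(100, 0.05, p_pcro = 0.5, pki_form = "binomial")
  p_eb <- pdin_node_prob(m_eb)
  p_b <- pdin_node_prob(m_b)
  expect_gt(p_b, p_eb)  # the size-biased focal law starves the low degrees
  expect_true(p_eb > 0 && p_b < 1)
})
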