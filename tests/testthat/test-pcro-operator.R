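test_that("constraints resolve to literals, averages, and maxima", {
  g <- fixture_graph()
  expect_equal(resolve_constraint(as_constraint(1), g), 1)
  expect_equal(resolve_constraint(as_constraint("avg_pre"), g), 10 / 6)
  expect_equal(resolve_constraint(as_constraint("max_pre"), g), 3)
  path <- igraph::graph_from_edgelist(matrix(c(1, 2, 2, 3), ncol = 2,
                                             byrow = TRUE), directed = FALSE)
  expect_equal(resolve_constraint(as_constraint("max_post"), path), 2)
  expect_error(as_constraint("bogus"))
  expect_error(as_constraint(-1))
})

test_that("candidate selection keeps exactly the in-band degrees", {
  g <- fixture_graph()  # degrees [3,2,2,1,1,1]
  expect_setequal(identify_candidates(g, 1, 10 / 6), c(4, 5, 6))
  expect_setequal(identify_candidates(g, 1, 2), c(2, 3, 4, 5, 6))
  expect_error(identify_candidates(g, 1, 0.5))
  empty <- igraph::make_empty_graph(4, directed = FALSE)
  expect_length(identify_candidates(empty, 1, 5), 0)
})

test_that("cutting at the probability extremes is exact", {
  g <- fixture_graph()
  cand <- identify_candidates(g, 1, 10 / 6)
  r0 <- cut_candidates(g, cand, 0)
  expect_equal(igraph::gsize(r0$post_cut), igraph::gsize(g))
  expect_length(r0$adin, 0)
  r1 <- cut_candidates(g, cand, 1)
  expect_equal(r1$adin, c(4L, 5L, 6L))
  expect_equal(sort(apply(igraph::as_edgelist(r1$post_cut), 1, paste, collapse = "-")),
               c("1-2", "1-3", "2-3"))
})

test_that("isolated nodes are classified into the three disjoint classes", {
  g <- fixture_graph()
  r1 <- cut_candidates(g, identify_candidates(g, 1, 10 / 6), 1)
  cls <- classify_isolated(g, r1$post_cut, r1$adin)
  expect_equal(cls$adin, c(4L, 5L, 6L))
  expect_length(cls$pdin, 0)
  expect_length(cls$nin, 0)
  # a node whose only neighbours are all cut becomes passively isolated
  star <- igraph::graph_from_edgelist(matrix(c(1, 2, 1, 3), ncol = 2,
                                             byrow = TRUE), directed = FALSE)
  rc <- cut_candidates(star, 1L, 1)  # cut the centre
  cls2 <- classify_isolated(star, rc$post_cut, rc$adin)
  expect_equal(cls2$adin, 1L)
  expect_setequal(cls2$pdin, c(2L, 3L))
  # pre-isolated node is naturally isolated regardless of the cut
  iso <- igraph::add_vertices(fixture_graph(), 1)
  r0 <- cut_candidates(iso, integer(0), 0)
  expect_equal(classify_isolated(iso, r0$post_cut, r0$adin)$nin, 7L)
  # inconsistent input: claimed cut node with surviving edges
  expect_error(classify_isolated(g, g, 1L), "surviving edges")
})

test_that("hub selection picks nodes closest to k3 with id tie-breaks", {
  g <- fixture_graph()
  post <- cut_candidates(g, c(4L, 5L, 6L), 1)$post_cut  # degrees [2,2,2,0,0,0]
  expect_equal(select_hubs(post, 2, 2), c(1L, 2L))
  star <- igraph::graph_from_edgelist(
    matrix(c(1, 2, 1, 3, 1, 4, 1, 5), ncol = 2, byrow = TRUE), directed = FALSE)
  expect_equal(select_hubs(star, 4, 1), 1L)
  expect_equal(select_hubs(star, 1, 2), c(2L, 3L))  # closest-to-1 by id
  empty <- igraph::make_empty_graph(5, directed = FALSE)
  expect_error(select_hubs(empty, 2, 2), class = "pcro_degenerate_error")
})

test_that("rewiring attaches every leaf to every hub and only that", {
  g <- fixture_graph()
  post <- cut_candidates(g, c(4L, 5L, 6L), 1)$post_cut
  final <- rewire_leaves(post, c(4L, 5L, 6L), c(1L, 2L))
  expect_equal(igraph::gsize(final), 9)
  expect_equal(unname(igraph::degree(final)[c(1, 2)]), c(5, 5))
  expect_equal(unname(igraph::degree(final)[4:6]), rep(2, 3))
  expect_identical(rewire_leaves(post, integer(0), c(1L, 2L)), post)
  one <- rewire_leaves(post, 4L, c(1L, 2L))
  expect_equal(unname(igraph::degree(one)[4]), 2)
  expect_error(rewire_leaves(post, c(1L, 4L), c(1L, 2L)), "overlap|leaf")
})

test_that("the full operation composes the stages and keeps its invariants", {
  g <- fixture_graph()
  res <- apply_pcro(g, pcro_config(p_pcro = 1), seed = 1)
  expect_equal(res$adin, c(4L, 5L, 6L))
  expect_equal(res$hubs, c(1L, 2L))
  expect_equal(igraph::gsize(res$final), 9)
  # p = 0 with a pre-isolated node: the lone natural isolate is the sole leaf
  iso <- igraph::add_vertices(fixture_graph(), 1)
  res0 <- apply_pcro(iso, pcro_config(p_pcro = 0), seed = 1)
  expect_equal(res0$cl, 7L)
  expect_equal(unname(igraph::degree(res0$final)[7]), 2)
  expect_equal(igraph::gsize(res0$final), igraph::gsize(iso) + 2)
})

test_that("random realizations satisfy conservation, edge accounting, and determinism", {
  set.seed(99)
  for (rep in 1:25) {
    g <- igraph::sample_gnp(40, 0.08)
    p <- runif(1)
    res <- apply_pcro(g, pcro_config(p_pcro = p), seed = 1000 + rep)
    n_cl <- length(res$cl)
    expect_equal(igraph::vcount(res$post_cut), 40)
    expect_equal(igraph::vcount(res$final), 40)
    expect_equal(igraph::gsize(res$final),
                 igraph::gsize(res$post_cut) + res$config$n_hubs * n_cl)
    expect_equal(n_cl, length(res$nin) + length(res$adin) + length(res$pdin))
    # monotone cutting: surviving edges are a subset avoiding cut nodes
    post_edges <- apply(igraph::as_edgelist(res$post_cut), 1, paste, collapse = "-")
    pre_edges <- apply(igraph::as_edgelist(res$pre), 1, paste, collapse = "-")
    expect_true(all(post_edges %in% pre_edges))
    expect_false(any(igraph::as_edgelist(res$post_cut) %in% res$adin))
    expect_equal(unname(res$classification$post_degree[res$cl]), rep(0L, n_cl))
  }
  g <- igraph::sample_gnp(40, 0.08)
  ra <- apply_pcro(g, pcro_config(p_pcro = 0.5), seed = 7)
  rb <- apply_pcro(g, pcro_config(p_pcro = 0.5), seed = 7)
  expect_identical(ra$classification, rb$classification)
  expect_identical(ra$hubs, rb$hubs)
})

test_that("at full cut probability the cut set equals the candidate set", {
  set.seed(5)
  for (rep in 1:10) {
    g <- igraph::sample_gnp(30, 0.1)
    res <- apply_pcro(g, pcro_config(p_pcro = 1), seed = rep)
    expect_setequal(res$adin, res$candidates)
  }
})

test_that("the cut-set mean follows the thinning of the candidate count", {
  set.seed(21)
  p <- 0.4
  nspccp <- adin <- numeric(400)
  for (r in 1:400) {
    g <- igraph::sample_gnp(100, 0.05)
    res <- apply_pcro(g, pcro_config(p_pcro = p))
    cc <- class_counts(res)
    nspccp[r] <- cc[["nspccp"]]
    adin[r] <- cc[["adin"]]
  }
  se <- sd(adin - p * nspccp) / sqrt(400)
  expect_lt(abs(mean(adin) - p * mean(nspccp)), 4 * se + 1e-9)
})

test_that("classification tables are written in the 0-based TSV dialect", {
  res <- apply_pcro(fixture_graph(), pcro_config(p_pcro = 1), seed = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_classification(res, path)
  lines <- readLines(path)
  expect_equal(lines[1], "#node_id\tpre_degree\tpost_degree\tlabel")
  tab <- read.delim(text = lines[-1], header = FALSE)
  expect_equal(tab$V1, 0:5)
  expect_equal(tab$V4, c("HUB", "HUB", "ORDINARY", "ADIN", "ADIN", "ADIN"))
})
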