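#' Preferential constraint specification
#'
#' The cutting band `[k1, k2]` and the rewiring target degree `k3` are either
#' literal numbers or symbolic quantities resolved on a realized graph:
#' \describe{
#'   \item{`avg_pre` / `avg_post`}{actual average degree `2L/N` of the graph
#'     before / after the cut (kept real-valued, never rounded).}
#'   \item{`max_pre` / `max_post`}{maximum degree before / after the cut.}
#' }
#'
#' @param x A single non-negative number (literal) or one of the strings
#'   `"avg_pre"`, `"max_pre"`, `"avg_post"`, `"max_post"`.
#' @return A `pcro_constraint` object.
#' @examples
#' as_constraint(1)
#' as_constraint("avg_pre")
#' @export
as_constraint <- function(x) {
  if (inherits(x, "pcro_constraint")) return(x)
  if (is.numeric(x)) {
    stopifnot(length(x) == 1, is.finite(x), x >= 0)
    return(structure(list(kind = "literal", value = as.numeric(x)),
                     class = "pcro_constraint"))
  }
  kind <- match.arg(x, c("avg_pre", "max_pre", "avg_post", "max_post"))
  structure(list(kind = kind, value = NULL), class = "pcro_constraint")
}

#' @export
format.pcro_constraint <- function(x, ...) {
  if (x$kind == "literal") format(x$value) else x$kind
}

#' @export
print.pcro_constraint <- function(x, ...) {
  cat("<constraint:", format(x), ">\n")
  invisible(x)
}

#' Resolve a constraint on a graph
#'
#' @param spec A [as_constraint()] specification.
#' @param g The graph the symbolic value refers to. The caller supplies the
#'   pre-cut graph for `avg_pre`/`max_pre` and the post-cut graph for
#'   `avg_post`/`max_post`.
#' @return A single numeric value.
#' @export
resolve_constraint <- function(spec, g) {
  spec <- as_constraint(spec)
  switch(spec$kind,
    literal = spec$value,
    avg_pre = ,
    avg_post = 2 * igraph::gsize(g) / igraph::vcount(g),
    max_pre = ,
    max_post = if (igraph::vcount(g)) max(igraph::degree(g)) else 0
  )
}

#' Configuration of a cutting--rewiring operation
#'
#' @param k1,k2 Lower/upper bound of the preferential cutting band; a node is
#'   a cutting candidate when its degree lies in `[k1, k2]` (inclusive; real
#'   bounds compared against integer degrees). Literal numbers or symbolic
#'   strings, see [as_constraint()]. Defaults `k1 = 1`, `k2 = "avg_pre"`.
#' @param k3 Target degree of the rewiring constraint; the hubs are the
#'   non-isolated post-cut nodes whose degree is closest to `k3`. Default
#'   `"max_post"` (the maximum post-cut degree).
#' @param p_pcro Probability with which each candidate is actually cut.
#' @param n_hubs Number of hubs every common leaf is attached to (default 2).
#' @return A `pcro_config` object.
#' @export
pcro_config <- function(k1 = 1, k2 = "avg_pre", k3 = "max_post",
                        p_pcro = 0.5, n_hubs = 2L) {
  stopifnot(length(p_pcro) == 1, p_pcro >= 0, p_pcro <= 1,
            length(n_hubs) == 1, n_hubs >= 1, n_hubs == round(n_hubs))
  structure(list(k1 = as_constraint(k1), k2 = as_constraint(k2),
                 k3 = as_constraint(k3), p_pcro = as.numeric(p_pcro),
                 n_hubs = as.integer(n_hubs)),
            class = "pcro_config")
}

#' @export
print.pcro_config <- function(x, ...) {
  cat(sprintf("PCRO configuration: band [%s, %s], rewiring target k3 = %s,\n",
              format(x$k1), format(x$k2), format(x$k3)))
  cat(sprintf("  cut probability p_pcro = %g, %d hub(s)\n", x$p_pcro, x$n_hubs))
  invisible(x)
}

#' Cutting candidates: nodes inside the degree band
#'
#' @param g A graph.
#' @param k1,k2 Resolved numeric band edges, `k1 <= k2`.
#' @return Integer vertex ids with `k1 <= degree <= k2`. Degree-0 nodes are
#'   never candidates when `k1 > 0`.
#' @export
identify_candidates <- function(g, k1, k2) {
  stopifnot(k1 <= k2)
  deg <- igraph::degree(g)
  which(deg >= k1 & deg <= k2)
}

#' Cutting stage: discard all links of probabilistically selected candidates
#'
#' Each candidate is independently selected with probability `p_pcro`; every
#' edge incident to a selected candidate is removed (unselected candidates
#' keep all their links). The selected candidates are the actively deleted
#' isolated nodes (ADINs).
#'
#' @param g Pre-cut graph.
#' @param candidates Integer vertex ids, the cutting candidates.
#' @param p_pcro Cut probability.
#' @return List with `post_cut` (graph) and `adin` (integer ids).
#' @export
cut_candidates <- function(g, candidates, p_pcro) {
  stopifnot(all(candidates >= 1), all(candidates <= igraph::vcount(g)))
  adin <- candidates[stats::runif(length(candidates)) < p_pcro]
  post <- if (length(adin)) {
    eids <- unlist(igraph::incident_edges(g, adin))
    igraph::delete_edges(g, unique(eids))
  } else g
  list(post_cut = post, adin = sort(as.integer(adin)))
}

#' Classify the isolated nodes produced by the cut
#'
#' Every node isolated after the cutting stage falls in exactly one class:
#' naturally isolated (NIN, degree 0 already before the cut), actively
#' deleted (ADIN, a cut candidate), or passively deleted (PDIN, isolated only
#' because all of its neighbours were cut).
#'
#' @param pre Pre-cut graph.
#' @param post_cut Post-cut graph (same node set).
#' @param adin Integer ids of the cut candidates.
#' @return List of integer id vectors `nin`, `adin`, `pdin`, `cl` (their
#'   union) plus the per-node factor `label`.
#' @export
classify_isolated <- function(pre, post_cut, adin) {
  n <- igraph::vcount(pre)
  stopifnot(igraph::vcount(post_cut) == n)
  deg_pre <- igraph::degree(pre)
  deg_post <- igraph::degree(post_cut)
  if (any(deg_post[adin] > 0))
    stop("internal inconsistency: a cut candidate still has surviving edges")
  nin <- which(deg_pre == 0)
  is_adin <- seq_len(n) %in% adin
  pdin <- which(deg_pre >= 1 & !is_adin & deg_post == 0)
  label <- rep("ORDINARY", n)
  label[nin] <- "NIN"
  label[adin] <- "ADIN"
  label[pdin] <- "PDIN"
  list(nin = as.integer(nin), adin = as.integer(adin), pdin = as.integer(pdin),
       cl = sort(as.integer(c(nin, adin, pdin))), label = label)
}

#' Select the rewiring target hubs
#'
#' Among the non-isolated post-cut nodes, picks the `n_hubs` nodes whose
#' degree is closest to the resolved `k3` (exactly the maximum-degree nodes
#' when `k3 = "max_post"`); ties are broken by ascending vertex id so the
#' choice is deterministic.
#'
#' @param post_cut Post-cut graph.
#' @param k3 Resolved numeric target degree.
#' @param n_hubs Number of hubs.
#' @return Ordered integer vertex ids.
#' @export
select_hubs <- function(post_cut, k3, n_hubs) {
  deg <- igraph::degree(post_cut)
  eligible <- which(deg >= 1)
  if (length(eligible) < n_hubs)
    stop(errorCondition(
      sprintf("degenerate network: only %d non-isolated node(s) available for %d hub(s)",
              length(eligible), n_hubs),
      class = c("pcro_degenerate_error", "error", "condition")))
  ord <- eligible[order(abs(deg[eligible] - k3), eligible)]
  as.integer(ord[seq_len(n_hubs)])
}

#' Rewiring stage: attach every common leaf to every hub
#'
#' @param post_cut Post-cut graph.
#' @param cl Integer ids of the common leaves (all post-cut isolated nodes).
#' @param hubs Integer hub ids.
#' @return The final graph: `post_cut` plus one edge from each leaf to each
#'   hub, so the edge count grows by `length(hubs) * length(cl)`.
#' @export
rewire_leaves <- function(post_cut, cl, hubs) {
  if (length(intersect(cl, hubs)))
    stop("internal inconsistency: common leaves and hubs overlap")
  if (any(igraph::degree(post_cut)[cl] > 0))
    stop("internal inconsistency: a common leaf has surviving edges")
  if (!length(cl)) return(post_cut)
  new_edges <- rbind(rep(cl, each = length(hubs)), rep(hubs, times = length(cl)))
  igraph::add_edges(post_cut, as.vector(new_edges))
}

#' Apply the full preferentially cutting--rewiring operation
#'
#' Runs the two-stage operation on a graph: resolve the cutting band
#' `[k1, k2]` on the pre-cut graph, select candidates, cut each with
#' probability `p_pcro`, classify the resulting isolated nodes, resolve `k3`
#' on the post-cut graph, select hubs, and rewire every isolated node as a
#' common leaf of all hubs.
#'
#' @param g An undirected simple igraph graph.
#' @param config A [pcro_config()].
#' @param seed Optional integer for a reproducible cut selection.
#' @return A `pcro_result` with the three graphs (`pre`, `post_cut`,
#'   `final`), a `classification` data frame (`node`, `pre_degree`,
#'   `post_degree`, `label`, `is_cl`), the resolved constraint values, the
#'   candidate ids, and the hub ids.
#' @examples
#' g <- sample_errn(100, 0.05, seed = 1)
#' res <- apply_pcro(g, pcro_config(p_pcro = 0.5), seed = 2)
#' res
#' @export
apply_pcro <- function(g, config = pcro_config(), seed = NULL) {
  stopifnot(inherits(config, "pcro_config"))
  with_seed(seed, {
    k1 <- resolve_constraint(config$k1, g)
    k2 <- resolve_constraint(config$k2, g)
    if (k1 > k2)
      stop(sprintf("resolved cutting band is empty: k1 = %g > k2 = %g", k1, k2))
    candidates <- identify_candidates(g, k1, k2)
    cutres <- cut_candidates(g, candidates, config$p_pcro)
    cls <- classify_isolated(g, cutres$post_cut, cutres$adin)
    k3 <- resolve_constraint(config$k3, cutres$post_cut)
    hubs <- select_hubs(cutres$post_cut, k3, config$n_hubs)
    final <- rewire_leaves(cutres$post_cut, cls$cl, hubs)
    label <- cls$label
    label[hubs] <- "HUB"
    classification <- data.frame(
      node = seq_len(igraph::vcount(g)),
      pre_degree = as.integer(igraph::degree(g)),
      post_degree = as.integer(igraph::degree(cutres$post_cut)),
      label = label,
      is_cl = label %in% c("NIN", "ADIN", "PDIN")
    )
    structure(list(pre = g, post_cut = cutres$post_cut, final = final,
                   classification = classification,
                   candidates = as.integer(candidates),
                   nin = cls$nin, adin = cls$adin, pdin = cls$pdin, cl = cls$cl,
                   hubs = hubs, k1 = k1, k2 = k2, k3 = k3, config = config),
              class = "pcro_result")
  })
}

#' Count the four node classes of a PCRO result
#'
#' @param result A `pcro_result`.
#' @return Named integer vector with components `nspccp` (candidates), `nin`,
#'   `adin`, `pdin`, and `cl` (= `nin + adin + pdin`).
#' @export
class_counts <- function(result) {
  stopifnot(inherits(result, "pcro_result"))
  c(nspccp = length(result$candidates), nin = length(result$nin),
    adin = length(result$adin), pdin = length(result$pdin),
    cl = length(result$cl))
}

#' @export
print.pcro_result <- function(x, ...) {
  cc <- class_counts(x)
  cat(sprintf("PCRO result on %d nodes\n", igraph::vcount(x$pre)))
  cat(sprintf("  edges: %d pre-cut, %d post-cut, %d final\n",
              igraph::gsize(x$pre), igraph::gsize(x$post_cut), igraph::gsize(x$final)))
  cat(sprintf("  resolved band [%g, %g], k3 = %g; hubs: %s\n",
              x$k1, x$k2, x$k3, paste(x$hubs, collapse = ", ")))
  cat(sprintf("  candidates: %d; NIN %d + ADIN %d + PDIN %d = %d common leaves\n",
              cc[["nspccp"]], cc[["nin"]], cc[["adin"]], cc[["pdin"]], cc[["cl"]]))
  invisible(x)
}

#' @export
summary.pcro_result <- function(object, ...) {
  print(object)
  cat("\nLabel counts:\n")
  print(table(object$classification$label))
  invisible(object)
}

#' Write a per-node classification table
#'
#' Tab-separated with a single `#`-prefixed header line; node ids are 0-based
#' to match the edge-list file dialect.
#'
#' @param result A `pcro_result`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_classification <- function(result, path) {
  cls <- result$classification
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#node_id\tpre_degree\tpost_degree\tlabel", con)
  writeLines(sprintf("%d\t%d\t%d\t%s", cls$node - 1L, cls$pre_degree,
                     cls$post_degree, cls$label), con)
  invisible(path)
}
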