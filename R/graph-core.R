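#' Generate an Erdos-Renyi random network
#'
#' Draws a G(N, p) random graph: each of the `N(N-1)/2` unordered node pairs
#' becomes an edge independently with probability `p_er`. Vertices are
#' `1..n_nodes`; isolated vertices are kept (they matter for the node
#' taxonomy of [apply_pcro()]).
#'
#' @param n_nodes Number of nodes (positive integer).
#' @param p_er Connection probability in `[0, 1]`.
#' @param seed Optional integer. When supplied the draw is made under a local
#'   RNG state seeded with `seed`, so the same seed always yields the same
#'   graph and the caller's RNG stream is left untouched.
#' @return An undirected simple [igraph::igraph] graph.
#' @examples
#' g <- sample_errn(100, 0.05, seed = 1)
#' igraph::gsize(g)
#' @export
sample_errn <- function(n_nodes, p_er, seed = NULL) {
  stopifnot(length(n_nodes) == 1, n_nodes >= 1, n_nodes == round(n_nodes),
            length(p_er) == 1, p_er >= 0, p_er <= 1)
  with_seed(seed, igraph::sample_gnp(n_nodes, p_er, directed = FALSE, loops = FALSE))
}

#' Degree sequence of a graph
#'
#' @param g An igraph graph.
#' @return Integer vector; element `i` is the degree of vertex `i`. The sum
#'   equals twice the edge count.
#' @export
degree_sequence <- function(g) {
  as.integer(igraph::degree(g))
}

# Run expr under a locally seeded RNG; NULL seed = use the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Read a graph from a file
#'
#' Two plain-text formats are supported:
#' \describe{
#'   \item{`edgelist`}{One edge per line as two whitespace-separated 0-based
#'     integer ids. Lines starting with `#` are comments; the optional header
#'     `#nodes N` fixes the node count so trailing isolated nodes survive a
#'     round-trip (otherwise `N` = max id + 1). Self-loops are rejected;
#'     duplicate edges are dropped with a warning (the model is a simple
#'     graph).}
#'   \item{`graphml`}{Delegated to [igraph::read_graph()].}
#' }
#'
#' @param path File to read.
#' @param format `"edgelist"` or `"graphml"`.
#' @return An undirected simple igraph graph with vertices `1..N`.
#' @export
read_network <- function(path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    g <- igraph::as_undirected(g, mode = "collapse")
    return(igraph::simplify(g))
  }
  lines <- readLines(path)
  n_declared <- NA_integer_
  edges <- matrix(integer(0), ncol = 2)
  seen <- character(0)
  dup <- 0L
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "") next
    if (startsWith(ln, "#")) {
      m <- regmatches(ln, regexec("^#\\s*nodes\\s+(\\d+)\\s*$", ln))[[1]]
      if (length(m) == 2) n_declared <- as.integer(m[[2]])
      next
    }
    parts <- strsplit(ln, "\\s+")[[1]]
    ids <- suppressWarnings(as.integer(parts))
    if (length(ids) != 2 || anyNA(ids) || any(ids < 0))
      stop(sprintf("line %d: expected two non-negative integer ids, got '%s'", i, ln))
    if (ids[1] == ids[2])
      stop(sprintf("line %d: self-loop '%d %d' not allowed in a simple graph", i, ids[1], ids[2]))
    key <- paste(sort(ids), collapse = "-")
    if (key %in% seen) {
      dup <- dup + 1L
      next
    }
    seen <- c(seen, key)
    edges <- rbind(edges, ids)
  }
  if (dup > 0)
    warning(sprintf("%d duplicate edge(s) dropped while reading '%s'", dup, path))
  n <- if (!is.na(n_declared)) n_declared else if (nrow(edges)) max(edges) + 1L else 0L
  if (nrow(edges) && max(edges) >= n)
    stop(sprintf("edge id %d out of range for declared node count %d", max(edges), n))
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges + 1L))
  g
}

#' Write a graph to a file
#'
#' @param g An igraph graph.
#' @param path Output file.
#' @param format `"edgelist"` (0-based dialect of [read_network()], with a
#'   `#nodes N` header) or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(g, path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
    return(invisible(path))
  }
  em <- igraph::as_edgelist(g, names = FALSE) - 1L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#nodes %d", igraph::vcount(g)), con)
  if (nrow(em))
    writeLines(sprintf("%d %d", em[, 1], em[, 2]), con)
  invisible(path)
}
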