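#' Average clustering coefficient
#'
#' Mean over all nodes of the local clustering coefficient (closed triangles
#' over wedges); nodes with degree below 2 contribute 0, the common
#' convention for graphs with leaves and isolated nodes.
#'
#' @param g An igraph graph.
#' @return A number in `[0, 1]`.
#' @export
avg_clustering <- function(g) {
  if (igraph::vcount(g) == 0) return(0)
  local <- igraph::transitivity(g, type = "local", isolates = "zero")
  mean(local)
}

#' Mean shortest path length over connected pairs
#'
#' Average of the shortest-path distances over all connected ordered pairs.
#' Operated networks can be disconnected, so disconnected pairs are excluded
#' from the average and their fraction is reported alongside, letting either
#' convention be reconstructed.
#'
#' @param g An igraph graph with at least one connected pair.
#' @return List with `mean_distance` and `excluded_fraction` (fraction of
#'   ordered node pairs with no connecting path).
#' @export
mean_shortest_path <- function(g) {
  n <- igraph::vcount(g)
  d <- igraph::distances(g)
  off <- d[row(d) != col(d)]
  finite <- is.finite(off)
  if (!any(finite))
    stop(errorCondition("no connected pair: mean shortest path undefined",
                        class = c("pcro_metric_error", "error", "condition")))
  list(mean_distance = mean(off[finite]),
       excluded_fraction = mean(!finite))
}

#' Structure metrics of operated networks across the cut probability
#'
#' For each grid value of the cut probability, applies the full
#' cutting--rewiring operation to `R` fresh Erdos-Renyi substrates and
#' averages the clustering coefficient and mean shortest path of the final
#' (post-rewiring) graphs. Realizations where hub selection is degenerate
#' are skipped and counted.
#'
#' @param n_nodes,p_er Substrate parameters.
#' @param config A [pcro_config()]; its `p_pcro` is overridden per grid point.
#' @param p_grid Cut probabilities.
#' @param R Realizations per grid point.
#' @param seed Optional integer.
#' @return Data frame: `p_pcro`, `clustering`, `clustering_se`,
#'   `path_length`, `path_length_se`, `excluded_fraction`, `n_rejected`.
#' @examples
#' metric_curve(50, 0.06, R = 5, p_grid = c(0, 0.5), seed = 1)
#' @export
metric_curve <- function(n_nodes, p_er, config = pcro_config(),
                         p_grid = c(0, 0.25, 0.5, 0.75, 0.97), R = 100,
                         seed = NULL) {
  stopifnot(R >= 1)
  with_seed(seed, {
    rows <- lapply(p_grid, function(p) {
      cfg <- config
      cfg$p_pcro <- p
      cc <- pl <- ex <- numeric(0)
      rejected <- 0L
      for (r in seq_len(R)) {
        g <- igraph::sample_gnp(n_nodes, p_er, directed = FALSE, loops = FALSE)
        res <- tryCatch(apply_pcro(g, cfg),
                        pcro_degenerate_error = function(e) NULL)
        if (is.null(res)) {
          rejected <- rejected + 1L
          next
        }
        cc <- c(cc, avg_clustering(res$final))
        sp <- mean_shortest_path(res$final)
        pl <- c(pl, sp$mean_distance)
        ex <- c(ex, sp$excluded_fraction)
      }
      data.frame(p_pcro = p,
                 clustering = mean(cc),
                 clustering_se = stats::sd(cc) / sqrt(length(cc)),
                 path_length = mean(pl),
                 path_length_se = stats::sd(pl) / sqrt(length(pl)),
                 excluded_fraction = mean(ex),
                 n_rejected = rejected)
    })
    do.call(rbind, rows)
  })
}
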