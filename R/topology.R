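#' Density of a simple undirected graph
#'
#' Computes `2E / (N (N - 1))` over all nodes of the graph, the standard
#' simple-graph density. The bipartite structure is deliberately ignored in
#' the denominator so that values are comparable with the usual sparse/dense
#' vocabulary for association networks.
#'
#' @param g An `md_graph` or `dd_graph` with at least two nodes.
#' @return A single number in `[0, 1]`.
#' @examples
#' graph_density(md_graph(data.frame(mirna = "m1", disease = "d1", weight = 1)))
#' @export
graph_density <- function(g) {
  n <- length(md_nodes(g))
  if (n < 2L) stop("density is undefined for graphs with fewer than 2 nodes")
  e <- md_edge_count(g)
  2 * e / (n * (n - 1))
}

#' Degree distribution summary with optional power-law slope
#'
#' Tabulates the degree histogram of all nodes (isolated nodes included),
#' reports the graph density, and optionally fits a descriptive power law
#' `P(k) ~ k^-gamma` by least squares on `log10 P(k)` versus `log10 k` over
#' the degrees k >= 1 with non-zero counts. The fit is a qualitative
#' scale-freeness diagnostic, not a maximum-likelihood estimate.
#'
#' @param g An `md_graph` or `dd_graph`; must be non-empty.
#' @param fit_powerlaw Fit the log-log slope? Needs >= 3 distinct positive
#'   degrees; otherwise the estimate is `NA` with a warning.
#' @return A `degree_summary` list: `degree_histogram` (named integer vector,
#'   degree -> node count), `density`, `powerlaw_exponent_estimate` (gamma,
#'   or `NA`), `fit_r_squared` (or `NA`).
#' @export
degree_summary <- function(g, fit_powerlaw = FALSE) {
  nodes <- md_nodes(g)
  if (!length(nodes)) stop("degree summary of an empty graph is undefined")
  adj <- graph_adjacency(g)
  deg <- lengths(adj)
  tab <- table(deg)
  hist <- setNames(as.integer(tab), names(tab))
  gamma <- NA_real_
  r2 <- NA_real_
  if (isTRUE(fit_powerlaw)) {
    k <- as.integer(names(hist))
    keep <- k >= 1L
    k <- k[keep]
    pk <- hist[keep] / length(nodes)
    if (length(k) >= 3L) {
      fit <- lm(log10(pk) ~ log10(k))
      gamma <- -unname(coef(fit)[[2L]])
      r2 <- summary(fit)$r.squared
    } else {
      warning("too few distinct degrees for a power-law fit")
    }
  }
  structure(list(degree_histogram = hist,
                 density = if (length(nodes) >= 2L) graph_density(g) else NA_real_,
                 powerlaw_exponent_estimate = gamma,
                 fit_r_squared = r2),
            class = "degree_summary")
}

#' @export
print.degree_summary <- function(x, ...) {
  cat(sprintf("degree summary: %d nodes, density %.4f\n",
              sum(x$degree_histogram), x$density))
  h <- x$degree_histogram
  cat("  degrees:", paste0(names(h), "x", h, collapse = " "), "\n")
  if (!is.na(x$powerlaw_exponent_estimate))
    cat(sprintf("  power-law slope gamma = %.3f (R^2 = %.3f)\n",
                x$powerlaw_exponent_estimate, x$fit_r_squared))
  invisible(x)
}

#' One-mode projection onto the disease partition
#'
#' Two diseases are linked in the projection when at least one miRNA
#' regulates both; the edge records how many miRNAs they share. Diseases
#' without any shared miRNA are retained as isolated nodes, so the node set
#' of the projection always equals the disease partition of the input.
#'
#' @param g An `md_graph`.
#' @return A `dd_graph`: list with `diseases` and `edges`
#'   (`d1`, `d2`, `shared_mirnas`; pairs stored with `d1 < d2`).
#' @examples
#' g <- md_graph(data.frame(mirna = "m1", disease = c("d1", "d2", "d3"),
#'                          weight = 1))
#' project_diseases(g)
#' @export
project_diseases <- function(g) {
  stopifnot(inherits(g, "md_graph"))
  diseases <- g$diseases
  if (nrow(g$edges) == 0L || length(diseases) < 2L)
    return(new_dd_graph(diseases))
  # incidence crossproduct: shared-miRNA counts for every disease pair
  mi <- factor(g$edges$mirna, levels = sort_c(g$mirnas))
  di <- factor(g$edges$disease, levels = sort_c(diseases))
  inc <- matrix(0L, nlevels(mi), nlevels(di),
                dimnames = list(levels(mi), levels(di)))
  inc[cbind(as.integer(mi), as.integer(di))] <- 1L
  shared <- crossprod(inc)
  pairs <- which(upper.tri(shared) & shared > 0, arr.ind = TRUE)
  if (!nrow(pairs)) return(new_dd_graph(diseases))
  edges <- data.frame(d1 = rownames(shared)[pairs[, 1L]],
                      d2 = colnames(shared)[pairs[, 2L]],
                      shared_mirnas = as.integer(shared[pairs]),
                      stringsAsFactors = FALSE)
  swap <- edges$d1 > edges$d2
  tmp <- edges$d1[swap]; edges$d1[swap] <- edges$d2[swap]; edges$d2[swap] <- tmp
  edges <- edges[order_c(edges$d1, edges$d2), , drop = FALSE]
  rownames(edges) <- NULL
  new_dd_graph(diseases, edges)
}

new_dd_graph <- function(diseases, edges = NULL) {
  if (is.null(edges))
    edges <- data.frame(d1 = character(0), d2 = character(0),
                        shared_mirnas = integer(0), stringsAsFactors = FALSE)
  structure(list(diseases = diseases, edges = edges), class = "dd_graph")
}

#' @export
print.dd_graph <- function(x, ...) {
  cat(sprintf("dd_graph (disease projection): %d diseases, %d edges\n",
              length(x$diseases), nrow(x$edges)))
  if (nrow(x$edges)) print(utils::head(x$edges, 6L), row.names = FALSE)
  invisible(x)
}

#' Deterministic shortest path between two nodes
#'
#' Minimum-hop path in the bipartite association graph (so the node sequence
#' alternates between miRNAs and diseases). Among equal-length shortest
#' paths the lexicographically smallest node sequence is returned, making
#' the result reproducible across platforms.
#'
#' @param g An `md_graph`.
#' @param from,to Node identifiers (miRNA or disease, either end).
#' @return Character vector of node ids from `from` to `to`, or `NULL` when
#'   the two nodes are disconnected.
#' @examples
#' g <- md_graph(data.frame(mirna = "m1", disease = c("d1", "d2"), weight = 1))
#' shortest_path(g, "d1", "d2")
#' @export
shortest_path <- function(g, from, to) {
  stopifnot(inherits(g, "md_graph"))
  nodes <- md_nodes(g)
  src <- resolve_ids(from, nodes)
  dst <- resolve_ids(to, nodes)
  if (is.na(src)) stop(sprintf("unknown node id '%s'", from))
  if (is.na(dst)) stop(sprintf("unknown node id '%s'", to))
  if (src == dst) return(src)
  adj <- graph_adjacency(g)
  ds <- bfs_dist(adj, src)
  if (is.infinite(ds[[dst]])) return(NULL)
  dt <- bfs_dist(adj, dst)
  # walk forward, always taking the smallest neighbor that stays on a
  # shortest path (one hop closer to the target)
  path <- src
  cur <- src
  while (cur != dst) {
    nb <- adj[[cur]]
    ok <- nb[ds[nb] == ds[[cur]] + 1 & dt[nb] == dt[[cur]] - 1]
    cur <- sort_c(ok)[[1L]]
    path <- c(path, cur)
  }
  path
}

bfs_dist <- function(adj, start) {
  dist <- setNames(rep(Inf, length(adj)), names(adj))
  dist[[start]] <- 0
  frontier <- start
  while (length(frontier)) {
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[is.infinite(dist[nxt])]
    if (!length(nxt)) break
    dist[nxt] <- dist[[frontier[[1L]]]] + 1
    frontier <- nxt
  }
  dist
}
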