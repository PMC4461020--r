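#' Scale-free bipartite network generator
#'
#' Grows a bipartite miRNA-disease network by preferential attachment,
#' emulating the long-tailed degree distributions observed in curated
#' association databases: starting from a single m1-d1 edge, nodes are added
#' one at a time to the currently smaller partition (miRNAs first on ties)
#' and each new node attaches to `edges_per_new_node` distinct existing
#' nodes of the opposite partition, chosen with probability proportional to
#' degree + 1 (the +1 lets low-degree nodes stay reachable on the small seed
#' graph). When fewer opposite-partition nodes exist than requested, all of
#' them are used, so for `edges_per_new_node = 2` and balanced partitions of
#' size n each the edge count is exactly `2 (2n - 2)`. Edge weights are
#' drawn from a geometric law on 1, 2, ... -- small positive counts with a
#' long tail, like supporting-publication counts.
#'
#' @param n_mirnas,n_diseases Partition sizes (>= 1).
#' @param edges_per_new_node Attachments per added node (>= 1).
#' @param weight_prob Success probability of the geometric weight law
#'   (weight = 1 + geometric; default 0.4, mean 2.5).
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @return An `md_graph` with miRNAs `m1..m<n>` and diseases `d1..d<n>`.
#' @examples
#' g <- scale_free_bipartite(50, 50, 2, seed = 1)
#' degree_summary(g)
#' @export
scale_free_bipartite <- function(n_mirnas, n_diseases, edges_per_new_node = 2L,
                                 weight_prob = 0.4, seed = 1L) {
  if (n_mirnas < 1L || n_diseases < 1L)
    stop("both partitions need at least one node")
  if (edges_per_new_node < 1L)
    stop("edges_per_new_node must be >= 1")
  if (weight_prob <= 0 || weight_prob > 1)
    stop("weight_prob must be in (0, 1]")
  set.seed(seed)
  mirnas <- paste0("m", seq_len(n_mirnas))
  diseases <- paste0("d", seq_len(n_diseases))
  deg_m <- setNames(integer(n_mirnas), mirnas)
  deg_d <- setNames(integer(n_diseases), diseases)
  em <- character(0); ed <- character(0)
  # seed edge m1-d1
  em <- "m1"; ed <- "d1"
  deg_m[["m1"]] <- 1L; deg_d[["d1"]] <- 1L
  nm <- 1L; nd <- 1L
  while (nm < n_mirnas || nd < n_diseases) {
    add_mirna <- if (nm >= n_mirnas) FALSE
      else if (nd >= n_diseases) TRUE
      else nm <= nd
    if (add_mirna) {
      nm <- nm + 1L
      new_node <- mirnas[[nm]]
      pool <- diseases[seq_len(nd)]
      wts <- deg_d[pool] + 1L
    } else {
      nd <- nd + 1L
      new_node <- diseases[[nd]]
      pool <- mirnas[seq_len(nm)]
      wts <- deg_m[pool] + 1L
    }
    k <- min(edges_per_new_node, length(pool))
    targets <- if (length(pool) == 1L) pool
      else sample(pool, k, replace = FALSE, prob = wts)
    if (add_mirna) {
      em <- c(em, rep(new_node, k)); ed <- c(ed, targets)
      deg_m[[new_node]] <- k
      deg_d[targets] <- deg_d[targets] + 1L
    } else {
      em <- c(em, targets); ed <- c(ed, rep(new_node, k))
      deg_d[[new_node]] <- k
      deg_m[targets] <- deg_m[targets] + 1L
    }
  }
  w <- 1L + rgeom(length(em), prob = weight_prob)
  md_graph(em, ed, weight = w)
}

#' Erdos-Renyi bipartite network generator
#'
#' Null fixture generator: every (miRNA, disease) pair is independently an
#' edge with probability `edge_prob`, with uniform integer weights in
#' `1..max_weight`.
#'
#' @param n_mirnas,n_diseases Partition sizes.
#' @param edge_prob Edge probability in `[0, 1]`.
#' @param max_weight Upper bound of the uniform weight law (default 30).
#' @param seed Integer seed.
#' @return An `md_graph` (possibly with isolated nodes).
#' @export
er_bipartite <- function(n_mirnas, n_diseases, edge_prob, max_weight = 30L,
                         seed = 1L) {
  if (edge_prob < 0 || edge_prob > 1) stop("edge_prob must be in [0, 1]")
  set.seed(seed)
  mirnas <- paste0("m", seq_len(n_mirnas))
  diseases <- paste0("d", seq_len(n_diseases))
  pairs <- expand.grid(mirna = mirnas, disease = diseases,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pairs <- pairs[order_c(pairs$mirna, pairs$disease), , drop = FALSE]
  keep <- runif(nrow(pairs)) < edge_prob
  pairs <- pairs[keep, , drop = FALSE]
  if (nrow(pairs) == 0L)
    return(new_md_graph(mirnas, diseases))
  w <- sample.int(max_weight, nrow(pairs), replace = TRUE)
  g <- md_graph(pairs$mirna, pairs$disease, weight = w)
  # retain isolated nodes so densities refer to the full partition sizes
  new_md_graph(mirnas, diseases, g$edges)
}

#' The five-edge worked example network
#'
#' The small instance used throughout the documentation: three miRNAs, four
#' diseases and five weighted associations (m1-d1 = 20, m1-d2 = 30,
#' m2-d3 = 2, m3-d3 = 16, m3-d4 = 10). Its maximum-weight matching selects
#' (m1, d2) and (m3, d3) with objective 46, leaving the well-supported pair
#' m1-d1 to be recovered by the merge rule.
#'
#' @return An `md_graph` with 3 miRNAs, 4 diseases and 5 edges.
#' @examples
#' worked_example()
#' @export
worked_example <- function() {
  md_graph(c("m1", "m1", "m2", "m3", "m3"),
           c("d1", "d2", "d3", "d3", "d4"),
           weight = c(20L, 30L, 2L, 16L, 10L))
}
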