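# Independent brute-force oracles used to validate the package's optimized
# implementations. These deliberately share no code with the package
# internals: everything here works off a plain adjacency matrix.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Symmetric adjacency matrix over all nodes of an md_graph.
oracle_adjacency <- function(g) {
  nodes <- sort(c(g$mirnas, g$diseases), method = "radix")
  A <- matrix(FALSE, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  e <- g$edges
  for (r in seq_len(nrow(e))) {
    A[e$mirna[[r]], e$disease[[r]]] <- TRUE
    A[e$disease[[r]], e$mirna[[r]]] <- TRUE
  }
  A
}

# All-subsets census: test every k-node subset for connectivity and class.
oracle_census <- function(g) {
  A <- oracle_adjacency(g)
  nodes <- rownames(A)
  counts <- c(path3 = 0L, triangle3 = 0L, path4 = 0L, star4 = 0L,
              cycle4 = 0L, other4 = 0L)
  part <- new.env(parent = emptyenv())
  for (k in 3:4) {
    if (length(nodes) < k) next
    for (idx in utils::combn(length(nodes), k, simplify = FALSE)) {
      sub <- A[idx, idx] * 1
      deg <- colSums(sub)
      ec <- sum(sub) / 2
      reach <- (sub + diag(k)) > 0
      for (t in seq_len(k)) reach <- (reach %*% sub + reach) > 0
      if (!all(reach[1L, ])) next
      ds <- sort(deg)
      cls <- if (k == 3) {
        if (ec == 2) "path3" else "triangle3"
      } else if (ec == 3 && all(ds == c(1, 1, 2, 2))) "path4"
      else if (ec == 3 && all(ds == c(1, 1, 1, 3))) "star4"
      else if (ec == 4 && all(ds == c(2, 2, 2, 2))) "cycle4"
      else "other4"
      counts[[cls]] <- counts[[cls]] + 1L
      for (nd in nodes[idx]) {
        key <- paste(nd, cls)
        assign(key, (part[[key]] %||% 0L) + 1L, part)
      }
    }
  }
  list(counts = counts, participation = part)
}

# Common-neighbor counts for every unordered disease pair.
oracle_projection <- function(g) {
  ds <- sort(g$diseases, method = "radix")
  out <- data.frame(d1 = character(0), d2 = character(0),
                    shared = integer(0), stringsAsFactors = FALSE)
  if (length(ds) < 2) return(out)
  neigh <- lapply(ds, function(d) g$edges$mirna[g$edges$disease == d])
  names(neigh) <- ds
  for (i in seq_len(length(ds) - 1L)) {
    for (j in seq(i + 1L, length(ds))) {
      sh <- length(intersect(neigh[[i]], neigh[[j]]))
      if (sh > 0)
        out <- rbind(out, data.frame(d1 = ds[[i]], d2 = ds[[j]],
                                     shared = sh, stringsAsFactors = FALSE))
    }
  }
  out
}

# Length of the shortest path between two nodes by exhaustive simple-path
# search (small graphs only). Returns Inf when disconnected.
oracle_shortest_length <- function(g, from, to) {
  A <- oracle_adjacency(g)
  best <- Inf
  walk <- function(cur, seen, len) {
    if (len >= best) return(invisible(NULL))
    if (cur == to) { best <<- len; return(invisible(NULL)) }
    for (nb in rownames(A)[A[cur, ]])
      if (!(nb %in% seen)) walk(nb, c(seen, nb), len + 1L)
  }
  walk(from, from, 0L)
  best
}

# Degree of every node, straight off the edge table.
oracle_degrees <- function(g) {
  nodes <- sort(c(g$mirnas, g$diseases), method = "radix")
  tab <- table(factor(c(g$edges$mirna, g$edges$disease), levels = nodes))
  stats::setNames(as.integer(tab), nodes)
}
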