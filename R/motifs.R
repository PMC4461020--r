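# Connected 3-/4-node subgraph classes. In a bipartite association network
# only the first and the last three can occur; triangle3/other4 arise when a
# census is run on the (non-bipartite) disease-disease projection.
.motif_classes <- c("path3", "triangle3", "path4", "star4", "cycle4", "other4")

# Sorted node ids and integer adjacency for fast enumeration.
adj_index <- function(g) {
  nodes <- sort_c(md_nodes(g))
  adj <- graph_adjacency(g)[nodes]
  list(nodes = nodes,
       adj = lapply(adj, function(nb) sort.int(match(nb, nodes))))
}

#' Enumerate connected induced subgraphs of size 3 or 4
#'
#' ESU-style enumeration: every connected induced k-node subgraph is visited
#' exactly once as an unordered node set, in a deterministic (sorted) order.
#'
#' @param g An `md_graph` or `dd_graph`.
#' @param k Subgraph size, 3 or 4.
#' @return List of character vectors (sorted node ids), one per occurrence.
#' @examples
#' g <- md_graph(data.frame(mirna = "m1", disease = c("d1", "d2", "d3"),
#'                          weight = 1))
#' enumerate_subgraphs(g, 3)
#' @export
enumerate_subgraphs <- function(g, k) {
  if (!k %in% c(3L, 4L)) stop("only subgraph sizes 3 and 4 are supported")
  ix <- adj_index(g)
  sets <- esu_enumerate(ix$adj, as.integer(k))
  lapply(sets, function(s) ix$nodes[s])
}

esu_enumerate <- function(adj, k) {
  n <- length(adj)
  out <- list()
  cnt <- 0L
  record <- function(sub) {
    cnt <<- cnt + 1L
    out[[cnt]] <<- sort.int(sub)
  }
  extend <- function(sub, ext, nbh, v) {
    if (length(sub) == k) { record(sub); return(invisible(NULL)) }
    while (length(ext)) {
      w <- ext[[1L]]
      ext <- ext[-1L]
      wn <- adj[[w]]
      excl <- wn[wn > v & !(wn %in% nbh)]
      extend(c(sub, w), c(ext, excl), c(nbh, w, excl), v)
    }
  }
  for (v in seq_len(n)) {
    vn <- adj[[v]]
    ext <- vn[vn > v]
    extend(v, ext, c(v, ext), v)
  }
  length(out) <- cnt
  out
}

#' Classify a connected 3- or 4-node induced subgraph
#'
#' Classification is by the induced degree sequence (plus edge count): a
#' connected 3-node subgraph with 2 edges is a `path3` (one miRNA regulating
#' two diseases, or two miRNAs regulating one disease -- undirected, the two
#' readings are one class) and with 3 edges a `triangle3` (projection
#' networks only). Connected 4-node subgraphs: degree sequence (1,1,2,2) is
#' `path4`, (1,1,1,3) `star4`, (2,2,2,2) with 4 edges the square `cycle4`;
#' anything denser (possible only off the bipartite network) is `other4`.
#'
#' @param g An `md_graph` or `dd_graph`.
#' @param nodes Character vector of 3 or 4 node ids inducing a connected
#'   subgraph.
#' @return One of `"path3"`, `"triangle3"`, `"path4"`, `"star4"`,
#'   `"cycle4"`, `"other4"`.
#' @export
classify_motif <- function(g, nodes) {
  nodes <- unique(as.character(nodes))
  k <- length(nodes)
  if (!k %in% c(3L, 4L)) stop("motif classification needs 3 or 4 distinct nodes")
  all_nodes <- md_nodes(g)
  if (!all(nodes %in% all_nodes)) stop("unknown node id in motif candidate")
  adj <- graph_adjacency(g)[nodes]
  deg <- vapply(adj, function(nb) sum(nb %in% nodes), integer(1L))
  ecount <- sum(deg) / 2L
  if (!connected_subset(adj, nodes))
    stop("node set does not induce a connected subgraph")
  classify_degseq(sort.int(unname(deg)), k, as.integer(ecount))
}

classify_degseq <- function(deg, k, ecount) {
  if (k == 3L) {
    if (ecount == 2L) return("path3")
    return("triangle3")
  }
  if (ecount == 3L && identical(deg, c(1L, 1L, 2L, 2L))) return("path4")
  if (ecount == 3L && identical(deg, c(1L, 1L, 1L, 3L))) return("star4")
  if (ecount == 4L && identical(deg, c(2L, 2L, 2L, 2L))) return("cycle4")
  "other4"
}

connected_subset <- function(adj, nodes) {
  seen <- nodes[[1L]]
  frontier <- seen
  while (length(frontier)) {
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- setdiff(intersect(nxt, nodes), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  length(seen) == length(nodes)
}

#' Census of 3- and 4-node connected subgraphs
#'
#' Enumerates every connected induced subgraph on 3 and 4 nodes, classifies
#' each occurrence, and tallies per-class occurrence counts and (optionally)
#' per-node participation counts -- the number of occurrences of a class
#' containing each node, the motif-route prioritization score.
#'
#' @param g A non-empty `md_graph` or `dd_graph`.
#' @param participation Tally per-node participation? (default `TRUE`)
#' @param keep_occurrences Retain the occurrence node sets (needed for
#'   uniqueness computation; default `FALSE`).
#' @return A `motif_census`: list with `counts` (named integer vector over
#'   the motif classes), `participation` (data frame `node`, `class`,
#'   `count`, or `NULL`), and `occurrences` (list class -> list of node
#'   sets, or `NULL`).
#' @examples
#' motif_census(md_graph(data.frame(mirna = "m1",
#'   disease = c("d1", "d2", "d3"), weight = 1)))$counts
#' @export
motif_census <- function(g, participation = TRUE, keep_occurrences = FALSE) {
  if (!length(md_nodes(g))) stop("census of an empty graph is undefined")
  ix <- adj_index(g)
  counts <- setNames(integer(length(.motif_classes)), .motif_classes)
  occ <- if (keep_occurrences)
    setNames(lapply(.motif_classes, function(x) list()), .motif_classes)
  part_env <- if (participation) new.env(parent = emptyenv())
  for (k in c(3L, 4L)) {
    sets <- esu_enumerate(ix$adj, k)
    for (s in sets) {
      deg <- sort.int(vapply(s, function(u) sum(ix$adj[[u]] %in% s), integer(1L)))
      cls <- classify_degseq(deg, k, sum(deg) %/% 2L)
      counts[[cls]] <- counts[[cls]] + 1L
      if (keep_occurrences) occ[[cls]][[length(occ[[cls]]) + 1L]] <- ix$nodes[s]
      if (participation) {
        for (u in s) {
          key <- paste(cls, u, sep = "\r")
          part_env[[key]] <- (part_env[[key]] %||% 0L) + 1L
        }
      }
    }
  }
  part <- NULL
  if (participation) {
    keys <- ls(part_env, sorted = FALSE)
    if (length(keys)) {
      bits <- strsplit(keys, "\r", fixed = TRUE)
      part <- data.frame(
        node = ix$nodes[as.integer(vapply(bits, `[[`, character(1L), 2L))],
        class = vapply(bits, `[[`, character(1L), 1L),
        count = vapply(keys, function(kk) part_env[[kk]], integer(1L)),
        stringsAsFactors = FALSE)
      part <- part[order_c(part$node, part$class), , drop = FALSE]
      rownames(part) <- NULL
    } else {
      part <- data.frame(node = character(0), class = character(0),
                         count = integer(0), stringsAsFactors = FALSE)
    }
  }
  structure(list(counts = counts, participation = part,
                 occurrences = occ, ensemble_stats = NULL,
                 ensemble_size = NULL, seed = NULL),
            class = "motif_census")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.motif_census <- function(x, ...) {
  cat("motif census:\n")
  shown <- x$counts[x$counts > 0 | names(x$counts) %in%
                      c("path3", "path4", "star4", "cycle4")]
  for (nm in names(shown)) cat(sprintf("  %-9s %d\n", nm, shown[[nm]]))
  if (!is.null(x$ensemble_stats)) {
    cat(sprintf("null ensemble: %d degree-preserving randomizations (seed %s)\n",
                x$ensemble_size, format(x$seed)))
    print(x$ensemble_stats, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Degree-preserving randomization by double edge swaps
#'
#' Generates a null network with exactly the input's degree sequence:
#' `round(swap_factor * E)` attempted swaps each pick two edges (a,b) and
#' (c,d) (a, c miRNAs) and rewire them to (a,d), (c,b) when neither rewired
#' edge already exists; bipartiteness and simplicity are preserved by
#' construction. Each edge's weight travels with its miRNA endpoint;
#' citation records are dropped (a rewired association has no provenance).
#'
#' @param g An `md_graph` with at least 2 edges.
#' @param swap_factor Attempted swaps per edge (default 10).
#' @param seed Optional integer; when given, seeds the RNG for a
#'   reproducible randomization. `NULL` uses (and advances) the current RNG
#'   state.
#' @return A randomized `md_graph` with the same nodes and degree sequence.
#' @export
randomize_edges <- function(g, swap_factor = 10, seed = NULL) {
  stopifnot(inherits(g, "md_graph"))
  e <- nrow(g$edges)
  if (e < 2L) stop("randomization needs at least 2 edges")
  if (swap_factor < 0) stop("swap_factor must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  m <- g$edges$mirna
  d <- g$edges$disease
  w <- g$edges$weight
  exists <- new.env(parent = emptyenv(), size = 2L * e)
  for (i in seq_len(e)) assign(paste(m[[i]], d[[i]], sep = "\r"), TRUE, exists)
  attempts <- round(swap_factor * e)
  for (a in seq_len(max(0L, attempts))) {
    ij <- sample.int(e, 2L)
    i <- ij[[1L]]; j <- ij[[2L]]
    if (m[[i]] == m[[j]] || d[[i]] == d[[j]]) next
    k1 <- paste(m[[i]], d[[j]], sep = "\r")
    k2 <- paste(m[[j]], d[[i]], sep = "\r")
    if (exists(k1, envir = exists, inherits = FALSE) ||
        exists(k2, envir = exists, inherits = FALSE)) next
    rm(list = c(paste(m[[i]], d[[i]], sep = "\r"),
                paste(m[[j]], d[[j]], sep = "\r")), envir = exists)
    tmp <- d[[i]]; d[[i]] <- d[[j]]; d[[j]] <- tmp
    assign(k1, TRUE, exists)
    assign(k2, TRUE, exists)
  }
  edges <- data.frame(mirna = m, disease = d, weight = w,
                      stringsAsFactors = FALSE)
  edges$pubmed_ids <- rep(list(character(0)), e)
  edges$directions <- rep(list(character(0)), e)
  edges <- edges[order_c(edges$mirna, edges$disease), , drop = FALSE]
  rownames(edges) <- NULL
  new_md_graph(g$mirnas, g$diseases, edges)
}

#' Motif significance against a degree-preserving null ensemble
#'
#' Runs the census on the real network and on `ensemble_size` independent
#' degree-preserving randomizations, and reports per class: the random mean
#' and standard deviation, the Z-score `(real - mean)/sd` (flagged `NA` when
#' the ensemble is degenerate with sd 0), the empirical p-value (fraction of
#' random networks with count >= real), and the uniqueness (size of a greedy
#' edge-disjoint packing of the real occurrences, taken in sorted order). A
#' motif is flagged significant when `z >= z_threshold`,
#' `p <= p_threshold` and `uniqueness >= uniqueness_threshold`, the
#' conventional census-tool criteria; thresholds are configurable.
#'
#' @param g An `md_graph`.
#' @param ensemble_size Number of random networks (>= 2; default 1000).
#' @param swap_factor Attempted swaps per edge per randomization.
#' @param seed Integer seed; the whole computation is reproducible from it.
#' @param z_threshold,p_threshold,uniqueness_threshold Significance flags.
#' @return A `motif_census` whose `ensemble_stats` data frame has columns
#'   `class`, `real_count`, `random_mean`, `random_std`, `z_score`,
#'   `empirical_p`, `uniqueness`, `significant`.
#' @export
motif_significance <- function(g, ensemble_size = 1000L, swap_factor = 10,
                               seed = 1L, z_threshold = 2,
                               p_threshold = 0.01, uniqueness_threshold = 4) {
  stopifnot(inherits(g, "md_graph"))
  if (ensemble_size < 2L)
    stop("ensemble_size must be >= 2 (standard deviation undefined otherwise)")
  real <- motif_census(g, participation = TRUE, keep_occurrences = TRUE)
  set.seed(seed)
  rand_counts <- matrix(0L, nrow = ensemble_size, ncol = length(.motif_classes),
                        dimnames = list(NULL, .motif_classes))
  for (r in seq_len(ensemble_size)) {
    rg <- randomize_edges(g, swap_factor = swap_factor, seed = NULL)
    rand_counts[r, ] <- motif_census(rg, participation = FALSE)$counts
  }
  stats <- data.frame(class = .motif_classes, stringsAsFactors = FALSE)
  stats$real_count <- as.integer(real$counts[.motif_classes])
  stats$random_mean <- colMeans(rand_counts)
  stats$random_std <- apply(rand_counts, 2L, sd)
  stats$z_score <- ifelse(stats$random_std > 0,
                          (stats$real_count - stats$random_mean) / stats$random_std,
                          NA_real_)
  stats$empirical_p <- vapply(seq_along(.motif_classes), function(ci)
    mean(rand_counts[, ci] >= stats$real_count[[ci]]), numeric(1L))
  ekeys <- edge_key_set(g)
  stats$uniqueness <- vapply(.motif_classes, function(cls)
    uniqueness_count(real$occurrences[[cls]], ekeys), integer(1L))
  stats$significant <- !is.na(stats$z_score) &
    stats$z_score >= z_threshold &
    stats$empirical_p <= p_threshold &
    stats$uniqueness >= uniqueness_threshold
  real$ensemble_stats <- stats
  real$ensemble_size <- as.integer(ensemble_size)
  real$seed <- seed
  real
}

# Unordered-pair keys of a graph's edges, for induced-edge lookups.
edge_key_set <- function(g) {
  if (inherits(g, "md_graph")) {
    a <- g$edges$mirna; b <- g$edges$disease
  } else {
    a <- g$edges$d1; b <- g$edges$d2
  }
  lo <- pmin(a, b); hi <- pmax(a, b)
  keys <- paste(lo, hi, sep = "\r")
  env <- new.env(parent = emptyenv(), size = max(2L, 2L * length(keys)))
  for (k in keys) assign(k, TRUE, env)
  env
}

# Greedy edge-disjoint packing of occurrences (sorted occurrence order): the
# number of occurrences whose induced edges share no edge with an earlier
# kept occurrence.
uniqueness_count <- function(occurrences, edge_set) {
  if (is.null(occurrences) || !length(occurrences)) return(0L)
  keys <- vapply(occurrences, paste, character(1L), collapse = "\r")
  occurrences <- occurrences[order_c(keys)]
  used <- new.env(parent = emptyenv())
  kept <- 0L
  for (s in occurrences) {
    s <- sort_c(s)
    pairs <- utils::combn(s, 2L, simplify = FALSE)
    ekeys <- vapply(pairs, paste, character(1L), collapse = "\r")
    ekeys <- ekeys[vapply(ekeys, exists, logical(1L),
                          envir = edge_set, inherits = FALSE)]
    if (any(vapply(ekeys, exists, logical(1L), envir = used, inherits = FALSE)))
      next
    for (ek in ekeys) assign(ek, TRUE, used)
    kept <- kept + 1L
  }
  kept
}

#' Motif-participation disease prioritization
#'
#' The structural alternative to the matching route: restrict the network to
#' the queried miRNAs and their adjacent diseases, run the census there, and
#' rank diseases by their total participation across the requested motif
#' classes (descending, ties by disease id). Diseases participating in no
#' occurrence are omitted.
#'
#' @param g An `md_graph`.
#' @param query Character vector of miRNA ids.
#' @param classes Motif classes to pool (default: all four bipartite
#'   classes).
#' @return Data frame with columns `disease` and `participation`, the
#'   resolved query attached as attribute `query`.
#' @examples
#' g <- md_graph(data.frame(mirna = "m1", disease = c("d1", "d2", "d3"),
#'                          weight = 1))
#' motif_prioritize(g, "m1", classes = "path3")
#' @export
motif_prioritize <- function(g, query,
                             classes = c("path3", "path4", "star4", "cycle4")) {
  stopifnot(inherits(g, "md_graph"))
  if (!length(query)) stop("query must contain at least one miRNA id")
  bad <- setdiff(classes, .motif_classes)
  if (length(bad)) stop(sprintf("unknown motif class '%s'", bad[[1L]]))
  res <- resolve_ids(query, g$mirnas)
  if (anyNA(res)) {
    warning(sprintf("dropping %d unknown query miRNA(s)", sum(is.na(res))))
    res <- unique(res[!is.na(res)])
  } else res <- unique(res)
  if (!length(res)) stop("no query miRNA is present in the graph")
  sub <- induced_query_graph(g, res)
  empty <- data.frame(disease = character(0), participation = integer(0),
                      stringsAsFactors = FALSE)
  if (length(md_nodes(sub)) < 3L) {
    warning("induced subnetwork too small for motifs; empty ranking")
    return(structure(empty, query = res, class = c("motif_ranking", "data.frame")))
  }
  cen <- motif_census(sub, participation = TRUE)
  part <- cen$participation
  part <- part[part$class %in% classes & part$node %in% sub$diseases, , drop = FALSE]
  if (!nrow(part)) {
    warning("no motif occurrences in the induced subnetwork")
    return(structure(empty, query = res, class = c("motif_ranking", "data.frame")))
  }
  agg <- aggregate(list(participation = part$count), list(disease = part$node), sum)
  agg$participation <- as.integer(agg$participation)
  agg <- agg[order_c(-agg$participation, agg$disease), , drop = FALSE]
  rownames(agg) <- NULL
  structure(agg, query = res, class = c("motif_ranking", "data.frame"))
}
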