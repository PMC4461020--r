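#' Exact maximum-weight bipartite matching
#'
#' Solves the core optimization of the association model: select a set of
#' vertex-disjoint (miRNA, disease) edges maximizing the total publication
#' weight, i.e.
#' \deqn{\max \sum_{i,j} W_{ij} X_{ij}, \quad \sum_j X_{ij} \le 1,
#'       \; \sum_i X_{ij} \le 1, \; X_{ij} \in \{0,1\},}
#' with one constraint per miRNA and one per disease. The solver runs the
#' O(n^3) Hungarian algorithm on the padded assignment profit matrix (the
#' assignment LP is integral on bipartite graphs, so this is exact), then
#' resolves ties: among all maximum-weight matchings the one whose sorted
#' pair list is lexicographically smallest is returned, by greedily forcing
#' edges in id order and re-solving the reduced problem. Weight arithmetic
#' is exact integer arithmetic.
#'
#' @param g An `md_graph` (may be empty).
#' @return An `mwm_solution`: list with `pairs` (data frame `mirna`,
#'   `disease`, `weight`, sorted) and integer `objective`.
#' @examples
#' g <- worked_example()
#' mwm_solve(g)
#' @export
mwm_solve <- function(g) {
  stopifnot(inherits(g, "md_graph"))
  edges <- g$edges[, c("mirna", "disease", "weight"), drop = FALSE]
  if (nrow(edges) == 0L) return(new_mwm_solution(edges, 0L))
  best <- assignment_value(edges)
  # lexicographic refinement: force edges in sorted order while optimality
  # is preserved on the remaining reduced instance
  edges <- edges[order_c(edges$mirna, edges$disease), , drop = FALSE]
  chosen <- integer(0)
  used_m <- character(0)
  used_d <- character(0)
  got <- 0L
  for (i in seq_len(nrow(edges))) {
    if (got == best) break
    e <- edges[i, ]
    if (e$mirna %in% used_m || e$disease %in% used_d) next
    rest <- edges[-seq_len(i), , drop = FALSE]
    rest <- rest[!(rest$mirna %in% c(used_m, e$mirna)) &
                   !(rest$disease %in% c(used_d, e$disease)), , drop = FALSE]
    if (got + e$weight + assignment_value(rest) == best) {
      chosen <- c(chosen, i)
      used_m <- c(used_m, e$mirna)
      used_d <- c(used_d, e$disease)
      got <- got + e$weight
    }
  }
  pairs <- edges[chosen, , drop = FALSE]
  rownames(pairs) <- NULL
  new_mwm_solution(pairs, as.integer(best))
}

new_mwm_solution <- function(pairs, objective) {
  structure(list(pairs = pairs, objective = objective), class = "mwm_solution")
}

#' @export
print.mwm_solution <- function(x, ...) {
  cat(sprintf("maximum-weight matching: %d pairs, objective %d\n",
              nrow(x$pairs), x$objective))
  if (nrow(x$pairs)) print(x$pairs, row.names = FALSE)
  invisible(x)
}

# Optimal matching weight of an edge table, via Hungarian assignment on the
# zero-padded square profit matrix. Non-edges have profit 0, so dropping
# zero-profit assignments afterwards leaves a maximum-weight matching.
assignment_value <- function(edges) {
  if (nrow(edges) == 0L) return(0L)
  ms <- sort_c(unique(edges$mirna))
  ds <- sort_c(unique(edges$disease))
  n <- max(length(ms), length(ds))
  profit <- matrix(0, n, n)
  profit[cbind(match(edges$mirna, ms), match(edges$disease, ds))] <- edges$weight
  cost <- max(profit) - profit
  assign_col <- hungarian_min(cost)
  total <- 0L
  for (j in seq_len(n)) {
    i <- assign_col[[j]]
    total <- total + as.integer(profit[i, j])
  }
  total
}

# Hungarian algorithm (Jonker-Volgenant style potentials) for the min-cost
# perfect assignment of a square cost matrix. Returns, for each column, the
# assigned row.
hungarian_min <- function(cost) {
  n <- nrow(cost)
  u <- numeric(n + 1L)       # row potentials (index 1 = virtual row 0)
  v <- numeric(n + 1L)       # column potentials (index 1 = virtual col 0)
  p <- integer(n + 1L)       # p[j+1]: row matched to column j (0 = none)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      free_j <- which(!used[-1L])          # candidate columns 1..n
      cur <- cost[i0, free_j] - u[i0 + 1L] - v[free_j + 1L]
      upd <- cur < minv[free_j + 1L]
      minv[free_j[upd] + 1L] <- cur[upd]
      way[free_j[upd] + 1L] <- j0
      k <- which.min(minv[free_j + 1L])
      j1 <- free_j[k]
      delta <- minv[j1 + 1L]
      u[p[used] + 1L] <- u[p[used] + 1L] + delta
      v[used] <- v[used] - delta
      minv[!used] <- minv[!used] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  p[-1L]
}

#' Brute-force matching oracle
#'
#' Exhaustively enumerates every matching of the graph by assigning each
#' miRNA, in sorted order, either no partner or one of its free adjacent
#' diseases, and keeps the best under the same ordering as [mwm_solve()]:
#' larger total weight first, then the lexicographically smallest sorted
#' pair list. Intended as an independent correctness oracle on small
#' instances; refuses graphs above `max_edges` edges.
#'
#' @param g An `md_graph`.
#' @param max_edges Guard against exponential blow-up (default 20).
#' @return An `mwm_solution`.
#' @export
mwm_brute_force <- function(g, max_edges = 20L) {
  stopifnot(inherits(g, "md_graph"))
  edges <- g$edges[, c("mirna", "disease", "weight"), drop = FALSE]
  if (nrow(edges) > max_edges)
    stop(sprintf("brute force refused: %d edges exceeds the %d-edge guard",
                 nrow(edges), max_edges))
  if (nrow(edges) == 0L) return(new_mwm_solution(edges, 0L))
  edges <- edges[order_c(edges$mirna, edges$disease), , drop = FALSE]
  by_m <- split(seq_len(nrow(edges)), edges$mirna)
  by_m <- by_m[sort_c(names(by_m))]
  max_w <- vapply(by_m, function(ix) max(edges$weight[ix]), numeric(1L))
  suffix <- rev(cumsum(rev(max_w)))   # bound on attainable weight from miRNA i on

  best_obj <- -1L
  best_key <- NULL

  recurse <- function(i, used_d, obj, key) {
    if (i > length(by_m)) {
      key <- sort_c(key)
      if (obj > best_obj ||
          (obj == best_obj && pairlist_less(key, best_key))) {
        best_obj <<- obj
        best_key <<- key
      }
      return(invisible(NULL))
    }
    if (obj + suffix[[i]] < best_obj) return(invisible(NULL))  # ties kept
    for (ei in by_m[[i]]) {
      d <- edges$disease[[ei]]
      if (!(d %in% used_d))
        recurse(i + 1L, c(used_d, d), obj + edges$weight[[ei]],
                c(key, paste(edges$mirna[[ei]], d, sep = "\r")))
    }
    recurse(i + 1L, used_d, obj, key)   # leave this miRNA unmatched
  }
  recurse(1L, character(0), 0L, character(0))

  if (length(best_key)) {
    parts <- strsplit(best_key, "\r", fixed = TRUE)
    sel <- match(best_key, paste(edges$mirna, edges$disease, sep = "\r"))
    pairs <- edges[sel, , drop = FALSE]
  } else {
    pairs <- edges[0L, , drop = FALSE]
  }
  rownames(pairs) <- NULL
  new_mwm_solution(pairs, as.integer(best_obj))
}

# TRUE when sorted key vector a precedes b lexicographically.
pairlist_less <- function(a, b) {
  if (is.null(b)) return(TRUE)
  n <- min(length(a), length(b))
  if (n > 0L) {
    for (i in seq_len(n)) {
      if (a[[i]] < b[[i]]) return(TRUE)
      if (a[[i]] > b[[i]]) return(FALSE)
    }
  }
  length(a) < length(b)
}

#' Validate a matching against its source graph
#'
#' Checks the matching invariants: every selected pair is an edge of the
#' graph, no miRNA or disease is used twice, and the stated objective equals
#' the sum of the selected edge weights.
#'
#' @param g An `md_graph`.
#' @param solution An `mwm_solution`.
#' @return List with `valid` (logical) and `violations` (character vector).
#' @export
mwm_verify <- function(g, solution) {
  stopifnot(inherits(g, "md_graph"), inherits(solution, "mwm_solution"))
  v <- character(0)
  p <- solution$pairs
  ekey <- paste(g$edges$mirna, g$edges$disease, sep = "\r")
  pkey <- paste(p$mirna, p$disease, sep = "\r")
  missing <- !(pkey %in% ekey)
  if (any(missing))
    v <- c(v, sprintf("pair (%s, %s) is not an edge of the graph",
                      p$mirna[missing], p$disease[missing]))
  for (col in c("mirna", "disease")) {
    dup <- unique(p[[col]][duplicated(p[[col]])])
    if (length(dup))
      v <- c(v, sprintf("vertex %s repeated", dup))
  }
  w <- g$edges$weight[match(pkey, ekey)]
  if (!any(missing) && sum(w) != solution$objective)
    v <- c(v, sprintf("objective %d does not equal the pair weight sum %d",
                      solution$objective, sum(w)))
  list(valid = length(v) == 0L, violations = v)
}
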