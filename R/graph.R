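#' @importFrom stats lm coef rgeom runif setNames aggregate sd
#' @importFrom utils read.csv write.csv
NULL

# Canonical identifier key: case-insensitive, whitespace-trimmed.
canon_id <- function(x) tolower(trimws(as.character(x)))

# Locale-independent (byte-order) sort, used everywhere determinism matters.
sort_c <- function(x) x[order(x, method = "radix")]

order_c <- function(...) order(..., method = "radix")

.directions <- c("up", "down", "unspecified")

#' Build a weighted bipartite miRNA-disease association graph
#'
#' Constructs and validates the central data structure of the package: a
#' simple undirected bipartite graph whose two partitions are miRNAs and
#' diseases and whose integer edge weights count the publications supporting
#' each association. Identifiers are compared case-insensitively after
#' trimming whitespace but stored in their first-seen form. Duplicate
#' (miRNA, disease) records are merged: their citation sets are pooled and
#' the weight recomputed as the number of distinct PubMed identifiers; for
#' citation-free duplicates the weights are summed.
#'
#' @param mirna Either a data frame with columns `mirna`, `disease` and
#'   optionally `weight`, `pubmed_ids`, `direction`, or a character vector of
#'   miRNA identifiers.
#' @param disease Character vector of disease identifiers (ignored when
#'   `mirna` is a data frame).
#' @param weight Integer vector of publication counts (>= 1). May be omitted
#'   when `pubmed_ids` is given, in which case the weight is the number of
#'   distinct PubMed ids. When both are present and disagree, the citation
#'   count wins with a warning.
#' @param pubmed_ids Citations per record: a list of character vectors, or a
#'   character vector of `";"`-separated PubMed ids (`NA`/empty for none).
#' @param direction Regulation direction per citation: same shape as
#'   `pubmed_ids` (a single value per record is recycled over its citations).
#'   Values must be `"up"`, `"down"` or `"unspecified"`.
#' @return An object of class `md_graph`: a list with elements `mirnas`,
#'   `diseases` (character vectors, first-seen forms) and `edges` (a data
#'   frame with columns `mirna`, `disease`, `weight` and list columns
#'   `pubmed_ids`, `directions`).
#' @examples
#' g <- md_graph(data.frame(mirna = c("m1", "m1"), disease = c("d1", "d2"),
#'                          weight = c(20, 30)))
#' g
#' @export
md_graph <- function(mirna, disease = NULL, weight = NULL, pubmed_ids = NULL,
                     direction = NULL) {
  if (is.data.frame(mirna)) {
    df <- mirna
    if (!all(c("mirna", "disease") %in% names(df)))
      stop("edge records need 'mirna' and 'disease' columns")
    return(md_graph(df$mirna, df$disease,
                    weight = if ("weight" %in% names(df)) df$weight,
                    pubmed_ids = if ("pubmed_ids" %in% names(df)) df$pubmed_ids,
                    direction = if ("direction" %in% names(df)) df$direction))
  }
  mirna <- as.character(mirna)
  disease <- as.character(disease)
  n <- length(mirna)
  if (length(disease) != n)
    stop("mirna and disease vectors must have equal length")
  if (n == 0L) return(new_md_graph())

  if (any(!nzchar(trimws(mirna))) || any(!nzchar(trimws(disease))))
    stop("empty identifier in edge records")

  pmids <- normalize_multi(pubmed_ids, n, "pubmed_ids")
  dirs <- normalize_multi(direction, n, "direction")
  for (i in seq_len(n)) {
    np <- length(pmids[[i]])
    nd <- length(dirs[[i]])
    if (nd == 0L) {
      dirs[[i]] <- rep("unspecified", np)
    } else if (nd == 1L && np > 1L) {
      dirs[[i]] <- rep(dirs[[i]], np)
    } else if (nd != np) {
      stop(sprintf("record %d: %d directions for %d pubmed ids", i, nd, np))
    }
    bad <- setdiff(dirs[[i]], .directions)
    if (length(bad))
      stop(sprintf("record %d: invalid direction '%s'", i, bad[[1L]]))
  }

  if (is.null(weight)) {
    weight <- vapply(pmids, function(p) length(unique(p)), integer(1L))
    if (any(weight < 1L))
      stop("records without weight must carry at least one pubmed id")
  } else {
    if (!length(weight) %in% c(1L, n))
      stop("weight must have length 1 or one value per edge record")
    weight <- rep_len(as.numeric(weight), n)
    has_pm <- lengths(pmids) > 0L
    if (any(is.na(weight) & !has_pm))
      stop("missing weight on a record without pubmed ids")
    npm <- vapply(pmids, function(p) length(unique(p)), integer(1L))
    weight[is.na(weight)] <- npm[is.na(weight)]
    if (any(weight != as.integer(weight)))
      stop("edge weights must be integers")
    weight <- as.integer(weight)
    if (any(weight < 1L))
      stop("edge weights must be >= 1")
    clash <- has_pm & weight != npm
    if (any(clash)) {
      warning(sprintf(
        "%d record(s) with weight differing from distinct pubmed count; using the citation count",
        sum(clash)))
      weight[clash] <- npm[clash]
    }
  }

  mk <- canon_id(mirna)
  dk <- canon_id(disease)
  both <- intersect(unique(mk), unique(dk))
  if (length(both))
    stop(sprintf("identifier '%s' appears as both miRNA and disease; the partitions must be disjoint",
                 both[[1L]]))

  # merge duplicate (miRNA, disease) records
  key <- paste(mk, dk, sep = "\r")
  first <- !duplicated(key)
  idx <- split(seq_len(n), factor(key, levels = key[first]))
  m_out <- mirna[first]
  d_out <- disease[first]
  w_out <- integer(length(idx))
  p_out <- vector("list", length(idx))
  dir_out <- vector("list", length(idx))
  for (j in seq_along(idx)) {
    rows <- idx[[j]]
    pm <- unlist(pmids[rows], use.names = FALSE)
    dr <- unlist(dirs[rows], use.names = FALSE)
    if (length(pm)) {
      keep <- !duplicated(paste(pm, dr, sep = "\r"))
      p_out[[j]] <- pm[keep]
      dir_out[[j]] <- dr[keep]
      w_out[[j]] <- length(unique(pm[keep]))
    } else {
      p_out[[j]] <- character(0)
      dir_out[[j]] <- character(0)
      w_out[[j]] <- sum(weight[rows])
    }
  }

  edges <- data.frame(mirna = m_out, disease = d_out, weight = w_out,
                      stringsAsFactors = FALSE)
  edges$pubmed_ids <- p_out
  edges$directions <- dir_out
  o <- order_c(edges$mirna, edges$disease)
  edges <- edges[o, , drop = FALSE]
  rownames(edges) <- NULL

  mirnas <- mirna[!duplicated(mk)]
  diseases <- disease[!duplicated(dk)]
  new_md_graph(mirnas, diseases, edges)
}

new_md_graph <- function(mirnas = character(0), diseases = character(0),
                         edges = NULL) {
  if (is.null(edges)) {
    edges <- data.frame(mirna = character(0), disease = character(0),
                        weight = integer(0), stringsAsFactors = FALSE)
    edges$pubmed_ids <- list()
    edges$directions <- list()
  }
  structure(list(mirnas = mirnas, diseases = diseases, edges = edges),
            class = "md_graph")
}

#' @export
print.md_graph <- function(x, ...) {
  cat(sprintf("md_graph: %d miRNAs, %d diseases, %d weighted associations\n",
              length(x$mirnas), length(x$diseases), nrow(x$edges)))
  if (nrow(x$edges)) {
    show <- utils::head(x$edges[, c("mirna", "disease", "weight")], 6L)
    print(show, row.names = FALSE)
    if (nrow(x$edges) > 6L) cat(sprintf("... %d more edges\n", nrow(x$edges) - 6L))
  }
  invisible(x)
}

#' Number of nodes and edges
#'
#' @param g An `md_graph` or `dd_graph`.
#' @return `md_nodes`: character vector of all node identifiers;
#'   `md_edge_count`: integer edge count.
#' @keywords internal
#' @export
md_nodes <- function(g) UseMethod("md_nodes")

#' @export
md_nodes.md_graph <- function(g) c(g$mirnas, g$diseases)

#' @export
md_nodes.dd_graph <- function(g) g$diseases

#' @rdname md_nodes
#' @export
md_edge_count <- function(g) UseMethod("md_edge_count")

#' @export
md_edge_count.md_graph <- function(g) nrow(g$edges)

#' @export
md_edge_count.dd_graph <- function(g) nrow(g$edges)

# Named adjacency list (neighbors sorted byte-wise), covering isolated nodes.
graph_adjacency <- function(g) {
  if (inherits(g, "md_graph")) {
    from <- g$edges$mirna; to <- g$edges$disease
  } else {
    from <- g$edges$d1; to <- g$edges$d2
  }
  nodes <- md_nodes(g)
  adj <- setNames(vector("list", length(nodes)), nodes)
  for (nm in nodes) adj[[nm]] <- character(0)
  if (length(from)) {
    sp1 <- split(to, from)
    sp2 <- split(from, to)
    for (nm in names(sp1)) adj[[nm]] <- sp1[[nm]]
    for (nm in names(sp2)) adj[[nm]] <- c(adj[[nm]], sp2[[nm]])
  }
  lapply(adj, sort_c)
}

# Resolve user-supplied ids against a stored id vector (case/space tolerant).
# Returns stored forms; unknown ids yield NA.
resolve_ids <- function(ids, stored) {
  stored[match(canon_id(ids), canon_id(stored))]
}

#' Convert an association graph to an igraph object
#'
#' Builds an undirected [igraph::igraph] graph with a logical `type` vertex
#' attribute (`FALSE` for miRNAs, `TRUE` for diseases) and the publication
#' count as edge `weight`, suitable for igraph's layout, community and path
#' machinery.
#'
#' @param g An `md_graph`.
#' @return An igraph graph.
#' @export
as_igraph <- function(g) {
  stopifnot(inherits(g, "md_graph"))
  verts <- data.frame(name = c(g$mirnas, g$diseases),
                      type = c(rep(FALSE, length(g$mirnas)),
                               rep(TRUE, length(g$diseases))),
                      stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(
    g$edges[, c("mirna", "disease", "weight"), drop = FALSE],
    directed = FALSE, vertices = verts)
}

# Induced subgraph on a set of query miRNAs plus all their adjacent diseases.
# `query` must already be resolved to stored forms.
induced_query_graph <- function(g, query) {
  keep <- g$edges$mirna %in% query
  edges <- g$edges[keep, , drop = FALSE]
  rownames(edges) <- NULL
  new_md_graph(intersect(g$mirnas, unique(edges$mirna)),
               intersect(g$diseases, unique(edges$disease)),
               edges)
}

normalize_multi <- function(x, n, what) {
  if (is.null(x)) return(rep(list(character(0)), n))
  if (length(x) == 1L && n > 1L) x <- rep_len(x, n)
  if (is.list(x)) {
    out <- lapply(x, function(v) {
      v <- as.character(v)
      v[!is.na(v) & nzchar(trimws(v))]
    })
  } else {
    x <- as.character(x)
    out <- lapply(x, function(v) {
      if (is.na(v) || !nzchar(trimws(v))) return(character(0))
      parts <- trimws(strsplit(v, ";", fixed = TRUE)[[1L]])
      parts[nzchar(parts)]
    })
  }
  if (length(out) != n)
    stop(sprintf("%s must have one entry per edge record", what))
  out
}
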