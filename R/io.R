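#' Edge-list CSV dialect
#'
#' Describes the on-disk CSV layout for association edge lists. Multi-valued
#' cells (several PubMed ids or directions on one association) use a single
#' list separator, `";"` by default, to avoid colliding with the comma field
#' delimiter.
#'
#' @param mirna,disease,weight,pubmed_ids,direction Column names.
#' @param sep Single-character list separator for multi-valued cells.
#' @return An `edge_csv_dialect` list.
#' @export
edge_csv_dialect <- function(mirna = "mirna", disease = "disease",
                             weight = "weight", pubmed_ids = "pubmed_ids",
                             direction = "direction", sep = ";") {
  cols <- c(mirna, disease, weight, pubmed_ids, direction)
  if (anyDuplicated(cols)) stop("dialect column names must be unique")
  if (nchar(sep) != 1L || sep == ",")
    stop("list separator must be a single character distinct from ','")
  structure(list(mirna = mirna, disease = disease, weight = weight,
                 pubmed_ids = pubmed_ids, direction = direction, sep = sep),
            class = "edge_csv_dialect")
}

#' Read a weighted association edge list from CSV
#'
#' Reads an edge CSV (RFC-4180, UTF-8, header required) and builds a
#' validated [md_graph()]. The `mirna` and `disease` columns are mandatory;
#' at least one of `weight` and `pubmed_ids` must be present. When only
#' citations are given the weight is the distinct PubMed count; when both
#' are present and disagree, the citation count wins (with a warning).
#' Unknown extra columns are carried along on the edge table and ignored by
#' all algorithms.
#'
#' @param path CSV file path.
#' @param dialect An [edge_csv_dialect()].
#' @return An `md_graph`.
#' @export
read_edge_csv <- function(path, dialect = edge_csv_dialect()) {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                 check.names = FALSE)
  for (col in c(dialect$mirna, dialect$disease)) {
    if (!col %in% names(df))
      stop(sprintf("missing mandatory column '%s' in %s", col, path))
  }
  has_w <- dialect$weight %in% names(df)
  has_p <- dialect$pubmed_ids %in% names(df)
  if (!has_w && !has_p)
    stop(sprintf("need a '%s' or '%s' column in %s",
                 dialect$weight, dialect$pubmed_ids, path))
  if (nrow(df) == 0L) return(new_md_graph())
  w <- NULL
  if (has_w) {
    wraw <- trimws(df[[dialect$weight]])
    w <- suppressWarnings(as.numeric(wraw))
    bad <- which(nzchar(wraw) & (is.na(w) | w != floor(w)))
    if (length(bad))
      stop(sprintf("non-integer weight '%s' on data row %d of %s",
                   wraw[[bad[[1L]]]], bad[[1L]], path))
    w[!nzchar(wraw)] <- NA_real_
  }
  pm <- if (has_p) df[[dialect$pubmed_ids]]
  dir <- if (dialect$direction %in% names(df)) df[[dialect$direction]]
  if (dialect$sep != ";") {
    resep <- function(x) if (is.null(x)) NULL
      else gsub(dialect$sep, ";", x, fixed = TRUE)
    pm <- resep(pm); dir <- resep(dir)
  }
  g <- md_graph(df[[dialect$mirna]], df[[dialect$disease]], weight = w,
                pubmed_ids = pm, direction = dir)
  known <- c(dialect$mirna, dialect$disease, dialect$weight,
             dialect$pubmed_ids, dialect$direction)
  extra <- setdiff(names(df), known)
  if (length(extra)) attr(g, "extra_columns") <- df[, extra, drop = FALSE]
  g
}

#' Write an association edge list to CSV
#'
#' Inverse of [read_edge_csv()]: one row per association with weight, pooled
#' PubMed ids and directions (`";"`-separated), in deterministic
#' (miRNA, disease) order.
#'
#' @param g An `md_graph`.
#' @param path Output file path.
#' @param dialect An [edge_csv_dialect()].
#' @return The number of data rows written, invisibly.
#' @export
write_edge_csv <- function(g, path, dialect = edge_csv_dialect()) {
  stopifnot(inherits(g, "md_graph"))
  e <- g$edges
  out <- data.frame(a = e$mirna, b = e$disease, w = e$weight,
                    p = vapply(e$pubmed_ids, paste, character(1L),
                               collapse = dialect$sep),
                    d = vapply(e$directions, paste, character(1L),
                               collapse = dialect$sep),
                    stringsAsFactors = FALSE)
  names(out) <- c(dialect$mirna, dialect$disease, dialect$weight,
                  dialect$pubmed_ids, dialect$direction)
  write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(nrow(out))
}

#' Export a prioritization result with provenance to CSV
#'
#' Writes one row per (miRNA, disease) association in the result's induced
#' subnetwork -- the edges linking the query miRNAs to the result's ranked
#' diseases -- with weight, pooled PubMed ids, a direction summary, the
#' disease's rank and score, and the method name. Rows are ordered by rank,
#' then disease, then miRNA.
#'
#' @param result A `prioritized_result` (matching route) or a
#'   `motif_ranking` (motif route).
#' @param g The source `md_graph` the result was computed from.
#' @param path Output CSV path.
#' @return The number of data rows written.
#' @export
write_result_csv <- function(result, g, path) {
  stopifnot(inherits(g, "md_graph"))
  if (inherits(result, "prioritized_result")) {
    diseases <- result$final_diseases
    scores <- result$ranking$impact[match(diseases, result$ranking$disease)]
    query <- attr(result$ranking, "query")
    method <- "mwm"
  } else if (inherits(result, "motif_ranking")) {
    diseases <- result$disease
    scores <- result$participation
    query <- attr(result, "query")
    method <- "motif"
  } else stop("unsupported result type")
  rows <- data.frame(rank = integer(0), disease = character(0),
                     mirna = character(0), weight = integer(0),
                     pubmed_ids = character(0), directions = character(0),
                     score = integer(0), method = character(0),
                     stringsAsFactors = FALSE)
  if (length(diseases)) {
    e <- g$edges[g$edges$disease %in% diseases &
                   (if (is.null(query)) TRUE else g$edges$mirna %in% query), ,
                 drop = FALSE]
    if (nrow(e)) {
      r <- match(e$disease, diseases)
      rows <- data.frame(
        rank = r, disease = e$disease, mirna = e$mirna, weight = e$weight,
        pubmed_ids = vapply(e$pubmed_ids, paste, character(1L), collapse = ";"),
        directions = vapply(e$directions, paste, character(1L), collapse = ";"),
        score = scores[r], method = method, stringsAsFactors = FALSE)
      rows <- rows[order_c(rows$rank, rows$disease, rows$mirna), , drop = FALSE]
    }
  }
  write.csv(rows, path, row.names = FALSE, quote = TRUE)
  nrow(rows)
}

#' Export the matching model as a GNU MathProg (GMPL) program
#'
#' Emits the maximum-weight matching integer program in MathProg syntax: one
#' binary variable per existing association, the weighted-sum objective, and
#' one at-most-one constraint per miRNA and per disease incident to at least
#' one edge. The model is self-contained (ends with `solve; end;`) and can
#' be handed to any MathProg-capable solver; its optimum equals
#' [mwm_solve()]'s objective.
#'
#' @param g A non-empty `md_graph`.
#' @param path Optional output path; when `NULL` the text is only returned.
#' @return The model text, invisibly when `path` is given.
#' @export
export_gmpl <- function(g, path = NULL) {
  stopifnot(inherits(g, "md_graph"))
  e <- g$edges
  if (nrow(e) == 0L) stop("nothing to export: the graph has no edges")
  e <- e[order_c(e$mirna, e$disease), , drop = FALSE]
  sym <- gmpl_symbols(c(e$mirna, e$disease))
  vm <- sym[seq_len(nrow(e))]
  vd <- sym[nrow(e) + seq_len(nrow(e))]
  var <- paste0("x_", vm, "__", vd)
  lines <- c("/* maximum-weight miRNA-disease matching */",
             paste0("var ", var, " binary;"),
             "",
             paste0("maximize total_weight: ",
                    paste(sprintf("%d*%s", e$weight, var), collapse = " + "),
                    ";"))
  for (side in c("mirna", "disease")) {
    ids <- sort_c(unique(e[[side]]))
    for (id in ids) {
      members <- var[e[[side]] == id]
      lines <- c(lines, sprintf(
        "s.t. %s_%s: %s <= 1;",
        if (side == "mirna") "mir" else "dis",
        gmpl_symbols(id), paste(members, collapse = " + ")))
    }
  }
  lines <- c(lines, "", "solve;", "end;")
  text <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(text, path)
    return(invisible(text))
  }
  text
}

# Deterministic MathProg-safe symbol for each identifier.
gmpl_symbols <- function(ids) {
  # disambiguate clashes introduced by sanitization, stable in input order
  u <- unique(ids)
  su <- gsub("[^A-Za-z0-9]", "_", u)
  su <- ifelse(grepl("^[0-9]", su), paste0("n", su), su)
  dup <- duplicated(su)
  su[dup] <- paste0(su[dup], "_", seq_len(sum(dup)))
  su[match(ids, u)]
}
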