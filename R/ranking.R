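#' Cumulative impact of a query miRNA set on each disease
#'
#' For every disease adjacent to at least one queried miRNA, sums the edge
#' weights (supporting-publication counts) from all queried miRNAs to that
#' disease. The result is the prioritization score of the ranking route:
#' diseases are ordered by non-increasing cumulative impact, ties broken by
#' disease id.
#'
#' @param g An `md_graph`.
#' @param query Character vector of miRNA identifiers. Unknown ids are
#'   dropped with a warning; if none remain, an error is raised.
#' @return A `disease_ranking`: data frame with columns `disease` and
#'   `impact`, with the resolved query attached as attribute `query`.
#' @examples
#' cumulative_impact(worked_example(), c("m1", "m2", "m3"))
#' @export
cumulative_impact <- function(g, query) {
  stopifnot(inherits(g, "md_graph"))
  if (!length(query)) stop("query must contain at least one miRNA id")
  res <- resolve_ids(query, g$mirnas)
  if (anyNA(res)) {
    warning(sprintf("dropping %d unknown query miRNA(s): %s",
                    sum(is.na(res)), paste(query[is.na(res)], collapse = ", ")))
    res <- res[!is.na(res)]
  }
  res <- unique(res)
  if (!length(res)) stop("no query miRNA is present in the graph")
  sel <- g$edges[g$edges$mirna %in% res, , drop = FALSE]
  if (nrow(sel)) {
    agg <- aggregate(list(impact = sel$weight), list(disease = sel$disease), sum)
  } else {
    agg <- data.frame(disease = character(0), impact = integer(0))
  }
  agg$impact <- as.integer(agg$impact)
  agg <- agg[order_c(-agg$impact, agg$disease), , drop = FALSE]
  rownames(agg) <- NULL
  structure(agg, query = res, class = c("disease_ranking", "data.frame"))
}

#' Merge the matching's disease set with the cumulative-impact ranking
#'
#' The matching's vertex-disjointness can discard a strongly supported
#' association when its miRNA is better used elsewhere. The merge rule
#' repairs this: take the least cumulative impact t among the diseases the
#' matching selected, and add every disease whose cumulative impact is
#' strictly greater than t. The final list is emitted in ranking order.
#'
#' @param mwm_diseases Character vector of disease ids selected by the
#'   matching; must all appear in `ranking`. May be empty (degenerate input:
#'   the final list is empty and the trace says so).
#' @param ranking A `disease_ranking` from [cumulative_impact()].
#' @return A `prioritized_result`: list with `mwm_diseases`, `ranking`,
#'   `final_diseases` (ordered) and `method_trace` (threshold impact `t`,
#'   the threshold disease, and a note).
#' @examples
#' rk <- structure(data.frame(disease = c("d2", "d4", "d1", "d5", "d3"),
#'                            impact = c(50L, 40L, 30L, 20L, 10L)),
#'                 class = c("disease_ranking", "data.frame"))
#' merge_ranking(c("d2", "d3", "d4", "d5"), rk)$final_diseases
#' @export
merge_ranking <- function(mwm_diseases, ranking) {
  stopifnot(inherits(ranking, "disease_ranking"))
  mwm_diseases <- unique(as.character(mwm_diseases))
  if (!length(mwm_diseases)) {
    return(new_prioritized_result(
      character(0), ranking, character(0),
      list(threshold = NA_integer_, threshold_disease = NA_character_,
           note = "degenerate input: empty matching disease set")))
  }
  res <- resolve_ids(mwm_diseases, ranking$disease)
  if (anyNA(res))
    stop(sprintf("matching disease(s) absent from the ranking: %s",
                 paste(mwm_diseases[is.na(res)], collapse = ", ")))
  imp <- ranking$impact[match(res, ranking$disease)]
  t <- min(imp)
  t_disease <- sort_c(res[imp == t])[[1L]]
  keep <- ranking$disease %in% res | ranking$impact > t
  final <- ranking$disease[keep]
  new_prioritized_result(
    res, ranking, final,
    list(threshold = t, threshold_disease = t_disease,
         note = sprintf("threshold impact %d at disease %s", t, t_disease)))
}

new_prioritized_result <- function(mwm_diseases, ranking, final, trace) {
  structure(list(mwm_diseases = mwm_diseases, ranking = ranking,
                 final_diseases = final, method_trace = trace),
            class = "prioritized_result")
}

#' @export
print.prioritized_result <- function(x, ...) {
  cat("prioritized diseases:",
      if (length(x$final_diseases)) paste(x$final_diseases, collapse = ", ")
      else "(none)", "\n")
  cat("  from matching:",
      if (length(x$mwm_diseases)) paste(sort_c(x$mwm_diseases), collapse = ", ")
      else "(none)", "\n")
  if (!is.na(x$method_trace$threshold))
    cat(" ", x$method_trace$note, "\n")
  invisible(x)
}

#' Matching-based disease prioritization pipeline
#'
#' The end-to-end automated pipeline for a query set of miRNAs:
#' \enumerate{
#'   \item restrict the network to the queried miRNAs and all their
#'     adjacent diseases (each miRNA's sphere of influence);
#'   \item solve the maximum-weight matching on this subnetwork;
#'   \item rank all adjacent diseases by cumulative impact;
#'   \item merge the two with [merge_ranking()].
#' }
#'
#' @param g An `md_graph`.
#' @param query Character vector of miRNA ids (unknown ids dropped with a
#'   warning). If none of the remaining miRNAs has any association, an empty
#'   result is returned with a warning.
#' @return A `prioritized_result` (see [merge_ranking()]); the matching
#'   itself is attached as element `matching`.
#' @examples
#' prioritize(worked_example(), c("m1", "m2", "m3"))$final_diseases
#' @export
prioritize <- function(g, query) {
  stopifnot(inherits(g, "md_graph"))
  if (!length(query)) stop("query must contain at least one miRNA id")
  res <- resolve_ids(query, g$mirnas)
  if (anyNA(res)) {
    warning(sprintf("dropping %d unknown query miRNA(s): %s",
                    sum(is.na(res)), paste(query[is.na(res)], collapse = ", ")))
    res <- res[!is.na(res)]
  }
  res <- unique(res)
  if (!length(res)) stop("no query miRNA is present in the graph")
  sub <- induced_query_graph(g, res)
  if (nrow(sub$edges) == 0L) {
    warning("queried miRNAs have no associations; empty result")
    empty_ranking <- structure(
      data.frame(disease = character(0), impact = integer(0)),
      query = res, class = c("disease_ranking", "data.frame"))
    out <- new_prioritized_result(
      character(0), empty_ranking, character(0),
      list(threshold = NA_integer_, threshold_disease = NA_character_,
           note = "degenerate input: query without associations"))
    out$matching <- new_mwm_solution(sub$edges, 0L)
    return(out)
  }
  sol <- mwm_solve(sub)
  ranking <- cumulative_impact(sub, res)
  out <- merge_ranking(unique(sol$pairs$disease), ranking)
  out$matching <- sol
  out
}
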