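#' Propagate gene annotations up the ontology (true-path rule)
#'
#' Each term's annotated gene set becomes the union of its own direct
#' annotations and those of all its descendants, so that annotation counts
#' are consistent along the DAG.
#'
#' @param dag A [go_dag()].
#' @param direct Tibble with columns `term_id` and `gene_id` (direct
#'   annotations); every `term_id` must exist in `dag`.
#' @return Tibble with columns `term_id`, `gene_id`, one row per propagated
#'   annotation (unique pairs).
#' @export
annotate_with_ancestors <- function(dag, direct) {
  stopifnot(inherits(dag, "go_dag"))
  direct <- as_tibble(direct)
  unknown <- setdiff(direct$term_id, igraph::V(dag$graph)$name)
  if (length(unknown)) {
    abort(sprintf("Annotation references unknown term(s): %s.",
                  paste(head(unknown, 3), collapse = ", ")))
  }
  sets <- split(direct$gene_id, direct$term_id)
  ord <- igraph::topo_sort(dag$graph, mode = "out")$name  # children first
  el <- igraph::as_edgelist(dag$graph)
  kids <- split(el[, 1], el[, 2])   # parent -> children
  acc <- lapply(setNames(ord, ord), function(t) unique(sets[[t]]))
  for (t in ord) {
    below <- unlist(acc[kids[[t]]], use.names = FALSE)
    if (length(below)) acc[[t]] <- unique(c(acc[[t]], below))
  }
  acc <- acc[lengths(acc) > 0]
  tibble(term_id = rep(names(acc), lengths(acc)),
         gene_id = unlist(acc, use.names = FALSE))
}

#' Hypergeometric over-representation test per ontology term
#'
#' For each term with at least one annotated background gene, tests whether
#' the query set contains more of the term's genes than expected by chance:
#' one-sided hypergeometric tail `P(X >= k)` with `N` background genes, `K`
#' of them annotated to the term, and a query of size `n` containing `k`.
#' The enrichment score is the fold enrichment `(k/n) / (K/N)`.
#'
#' @param query Character vector of query gene ids (must be a subset of
#'   `background`).
#' @param background Character vector of background gene ids (the gene
#'   universe: whole annotation or expressed genes).
#' @param ann Tibble `term_id`, `gene_id` — usually the output of
#'   [annotate_with_ancestors()].
#' @param adjust Multiple-testing adjustment: `"bonferroni"` (default) or
#'   `"BH"`.
#' @return A tibble of class `enrichment_result`: `term_id`, `k`, `n`, `K`,
#'   `N`, `p`, `p_adj`, `enrichment_score`, sorted by `p`.
#' @export
hypergeom_enrich <- function(query, background, ann,
                             adjust = c("bonferroni", "BH")) {
  adjust <- match.arg(adjust)
  query <- unique(query); background <- unique(background)
  if (!length(query)) abort("Empty query set.")
  if (!length(background)) abort("Empty background set.")
  outside <- setdiff(query, background)
  if (length(outside)) {
    abort(sprintf("Query gene(s) outside the background: %s.",
                  paste(head(outside, 3), collapse = ", ")))
  }
  ann <- dplyr::filter(as_tibble(ann), .data$gene_id %in% background) %>%
    distinct(.data$term_id, .data$gene_id)
  N <- length(background); n <- length(query)
  per_term <- ann %>%
    group_by(.data$term_id) %>%
    summarise(K = n(), k = sum(.data$gene_id %in% query), .groups = "drop")
  p <- phyper(per_term$k - 1, per_term$K, N - per_term$K, n,
              lower.tail = FALSE)
  out <- per_term %>%
    mutate(n = n, N = N, p = p,
           p_adj = pmin(p.adjust(p, method = adjust), 1),
           enrichment_score = (.data$k / n) / (.data$K / N)) %>%
    select("term_id", "k", "n", "K", "N", "p", "p_adj",
           "enrichment_score") %>%
    arrange(.data$p)
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Significantly enriched terms
#'
#' @param results An `enrichment_result` from [hypergeom_enrich()].
#' @param alpha Adjusted-p threshold, inclusive (default `1e-6`; the stricter
#'   `1e-7` preset matches a figure-level filter).
#' @return Character vector of significant term ids.
#' @export
significant_terms <- function(results, alpha = 1e-6) {
  stop_if_not_number(alpha, "alpha", min = 0)
  results$term_id[results$p_adj <= alpha]
}

#' Common child terms among significant ontology terms
#'
#' Given the set of significantly enriched terms, reports every significant
#' term that is a proper descendant of at least `k_min` other significant
#' terms — the "common child" naming the biological theme shared by its
#' significant ancestors — and flags the leaves of the significant subgraph
#' (significant terms with no significant descendant).
#'
#' @param dag A [go_dag()].
#' @param significant Character vector of significant term ids (must exist
#'   in `dag`).
#' @param k_min Minimum number of significant proper ancestors (default 2).
#' @return A `common_child_report`: list with `significant` (input set) and
#'   `report`, a tibble over all significant terms with `n_significant_ancestors`,
#'   `ancestors` (list-column), `is_common_child`, `is_leaf`.
#' @export
common_child_terms <- function(dag, significant, k_min = 2) {
  stopifnot(inherits(dag, "go_dag"))
  if (k_min < 2) abort("`k_min` must be >= 2.")
  significant <- unique(significant)
  unknown <- setdiff(significant, igraph::V(dag$graph)$name)
  if (length(unknown)) {
    abort(sprintf("Unknown term(s): %s.",
                  paste(head(unknown, 3), collapse = ", ")))
  }
  if (!length(significant)) {
    return(structure(list(significant = character(),
                          report = tibble(term_id = character(),
                                          n_significant_ancestors = integer(),
                                          ancestors = list(),
                                          is_common_child = logical(),
                                          is_leaf = logical())),
                     class = "common_child_report"))
  }
  anc <- lapply(significant, function(t) {
    up <- igraph::subcomponent(dag$graph, t, mode = "out")$name
    intersect(setdiff(up, t), significant)
  })
  names(anc) <- significant
  desc_sig <- vapply(significant, function(t) {
    down <- igraph::subcomponent(dag$graph, t, mode = "in")$name
    length(intersect(setdiff(down, t), significant)) > 0
  }, logical(1))
  report <- tibble(
    term_id = significant,
    n_significant_ancestors = unname(lengths(anc)),
    ancestors = unname(anc),
    is_common_child = unname(lengths(anc) >= k_min),
    is_leaf = unname(!desc_sig)
  )
  structure(list(significant = significant, report = report),
            class = "common_child_report")
}

#' @export
print.common_child_report <- function(x, ...) {
  cat(sprintf("<common_child_report> %d significant terms, %d common children\n",
              length(x$significant), sum(x$report$is_common_child)))
  print(dplyr::filter(x$report, .data$is_common_child))
  invisible(x)
}

#' @export
tidy.common_child_report <- function(x, ...) x$report

#' @export
glance.enrichment_result <- function(x, ...) {
  tibble(n_terms_tested = nrow(x),
         n_significant_1e6 = sum(x$p_adj <= 1e-6),
         min_p_adj = if (nrow(x)) min(x$p_adj) else NA_real_)
}
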