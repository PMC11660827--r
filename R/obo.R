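#' Construct an ontology DAG
#'
#' @param terms Tibble with columns `term_id`, `name`, `namespace`.
#' @param edges Tibble with columns `child`, `parent` (and optionally
#'   `relation`); edges point from each term to its more general parents.
#' @return A `go_dag` object (list with `terms`, `edges`, `graph`). Edges
#'   whose parent is not itself a term are kept but recorded as dangling.
#' @export
go_dag <- function(terms, edges) {
  terms <- as_tibble(terms)
  edges <- as_tibble(edges)
  if (!"relation" %in% names(edges)) edges$relation <- "is_a"
  dangling <- setdiff(edges$parent, terms$term_id)
  if (length(dangling)) {
    warn(sprintf("%d edge parent(s) not defined as terms (dangling): %s",
                 length(dangling), paste(head(dangling, 3), collapse = ", ")))
  }
  ids <- union(terms$term_id, union(edges$child, edges$parent))
  g <- igraph::graph_from_data_frame(edges[, c("child", "parent")],
                                     directed = TRUE,
                                     vertices = data.frame(name = ids))
  if (!igraph::is_dag(g)) abort("Ontology graph contains a cycle.")
  structure(list(terms = terms, edges = edges, graph = g,
                 dangling = dangling),
            class = "go_dag")
}

#' Parse an OBO ontology file
#'
#' Minimal reader for OBO 1.2/1.4 `[Term]` stanzas: extracts term id, name,
#' namespace and `is_a` parents (plus `relationship: part_of` when
#' requested). Obsolete terms are dropped. Cyclic graphs are rejected.
#'
#' @param path Path to an OBO file.
#' @param part_of Also treat `relationship: part_of` as parentage
#'   (default `FALSE`: `is_a` only).
#' @return A [go_dag()].
#' @export
parse_obo <- function(path, part_of = FALSE) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^\\[", lines)
  if (!length(starts)) abort("No stanzas found; not an OBO file?")
  bounds <- c(starts, length(lines) + 1L)
  terms <- list(); edges <- list()
  for (i in seq_along(starts)) {
    if (!identical(lines[starts[i]], "[Term]")) next
    body <- lines[(starts[i] + 1L):(bounds[i + 1L] - 1L)]
    field <- function(key) {
      v <- sub(paste0("^", key, ": *"), "", grep(paste0("^", key, ":"), body,
                                                 value = TRUE))
      sub(" *!.*$", "", v)  # strip trailing comments
    }
    id <- field("id")
    if (length(id) != 1L || !nzchar(id)) {
      abort(sprintf("Unparseable [Term] stanza near line %d (missing id).",
                    starts[i]))
    }
    if (any(grepl("^is_obsolete: *true", body))) next
    parents <- field("is_a")
    rel <- c()
    if (part_of) {
      po <- field("relationship")
      po <- po[grepl("^part_of ", po)]
      rel <- sub("^part_of +", "", po)
    }
    terms[[id]] <- tibble(term_id = id,
                          name = field("name")[1] %||% NA_character_,
                          namespace = field("namespace")[1] %||% NA_character_)
    if (length(parents) || length(rel)) {
      edges[[id]] <- tibble(
        child = id,
        parent = c(parents, rel),
        relation = rep(c("is_a", "part_of"), c(length(parents), length(rel))))
    }
  }
  terms <- bind_rows(terms)
  edges <- if (length(edges)) bind_rows(edges) else
    tibble(child = character(), parent = character(), relation = character())
  if (nrow(terms) == 0) abort("No non-obsolete [Term] stanzas found.")
  go_dag(terms, edges)
}

#' Serialize an ontology DAG to OBO text
#'
#' Writes `[Term]` stanzas with `id`, `name`, `namespace` and `is_a` /
#' `relationship: part_of` lines, sufficient to round-trip through
#' [parse_obo()].
#'
#' @param dag A [go_dag()].
#' @param path Output path.
#' @return `dag`, invisibly.
#' @export
write_obo <- function(dag, path) {
  stopifnot(inherits(dag, "go_dag"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (i in seq_len(nrow(dag$terms))) {
    t <- dag$terms[i, ]
    e <- dag$edges[dag$edges$child == t$term_id, ]
    isa <- e$parent[e$relation == "is_a"]
    po <- e$parent[e$relation == "part_of"]
    writeLines(c("", "[Term]", paste0("id: ", t$term_id),
                 if (!is.na(t$name)) paste0("name: ", t$name),
                 if (!is.na(t$namespace)) paste0("namespace: ", t$namespace),
                 if (length(isa)) paste0("is_a: ", isa),
                 if (length(po)) paste0("relationship: part_of ", po)), con)
  }
  invisible(dag)
}

#' @export
print.go_dag <- function(x, ...) {
  cat(sprintf("<go_dag> %d terms, %d edges%s\n", nrow(x$terms), nrow(x$edges),
              if (length(x$dangling))
                sprintf(" (%d dangling parents)", length(x$dangling)) else ""))
  invisible(x)
}

#' @export
tidy.go_dag <- function(x, ...) x$terms

#' @export
glance.go_dag <- function(x, ...) {
  tibble(n_terms = nrow(x$terms), n_edges = nrow(x$edges),
         n_dangling = length(x$dangling), acyclic = TRUE)
}
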