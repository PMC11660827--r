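# small programmatic fixtures shared across tests

make_cs <- function(mat, groups) {
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("g%04d", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- sprintf("s%02d", seq_len(ncol(mat)))
  count_study(mat, data.frame(sample_id = colnames(mat), group = groups))
}

rand_cs <- function(n_genes, n_per_group, groups = c("control", "disease"),
                    mu = 100, dispersion = 0.05) {
  n <- n_genes * n_per_group * length(groups)
  mat <- matrix(rnbinom(n, mu = mu, size = 1 / dispersion), nrow = n_genes)
  make_cs(mat, rep(groups, each = n_per_group))
}

# random DAG: edges only from higher to lower index, so always acyclic
rand_dag <- function(n_terms = 50, p_edge = 0.08) {
  ids <- sprintf("T:%04d", seq_len(n_terms))
  terms <- tibble::tibble(term_id = ids, name = paste("term", seq_len(n_terms)),
                          namespace = "test_ns")
  pairs <- which(upper.tri(matrix(TRUE, n_terms, n_terms)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < p_edge
  edges <- tibble::tibble(child = ids[pairs[keep, 2]],
                          parent = ids[pairs[keep, 1]])
  suppressWarnings(go_dag(terms, edges))
}

# brute-force transitive "genes reachable below each term" oracle
propagate_oracle <- function(edges, direct) {
  # adjacency: parent -> children, repeated union to fixed point
  sets <- split(direct$gene_id, direct$term_id)
  terms <- unique(c(edges$child, edges$parent, direct$term_id))
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(edges))) {
      ch <- sets[[edges$child[i]]]
      pa <- sets[[edges$parent[i]]]
      u <- unique(c(pa, ch))
      if (length(u) != length(pa)) {
        sets[[edges$parent[i]]] <- u
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  sets
}
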