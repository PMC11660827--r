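obo_text <- function(...) {
  f <- withr::local_tempfile(fileext = ".obo", .local_envir = parent.frame())
  writeLines(c("format-version: 1.2", ...), f)
  f
}

test_that("OBO parsing builds the DAG and drops obsolete terms", {
  f <- obo_text(
    "", "[Term]", "id: T:1", "name: root", "namespace: ns",
    "", "[Term]", "id: T:2", "name: mid", "is_a: T:1 ! root",
    "", "[Term]", "id: T:3", "name: leaf", "is_a: T:2",
    "", "[Term]", "id: T:9", "name: gone", "is_obsolete: true", "is_a: T:1")
  dag <- parse_obo(f)
  expect_setequal(dag$terms$term_id, c("T:1", "T:2", "T:3"))
  expect_identical(nrow(dag$edges), 2L)
  expect_identical(dag$terms$name[dag$terms$term_id == "T:2"], "mid")

  cyc <- obo_text("", "[Term]", "id: A", "is_a: B",
                  "", "[Term]", "id: B", "is_a: A")
  expect_error(parse_obo(cyc), "cycle")
})

test_that("a random DAG survives an OBO round-trip", {
  set.seed(31)
  dag <- rand_dag(50, 0.08)
  f <- withr::local_tempfile(fileext = ".obo")
  write_obo(dag, f)
  back <- parse_obo(f)
  expect_setequal(back$terms$term_id, dag$terms$term_id)
  e1 <- paste(dag$edges$child, dag$edges$parent)
  e2 <- paste(back$edges$child, back$edges$parent)
  expect_setequal(e2, e1)
})

test_that("ancestor propagation obeys the true-path rule", {
  dag <- go_dag(tibble::tibble(term_id = c("A", "B", "C"),
                               name = NA, namespace = NA),
                tibble::tibble(child = c("C", "B"), parent = c("B", "A")))
  direct <- tibble::tibble(term_id = "C", gene_id = "g1")
  prop <- annotate_with_ancestors(dag, direct)
  expect_setequal(prop$term_id[prop$gene_id == "g1"], c("A", "B", "C"))

  # no edges: map unchanged
  lone <- go_dag(tibble::tibble(term_id = c("X", "Y"), name = NA,
                                namespace = NA),
                 tibble::tibble(child = character(), parent = character()))
  d2 <- tibble::tibble(term_id = c("X", "Y"), gene_id = c("g1", "g2"))
  expect_equal(dplyr::arrange(annotate_with_ancestors(lone, d2), term_id),
               dplyr::arrange(d2, term_id))
  expect_error(annotate_with_ancestors(lone, tibble::tibble(term_id = "Z",
                                                            gene_id = "g")),
               "unknown term")
})

test_that("propagation equals a brute-force transitive-closure oracle", {
  set.seed(37)
  dag <- rand_dag(40, 0.1)
  genes <- sprintf("g%02d", 1:30)
  direct <- tibble::tibble(
    term_id = sample(dag$terms$term_id, 60, replace = TRUE),
    gene_id = sample(genes, 60, replace = TRUE)) |> dplyr::distinct()
  prop <- annotate_with_ancestors(dag, direct)
  oracle <- propagate_oracle(dag$edges, direct)
  got <- split(prop$gene_id, prop$term_id)
  for (t in names(oracle)) {
    expect_setequal(got[[t]], unique(oracle[[t]]))
  }
  # child term sets never exceed their parents' after propagation
  for (i in seq_len(nrow(dag$edges))) {
    ch <- got[[dag$edges$child[i]]]
    if (!is.null(ch)) {
      expect_true(all(ch %in% got[[dag$edges$parent[i]]]))
    }
  }
})

test_that("hypergeometric enrichment matches enumeration and its score formula", {
  bg <- sprintf("g%03d", 1:100)
  ann <- tibble::tibble(term_id = "T", gene_id = bg[1:10])
  query <- c(bg[1:3], bg[50:51])           # k = 3 of n = 5
  res <- hypergeom_enrich(query, bg, ann)
  expect_equal(res$enrichment_score, (3 / 5) / (10 / 100))
  # exhaustive enumeration over all C(100,5) draws via the density identity
  enum_p <- sum(vapply(3:5, function(k) {
    choose(10, k) * choose(90, 5 - k) / choose(100, 5)
  }, numeric(1)))
  expect_equal(res$p, enum_p, tolerance = 1e-12)

  # saturated term: p = 1, score = 1
  full <- hypergeom_enrich(query, bg, tibble::tibble(term_id = "S",
                                                     gene_id = bg))
  expect_equal(full$p, 1)
  expect_equal(full$enrichment_score, 1)

  # k = 0 keeps p = 1 (tail includes zero)
  miss <- hypergeom_enrich(bg[90:94], bg,
                           tibble::tibble(term_id = "T", gene_id = bg[1:10]))
  expect_equal(miss$p, 1)

  expect_error(hypergeom_enrich(c("nope"), bg, ann), "outside the background")
  expect_error(hypergeom_enrich(character(), bg, ann), "Empty query")
})

test_that("enrichment p-values are invariant to gene relabeling", {
  set.seed(41)
  bg <- sprintf("g%03d", 1:60)
  ann <- tibble::tibble(term_id = rep(c("T1", "T2"), c(12, 20)),
                        gene_id = c(sample(bg, 12), sample(bg, 20)))
  query <- sample(bg, 8)
  res1 <- hypergeom_enrich(query, bg, ann)
  relabel <- setNames(sprintf("x%03d", 1:60), bg)
  res2 <- hypergeom_enrich(unname(relabel[query]), unname(relabel),
                           tibble::tibble(term_id = ann$term_id,
                                          gene_id = unname(relabel[ann$gene_id])))
  expect_equal(res1$p, res2$p[match(res1$term_id, res2$term_id)])
})

test_that("adjustment ordering holds: bonferroni >= BH >= raw p", {
  set.seed(43)
  bg <- sprintf("g%03d", 1:80)
  ann <- tibble::tibble(
    term_id = rep(sprintf("T%d", 1:8), each = 10),
    gene_id = sample(bg, 80, replace = TRUE)) |> dplyr::distinct()
  query <- sample(bg, 10)
  bon <- hypergeom_enrich(query, bg, ann, adjust = "bonferroni")
  bh <- hypergeom_enrich(query, bg, ann, adjust = "BH")
  bh <- bh[match(bon$term_id, bh$term_id), ]
  expect_true(all(bon$p_adj >= bh$p_adj - 1e-12))
  expect_true(all(bh$p_adj >= bh$p - 1e-12))
})

test_that("the significance filter is inclusive at the threshold", {
  res <- tibble::tibble(term_id = c("a", "b", "c"),
                        p_adj = c(1e-6, 9.9e-7, 0.01))
  expect_setequal(significant_terms(res, 1e-6), c("a", "b"))
  expect_length(significant_terms(res, 1e-8), 0)
})

test_that("common children are proper descendants of enough significant terms", {
  dag <- go_dag(tibble::tibble(term_id = c("A", "B", "C"), name = NA,
                               namespace = NA),
                tibble::tibble(child = c("C", "B"), parent = c("B", "A")))
  rep_ <- common_child_terms(dag, c("A", "B", "C"))
  tabC <- dplyr::filter(rep_$report, term_id == "C")
  expect_true(tabC$is_common_child)
  expect_setequal(tabC$ancestors[[1]], c("A", "B"))
  expect_identical(rep_$report$term_id[rep_$report$is_leaf], "C")
  expect_length(common_child_terms(dag, character())$significant, 0)
})

test_that("common-child detection equals a reachability oracle on random DAGs", {
  set.seed(47)
  for (i in 1:5) {
    dag <- rand_dag(100, 0.04)
    sig <- sample(dag$terms$term_id, 30)
    rep_ <- common_child_terms(dag, sig)
    # oracle: repeated-squaring style reachability over the edge list
    reach <- new.env()
    parents <- split(dag$edges$parent, dag$edges$child)
    anc_of <- function(t) {
      seen <- character(); frontier <- parents[[t]]
      while (length(frontier)) {
        new <- setdiff(frontier, seen)
        seen <- c(seen, new)
        frontier <- unlist(parents[new], use.names = FALSE)
      }
      unique(seen)
    }
    for (t in sig) {
      want <- intersect(anc_of(t), sig)
      row <- rep_$report[rep_$report$term_id == t, ]
      expect_setequal(row$ancestors[[1]], want)
      expect_identical(row$is_common_child, length(want) >= 2)
    }
  }
})
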