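test_that("count files round-trip through read and write", {
  mat <- matrix(c(5L, 10L, 0L, 7L, 12L, 1L), nrow = 2,
                dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  design <- data.frame(sample_id = c("s1", "s2", "s3"),
                       group = c("control", "disease", "disease_drug"))
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(gene_id = rownames(mat),
                                  as.data.frame(mat)), f)
  cs <- read_counts(f, design)
  expect_identical(dim(cs), c(2L, 3L))
  expect_identical(unname(cs$counts), unname(mat))

  # randomly generated matrix: write then read reproduces the values
  set.seed(3)
  big <- matrix(rnbinom(50 * 14, mu = 60, size = 10), nrow = 50,
                dimnames = list(sprintf("g%02d", 1:50), sprintf("s%02d", 1:14)))
  cs2 <- make_cs(big, rep(c("control", "disease", "disease_drug"),
                          c(4, 5, 5)))
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_counts(cs2, f2)
  back <- read_counts(f2, cs2$design)
  expect_identical(back$counts, cs2$counts)
  expect_identical(back$design, cs2$design)
})

test_that("malformed count input is rejected with a named offender", {
  design <- data.frame(sample_id = c("s1", "s2"), group = c("control", "disease"))
  m <- matrix(c(1L, -2L, 3L, 4L), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(count_study(m, design), "non-negative.*'b'")
  m2 <- matrix(c(1.5, 2, 3, 4), 2, 2,
               dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(count_study(m2, design), "non-negative integers")
  m3 <- matrix(1:4, 2, 2, dimnames = list(c("a", "a"), c("s1", "s2")))
  expect_error(count_study(m3, design), "Duplicate gene id: 'a'")
  m4 <- matrix(1:4, 2, 2, dimnames = list(c("a", "b"), c("s1", "sX")))
  expect_error(count_study(m4, design), "missing from design: sX")
})

test_that("FPM normalization matches the per-column rescaling definition", {
  # single gene: always exactly 1e6
  one <- make_cs(matrix(c(7L, 3L, 12L), 1), rep("control", 3))
  expect_equal(unname(normalize_fpm(one)$fpm[1, ]), rep(1e6, 3))

  # count of 3 in a million-fragment library is 3 FPM
  two <- make_cs(matrix(c(3L, 999997L), 2, 1), "control")
  expect_equal(normalize_fpm(two)$fpm[1, 1], 3)

  # random matrix vs an independently coded rescaling oracle
  set.seed(5)
  mat <- matrix(rpois(100, 40), 20, 5)
  cs <- make_cs(mat, rep(c("control", "disease"), c(2, 3)))
  fpm <- normalize_fpm(cs)$fpm
  oracle <- apply(mat, 2, function(col) col / sum(col) * 1e6)
  expect_equal(unname(fpm), oracle, tolerance = 1e-9)
  expect_equal(unname(colSums(fpm)), rep(1e6, 5), tolerance = 1e-6)

  zero <- make_cs(matrix(c(1L, 0L), 1), c("control", "disease"))
  expect_error(normalize_fpm(zero), "all-zero")
})

test_that("protein-coding filtering applies the missing-gene policy", {
  set.seed(8)
  cs <- rand_cs(15, 2)
  ann <- tibble::tibble(gene_id = rownames(cs$counts)[1:12],
                        biotype = rep(c("protein_coding", "lncRNA"),
                                      c(10, 2)))
  expect_message(out <- filter_protein_coding(cs, ann, missing = "drop"),
                 "3 gene")
  expect_identical(nrow(out$counts), 10L)
  expect_identical(ncol(out$counts), ncol(cs$counts))
  # independently computed retained set
  expect_setequal(rownames(out$counts),
                  intersect(rownames(cs$counts),
                            ann$gene_id[ann$biotype == "protein_coding"]))
  # keep retains the unannotated, error refuses them
  expect_message(kept <- filter_protein_coding(cs, ann, missing = "keep"))
  expect_identical(nrow(kept$counts), 13L)
  expect_error(filter_protein_coding(cs, ann, missing = "error"),
               "Unannotated")
  # idempotence and identity on an all-coding annotation
  again <- suppressMessages(filter_protein_coding(out, ann))
  expect_identical(again$counts, out$counts)
  full <- tibble::tibble(gene_id = rownames(cs$counts),
                         biotype = "protein_coding")
  expect_identical(filter_protein_coding(cs, full)$counts, cs$counts)
})

test_that("PCA QC flags a displaced sample but spares tiny groups", {
  # identical samples: zero distances, nothing flagged
  flat <- make_cs(matrix(50L, 20, 6), rep(c("control", "disease"), each = 3))
  expect_false(any(pca_sample_qc(normalize_fpm(flat))$flagged))

  # one of five samples shifted by +5 log2 units on half the genes
  set.seed(1)
  mat <- matrix(rnbinom(200 * 10, mu = 100, size = 20), 200,
                dimnames = list(sprintf("g%03d", 1:200), sprintf("s%02d", 1:10)))
  mat[1:100, 5] <- mat[1:100, 5] * 32L
  cs <- make_cs(mat, rep(c("control", "disease"), each = 5))
  qc <- pca_sample_qc(normalize_fpm(cs))
  expect_true(qc$flagged[qc$sample_id == "s05"])
  expect_identical(sum(qc$flagged), 1L)

  # groups of size 2 are never flagged, by contract
  small <- make_cs(mat[, c(1:2, 6:10)], rep(c("control", "disease"), c(2, 5)))
  small$counts[1:100, 1] <- small$counts[1:100, 1] * 32L
  qc2 <- pca_sample_qc(normalize_fpm(small))
  expect_false(any(qc2$flagged[qc2$group == "control"]))
})

test_that("PCA QC is invariant to gene and sample order", {
  set.seed(4)
  mat <- matrix(rnbinom(150 * 9, mu = 80, size = 15), 150,
                dimnames = list(sprintf("g%03d", 1:150), sprintf("s%02d", 1:9)))
  mat[, 3] <- mat[, 3] * 8L
  cs <- make_cs(mat, rep(c("control", "disease", "disease_drug"), each = 3))
  qc <- pca_sample_qc(normalize_fpm(cs))
  perm_g <- sample(nrow(mat)); perm_s <- sample(ncol(mat))
  cs2 <- count_study(mat[perm_g, perm_s], cs$design[perm_s, ])
  qc2 <- pca_sample_qc(normalize_fpm(cs2))
  qc2 <- qc2[match(qc$sample_id, qc2$sample_id), ]
  expect_equal(qc2$centroid_dist, qc$centroid_dist, tolerance = 1e-8)
  expect_identical(qc2$flagged, qc$flagged)
})
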