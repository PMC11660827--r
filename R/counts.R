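#' Construct a three-group count study
#'
#' Bundles an integer gene-by-sample fragment-count matrix (featureCounts-style)
#' with a sample design assigning each sample to one of the study groups,
#' typically `control`, `disease` and `disease_drug`.
#'
#' @param counts Integer matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids). All values must be non-negative whole
#'   numbers.
#' @param design A data frame with columns `sample_id` and `group`, covering
#'   every column of `counts`.
#' @return An object of class `count_study`: a list with elements `counts`
#'   (integer matrix) and `design` (tibble).
#' @examples
#' cs <- count_study(
#'   matrix(c(5L, 10L, 0L, 7L, 12L, 1L), nrow = 2,
#'          dimnames = list(c("g1", "g2"), c("s1", "s2", "s3"))),
#'   data.frame(sample_id = c("s1", "s2", "s3"),
#'              group = c("control", "disease", "disease_drug"))
#' )
#' cs
#' @export
count_study <- function(counts, design) {
  if (!is.matrix(counts)) abort("`counts` must be a matrix.")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("`counts` must have gene ids as rownames and sample ids as colnames.")
  }
  if (anyDuplicated(rownames(counts))) {
    dup <- rownames(counts)[duplicated(rownames(counts))][1]
    abort(sprintf("Duplicate gene id: '%s'.", dup))
  }
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    bad <- which(is.na(counts) | counts < 0 | counts != round(counts),
                 arr.ind = TRUE)[1, ]
    abort(sprintf(
      "Counts must be non-negative integers; offending cell gene '%s', sample '%s'.",
      rownames(counts)[bad[1]], colnames(counts)[bad[2]]))
  }
  storage.mode(counts) <- "integer"
  design <- as_tibble(design)
  if (!all(c("sample_id", "group") %in% names(design))) {
    abort("`design` needs columns `sample_id` and `group`.")
  }
  design$sample_id <- as.character(design$sample_id)
  design$group <- as.character(design$group)
  missing <- setdiff(colnames(counts), design$sample_id)
  if (length(missing)) {
    abort(sprintf("Sample(s) missing from design: %s.",
                  paste(missing, collapse = ", ")))
  }
  design <- design[match(colnames(counts), design$sample_id), ]
  structure(list(counts = counts, design = design), class = "count_study")
}

#' @export
print.count_study <- function(x, ...) {
  cat(sprintf("<count_study> %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  print(dplyr::count(x$design, .data$group))
  invisible(x)
}

#' @export
dim.count_study <- function(x) dim(x$counts)

#' Read a count matrix and design from delimited text
#'
#' Reads a featureCounts-style tab-delimited table whose first column holds
#' gene ids and whose remaining columns hold integer fragment counts, one per
#' sample.
#'
#' @param path Path to a tab-delimited counts file with a header row.
#' @param design Either a data frame with columns `sample_id` and `group`, or
#'   a path to a two-column TSV (`sample_id`, `group`).
#' @return A [count_study()].
#' @seealso [write_counts()]
#' @export
read_counts <- function(path, design) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(tab) < 2) abort("Counts file needs a gene-id column plus sample columns.")
  gene_ids <- as.character(tab[[1]])
  mat <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- names(tab)[-1][!vapply(tab[-1], is.numeric, logical(1))][1]
    abort(sprintf("Malformed counts column '%s': not numeric.", bad))
  }
  rownames(mat) <- gene_ids
  if (is.character(design)) {
    design <- readr::read_tsv(design, show_col_types = FALSE, progress = FALSE)
  }
  count_study(mat, design)
}

#' Write a count study to tab-delimited text
#'
#' Inverse of [read_counts()]: writes `gene_id` plus one column per sample.
#'
#' @param x A [count_study()].
#' @param path Output path for the counts TSV.
#' @param design_path Optional path for the two-column design TSV.
#' @return `x`, invisibly.
#' @export
write_counts <- function(x, path, design_path = NULL) {
  stopifnot(inherits(x, "count_study"))
  tab <- tibble(gene_id = rownames(x$counts))
  tab <- dplyr::bind_cols(tab, as_tibble(x$counts))
  readr::write_tsv(tab, path, progress = FALSE)
  if (!is.null(design_path)) {
    readr::write_tsv(x$design, design_path, progress = FALSE)
  }
  invisible(x)
}

#' Restrict a count study to protein-coding genes
#'
#' Keeps only genes annotated with biotype `protein_coding`. Genes absent from
#' the annotation are handled by `missing`: dropped (default, with a message),
#' kept, or treated as an error.
#'
#' @param x A [count_study()].
#' @param annotation Data frame with columns `gene_id` and `biotype`, or a
#'   named character vector of biotypes.
#' @param missing Policy for unannotated genes: `"drop"`, `"keep"` or
#'   `"error"`.
#' @return A filtered [count_study()]; the sample set is unchanged.
#' @export
filter_protein_coding <- function(x, annotation,
                                  missing = c("drop", "keep", "error")) {
  stopifnot(inherits(x, "count_study"))
  missing <- match.arg(missing)
  if (is.data.frame(annotation)) {
    biotype <- setNames(as.character(annotation$biotype),
                        as.character(annotation$gene_id))
  } else {
    biotype <- annotation
  }
  bt <- biotype[rownames(x$counts)]
  unann <- is.na(bt)
  if (any(unann)) {
    if (missing == "error") {
      abort(sprintf("Unannotated gene id(s), e.g. '%s'.",
                    rownames(x$counts)[unann][1]))
    }
    inform(sprintf("%d gene(s) without biotype annotation: policy '%s'.",
                   sum(unann), missing))
  }
  keep <- (!is.na(bt) & bt == "protein_coding") | (unann & missing == "keep")
  count_study(x$counts[keep, , drop = FALSE], x$design)
}

#' @export
tidy.count_study <- function(x, ...) {
  as_tibble(as.data.frame.table(x$counts, responseName = "count",
                                stringsAsFactors = FALSE)) %>%
    rename(gene_id = "Var1", sample_id = "Var2") %>%
    left_join(x$design, by = "sample_id")
}

#' @export
glance.count_study <- function(x, ...) {
  tibble(n_genes = nrow(x$counts), n_samples = ncol(x$counts),
         n_groups = dplyr::n_distinct(x$design$group),
         total_fragments = sum(as.numeric(x$counts)))
}
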