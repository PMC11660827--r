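#' Normalize counts to fragments per million (FPM)
#'
#' Rescales each sample column so it sums to one million counted fragments:
#' `fpm[g, s] = counts[g, s] / sum_g counts[g, s] * 1e6`. This is per-sample
#' depth normalization with no gene-length correction, so the library size is
#' the sum of counts in the matrix as given — typically after restricting to
#' the analyzed gene universe (see [filter_protein_coding()]).
#'
#' @param x A [count_study()].
#' @return An object of class `abundance_matrix`: list with `fpm` (numeric
#'   matrix, each nonzero column summing to 1e6) and `design` (tibble).
#' @examples
#' cs <- count_study(
#'   matrix(c(3L, 999997L), 2, 1, dimnames = list(c("a", "b"), "s1")),
#'   data.frame(sample_id = "s1", group = "control")
#' )
#' normalize_fpm(cs)$fpm["a", "s1"]  # 3 FPM
#' @export
normalize_fpm <- function(x) {
  stopifnot(inherits(x, "count_study"))
  libsize <- colSums(x$counts)
  if (any(libsize == 0)) {
    abort(sprintf("Sample '%s' has all-zero counts; FPM undefined.",
                  colnames(x$counts)[libsize == 0][1]))
  }
  fpm <- sweep(x$counts, 2, libsize, "/") * 1e6
  structure(list(fpm = fpm, design = x$design), class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("<abundance_matrix> %d genes x %d samples (FPM)\n",
              nrow(x$fpm), ncol(x$fpm)))
  invisible(x)
}

#' @export
dim.abundance_matrix <- function(x) dim(x$fpm)

#' @export
tidy.abundance_matrix <- function(x, ...) {
  as_tibble(as.data.frame.table(x$fpm, responseName = "fpm",
                                stringsAsFactors = FALSE)) %>%
    rename(gene_id = "Var1", sample_id = "Var2") %>%
    left_join(x$design, by = "sample_id")
}

#' Write an abundance matrix as TSV
#'
#' @param x An `abundance_matrix` from [normalize_fpm()].
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_fpm <- function(x, path) {
  stopifnot(inherits(x, "abundance_matrix"))
  tab <- dplyr::bind_cols(tibble(gene_id = rownames(x$fpm)), as_tibble(x$fpm))
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(x)
}

# group-wise FPM column indices, in design order
group_indices <- function(design, group) {
  which(design$group == group)
}

# mean FPM per gene for one group
group_mean_fpm <- function(am, group) {
  idx <- group_indices(am$design, group)
  if (!length(idx)) abort(sprintf("Group '%s' absent from design.", group))
  rowMeans(am$fpm[, idx, drop = FALSE])
}
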