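#' PCA-based sample quality control
#'
#' Projects samples onto the first two principal components of log2(FPM + 1)
#' expression and flags samples lying unusually far from their own group
#' centroid, the situation in which a bulk RNA-seq study would exclude a
#' sample before differential analysis. A sample is flagged when its distance
#' to the group centroid in PC1/PC2 exceeds `c_mult` times the median
#' within-group centroid distance across all samples. Groups with fewer than
#' three members are never flagged: with n = 2 each sample defines the
#' centroid as much as its partner, so "outlyingness" is undefined.
#'
#' @param am An `abundance_matrix` from [normalize_fpm()].
#' @param c_mult Flagging multiplier on the median centroid distance
#'   (default 3).
#' @return A tibble of class `sample_qc` with one row per sample: `sample_id`,
#'   `group`, `PC1`, `PC2`, `centroid_dist`, `flagged`. The proportion of
#'   variance explained by the two components is stored in attribute
#'   `var_explained`.
#' @export
pca_sample_qc <- function(am, c_mult = 3) {
  stopifnot(inherits(am, "abundance_matrix"))
  stop_if_not_number(c_mult, "c_mult", min = 0, strict_min = TRUE)
  if (nrow(am$fpm) < 2) abort("Need at least 2 genes for PCA QC.")
  if (ncol(am$fpm) < 3) abort("Need at least 3 samples for PCA QC.")
  lg <- t(log2(am$fpm + 1))                 # samples x genes
  pc <- prcomp(lg, center = TRUE, scale. = FALSE, rank. = 2)
  scores <- pc$x
  if (ncol(scores) < 2) scores <- cbind(scores, PC2 = 0)
  out <- tibble(
    sample_id = rownames(scores),
    PC1 = scores[, 1], PC2 = scores[, 2]
  ) %>% left_join(am$design, by = "sample_id")
  cent <- out %>%
    group_by(.data$group) %>%
    summarise(cx = mean(.data$PC1), cy = mean(.data$PC2), gsize = n(),
              .groups = "drop")
  out <- out %>%
    left_join(cent, by = "group") %>%
    mutate(centroid_dist = sqrt((.data$PC1 - .data$cx)^2 +
                                  (.data$PC2 - .data$cy)^2))
  med <- median(out$centroid_dist)
  out <- out %>%
    mutate(flagged = .data$gsize >= 3 & .data$centroid_dist > c_mult * med) %>%
    select("sample_id", "group", "PC1", "PC2", "centroid_dist", "flagged")
  tot <- sum(pc$sdev^2)
  attr(out, "var_explained") <-
    if (tot > 0) pc$sdev[1:2]^2 / tot else c(NA_real_, NA_real_)
  class(out) <- c("sample_qc", class(out))
  out
}

#' Drop QC-flagged samples from a count study
#'
#' Flagged samples are removed worst-first (largest centroid distance), but
#' a group is never reduced below `min_group` samples: below three members
#' the group centroid is defined by the remaining samples as much as by any
#' candidate outlier, and downstream confidence intervals degenerate.
#'
#' @param x A [count_study()].
#' @param qc A `sample_qc` report from [pca_sample_qc()].
#' @param min_group Minimum retained group size (default 3).
#' @return A [count_study()] without the dropped samples.
#' @export
drop_flagged_samples <- function(x, qc, min_group = 3) {
  stopifnot(inherits(x, "count_study"))
  flagged <- qc[qc$flagged, ]
  flagged <- flagged[order(-flagged$centroid_dist), ]
  size <- table(x$design$group)
  drop <- character()
  for (i in seq_len(nrow(flagged))) {
    g <- flagged$group[i]
    if (size[[g]] > min_group) {
      drop <- c(drop, flagged$sample_id[i])
      size[[g]] <- size[[g]] - 1L
    } else {
      inform(sprintf(
        "Keeping flagged sample '%s': group '%s' already at %d sample(s).",
        flagged$sample_id[i], g, size[[g]]))
    }
  }
  if (!length(drop)) return(x)
  inform(sprintf("Dropping %d QC-flagged sample(s): %s.",
                 length(drop), paste(drop, collapse = ", ")))
  keep <- setdiff(x$design$sample_id, drop)
  count_study(x$counts[, keep, drop = FALSE],
              x$design[x$design$sample_id %in% keep, ])
}
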