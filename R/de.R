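#' Log2 fold change between group means
#'
#' `log2((mean_b + pseudocount) / (mean_a + pseudocount))`, the moderated
#' ratio of group-mean abundances. Positive values mean higher expression in
#' group B; the function is antisymmetric under swapping the groups.
#'
#' @param mean_a,mean_b Non-negative group-mean abundances (e.g. mean FPM);
#'   vectorized.
#' @param pseudocount Positive stabilizer added to both means (default 1).
#' @return Numeric vector of log2 fold changes.
#' @examples
#' log2_fold_change(10, 41)  # log2(42/11) ~ 1.933
#' @export
log2_fold_change <- function(mean_a, mean_b, pseudocount = 1) {
  stop_if_not_number(pseudocount, "pseudocount", min = 0, strict_min = TRUE)
  if (any(mean_a < 0, na.rm = TRUE) || any(mean_b < 0, na.rm = TRUE)) {
    abort("Group means must be non-negative.")
  }
  log2((mean_b + pseudocount) / (mean_a + pseudocount))
}

# median-of-ratios size factors (relative to the gene-wise geometric mean),
# robust to asymmetric differential expression; falls back to total-count
# scaling when too few genes are positive in every sample
size_factors <- function(cnt, min_ref_genes = 20) {
  pos <- rowSums(cnt == 0) == 0
  if (sum(pos) >= min_ref_genes) {
    lg <- log(cnt[pos, , drop = FALSE])
    ref <- rowMeans(lg)
    sf <- apply(lg, 2, function(col) exp(median(col - ref)))
  } else {
    sf <- colSums(cnt)
  }
  sf / mean(sf)
}

# comparison samples, validated
comparison_cols <- function(x, comparison) {
  if (length(comparison) != 2) abort("`comparison` must name two groups.")
  idx <- lapply(comparison, function(g) {
    i <- which(x$design$group == g)
    if (length(i) < 2) abort(sprintf("Group '%s' needs >= 2 samples.", g))
    i
  })
  setNames(idx, c("a", "b"))
}

#' Negative-binomial Wald test for a two-group comparison
#'
#' Per-gene two-sided test of equal expression between two groups under a
#' negative-binomial model with a log link. Counts are scaled by per-sample
#' median-of-ratios size factors (robust to asymmetric differential
#' expression); the per-gene dispersion is estimated by the
#' method of moments on the pooled within-group variance and shrunk with
#' equal weight toward the genome-wide median dispersion. The Wald statistic
#' on the log ratio of group means is referred to a t distribution whose
#' degrees of freedom are doubled relative to the residual df, reflecting the
#' information gained by the equal-weight dispersion shrinkage (prior df =
#' residual df).
#'
#' Genes with zero counts in every sample of both groups have no defined
#' contrast; they are reported with `p = 1` and `all_zero = TRUE`.
#'
#' @param x A [count_study()].
#' @param comparison Character vector of two group labels, reference first.
#' @return Tibble with `gene_id`, `p`, `all_zero`.
#' @export
nb_wald_test <- function(x, comparison = c("control", "disease")) {
  stopifnot(inherits(x, "count_study"))
  idx <- comparison_cols(x, comparison)
  cnt <- x$counts[, c(idx$a, idx$b), drop = FALSE]
  ia <- seq_along(idx$a); ib <- length(idx$a) + seq_along(idx$b)
  if (any(colSums(cnt) == 0)) {
    abort("A sample in the comparison has zero total counts.")
  }
  sf <- size_factors(cnt)
  y <- sweep(cnt, 2, sf, "/")
  nA <- length(ia); nB <- length(ib)
  mA <- rowMeans(y[, ia, drop = FALSE]); mB <- rowMeans(y[, ib, drop = FALSE])
  vA <- apply(y[, ia, drop = FALSE], 1, var)
  vB <- apply(y[, ib, drop = FALSE], 1, var)
  mu_pool <- (nA * mA + nB * mB) / (nA + nB)
  v_pool <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
  disp_raw <- (v_pool - mu_pool) / mu_pool^2
  disp_raw[!is.finite(disp_raw) | disp_raw < 1e-8] <- 1e-8
  disp_med <- median(disp_raw[mu_pool > 0])
  if (!is.finite(disp_med)) disp_med <- 1e-8
  disp <- 0.5 * disp_raw + 0.5 * disp_med

  all_zero <- mA == 0 & mB == 0
  # half a fragment per group as expression floor for one-sided zeros
  qA <- pmax(mA, 0.5 / nA); qB <- pmax(mB, 0.5 / nB)
  # Var(mean_j c_j/s_j) = (q sum(1/s_j) + disp q^2 n) / n^2; delta method on log
  vlA <- (qA * sum(1 / sf[ia]) + disp * qA^2 * nA) / nA^2 / qA^2
  vlB <- (qB * sum(1 / sf[ib]) + disp * qB^2 * nB) / nB^2 / qB^2
  stat <- log(qB / qA) / sqrt(vlA + vlB)
  p <- 2 * pt(-abs(stat), df = 2 * (nA + nB - 2))
  p[all_zero] <- 1
  tibble(gene_id = rownames(cnt), p = unname(p), all_zero = unname(all_zero))
}

#' Moderated Welch t-test on log2 CPM
#'
#' Per-gene two-sided test on `log2(CPM + 1)` values (CPM computed with
#' median-of-ratios size factors scaled to the mean library size). Gene-wise group
#' variances are shrunk with equal weight toward the across-gene mean
#' variance of their group, then combined into a Welch statistic; the
#' Welch–Satterthwaite degrees of freedom are computed with each group's
#' residual df doubled, the df gain implied by equal-weight shrinkage.
#' A gene with zero shrunk variance and equal group means (all genes
#' constant) gets `p = 1` by convention.
#'
#' @inheritParams nb_wald_test
#' @return Tibble with `gene_id`, `p`, `all_zero`.
#' @export
logcpm_moderated_t <- function(x, comparison = c("control", "disease")) {
  stopifnot(inherits(x, "count_study"))
  idx <- comparison_cols(x, comparison)
  cnt <- x$counts[, c(idx$a, idx$b), drop = FALSE]
  tot <- colSums(cnt)
  if (any(tot == 0)) abort("A sample in the comparison has zero total counts.")
  sf <- size_factors(cnt) * mean(tot)
  l <- log2(sweep(cnt, 2, sf, "/") * 1e6 + 1)
  ia <- seq_along(idx$a); ib <- length(idx$a) + seq_along(idx$b)
  a <- l[, ia, drop = FALSE]; b <- l[, ib, drop = FALSE]
  nA <- ncol(a); nB <- ncol(b)
  mA <- rowMeans(a); mB <- rowMeans(b)
  vA <- apply(a, 1, var); vB <- apply(b, 1, var)
  vA <- 0.5 * vA + 0.5 * mean(vA)
  vB <- 0.5 * vB + 0.5 * mean(vB)
  se2 <- vA / nA + vB / nB
  dfA <- 2 * (nA - 1); dfB <- 2 * (nB - 1)
  df <- se2^2 / ((vA / nA)^2 / dfA + (vB / nB)^2 / dfB)
  p <- ifelse(se2 > 0, 2 * pt(-abs((mB - mA) / sqrt(se2)), df),
              as.numeric(mA == mB))
  all_zero <- rowSums(cnt) == 0
  p[all_zero] <- 1
  tibble(gene_id = rownames(cnt), p = unname(p), all_zero = unname(all_zero))
}

#' Benjamini–Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, monotone in rank and capped at 1.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0 | p > 1)) {
    abort("p-values must be finite and within [0, 1].")
  }
  p.adjust(p, method = "BH")
}

#' Consensus differential-expression call
#'
#' A gene is a consensus DEG when its FDR is strictly below `alpha` in both
#' callers ("significant in both"), the overlap criterion used to define the
#' analyzed DEG set.
#'
#' @param fdr1,fdr2 Adjusted p-value vectors over the same gene universe;
#'   if named, names must match as sets.
#' @param alpha Significance threshold (default 0.05, strict `<`).
#' @return Logical vector, aligned to `fdr1`.
#' @export
consensus_deg <- function(fdr1, fdr2, alpha = 0.05) {
  if (length(fdr1) != length(fdr2)) abort("FDR vectors have different lengths.")
  if (!is.null(names(fdr1)) && !is.null(names(fdr2))) {
    if (!setequal(names(fdr1), names(fdr2))) {
      abort("FDR vectors cover different gene sets.")
    }
    fdr2 <- fdr2[names(fdr1)]
  }
  fdr1 < alpha & fdr2 < alpha
}

#' Dual-caller differential expression for one comparison
#'
#' Runs both built-in callers ([nb_wald_test()] and [logcpm_moderated_t()]),
#' adjusts each with [bh_fdr()], combines them by the strict "significant in
#' both" consensus, and attaches the log2 fold change computed from
#' group-mean FPM with a pseudocount.
#'
#' @inheritParams nb_wald_test
#' @param alpha Consensus FDR threshold (default 0.05).
#' @param pseudocount Pseudocount for the fold-change estimate (default 1).
#' @return A tibble of class `de_result`: `gene_id`, `mean_fpm_a`,
#'   `mean_fpm_b`, `log2fc`, `p_nb`, `p_modt`, `fdr_nb`, `fdr_modt`,
#'   `consensus`.
#' @export
de_consensus <- function(x, comparison = c("control", "disease"),
                         alpha = 0.05, pseudocount = 1) {
  stopifnot(inherits(x, "count_study"))
  am <- normalize_fpm(x)
  r1 <- nb_wald_test(x, comparison)
  r2 <- logcpm_moderated_t(x, comparison)
  mean_a <- group_mean_fpm(am, comparison[1])
  mean_b <- group_mean_fpm(am, comparison[2])
  out <- tibble(
    gene_id = r1$gene_id,
    mean_fpm_a = unname(mean_a[r1$gene_id]),
    mean_fpm_b = unname(mean_b[r1$gene_id]),
    log2fc = unname(log2_fold_change(mean_a[r1$gene_id], mean_b[r1$gene_id],
                                     pseudocount)),
    p_nb = r1$p, p_modt = r2$p,
    fdr_nb = bh_fdr(r1$p), fdr_modt = bh_fdr(r2$p)
  )
  out$consensus <- consensus_deg(out$fdr_nb, out$fdr_modt, alpha)
  attr(out, "comparison") <- comparison
  attr(out, "alpha") <- alpha
  class(out) <- c("de_result", class(out))
  out
}

#' @export
glance.de_result <- function(x, ...) {
  tibble(comparison = paste(attr(x, "comparison"), collapse = "_vs_"),
         n_genes = nrow(x),
         n_consensus = sum(x$consensus),
         alpha = attr(x, "alpha"))
}
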