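#' Confidence interval for one group's abundances
#'
#' Student-t confidence interval for the group mean. On the default
#' `"log2p1"` scale the interval is computed as mean +/- t * sd/sqrt(n) on
#' `log2(x + 1)` and the endpoints (and point estimate) are back-transformed
#' by `2^y - 1`, which stabilizes the variance of count-derived abundances.
#' A `"linear"` scale computes the interval directly on the raw values.
#'
#' @param values Non-negative abundance values (e.g. FPM) for one group,
#'   length >= 2.
#' @param level Confidence level (default 0.95).
#' @param scale `"log2p1"` (default) or `"linear"`.
#' @param group Optional group label carried into the output.
#' @return One-row tibble: `group`, `n`, `estimate`, `lower`, `upper`,
#'   `mean_fpm` (arithmetic mean of the raw values), `level`, `scale`.
#' @export
group_ci <- function(values, level = 0.95, scale = c("log2p1", "linear"),
                     group = NA_character_) {
  scale <- match.arg(scale)
  if (length(values) < 2) abort("Confidence interval undefined for n < 2.")
  if (any(values < 0)) abort("Abundances must be non-negative.")
  stop_if_not_number(level, "level", min = 0, strict_min = TRUE)
  if (level >= 1) abort("`level` must be in (0, 1).")
  ci <- ci_rows(matrix(values, nrow = 1), level, scale)
  tibble(group = group, n = length(values),
         estimate = ci$estimate, lower = ci$lower, upper = ci$upper,
         mean_fpm = mean(values), level = level, scale = scale)
}

# vectorized t-intervals over rows of a genes x samples block
ci_rows <- function(mat, level, scale) {
  n <- ncol(mat)
  z <- if (scale == "log2p1") log2(mat + 1) else mat
  m <- rowMeans(z)
  s <- sqrt(rowSums((z - m)^2) / (n - 1))
  margin <- qt(1 - (1 - level) / 2, df = n - 1) * s / sqrt(n)
  lo <- m - margin; hi <- m + margin
  if (scale == "log2p1") {
    list(estimate = 2^m - 1, lower = pmax(2^lo - 1, 0), upper = 2^hi - 1)
  } else {
    list(estimate = m, lower = lo, upper = hi)
  }
}

#' Do two group confidence intervals overlap?
#'
#' Closed-interval test: intervals overlap iff `a$lower <= b$upper` and
#' `b$lower <= a$upper`, so touching endpoints count as overlapping.
#'
#' @param a,b One-row interval tibbles from [group_ci()], with matching
#'   `scale` tags.
#' @return Logical scalar.
#' @export
intervals_overlap <- function(a, b) {
  if (!identical(a$scale, b$scale)) {
    abort("Intervals computed on different scales cannot be compared.")
  }
  a$lower <= b$upper & b$lower <= a$upper
}

# vectorized five-rule evaluation over an abundance matrix
strategy_b_rules <- function(am, groups = c("control", "disease", "disease_drug"),
                             fpm_min = 3, lfc_min = 1, ci_level = 0.95,
                             scale = c("log2p1", "linear"), pseudocount = 1) {
  scale <- match.arg(scale)
  blocks <- lapply(groups, function(g) {
    idx <- group_indices(am$design, g)
    if (length(idx) < 2) abort(sprintf("Group '%s' needs >= 2 samples.", g))
    am$fpm[, idx, drop = FALSE]
  })
  names(blocks) <- c("ctl", "dis", "drg")
  means <- lapply(blocks, rowMeans)
  cis <- lapply(blocks, ci_rows, level = ci_level, scale = scale)
  overlap <- function(u, v) u$lower <= v$upper & v$lower <= u$upper
  lfc_cd <- log2_fold_change(means$ctl, means$dis, pseudocount)
  lfc_ce <- log2_fold_change(means$ctl, means$drg, pseudocount)
  r1 <- pmax(means$ctl, means$dis, means$drg) > fpm_min
  r2 <- abs(lfc_cd) > lfc_min
  r3 <- !overlap(cis$ctl, cis$dis)
  r4 <- !overlap(cis$dis, cis$drg)
  r5 <- overlap(cis$ctl, cis$drg)
  tibble(
    gene_id = rownames(am$fpm),
    mean_fpm_control = unname(means$ctl), mean_fpm_disease = unname(means$dis),
    mean_fpm_drug = unname(means$drg),
    lfc_cd = unname(lfc_cd), lfc_ce = unname(lfc_ce),
    r1 = unname(r1), r2 = unname(r2), r3 = unname(r3), r4 = unname(r4),
    r5 = unname(r5),
    strategy_b = unname(r1 & r2 & r3 & r4 & r5)
  )
}

#' Five-rule rescue classification for a single gene
#'
#' Evaluates the abundance / CI-overlap rule set on one gene's per-group
#' abundances: (1) mean abundance above `fpm_min` in at least one group
#' (strict); (2) `|log2FC|` control vs disease above `lfc_min` (strict);
#' (3) control and disease CIs disjoint; (4) disease and disease+drug CIs
#' disjoint; (5) control and disease+drug CIs overlapping. The gene is
#' rescue-sensitive when all five hold; the direction of dysregulation is
#' the sign of the control-to-disease log2 fold change.
#'
#' @param control,disease,disease_drug Numeric FPM vectors (each n >= 2).
#' @param fpm_min Abundance gate (default 3 FPM).
#' @param lfc_min Fold-change gate (default 1, strict).
#' @param ci_level,scale,pseudocount See [group_ci()] and
#'   [log2_fold_change()].
#' @param gene_id Label carried into the output.
#' @return One-row tibble with the per-rule record (`r1`..`r5`), `direction`
#'   and `strategy_b`.
#' @export
classify_strategy_b <- function(control, disease, disease_drug,
                                fpm_min = 3, lfc_min = 1, ci_level = 0.95,
                                scale = c("log2p1", "linear"),
                                pseudocount = 1, gene_id = "gene") {
  scale <- match.arg(scale)
  mat <- rbind(c(control, disease, disease_drug))
  rownames(mat) <- gene_id
  design <- tibble(
    sample_id = paste0("s", seq_len(ncol(mat))),
    group = rep(c("control", "disease", "disease_drug"),
                c(length(control), length(disease), length(disease_drug)))
  )
  colnames(mat) <- design$sample_id
  am <- structure(list(fpm = mat, design = design), class = "abundance_matrix")
  calls <- strategy_b_rules(am, fpm_min = fpm_min, lfc_min = lfc_min,
                            ci_level = ci_level, scale = scale,
                            pseudocount = pseudocount)
  calls$direction <- direction_label(calls$lfc_cd)
  calls
}

# up/down/none labels; threshold inclusive so that both strategies'
# fold-change gates (> 1 strict and >= 1) imply a non-none direction
direction_label <- function(lfc, threshold = 1) {
  dplyr::case_when(lfc >= threshold ~ "up",
                   lfc <= -threshold ~ "down",
                   TRUE ~ "none")
}

#' DE-based "normalized" rescue classification (strategy A)
#'
#' A gene is rescue-sensitive when it is a consensus DEG with
#' `|log2FC| >= 1` in control vs disease, but is no longer differentially
#' expressed comparing control vs disease+drug (not a consensus DEG and
#' `|log2FC| <= 1` there).
#'
#' @param de_cd `de_result` for control vs disease.
#' @param de_ce `de_result` for control vs disease+drug.
#' @param lfc_min Fold-change gate (default 1; `>=` in the disease
#'   comparison, `<=` in the drug comparison).
#' @return Tibble `gene_id`, `strategy_a`.
#' @export
classify_strategy_a <- function(de_cd, de_ce, lfc_min = 1) {
  if (!setequal(de_cd$gene_id, de_ce$gene_id)) {
    abort("The two DE results cover different gene sets.")
  }
  ce <- de_ce[match(de_cd$gene_id, de_ce$gene_id), ]
  tibble(
    gene_id = de_cd$gene_id,
    strategy_a = de_cd$consensus & abs(de_cd$log2fc) >= lfc_min &
      !ce$consensus & abs(ce$log2fc) <= lfc_min
  )
}

#' Classify every gene's disease response and rescue sensitivity
#'
#' Combines the five-rule abundance/CI procedure (strategy B) with the
#' DE-based "normalized" criterion (strategy A) over a whole study.
#'
#' @param am `abundance_matrix` over the analyzed genes.
#' @param de_cd,de_ce `de_result` objects for control-vs-disease and
#'   control-vs-disease+drug (needed for strategy A; pass `NULL` to skip it).
#' @param groups Group labels, in the order control, disease, disease+drug.
#' @inheritParams classify_strategy_b
#' @return A tibble of class `rescue_calls`, one row per gene: group mean
#'   FPMs, `lfc_cd`, `lfc_ce`, `direction`, rules `r1`..`r5`, `strategy_a`,
#'   `strategy_b`.
#' @export
classify_rescue <- function(am, de_cd = NULL, de_ce = NULL,
                            groups = c("control", "disease", "disease_drug"),
                            fpm_min = 3, lfc_min = 1, ci_level = 0.95,
                            scale = c("log2p1", "linear"), pseudocount = 1) {
  stopifnot(inherits(am, "abundance_matrix"))
  scale <- match.arg(scale)
  calls <- strategy_b_rules(am, groups, fpm_min, lfc_min, ci_level, scale,
                            pseudocount)
  calls$direction <- direction_label(calls$lfc_cd)
  if (!is.null(de_cd) && !is.null(de_ce)) {
    a <- classify_strategy_a(de_cd, de_ce, lfc_min = lfc_min)
    calls <- left_join(calls, a, by = "gene_id")
    calls$strategy_a <- calls$strategy_a & calls$direction != "none"
  } else {
    calls$strategy_a <- NA
  }
  calls <- calls %>%
    select("gene_id", "direction", dplyr::starts_with("mean_fpm"),
           "lfc_cd", "lfc_ce", "r1", "r2", "r3", "r4", "r5",
           "strategy_a", "strategy_b")
  class(calls) <- c("rescue_calls", class(calls))
  calls
}

#' Summarize rescue calls per direction and strategy
#'
#' Produces the per-direction bookkeeping table for a rescue analysis: how
#' many disease-regulated genes are up vs down, what percentage of each
#' direction is rescue-sensitive under each strategy, the mean log2 fold
#' change in each cell, and the agreement between the two strategies
#' (Jaccard index and the fraction of strategy-B calls also made by
#' strategy A).
#'
#' @param calls A `rescue_calls` tibble (or any tibble with `direction`,
#'   `strategy_a`/`strategy_b` and optionally `lfc_cd`, `lfc_ce` columns).
#' @return A `strategy_summary` object: list with `overall` (one-row tibble)
#'   and `cells` (strategy x direction x sensitive tibble).
#' @export
summarize_strategies <- function(calls) {
  if (nrow(calls) == 0) abort("Empty call table.")
  if (!"lfc_cd" %in% names(calls)) calls$lfc_cd <- NA_real_
  if (!"lfc_ce" %in% names(calls)) calls$lfc_ce <- NA_real_
  reg <- dplyr::filter(calls, .data$direction != "none")
  n_reg <- nrow(reg)
  n_up <- sum(reg$direction == "up"); n_down <- sum(reg$direction == "down")
  pct <- function(num, den) if (den > 0) 100 * num / den else 0
  has_strategy <- function(strat) {
    col <- calls[[paste0("strategy_", strat)]]
    !is.null(col) && !all(is.na(col))
  }
  cells <- purrr::map_dfr(c("a", "b"), function(strat) {
    if (!has_strategy(strat)) return(tibble())
    flag <- reg[[paste0("strategy_", strat)]]
    purrr::map_dfr(c("up", "down"), function(dir) {
      in_dir <- reg$direction == dir
      purrr::map_dfr(c(TRUE, FALSE), function(sens) {
        sel <- in_dir & flag == sens
        tibble(strategy = strat, direction = dir, sensitive = sens,
               n = sum(sel), pct_of_direction = pct(sum(sel), sum(in_dir)),
               mean_lfc_cd = if (any(sel)) mean(reg$lfc_cd[sel]) else NA_real_,
               mean_lfc_ce = if (any(sel)) mean(reg$lfc_ce[sel]) else NA_real_)
      })
    })
  })
  a_set <- reg$gene_id[which(reg$strategy_a)]
  b_set <- reg$gene_id[which(reg$strategy_b)]
  uni <- length(union(a_set, b_set)); int <- length(intersect(a_set, b_set))
  overall <- tibble(
    n_regulated = n_reg, n_up = n_up, n_down = n_down,
    pct_up = pct(n_up, n_reg), pct_down = pct(n_down, n_reg),
    n_sensitive_a = if (!has_strategy("a")) NA_integer_
                    else sum(reg$strategy_a, na.rm = TRUE),
    n_sensitive_b = if (!has_strategy("b")) NA_integer_
                    else sum(reg$strategy_b, na.rm = TRUE),
    overlap_jaccard = if (uni > 0) int / uni else 0,
    overlap_b_in_a = if (length(b_set) > 0) int / length(b_set) else 0
  )
  structure(list(overall = overall, cells = cells),
            class = "strategy_summary")
}

#' @export
print.strategy_summary <- function(x, ...) {
  cat("<strategy_summary>\n")
  print(x$overall)
  print(x$cells)
  invisible(x)
}

#' @export
tidy.strategy_summary <- function(x, ...) x$cells

#' @export
glance.strategy_summary <- function(x, ...) x$overall

#' @export
glance.rescue_calls <- function(x, ...) {
  tibble(n_genes = nrow(x),
         n_regulated = sum(x$direction != "none"),
         n_up = sum(x$direction == "up"),
         n_down = sum(x$direction == "down"),
         n_sensitive_a = sum(x$strategy_a, na.rm = TRUE),
         n_sensitive_b = sum(x$strategy_b, na.rm = TRUE))
}
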