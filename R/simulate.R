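#' Configuration for a synthetic three-group study
#'
#' Describes the generative model used by [simulate_counts()]: a three-group
#' design of the study's size (4 control after QC exclusion, 5 disease, 5
#' disease+drug), gene-wise relative expression drawn log-normal,
#' negative-binomial counts with `variance = mu + dispersion * mu^2`, and
#' planted gene classes: `null` genes (no effect), `up_persistent` /
#' `down_persistent` genes shifted in disease and unchanged by the drug, and
#' `up_rescued` / `down_rescued` genes shifted in disease and returned
#' toward the control mean in the drug group.
#'
#' Genes carrying a planted effect are drawn from the expressed part of the
#' abundance distribution (expected FPM above `min_expressed_fpm`), since a
#' fold change on an undetectable gene is not a recoverable signal.
#'
#' @param n_genes Number of genes (default 13628, the protein-coding scale
#'   of the emulated study).
#' @param group_sizes Named sizes for `control`, `disease`, `disease_drug`
#'   (default 4/5/5).
#' @param baseline_sdlog Log-normal sd (natural log) of relative expression
#'   across genes (default 2).
#' @param class_props Named proportions over the five gene classes; must sum
#'   to 1 (default 80% null, 5% each planted class).
#' @param effect_lfc Absolute log2 fold change of planted disease effects
#'   (default 1.5).
#' @param dispersion NB dispersion (default 0.05).
#' @param dispersion_sdlog Optional log-normal spread of per-gene dispersion
#'   around `dispersion` (default 0 = constant).
#' @param rescue_completeness Fraction of the disease shift removed in the
#'   drug group for rescued classes, on the log2 scale (default 1: drug mean
#'   equals control mean).
#' @param libsize_meanlog,libsize_sdlog Log-normal library-size model
#'   (default around 2e7 fragments).
#' @param min_expressed_fpm Expressed-gene floor for planted classes
#'   (default 5 FPM).
#' @param seed Default random seed used by [simulate_counts()].
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 13628,
                              group_sizes = c(control = 4, disease = 5,
                                              disease_drug = 5),
                              baseline_sdlog = 2,
                              class_props = c(null = 0.8,
                                              up_persistent = 0.05,
                                              down_persistent = 0.05,
                                              up_rescued = 0.05,
                                              down_rescued = 0.05),
                              effect_lfc = 1.5,
                              dispersion = 0.05,
                              dispersion_sdlog = 0,
                              rescue_completeness = 1,
                              libsize_meanlog = log(2e7),
                              libsize_sdlog = 0.2,
                              min_expressed_fpm = 5,
                              seed = 1) {
  classes <- c("null", "up_persistent", "down_persistent", "up_rescued",
               "down_rescued")
  if (!setequal(names(class_props), classes)) {
    abort(sprintf("`class_props` must be named: %s.",
                  paste(classes, collapse = ", ")))
  }
  if (abs(sum(class_props) - 1) > 1e-8) abort("`class_props` must sum to 1.")
  if (any(class_props < 0)) abort("`class_props` must be non-negative.")
  if (any(group_sizes < 2)) abort("Each group needs >= 2 samples.")
  stop_if_not_number(n_genes, "n_genes", min = 2)
  stop_if_not_number(effect_lfc, "effect_lfc", min = 0)
  stop_if_not_number(dispersion, "dispersion", min = 0, strict_min = TRUE)
  if (rescue_completeness < 0 || rescue_completeness > 1) {
    abort("`rescue_completeness` must be in [0, 1].")
  }
  structure(list(n_genes = as.integer(n_genes), group_sizes = group_sizes,
                 baseline_sdlog = baseline_sdlog,
                 class_props = class_props[classes],
                 effect_lfc = effect_lfc, dispersion = dispersion,
                 dispersion_sdlog = dispersion_sdlog,
                 rescue_completeness = rescue_completeness,
                 libsize_meanlog = libsize_meanlog,
                 libsize_sdlog = libsize_sdlog,
                 min_expressed_fpm = min_expressed_fpm,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a three-group count study with planted truth
#'
#' Draws a [count_study()] from the generative model described in
#' [simulation_config()], together with the planted per-gene truth enabling
#' recovery benchmarking.
#'
#' @param config A [simulation_config()].
#' @param seed Random seed (default `config$seed`); identical seeds give
#'   identical studies.
#' @return List with `study` (a [count_study()]), `truth` (tibble:
#'   `gene_id`, `class`, `base_fpm`, `lfc_disease`, `lfc_drug`) and
#'   `lib_sizes` (named vector of the true expected library sizes, part of
#'   the ground truth: planted effects shift column totals, so effect
#'   recovery on the true scale needs the generating library sizes rather
#'   than observed totals).
#' @export
simulate_counts <- function(config = simulation_config(),
                            seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(seed)
  G <- config$n_genes
  sizes <- config$group_sizes
  n_tot <- sum(sizes)
  groups <- rep(names(sizes), sizes)

  # planted class assignment
  n_class <- floor(G * config$class_props)
  n_class["null"] <- G - sum(n_class[names(n_class) != "null"])
  class <- sample(rep(names(n_class), n_class))

  # relative expression; planted genes resampled above the expressed floor
  r <- rlnorm(G, meanlog = 0, sdlog = config$baseline_sdlog)
  rmin <- config$min_expressed_fpm * sum(r) / 1e6
  low <- class != "null" & r < rmin
  if (any(low)) {
    pmin_ <- stats::plnorm(rmin, 0, config$baseline_sdlog)
    u <- runif(sum(low), min = pmin_, max = 1)
    r[low] <- stats::qlnorm(u, 0, config$baseline_sdlog)
  }

  e <- config$effect_lfc
  sign <- dplyr::case_when(grepl("^up", class) ~ 1,
                           grepl("^down", class) ~ -1,
                           TRUE ~ 0)
  lfc_disease <- sign * e
  lfc_drug <- ifelse(grepl("rescued", class),
                     (1 - config$rescue_completeness) * lfc_disease,
                     lfc_disease)

  lib <- rlnorm(n_tot, config$libsize_meanlog, config$libsize_sdlog)
  eff <- cbind(control = rep(0, G), disease = lfc_disease, drug = lfc_drug)
  colmap <- c(control = 1L, disease = 2L, disease_drug = 3L)
  disp <- if (config$dispersion_sdlog > 0) {
    rlnorm(G, log(config$dispersion), config$dispersion_sdlog)
  } else rep(config$dispersion, G)

  counts <- matrix(0L, G, n_tot)
  sumr <- sum(r)
  for (j in seq_len(n_tot)) {
    mu <- lib[j] * r * 2^eff[, colmap[groups[j]]] / sumr
    counts[, j] <- rnbinom(G, mu = mu, size = 1 / disp)
  }
  gene_ids <- sprintf("gene%05d", seq_len(G))
  sample_ids <- paste0(groups, "_", stats::ave(seq_len(n_tot), groups,
                                               FUN = seq_along))
  dimnames(counts) <- list(gene_ids, sample_ids)
  study <- count_study(counts, tibble(sample_id = sample_ids, group = groups))
  truth <- tibble(gene_id = gene_ids, class = class,
                  base_fpm = r / sumr * 1e6,
                  lfc_disease = lfc_disease, lfc_drug = lfc_drug)
  list(study = study, truth = truth,
       lib_sizes = setNames(lib, sample_ids))
}

#' Simulate a noisy mito-stress OCR trace
#'
#' Phase-wise Gaussian noise around true plateau values (truncated at zero),
#' for benchmarking [mito_stress_params()].
#'
#' @param initial,min_oligo,min_rotaa True plateau OCR values; must satisfy
#'   `min_rotaa <= min_oligo <= initial`.
#' @param fccp_peak Optional FCCP plateau (default `1.2 * initial`; set
#'   `NA` to omit the phase).
#' @param cycles_per_phase Measurement cycles per phase (default 3).
#' @param noise_sd Gaussian noise sd (default 0).
#' @param seed Optional random seed.
#' @return A [mito_trace()].
#' @export
simulate_mito_trace <- function(initial, min_oligo, min_rotaa,
                                fccp_peak = 1.2 * initial,
                                cycles_per_phase = 3, noise_sd = 0,
                                seed = NULL) {
  if (!(min_rotaa <= min_oligo && min_oligo <= initial)) {
    abort("Plateaus must satisfy min_rotaa <= min_oligo <= initial.")
  }
  if (any(c(initial, min_oligo, min_rotaa) < 0)) {
    abort("Plateau values must be non-negative.")
  }
  if (!is.null(seed)) set.seed(seed)
  phases <- c("basal", "post_oligomycin", "post_fccp",
              "post_rotenone_antimycin")
  truth <- c(initial, min_oligo, fccp_peak, min_rotaa)
  keep <- !is.na(truth)
  phase <- rep(phases[keep], each = cycles_per_phase)
  ocr <- rep(truth[keep], each = cycles_per_phase) +
    rnorm(sum(keep) * cycles_per_phase, 0, noise_sd)
  mito_trace(phase, pmax(ocr, 0))
}

#' Recovery of planted rescued genes
#'
#' Compares rescue calls against the planted truth of a simulated study:
#' sensitivity (recall over planted rescued genes), specificity (over
#' non-rescued genes) and the false-discovery proportion of the calls, per
#' strategy.
#'
#' @param calls A `rescue_calls` tibble from [classify_rescue()].
#' @param truth Truth tibble from [simulate_counts()] (needs `gene_id`,
#'   `class`).
#' @return Tibble with one row per strategy: `strategy`, `sensitivity`,
#'   `specificity`, `fdp`, `n_planted`, `n_called`.
#' @export
recovery_metrics <- function(calls, truth) {
  if (!setequal(calls$gene_id, truth$gene_id)) {
    abort("Call and truth tables cover different gene universes.")
  }
  truth <- truth[match(calls$gene_id, truth$gene_id), ]
  planted <- grepl("rescued", truth$class)
  purrr::map_dfr(c("a", "b"), function(strat) {
    called <- calls[[paste0("strategy_", strat)]]
    if (all(is.na(called))) return(tibble())
    called <- called %in% TRUE
    tp <- sum(called & planted); fp <- sum(called & !planted)
    tibble(strategy = strat,
           sensitivity = if (any(planted)) tp / sum(planted) else NA_real_,
           specificity = sum(!called & !planted) / sum(!planted),
           fdp = if (tp + fp > 0) fp / (tp + fp) else 0,
           n_planted = sum(planted), n_called = tp + fp)
  })
}
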