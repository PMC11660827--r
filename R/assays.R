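#' Build a mitochondrial stress-test trace
#'
#' An ordered OCR (oxygen consumption rate) time series over the injection
#' phases of a mito-stress assay: basal measurement, then oligomycin
#' (ATP-synthase inhibition), then optionally FCCP (uncoupling), then
#' rotenone/antimycin A (complex I/III inhibition).
#'
#' @param phase Character vector of phase labels, in measurement order; one
#'   of `basal`, `post_oligomycin`, `post_fccp`, `post_rotenone_antimycin`.
#' @param ocr Non-negative OCR values (pmol O2/min per normalized cell
#'   unit), same length as `phase`.
#' @return Tibble of class `mito_trace` with columns `cycle`, `phase`, `ocr`.
#' @export
mito_trace <- function(phase, ocr) {
  levels <- c("basal", "post_oligomycin", "post_fccp",
              "post_rotenone_antimycin")
  if (length(phase) != length(ocr)) abort("`phase` and `ocr` lengths differ.")
  if (!all(phase %in% levels)) {
    abort(sprintf("Unknown phase label '%s'.", setdiff(phase, levels)[1]))
  }
  if (any(ocr < 0)) abort("OCR values must be non-negative.")
  seen <- match(unique(phase), levels)
  if (is.unsorted(seen)) abort("Phases out of injection order.")
  out <- tibble(cycle = seq_along(phase), phase = phase, ocr = as.numeric(ocr))
  class(out) <- c("mito_trace", class(out))
  out
}

#' Mito-stress test parameters from an OCR trace
#'
#' Summarizes the injection phases into the standard respiration parameters:
#' \describe{
#'   \item{NMOC}{non-mitochondrial oxygen consumption, the minimum OCR after
#'     rotenone/antimycin A;}
#'   \item{basal respiration}{initial OCR (mean of pre-injection cycles)
#'     minus NMOC;}
#'   \item{proton leak}{minimum OCR after oligomycin minus NMOC;}
#'   \item{ATP-linked OCR}{initial OCR minus the post-oligomycin minimum
#'     (`atp_mode = "standard"`); `atp_mode = "as_printed"` instead audits a
#'     variant equal to basal respiration;}
#'   \item{coupling efficiency}{((basal + NMOC) - (proton leak + NMOC)) /
#'     (basal + NMOC), dimensionless in `[0, 1]` for any trace whose
#'     post-rotenone minimum <= post-oligomycin minimum <= initial value.}
#' }
#'
#' @param trace A [mito_trace()] (or data frame with `phase`, `ocr`)
#'   containing at least the `basal`, `post_oligomycin` and
#'   `post_rotenone_antimycin` phases.
#' @param post_summary Summary of post-injection plateaus: `"min"` (default)
#'   or `"mean"`.
#' @param atp_mode `"standard"` (initial minus post-oligomycin minimum) or
#'   `"as_printed"` (identical to basal respiration, retained for audit).
#' @return One-row tibble: `nmoc`, `basal_respiration`, `atp_linked`,
#'   `proton_leak`, `coupling_efficiency`, `leak_fraction_of_basal`.
#' @examples
#' tr <- mito_trace(rep(c("basal", "post_oligomycin",
#'                        "post_rotenone_antimycin"), each = 1),
#'                  c(100, 40, 20))
#' mito_stress_params(tr)  # coupling efficiency 0.6
#' @export
mito_stress_params <- function(trace, post_summary = c("min", "mean"),
                               atp_mode = c("standard", "as_printed")) {
  post_summary <- match.arg(post_summary)
  atp_mode <- match.arg(atp_mode)
  need <- c("basal", "post_oligomycin", "post_rotenone_antimycin")
  miss <- setdiff(need, unique(trace$phase))
  if (length(miss)) abort(sprintf("Missing phase(s): %s.",
                                  paste(miss, collapse = ", ")))
  if (any(trace$ocr < 0)) abort("OCR values must be non-negative.")
  post <- if (post_summary == "min") min else mean
  initial <- mean(trace$ocr[trace$phase == "basal"])
  min_oligo <- post(trace$ocr[trace$phase == "post_oligomycin"])
  min_rotaa <- post(trace$ocr[trace$phase == "post_rotenone_antimycin"])
  nmoc <- min_rotaa
  basal <- initial - min_rotaa
  leak <- min_oligo - min_rotaa
  atp <- if (atp_mode == "standard") initial - min_oligo else basal
  if (basal + nmoc == 0) abort("Coupling efficiency undefined: basal + NMOC = 0.")
  coupling <- ((basal + nmoc) - (leak + nmoc)) / (basal + nmoc)
  tibble(nmoc = nmoc, basal_respiration = basal, atp_linked = atp,
         proton_leak = leak, coupling_efficiency = coupling,
         leak_fraction_of_basal = if (basal != 0) leak / basal else NA_real_)
}

#' Excess lactate beyond the glycolytic ceiling
#'
#' Glycolysis yields at most two lactate molecules per glucose molecule
#' consumed. Lactate output above that stoichiometric ceiling must come from
#' other carbon sources; the excess fraction is `max(0, 1 - 2 / ratio)`
#' where `ratio = lactate / glucose`.
#'
#' @param glucose_consumed Positive glucose consumption (mol per time per
#'   protein, or any consistent basis).
#' @param lactate_produced Non-negative lactate production on the same basis.
#' @return One-row tibble: `glucose_consumed`, `lactate_produced`,
#'   `lactate_glucose_ratio`, `excess_lactate_fraction`.
#' @examples
#' excess_lactate_fraction(1, 3.5)$excess_lactate_fraction  # ~0.4286
#' @export
excess_lactate_fraction <- function(glucose_consumed, lactate_produced) {
  if (any(glucose_consumed <= 0)) abort("`glucose_consumed` must be > 0.")
  if (any(lactate_produced < 0)) abort("`lactate_produced` must be >= 0.")
  ratio <- lactate_produced / glucose_consumed
  tibble(glucose_consumed = glucose_consumed,
         lactate_produced = lactate_produced,
         lactate_glucose_ratio = ratio,
         excess_lactate_fraction = pmax(0, 1 - 2 / ratio))
}

#' Relative expression by delta-delta-Cq, as percent of control
#'
#' Normalizes each sample's target Cq to the mean of two reference genes
#' (`dCq = Cq_target - mean(Cq_ref1, Cq_ref2)`), then to the control-group
#' mean (`ddCq = dCq - mean(dCq | control)`), and reports
#' `100 * 2^(-ddCq)`. The control group's geometric center is 100% by
#' construction.
#'
#' @param cq Data frame with columns `sample_id`, `group`, `cq_target`,
#'   `cq_ref1`, `cq_ref2`.
#' @param control Control group label (default `"control"`).
#' @return Tibble per sample with `dcq`, `ddcq`, `percent_of_control`.
#' @export
ddcq_percent_of_control <- function(cq, control = "control") {
  cq <- as_tibble(cq)
  need <- c("sample_id", "group", "cq_target", "cq_ref1", "cq_ref2")
  if (!all(need %in% names(cq))) {
    abort(sprintf("Cq table needs columns: %s.", paste(need, collapse = ", ")))
  }
  vals <- unlist(cq[, c("cq_target", "cq_ref1", "cq_ref2")])
  if (any(!is.finite(vals))) abort("Cq values must be finite.")
  if (!any(cq$group == control)) {
    abort(sprintf("No samples in control group '%s'.", control))
  }
  out <- cq %>%
    mutate(dcq = .data$cq_target - (.data$cq_ref1 + .data$cq_ref2) / 2)
  ctl_mean <- mean(out$dcq[out$group == control])
  out %>%
    mutate(ddcq = .data$dcq - ctl_mean,
           percent_of_control = 100 * 2^(-.data$ddcq))
}

#' Fraction of cellular LDH released into the medium
#'
#' `medium / (medium + lysate)`: the measured medium activity relative to
#' the total cellular LDH content, a cytotoxicity readout in `[0, 1]`.
#'
#' @param medium_activity,lysate_activity Non-negative activities;
#'   vectorized, `medium + lysate` must be positive.
#' @return Numeric vector of release fractions.
#' @export
ldh_release_fraction <- function(medium_activity, lysate_activity) {
  if (any(medium_activity < 0) || any(lysate_activity < 0)) {
    abort("Activities must be non-negative.")
  }
  total <- medium_activity + lysate_activity
  if (any(total == 0)) abort("Total LDH activity must be positive.")
  medium_activity / total
}

#' Normalize a signal to protein content
#'
#' @param signal Measured signal (vectorized).
#' @param protein_amount Positive protein amount per sample.
#' @return `signal / protein_amount`.
#' @export
per_protein_normalize <- function(signal, protein_amount) {
  if (any(protein_amount <= 0)) abort("`protein_amount` must be > 0.")
  signal / protein_amount
}

#' Robust outlier screening
#'
#' `method = "modified_z"` applies the Iglewicz–Hoaglin modified Z-score
#' `M_i = 0.6745 (x_i - median) / MAD` and flags `|M_i| >= cutoff`
#' (default 3.5); when the MAD is zero no value is flagged and a warning is
#' issued. `method = "grubbs"` applies the iterative two-sided Grubbs test
#' at `P < alpha` using the t-based critical value, removing the most
#' extreme value and retesting until no value exceeds the criterion.
#'
#' @param values Numeric vector, length >= 3.
#' @param method `"modified_z"` (default) or `"grubbs"`.
#' @param cutoff Modified Z-score cutoff (default 3.5).
#' @param alpha Grubbs significance level (default 0.05).
#' @return Tibble with `value`, `score`, `flagged`, `method`.
#' @export
detect_outliers <- function(values, method = c("modified_z", "grubbs"),
                            cutoff = 3.5, alpha = 0.05) {
  method <- match.arg(method)
  if (length(values) < 3) abort("Outlier screening needs n >= 3.")
  if (any(!is.finite(values))) abort("Values must be finite.")
  if (method == "modified_z") {
    mad0 <- median(abs(values - median(values)))
    if (mad0 == 0) {
      warn("MAD is zero; no outliers flagged.")
      score <- rep(NA_real_, length(values))
      flag <- rep(FALSE, length(values))
    } else {
      score <- 0.6745 * (values - median(values)) / mad0
      flag <- abs(score) >= cutoff
    }
  } else {
    flag <- rep(FALSE, length(values))
    score <- rep(NA_real_, length(values))
    active <- seq_along(values)
    repeat {
      n <- length(active)
      if (n < 3) break
      x <- values[active]
      s <- sd(x)
      if (s == 0) break
      g <- abs(x - mean(x)) / s
      imax <- which.max(g)
      tcrit <- qt(alpha / (2 * n), df = n - 2, lower.tail = FALSE)
      gcrit <- (n - 1) / sqrt(n) * sqrt(tcrit^2 / (n - 2 + tcrit^2))
      score[active[imax]] <- g[imax]
      if (g[imax] > gcrit) {
        flag[active[imax]] <- TRUE
        active <- active[-imax]
      } else break
    }
    if (length(active) >= 3 && sd(values[active]) > 0) {
      x <- values[active]
      score[active] <- abs(x - mean(x)) / sd(x)
    }
  }
  tibble(value = values, score = score, flagged = flag, method = method)
}
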