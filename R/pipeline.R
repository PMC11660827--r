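#' Pipeline configuration
#'
#' Collects every threshold of the rescue analysis in one serializable
#' object: the abundance gate (`fpm_min`, default 3 FPM), the fold-change
#' gate (`lfc_min`, default 1), the consensus FDR level (`fdr_alpha`,
#' default 0.05), the CI level (`ci_level`, default 0.95), the enrichment
#' threshold (`go_alpha`, default 1e-6) and adjustment method, the
#' fold-change pseudocount, and the QC multiplier.
#'
#' @param fpm_min,lfc_min,fdr_alpha,ci_level,go_alpha,go_adjust,pseudocount
#'   Analysis thresholds; see Description.
#' @param ci_scale CI scale, `"log2p1"` or `"linear"`.
#' @param qc_multiplier Flagging multiplier for [pca_sample_qc()].
#' @param qc_drop Drop QC-flagged samples before analysis (default `TRUE`).
#' @param biotype_missing Policy for unannotated genes in
#'   [filter_protein_coding()].
#' @param seed Seed recorded for provenance.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(fpm_min = 3, lfc_min = 1, fdr_alpha = 0.05,
                            ci_level = 0.95, ci_scale = "log2p1",
                            go_alpha = 1e-6, go_adjust = "bonferroni",
                            pseudocount = 1, qc_multiplier = 3,
                            qc_drop = TRUE, biotype_missing = "drop",
                            seed = 1) {
  stop_if_not_number(fpm_min, "fpm_min", min = 0)
  stop_if_not_number(lfc_min, "lfc_min", min = 0)
  stop_if_not_number(fdr_alpha, "fdr_alpha", min = 0, strict_min = TRUE)
  if (fdr_alpha > 1) abort("`fdr_alpha` must be in (0, 1].")
  stop_if_not_number(ci_level, "ci_level", min = 0, strict_min = TRUE)
  if (ci_level >= 1) abort("`ci_level` must be in (0, 1).")
  stop_if_not_number(go_alpha, "go_alpha", min = 0)
  stop_if_not_number(pseudocount, "pseudocount", min = 0, strict_min = TRUE)
  stop_if_not_number(qc_multiplier, "qc_multiplier", min = 0,
                     strict_min = TRUE)
  structure(list(fpm_min = fpm_min, lfc_min = lfc_min,
                 fdr_alpha = fdr_alpha, ci_level = ci_level,
                 ci_scale = match.arg(ci_scale, c("log2p1", "linear")),
                 go_alpha = go_alpha,
                 go_adjust = match.arg(go_adjust, c("bonferroni", "BH")),
                 pseudocount = pseudocount, qc_multiplier = qc_multiplier,
                 qc_drop = isTRUE(qc_drop),
                 biotype_missing = match.arg(biotype_missing,
                                             c("drop", "keep", "error")),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Save / load a pipeline configuration
#'
#' JSON round-trip: `load_config(save_config(cfg, path))` reproduces `cfg`.
#'
#' @param config A [pipeline_config()].
#' @param path JSON path.
#' @return `save_config` returns `path` invisibly; `load_config` returns a
#'   `pipeline_config`.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, vals)
}

#' Run the full rescue analysis
#'
#' Executes the analysis stages in fixed order: restrict to detected genes
#' (any nonzero count), restrict to protein-coding genes (when an annotation
#' is supplied), normalize to FPM, PCA sample QC (flagged samples dropped
#' when `config$qc_drop`), dual-caller DE consensus for control-vs-disease
#' and control-vs-disease+drug, rescue classification by both strategies,
#' per-direction summary, and (when an ontology and term annotation are
#' supplied) GO over-representation of the sensitive genes with
#' common-child-term identification.
#'
#' @param study A [count_study()] with groups `control`, `disease`,
#'   `disease_drug`.
#' @param annotation Optional gene biotype annotation (see
#'   [filter_protein_coding()]).
#' @param config A [pipeline_config()].
#' @param dag Optional [go_dag()] for enrichment.
#' @param go_annotation Optional direct term-to-gene annotation tibble
#'   (`term_id`, `gene_id`); propagated with [annotate_with_ancestors()].
#' @param go_background `"expressed"` (analyzed genes, default) or
#'   `"annotation"` (all annotated genes).
#' @return A `run_report`: list with `config`, `counts` (stage bookkeeping),
#'   `qc`, `de_cd`, `de_ce`, `calls`, `summary`, and optionally
#'   `enrichment` (list per query: `all`, `up`, `down`) and `common_children`.
#' @export
run_pipeline <- function(study, annotation = NULL,
                         config = pipeline_config(), dag = NULL,
                         go_annotation = NULL,
                         go_background = c("expressed", "annotation")) {
  stopifnot(inherits(study, "count_study"),
            inherits(config, "pipeline_config"))
  go_background <- match.arg(go_background)
  need <- c("control", "disease", "disease_drug")
  miss <- setdiff(need, unique(study$design$group))
  if (length(miss)) {
    abort(sprintf("[stage design] design lacks group(s): %s.",
                  paste(miss, collapse = ", ")))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("[stage %s] %s", name, conditionMessage(e)))
    })
  }
  n_input <- nrow(study$counts)
  detected <- rowSums(study$counts) > 0
  study <- stage("detect", count_study(study$counts[detected, , drop = FALSE],
                                       study$design))
  n_detected <- nrow(study$counts)
  if (!is.null(annotation)) {
    study <- stage("protein_coding",
                   filter_protein_coding(study, annotation,
                                         missing = config$biotype_missing))
  }
  n_coding <- nrow(study$counts)
  am <- stage("fpm", normalize_fpm(study))
  qc <- stage("qc", pca_sample_qc(am, c_mult = config$qc_multiplier))
  if (config$qc_drop && any(qc$flagged)) {
    study <- stage("qc", drop_flagged_samples(study, qc))
    am <- stage("fpm", normalize_fpm(study))
  }
  de_cd <- stage("de_consensus",
                 de_consensus(study, c("control", "disease"),
                              alpha = config$fdr_alpha,
                              pseudocount = config$pseudocount))
  de_ce <- stage("de_consensus",
                 de_consensus(study, c("control", "disease_drug"),
                              alpha = config$fdr_alpha,
                              pseudocount = config$pseudocount))
  calls <- stage("rescue",
                 classify_rescue(am, de_cd, de_ce,
                                 fpm_min = config$fpm_min,
                                 lfc_min = config$lfc_min,
                                 ci_level = config$ci_level,
                                 scale = config$ci_scale,
                                 pseudocount = config$pseudocount))
  summ <- stage("summary", summarize_strategies(calls))
  report <- list(
    config = config,
    counts = list(n_input = n_input, n_detected = n_detected,
                  n_protein_coding = n_coding,
                  n_samples_used = ncol(study$counts),
                  n_regulated = summ$overall$n_regulated,
                  n_up = summ$overall$n_up, n_down = summ$overall$n_down,
                  n_sensitive_a = summ$overall$n_sensitive_a,
                  n_sensitive_b = summ$overall$n_sensitive_b),
    qc = qc, de_cd = de_cd, de_ce = de_ce, calls = calls, summary = summ,
    package_version = as.character(utils::packageVersion("generescue"))
  )
  if (!is.null(dag) && !is.null(go_annotation)) {
    ann <- stage("enrichment", annotate_with_ancestors(dag, go_annotation))
    bg <- if (go_background == "expressed") {
      intersect(calls$gene_id, unique(go_annotation$gene_id))
    } else unique(go_annotation$gene_id)
    sens <- calls$gene_id[calls$strategy_a %in% TRUE]
    queries <- list(all = sens,
                    up = calls$gene_id[calls$strategy_a %in% TRUE &
                                         calls$direction == "up"],
                    down = calls$gene_id[calls$strategy_a %in% TRUE &
                                           calls$direction == "down"])
    report$enrichment <- lapply(queries, function(q) {
      q <- intersect(q, bg)
      if (!length(q)) return(NULL)
      stage("enrichment",
            hypergeom_enrich(q, bg, ann, adjust = config$go_adjust))
    })
    sig_all <- unique(unlist(lapply(report$enrichment, function(r) {
      if (is.null(r)) character() else significant_terms(r, config$go_alpha)
    })))
    report$common_children <- stage("enrichment",
                                    common_child_terms(dag, sig_all))
  }
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  utils::str(x$counts, no.list = TRUE)
  invisible(x)
}

#' Write a run report to disk
#'
#' Writes the analysis tables (rescue calls, both DE results, the
#' Fig-2B-style per-direction summary, enrichment tables when present) as
#' TSV with stable column order, a JSON summary, and a human-readable log.
#'
#' @param report A `run_report` from [run_pipeline()].
#' @param outdir Output directory (created if needed).
#' @return Character vector of file paths written, invisibly.
#' @export
write_report <- function(report, outdir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  put_tsv <- function(tab, name) {
    p <- file.path(outdir, name)
    readr::write_tsv(as_tibble(tab), p, progress = FALSE)
    written <<- c(written, p)
  }
  calls_out <- report$calls
  for (r in c("r1", "r2", "r3", "r4", "r5")) {
    calls_out[[r]] <- as.integer(calls_out[[r]])
  }
  put_tsv(calls_out, "rescue_calls.tsv")
  put_tsv(report$de_cd, "de_control_vs_disease.tsv")
  put_tsv(report$de_ce, "de_control_vs_disease_drug.tsv")
  put_tsv(report$summary$cells, "strategy_summary_cells.tsv")
  put_tsv(report$qc, "sample_qc.tsv")
  if (!is.null(report$enrichment)) {
    for (nm in names(report$enrichment)) {
      if (!is.null(report$enrichment[[nm]])) {
        put_tsv(report$enrichment[[nm]], sprintf("enrichment_%s.tsv", nm))
      }
    }
  }
  jp <- file.path(outdir, "report.json")
  jsonlite::write_json(
    list(counts = report$counts, overall = report$summary$overall,
         config = unclass(report$config),
         package_version = report$package_version),
    jp, auto_unbox = TRUE, digits = NA)
  written <- c(written, jp)
  lp <- file.path(outdir, "run.log")
  writeLines(c(sprintf("generescue %s run at %s", report$package_version,
                       format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
               sprintf("genes input/detected/coding: %d/%d/%d",
                       report$counts$n_input, report$counts$n_detected,
                       report$counts$n_protein_coding),
               sprintf("regulated: %d (up %d / down %d)",
                       report$counts$n_regulated, report$counts$n_up,
                       report$counts$n_down)), lp)
  invisible(c(written, lp))
}
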