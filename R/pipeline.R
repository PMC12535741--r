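#' Default pipeline configuration
#'
#' One flat configuration covering paths, thresholds and modes; any key can
#' be overridden by [run_pipeline()]'s caller or a CLI flag. All randomness
#' derives from the single `seed` through fixed per-stage substreams, so
#' stages are independently reproducible.
#'
#' @param ... Overrides of the defaults.
#' @return Named list classed `"RunConfig"`.
#' @export
run_config <- function(...) {
  cfg <- list(
    expr = NULL, cnv = NULL, clinical = NULL, gtf = NULL, gmt = NULL,
    outdir = NULL,
    alpha_cox = 0.05, alpha_kw = 0.05, alpha_multi = 0.05, r_min = 0.5,
    min_samples = 20, min_group_size = 3,
    low_expr_min_count = 5, low_expr_min_fraction = 0.10,
    collapse_aberrant = FALSE, no_multivariate = FALSE, fdr = FALSE,
    n_permutations = 1000, n_boot = 1000, seed = 1
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "),
                            call. = FALSE)
  cfg[names(over)] <- over
  for (k in c("alpha_cox", "alpha_kw", "alpha_multi", "r_min")) {
    if (cfg[[k]] <= 0 || cfg[[k]] >= 1) stop(k, " must lie in (0, 1)", call. = FALSE)
  }
  if (cfg$seed < 1 || cfg$n_permutations < 1 || cfg$n_boot < 1) {
    stop("seed and replicate counts must be positive", call. = FALSE)
  }
  structure(cfg, class = c("RunConfig", "list"))
}

# Fixed per-stage seed substreams (kept well below 2^31).
.stage_seed <- function(seed, stage) {
  offset <- c(simulate = 0L, correlate = 101L, bootstrap = 202L)[[stage]]
  as.integer((as.numeric(seed) + offset) %% .Machine$integer.max)
}

#' Persist a matched cohort as plain-text tables
#'
#' Writes the normalized lncRNA/PCG expression, lncRNA CNV, clinical table
#' and VST model of a cohort so later stages can run standalone. Doubles are
#' serialized losslessly, so a save/load round trip reproduces the cohort
#' exactly.
#'
#' @param cohort A `"MatchedCohort"`.
#' @param dir Output directory.
#' @return Named vector of file paths, invisibly.
#' @export
save_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(expr_lnc = file.path(dir, "expr_lnc.tsv"),
             expr_pcg = file.path(dir, "expr_pcg.tsv"),
             cnv_lnc = file.path(dir, "cnv_lnc.tsv"),
             clinical = file.path(dir, "clinical.tsv"),
             annotation = file.path(dir, "annotation.tsv"),
             vst = file.path(dir, "vst.json"))
  .write_matrix_tsv(unclass(cohort$expr_lnc), paths[["expr_lnc"]], "lncRNA_id")
  .write_matrix_tsv(unclass(cohort$expr_pcg), paths[["expr_pcg"]], "pcg_id")
  .write_matrix_tsv(unclass(cohort$cnv_lnc), paths[["cnv_lnc"]], "lncRNA_id")
  .write_tsv(cohort$clinical, paths[["clinical"]])
  .write_tsv(as.data.frame(cohort$annotation), paths[["annotation"]])
  jsonlite::write_json(list(size_factors = as.list(cohort$vst$size_factors),
                            a0 = cohort$vst$a0, a1 = cohort$vst$a1,
                            attrition = cohort$attrition),
                       paths[["vst"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

.read_saved_matrix <- function(path, kind) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          colClasses = list(character = 1), showProgress = FALSE)
  m <- as.matrix(dt[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- dt[[1L]]
  omics_matrix(m, kind)
}

#' Load a cohort saved by [save_cohort()]
#'
#' @param dir Directory written by [save_cohort()].
#' @return A `"MatchedCohort"`.
#' @export
load_cohort <- function(dir) {
  expr_lnc <- .read_saved_matrix(file.path(dir, "expr_lnc.tsv"), "normalized")
  expr_pcg <- .read_saved_matrix(file.path(dir, "expr_pcg.tsv"), "normalized")
  cnv_lnc <- .read_saved_matrix(file.path(dir, "cnv_lnc.tsv"), "absolute_cn")
  clin <- data.table::fread(file.path(dir, "clinical.tsv"), sep = "\t",
                            header = TRUE, data.table = FALSE, showProgress = FALSE)
  clin$sample_id <- as.character(clin$sample_id)
  class(clin) <- c("ClinicalTable", "data.frame")
  ann <- data.table::fread(file.path(dir, "annotation.tsv"), sep = "\t",
                           header = TRUE, data.table = FALSE, showProgress = FALSE)
  class(ann) <- c("GeneAnnotation", "data.frame")
  vst <- jsonlite::read_json(file.path(dir, "vst.json"), simplifyVector = TRUE)
  model <- structure(list(size_factors = unlist(vst$size_factors),
                          a0 = vst$a0, a1 = vst$a1), class = "VSTModel")
  cohort <- structure(list(samples = colnames(expr_lnc),
                           expr_lnc = expr_lnc, expr_pcg = expr_pcg,
                           cnv_lnc = cnv_lnc, clinical = clin, vst = model,
                           annotation = ann, attrition = as.list(vst$attrition)),
                      class = "MatchedCohort")
  validate_cohort(cohort)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage %s: %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full integration pipeline
#'
#' Executes read -> preprocess -> correlate (with permutation null) ->
#' Cox/Kruskal-Wallis screen -> risk model -> enrichment -> write, logging
#' attrition at each stage. Any stage error is re-raised with the stage
#' named. With `config$outdir` set, all result tables plus a JSON run
#' summary are written and the manifest returned; two runs with the same
#' config and seed produce byte-identical outputs.
#'
#' @param config A [run_config()] with at least `expr`, `cnv`, `clinical`
#'   and `gtf` paths set (enrichment runs only when `gmt` is set). Instead
#'   of paths, `expr`/`cnv` may be `OmicsMatrix` objects, `clinical` a
#'   `ClinicalTable` and `gtf` a `GeneAnnotation` table, which makes the
#'   simulated cohorts directly runnable.
#' @return List classed `"PipelineResult"`: `cohort`, `correlation`,
#'   `null`, `correlation_summary`, `screen`, `violin`, `refinement`,
#'   `risk_model`, `km`, `logrank`, `evaluation`, `enrichment` (NULL when
#'   skipped), `manifest` (NULL when `outdir` unset), `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  cfg <- config

  expr <- .stage("read", if (inherits(cfg$expr, "OmicsMatrix")) cfg$expr
                 else read_expression(cfg$expr))
  cnv <- .stage("read", if (inherits(cfg$cnv, "OmicsMatrix")) cfg$cnv
                else read_cnv(cfg$cnv))
  clin <- .stage("read", if (inherits(cfg$clinical, "data.frame")) cfg$clinical
                 else read_clinical(cfg$clinical))
  ann <- .stage("read", if (inherits(cfg$gtf, "data.frame")) cfg$gtf
                else read_gtf(cfg$gtf))

  cohort <- .stage("preprocess", build_cohort(
    expr, cnv, clin, ann,
    min_samples = cfg$min_samples,
    low_expr_min_count = cfg$low_expr_min_count,
    low_expr_min_fraction = cfg$low_expr_min_fraction))
  message(sprintf("preprocess: %d samples, %d lncRNAs, %d PCGs",
                  length(cohort$samples), nrow(cohort$expr_lnc), nrow(cohort$expr_pcg)))

  correlation <- .stage("correlate", correlate_all(cohort))
  null <- .stage("correlate", permutation_null(
    cohort, n_permutations = cfg$n_permutations,
    seed = .stage_seed(cfg$seed, "correlate")))
  csum <- .stage("correlate", correlation_summary(correlation, null))

  uni <- .stage("screen", univariate_screen(cohort, alpha_cox = cfg$alpha_cox))
  scr <- .stage("screen", cnv_group_screen(
    cohort, uni, alpha_kw = cfg$alpha_kw,
    collapse_aberrant = cfg$collapse_aberrant,
    min_group_size = cfg$min_group_size, correlations = correlation))
  records <- scr$records
  if (cfg$fdr) {
    records$cox_fdr <- stats::p.adjust(records$cox_p, method = "BH")
    records$kw_fdr <- stats::p.adjust(records$kw_p, method = "BH")
  }
  survivors <- records$lncRNA_id[records$passed_cox & records$passed_kw]
  message(sprintf("screen: %d tested, %d passed Cox, %d passed Cox+KW",
                  nrow(records), sum(records$passed_cox), length(survivors)))

  refinement <- .stage("model", {
    if (length(survivors) == 0L) {
      stop("no lncRNA passed both screens; nothing to model", call. = FALSE)
    }
    if (cfg$no_multivariate) {
      list(pr_lncRNAs = survivors,
           beta = stats::setNames(records$cox_beta[match(survivors, records$lncRNA_id)],
                                  survivors),
           fit = NULL, pruned_collinear = character(0), eliminated = character(0))
    } else {
      multivariate_refine(cohort, survivors, alpha = cfg$alpha_multi)
    }
  })
  model <- .stage("model", score_samples(cohort, refinement$pr_lncRNAs,
                                         refinement$beta))
  km <- .stage("model", {
    do.call(rbind, lapply(levels(model$group), function(g) {
      sel <- model$group == g
      cbind(group = g, kaplan_meier(cohort$clinical$survival_time[sel],
                                    cohort$clinical$status[sel]))
    }))
  })
  logrank <- .stage("model", logrank_test(cohort$clinical$survival_time,
                                          cohort$clinical$status, model$group))
  evaluation <- .stage("model", evaluate_auc(
    model$risk_scores, cohort$clinical$status,
    n_boot = cfg$n_boot, seed = .stage_seed(cfg$seed, "bootstrap")))
  message(sprintf("model: %d signature lncRNAs, AUC %.3f, log-rank p %.3g",
                  length(model$pr_lncRNAs), evaluation$auc, logrank$p))

  targets <- NULL; enrichment <- NULL
  if (!is.null(cfg$gmt) && length(cfg$gmt) > 0) {
    targets <- .stage("enrichment", correlate_targets(cohort, model$pr_lncRNAs,
                                                      r_min = cfg$r_min))
    collections <- .stage("enrichment", {
      paths <- cfg$gmt
      if (is.list(paths) && inherits(paths[[1L]], "GeneSetCollection")) paths
      else {
        cl <- lapply(paths, read_gmt)
        names(cl) <- if (!is.null(names(paths)) && all(nzchar(names(paths)))) names(paths)
                     else sub("\\.gmt$", "", basename(unlist(paths)))
        cl
      }
    })
    enrichment <- .stage("enrichment", enrich(targets, collections))
    message(sprintf("enrichment: %d selected PCGs, %d terms tested",
                    length(targets$selected), nrow(enrichment)))
  }

  eval_json <- list(
    auc = evaluation$auc, ci_low = evaluation$ci_low, ci_high = evaluation$ci_high,
    n_boot = evaluation$n_boot, auc_seed = evaluation$seed,
    logrank_chi2 = logrank$chi2, logrank_p = logrank$p,
    threshold = model$threshold,
    pr_lncRNAs = as.list(stats::setNames(as.numeric(refinement$beta),
                                         refinement$pr_lncRNAs))
  )
  manifest <- NULL
  if (!is.null(cfg$outdir)) {
    results <- list(
      screen = records,
      correlation = correlation,
      null_summary = data.frame(
        n_permutations = null$n_permutations, n_features = null$n_features,
        null_mean_r = mean(null$r_values), null_sd_r = stats::sd(null$r_values),
        ks_statistic = csum$ks_statistic, frac_significant = csum$frac_significant),
      histogram = csum$histogram,
      violin = scr$violin,
      risk = data.frame(sample_id = cohort$samples,
                        score = as.numeric(model$risk_scores),
                        group = as.character(model$group),
                        time = cohort$clinical$survival_time,
                        status = cohort$clinical$status,
                        stringsAsFactors = FALSE),
      km = km,
      targets = if (!is.null(targets)) targets$pcgs else NULL,
      enrichment = enrichment,
      evaluation = eval_json,
      counts = c(cohort$attrition,
                 list(lncRNAs_tested = nrow(records),
                      passed_cox = sum(records$passed_cox),
                      passed_cox_kw = length(survivors),
                      pr_lncRNAs = length(model$pr_lncRNAs)))
    )
    manifest <- .stage("write", write_results(
      cfg$outdir, results,
      config = cfg[names(cfg) != "outdir" & !vapply(cfg, is.object, TRUE) &
                     !vapply(cfg, function(x) inherits(x, c("OmicsMatrix", "data.frame")), TRUE)],
      seed = cfg$seed))
  }
  structure(list(cohort = cohort, correlation = correlation, null = null,
                 correlation_summary = csum, screen = records,
                 violin = scr$violin, refinement = refinement,
                 risk_model = model, km = km, logrank = logrank,
                 evaluation = evaluation, targets = targets,
                 enrichment = enrichment, manifest = manifest, config = cfg),
            class = "PipelineResult")
}
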