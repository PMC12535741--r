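#' Restrict expression, CNV and clinical data to their common samples
#'
#' The three data types are typically assembled from different portals and
#' rarely share an identical sample set; all downstream analysis operates on
#' the sorted intersection of sample identifiers, in the same order in every
#' component.
#'
#' @param expr Raw-count [omics_matrix()].
#' @param cnv Absolute copy-number [omics_matrix()].
#' @param clin [read_clinical()] table.
#' @param min_samples Minimum acceptable intersection size (default 20; Cox
#'   and rank tests are not meaningful below this).
#' @return List with elements `expr`, `cnv`, `clinical`, restricted and
#'   ordered identically, plus `dropped` counts per source.
#' @export
harmonize_samples <- function(expr, cnv, clin, min_samples = 20) {
  common <- sort(intersect(intersect(colnames(expr), colnames(cnv)), clin$sample_id))
  if (length(common) < min_samples) {
    stop(sprintf(paste0("common-sample intersection too small: expr=%d, cnv=%d, ",
                        "clinical=%d, common=%d (min_samples=%d)"),
                 ncol(expr), ncol(cnv), nrow(clin), length(common), min_samples),
         call. = FALSE)
  }
  dropped <- c(expr = ncol(expr) - length(common),
               cnv = ncol(cnv) - length(common),
               clinical = nrow(clin) - length(common))
  if (any(dropped > 0)) {
    message(sprintf("harmonize_samples: %d common samples (dropped expr=%d, cnv=%d, clinical=%d)",
                    length(common), dropped[["expr"]], dropped[["cnv"]], dropped[["clinical"]]))
  }
  clin2 <- clin[match(common, clin$sample_id), , drop = FALSE]
  rownames(clin2) <- NULL
  list(expr = expr[, common, drop = FALSE],
       cnv = cnv[, common, drop = FALSE],
       clinical = clin2,
       dropped = as.list(dropped))
}

#' Median-of-ratios size factors
#'
#' Per-sample scaling constants: for each sample, the median over genes of
#' the ratio between its count and the gene's geometric mean across samples,
#' restricted to genes with strictly positive counts in every sample. If no
#' such gene exists, a pseudocount of 1 is added for factor estimation only
#' (with a warning). Factors are rescaled to geometric mean 1, removing the
#' overall scale indeterminacy.
#'
#' @param counts Raw-count [omics_matrix()] or numeric matrix.
#' @return Named numeric vector of positive per-sample size factors.
#' @export
estimate_size_factors <- function(counts) {
  m <- unclass(counts)
  if (ncol(m) == 1L) return(stats::setNames(1, colnames(m)))
  complete <- rowSums(is.na(m)) == 0L
  allpos <- complete & apply(m, 1L, function(r) all(r > 0))
  if (!any(allpos)) {
    warning("no gene with positive counts in every sample; using pseudocount 1 for size-factor estimation",
            call. = FALSE)
    m <- m + 1
    allpos <- complete
  }
  logm <- log(m[allpos, , drop = FALSE])
  loggeo <- rowMeans(logm)
  logsf <- apply(logm - loggeo, 2L, stats::median)
  logsf <- logsf - mean(logsf)  # geometric mean 1
  stats::setNames(exp(logsf), colnames(m))
}

#' Fit a negative-binomial dispersion trend for the VST
#'
#' Estimates per-gene method-of-moments dispersions on size-factor-scaled
#' counts and fits the trend `alpha(mu) = a1/mu + a0` by iteratively
#' reweighted least squares (10 iterations, weights `1/fit^2`), using genes
#' with mean at least 1 and a positive dispersion estimate.
#'
#' @param counts Raw-count [omics_matrix()] or numeric matrix.
#' @param size_factors Output of [estimate_size_factors()] (computed if
#'   omitted).
#' @return List classed `"VSTModel"` with `size_factors`, `a0` (asymptotic
#'   dispersion, floored at 1e-8), `a1` (Poisson-like extra term) and the
#'   per-gene estimates used in the fit.
#' @export
fit_vst <- function(counts, size_factors = NULL) {
  m <- unclass(counts)
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  if (!all(size_factors > 0)) stop("size factors must be positive", call. = FALSE)
  sc <- sweep(m, 2L, size_factors, `/`)
  mu <- rowMeans(sc, na.rm = TRUE)
  if (sum(mu > 0, na.rm = TRUE) < 50L) {
    stop("fewer than 50 genes with positive mean; too little information to fit a dispersion trend (consider a log2(x/sf + 1) transform instead)",
         call. = FALSE)
  }
  v <- apply(sc, 1L, stats::var, na.rm = TRUE)
  xi <- mean(1 / size_factors)
  disp <- (v - xi * mu) / mu^2
  use <- is.finite(disp) & disp > 0 & mu >= 1
  if (sum(use) < 10L) {
    stop("fewer than 10 genes with usable dispersion estimates", call. = FALSE)
  }
  d <- disp[use]; mus <- mu[use]
  X <- cbind(1, 1 / mus)
  coef <- c(stats::median(d), 0)  # start from a flat trend
  for (i in seq_len(10L)) {
    fit <- pmax(X %*% coef, 1e-8)
    w <- as.vector(1 / fit^2)
    coef <- stats::lsfit(X, d, wt = w, intercept = FALSE)$coefficients
    coef <- pmax(coef, 0)
  }
  a0 <- coef[[1L]]; a1 <- coef[[2L]]
  if (a0 <= 0) {
    warning("fitted asymptotic dispersion non-positive; clamped to 1e-8", call. = FALSE)
    a0 <- 1e-8
  }
  structure(list(size_factors = size_factors, a0 = a0, a1 = a1,
                 gene_mean = mus, gene_dispersion = d),
            class = "VSTModel")
}

#' Apply the variance-stabilizing transformation
#'
#' Maps size-factor-scaled counts `q = count/sf` through the closed-form
#' variance-stabilizing transform implied by the negative-binomial dispersion
#' trend `alpha(mu) = a1/mu + a0`:
#' `vst(q) = log2((1 + a1 + 2*a0*q + 2*sqrt(a0*q*(1 + a1 + a0*q))) / (4*a0))`.
#' The transform is monotone non-decreasing in the count and approaches
#' `log2(q)` for large `q`, so a doubling of expression adds ~1 unit.
#'
#' @param counts Raw-count [omics_matrix()] or numeric matrix.
#' @param model A `"VSTModel"` from [fit_vst()].
#' @return Transformed matrix; an `OmicsMatrix` with
#'   `value_kind = "normalized"` when the input carried dimnames.
#' @export
apply_vst <- function(counts, model) {
  stopifnot(inherits(model, "VSTModel"))
  m <- unclass(counts)
  if (is.matrix(m)) {
    sf <- model$size_factors[colnames(m)]
    if (anyNA(sf)) sf <- rep(model$size_factors, length.out = ncol(m))
    q <- sweep(m, 2L, sf, `/`)
  } else {
    q <- m / model$size_factors[1L]
  }
  a0 <- model$a0; a1 <- model$a1
  out <- log2((1 + a1 + 2 * a0 * q + 2 * sqrt(a0 * q * (1 + a1 + a0 * q))) / (4 * a0))
  if (is.matrix(out) && !is.null(rownames(out)) && !is.null(colnames(out))) {
    out <- omics_matrix(out, "normalized")
  }
  out
}

# Biotypes recognized as long non-coding; both the common and the plural
# spelling of processed_transcript are accepted.
.lnc_biotypes <- c("processed_transcript", "processed_transcripts",
                   "3prime_overlapping_ncRNA", "sense_intronic",
                   "sense_overlapping", "antisense", "lincRNA")

#' Classify a gene biotype into lncRNA / PCG / other
#'
#' lncRNA for the long non-coding biotypes (`processed_transcript`,
#' `3prime_overlapping_ncRNA`, `sense_intronic`, `sense_overlapping`,
#' `antisense`, `lincRNA`); PCG for `protein_coding`; otherwise `other`.
#'
#' @param biotype Character vector of GTF biotype labels.
#' @return Character vector over `{"lncRNA", "PCG", "other"}`.
#' @export
classify_biotype <- function(biotype) {
  out <- rep("other", length(biotype))
  out[biotype %in% .lnc_biotypes] <- "lncRNA"
  out[biotype == "protein_coding"] <- "PCG"
  out
}

#' Assemble a matched cohort
#'
#' Harmonizes samples, normalizes counts with the VST, splits expression into
#' lncRNA and protein-coding compartments by annotation class, and restricts
#' the CNV matrix to lncRNAs present in both expression and CNV inputs.
#' Genes failing the low-expression filter (scaled count >=
#' `low_expr_min_count` in at least `low_expr_min_fraction` of samples) are
#' removed before transformation.
#'
#' @param expr Raw-count [omics_matrix()].
#' @param cnv Absolute copy-number [omics_matrix()].
#' @param clin [read_clinical()] table.
#' @param annotation [read_gtf()] table (or equivalent data frame).
#' @param min_samples Minimum common-sample count (default 20).
#' @param low_expr_min_count,low_expr_min_fraction Expression filter: keep a
#'   gene if its size-factor-scaled count is at least `low_expr_min_count`
#'   in at least `low_expr_min_fraction` of samples (defaults 5 and 0.10).
#' @return List classed `"MatchedCohort"`: `samples`, `expr_lnc`, `expr_pcg`
#'   (normalized `OmicsMatrix`), `cnv_lnc` (absolute_cn), `clinical`, `vst`
#'   (the fitted `VSTModel`), `annotation`, and per-filter `attrition` counts.
#' @export
build_cohort <- function(expr, cnv, clin, annotation,
                         min_samples = 20,
                         low_expr_min_count = 5,
                         low_expr_min_fraction = 0.10) {
  h <- harmonize_samples(expr, cnv, clin, min_samples = min_samples)
  expr <- h$expr; cnv <- h$cnv; clin <- h$clinical

  sf <- estimate_size_factors(expr)
  sc <- sweep(unclass(expr), 2L, sf, `/`)
  keep <- rowMeans(sc >= low_expr_min_count, na.rm = TRUE) >= low_expr_min_fraction
  attrition <- list(genes_input = nrow(expr), genes_low_expression = sum(!keep))
  expr_f <- expr[keep, , drop = FALSE]
  if (nrow(expr_f) < 50L) {
    stop("fewer than 50 genes survive the expression filter; attrition: ",
         paste(names(attrition), unlist(attrition), sep = "=", collapse = ", "),
         call. = FALSE)
  }
  model <- fit_vst(expr_f, sf)
  norm <- apply_vst(expr_f, model)

  cls <- annotation$gene_class[match(rownames(norm), annotation$gene_id)]
  lnc_ids <- rownames(norm)[!is.na(cls) & cls == "lncRNA"]
  pcg_ids <- rownames(norm)[!is.na(cls) & cls == "PCG"]
  lnc_in_cnv <- intersect(lnc_ids, rownames(cnv))
  attrition$lncRNAs_annotated <- length(lnc_ids)
  attrition$lncRNAs_without_cnv <- length(lnc_ids) - length(lnc_in_cnv)
  attrition$pcgs_annotated <- length(pcg_ids)
  if (length(lnc_in_cnv) == 0L) {
    stop("no lncRNA present in both expression and CNV inputs; attrition: ",
         paste(names(attrition), unlist(attrition), sep = "=", collapse = ", "),
         call. = FALSE)
  }
  cohort <- structure(list(
    samples = colnames(norm),
    expr_lnc = norm[lnc_in_cnv, , drop = FALSE],
    expr_pcg = norm[pcg_ids, , drop = FALSE],
    cnv_lnc = cnv[lnc_in_cnv, , drop = FALSE],
    clinical = clin,
    vst = model,
    annotation = annotation,
    attrition = attrition
  ), class = "MatchedCohort")
  validate_cohort(cohort)
}

#' Validate MatchedCohort invariants
#'
#' Asserts the identical sample order of all four data components and the
#' lncRNA feature agreement between expression and CNV compartments.
#'
#' @param cohort A `"MatchedCohort"`.
#' @return `cohort` invisibly unchanged, or an error.
#' @export
validate_cohort <- function(cohort) {
  s <- cohort$samples
  if (!identical(colnames(cohort$expr_lnc), s) ||
      !identical(colnames(cohort$expr_pcg), s) ||
      !identical(colnames(cohort$cnv_lnc), s) ||
      !identical(cohort$clinical$sample_id, s)) {
    stop("cohort components disagree on sample order", call. = FALSE)
  }
  if (!identical(rownames(cohort$expr_lnc), rownames(cohort$cnv_lnc))) {
    stop("expr_lnc and cnv_lnc feature sets differ", call. = FALSE)
  }
  cohort
}

#' @export
print.MatchedCohort <- function(x, ...) {
  cat(sprintf("MatchedCohort: %d samples, %d lncRNAs (with CNV), %d PCGs, %d events\n",
              length(x$samples), nrow(x$expr_lnc), nrow(x$expr_pcg),
              sum(x$clinical$status == 1)))
  invisible(x)
}
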