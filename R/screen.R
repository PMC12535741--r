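#' Fit a Cox proportional-hazards model
#'
#' Maximizes the Cox partial likelihood with Efron handling of tied event
#' times and reports Wald statistics per covariate. A fit whose likelihood is
#' monotone (perfect separation) or that fails to converge is flagged
#' `converged = FALSE` and treated as non-significant downstream.
#'
#' @param time Positive survival/censoring times.
#' @param status Event indicator (1 = event, 0 = censored); at least one
#'   event required.
#' @param covariates Numeric vector or matrix (samples x covariates) of
#'   finite values; zero-variance columns are an error.
#' @return List classed `"CoxFit"`: `beta`, `se`, `wald_z`, `wald_p` (named
#'   per covariate), `loglik` (maximized partial log-likelihood),
#'   `loglik_null`, `n`, `n_events`, `converged`.
#' @export
cox_fit <- function(time, status, covariates) {
  x <- as.matrix(covariates)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (length(time) != nrow(x) || length(status) != nrow(x)) {
    stop("time, status and covariates disagree on sample count", call. = FALSE)
  }
  if (sum(status == 1) < 1) stop("no events: Cox model undefined", call. = FALSE)
  if (any(!is.finite(x))) stop("non-finite covariate values", call. = FALSE)
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance covariate(s): ", paste(colnames(x)[sds == 0], collapse = ", "),
         call. = FALSE)
  }
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, status) ~ x, ties = "efron",
                    control = survival::coxph.control(eps = 1e-9, iter.max = 50)),
    warning = function(w) {
      if (grepl("converge|infinite|beta may be infinite|out of iterations",
                conditionMessage(w), ignore.case = TRUE)) {
        converged <<- FALSE
      }
      invokeRestart("muffleWarning")
    }
  )
  s <- summary(fit)
  beta <- unname(stats::coef(fit))
  se <- unname(sqrt(diag(fit$var)))
  if (any(!is.finite(beta)) || any(!is.finite(se)) || any(abs(beta) > 50)) {
    converged <- FALSE
  }
  z <- beta / se
  structure(list(
    beta = stats::setNames(beta, colnames(x)),
    se = stats::setNames(se, colnames(x)),
    wald_z = stats::setNames(z, colnames(x)),
    wald_p = stats::setNames(2 * stats::pnorm(-abs(z)), colnames(x)),
    loglik = fit$loglik[2L],
    loglik_null = fit$loglik[1L],
    n = length(time),
    n_events = sum(status == 1),
    converged = converged
  ), class = "CoxFit")
}

#' Univariate Cox screen over cohort lncRNAs
#'
#' Fits one univariate proportional-hazards model per lncRNA on its
#' (optionally z-scored) normalized expression; a feature passes when the
#' Wald p-value is below `alpha_cox` and the fit converged.
#'
#' @param cohort A `"MatchedCohort"`.
#' @param alpha_cox Significance cut-off (default 0.05).
#' @param scale Z-score expression per lncRNA before fitting (default TRUE),
#'   so coefficients are per-SD and comparable across features.
#' @return Data frame: `lncRNA_id`, `cox_beta`, `cox_se`, `cox_z`, `cox_p`,
#'   `converged`, `passed_cox`.
#' @export
univariate_screen <- function(cohort, alpha_cox = 0.05, scale = TRUE) {
  time <- cohort$clinical$survival_time
  status <- cohort$clinical$status
  ids <- sort(rownames(cohort$expr_lnc))
  rows <- lapply(ids, function(id) {
    xv <- as.numeric(cohort$expr_lnc[id, ])
    if (stats::sd(xv) == 0) {
      return(data.frame(lncRNA_id = id, cox_beta = NA_real_, cox_se = NA_real_,
                        cox_z = NA_real_, cox_p = NA_real_, converged = FALSE,
                        passed_cox = FALSE, stringsAsFactors = FALSE))
    }
    if (scale) xv <- as.numeric(base::scale(xv))
    f <- cox_fit(time, status, matrix(xv, ncol = 1, dimnames = list(NULL, id)))
    data.frame(lncRNA_id = id, cox_beta = f$beta[[1L]], cox_se = f$se[[1L]],
               cox_z = f$wald_z[[1L]], cox_p = f$wald_p[[1L]],
               converged = f$converged,
               passed_cox = isTRUE(f$converged) && f$wald_p[[1L]] < alpha_cox,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Categorize absolute copy number into CNV groups
#'
#' Copy number below 2 is a deletion, exactly 2 diploid, above 2 an
#' amplification.
#'
#' @param copy_number Numeric vector of non-negative copy numbers.
#' @return Factor with levels `deletion`, `diploid`, `amplification`.
#' @export
categorize_cnv <- function(copy_number) {
  out <- ifelse(copy_number < 2, "deletion",
                ifelse(copy_number == 2, "diploid", "amplification"))
  factor(out, levels = c("deletion", "diploid", "amplification"))
}

#' Kruskal-Wallis rank test across groups
#'
#' Standard tie-corrected H statistic with a chi-square reference on
#' `groups_used - 1` degrees of freedom. Groups smaller than
#' `min_group_size` are dropped; with fewer than two eligible groups the
#' feature is untestable (`H`, `p` = NA). All-tied data yields `H = 0`,
#' `p = 1`.
#'
#' @param values Numeric vector.
#' @param groups Group labels (factor or character), same length.
#' @param min_group_size Minimum members per group (default 3).
#' @return List: `H`, `p`, `groups_used`, `group_sizes` (named, post-filter).
#' @export
kruskal_wallis <- function(values, groups, min_group_size = 3) {
  groups <- as.character(groups)
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- groups[ok]
  sizes <- table(groups)
  keep <- names(sizes)[sizes >= min_group_size]
  sel <- groups %in% keep
  values <- values[sel]; groups <- factor(groups[sel])
  sizes <- table(groups)
  if (nlevels(groups) < 2L) {
    return(list(H = NA_real_, p = NA_real_, groups_used = nlevels(groups),
                group_sizes = as.list(sizes)))
  }
  if (length(unique(values)) == 1L) {
    return(list(H = 0, p = 1, groups_used = nlevels(groups),
                group_sizes = as.list(sizes)))
  }
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), p = kt$p.value,
       groups_used = nlevels(groups), group_sizes = as.list(sizes))
}

#' Kruskal-Wallis screen of Cox survivors across CNV groups
#'
#' Second stage of the filtering cascade: for each lncRNA that passed the
#' univariate Cox screen, tests whether its normalized expression differs
#' across its copy-number groups (deletion / diploid / amplification, or
#' diploid vs aberrant when `collapse_aberrant = TRUE`). Also emits the
#' per-sample expression-by-group table behind violin-box plots.
#'
#' @param cohort A `"MatchedCohort"`.
#' @param cox_screen Output of [univariate_screen()].
#' @param alpha_kw Significance cut-off (default 0.05).
#' @param collapse_aberrant Merge deletion and amplification into one
#'   `aberrant` group (default FALSE).
#' @param min_group_size Minimum CNV-group size (default 3).
#' @param correlations Optional [correlate_all()] output merged into the
#'   records.
#' @return List with `records` (one row per tested lncRNA: correlation, Cox
#'   and KW statistics plus `passed_cox`, `passed_kw`) and `violin`
#'   (`lncRNA_id`, `sample_id`, `group`, `expression` for Cox survivors).
#' @export
cnv_group_screen <- function(cohort, cox_screen, alpha_kw = 0.05,
                             collapse_aberrant = FALSE, min_group_size = 3,
                             correlations = NULL) {
  records <- cox_screen
  records$kw_H <- NA_real_
  records$kw_p <- NA_real_
  records$kw_groups <- 0L
  records$n_deletion <- 0L
  records$n_diploid <- 0L
  records$n_amplification <- 0L
  records$passed_kw <- FALSE
  violin <- list()
  for (i in seq_len(nrow(records))) {
    if (!records$passed_cox[i]) next
    id <- records$lncRNA_id[i]
    expr <- as.numeric(cohort$expr_lnc[id, ])
    grp <- categorize_cnv(as.numeric(cohort$cnv_lnc[id, ]))
    sizes <- table(grp)
    records$n_deletion[i] <- sizes[["deletion"]]
    records$n_diploid[i] <- sizes[["diploid"]]
    records$n_amplification[i] <- sizes[["amplification"]]
    test_grp <- if (collapse_aberrant) {
      factor(ifelse(grp == "diploid", "diploid", "aberrant"),
             levels = c("diploid", "aberrant"))
    } else grp
    kw <- kruskal_wallis(expr, test_grp, min_group_size = min_group_size)
    records$kw_H[i] <- kw$H
    records$kw_p[i] <- kw$p
    records$kw_groups[i] <- kw$groups_used
    records$passed_kw[i] <- !is.na(kw$p) && kw$p < alpha_kw
    violin[[id]] <- data.frame(lncRNA_id = id, sample_id = cohort$samples,
                               group = as.character(grp), expression = expr,
                               stringsAsFactors = FALSE)
  }
  if (!is.null(correlations)) {
    m <- match(records$lncRNA_id, correlations$lncRNA_id)
    records$r <- correlations$r[m]
    records$r_p <- correlations$p[m]
  }
  violin <- if (length(violin)) do.call(rbind, violin) else
    data.frame(lncRNA_id = character(0), sample_id = character(0),
               group = character(0), expression = numeric(0))
  rownames(violin) <- NULL
  list(records = records, violin = violin)
}
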