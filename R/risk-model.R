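#' Multivariate Cox refinement of screen survivors
#'
#' Fits a joint proportional-hazards model on all screen survivors
#' (z-scored normalized expression) and backward-eliminates the covariate
#' with the largest Wald p-value, refitting each step, until every retained
#' covariate has p below `alpha`. Near-duplicate features (pairwise
#' |r| above `collinearity_cap`) are pruned before fitting; a
#' non-convergent joint fit falls back to a ridge-stabilized fit with a
#' warning.
#'
#' @param cohort A `"MatchedCohort"`.
#' @param features Character vector of screen-passing lncRNA ids (>= 1).
#' @param alpha Retention cut-off (default 0.05).
#' @param collinearity_cap Pairwise correlation cap (default 0.95); of a
#'   violating pair the later feature (by input order) is dropped.
#' @param ridge_penalty Ridge penalty used by the fallback fit (default 1e-4).
#' @return List: `pr_lncRNAs` (retained ids), `beta` (named final
#'   coefficients), `fit` (the final `"CoxFit"`), `pruned_collinear`,
#'   `eliminated` (ids in drop order).
#' @export
multivariate_refine <- function(cohort, features, alpha = 0.05,
                                collinearity_cap = 0.95, ridge_penalty = 1e-4) {
  if (length(features) < 1L) stop("no screen survivors to refine", call. = FALSE)
  features <- features[features %in% rownames(cohort$expr_lnc)]
  X <- base::scale(t(unclass(cohort$expr_lnc)[features, , drop = FALSE]))
  attr(X, "scaled:center") <- attr(X, "scaled:scale") <- NULL
  colnames(X) <- features
  pruned <- character(0)
  if (ncol(X) > 1L) {
    cm <- abs(stats::cor(X))
    drop <- rep(FALSE, ncol(X))
    for (j in seq_len(ncol(X))) {
      if (drop[j]) next
      later <- which(cm[j, ] > collinearity_cap)
      later <- later[later > j]
      drop[later] <- TRUE
    }
    pruned <- colnames(X)[drop]
    if (length(pruned)) {
      warning("pruned collinear feature(s): ", paste(pruned, collapse = ", "),
              call. = FALSE)
      X <- X[, !drop, drop = FALSE]
    }
  }
  time <- cohort$clinical$survival_time
  status <- cohort$clinical$status
  fit_once <- function(Xc) {
    f <- tryCatch(cox_fit(time, status, Xc), error = function(e) NULL)
    if (is.null(f) || !f$converged) {
      warning("joint Cox fit did not converge; using ridge-stabilized fit",
              call. = FALSE)
      rf <- survival::coxph(
        survival::Surv(time, status) ~ survival::ridge(Xc, theta = ridge_penalty,
                                                       scale = FALSE),
        ties = "efron")
      beta <- unname(stats::coef(rf))
      se <- unname(sqrt(diag(rf$var)))
      z <- beta / se
      f <- structure(list(
        beta = stats::setNames(beta, colnames(Xc)),
        se = stats::setNames(se, colnames(Xc)),
        wald_z = stats::setNames(z, colnames(Xc)),
        wald_p = stats::setNames(2 * stats::pnorm(-abs(z)), colnames(Xc)),
        loglik = rf$loglik[2L], loglik_null = rf$loglik[1L],
        n = length(time), n_events = sum(status == 1), converged = TRUE
      ), class = "CoxFit")
    }
    f
  }
  eliminated <- character(0)
  repeat {
    fit <- fit_once(X)
    worst <- which.max(fit$wald_p)
    if (fit$wald_p[worst] < alpha) break
    if (ncol(X) == 1L) {
      stop("no feature retained at alpha = ", alpha,
           "; consider relaxing the cut-off", call. = FALSE)
    }
    eliminated <- c(eliminated, colnames(X)[worst])
    X <- X[, -worst, drop = FALSE]
  }
  list(pr_lncRNAs = colnames(X), beta = fit$beta, fit = fit,
       pruned_collinear = pruned, eliminated = eliminated)
}

#' Build per-sample risk scores and the two risk groups
#'
#' Risk score = Cox linear predictor, the sum over signature lncRNAs of
#' coefficient times z-scored normalized expression. Samples at or below the
#' median score are labelled `low`, the rest `high` (ties go low).
#'
#' @param cohort A `"MatchedCohort"`.
#' @param pr_lncRNAs Signature feature ids.
#' @param beta Named coefficients (one per signature feature).
#' @return List classed `"RiskModel"`: `pr_lncRNAs`, `beta`, `risk_scores`
#'   (named per sample), `threshold` (median score), `group` (named factor
#'   `low`/`high`), `degenerate` (TRUE when all scores tie).
#' @export
score_samples <- function(cohort, pr_lncRNAs, beta) {
  if (length(pr_lncRNAs) != length(beta)) {
    stop("pr_lncRNAs and beta lengths differ", call. = FALSE)
  }
  beta <- if (is.null(names(beta))) stats::setNames(beta, pr_lncRNAs) else beta[pr_lncRNAs]
  Z <- base::scale(t(unclass(cohort$expr_lnc)[pr_lncRNAs, , drop = FALSE]))
  scores <- as.numeric(Z %*% as.numeric(beta))
  names(scores) <- cohort$samples
  threshold <- stats::median(scores)
  degenerate <- stats::sd(scores) == 0
  if (degenerate) warning("all risk scores identical; grouping is degenerate", call. = FALSE)
  group <- factor(ifelse(scores <= threshold, "low", "high"), levels = c("low", "high"))
  names(group) <- cohort$samples
  structure(list(pr_lncRNAs = pr_lncRNAs, beta = beta, risk_scores = scores,
                 threshold = threshold, group = group, degenerate = degenerate),
            class = "RiskModel")
}

#' Kaplan-Meier product-limit curve
#'
#' Product-limit survival estimate with the usual events-before-censorings
#' convention at tied times, via `survival::survfit`.
#'
#' @param time Survival/censoring times.
#' @param status Event indicator (1 = event).
#' @return Data frame: `time`, `n_risk`, `n_event`, `n_censor`, `surv`,
#'   starting from the first observed time (survival is 1 before it).
#' @export
kaplan_meier <- function(time, status) {
  if (length(time) < 1L) stop("empty group", call. = FALSE)
  sf <- survival::survfit(survival::Surv(time, status) ~ 1)
  data.frame(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
             n_censor = sf$n.censor, surv = sf$surv)
}

#' Two-group log-rank test
#'
#' Standard 1-df log-rank chi-square summing observed-minus-expected events
#' over event times with the hypergeometric variance, via
#' `survival::survdiff`.
#'
#' @param time Survival/censoring times.
#' @param status Event indicator.
#' @param groups Two-level grouping (factor/character).
#' @return List: `chi2`, `p`.
#' @export
logrank_test <- function(time, status, groups) {
  groups <- factor(groups)
  tab <- table(groups)
  if (nlevels(groups) != 2L || any(tab == 0)) {
    stop("log-rank test requires two non-empty groups", call. = FALSE)
  }
  if (sum(status == 1) < 1) stop("no events", call. = FALSE)
  sd0 <- survival::survdiff(survival::Surv(time, status) ~ groups)
  chi2 <- unname(sd0$chisq)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1L, lower.tail = FALSE))
}

#' Rank-based AUC of the risk score against event status
#'
#' AUC is the probability that a randomly chosen event sample outscores a
#' randomly chosen non-event sample, ties counting one half (the
#' Wilcoxon-Mann-Whitney form), with a seeded percentile bootstrap CI over
#' samples.
#'
#' @param risk_scores Numeric scores.
#' @param status Binary outcome (1 = event); both classes must be present.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @return List classed `"ModelEvaluation"`: `auc`, `ci_low`, `ci_high`,
#'   `n_boot`, `seed`.
#' @export
evaluate_auc <- function(risk_scores, status, n_boot = 1000, seed = 1) {
  if (length(risk_scores) != length(status)) stop("length mismatch", call. = FALSE)
  if (!all(status %in% c(0, 1))) stop("status must be binary 0/1", call. = FALSE)
  n1 <- sum(status == 1); n0 <- sum(status == 0)
  if (n1 == 0 || n0 == 0) stop("both outcome classes must be present", call. = FALSE)
  auc_of <- function(s, st) {
    r <- rank(s)
    np <- sum(st == 1)
    (sum(r[st == 1]) - np * (np + 1) / 2) / (np * sum(st == 0))
  }
  auc <- auc_of(risk_scores, status)
  set.seed(seed)
  boots <- rep(NA_real_, n_boot)
  n <- length(status)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, replace = TRUE)
    st <- status[idx]
    if (sum(st == 1) == 0 || sum(st == 0) == 0) next
    boots[b] <- auc_of(risk_scores[idx], st)
  }
  ci <- stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  structure(list(auc = auc, ci_low = ci[1L], ci_high = ci[2L],
                 n_boot = n_boot, seed = seed),
            class = "ModelEvaluation")
}
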