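make_risk_fixture <- function(seed = 17, n = 300, n_true = 2, n_null = 4,
                              beta = 0.8) {
  set.seed(seed)
  samples <- sprintf("S%03d", seq_len(n))
  ids <- c(sprintf("TRUE%d", seq_len(n_true)), sprintf("NULL%d", seq_len(n_null)))
  X <- matrix(rnorm(n * (n_true + n_null)), nrow = n_true + n_null,
              dimnames = list(ids, samples))
  lp <- beta * colSums(X[seq_len(n_true), , drop = FALSE])
  t_ev <- rexp(n, rate = 0.01 * exp(lp))
  cens <- runif(n, 0, quantile(t_ev, 0.9) * 2)
  time <- pmin(t_ev, cens); status <- as.integer(t_ev <= cens)
  cn <- matrix(2, nrow = nrow(X), ncol = n, dimnames = dimnames(X))
  toy_cohort(X, cn, toy_clinical(samples, pmax(time, 1e-3), status))
}

test_that("multivariate refinement keeps planted features and drops noise", {
  cohort <- make_risk_fixture()
  ref <- multivariate_refine(cohort, rownames(cohort$expr_lnc), alpha = 0.05)
  expect_true(all(c("TRUE1", "TRUE2") %in% ref$pr_lncRNAs))
  expect_identical(length(ref$pr_lncRNAs), length(ref$beta))
  expect_true(all(ref$fit$wald_p < 0.05))
})

test_that("a single survivor reduces to the univariate fit", {
  cohort <- make_risk_fixture()
  ref <- multivariate_refine(cohort, "TRUE1")
  z <- as.numeric(scale(as.numeric(cohort$expr_lnc["TRUE1", ])))
  uni <- cox_fit(cohort$clinical$survival_time, cohort$clinical$status, z)
  expect_equal(unname(ref$beta), unname(uni$beta), tolerance = 1e-8)
})

test_that("an exact duplicate feature is pruned before fitting", {
  cohort <- make_risk_fixture()
  dup <- unclass(cohort$expr_lnc)[c("TRUE1", "TRUE1", "TRUE2"), ]
  rownames(dup) <- c("TRUE1", "COPY1", "TRUE2")
  cohort2 <- toy_cohort(dup, matrix(2, 3, ncol(dup), dimnames = dimnames(dup)),
                        cohort$clinical)
  expect_warning(ref <- multivariate_refine(cohort2, rownames(dup)), "collinear")
  expect_identical(ref$pruned_collinear, "COPY1")
  expect_false("COPY1" %in% ref$pr_lncRNAs)
})

test_that("risk scores are the linear predictor with a tie-goes-low median split", {
  cohort <- make_risk_fixture(n = 101)
  model <- score_samples(cohort, "TRUE1", c(TRUE1 = 1))
  z <- as.numeric(scale(as.numeric(cohort$expr_lnc["TRUE1", ])))
  expect_equal(unname(model$risk_scores), z, tolerance = 1e-12)
  expect_identical(sum(model$group == "low"), 51L)  # ceil(n/2) with ties to low

  m2 <- score_samples(cohort, c("TRUE1", "TRUE2"), c(TRUE1 = 0.5, TRUE2 = -1))
  m3 <- score_samples(cohort, c("TRUE2", "TRUE1"), c(TRUE2 = -1, TRUE1 = 0.5))
  expect_equal(model$threshold, stats::median(model$risk_scores))
  expect_equal(unname(m2$risk_scores), unname(m3$risk_scores), tolerance = 1e-12)

  expect_warning(mz <- score_samples(cohort, "TRUE1", c(TRUE1 = 0)), "degenerate")
  expect_true(all(mz$risk_scores == 0))
})

test_that("Kaplan-Meier estimator matches the hand product-limit computation", {
  km <- kaplan_meier(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  # no events: curve constant at 1
  km0 <- kaplan_meier(c(5, 6, 7), c(0, 0, 0))
  expect_true(all(km0$surv == 1))
  # a subject censored after the last event only joins the risk sets
  km1 <- kaplan_meier(c(1, 2, 3, 10), c(1, 1, 1, 0))
  expect_equal(km1$surv[km1$n_event > 0], c(3 / 4, 1 / 2, 1 / 4))
  # moving that censoring time further out changes nothing at event times
  km1b <- kaplan_meier(c(1, 2, 3, 99), c(1, 1, 1, 0))
  expect_equal(km1b$surv[km1b$n_event > 0], km1$surv[km1$n_event > 0])
  # equals 1 - ECDF without censoring
  set.seed(8)
  tt <- sample(1:50, 20)
  km2 <- kaplan_meier(tt, rep(1, 20))
  expect_equal(km2$surv, 1 - stats::ecdf(tt)(km2$time), tolerance = 1e-12)
})

test_that("log-rank matches the brute-force O-E/variance sums", {
  # frozen 6-subject fixture, chi2 computed by explicit summation
  t6 <- c(1, 2, 3, 4, 5, 6); s6 <- c(1, 1, 1, 1, 0, 1); g6 <- c(0, 1, 0, 1, 0, 1)
  lr <- logrank_test(t6, s6, g6)
  expect_equal(lr$chi2, 0.0739030023, tolerance = 1e-8)
  expect_equal(lr$chi2, brute_logrank(t6, s6, g6), tolerance = 1e-10)

  set.seed(66)
  for (i in 1:20) {
    n <- sample(10:40, 1)
    time <- sample(1:15, n, replace = TRUE)  # ties included
    status <- rbinom(n, 1, 0.7); if (sum(status) == 0) status[1] <- 1
    grp <- sample(c("a", "b"), n, replace = TRUE)
    if (min(table(grp)) == 0) next
    lr2 <- logrank_test(time, status, grp)
    expect_equal(lr2$chi2, brute_logrank(time, status, grp), tolerance = 1e-8)
    # relabeling invariance: swapping the two group names changes nothing
    swapped <- ifelse(grp == "a", "b", "a")
    expect_equal(logrank_test(time, status, swapped)$chi2, lr2$chi2,
                 tolerance = 1e-10)
  }
  # identical survival in both groups: O = E
  tt <- rep(c(1, 2, 3), 2); ss <- rep(1, 6); gg <- rep(c("a", "b"), 3)
  expect_equal(logrank_test(tt, ss, gg)$chi2, 0, tolerance = 1e-12)
  expect_error(logrank_test(1:3, c(1, 1, 1), rep("a", 3)), "two non-empty groups")
})

test_that("AUC is the pairwise win probability with half-credit ties", {
  expect_equal(evaluate_auc(c(4, 3, 2, 1), c(1, 1, 0, 0), n_boot = 50)$auc, 1)
  expect_equal(evaluate_auc(rep(2, 10), rep(c(0, 1), 5), n_boot = 50)$auc, 0.5)
  # enumeration fixture: events {4,2}, non-events {3,1} -> 3 wins of 4 pairs
  expect_equal(evaluate_auc(c(4, 2, 3, 1), c(1, 1, 0, 0), n_boot = 50)$auc, 3 / 4)
  set.seed(77)
  for (i in 1:30) {
    n <- sample(6:25, 1)
    s <- sample(1:8, n, replace = TRUE)
    st <- rbinom(n, 1, 0.5)
    if (sum(st) == 0 || sum(st) == n) next
    got <- evaluate_auc(s, st, n_boot = 10, seed = 1)$auc
    expect_equal(got, brute_auc(s, st), tolerance = 1e-12)
    expect_equal(evaluate_auc(exp(s), st, n_boot = 10, seed = 1)$auc, got,
                 tolerance = 1e-12)  # monotone-transform invariance
  }
  ev <- evaluate_auc(rnorm(50), rbinom(50, 1, 0.5), n_boot = 200, seed = 2)
  expect_lte(ev$ci_low, ev$auc); expect_gte(ev$ci_high, ev$auc)
  expect_error(evaluate_auc(1:5, rep(1, 5), n_boot = 10), "both outcome classes")
})
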