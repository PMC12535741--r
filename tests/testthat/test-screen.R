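test_that("cox_fit matches grid-search maximization of the Efron partial likelihood", {
  # frozen 8-subject fixture: grid-refined oracle gives beta = 0.77515644
  time <- c(1, 2, 3, 4, 5, 6, 7, 8)
  status <- c(1, 1, 0, 1, 1, 0, 1, 1)
  x <- c(1, 0, 1, 1, 0, 0, 1, 0)
  fit <- cox_fit(time, status, x)
  expect_equal(unname(fit$beta), 0.77515644, tolerance = 1e-6)
  expect_equal(fit$loglik, brute_cox_loglik(unname(fit$beta), time, status, x),
               tolerance = 1e-8)
  expect_true(fit$converged)

  # parameterized small fixtures, including ties, against the oracle
  set.seed(33)
  for (i in 1:25) {
    n <- sample(8:14, 1)
    t2 <- sample(1:6, n, replace = TRUE)           # forces tied event times
    s2 <- rbinom(n, 1, 0.7)
    if (sum(s2) == 0) s2[1] <- 1
    x2 <- round(rnorm(n), 2)
    if (stats::sd(x2) == 0) next
    b_ref <- brute_cox_beta(t2, s2, x2, lo = -6, hi = 6)
    if (abs(b_ref) > 5) next                        # near-separation: skip unstable case
    fit2 <- cox_fit(t2, s2, x2)
    expect_lt(abs(unname(fit2$beta) - b_ref), 1e-6)
  }
})

test_that("cox_fit rejects degenerate designs and flags separation", {
  expect_error(cox_fit(1:4, rep(0, 4), rnorm(4)), "no events")
  expect_error(cox_fit(1:4, c(1, 0, 1, 0), rep(2, 4)), "zero-variance")
  # perfect separation: the covariate orders survival exactly
  time <- c(1, 2, 3, 10, 11, 12)
  status <- rep(1, 6)
  x <- c(5, 5, 5, -5, -5, -5)
  fit <- cox_fit(time, status, x)
  expect_false(fit$converged)
})

test_that("cox recovery and type-I behavior at moderate sample size", {
  set.seed(77)
  reps <- 60; n <- 300
  betas <- p_null <- numeric(reps)
  for (i in seq_len(reps)) {
    x <- rnorm(n)
    t_ev <- rexp(n, rate = 0.01 * exp(0.7 * x))
    cens <- runif(n, 0, quantile(t_ev, 0.9) * 2)
    time <- pmin(t_ev, cens); status <- as.integer(t_ev <= cens)
    betas[i] <- unname(cox_fit(time, status, x)$beta[1])
    xn <- rnorm(n)
    p_null[i] <- unname(cox_fit(time, status, xn)$wald_p[1])
  }
  expect_equal(mean(betas), 0.7, tolerance = 0.05)
  expect_lt(abs(mean(p_null < 0.05) - 0.05), 0.06)  # coarse at 60 reps
})

test_that("copy-number categorization follows the diploid convention", {
  expect_identical(as.character(categorize_cnv(c(0, 1, 2, 3, 6))),
                   c("deletion", "deletion", "diploid", "amplification", "amplification"))
})

test_that("kruskal_wallis matches the explicit rank formula", {
  v <- c(1, 4, 7, 2, 5, 8, 3, 6, 9)
  g <- rep(c("a", "b", "c"), each = 3)
  kw <- kruskal_wallis(v, g)
  expect_equal(kw$H, 0.8)  # brute-force rank formula on this fixture
  expect_equal(kw$H, brute_kw(v, g), tolerance = 1e-12)
  expect_identical(kw$groups_used, 3L)

  set.seed(44)
  for (i in 1:30) {
    n <- sample(12:30, 1)
    vals <- sample(1:10, n, replace = TRUE)  # plenty of ties
    grp <- sample(letters[1:3], n, replace = TRUE, prob = c(0.4, 0.3, 0.3))
    if (min(table(grp)) < 3) next
    expect_equal(kruskal_wallis(vals, grp)$H, brute_kw(vals, grp), tolerance = 1e-10)
  }
})

test_that("kruskal_wallis handles degenerate inputs and is rank-invariant", {
  all_same <- kruskal_wallis(rep(2, 9), rep(c("a", "b", "c"), each = 3))
  expect_identical(all_same$H, 0)
  expect_identical(all_same$p, 1)

  # groups below min size are dropped; <2 eligible groups -> untestable
  v <- c(1, 2, 3, 4, 5, 6, 7)
  g <- c("a", "a", "a", "a", "a", "b", "b")
  out <- kruskal_wallis(v, g, min_group_size = 3)
  expect_identical(out$groups_used, 1L)
  expect_true(is.na(out$p))

  set.seed(4)
  vals <- rnorm(24); grp <- rep(c("a", "b", "c"), 8)
  h1 <- kruskal_wallis(vals, grp)$H
  h2 <- kruskal_wallis(exp(vals) + 5, grp)$H  # strictly monotone transform
  expect_equal(h1, h2, tolerance = 1e-12)
})

test_that("two-group H agrees with the Wilcoxon chi-square form", {
  set.seed(55)
  for (i in 1:50) {
    n <- sample(10:30, 1)
    vals <- rnorm(n)
    grp <- sample(c("a", "b"), n, replace = TRUE)
    if (min(table(grp)) < 3) next
    H <- kruskal_wallis(vals, grp)$H
    # normal-approximation chi-square form of the rank-sum statistic
    r <- rank(vals); n1 <- sum(grp == "a"); n2 <- sum(grp == "b")
    W <- sum(r[grp == "a"])
    chi <- (W - n1 * (n + 1) / 2)^2 / (n1 * n2 * (n + 1) / 12)
    expect_equal(H, chi, tolerance = 1e-10)
  }
})

test_that("screen cascade applies Cox first, then KW, with monotone attrition", {
  sp <- small_planted_cohort(seed = 3)
  uni <- univariate_screen(sp$cohort)
  scr <- cnv_group_screen(sp$cohort, uni, correlations = correlate_all(sp$cohort))
  rec <- scr$records
  expect_true(all(rec$passed_kw[!rec$passed_cox] == FALSE))
  expect_lte(sum(rec$passed_cox & rec$passed_kw), sum(rec$passed_cox))
  expect_lte(sum(rec$passed_cox), nrow(rec))
  # KW ran only on Cox survivors
  expect_true(all(is.na(rec$kw_p[!rec$passed_cox])))
  # everywhere-diploid features that pass Cox are untestable by KW
  dip <- rec$lncRNA_id[!rec$lncRNA_id %in% sp$sim$truth$aberrant_ids & rec$passed_cox]
  if (length(dip)) expect_true(all(!rec$passed_kw[rec$lncRNA_id %in% dip]))
  # violin table covers every Cox survivor sample-by-sample
  expect_setequal(unique(scr$violin$lncRNA_id), rec$lncRNA_id[rec$passed_cox])
  expect_identical(nrow(scr$violin),
                   sum(rec$passed_cox) * length(sp$cohort$samples))
})

test_that("collapse_aberrant reduces the test to diploid vs aberrant", {
  sp <- small_planted_cohort(seed = 3)
  uni <- univariate_screen(sp$cohort)
  scr2 <- cnv_group_screen(sp$cohort, uni, collapse_aberrant = TRUE)
  tested <- scr2$records[scr2$records$passed_cox & !is.na(scr2$records$kw_p), ]
  expect_true(all(tested$kw_groups <= 2))
})
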