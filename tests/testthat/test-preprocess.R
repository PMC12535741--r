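test_that("sample harmonization takes the sorted three-way intersection", {
  mk <- function(samples, kind = "raw_count") {
    omics_matrix(matrix(1, nrow = 2, ncol = length(samples),
                        dimnames = list(c("G1", "G2"), samples)), kind)
  }
  expr <- mk(c("S3", "S1", "S2"))
  cnv <- mk(c("S2", "S3", "S4"), "absolute_cn")
  clin <- toy_clinical(c("S2", "S3"), c(10, 20), c(1, 0))
  h <- suppressMessages(harmonize_samples(expr, cnv, clin, min_samples = 2))
  expect_identical(colnames(h$expr), c("S2", "S3"))
  expect_identical(colnames(h$cnv), c("S2", "S3"))
  expect_identical(h$clinical$sample_id, c("S2", "S3"))

  h2 <- harmonize_samples(mk(c("S2", "S1")), mk(c("S1", "S2"), "absolute_cn"),
                          toy_clinical(c("S1", "S2"), c(1, 2), c(1, 1)),
                          min_samples = 2)
  expect_identical(colnames(h2$expr), c("S1", "S2"))

  expect_error(harmonize_samples(mk("S1"), mk("S2", "absolute_cn"),
                                 toy_clinical("S3", 1, 1), min_samples = 1),
               "intersection too small")
})

test_that("median-of-ratios size factors behave on exact-multiple columns", {
  base <- c(10, 20, 40, 80, 5)
  m <- cbind(S1 = base, S2 = 2 * base)
  rownames(m) <- paste0("G", 1:5)
  sf <- estimate_size_factors(omics_matrix(m, "raw_count"))
  # ratio 1:2, rescaled to geometric mean 1 => (1/sqrt(2), sqrt(2))
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

  ident <- cbind(S1 = base, S2 = base, S3 = base)
  rownames(ident) <- paste0("G", 1:5)
  expect_equal(unname(estimate_size_factors(omics_matrix(ident, "raw_count"))),
               rep(1, 3), tolerance = 1e-12)

  single <- matrix(base, ncol = 1, dimnames = list(paste0("G", 1:5), "S1"))
  expect_equal(unname(estimate_size_factors(omics_matrix(single, "raw_count"))), 1)
})

test_that("size factors of a permuted-sample matrix are the same permutation", {
  set.seed(42)
  m <- matrix(rnbinom(500, mu = 50, size = 2) + 1, nrow = 50,
              dimnames = list(paste0("G", 1:50), paste0("S", 1:10)))
  sf <- estimate_size_factors(omics_matrix(m, "raw_count"))
  perm <- sample(10)
  sf_p <- estimate_size_factors(omics_matrix(m[, perm], "raw_count"))
  expect_equal(unname(sf_p), unname(sf[perm]), tolerance = 1e-12)
})

test_that("size factors agree with an independent reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(7)
  m <- matrix(rnbinom(2000, mu = 80, size = 1.5) + 1, nrow = 200,
              dimnames = list(paste0("G", 1:200), paste0("S", 1:10)))
  ours <- estimate_size_factors(omics_matrix(m, "raw_count"))
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  ref <- ref / exp(mean(log(ref)))  # same geometric-mean-1 normalization
  expect_equal(unname(ours), unname(ref), tolerance = 1e-10)
})

test_that("dispersion trend is recovered from self-generated counts", {
  set.seed(11)
  G <- 2000; n <- 60; a0 <- 0.05; a1 <- 3
  mu <- pmin(pmax(exp(rnorm(G, log(50), 2)), 0.5), 5e4)
  disp <- a1 / mu + a0
  k <- matrix(rnbinom(G * n, mu = rep(mu, n), size = rep(1 / disp, n)), nrow = G,
              dimnames = list(sprintf("g%04d", 1:G), sprintf("s%02d", 1:n)))
  model <- fit_vst(k, stats::setNames(rep(1, n), colnames(k)))
  expect_gt(model$a0, a0 * 0.5); expect_lt(model$a0, a0 * 1.5)
  expect_gt(model$a1, a1 * 0.5); expect_lt(model$a1, a1 * 1.5)
})

test_that("Poisson counts drive the asymptotic dispersion to the floor", {
  set.seed(12)
  G <- 1000; n <- 50
  mu <- pmin(pmax(exp(rnorm(G, log(50), 1.5)), 1), 1e4)
  k <- matrix(rpois(G * n, rep(mu, n)), nrow = G,
              dimnames = list(sprintf("g%04d", 1:G), sprintf("s%02d", 1:n)))
  model <- suppressWarnings(fit_vst(k, stats::setNames(rep(1, n), colnames(k))))
  expect_lt(model$a0, 0.01)
  few <- k[1:30, , drop = FALSE]
  expect_error(fit_vst(few, stats::setNames(rep(1, n), colnames(k))), "fewer than 50")
})

test_that("VST is monotone, log2-like for large counts, and variance-flattening", {
  model <- structure(list(size_factors = c(S1 = 1), a0 = 0.05, a1 = 3),
                     class = "VSTModel")
  x <- matrix(c(0:1000, 3000, 1e4, 1e5), nrow = 1,
              dimnames = list("g", paste0("s", seq_len(1004))))
  model$size_factors <- stats::setNames(rep(1, ncol(x)), colnames(x))
  y <- as.numeric(apply_vst(x, model))
  expect_true(all(diff(y) > 0))          # strictly increasing over the grid
  v2 <- function(q) log2((1 + 3 + 2 * .05 * q + 2 * sqrt(.05 * q * (1 + 3 + .05 * q))) / (4 * .05))
  expect_equal(y[1], v2(0))
  expect_equal(v2(2e5) - v2(1e5), 1, tolerance = 0.05)  # doubling adds ~1

  set.seed(11)
  G <- 2000; n <- 60
  mu <- pmin(pmax(exp(rnorm(G, log(20), 2)), 0.5), 2e4)
  disp <- 3 / mu + 0.05
  k <- matrix(rnbinom(G * n, mu = rep(mu, n), size = rep(1 / disp, n)), nrow = G,
              dimnames = list(sprintf("g%04d", 1:G), sprintf("s%02d", 1:n)))
  m2 <- fit_vst(k, stats::setNames(rep(1, n), colnames(k)))
  v <- unclass(apply_vst(k, m2)); lg <- log2(k + 1)
  dec <- cut(rank(mu), breaks = stats::quantile(rank(mu), 0:10 / 10), include.lowest = TRUE)
  ratio <- function(mat) {
    bv <- tapply(seq_len(G), dec, function(i) stats::median(apply(mat[i, , drop = FALSE], 1, stats::var)))
    max(bv) / min(bv)
  }
  expect_lt(ratio(v), 3)
  expect_gt(ratio(lg), 2 * ratio(v))  # log2(x+1) is far less variance-stable
})

test_that("biotype classification is total, pure and disjoint", {
  lnc <- c("processed_transcript", "processed_transcripts", "3prime_overlapping_ncRNA",
           "sense_intronic", "sense_overlapping", "antisense", "lincRNA")
  expect_identical(classify_biotype(lnc), rep("lncRNA", 7))
  expect_identical(classify_biotype("protein_coding"), "PCG")
  expect_identical(classify_biotype(c("snoRNA", "miRNA", "rRNA", "")),
                   rep("other", 4))
  mixed <- c("antisense", "protein_coding", "miRNA")
  expect_identical(classify_biotype(mixed), classify_biotype(mixed))  # pure
})

test_that("cohort assembly splits classes, intersects CNV and enforces order", {
  sp <- small_planted_cohort(seed = 3)
  cohort <- sp$cohort; sim <- sp$sim
  expect_identical(colnames(cohort$expr_lnc), cohort$samples)
  expect_identical(cohort$clinical$sample_id, cohort$samples)
  expect_identical(rownames(cohort$expr_lnc), rownames(cohort$cnv_lnc))
  expect_true(all(grepl("^LNC", rownames(cohort$expr_lnc))))
  expect_true(all(grepl("^PCG", rownames(cohort$expr_pcg))))
  expect_identical(value_kind(cohort$expr_lnc), "normalized")

  # a lncRNA absent from the CNV matrix is excluded from both compartments
  cnv2 <- sim$cnv[-1, , drop = FALSE]
  cohort2 <- build_cohort(sim$expr, cnv2, sim$clinical, sim$annotation)
  expect_false(rownames(sim$cnv)[1] %in% rownames(cohort2$expr_lnc))

  # scrambling one component's samples must trip the validator
  broken <- cohort
  broken$clinical <- cohort$clinical[rev(seq_len(nrow(cohort$clinical))), ]
  expect_error(validate_cohort(broken), "sample order")
})
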