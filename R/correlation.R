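#' Pearson correlation with a t-based two-sided p-value
#'
#' Textbook Pearson r after pairwise removal of missing values, with the
#' two-sided p-value from `t = r*sqrt((n-2)/(1-r^2))` on `n-2` degrees of
#' freedom (`p = 0` at `|r| = 1`). A zero-variance vector makes r undefined:
#' the record is flagged rather than silently reported as 0.
#'
#' @param x,y Numeric vectors of equal length.
#' @return List with `r`, `p`, `n` (pairs used) and `flag` (`"ok"`,
#'   `"degenerate"` for zero variance, `"too_few"` for n < 3).
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) return(list(r = NA_real_, p = NA_real_, n = n, flag = "too_few"))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = n, flag = "degenerate"))
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = n, flag = "ok")
}

#' Correlate every lncRNA's expression with its copy-number profile
#'
#' One Pearson record per lncRNA present in both the normalized expression
#' and CNV compartments of the cohort, in deterministic feature-id order.
#' CNV states enter as raw absolute copy numbers.
#'
#' @param cohort A `"MatchedCohort"` from [build_cohort()].
#' @return Data frame with columns `lncRNA_id`, `r`, `p`, `n`, `flag`.
#' @export
correlate_all <- function(cohort) {
  ids <- sort(rownames(cohort$expr_lnc))
  recs <- lapply(ids, function(id) {
    pc <- pearson_cor(as.numeric(cohort$expr_lnc[id, ]),
                      as.numeric(cohort$cnv_lnc[id, ]))
    data.frame(lncRNA_id = id, r = pc$r, p = pc$p, n = pc$n, flag = pc$flag,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

# Row-standardize a matrix (mean 0, unit variance per row); rows with zero
# variance come back as all-NA.
.row_standardize <- function(m) {
  mu <- rowMeans(m)
  s <- apply(m, 1L, stats::sd)
  s[s == 0] <- NA_real_
  (m - mu) / s
}

#' Permutation null for the expression-CNV correlation distribution
#'
#' For each permutation, the sample labels of the CNV matrix are shuffled
#' once (the same shuffle for every feature, preserving within-sample CNV
#' structure) and all per-lncRNA Pearson coefficients are recomputed. The
#' resulting pool is the random background the observed correlation
#' distribution is compared against.
#'
#' @param cohort A `"MatchedCohort"`.
#' @param n_permutations Number of shuffles (minimum 100; default 1000).
#' @param seed Integer seed; the null is fully reproducible.
#' @return List classed `"NullDistribution"` with `r_values` (features x
#'   permutations pool, flattened), `n_permutations`, `n_features`, `seed`.
#' @export
permutation_null <- function(cohort, n_permutations = 1000, seed = 1) {
  if (n_permutations < 100) {
    stop("n_permutations must be at least 100 (the null is too coarse below that)",
         call. = FALSE)
  }
  E <- .row_standardize(unclass(cohort$expr_lnc))
  C <- .row_standardize(unclass(cohort$cnv_lnc))
  usable <- rowSums(is.na(E)) == 0L & rowSums(is.na(C)) == 0L
  E <- E[usable, , drop = FALSE]; C <- C[usable, , drop = FALSE]
  n <- ncol(E)
  r_values <- matrix(NA_real_, nrow = nrow(E), ncol = n_permutations)
  set.seed(seed)
  for (b in seq_len(n_permutations)) {
    perm <- sample.int(n)
    r_values[, b] <- rowSums(E * C[, perm, drop = FALSE]) / (n - 1)
  }
  structure(list(r_values = as.numeric(r_values),
                 n_permutations = n_permutations,
                 n_features = nrow(E), seed = seed),
            class = "NullDistribution")
}

#' Summarize observed vs permutation-null correlation distributions
#'
#' Emits the histogram bin counts behind the correlation-distribution plot,
#' the fraction of lncRNAs with p < 0.05, and a two-sample
#' Kolmogorov-Smirnov statistic contrasting observed and null r values.
#'
#' @param observed [correlate_all()] output.
#' @param null [permutation_null()] output.
#' @param breaks Histogram breaks over `[-1, 1]` (default width 0.1).
#' @return List with `histogram` (data frame: bin_low, bin_high,
#'   observed_count, null_count with null counts rescaled to the observed
#'   total), `frac_significant`, `ks_statistic`, `ks_p`.
#' @export
correlation_summary <- function(observed, null, breaks = seq(-1, 1, by = 0.1)) {
  obs_r <- observed$r[observed$flag == "ok"]
  null_r <- null$r_values
  h_obs <- graphics::hist(obs_r, breaks = breaks, plot = FALSE)
  h_null <- graphics::hist(null_r[null_r >= -1 & null_r <= 1], breaks = breaks, plot = FALSE)
  ks <- suppressWarnings(stats::ks.test(obs_r, null_r))
  list(
    histogram = data.frame(
      bin_low = utils::head(breaks, -1L),
      bin_high = breaks[-1L],
      observed_count = h_obs$counts,
      null_count = h_null$counts * (length(obs_r) / max(length(null_r), 1L))
    ),
    frac_significant = mean(observed$p[observed$flag == "ok"] < 0.05),
    ks_statistic = unname(ks$statistic),
    ks_p = ks$p.value
  )
}

#' Per-chromosome count of aberrant lncRNAs
#'
#' The tabular equivalent of a genome-wide CNV distribution plot: for each
#' chromosome, how many cohort lncRNAs show any non-diploid sample.
#'
#' @param cohort A `"MatchedCohort"`.
#' @return Data frame with `chrom`, `n_lncRNAs`, `n_aberrant`.
#' @export
genome_cnv_distribution <- function(cohort) {
  ann <- cohort$annotation
  ids <- rownames(cohort$cnv_lnc)
  chrom <- ann$chrom[match(ids, ann$gene_id)]
  aberrant <- apply(unclass(cohort$cnv_lnc), 1L, function(r) any(r != 2, na.rm = TRUE))
  out <- data.frame(chrom = chrom, aberrant = aberrant, stringsAsFactors = FALSE)
  out <- out[!is.na(out$chrom), , drop = FALSE]
  agg <- stats::aggregate(cbind(n_lncRNAs = rep(1L, nrow(out)), n_aberrant = out$aberrant)
                          ~ chrom, data = out, FUN = sum)
  agg[order(agg$chrom), , drop = FALSE]
}
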