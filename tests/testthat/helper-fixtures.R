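# Fixture builders: every input is generated in code at test time.

write_tsv_fixture <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

# A minimal hand-built matched cohort for unit tests of the screen and
# risk-model stages: expression values are supplied directly as "normalized".
toy_cohort <- function(expr_lnc, cnv_lnc, clinical, expr_pcg = NULL) {
  samples <- colnames(expr_lnc)
  if (is.null(expr_pcg)) {
    expr_pcg <- matrix(numeric(0), nrow = 0, ncol = length(samples),
                       dimnames = list(character(0), samples))
  }
  cohort <- structure(list(
    samples = samples,
    expr_lnc = omics_matrix(expr_lnc, "normalized"),
    expr_pcg = if (nrow(expr_pcg) > 0) omics_matrix(expr_pcg, "normalized")
               else structure(expr_pcg, value_kind = "normalized",
                              class = c("OmicsMatrix", "matrix", "array")),
    cnv_lnc = omics_matrix(cnv_lnc, "absolute_cn"),
    clinical = clinical,
    vst = NULL,
    annotation = NULL,
    attrition = list()
  ), class = "MatchedCohort")
  cohort
}

toy_clinical <- function(samples, time, status) {
  cl <- data.frame(sample_id = samples, survival_time = time, status = status,
                   stringsAsFactors = FALSE)
  class(cl) <- c("ClinicalTable", "data.frame")
  cl
}

# A small planted cohort built through the real generator + preprocessing.
small_planted_cohort <- function(seed = 3, n_samples = 150, n_lnc = 80,
                                 n_pcg = 200, ...) {
  sim <- simulate_cohort(sim_config(n_samples = n_samples, n_lnc = n_lnc,
                                    n_pcg = n_pcg, seed = seed, ...))
  cohort <- build_cohort(sim$expr, sim$cnv, sim$clinical, sim$annotation)
  list(sim = sim, cohort = cohort)
}

expect_file_identical <- function(a, b) {
  expect_identical(readLines(a), readLines(b))
}
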