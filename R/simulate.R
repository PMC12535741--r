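#' Configuration for the synthetic cohort generator
#'
#' Defaults mirror a small TCGA-like tumor cohort: 300 samples, 500 lncRNAs
#' and 2,000 protein-coding genes; 10% of lncRNAs carry copy-number
#' aberrations with a proportional dosage effect on expression, and 30% of
#' those are additionally prognostic. Counts are negative binomial with the
#' dispersion trend `alpha(mu) = a1/mu + a0`; survival is exponential in the
#' latent (noise-free) expression of prognostic features with independent
#' uniform censoring tuned to the target censoring fraction.
#'
#' @param n_samples,n_lnc,n_pcg Cohort dimensions.
#' @param frac_cnv_driven Fraction of lncRNAs with aberrant copy number.
#' @param frac_prognostic Fraction of aberrant lncRNAs that are prognostic.
#' @param gamma Dosage exponent: expression mean scales as `(cn/2)^gamma`.
#'   `gamma = 0` decouples expression from copy number (null generator).
#' @param beta_surv Per-SD log-hazard of each prognostic lncRNA.
#' @param a0,a1 Dispersion-trend coefficients of the count model.
#' @param cn_probs Category probabilities over copy numbers 0:4 for aberrant
#'   features (must sum to 1).
#' @param baseline_hazard Baseline exponential hazard (per day).
#' @param censor_frac Target fraction of censored samples.
#' @param n_linked_pcg Correlated target PCGs generated per prognostic
#'   lncRNA.
#' @param pcg_noise_sd Gaussian noise SD on the latent log2 profile of
#'   linked PCGs (0.75 puts the latent correlation near 0.8).
#' @param seed Integer seed; generation is fully reproducible.
#' @return Named list classed `"SimulationConfig"`.
#' @export
sim_config <- function(n_samples = 300, n_lnc = 500, n_pcg = 2000,
                       frac_cnv_driven = 0.10, frac_prognostic = 0.30,
                       gamma = 1, beta_surv = 0.8,
                       a0 = 0.05, a1 = 3,
                       cn_probs = c(0.05, 0.20, 0.35, 0.25, 0.15),
                       baseline_hazard = 1 / 1000, censor_frac = 0.30,
                       n_linked_pcg = 5, pcg_noise_sd = 0.75,
                       seed = 1) {
  cfg <- list(n_samples = n_samples, n_lnc = n_lnc, n_pcg = n_pcg,
              frac_cnv_driven = frac_cnv_driven, frac_prognostic = frac_prognostic,
              gamma = gamma, beta_surv = beta_surv, a0 = a0, a1 = a1,
              cn_probs = cn_probs, baseline_hazard = baseline_hazard,
              censor_frac = censor_frac, n_linked_pcg = n_linked_pcg,
              pcg_noise_sd = pcg_noise_sd, seed = seed)
  fr <- c(frac_cnv_driven, frac_prognostic, censor_frac)
  if (any(fr < 0) || any(fr > 1)) stop("fractions must lie in [0, 1]", call. = FALSE)
  if (gamma < 0) stop("gamma must be non-negative", call. = FALSE)
  if (length(cn_probs) != 5L || abs(sum(cn_probs) - 1) > 1e-8 || any(cn_probs < 0)) {
    stop("cn_probs must be 5 non-negative probabilities over copy numbers 0:4 summing to 1",
         call. = FALSE)
  }
  if (n_samples < 20) stop("n_samples must be at least 20", call. = FALSE)
  if (a0 < 0 || a1 < 0 || baseline_hazard <= 0) {
    stop("dispersion coefficients must be non-negative and baseline_hazard positive",
         call. = FALSE)
  }
  structure(cfg, class = c("SimulationConfig", "list"))
}

#' Synthetic GTF annotation text
#'
#' Emits GENCODE-dialect `gene` records for `n_lnc` long non-coding and
#' `n_pcg` protein-coding genes on chr1-chr22, with non-overlapping 1-based
#' inclusive coordinates. All six lncRNA biotypes are used in rotation, so
#' every one appears once `n_lnc >= 6`.
#'
#' @param n_lnc,n_pcg Gene counts (>= 1 each).
#' @param seed Integer seed.
#' @return Character vector of GTF lines, with the matching annotation data
#'   frame attached as attribute `"annotation"`.
#' @export
fixture_gtf <- function(n_lnc, n_pcg, seed = 1) {
  if (n_lnc < 1 || n_pcg < 1) stop("n_lnc and n_pcg must be at least 1", call. = FALSE)
  set.seed(seed)
  lnc_bio <- c("lincRNA", "antisense", "sense_intronic", "sense_overlapping",
               "processed_transcript", "3prime_overlapping_ncRNA")
  ids <- c(sprintf("LNC%04d", seq_len(n_lnc)), sprintf("PCG%04d", seq_len(n_pcg)))
  biotype <- c(rep_len(lnc_bio, n_lnc), rep("protein_coding", n_pcg))
  n <- n_lnc + n_pcg
  chrom <- paste0("chr", sample(1:22, n, replace = TRUE))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  width <- sample(500:20000, n, replace = TRUE)
  gap <- sample(1000:50000, n, replace = TRUE)
  start <- integer(n); end <- integer(n)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    pos <- 1L
    for (i in idx) {
      start[i] <- pos + gap[i]
      end[i] <- start[i] + width[i] - 1L
      pos <- end[i]
    }
  }
  attrs <- sprintf('gene_id "%s"; gene_type "%s"; gene_name "%s";', ids, biotype, ids)
  lines <- sprintf("%s\tsynthetic\tgene\t%d\t%d\t.\t%s\t.\t%s",
                   chrom, start, end, strand, attrs)
  ann <- data.frame(gene_id = ids, original_id = ids, gene_name = ids,
                    biotype = biotype, gene_class = classify_biotype(biotype),
                    chrom = chrom, start = start, end = end, strand = strand,
                    stringsAsFactors = FALSE)
  class(ann) <- c("GeneAnnotation", "data.frame")
  structure(lines, annotation = ann)
}

#' Toy gene-set collection for offline enrichment
#'
#' Builds a GMT-style collection of random gene sets over the supplied
#' identifiers, optionally spiking one term with a given gene list, for
#' testing and demonstrating the over-representation stage without external
#' resources.
#'
#' @param gene_ids Candidate member genes.
#' @param n_terms Number of sets (default 20).
#' @param min_size,max_size Set-size range (defaults 5 and 50).
#' @param spike Optional character vector forming an extra term
#'   `"SPIKED_SET"`.
#' @param seed Integer seed.
#' @return A `"GeneSetCollection"` as returned by [read_gmt()].
#' @export
fixture_gmt <- function(gene_ids, n_terms = 20, min_size = 5, max_size = 50,
                        spike = NULL, seed = 1) {
  set.seed(seed)
  max_size <- min(max_size, length(gene_ids))
  sets <- lapply(seq_len(n_terms), function(i) {
    k <- sample(min_size:max_size, 1L)
    list(description = sprintf("synthetic term %d", i),
         genes = sample(gene_ids, k))
  })
  names(sets) <- sprintf("TERM_%02d", seq_len(n_terms))
  if (!is.null(spike)) {
    sets$SPIKED_SET <- list(description = "spiked term", genes = unique(spike))
  }
  class(sets) <- c("GeneSetCollection", "list")
  sets
}

#' Simulate a matched expression / CNV / clinical cohort
#'
#' Generates a cohort with known ground truth in the pipeline's own input
#' dialects. Aberrant lncRNAs draw integer copy-number states from
#' `cn_probs`; all other features are diploid. Counts are negative binomial
#' with mean `mu_g * (cn/2)^gamma * size_factor` and dispersion
#' `a1/mu + a0`. Prognostic lncRNAs act on an exponential hazard through
#' their latent (noise-free, z-scored) log2 expression, so recovery rates
#' reflect the screen's handling of count noise rather than generator
#' leakage. Linked target PCGs share their lncRNA's latent profile plus
#' Gaussian noise. Uniform censoring is tuned to the target fraction.
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory; when given, writes
#'   `expression.tsv`, `cnv.tsv`, `clinical.tsv`, `annotation.gtf` and
#'   `truth.json` (byte-identical across runs with the same config).
#' @return List classed `"SyntheticCohort"`: `expr` (raw_count
#'   [omics_matrix()], lncRNAs + PCGs), `cnv` (absolute_cn, lncRNAs),
#'   `clinical`, `annotation`, `gtf` (text lines), `truth` (list:
#'   `cnv_driven_ids`, `prognostic_ids`, `linked_pcg_map`, `aberrant_ids`),
#'   `config`, and `paths` when written.
#' @export
simulate_cohort <- function(config = sim_config(), dir = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  cfg <- config
  gtf <- fixture_gtf(cfg$n_lnc, cfg$n_pcg, seed = cfg$seed)
  ann <- attr(gtf, "annotation")
  lnc_ids <- ann$gene_id[ann$gene_class == "lncRNA"]
  pcg_ids <- ann$gene_id[ann$gene_class == "PCG"]

  set.seed(cfg$seed + 1L)
  n <- cfg$n_samples
  samples <- sprintf("S%04d", seq_len(n))

  sf <- exp(stats::rnorm(n, 0, 0.2))
  sf <- sf / exp(mean(log(sf)))

  n_aber <- round(cfg$frac_cnv_driven * cfg$n_lnc)
  aberrant <- sort(sample(lnc_ids, n_aber))
  n_prog <- round(cfg$frac_prognostic * n_aber)
  prognostic <- sort(sample(aberrant, n_prog))

  cnv <- matrix(2, nrow = cfg$n_lnc, ncol = n, dimnames = list(lnc_ids, samples))
  for (id in aberrant) {
    cnv[id, ] <- sample(0:4, n, replace = TRUE, prob = cfg$cn_probs)
  }

  mu_lnc <- stats::setNames(exp(stats::rnorm(cfg$n_lnc, log(100), 1)), lnc_ids)
  mu_pcg <- stats::setNames(exp(stats::rnorm(cfg$n_pcg, log(100), 1)), pcg_ids)

  nb_counts <- function(mu_mat, disp_vec) {
    k <- matrix(stats::rnbinom(length(mu_mat), mu = mu_mat,
                               size = rep(1 / disp_vec, ncol(mu_mat))),
                nrow = nrow(mu_mat), dimnames = dimnames(mu_mat))
    k
  }

  # lncRNA counts: dosage scaling (cn/2)^gamma on the mean
  dosage <- (cnv / 2)^cfg$gamma
  mu_mat_lnc <- (mu_lnc * dosage) * rep(sf, each = cfg$n_lnc)
  disp_lnc <- cfg$a1 / mu_lnc + cfg$a0
  counts_lnc <- nb_counts(mu_mat_lnc, disp_lnc)

  # latent (noise-free) per-sample log2 profile of each prognostic lncRNA,
  # z-scored; copy number 0 floored at 0.5 to keep the latent finite
  latent_z <- matrix(0, nrow = length(prognostic), ncol = n,
                     dimnames = list(prognostic, samples))
  for (id in prognostic) {
    l <- log2(mu_lnc[id] * (pmax(cnv[id, ], 0.5) / 2)^cfg$gamma)
    latent_z[id, ] <- if (stats::sd(l) > 0) as.numeric(base::scale(l)) else 0
  }

  # PCG counts; linked targets inherit their lncRNA's latent profile + noise
  linked_map <- list()
  log2_mu_pcg <- matrix(log2(mu_pcg), nrow = cfg$n_pcg, ncol = n,
                        dimnames = list(pcg_ids, samples))
  if (length(prognostic) > 0L && cfg$n_linked_pcg > 0L) {
    pool <- pcg_ids
    for (id in prognostic) {
      k <- min(cfg$n_linked_pcg, length(pool))
      if (k == 0L) break
      tgt <- sort(sample(pool, k))
      pool <- setdiff(pool, tgt)
      linked_map[[id]] <- tgt
      for (p in tgt) {
        log2_mu_pcg[p, ] <- log2(mu_pcg[p]) + latent_z[id, ] +
          stats::rnorm(n, 0, cfg$pcg_noise_sd)
      }
    }
  }
  mu_mat_pcg <- 2^log2_mu_pcg * rep(sf, each = cfg$n_pcg)
  disp_pcg <- cfg$a1 / mu_pcg + cfg$a0
  counts_pcg <- nb_counts(mu_mat_pcg, disp_pcg)

  # survival: exponential hazard in the latent profiles, uniform censoring
  lp <- if (length(prognostic) > 0L && cfg$beta_surv != 0) {
    as.numeric(cfg$beta_surv * colSums(latent_z))
  } else rep(0, n)
  hazard <- cfg$baseline_hazard * exp(lp)
  T_event <- stats::rexp(n, rate = hazard)
  if (cfg$censor_frac > 0) {
    f <- function(cmax) mean(pmin(T_event / cmax, 1)) - cfg$censor_frac
    cmax <- stats::uniroot(f, interval = c(min(T_event) / 2, max(T_event) * 100),
                           extendInt = "downX", tol = 1e-8)$root
    C <- stats::runif(n, 0, cmax)
    status <- as.integer(T_event <= C)
    time <- pmin(T_event, C)
  } else {
    status <- rep(1L, n)
    time <- T_event
  }
  time <- pmax(time, 1e-3)
  clinical <- data.frame(sample_id = samples, survival_time = time,
                         status = status,
                         age = round(stats::runif(n, 35, 85)),
                         stringsAsFactors = FALSE)
  class(clinical) <- c("ClinicalTable", "data.frame")

  expr <- omics_matrix(rbind(counts_lnc, counts_pcg), "raw_count")
  cnv_m <- omics_matrix(cnv, "absolute_cn")
  truth <- list(
    aberrant_ids = aberrant,
    cnv_driven_ids = if (cfg$gamma > 0) aberrant else character(0),
    prognostic_ids = if (cfg$beta_surv != 0) prognostic else character(0),
    linked_pcg_map = linked_map
  )
  out <- structure(list(expr = expr, cnv = cnv_m, clinical = clinical,
                        annotation = ann, gtf = as.character(gtf),
                        truth = truth, config = cfg),
                   class = "SyntheticCohort")
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- c(
      expression = file.path(dir, "expression.tsv"),
      cnv = file.path(dir, "cnv.tsv"),
      clinical = file.path(dir, "clinical.tsv"),
      gtf = file.path(dir, "annotation.gtf"),
      truth = file.path(dir, "truth.json")
    )
    .write_matrix_tsv(unclass(expr), paths[["expression"]], id_col = "gene_id")
    .write_matrix_tsv(unclass(cnv_m), paths[["cnv"]], id_col = "feature_id")
    clin_out <- clinical
    colnames(clin_out)[1:3] <- c("Sample_ID", "Survival_Time", "Status")
    .write_tsv(clin_out, paths[["clinical"]])
    writeLines(as.character(gtf), paths[["gtf"]])
    jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    out$paths <- paths
  }
  out
}

#' Global-null synthetic cohort
#'
#' The generator used for type-I-error calibration: copy-number aberrations
#' are retained but completely decoupled from expression (`gamma = 0`) and
#' survival carries no expression effect (`beta_surv = 0`), so the Cox and
#' Kruskal-Wallis screens test independent data aspects and should reject at
#' their nominal levels.
#'
#' @param config A [sim_config()]; its `gamma` and `beta_surv` are overridden.
#' @param dir Optional output directory, as in [simulate_cohort()].
#' @return A `"SyntheticCohort"` (see [simulate_cohort()]).
#' @export
make_null_cohort <- function(config = sim_config(), dir = NULL) {
  cfg <- config
  cfg$gamma <- 0
  cfg$beta_surv <- 0
  simulate_cohort(cfg, dir = dir)
}
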