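#' Protein-coding genes correlated with the signature lncRNAs
#'
#' Pearson correlation between each signature (pr-)lncRNA and every
#' protein-coding gene on normalized expression. A PCG is selected when its
#' maximum |r| across the signature reaches `r_min` (default 0.5), or —
#' alternatively — when it is among the `top_k` strongest correlates of any
#' signature lncRNA. Constant PCGs are flagged and never selected.
#'
#' @param cohort A `"MatchedCohort"`.
#' @param pr_lncRNAs Non-empty character vector of signature lncRNA ids.
#' @param r_min Absolute-correlation selection threshold (default 0.5).
#' @param top_k If non-NULL, select the top_k PCGs by |r| per lncRNA instead
#'   of thresholding.
#' @return List classed `"TargetGeneTable"`: `pairs` (lncRNA_id, pcg_id, r,
#'   p), `pcgs` (pcg_id, max_abs_r, selected, flag), `selected` (character
#'   vector).
#' @export
correlate_targets <- function(cohort, pr_lncRNAs, r_min = 0.5, top_k = NULL) {
  if (length(pr_lncRNAs) < 1L) stop("no signature lncRNAs supplied", call. = FALSE)
  if (nrow(cohort$expr_pcg) < 1L) stop("cohort has no PCG expression", call. = FALSE)
  pr_lncRNAs <- intersect(pr_lncRNAs, rownames(cohort$expr_lnc))
  E <- unclass(cohort$expr_lnc)[pr_lncRNAs, , drop = FALSE]
  P <- unclass(cohort$expr_pcg)
  n <- ncol(P)
  const <- apply(P, 1L, function(r) stats::sd(r) == 0)
  R <- suppressWarnings(stats::cor(t(E), t(P)))  # lnc x pcg; NA for constants
  tstat <- R * sqrt((n - 2) / pmax(1 - R^2, .Machine$double.eps))
  Pv <- 2 * stats::pt(-abs(tstat), df = n - 2)
  Pv[abs(R) == 1] <- 0
  pairs <- data.frame(
    lncRNA_id = rep(rownames(R), times = ncol(R)),
    pcg_id = rep(colnames(R), each = nrow(R)),
    r = as.numeric(R), p = as.numeric(Pv),
    stringsAsFactors = FALSE
  )
  max_abs <- apply(abs(R), 2L, function(col) if (all(is.na(col))) NA_real_ else max(col, na.rm = TRUE))
  if (is.null(top_k)) {
    selected <- !is.na(max_abs) & max_abs >= r_min
  } else {
    selected <- rep(FALSE, ncol(R))
    names(selected) <- colnames(R)
    for (i in seq_len(nrow(R))) {
      ord <- order(abs(R[i, ]), decreasing = TRUE, na.last = NA)
      selected[ord[seq_len(min(top_k, length(ord)))]] <- TRUE
    }
  }
  selected[const] <- FALSE
  pcgs <- data.frame(pcg_id = colnames(R), max_abs_r = max_abs,
                     selected = selected,
                     flag = ifelse(const, "degenerate", "ok"),
                     stringsAsFactors = FALSE)
  rownames(pcgs) <- NULL
  if (!any(selected)) {
    stop("no PCG selected at r_min = ", r_min, "; consider relaxing the threshold",
         call. = FALSE)
  }
  structure(list(pairs = pairs, pcgs = pcgs, selected = pcgs$pcg_id[pcgs$selected]),
            class = "TargetGeneTable")
}

#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability `P(X >= k)` for X hypergeometric with
#' `universe_size` balls of which `set_in_universe` are white and
#' `selected_size` are drawn. `k = 0` gives p = 1.
#'
#' @param k Overlap between the selected genes and the set.
#' @param selected_size Number of selected genes in the universe.
#' @param set_in_universe Size of the gene set restricted to the universe.
#' @param universe_size Universe size.
#' @return The upper-tail p-value.
#' @export
hypergeom_test <- function(k, selected_size, set_in_universe, universe_size) {
  if (any(c(k, selected_size, set_in_universe, universe_size) < 0) ||
      k > min(selected_size, set_in_universe) ||
      selected_size > universe_size || set_in_universe > universe_size) {
    stop("inconsistent hypergeometric counts", call. = FALSE)
  }
  stats::phyper(k - 1, set_in_universe, universe_size - set_in_universe,
                selected_size, lower.tail = FALSE)
}

#' Over-representation analysis of selected target genes
#'
#' Tests each term of each collection for over-representation of the
#' selected PCGs in the cohort universe (all filtered cohort PCGs), with
#' Benjamini-Hochberg adjustment within each collection. Gene symbols are
#' matched case-insensitively; terms with no member in the universe are
#' skipped.
#'
#' @param targets A `"TargetGeneTable"` from [correlate_targets()], or a
#'   character vector of selected genes.
#' @param collections A `"GeneSetCollection"` or named list of them.
#' @param universe Character vector of universe genes; defaults to all PCGs
#'   in `targets`.
#' @return Data frame sorted by p within collection: `collection`, `term`,
#'   `overlap`, `set_size`, `set_in_universe`, `selected_size`,
#'   `universe_size`, `p`, `fdr`, `genes` (';'-joined overlap).
#' @export
enrich <- function(targets, collections, universe = NULL) {
  if (inherits(targets, "TargetGeneTable")) {
    selected <- targets$selected
    if (is.null(universe)) universe <- targets$pcgs$pcg_id
  } else {
    selected <- as.character(targets)
    if (is.null(universe)) stop("universe required when targets is a plain vector",
                                call. = FALSE)
  }
  if (inherits(collections, "GeneSetCollection")) {
    collections <- list(collection = collections)
  }
  if (length(collections) < 1L) stop("at least one gene-set collection required",
                                     call. = FALSE)
  uni_u <- toupper(unique(universe))
  sel_u <- toupper(unique(selected))
  sel_u <- intersect(sel_u, uni_u)
  out <- list()
  for (cn in names(collections)) {
    coll <- collections[[cn]]
    unmatched <- 0L
    rows <- list()
    for (term in names(coll)) {
      genes <- toupper(coll[[term]]$genes)
      unmatched <- unmatched + sum(!genes %in% uni_u)
      in_uni <- intersect(genes, uni_u)
      if (length(in_uni) == 0L) next
      ov <- intersect(in_uni, sel_u)
      p <- hypergeom_test(length(ov), length(sel_u), length(in_uni), length(uni_u))
      rows[[term]] <- data.frame(
        collection = cn, term = term, overlap = length(ov),
        set_size = length(genes), set_in_universe = length(in_uni),
        selected_size = length(sel_u), universe_size = length(uni_u),
        p = p, genes = paste(sort(ov), collapse = ";"),
        stringsAsFactors = FALSE
      )
    }
    if (unmatched > 0L) {
      message(sprintf("enrich: %d member symbol(s) of collection '%s' not in the universe",
                      unmatched, cn))
    }
    if (length(rows) == 0L) next
    tab <- do.call(rbind, rows)
    tab$fdr <- stats::p.adjust(tab$p, method = "BH")
    tab <- tab[order(tab$p), , drop = FALSE]
    out[[cn]] <- tab
  }
  if (length(out) == 0L) stop("no term overlaps the universe", call. = FALSE)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("collection", "term", "overlap", "set_size", "set_in_universe",
          "selected_size", "universe_size", "p", "fdr", "genes")]
}
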