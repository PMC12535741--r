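#' @importFrom data.table fread
NULL

# Tokens treated as missing in every tab-delimited input.
.na_tokens <- c("", "NA", "NaN", "null")

# Read a features-x-samples tab-delimited matrix: first row sample IDs,
# first column feature IDs. Returns list(ids, values) before any collapsing.
.read_value_table <- function(path, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path, call. = FALSE)
  if (file.size(path) == 0) stop(what, " file is empty: ", path, call. = FALSE)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          na.strings = .na_tokens, colClasses = list(character = 1),
                          showProgress = FALSE)
  if (nrow(dt) == 0L || ncol(dt) < 2L) {
    stop(what, " file is empty or has no sample columns: ", path, call. = FALSE)
  }
  ids <- trimws(dt[[1L]])
  samples <- trimws(colnames(dt)[-1L])
  if (anyDuplicated(samples)) {
    stop(what, ": duplicate sample identifiers: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "), call. = FALSE)
  }
  vals <- as.matrix(dt[, -1L, drop = FALSE])
  if (is.character(vals)) {
    num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
    bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
    if (nrow(bad) > 0L) {
      stop(sprintf("%s: non-numeric value '%s' at feature '%s', sample '%s'",
                   what, vals[bad[1L, 1L], bad[1L, 2L]],
                   ids[bad[1L, 1L]], samples[bad[1L, 2L]]), call. = FALSE)
    }
    vals <- num
  }
  storage.mode(vals) <- "double"
  dimnames(vals) <- list(ids, samples)
  vals
}

#' Read a raw expression count matrix
#'
#' Reads a tab-delimited genes-x-samples count table (first row sample IDs,
#' first column gene IDs). Gene identifier version suffixes are stripped for
#' matching across sources; the originals are kept in the `original_ids`
#' attribute. Duplicate gene rows (including duplicates created by version
#' stripping) are collapsed by summation, the natural re-aggregation for
#' fragment counts.
#'
#' @param path Path to the tab-delimited count file.
#' @return An [omics_matrix()] with `value_kind = "raw_count"`.
#' @export
read_expression <- function(path) {
  vals <- .read_value_table(path, "expression")
  if (any(vals[!is.na(vals)] < 0)) {
    stop("expression: negative count values present", call. = FALSE)
  }
  original <- rownames(vals)
  stripped <- strip_gene_version(original)
  if (anyDuplicated(stripped)) {
    n_dup <- sum(duplicated(stripped))
    warning(sprintf("expression: %d duplicate gene row(s) collapsed by summation", n_dup),
            call. = FALSE)
    keep_order <- unique(stripped)
    vals <- rowsum(vals, group = stripped, reorder = FALSE)
    vals <- vals[keep_order, , drop = FALSE]
    original <- original[!duplicated(stripped)]
  } else {
    rownames(vals) <- stripped
  }
  rownames(vals) <- unique(stripped)
  out <- omics_matrix(vals, "raw_count")
  attr(out, "original_ids") <- stats::setNames(original, rownames(vals))
  out
}

#' Read an absolute copy-number matrix
#'
#' Same dialect as [read_expression()]; cells are absolute copy numbers
#' (2 = diploid). Fractional calls are rounded half-to-even with a warning;
#' duplicate feature rows keep the first occurrence (summing copy-number
#' states is not meaningful).
#'
#' @param path Path to the tab-delimited CNV file.
#' @return An [omics_matrix()] with `value_kind = "absolute_cn"`.
#' @export
read_cnv <- function(path) {
  vals <- .read_value_table(path, "cnv")
  v <- vals[!is.na(vals)]
  if (any(v < 0)) stop("cnv: negative copy-number values present", call. = FALSE)
  if (any(v != round(v))) {
    warning(sprintf("cnv: %d non-integer copy number(s) rounded half-to-even",
                    sum(v != round(v))), call. = FALSE)
    vals[] <- round(vals)
  }
  original <- rownames(vals)
  stripped <- strip_gene_version(original)
  if (anyDuplicated(stripped)) {
    warning(sprintf("cnv: %d duplicate feature row(s); keeping first occurrence",
                    sum(duplicated(stripped))), call. = FALSE)
    keep <- !duplicated(stripped)
    vals <- vals[keep, , drop = FALSE]
    original <- original[keep]
    stripped <- stripped[keep]
  }
  rownames(vals) <- stripped
  out <- omics_matrix(vals, "absolute_cn")
  attr(out, "original_ids") <- stats::setNames(original, stripped)
  out
}

#' Read a clinical survival table
#'
#' Requires columns `Sample_ID`, `Survival_Time` and `Status` (matched
#' case-insensitively after trimming). `Status` must be 0 (censored) or
#' 1 (event); survival times must be strictly positive. Rows with missing
#' required values are dropped with a warning; extra columns are carried
#' through untouched.
#'
#' @param path Path to the tab-delimited clinical file.
#' @return A data frame with columns `sample_id`, `survival_time`, `status`
#'   plus any extra columns, classed `"ClinicalTable"`.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop("clinical file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          na.strings = .na_tokens, showProgress = FALSE)
  if (nrow(dt) == 0L) stop("clinical file is empty: ", path, call. = FALSE)
  nm <- tolower(trimws(colnames(dt)))
  required <- c(sample_id = "sample_id", survival_time = "survival_time", status = "status")
  idx <- match(required, nm)
  if (anyNA(idx)) {
    stop("clinical: missing required column(s): ",
         paste(names(required)[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  out <- data.frame(
    sample_id = as.character(dt[[idx[1L]]]),
    survival_time = suppressWarnings(as.numeric(dt[[idx[2L]]])),
    status = suppressWarnings(as.numeric(dt[[idx[3L]]])),
    stringsAsFactors = FALSE
  )
  extras <- dt[, -idx, drop = FALSE]
  if (ncol(extras) > 0L) out <- cbind(out, extras)
  miss <- is.na(out$sample_id) | is.na(out$survival_time) | is.na(out$status)
  if (any(miss)) {
    warning(sprintf("clinical: %d row(s) with missing required values dropped", sum(miss)),
            call. = FALSE)
    out <- out[!miss, , drop = FALSE]
  }
  if (nrow(out) == 0L) stop("clinical: no complete rows", call. = FALSE)
  if (!all(out$status %in% c(0, 1))) {
    stop("clinical: Status must be 0 or 1; found: ",
         paste(unique(out$status[!out$status %in% c(0, 1)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(out$survival_time <= 0)) {
    stop("clinical: Survival_Time must be strictly positive", call. = FALSE)
  }
  if (anyDuplicated(out$sample_id)) {
    stop("clinical: duplicate Sample_ID values", call. = FALSE)
  }
  rownames(out) <- NULL
  class(out) <- c("ClinicalTable", "data.frame")
  out
}

#' Read gene annotation from a GTF file
#'
#' Parses GENCODE-dialect GTF, keeps `gene` records only, and classifies each
#' gene as lncRNA, protein-coding (PCG) or other from its biotype (see
#' [classify_biotype()]). Coordinates are kept 1-based inclusive as in the
#' file. Identifier version suffixes are stripped for matching.
#'
#' @param path Path to a GTF file.
#' @return A data frame (one row per gene) with columns `gene_id`,
#'   `original_id`, `gene_name`, `biotype`, `gene_class`, `chrom`, `start`,
#'   `end`, `strand`, classed `"GeneAnnotation"`.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  if (!"type" %in% colnames(df)) stop("GTF: no feature type column parsed", call. = FALSE)
  df <- df[df$type == "gene", , drop = FALSE]
  if (nrow(df) == 0L) stop("GTF: no gene records found", call. = FALSE)
  if (!"gene_id" %in% colnames(df)) stop("GTF: gene records lack gene_id", call. = FALSE)
  biotype <- if ("gene_type" %in% colnames(df)) df$gene_type
             else if ("gene_biotype" %in% colnames(df)) df$gene_biotype
             else NA_character_
  bad <- is.na(df$gene_id) | is.na(biotype)
  if (any(bad)) {
    warning(sprintf("GTF: %d gene record(s) with missing gene_id/biotype skipped", sum(bad)),
            call. = FALSE)
    df <- df[!bad, , drop = FALSE]
    biotype <- biotype[!bad]
  }
  if (nrow(df) == 0L) stop("GTF: no usable gene records", call. = FALSE)
  ann <- data.frame(
    gene_id = strip_gene_version(df$gene_id),
    original_id = df$gene_id,
    gene_name = if ("gene_name" %in% colnames(df)) df$gene_name else df$gene_id,
    biotype = biotype,
    gene_class = classify_biotype(biotype),
    chrom = as.character(df$seqnames),
    start = df$start,
    end = df$end,
    strand = as.character(df$strand),
    stringsAsFactors = FALSE
  )
  ann <- ann[!duplicated(ann$gene_id), , drop = FALSE]
  rownames(ann) <- NULL
  class(ann) <- c("GeneAnnotation", "data.frame")
  ann
}

#' Read gene-set collections in GMT format
#'
#' Standard GMT: one set per line, `term <TAB> description <TAB> gene1 ...`.
#' Lines with fewer than three fields are skipped with a warning; member
#' symbols are deduplicated within each set.
#'
#' @param path Path to a GMT file.
#' @return A named list classed `"GeneSetCollection"`; each element is a list
#'   with `description` and character vector `genes`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("GMT file is empty: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(fields, length, 1L) >= 3L
  if (any(!ok)) {
    warning(sprintf("GMT: %d line(s) with fewer than 3 fields skipped", sum(!ok)),
            call. = FALSE)
  }
  fields <- fields[ok]
  if (length(fields) == 0L) stop("GMT: no valid gene sets", call. = FALSE)
  sets <- lapply(fields, function(f) {
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    list(description = f[2L], genes = genes)
  })
  names(sets) <- vapply(fields, `[[`, "", 1L)
  sets <- sets[vapply(sets, function(s) length(s$genes) > 0L, TRUE)]
  if (length(sets) == 0L) stop("GMT: no non-empty gene sets", call. = FALSE)
  class(sets) <- c("GeneSetCollection", "list")
  sets
}

# Deterministic TSV writer: doubles serialized with %.17g so values
# round-trip exactly and repeated runs are byte-identical.
.write_tsv <- function(df, path) {
  df <- as.data.frame(df)
  fmt <- function(col) {
    if (is.double(col)) {
      out <- sprintf("%.17g", col)
      out[is.na(col)] <- "NA"
      out
    } else as.character(col)
  }
  cells <- vapply(df, fmt, character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
  if (nrow(df) == 0L) cells <- matrix(character(0), ncol = ncol(df))
  lines <- c(paste(colnames(df), collapse = "\t"),
             if (nrow(df) > 0L) apply(cells, 1L, paste, collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

.write_matrix_tsv <- function(mat, path, id_col = "feature_id") {
  df <- data.frame(id = rownames(mat), as.data.frame(unclass(mat)[, , drop = FALSE]),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_col
  .write_tsv(df, path)
}

#' Write pipeline result artifacts
#'
#' Writes whichever stage outputs are present as tab-delimited tables plus a
#' JSON run summary (config, seed, per-stage counts), and returns the file
#' manifest. Re-running with the same inputs produces byte-identical files.
#'
#' @param dir Output directory (created if needed).
#' @param results Named list of stage outputs; recognized names:
#'   `screen`, `correlation`, `null_summary`, `histogram`, `violin`, `risk`,
#'   `km`, `targets`, `enrichment` (data frames), `evaluation` (list),
#'   `counts` (named list of attrition counts).
#' @param config Named list echoed into the run summary.
#' @param seed Integer seed echoed into the run summary.
#' @return Data frame manifest with columns `name` and `path`.
#' @export
write_results <- function(dir, results, config = list(), seed = NULL) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(dir)) stop("cannot create output directory: ", dir, call. = FALSE)
  }
  manifest <- data.frame(name = character(0), path = character(0),
                         stringsAsFactors = FALSE)
  emit <- function(name, writer) {
    path <- file.path(dir, name)
    writer(path)
    manifest <<- rbind(manifest, data.frame(name = name, path = path,
                                            stringsAsFactors = FALSE))
  }
  tables <- c("screen", "correlation", "null_summary", "histogram", "violin",
              "risk", "km", "targets", "enrichment")
  for (nm in tables) {
    if (!is.null(results[[nm]])) {
      tab <- results[[nm]]
      emit(paste0(nm, ".tsv"), function(p) .write_tsv(tab, p))
    }
  }
  summary <- list(
    package = "lnccnv",
    version = as.character(utils::packageVersion("lnccnv")),
    seed = seed,
    config = config,
    counts = results$counts %||% list(),
    evaluation = results$evaluation %||% list()
  )
  emit("run_summary.json", function(p) {
    jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })
  manifest
}

`%||%` <- function(a, b) if (is.null(a)) b else a
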