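#' Construct an omics value matrix
#'
#' A thin, validated container used throughout the pipeline for raw counts,
#' normalized expression and absolute copy-number states: a numeric matrix
#' with unique feature row names, unique sample column names and a
#' `value_kind` attribute recording what the cells mean.
#'
#' @param values Numeric matrix; rows are features, columns are samples. Row
#'   and column names are required and must be unique.
#' @param value_kind One of `"raw_count"`, `"normalized"`, `"absolute_cn"`.
#'   Raw counts must be finite and non-negative; absolute copy numbers must
#'   additionally be whole numbers. Missing values (`NA`) are permitted and
#'   handled pairwise downstream.
#' @return The matrix with class `"OmicsMatrix"` and attribute `value_kind`.
#' @export
omics_matrix <- function(values, value_kind = c("raw_count", "normalized", "absolute_cn")) {
  value_kind <- match.arg(value_kind)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have feature row names and sample column names", call. = FALSE)
  }
  x <- structure(values, value_kind = value_kind,
                 class = c("OmicsMatrix", class(values)))
  validate_omics(x)
}

#' Validate an OmicsMatrix
#'
#' Checks the container invariants: unique feature and sample identifiers,
#' and value constraints appropriate to the declared `value_kind`.
#'
#' @param x An object created by [omics_matrix()].
#' @return `x`, invisibly unchanged, or an error describing the violation.
#' @export
validate_omics <- function(x) {
  kind <- value_kind(x)
  if (anyDuplicated(rownames(x))) {
    stop("duplicate feature identifiers: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(x))) {
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "),
         call. = FALSE)
  }
  v <- x[!is.na(x)]
  if (any(!is.finite(v))) stop("non-finite values present", call. = FALSE)
  if (kind %in% c("raw_count", "absolute_cn") && any(v < 0)) {
    stop(kind, " values must be non-negative", call. = FALSE)
  }
  if (kind == "absolute_cn" && any(v != round(v))) {
    stop("absolute_cn values must be integers", call. = FALSE)
  }
  x
}

#' Value kind of an OmicsMatrix
#'
#' @param x An `OmicsMatrix`.
#' @return `"raw_count"`, `"normalized"` or `"absolute_cn"`.
#' @export
value_kind <- function(x) {
  k <- attr(x, "value_kind")
  if (is.null(k)) stop("not an OmicsMatrix: missing value_kind", call. = FALSE)
  k
}

# Keep class/attributes through subsetting so cohort slices stay OmicsMatrix.
#' @export
`[.OmicsMatrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) {
    attr(out, "value_kind") <- attr(x, "value_kind")
    class(out) <- class(x)
  }
  out
}

#' Strip Ensembl-style version suffixes from gene identifiers
#'
#' Expression, CNV and annotation sources frequently disagree on the version
#' suffix of the same gene (`ENSG00000123456.12` vs `.9`); matching is done on
#' the unversioned identifier while the original is retained for reporting.
#'
#' @param ids Character vector of gene identifiers.
#' @return Identifiers with a trailing `.<digits>` removed.
#' @export
strip_gene_version <- function(ids) sub("\\.[0-9]+$", "", ids)
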