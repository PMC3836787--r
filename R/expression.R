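#' Expression matrix container
#'
#' An `expr_mat` holds a genes-by-samples matrix of expression intensities
#' together with an optional sample-to-group mapping and a flag recording
#' whether values are on the linear or the log2 scale. It is the input type
#' of the correlation/network stage.
#'
#' @param values Numeric matrix, genes in rows (unique, non-empty rownames),
#'   samples in columns (unique colnames).
#' @param groups Optional named character vector mapping every sample id to a
#'   group label (e.g. phenotype), or `NULL`.
#' @param scale Either `"linear"` or `"log2"`; declares the scale of `values`.
#'   Fold changes are always computed on the linear scale, so log2 input is
#'   exponentiated first.
#' @param allow_na Logical; permit missing values (they must then be removed
#'   with [clean_expression()] before correlation).
#' @return An object of class `expr_mat`.
#' @export
expr_mat <- function(values, groups = NULL, scale = c("linear", "log2"),
                     allow_na = FALSE) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (genes x samples)", call. = FALSE)
  }
  gid <- rownames(values)
  sid <- colnames(values)
  if (is.null(gid) || any(!nzchar(gid))) {
    stop("gene ids (rownames) must be present and non-empty", call. = FALSE)
  }
  if (anyDuplicated(gid)) {
    stop("duplicate gene id: ", gid[duplicated(gid)][1L], call. = FALSE)
  }
  if (is.null(sid) || anyDuplicated(sid)) {
    stop("sample ids (colnames) must be present and unique", call. = FALSE)
  }
  if (!allow_na && anyNA(values)) {
    stop("expression matrix contains missing values; pass allow_na = TRUE ",
         "and run clean_expression()", call. = FALSE)
  }
  if (!is.null(groups)) {
    groups <- validate_groups(groups, sid)
  }
  structure(list(values = values, groups = groups, scale = scale),
            class = "expr_mat")
}

validate_groups <- function(groups, sample_ids) {
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stop("`groups` must be a named vector (names = sample ids)", call. = FALSE)
  }
  unknown <- setdiff(names(groups), sample_ids)
  if (length(unknown)) {
    stop("group file references unknown sample: ", unknown[1L], call. = FALSE)
  }
  missing <- setdiff(sample_ids, names(groups))
  if (length(missing)) {
    stop("sample without group label: ", missing[1L], call. = FALSE)
  }
  as.character(groups)[match(sample_ids, names(groups))] |>
    setNames(sample_ids)
}

#' @export
print.expr_mat <- function(x, ...) {
  cat(sprintf("<expr_mat> %d genes x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale))
  if (!is.null(x$groups)) {
    tab <- table(x$groups)
    cat("groups:", paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
                         collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.expr_mat <- function(x) dim(x$values)

#' Read an expression matrix from tab-separated text
#'
#' Expects a header row of sample ids and a first column of gene ids, with a
#' numeric body. Any cell that does not parse as a finite number (including a
#' literal `"NA"`, unless listed in `na`) is a hard error reporting its row
#' and column within the data body.
#'
#' @param path Path to the TSV expression file.
#' @param group_path Optional path to a two-column TSV `sample_id<TAB>group`
#'   (no header).
#' @param scale Scale flag recorded on the result, `"linear"` or `"log2"`.
#' @param na Character vector of cell values to read as missing (default:
#'   none — missing markers are an error). If used, clean the matrix with
#'   [clean_expression()] before computing correlations.
#' @return An [expr_mat()].
#' @export
read_expression <- function(path, group_path = NULL,
                            scale = c("linear", "log2"), na = character()) {
  scale <- match.arg(scale)
  raw <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                    check.names = FALSE, quote = "", comment.char = "")
  if (ncol(raw) < 2L) stop("expression file needs gene ids plus >=1 sample column",
                           call. = FALSE)
  gid <- raw[[1L]]
  if (anyDuplicated(gid)) {
    stop("duplicate gene id: ", gid[duplicated(gid)][1L], call. = FALSE)
  }
  body <- as.matrix(raw[, -1L, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  is_na_marker <- array(body %in% na, dim = dim(body))
  bad <- which(is.na(vals) & !is_na_marker, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric cell '%s' at row %d, column %d",
                 body[bad[1L, 1L], bad[1L, 2L]], bad[1L, 1L], bad[1L, 2L]),
         call. = FALSE)
  }
  dimnames(vals) <- list(gid, colnames(raw)[-1L])
  groups <- if (!is.null(group_path)) read_groups(group_path)
  expr_mat(vals, groups = groups, scale = scale, allow_na = TRUE)
}

#' Read a sample-to-group mapping
#'
#' @param path Two-column TSV `sample_id<TAB>group`, no header.
#' @return Named character vector (names = sample ids).
#' @export
read_groups <- function(path) {
  g <- read.delim(path, header = FALSE, sep = "\t", colClasses = "character",
                  quote = "", comment.char = "")
  if (ncol(g) != 2L) stop("group file must have exactly two columns", call. = FALSE)
  setNames(g[[2L]], g[[1L]])
}

#' Write an expression matrix as tab-separated text
#'
#' Inverse of [read_expression()]: header row of sample ids, first column of
#' gene ids. Finite decimal inputs round-trip bit-identically.
#'
#' @param x An [expr_mat()].
#' @param path Output file path.
#' @param group_path Optional path for the group mapping TSV.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, group_path = NULL) {
  stopifnot(inherits(x, "expr_mat"))
  df <- data.frame(gene_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(group_path) && !is.null(x$groups)) {
    write.table(data.frame(names(x$groups), unname(x$groups)), group_path,
                sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Remove or reject missing values
#'
#' With `policy = "drop_gene"`, every gene containing at least one missing
#' value is removed (a message reports how many); with `policy = "error"`,
#' any missing value is a hard error. The result never contains `NA`.
#'
#' @param x An [expr_mat()].
#' @param policy `"drop_gene"` (default) or `"error"`.
#' @return A complete [expr_mat()].
#' @export
clean_expression <- function(x, policy = c("drop_gene", "error")) {
  stopifnot(inherits(x, "expr_mat"))
  policy <- match.arg(policy)
  bad <- rowSums(is.na(x$values)) > 0L
  if (!any(bad)) return(x)
  if (policy == "error") {
    stop("missing values present in ", sum(bad), " gene(s), e.g. ",
         rownames(x$values)[bad][1L], call. = FALSE)
  }
  message("clean_expression: dropped ", sum(bad), " gene(s) with missing values")
  expr_mat(x$values[!bad, , drop = FALSE], groups = x$groups, scale = x$scale)
}

#' Select genes by fold change between two groups
#'
#' Computes, per gene, the ratio of arithmetic group means on the linear
#' scale (log2 input is exponentiated first) and keeps genes with
#' `mean(group_a) / mean(group_b) >= min_fold`. The conventional cut-off for
#' calling a gene up-regulated in `group_a` is a fold of 3.0.
#'
#' @param x An [expr_mat()] carrying a group mapping.
#' @param group_a,group_b Group labels; the fold is `mean_a / mean_b`.
#' @param min_fold Positive fold-change threshold (default 3.0).
#' @return A tibble with columns `gene_id`, `mean_a`, `mean_b`, `fold_change`
#'   for the passing genes, in input gene order.
#' @export
fold_change_filter <- function(x, group_a, group_b, min_fold = 3.0) {
  stopifnot(inherits(x, "expr_mat"))
  if (is.null(x$groups)) stop("expression matrix carries no group mapping", call. = FALSE)
  if (!is.numeric(min_fold) || min_fold <= 0) {
    stop("`min_fold` must be a positive number", call. = FALSE)
  }
  for (g in c(group_a, group_b)) {
    if (!g %in% x$groups) stop("unknown group label: ", g, call. = FALSE)
  }
  v <- if (x$scale == "log2") 2^x$values else x$values
  ma <- rowMeans(v[, x$groups == group_a, drop = FALSE])
  mb <- rowMeans(v[, x$groups == group_b, drop = FALSE])
  nonpos <- mb <= 0
  if (any(nonpos)) {
    warning(sum(nonpos), " gene(s) skipped: non-positive mean in group '",
            group_b, "'", call. = FALSE)
  }
  fold <- ifelse(nonpos, NA_real_, ma / mb)
  keep <- !nonpos & fold >= min_fold
  tibble(gene_id = rownames(x$values)[keep],
         mean_a = unname(ma[keep]), mean_b = unname(mb[keep]),
         fold_change = unname(fold[keep]))
}
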