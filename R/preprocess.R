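#' Log2-transform a copy-number matrix
#'
#' Applies \code{log2} entrywise and replaces every non-finite result
#' (\code{NaN} or infinities, e.g. from zero copy number) with 0, so that
#' homozygous deletions do not inject non-finite values into training.
#'
#' @param x Numeric cells x bins matrix (or data frame) of non-negative
#'   copy numbers; rows are cells.
#' @return A numeric matrix of the same shape with a `transform_log`
#'   attribute recording the step.
#' @examples
#' log2_transform_cn(matrix(c(1, 2, 4, 8), 2, 2))
#' @export
log2_transform_cn <- function(x) {
  x <- as_cell_matrix(x, "copy-number matrix")
  neg <- which(x < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    stop(sprintf("negative copy number at cell '%s', bin '%s'",
                 rownames(x)[neg[1, 1]], colnames(x)[neg[1, 2]]), call. = FALSE)
  }
  out <- suppressWarnings(log2(x))
  out[!is.finite(out)] <- 0
  dimnames(out) <- dimnames(x)
  log_step(out, list(op = "log2_transform_cn"))
}

#' Merge runs of adjacent identical columns
#'
#' Collapses maximal runs of consecutive columns whose value vectors are
#' exactly equal across all cells into a single column, preserving column
#' order. On copy-number matrices this shrinks constant segments (adjacent
#' genomic bins with the same profile) to one feature.
#'
#' @param x Numeric cells x features matrix.
#' @return Matrix with merged columns; attribute `feature_map` gives, for
#'   each retained column, the indices of the original columns it
#'   represents, and `selected_columns` the representative original index.
#' @export
merge_adjacent_identical <- function(x) {
  x <- as_cell_matrix(x)
  m <- ncol(x)
  if (m == 1L) {
    attr(x, "feature_map") <- list(1L)
    attr(x, "selected_columns") <- 1L
    return(log_step(x, list(op = "merge_adjacent_identical", kept = 1L)))
  }
  # TRUE where column j starts a new run
  new_run <- c(TRUE, vapply(2:m, function(j) !identical(unname(x[, j]), unname(x[, j - 1L])), logical(1)))
  run_id <- cumsum(new_run)
  keep <- which(new_run)
  out <- x[, keep, drop = FALSE]
  fmap <- split(seq_len(m), run_id)
  names(fmap) <- NULL
  prev_sel <- attr(x, "selected_columns") %||% seq_len(m)
  attr(out, "feature_map") <- fmap
  attr(out, "selected_columns") <- prev_sel[keep]
  attr(out, "transform_log") <- attr(x, "transform_log")
  log_step(out, list(op = "merge_adjacent_identical", kept = length(keep)))
}

#' Drop constant features
#'
#' Removes every column whose entries are all equal across cells; such
#' columns carry no information for clustering. Errors if nothing remains.
#'
#' @param x Numeric cells x features matrix.
#' @return Matrix with constant columns removed (order preserved).
#' @export
drop_constant_features <- function(x) {
  x <- as_cell_matrix(x)
  is_const <- apply(x, 2L, function(col) all(col == col[1L]))
  if (all(is_const)) stop("no informative features remain", call. = FALSE)
  keep <- which(!is_const)
  out <- x[, keep, drop = FALSE]
  prev_sel <- attr(x, "selected_columns") %||% seq_len(ncol(x))
  attr(out, "selected_columns") <- prev_sel[keep]
  attr(out, "transform_log") <- attr(x, "transform_log")
  log_step(out, list(op = "drop_constant_features", kept = length(keep)))
}

# Coefficient of variation per column: sample (n-1) sd over mean.
# Columns with mean <= 0 or undefined sd rank lowest (-Inf).
column_cv <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2L, stats::sd)
  cv <- sd / mu
  cv[!is.finite(cv) | mu <= 0] <- -Inf
  cv
}

#' Select the most variable features by coefficient of variation
#'
#' Retains the \code{k} columns with largest CV (sample standard deviation
#' divided by mean), keeping them in original column order so genomic
#' adjacency is preserved. Ties break by original column index; columns
#' with non-positive mean rank lowest. If there are at most \code{k}
#' columns the input is returned unchanged.
#'
#' @param x Numeric cells x features matrix.
#' @param k Number of features to keep (default 1024).
#' @return Matrix with at most \code{k} columns.
#' @export
select_top_cv <- function(x, k = 1024L) {
  x <- as_cell_matrix(x)
  stopifnot(k >= 1)
  if (ncol(x) <= k) return(log_step(x, list(op = "select_top_cv", k = k, kept = ncol(x))))
  cv <- column_cv(x)
  # order by decreasing CV, ties by ascending column index, then restore order
  ord <- order(-cv, seq_along(cv))
  keep <- sort(ord[seq_len(k)])
  out <- x[, keep, drop = FALSE]
  prev_sel <- attr(x, "selected_columns") %||% seq_len(ncol(x))
  attr(out, "selected_columns") <- prev_sel[keep]
  attr(out, "transform_log") <- attr(x, "transform_log")
  log_step(out, list(op = "select_top_cv", k = k, kept = length(keep)))
}

#' Depth-normalize a UMI count matrix
#'
#' Divides each cell's counts by its total UMI count, multiplies by the
#' median total across cells, adds a pseudo-count of 1 and log2-transforms:
#' entry \eqn{c_{ij} \to \log_2(c_{ij}/T_i \cdot \mathrm{median}(T) + 1)}.
#' Zero counts map exactly to 0. Cells with zero total are dropped with a
#' warning (or an error under \code{strict = TRUE}).
#'
#' @param counts Non-negative integer cells x genes matrix of UMI counts.
#' @param strict Error instead of warn on zero-total cells.
#' @return Normalized log-scale matrix.
#' @export
normalize_umi <- function(counts, strict = FALSE) {
  counts <- as_cell_matrix(counts, "UMI count matrix")
  if (any(counts < 0)) stop("UMI counts must be non-negative", call. = FALSE)
  totals <- rowSums(counts)
  if (any(totals == 0)) {
    bad <- rownames(counts)[totals == 0]
    msg <- sprintf("%d cell(s) with zero total UMI count dropped: %s",
                   length(bad), paste(utils::head(bad, 5), collapse = ", "))
    if (strict) stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
    counts <- counts[totals > 0, , drop = FALSE]
    totals <- totals[totals > 0]
  }
  med <- stats::median(totals)
  out <- log2(counts / totals * med + 1)
  dimnames(out) <- dimnames(counts)
  log_step(out, list(op = "normalize_umi", median_total = med))
}

#' Preprocess a copy-number matrix for embedding
#'
#' The copy-number branch of the pipeline: log2 transform (non-finite to
#' 0), merge adjacent identical columns, drop constant columns, then keep
#' the \code{k} highest-CV features.
#'
#' @inheritParams log2_transform_cn
#' @inheritParams select_top_cv
#' @return Processed matrix; attribute `selected_columns` maps retained
#'   features back to original bin indices, `transform_log` records steps.
#' @export
preprocess_cn <- function(x, k = 1024L) {
  x <- log2_transform_cn(x)
  x <- merge_adjacent_identical(x)
  x <- drop_constant_features(x)
  select_top_cv(x, k)
}

#' Preprocess a UMI count matrix for the adversarial branch
#'
#' Applies depth normalization and the same dimension-reduction steps as
#' the copy-number branch. By default normalization happens first so that
#' the CV ranking reflects biology rather than sequencing depth;
#' \code{order = "reduce-first"} applies the reduction to raw counts and
#' normalizes afterwards.
#'
#' @inheritParams normalize_umi
#' @inheritParams select_top_cv
#' @param order One of "normalize-first" (default) or "reduce-first".
#' @return Processed cells x features matrix (at most \code{k} features).
#' @export
preprocess_rna <- function(counts, k = 1024L,
                           order = c("normalize-first", "reduce-first"),
                           strict = FALSE) {
  order <- match.arg(order)
  reduce <- function(m) select_top_cv(drop_constant_features(merge_adjacent_identical(m)), k)
  if (order == "normalize-first") {
    reduce(normalize_umi(counts, strict = strict))
  } else {
    counts <- as_cell_matrix(counts, "UMI count matrix")
    normalize_umi(reduce(counts), strict = strict)
  }
}
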