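#' @keywords internal
#' @useDynLib cloneGAN, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

# Derive reproducible sub-seeds from one master seed so each stochastic
# component (init, training, clustering, simulation) owns an independent
# stream and can be tested in isolation. Values stay below 2^31 - 1.
derive_seeds <- function(seed, labels) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  s <- sample.int(.Machine$integer.max - 1L, length(labels))
  names(s) <- labels
  s
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

as_cell_matrix <- function(x, what = "matrix") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop(what, " must be a numeric matrix (cells as rows)", call. = FALSE)
  if (nrow(x) < 1L || ncol(x) < 1L)
    stop(what, " must have at least one row and one column", call. = FALSE)
  if (is.null(rownames(x))) rownames(x) <- sprintf("cell_%d", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- sprintf("f_%d", seq_len(ncol(x)))
  x
}

# Record of applied preprocessing steps, kept as an attribute so that a
# processed matrix carries its own provenance.
log_step <- function(x, step) {
  tl <- attr(x, "transform_log")
  attr(x, "transform_log") <- c(tl, list(step))
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
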