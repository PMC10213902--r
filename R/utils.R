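#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules.

stop_radage <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_radage(sprintf("'%s' must be a single finite number", name))
  }
  if (x < min || x > max) {
    stop_radage(sprintf("'%s' must be in [%s, %s], got %s", name, min, max, x))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  check_number(x, name, min = min)
  if (x != as.integer(x)) stop_radage(sprintf("'%s' must be an integer", name))
  invisible(as.integer(x))
}

#' Derive a child seed from a base seed and integer tags
#'
#' Combines a base seed with integer tags into a deterministic child seed
#' below 2^31, so pipeline stages and scan cells can be re-run in isolation
#' without sharing random-number streams.
#'
#' @param seed integer base seed.
#' @param ... integer tags identifying the stage, replicate or cell.
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  tags <- c(seed, ...)
  h <- 0
  for (t in tags) {
    h <- (h * 69069 + (as.numeric(t) %% 2147483647)) %% 2147483647
  }
  as.integer(h)
}

# Run expr with a local RNG state so callers' streams are untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

check_matrix_annotations <- function(matrix, annotations) {
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    stop_radage("expression must be a numeric matrix (genes x samples)")
  }
  if (is.null(rownames(matrix)) || is.null(colnames(matrix))) {
    stop_radage("expression matrix must carry gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(matrix))) stop_radage("duplicate gene ids in matrix")
  if (anyDuplicated(colnames(matrix))) stop_radage("duplicate sample ids in matrix")
  if (!all(is.finite(matrix))) stop_radage("expression matrix contains non-finite values")
  if (!is.data.frame(annotations) || is.null(annotations$sample_id)) {
    stop_radage("annotations must be a data.frame with a 'sample_id' column")
  }
  missing <- setdiff(colnames(matrix), annotations$sample_id)
  extra <- setdiff(annotations$sample_id, colnames(matrix))
  if (length(missing) || length(extra)) {
    stop_radage(
      "sample ids disagree between matrix and annotations; ",
      if (length(missing)) paste0("missing from annotations: ", paste(missing, collapse = ", "), ". "),
      if (length(extra)) paste0("missing from matrix: ", paste(extra, collapse = ", "), ".")
    )
  }
  invisible(TRUE)
}

# Align annotation rows to matrix column order.
align_annotations <- function(matrix, annotations) {
  annotations[match(colnames(matrix), annotations$sample_id), , drop = FALSE]
}
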