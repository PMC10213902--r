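# Reading, harmonising and preprocessing expression cohorts: dose binning,
# age dichotomisation, outlier detection, batch-effect regression, probe
# collapse.

#' Read a tab-delimited expression matrix with its annotation sheet
#'
#' The expression file carries gene ids in the first column and sample ids in
#' the header; the annotation sheet is tab-delimited with a `sample_id`
#' column. Sample ids must agree between the two files.
#'
#' @param path Expression table path.
#' @param annotation_path Annotation sheet path.
#' @return List with `matrix` and `annotations`.
#' @export
read_expression_table <- function(path, annotation_path) {
  if (!file.exists(path)) stop_radage("expression file not found: ", path)
  if (!file.exists(annotation_path)) {
    stop_radage("annotation file not found: ", annotation_path)
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(!vapply(df[-1], is.numeric, logical(1)))
    stop_radage("non-numeric expression values in column(s): ",
                paste(colnames(df)[bad + 1L], collapse = ", "))
  }
  rownames(mat) <- df[[1]]
  ann <- utils::read.table(annotation_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  for (col in c("sex", "smoking", "disease", "ethnicity", "split")) {
    if (!col %in% names(ann)) ann[[col]] <- NA_character_
    ann[[col]][is.na(ann[[col]]) | ann[[col]] == ""] <- "unknown"
  }
  check_matrix_annotations(mat, ann)
  list(matrix = mat, annotations = align_annotations(mat, ann))
}

#' Read an expression matrix in GEO series-matrix text layout
#'
#' Skips the metadata comment lines (beginning with `!`) and reads the table
#' between the series-matrix begin/end markers.
#'
#' @param path Series-matrix text file.
#' @return Numeric matrix, probes x samples.
#' @export
read_series_matrix <- function(path) {
  if (!file.exists(path)) stop_radage("file not found: ", path)
  lines <- readLines(path)
  keep <- !startsWith(lines, "!") & nzchar(lines)
  df <- utils::read.table(text = lines[keep], header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  storage.mode(mat) <- "double"
  mat
}

#' Assign radiation dose bins
#'
#' Absorbed dose \eqn{D_T} in Gy maps to one of four ordinal bins:
#' control (\eqn{D_T = 0}, code 0), low (\eqn{0 < D_T < 0.5}, code 1),
#' medium (\eqn{0.5 \le D_T < 1}, code 2), high (\eqn{D_T \ge 1}, code 3).
#' Boundaries are left-closed at 0.5 and 1.
#'
#' @param dose_Gy Numeric vector of doses in Gy, all >= 0.
#' @return List with `label` (factor control/low/medium/high) and `code`
#'   (integer 0-3).
#' @export
assign_radiation_bin <- function(dose_Gy) {
  if (!is.numeric(dose_Gy) || length(dose_Gy) == 0) {
    stop_radage("dose_Gy must be a non-empty numeric vector")
  }
  if (any(!is.finite(dose_Gy)) || any(dose_Gy < 0)) {
    stop_radage("dose_Gy must be finite and >= 0")
  }
  code <- ifelse(dose_Gy == 0, 0L,
          ifelse(dose_Gy < 0.5, 1L,
          ifelse(dose_Gy < 1, 2L, 3L)))
  label <- factor(c("control", "low", "medium", "high")[code + 1L],
                  levels = c("control", "low", "medium", "high"))
  list(label = label, code = code)
}

#' Dichotomise chronological age at a cutoff
#'
#' Young if and only if age <= cutoff (the boundary is inclusive on the young
#' side).
#'
#' @param age Ages in years, > 0.
#' @param cutoff Cutoff age in years.
#' @return Factor with levels young/old.
#' @export
dichotomize_age <- function(age, cutoff) {
  if (any(age <= 0)) stop_radage("ages must be positive")
  factor(ifelse(age <= cutoff, "young", "old"), levels = c("young", "old"))
}

#' Detect outlier samples in principal-component space
#'
#' Samples are projected onto the first two principal components of the
#' expression matrix; a sample is flagged when its Euclidean distance from
#' the coordinate-wise median centroid exceeds the median distance plus
#' `threshold_k` median absolute deviations of the distances.
#'
#' @param matrix Genes x samples matrix (>= 4 samples).
#' @param threshold_k Robust distance multiplier (> 0); default 6.
#' @return Character vector of flagged sample ids (possibly empty).
#' @export
detect_outlier_samples <- function(matrix, threshold_k = 6) {
  if (!is.numeric(threshold_k) || threshold_k <= 0) {
    stop_radage("threshold_k must be > 0")
  }
  if (ncol(matrix) < 4) stop_radage("need at least 4 samples")
  pc <- stats::prcomp(t(matrix), center = TRUE, scale. = FALSE, rank. = 2)
  sc <- pc$x[, 1:2, drop = FALSE]
  centroid <- apply(sc, 2, stats::median)
  d <- sqrt(rowSums(sweep(sc, 2, centroid)^2))
  lim <- stats::median(d) + threshold_k * stats::mad(d)
  colnames(matrix)[d > lim]
}

#' Remove additive batch effects by per-gene linear regression
#'
#' For every gene, fits an ordinary least-squares model with the protected
#' covariates plus batch indicators under sum-to-zero coding, and subtracts
#' the fitted batch component. Protected-covariate effects are untouched; the
#' operation is idempotent.
#'
#' @param matrix Genes x samples matrix.
#' @param batch Batch label per sample.
#' @param covariates Optional data.frame of covariates to protect (numeric or
#'   factor columns), rows in sample order.
#' @return Corrected matrix, same dimensions.
#' @export
remove_batch_effect <- function(matrix, batch, covariates = NULL) {
  batch <- as.factor(batch)
  if (length(batch) != ncol(matrix)) {
    stop_radage("batch must have one label per sample")
  }
  if (nlevels(droplevels(batch)) < 2) return(matrix)
  batch <- droplevels(batch)
  Xb <- stats::model.matrix(~ batch,
                            contrasts.arg = list(batch = stats::contr.sum))[, -1, drop = FALSE]
  Xc <- matrix(1, nrow = ncol(matrix), ncol = 1)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    Xc <- stats::model.matrix(~ ., data = covariates)
    full <- cbind(Xc, Xb)
    if (qr(full)$rank < ncol(full)) {
      stop_radage("batch is confounded with a protected covariate (",
                  paste(colnames(covariates), collapse = ", "),
                  "); cannot separate the effects")
    }
  }
  X <- cbind(Xc, Xb)
  # normal equations solved once for all genes
  XtX <- crossprod(X)
  B <- solve(XtX, crossprod(X, t(matrix)))
  bidx <- seq(ncol(Xc) + 1L, ncol(X))
  fitted_batch <- X[, bidx, drop = FALSE] %*% B[bidx, , drop = FALSE]
  matrix - t(fitted_batch)
}

#' Collapse microarray probes to genes
#'
#' One output row per gene. The default rule keeps the probe with the
#' largest variance across samples; `"mean"` averages the probes.
#'
#' @param matrix Probes x samples matrix.
#' @param probe_to_gene Named character vector or data.frame (probe_id,
#'   gene_id) mapping every probe row to a gene.
#' @param rule `"maxvar"` (default) or `"mean"`.
#' @return Genes x samples matrix.
#' @export
collapse_probes <- function(matrix, probe_to_gene, rule = c("maxvar", "mean")) {
  rule <- match.arg(rule)
  if (is.data.frame(probe_to_gene)) {
    map <- stats::setNames(as.character(probe_to_gene[[2]]),
                           as.character(probe_to_gene[[1]]))
  } else {
    map <- probe_to_gene
  }
  probes <- rownames(matrix)
  unmapped <- setdiff(probes, names(map))
  if (length(unmapped)) {
    stop_radage("unmapped probe(s): ", paste(unmapped, collapse = ", "))
  }
  genes <- map[probes]
  if (rule == "mean") {
    sums <- rowsum(matrix, group = genes)
    return(sums / as.vector(table(genes)[rownames(sums)]))
  }
  v <- apply(matrix, 1, stats::var)
  keep <- tapply(seq_along(probes), genes, function(i) i[which.max(v[i])])
  out <- matrix[as.integer(keep), , drop = FALSE]
  rownames(out) <- names(keep)
  out
}

#' Guard against linear-scale expression input
#'
#' Processed expression is expected on the log2 scale. Matrices whose maximum
#' exceeds 30 are likely linear scale; with `transform = TRUE` they are
#' converted via log2(x + 1), otherwise a warning is raised.
#'
#' @param matrix Expression matrix.
#' @param transform Apply log2(x + 1) when the matrix looks linear-scale.
#' @return Possibly transformed matrix.
#' @export
ensure_log2_scale <- function(matrix, transform = FALSE) {
  if (max(matrix) > 30) {
    if (transform) return(log2(matrix + 1))
    warning("matrix maximum exceeds 30; values may be linear-scale, not log2")
  }
  matrix
}
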