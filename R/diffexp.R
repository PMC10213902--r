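# Two-group differential expression across radiation bins, age classes and
# sex: per-gene t-tests, BH-FDR, UpSet-style intersection counts, dose-trend
# direction profiles.

# Welch (or pooled) two-sample t for a single gene; diff = mean(a) - mean(b).
welch_row <- function(a, b, var_equal = FALSE) {
  na <- length(a); nb <- length(b)
  ma <- mean(a); mb <- mean(b)
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    return(list(t = 0, p = 1, diff = ma - mb, df = NA_real_, zero_var = TRUE))
  }
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  t <- (ma - mb) / se
  list(t = t, p = 2 * stats::pt(-abs(t), df), diff = ma - mb, df = df,
       zero_var = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH q-values: \eqn{q_{(i)} = \min_{j \ge i} m \, p_{(j)} / j},
#' capped at 1, returned in the original order.
#'
#' @param p_values Numeric vector of p-values in [0, 1].
#' @return q-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop_radage("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Two-group differential expression
#'
#' Per-gene Welch t-statistic, two-sided p-value, BH q-value over all tested
#' genes, and log2 fold change defined as group-A mean minus group-B mean on
#' the log2 scale.
#'
#' @param matrix Genes x samples matrix.
#' @param ids_A,ids_B Disjoint sample-id vectors, each of size >= 2.
#' @param contrast Label stored with the table.
#' @param var_equal Pooled-variance t-test instead of Welch.
#' @return Data.frame: gene, t_statistic, p_value, fdr_q, log2FC, n_A, n_B,
#'   contrast.
#' @export
two_group_de <- function(matrix, ids_A, ids_B, contrast = "A_vs_B",
                         var_equal = FALSE) {
  if (length(intersect(ids_A, ids_B))) {
    stop_radage("groups overlap: ", paste(intersect(ids_A, ids_B), collapse = ", "))
  }
  if (length(ids_A) < 2 || length(ids_B) < 2) {
    stop_radage("each group needs at least 2 samples")
  }
  missing <- setdiff(c(ids_A, ids_B), colnames(matrix))
  if (length(missing)) {
    stop_radage("sample id(s) not in matrix: ", paste(missing, collapse = ", "))
  }
  A <- matrix[, ids_A, drop = FALSE]
  B <- matrix[, ids_B, drop = FALSE]
  na <- ncol(A); nb <- ncol(B)
  ma <- rowMeans(A); mb <- rowMeans(B)
  va <- rowSums((A - ma)^2) / (na - 1)
  vb <- rowSums((B - mb)^2) / (nb - 1)
  zero <- va == 0 & vb == 0
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, nrow(matrix))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  t <- (ma - mb) / se
  p <- 2 * stats::pt(-abs(t), df)
  if (any(zero)) {
    warning(sum(zero), " gene(s) with zero variance in both groups; t = 0, p = 1")
    t[zero] <- 0
    p[zero] <- 1
  }
  data.frame(
    gene = rownames(matrix),
    t_statistic = t,
    p_value = p,
    fdr_q = bh_adjust(p),
    log2FC = ma - mb,
    n_A = na, n_B = nb,
    contrast = contrast,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' The default contrast battery
#'
#' Builds the six standard group-pair definitions against a sample-annotation
#' sheet: control vs any radiation, control vs low, low vs medium, medium vs
#' high (restricted to samples with recorded dose), young vs old (samples
#' with age and an `age_class`), and male vs female (samples with known sex).
#'
#' @param annotations Sample annotations carrying `radiation_bin` and/or
#'   `age_class` and/or `sex`.
#' @return Named list of contrasts, each `list(A = ids, B = ids)`.
#' @export
default_contrasts <- function(annotations) {
  ids <- annotations$sample_id
  bin <- as.character(annotations$radiation_bin)
  has_dose <- !is.na(bin)
  out <- list()
  pick <- function(keep) ids[keep & !is.na(keep)]
  out$control_vs_any_radiation <- list(
    A = pick(has_dose & bin == "control"),
    B = pick(has_dose & bin != "control"))
  out$control_vs_low <- list(A = pick(has_dose & bin == "control"),
                             B = pick(has_dose & bin == "low"))
  out$low_vs_medium <- list(A = pick(has_dose & bin == "low"),
                            B = pick(has_dose & bin == "medium"))
  out$medium_vs_high <- list(A = pick(has_dose & bin == "medium"),
                             B = pick(has_dose & bin == "high"))
  if (!is.null(annotations$age_class)) {
    cls <- as.character(annotations$age_class)
    out$young_vs_old <- list(A = pick(cls == "young"), B = pick(cls == "old"))
  }
  if (!is.null(annotations$sex)) {
    sx <- as.character(annotations$sex)
    out$male_vs_female <- list(A = pick(sx == "male"), B = pick(sx == "female"))
  }
  out
}

#' Run a battery of two-group contrasts
#'
#' @param matrix Genes x samples matrix.
#' @param annotations Sample annotations.
#' @param contrasts Named list of contrasts (`list(A = ids, B = ids)`);
#'   defaults to [default_contrasts()].
#' @param var_equal Pooled-variance t-tests.
#' @return Named list of DE tables; contrasts with a side of fewer than 2
#'   samples are skipped with a warning and listed in `attr(, "skipped")`.
#' @export
run_contrasts <- function(matrix, annotations, contrasts = NULL,
                          var_equal = FALSE) {
  check_matrix_annotations(matrix, annotations)
  if (is.null(contrasts)) contrasts <- default_contrasts(annotations)
  out <- list()
  skipped <- character()
  for (nm in names(contrasts)) {
    co <- contrasts[[nm]]
    if (length(co$A) < 2 || length(co$B) < 2) {
      warning("contrast '", nm, "' has an underpopulated side; skipped")
      skipped <- c(skipped, nm)
      next
    }
    out[[nm]] <- two_group_de(matrix, co$A, co$B, contrast = nm,
                              var_equal = var_equal)
  }
  attr(out, "skipped") <- skipped
  out
}

#' UpSet-style intersection counts of significant genes
#'
#' For every non-empty subset of the supplied DE tables, counts the genes
#' significant in exactly that subset of tables (UpSet semantics, not the
#' cumulative Venn counts).
#'
#' @param tables Named list of DE tables (>= 2).
#' @param alpha Significance threshold applied to `use`.
#' @param use Column to threshold: `"fdr_q"` (default) or `"p_value"`.
#' @return Data.frame with one logical membership column per table plus
#'   `count`, covering all non-empty subsets.
#' @export
intersect_significant <- function(tables, alpha = 0.05,
                                  use = c("fdr_q", "p_value")) {
  use <- match.arg(use)
  if (length(tables) < 2) stop_radage("need at least 2 tables")
  sets <- lapply(tables, function(tb) tb$gene[tb[[use]] < alpha])
  universe <- unique(unlist(sets))
  k <- length(tables)
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1)
  grid <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), k)))
  colnames(grid) <- names(tables)
  grid <- grid[rowSums(grid) > 0, , drop = FALSE]
  count <- apply(grid, 1, function(g) {
    if (!length(universe)) return(0L)
    sum(apply(member, 1, function(m) all(m == g)))
  })
  out <- as.data.frame(grid)
  out$count <- as.integer(count)
  out
}

#' Dose-trend direction profiles
#'
#' Per gene, the signs of the successive radiation-bin mean differences
#' (control to low, low to medium, medium to high) on the log2 scale,
#' reported both as individual signs and a profile string such as `(+,+,+)`.
#'
#' @param matrix Genes x samples matrix.
#' @param annotations Annotations with `radiation_bin`; all four bins must be
#'   populated.
#' @param genes Genes to profile (default: all rows).
#' @return Data.frame: gene, control_to_low, low_to_medium, medium_to_high,
#'   profile.
#' @export
dose_trend <- function(matrix, annotations, genes = rownames(matrix)) {
  check_matrix_annotations(matrix, annotations)
  ann <- align_annotations(matrix, annotations)
  bins <- c("control", "low", "medium", "high")
  bin <- as.character(ann$radiation_bin)
  empty <- bins[!bins %in% bin]
  if (length(empty)) {
    stop_radage("empty radiation bin(s): ", paste(empty, collapse = ", "))
  }
  missing <- setdiff(genes, rownames(matrix))
  if (length(missing)) {
    stop_radage("gene(s) not in matrix: ", paste(missing, collapse = ", "))
  }
  means <- vapply(bins, function(b) {
    rowMeans(matrix[genes, bin == b, drop = FALSE])
  }, numeric(length(genes)))
  if (length(genes) == 1L) means <- matrix(means, nrow = 1)
  d <- means[, -1, drop = FALSE] - means[, -4, drop = FALSE]
  sgn <- function(x) c("-", "0", "+")[sign(x) + 2]
  out <- data.frame(
    gene = genes,
    control_to_low = sgn(d[, 1]),
    low_to_medium = sgn(d[, 2]),
    medium_to_high = sgn(d[, 3]),
    stringsAsFactors = FALSE
  )
  out$profile <- sprintf("(%s,%s,%s)", out$control_to_low,
                         out$low_to_medium, out$medium_to_high)
  out
}

#' Write a DE table as tab-delimited text
#'
#' @param table A DE table from [two_group_de()].
#' @param path Output path.
#' @export
write_de_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
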