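# Empirical young/old age-threshold determination: loop candidate cutoffs,
# per-gene t-tests and fold changes, balanced-subsample single-gene classifier
# AUC averaged over permutations, and a cutoff selection rule.

#' The default aging gene panel
#'
#' Twelve well-characterised aging-associated genes used to scan candidate
#' young/old cutoffs.
#'
#' @return Character vector of gene symbols.
#' @export
aging_panel <- function() {
  c("CDKN2A", "FOXO1", "SIRT1", "IL6", "TFAM", "MTOR",
    "TSC1", "TP53", "SIRT6", "MLKL", "ALOX15B", "TNFAIP3")
}

#' Match a gene panel against an expression matrix
#'
#' Panel members absent from the matrix are reported via warning and dropped,
#' mirroring how unavailable panel genes are handled in practice.
#'
#' @param symbols Ordered gene symbols.
#' @param matrix Expression matrix with gene rownames.
#' @return Character vector of matched symbols with attribute `dropped`.
#' @export
gene_panel <- function(symbols, matrix) {
  if (!length(symbols)) stop_radage("panel must be non-empty")
  present <- symbols[symbols %in% rownames(matrix)]
  dropped <- setdiff(symbols, present)
  if (length(dropped)) {
    warning("panel gene(s) not in matrix, dropped: ",
            paste(dropped, collapse = ", "))
  }
  if (!length(present)) stop_radage("no panel gene present in the matrix")
  structure(present, dropped = dropped)
}

#' Threshold-scan configuration
#'
#' @param cutoff_min,cutoff_max Candidate cutoff range in years (defaults
#'   21 and 65).
#' @param alpha Per-gene significance level (default 0.05).
#' @param n_perm Balanced-subsampling permutations per cell (default 1000).
#' @param train_fraction Train share of the 60/40 split (default 0.6).
#' @param seed Integer base seed; per-cell streams are derived from it so
#'   cells are reproducible in isolation.
#' @return Object of class `threshold_scan_config`.
#' @export
threshold_scan_config <- function(cutoff_min = 21, cutoff_max = 65,
                                  alpha = 0.05, n_perm = 1000,
                                  train_fraction = 0.6, seed = 1L) {
  check_number(cutoff_min, "cutoff_min")
  check_number(cutoff_max, "cutoff_max")
  if (cutoff_min >= cutoff_max) stop_radage("cutoff_min must be < cutoff_max")
  check_number(alpha, "alpha", 0, 1)
  n_perm <- check_count(n_perm, "n_perm")
  check_number(train_fraction, "train_fraction", 1e-9, 1 - 1e-9)
  structure(
    list(cutoff_min = cutoff_min, cutoff_max = cutoff_max, alpha = alpha,
         n_perm = n_perm, train_fraction = train_fraction,
         seed = as.integer(seed)),
    class = "threshold_scan_config"
  )
}

# Mann-Whitney rank AUC of a score for a positive-class indicator.
rank_auc <- function(score, positive) {
  n1 <- sum(positive)
  n0 <- length(positive) - n1
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Quartile-bin ids of a covariate (single bin when cov is NULL). Bins are
# fixed per class before permuting, so each permutation only samples.
strat_bins <- function(idx, cov) {
  if (is.null(cov)) return(rep(1L, length(idx)))
  br <- unique(stats::quantile(cov[idx], probs = c(0.25, 0.5, 0.75)))
  findInterval(cov[idx], br)
}

# Split indices train/test at `frac` within precomputed strata.
strat_split <- function(idx, bins, frac) {
  take <- logical(length(idx))
  for (b in unique(bins)) {
    pos <- which(bins == b)
    k <- round(frac * length(pos))
    if (k >= 1L) take[pos[sample.int(length(pos), k)]] <- TRUE
  }
  if (!any(take)) take[1] <- TRUE
  if (all(take)) take[which(take)[1]] <- FALSE
  list(train = idx[take], test = idx[!take])
}

#' Balanced-subsampling classifier AUC for one gene
#'
#' Repeatedly downsamples the majority age class to the minority size so both
#' classes are exactly balanced, splits 60/40 into train/test (stratified by
#' quartile bins of the continuous covariate, typically age, within each
#' class), fits a univariate linear-score classifier on the training half —
#' because ROC AUC depends only on the ordering of scores, any monotone link
#' (logistic included) gives the identical AUC, so the score is the expression
#' value oriented by the train-fitted direction — and averages the train and
#' test ROC AUCs over permutations.
#'
#' @param values Per-sample expression of one gene.
#' @param labels Factor with levels young/old; young is the positive class.
#' @param config A [threshold_scan_config()].
#' @param covariate Optional continuous covariate (age) used to stratify the
#'   split.
#' @return List: `auc_train_mean`, `auc_test_mean`, `n_young`, `n_old`,
#'   `unstable` (TRUE when the minority class has fewer than 4 samples).
#' @export
balanced_auc <- function(values, labels, config = threshold_scan_config(),
                         covariate = NULL) {
  labels <- factor(labels, levels = c("young", "old"))
  idx_y <- which(labels == "young")
  idx_o <- which(labels == "old")
  if (!length(idx_y) || !length(idx_o)) {
    stop_radage("both age classes must be non-empty")
  }
  if (stats::var(values) == 0) {
    warning("constant expression vector; AUC defined as 0.5")
    return(list(auc_train_mean = 0.5, auc_test_mean = 0.5,
                n_young = length(idx_y), n_old = length(idx_o),
                unstable = min(length(idx_y), length(idx_o)) < 4))
  }
  m <- min(length(idx_y), length(idx_o))
  frac <- config$train_fraction
  bins_y <- strat_bins(idx_y, covariate)
  bins_o <- strat_bins(idx_o, covariate)
  # within-subset ranks via one precomputed global ordering: the position of
  # a subset member along the global order, counted among subset members,
  # is its subset rank (values are continuous, so ties are measure-zero;
  # exact ties fall back to first-occurrence ranks)
  n_all <- length(values)
  ord <- order(values)
  inv <- integer(n_all)
  inv[ord] <- seq_len(n_all)
  subset_auc <- function(subset_idx, pos_idx) {
    member <- logical(n_all)
    member[subset_idx] <- TRUE
    cs <- cumsum(member[ord])
    n1 <- length(pos_idx)
    n0 <- length(subset_idx) - n1
    (sum(cs[inv[pos_idx]]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  tr_auc <- te_auc <- numeric(config$n_perm)
  for (p in seq_len(config$n_perm)) {
    sel_y <- if (length(idx_y) > m) sample.int(length(idx_y), m)
             else seq_along(idx_y)
    sel_o <- if (length(idx_o) > m) sample.int(length(idx_o), m)
             else seq_along(idx_o)
    sy <- strat_split(idx_y[sel_y], bins_y[sel_y], frac)
    so <- strat_split(idx_o[sel_o], bins_o[sel_o], frac)
    # univariate linear score refit on the balanced training subsample:
    # orientation is the sign of the young-minus-old train mean difference
    dir <- sign(sum(values[sy$train]) / length(sy$train) -
                sum(values[so$train]) / length(so$train))
    if (dir == 0) dir <- 1
    a_tr <- subset_auc(c(sy$train, so$train), sy$train)
    a_te <- subset_auc(c(sy$test, so$test), sy$test)
    if (dir < 0) { a_tr <- 1 - a_tr; a_te <- 1 - a_te }
    tr_auc[p] <- a_tr
    te_auc[p] <- a_te
  }
  list(auc_train_mean = mean(tr_auc), auc_test_mean = mean(te_auc),
       n_young = length(idx_y), n_old = length(idx_o), unstable = m < 4)
}

#' Scan candidate young/old age cutoffs
#'
#' For every candidate cutoff in the configured range, samples are
#' dichotomised (young iff age <= cutoff) and, per panel gene, a Welch
#' two-sample t-test p-value, the log2 fold change (young minus old) and the
#' balanced-subsampling train/test AUC are computed. Cutoffs whose minority
#' class has fewer than 4 samples are skipped and recorded.
#'
#' @param matrix Genes x samples matrix.
#' @param annotations Sample annotations with `age`.
#' @param panel Gene symbols (matched against the matrix via [gene_panel()]).
#' @param config A [threshold_scan_config()].
#' @param var_equal Use pooled-variance t-tests instead of Welch.
#' @return Data.frame of class `threshold_scan`: one row per evaluated
#'   (cutoff, gene) with p_value, log2FC, auc_train_mean, auc_test_mean,
#'   n_young, n_old. Skipped cutoffs in `attr(, "skipped_cutoffs")`.
#' @export
scan_thresholds <- function(matrix, annotations, panel = aging_panel(),
                            config = threshold_scan_config(),
                            var_equal = FALSE) {
  check_matrix_annotations(matrix, annotations)
  ann <- align_annotations(matrix, annotations)
  panel <- gene_panel(panel, matrix)
  age <- ann$age
  cutoffs <- seq(config$cutoff_min, config$cutoff_max)
  rows <- vector("list", length(cutoffs))
  skipped <- numeric()
  for (ci in seq_along(cutoffs)) {
    cutoff <- cutoffs[ci]
    cls <- dichotomize_age(age, cutoff)
    ny <- sum(cls == "young"); no <- sum(cls == "old")
    if (min(ny, no) < 4) {
      skipped <- c(skipped, cutoff)
      next
    }
    res <- lapply(seq_along(panel), function(gi) {
      x <- matrix[panel[gi], ]
      tt <- welch_row(x[cls == "young"], x[cls == "old"], var_equal = var_equal)
      auc <- with_seed(derive_seed(config$seed, ci, gi), {
        balanced_auc(x, cls, config, covariate = age)
      })
      data.frame(
        cutoff = cutoff, gene = panel[gi],
        p_value = tt$p, log2FC = tt$diff,
        auc_train_mean = auc$auc_train_mean,
        auc_test_mean = auc$auc_test_mean,
        n_young = ny, n_old = no,
        stringsAsFactors = FALSE
      )
    })
    rows[[ci]] <- do.call(rbind, res)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop_radage("no cutoff was evaluable under the data's age span")
  attr(out, "skipped_cutoffs") <- skipped
  attr(out, "config") <- config
  class(out) <- c("threshold_scan", class(out))
  out
}

#' Select the young/old cutoff from a threshold scan
#'
#' Primary criterion: the cutoff with the most panel genes significant at
#' `alpha`. Ties break first to the higher mean test AUC over the significant
#' genes at that cutoff, then to the smaller cutoff. If no cutoff has any
#' significant gene, the cutoff maximising the mean test AUC over all genes
#' is returned with a warning flag.
#'
#' @param result A `threshold_scan` result.
#' @param alpha Significance level (default 0.05).
#' @return List: `cutoff`, `n_significant`, `mean_test_auc_significant`,
#'   `fallback` (TRUE when no gene was significant anywhere).
#' @export
select_cutoff <- function(result, alpha = 0.05) {
  if (!nrow(result)) stop_radage("empty scan result")
  sig <- result$p_value < alpha
  per <- split(seq_len(nrow(result)), result$cutoff)
  stats_tab <- do.call(rbind, lapply(names(per), function(co) {
    i <- per[[co]]
    s <- i[sig[i]]
    data.frame(
      cutoff = as.numeric(co),
      n_significant = length(s),
      mean_auc_sig = if (length(s)) mean(result$auc_test_mean[s]) else NA_real_,
      mean_auc_all = mean(result$auc_test_mean[i])
    )
  }))
  if (all(stats_tab$n_significant == 0)) {
    warning("no cutoff has a significant panel gene; ",
            "falling back to the overall-AUC maximiser")
    best <- stats_tab[order(-stats_tab$mean_auc_all, stats_tab$cutoff), ][1, ]
    return(list(cutoff = best$cutoff, n_significant = 0L,
                mean_test_auc_significant = NA_real_, fallback = TRUE))
  }
  ord <- order(-stats_tab$n_significant, -stats_tab$mean_auc_sig, stats_tab$cutoff)
  best <- stats_tab[ord[1], ]
  list(cutoff = best$cutoff, n_significant = best$n_significant,
       mean_test_auc_significant = best$mean_auc_sig, fallback = FALSE)
}

#' Reshape a threshold scan into a heat-map-ready wide table
#'
#' @param result A `threshold_scan` result.
#' @param stat One of `"p_value"`, `"log2FC"`, `"auc_train_mean"`,
#'   `"auc_test_mean"`.
#' @return Matrix cutoffs x genes.
#' @export
scan_wide <- function(result, stat = c("p_value", "log2FC",
                                       "auc_train_mean", "auc_test_mean")) {
  stat <- match.arg(stat)
  genes <- unique(result$gene)
  cutoffs <- sort(unique(result$cutoff))
  out <- matrix(NA_real_, length(cutoffs), length(genes),
                dimnames = list(cutoffs, genes))
  out[cbind(match(result$cutoff, cutoffs), match(result$gene, genes))] <-
    result[[stat]]
  out
}
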