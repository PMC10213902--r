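# Per-gene age-by-radiation interaction models, the p < 0.05 screen, the
# union across age modes, and preranked-list export.

#' Fit the per-gene age-by-radiation interaction model
#'
#' Ordinary least squares on
#' \deqn{y = b_0 + b_1 \, a + b_2 \, r + b_3 \, a r + \varepsilon}
#' where the age term \eqn{a} is centred age in years (continuous mode) or
#' the young indicator at `cutoff` (categorical mode), and \eqn{r} is the
#' ordinal radiation-bin code 0-3 (or dose in Gy when `rad` is passed on that
#' scale). The interaction p-value is the two-sided t-test on \eqn{b_3} with
#' residual degrees of freedom. Centring the continuous age term does not
#' change the interaction test.
#'
#' @param y Per-sample expression of one gene.
#' @param age Ages in years.
#' @param rad Radiation ordinal bin code (0-3) per sample.
#' @param age_mode `"continuous"` or `"categorical"`.
#' @param cutoff Young/old cutoff in years (used by categorical mode and for
#'   the age fold change).
#' @return List: `coefficients` (b0, b1_age, b2_rad, b3_interaction),
#'   `std_errors`, `p_interaction`, `age_mode`, `log2FC_radiation`
#'   (any-radiation minus control means), `log2FC_age` (young minus old
#'   means at the cutoff), `df_residual`.
#' @export
fit_gene_interaction <- function(y, age, rad,
                                 age_mode = c("continuous", "categorical"),
                                 cutoff = 29) {
  age_mode <- match.arg(age_mode)
  n <- length(y)
  if (n < 8) stop_radage("need at least 8 samples")
  if (length(age) != n || length(rad) != n) {
    stop_radage("y, age, rad must have equal length")
  }
  a <- if (age_mode == "continuous") age - mean(age)
       else as.numeric(age <= cutoff)
  X <- cbind(intercept = 1, age = a, rad = rad, age_rad = a * rad)
  qrX <- qr(X)
  if (qrX$rank < 4) {
    dropped <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    stop_radage("rank-deficient interaction design; collinear term(s): ",
                paste(dropped, collapse = ", "),
                " (does radiation vary and do both age classes occur?)")
  }
  XtX_inv <- solve(crossprod(X))
  b <- drop(XtX_inv %*% crossprod(X, y))
  names(b) <- colnames(X)
  res <- y - drop(X %*% b)
  df <- n - 4
  sigma2 <- sum(res^2) / df
  se <- sqrt(sigma2 * diag(XtX_inv))
  names(se) <- colnames(X)
  tstat <- b / se
  p_int <- 2 * stats::pt(-abs(tstat["age_rad"]), df)
  young <- age <= cutoff
  irr <- rad > 0
  list(
    coefficients = stats::setNames(as.numeric(b), colnames(X)),
    std_errors = se,
    p_interaction = unname(p_int),
    age_mode = age_mode,
    log2FC_radiation = if (any(irr) && any(!irr)) mean(y[irr]) - mean(y[!irr]) else NA_real_,
    log2FC_age = if (any(young) && any(!young)) mean(y[young]) - mean(y[!young]) else NA_real_,
    df_residual = df
  )
}

#' Screen all genes for age-by-radiation interactions
#'
#' Fits [fit_gene_interaction()] per gene and reports genes with a raw
#' interaction p-value below `alpha` (no multiplicity adjustment is applied
#' at this stage, deliberately unlike the FDR-controlled two-group
#' contrasts). Genes whose model fails to fit are recorded, not silently
#' dropped.
#'
#' @param matrix Genes x samples matrix.
#' @param annotations Annotations with `age` and `rad_code` (or
#'   `radiation_bin` from which codes are derived).
#' @param age_mode `"continuous"` or `"categorical"`.
#' @param alpha Raw significance level (default 0.05).
#' @param cutoff Young/old cutoff in years.
#' @return List: `significant` (gene ids, alphabetical), `results`
#'   (per-gene data.frame), `failed` (gene ids with fit errors).
#' @export
run_interaction_screen <- function(matrix, annotations,
                                   age_mode = c("continuous", "categorical"),
                                   alpha = 0.05, cutoff = 29) {
  age_mode <- match.arg(age_mode)
  check_matrix_annotations(matrix, annotations)
  ann <- align_annotations(matrix, annotations)
  if (is.null(ann$age)) stop_radage("annotations must carry 'age'")
  rad <- ann$rad_code
  if (is.null(rad)) {
    if (is.null(ann$radiation_bin)) {
      stop_radage("annotations must carry 'rad_code' or 'radiation_bin'")
    }
    rad <- match(as.character(ann$radiation_bin),
                 c("control", "low", "medium", "high")) - 1L
  }
  rows <- vector("list", nrow(matrix))
  failed <- character()
  for (g in seq_len(nrow(matrix))) {
    fit <- tryCatch(
      fit_gene_interaction(matrix[g, ], ann$age, rad, age_mode, cutoff),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      failed <- c(failed, rownames(matrix)[g])
      next
    }
    rows[[g]] <- data.frame(
      gene = rownames(matrix)[g],
      b_age = fit$coefficients[["age"]],
      b_rad = fit$coefficients[["rad"]],
      b_interaction = fit$coefficients[["age_rad"]],
      p_interaction = fit$p_interaction,
      log2FC_radiation = fit$log2FC_radiation,
      log2FC_age = fit$log2FC_age,
      stringsAsFactors = FALSE
    )
  }
  results <- do.call(rbind, rows)
  sig <- if (is.null(results)) character()
         else sort(results$gene[results$p_interaction < alpha])
  list(significant = sig, results = results, failed = failed,
       age_mode = age_mode, alpha = alpha)
}

#' Union of interaction gene lists across age modes
#'
#' @param list_continuous,list_categorical Gene id vectors.
#' @return Deterministic alphabetical set union.
#' @export
union_interaction_genes <- function(list_continuous, list_categorical) {
  sort(unique(c(list_continuous, list_categorical)))
}

#' Build a preranked gene list
#'
#' Default metric: \eqn{sign(log2FC_{radiation}) \times -log_{10} p}. Genes
#' sort by score descending; ties break alphabetically. Zero p-values cap
#' the score magnitude at 308 with a warning.
#'
#' @param results Per-gene results data.frame from
#'   [run_interaction_screen()]`$results`.
#' @param metric `"signed_logp"` (default), or export one fold change
#'   directly: `"log2FC_radiation"`, `"log2FC_age"`.
#' @return Data.frame (gene, score) of class `ranked_list`.
#' @export
build_preranked <- function(results, metric = c("signed_logp",
                                                "log2FC_radiation",
                                                "log2FC_age")) {
  metric <- match.arg(metric)
  need <- c("gene", "p_interaction", "log2FC_radiation", "log2FC_age")
  if (any(!need %in% names(results)) ||
      anyNA(results[, setdiff(need, "gene")])) {
    stop_radage("results must carry complete p and fold-change columns")
  }
  score <- switch(metric,
    signed_logp = {
      s <- sign(results$log2FC_radiation) * -log10(results$p_interaction)
      if (any(is.infinite(s))) {
        warning("p = 0 encountered; score capped at +/-308")
        s[is.infinite(s)] <- sign(s[is.infinite(s)]) * 308
      }
      s
    },
    log2FC_radiation = results$log2FC_radiation,
    log2FC_age = results$log2FC_age
  )
  out <- data.frame(gene = results$gene, score = score,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$gene), ]
  rownames(out) <- NULL
  class(out) <- c("ranked_list", class(out))
  out
}

#' Write / read a two-column .rnk file
#'
#' Tab-delimited gene/score pairs without a header, the layout consumed by
#' preranked enrichment tools.
#'
#' @param ranked A `ranked_list` (gene, score).
#' @param path Output path.
#' @export
write_rnk <- function(ranked, path) {
  utils::write.table(ranked[, c("gene", "score")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_rnk
#' @export
read_rnk <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("gene", "score"),
                           stringsAsFactors = FALSE)
  class(out) <- c("ranked_list", class(out))
  out
}
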