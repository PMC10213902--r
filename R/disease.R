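# Clinical evaluation of the rad-age gene list on a multi-split disease
# cohort: one-vs-rest contrasts per factor per split, the cross-split
# candidate filter, and the three-way disease x ethnicity x sex interaction
# model.

#' Candidate-filter configuration
#'
#' @param alpha Per-test significance level (default 0.05).
#' @param min_test_cases Minimum number of one-vs-rest test cases a gene must
#'   pass within each split (default 2); test cases are pooled across the
#'   disease, ethnicity and sex factors.
#' @param fc_threshold Fold-change gate (default 2, on the log2 scale).
#' @param required_splits Splits the rule must hold in (default all three).
#' @param signed_only Gate on signed log2FC > threshold instead of |log2FC|.
#' @param fc_on `"log2"` gates |log2FC| > `fc_threshold`; `"linear"` reads
#'   `fc_threshold` as a raw fold change (gate |log2FC| > log2(threshold)).
#' @return Object of class `candidate_filter_config`.
#' @export
candidate_filter_config <- function(alpha = 0.05, min_test_cases = 2,
                                    fc_threshold = 2,
                                    required_splits = c("train", "test", "validation"),
                                    signed_only = FALSE,
                                    fc_on = c("log2", "linear")) {
  check_number(alpha, "alpha", 1e-12, 1 - 1e-12)
  min_test_cases <- check_count(min_test_cases, "min_test_cases")
  check_number(fc_threshold, "fc_threshold", min = 0)
  structure(
    list(alpha = alpha, min_test_cases = min_test_cases,
         fc_threshold = fc_threshold, required_splits = required_splits,
         signed_only = signed_only, fc_on = match.arg(fc_on)),
    class = "candidate_filter_config"
  )
}

#' Merge rare factor levels into "other"
#'
#' Levels with fewer than `min_n` samples in any split cannot be tested
#' one-vs-rest in every split; they are pooled into an `"other"` level.
#'
#' @param annotations Sample annotations with `split`.
#' @param factor_name Column to recode.
#' @param min_n Minimum per-split size to keep a level (default 4).
#' @return Annotations with the recoded column.
#' @export
merge_rare_levels <- function(annotations, factor_name, min_n = 4) {
  x <- as.character(annotations[[factor_name]])
  tab <- table(x, annotations$split)
  rare <- rownames(tab)[apply(tab, 1, min) < min_n]
  x[x %in% rare] <- "other"
  annotations[[factor_name]] <- x
  annotations
}

#' One-vs-rest DE tables for a clinical factor within one split
#'
#' For each level of the factor, runs [two_group_de()] of that level against
#' all other samples, restricted to the split. Levels with fewer than 2
#' samples on either side are skipped and recorded. For a two-level factor
#' only the first (alphabetical) level is tested — the second table would be
#' its mirror.
#'
#' @param matrix Genes x samples matrix.
#' @param annotations Annotations with the factor column and `split`.
#' @param factor_name One of `"disease"`, `"ethnicity"`, `"sex"` (any
#'   annotation column works).
#' @param split Split label to restrict to.
#' @return Named list of DE tables (one per tested level); skipped levels in
#'   `attr(, "skipped")`.
#' @export
one_vs_rest_tables <- function(matrix, annotations, factor_name, split) {
  check_matrix_annotations(matrix, annotations)
  if (is.null(annotations[[factor_name]])) {
    stop_radage("factor '", factor_name, "' absent from annotations")
  }
  if (!split %in% annotations$split) {
    stop_radage("split '", split, "' absent from annotations")
  }
  ann <- annotations[annotations$split == split, , drop = FALSE]
  x <- as.character(ann[[factor_name]])
  levels_here <- sort(unique(x))
  test_levels <- if (length(levels_here) == 2L) levels_here[1] else levels_here
  out <- list()
  skipped <- character()
  for (lv in test_levels) {
    ids_A <- ann$sample_id[x == lv]
    ids_B <- ann$sample_id[x != lv]
    if (length(ids_A) < 2 || length(ids_B) < 2) {
      skipped <- c(skipped, lv)
      next
    }
    out[[paste0(factor_name, ".", lv, "_vs_rest")]] <-
      two_group_de(matrix, ids_A, ids_B,
                   contrast = paste0(split, ":", factor_name, ":", lv))
  }
  attr(out, "skipped") <- skipped
  out
}

#' All one-vs-rest tables across factors and splits
#'
#' @param matrix Genes x samples matrix.
#' @param annotations Annotations with disease, ethnicity, sex and split.
#' @param factors Factor columns to test.
#' @param splits Splits to cover.
#' @return Nested list: `tables[[split]]` is the pooled named list of
#'   one-vs-rest DE tables for all factors in that split.
#' @export
one_vs_rest_battery <- function(matrix, annotations,
                                factors = c("disease", "ethnicity", "sex"),
                                splits = c("train", "test", "validation")) {
  out <- list()
  for (s in splits) {
    tabs <- list()
    for (f in factors) {
      tabs <- c(tabs, one_vs_rest_tables(matrix, annotations, f, s))
    }
    out[[s]] <- tabs
  }
  out
}

#' Cross-split candidate gene filter
#'
#' A gene survives when, in every required split, it passes at least
#' `min_test_cases` distinct one-vs-rest test cases, where passing a test
#' case means p below `alpha` together with a fold change beyond the gate.
#' Relaxing `alpha` or `fc_threshold` never shrinks the surviving set.
#'
#' @param gene_list Genes to evaluate (evaluation is restricted to them).
#' @param tables_by_split Output of [one_vs_rest_battery()].
#' @param config A [candidate_filter_config()].
#' @return Character vector of surviving genes (alphabetical), with the
#'   number of genes absent from the disease tables in `attr(, "n_missing")`.
#' @export
filter_candidates <- function(gene_list, tables_by_split,
                              config = candidate_filter_config()) {
  missing_splits <- setdiff(config$required_splits, names(tables_by_split))
  if (length(missing_splits)) {
    stop_radage("tables missing for split(s): ",
                paste(missing_splits, collapse = ", "))
  }
  fc_gate <- if (config$fc_on == "linear") log2(config$fc_threshold)
             else config$fc_threshold
  all_genes <- unique(unlist(lapply(tables_by_split[[config$required_splits[1]]],
                                    function(tb) tb$gene)))
  absent <- setdiff(gene_list, all_genes)
  if (length(absent)) {
    warning(length(absent), " gene(s) absent from the disease tables, dropped")
  }
  genes <- setdiff(gene_list, absent)
  survives <- vapply(genes, function(g) {
    all(vapply(config$required_splits, function(s) {
      hits <- vapply(tables_by_split[[s]], function(tb) {
        row <- tb[tb$gene == g, , drop = FALSE]
        if (!nrow(row)) return(FALSE)
        fc_ok <- if (config$signed_only) row$log2FC > fc_gate
                 else abs(row$log2FC) > fc_gate
        row$p_value < config$alpha && fc_ok
      }, logical(1))
      sum(hits) >= config$min_test_cases
    }, logical(1)))
  }, logical(1))
  out <- sort(genes[survives])
  attr(out, "n_missing") <- length(absent)
  out
}

#' Three-way disease x ethnicity x sex interaction model for one gene
#'
#' Ordinary least squares with full factorial dummy coding,
#' `y ~ disease * ethnicity * sex`. The three-way p-value is the partial
#' F-test comparing the full model with the model holding all terms up to
#' two-way interactions; two-way and main-effect blocks are tested the same
#' way against the model without the respective block (type-II style).
#' Empty factorial cells are handled by dropping aliased coefficients, and
#' the number dropped is reported.
#'
#' @param y Per-sample expression of one gene.
#' @param disease,ethnicity,sex Factor labels per sample.
#' @return List: `p_three_way`, `p_two_way` (named), `p_main` (named),
#'   `df_residual`, `n_dropped_coef`.
#' @export
fit_three_way <- function(y, disease, ethnicity, sex) {
  d <- droplevels(as.factor(disease))
  e <- droplevels(as.factor(ethnicity))
  s <- droplevels(as.factor(sex))
  for (f in list(disease = d, ethnicity = e, sex = s)) {
    if (nlevels(f) < 2) {
      stop_radage("every factor needs at least 2 levels present")
    }
  }
  tab <- table(d, e, s)
  dat <- data.frame(y = y, d = d, e = e, s = s)
  full <- stats::lm(y ~ d * e * s, data = dat)
  if (full$df.residual == 0) {
    stop_radage("saturated model with zero residual df; merge factor levels")
  }
  n_dropped <- sum(is.na(stats::coef(full)))
  two_way <- stats::lm(y ~ (d + e + s)^2, data = dat)
  p3 <- stats::anova(two_way, full)[2, "Pr(>F)"]
  drop_p <- function(base_formula, drop_term, against) {
    red <- stats::lm(stats::update(base_formula, paste("~ . -", drop_term)),
                     data = dat)
    stats::anova(red, against)[2, "Pr(>F)"]
  }
  p2 <- c(
    disease_ethnicity = drop_p(y ~ (d + e + s)^2, "d:e", two_way),
    disease_sex = drop_p(y ~ (d + e + s)^2, "d:s", two_way),
    ethnicity_sex = drop_p(y ~ (d + e + s)^2, "e:s", two_way)
  )
  main <- stats::lm(y ~ d + e + s, data = dat)
  p1 <- c(
    disease = drop_p(y ~ d + e + s, "d", main),
    ethnicity = drop_p(y ~ d + e + s, "e", main),
    sex = drop_p(y ~ d + e + s, "s", main)
  )
  list(p_three_way = p3, p_two_way = p2, p_main = p1,
       df_residual = full$df.residual, n_dropped_coef = n_dropped)
}

#' Three-way interaction table for a gene set
#'
#' @param matrix Genes x samples matrix.
#' @param annotations Annotations with disease, ethnicity, sex.
#' @param genes Genes to fit (default all).
#' @return Data.frame: gene, p_three_way, p_two_way_min, p_main_min,
#'   df_residual.
#' @export
three_way_table <- function(matrix, annotations, genes = rownames(matrix)) {
  check_matrix_annotations(matrix, annotations)
  ann <- align_annotations(matrix, annotations)
  rows <- lapply(genes, function(g) {
    fit <- fit_three_way(matrix[g, ], ann$disease, ann$ethnicity, ann$sex)
    data.frame(gene = g,
               p_three_way = fit$p_three_way,
               p_two_way_min = min(fit$p_two_way),
               p_main_min = min(fit$p_main),
               df_residual = fit$df_residual,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Tiered clinical-gene report
#'
#' Genes are tiered by the deepest significant interaction: tier 1 for a
#' significant three-way interaction, tier 2 for any significant two-way
#' interaction, tier 3 for any significant main effect; others are
#' unassigned (tier NA). Within a tier, genes sort by the tier's p-value.
#'
#' @param results Data.frame from [three_way_table()].
#' @param alpha Significance level (default 0.05).
#' @return Data.frame: gene, tier, tier_p, p_three_way, p_two_way_min,
#'   p_main_min.
#' @export
rank_clinical_genes <- function(results, alpha = 0.05) {
  if (!nrow(results)) stop_radage("empty results")
  tier <- ifelse(results$p_three_way < alpha, 1L,
          ifelse(results$p_two_way_min < alpha, 2L,
          ifelse(results$p_main_min < alpha, 3L, NA_integer_)))
  tier_p <- ifelse(!is.na(tier) & tier == 1L, results$p_three_way,
            ifelse(!is.na(tier) & tier == 2L, results$p_two_way_min,
            ifelse(!is.na(tier) & tier == 3L, results$p_main_min, NA_real_)))
  out <- data.frame(gene = results$gene, tier = tier, tier_p = tier_p,
                    p_three_way = results$p_three_way,
                    p_two_way_min = results$p_two_way_min,
                    p_main_min = results$p_main_min,
                    stringsAsFactors = FALSE)
  out[order(out$tier, out$tier_p, out$gene, na.last = TRUE), ]
}
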