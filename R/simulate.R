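# Synthetic cohort generator: expression matrices with controllable age, dose,
# interaction, batch and disease structure, for testing every pipeline stage
# against known ground truth.

#' Describe a synthetic radiation/age cohort
#'
#' A cohort design captures the sampling frame the generator draws from:
#' cohort size, number of genes, the chronological-age range, the absorbed-dose
#' levels (Gy) with their sampling weights, the sex ratio, batch structure and
#' the log2-scale noise level.
#'
#' @param n_samples Number of samples.
#' @param n_genes Number of genes.
#' @param age_range Length-2 numeric, min/max age in years (within 18-90).
#'   Ages are drawn uniformly over the range so every candidate cutoff in a
#'   threshold scan has support.
#' @param dose_levels Absorbed dose levels in Gy (all >= 0).
#' @param dose_weights Sampling weights for `dose_levels`; normalised to sum 1.
#' @param sex_ratio Fraction of male samples in [0, 1].
#' @param n_batches Number of batches (cohorts/studies).
#' @param batch_shifts Per-batch additive offsets in log2 units
#'   (length `n_batches`; default all zero).
#' @param noise_sd Gaussian noise standard deviation, log2 units (> 0).
#' @param baseline_mean Baseline log2 expression level.
#' @param dose_scale How gene effects scale with exposure: `"bin"` applies
#'   effects per ordinal radiation-bin code 0-3 (the scale the downstream
#'   interaction models use), `"Gy"` per gray.
#' @return An object of class `cohort_design`.
#' @seealso [simulate_cohort()], [effect_spec()]
#' @export
cohort_design <- function(n_samples, n_genes,
                          age_range = c(21, 69),
                          dose_levels = c(0, 0.1, 0.2, 0.5, 2),
                          dose_weights = NULL,
                          sex_ratio = 0.5,
                          n_batches = 1,
                          batch_shifts = NULL,
                          noise_sd = 1,
                          baseline_mean = 8,
                          dose_scale = c("bin", "Gy")) {
  n_samples <- check_count(n_samples, "n_samples")
  n_genes <- check_count(n_genes, "n_genes")
  if (length(age_range) != 2L || age_range[1] >= age_range[2]) {
    stop_radage("age_range must be (min, max) with min < max")
  }
  if (age_range[1] < 18 || age_range[2] > 90) {
    stop_radage("age_range must lie within [18, 90] years")
  }
  if (any(dose_levels < 0)) stop_radage("dose_levels must all be >= 0 Gy")
  if (is.null(dose_weights)) dose_weights <- rep(1, length(dose_levels))
  if (length(dose_weights) != length(dose_levels) || any(dose_weights < 0)) {
    stop_radage("dose_weights must be non-negative and match dose_levels")
  }
  dose_weights <- dose_weights / sum(dose_weights)
  check_number(sex_ratio, "sex_ratio", 0, 1)
  n_batches <- check_count(n_batches, "n_batches")
  if (is.null(batch_shifts)) batch_shifts <- rep(0, n_batches)
  if (length(batch_shifts) != n_batches) {
    stop_radage("batch_shifts must have one entry per batch")
  }
  check_number(noise_sd, "noise_sd", min = 1e-12)
  check_number(baseline_mean, "baseline_mean")
  structure(
    list(
      n_samples = n_samples, n_genes = n_genes, age_range = age_range,
      dose_levels = dose_levels, dose_weights = dose_weights,
      sex_ratio = sex_ratio, n_batches = n_batches,
      batch_shifts = batch_shifts, noise_sd = noise_sd,
      baseline_mean = baseline_mean, dose_scale = match.arg(dose_scale)
    ),
    class = "cohort_design"
  )
}

#' Declare a per-gene ground-truth effect
#'
#' Encodes the generative counterpart of the per-gene linear interaction model:
#' an age effect (linear slope per year or a step of height `age_effect` at
#' `true_cutoff`), a radiation-dose effect, and an age-by-dose interaction.
#'
#' @param gene_index 1-based gene index within the cohort design.
#' @param age_mode One of `"none"`, `"linear"`, `"step"`.
#' @param age_effect Log2 units: slope per year (linear) or step height at
#'   `true_cutoff` (step), applied to the young side (age <= cutoff).
#' @param true_cutoff Age in years at which a step effect switches.
#' @param dose_effect Log2 units per dose unit (bin code or Gy, per the
#'   design's `dose_scale`).
#' @param interaction_effect Log2 units for the age-term-by-dose product.
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(gene_index, age_mode = c("none", "linear", "step"),
                        age_effect = 0, true_cutoff = NA_real_,
                        dose_effect = 0, interaction_effect = 0) {
  gene_index <- check_count(gene_index, "gene_index")
  age_mode <- match.arg(age_mode)
  if (age_mode == "step" && !is.finite(true_cutoff)) {
    stop_radage("step mode requires a finite true_cutoff")
  }
  structure(
    list(
      gene_index = gene_index, age_mode = age_mode, age_effect = age_effect,
      true_cutoff = true_cutoff, dose_effect = dose_effect,
      interaction_effect = interaction_effect
    ),
    class = "effect_spec"
  )
}

age_term_for <- function(spec, age) {
  switch(spec$age_mode,
    none = rep(0, length(age)),
    linear = age - mean(age),
    step = as.numeric(age <= spec$true_cutoff)
  )
}

#' Simulate a radiation/age expression cohort
#'
#' Draws ages uniformly over the design's age range, assigns doses from the
#' design's dose levels, and generates log2 expression per gene g and sample s
#' as
#' \deqn{y = baseline + effect_{age} \cdot a(s) + effect_{dose} \cdot d(s) +
#'       effect_{int} \cdot a(s) d(s) + shift_{batch(s)} + N(0, \sigma^2)}
#' where the age term \eqn{a(s)} is centred age (linear mode) or the young
#' indicator \eqn{1\{age \le cutoff\}} (step mode), and \eqn{d(s)} is the dose
#' on the design's `dose_scale`. Output is bit-identical for a fixed seed.
#'
#' @param design A [cohort_design()].
#' @param effects List of [effect_spec()] objects (genes without a spec are
#'   pure noise around the baseline).
#' @param seed Integer seed.
#' @return A list with `matrix` (genes x samples, log2 scale) and
#'   `annotations` (data.frame: sample_id, dataset_id, donor_id, age, dose_Gy,
#'   radiation_bin, rad_code, sex).
#' @export
simulate_cohort <- function(design, effects = list(), seed = 1L) {
  stopifnot(inherits(design, "cohort_design"))
  if (inherits(effects, "effect_spec")) effects <- list(effects)
  for (e in effects) {
    stopifnot(inherits(e, "effect_spec"))
    if (e$gene_index > design$n_genes) {
      stop_radage(sprintf("effect gene_index %d out of range (n_genes = %d)",
                          e$gene_index, design$n_genes))
    }
    if (e$age_mode == "step" &&
        (e$true_cutoff < design$age_range[1] || e$true_cutoff > design$age_range[2])) {
      stop_radage("step true_cutoff must lie inside the design age_range")
    }
  }
  with_seed(derive_seed(seed, 11L), {
    n <- design$n_samples
    g <- design$n_genes
    age <- round(stats::runif(n, design$age_range[1], design$age_range[2]))
    dose <- sample(design$dose_levels, n, replace = TRUE, prob = design$dose_weights)
    sex <- ifelse(stats::runif(n) < design$sex_ratio, "male", "female")
    batch <- sample(rep_len(seq_len(design$n_batches), n))
    sample_id <- sprintf("S%04d", seq_len(n))
    bins <- assign_radiation_bin(dose)
    ann <- data.frame(
      sample_id = sample_id,
      dataset_id = paste0("batch", batch),
      donor_id = sample_id,
      age = age,
      dose_Gy = dose,
      radiation_bin = bins$label,
      rad_code = bins$code,
      sex = sex,
      stringsAsFactors = FALSE
    )
    d <- if (design$dose_scale == "bin") bins$code else dose
    mat <- matrix(stats::rnorm(g * n, 0, design$noise_sd), nrow = g, ncol = n)
    mat <- mat + design$baseline_mean
    mat <- sweep(mat, 2, design$batch_shifts[batch], "+")
    for (e in effects) {
      a <- age_term_for(e, age)
      mat[e$gene_index, ] <- mat[e$gene_index, ] +
        e$age_effect * a + e$dose_effect * d + e$interaction_effect * a * d
    }
    rownames(mat) <- sprintf("gene%04d", seq_len(g))
    colnames(mat) <- sample_id
    list(matrix = mat, annotations = ann)
  })
}

#' Describe a synthetic lung-disease cohort
#'
#' Mirrors the structure of a multi-split clinical expression cohort: samples
#' pre-assigned to train/test/validation splits carrying disease, ethnicity and
#' sex labels. Defaults reproduce the reference cohort layout used by the
#' pipeline's clinical stage: splits of 93/102/41 samples (236 total) with
#' control, pneumonia, TB, active/non-active sarcoidosis and lung-cancer
#' disease levels.
#'
#' @param n_per_split Named counts for train/test/validation.
#' @param n_genes Number of genes.
#' @param disease_levels,ethnicity_levels,sex_levels Factor level sets.
#' @param marker_specs List of [disease_marker()] objects.
#' @param noise_sd Gaussian noise sd, log2 units.
#' @param baseline_mean Baseline log2 expression.
#' @return Object of class `disease_design`.
#' @export
disease_design <- function(n_per_split = c(train = 93, test = 102, validation = 41),
                           n_genes = 100,
                           disease_levels = c("control", "pneumonia", "TB",
                                              "active_sarcoidosis",
                                              "non_active_sarcoidosis",
                                              "lung_cancer"),
                           ethnicity_levels = c("Caucasian", "African", "Indian"),
                           sex_levels = c("male", "female"),
                           marker_specs = list(),
                           noise_sd = 1,
                           baseline_mean = 8) {
  if (is.null(names(n_per_split)) ||
      !setequal(names(n_per_split), c("train", "test", "validation"))) {
    stop_radage("n_per_split must be named train/test/validation")
  }
  if (any(n_per_split <= 0)) stop_radage("every split count must be > 0")
  n_genes <- check_count(n_genes, "n_genes")
  for (lv in list(disease_levels, ethnicity_levels, sex_levels)) {
    if (!length(lv)) stop_radage("factor level sets must be non-empty")
  }
  if (inherits(marker_specs, "disease_marker")) marker_specs <- list(marker_specs)
  for (m in marker_specs) {
    stopifnot(inherits(m, "disease_marker"))
    if (m$gene_index > n_genes) stop_radage("marker gene_index out of range")
  }
  check_number(noise_sd, "noise_sd", min = 1e-12)
  structure(
    list(
      n_per_split = n_per_split[c("train", "test", "validation")],
      n_genes = n_genes, disease_levels = disease_levels,
      ethnicity_levels = ethnicity_levels, sex_levels = sex_levels,
      marker_specs = marker_specs, noise_sd = noise_sd,
      baseline_mean = baseline_mean
    ),
    class = "disease_design"
  )
}

#' Declare a disease-cohort marker gene
#'
#' The additive `shift` applies to samples matching every level that is
#' specified; leaving a factor `NULL` matches any level. Specifying one factor
#' gives a main effect, two a two-way cell effect, all three a pure three-way
#' cell offset.
#'
#' @param gene_index 1-based gene index.
#' @param disease,ethnicity,sex Optional level names the shift is conditioned on.
#' @param shift Additive log2 shift.
#' @export
disease_marker <- function(gene_index, disease = NULL, ethnicity = NULL,
                           sex = NULL, shift = 0) {
  gene_index <- check_count(gene_index, "gene_index")
  structure(
    list(gene_index = gene_index, disease = disease, ethnicity = ethnicity,
         sex = sex, shift = shift),
    class = "disease_marker"
  )
}

#' Simulate a multi-split lung-disease cohort
#'
#' Labels are assigned independently per factor within each split (label
#' vectors are permuted to decouple factors), marker genes are shifted per
#' their [disease_marker()] specs, and all remaining structure is Gaussian
#' noise on the log2 scale. Seed-deterministic.
#'
#' @param design A [disease_design()].
#' @param seed Integer seed.
#' @return List with `matrix` and `annotations` (sample_id, disease,
#'   ethnicity, sex, split).
#' @export
simulate_disease_cohort <- function(design, seed = 1L) {
  stopifnot(inherits(design, "disease_design"))
  with_seed(derive_seed(seed, 13L), {
    splits <- rep(names(design$n_per_split), design$n_per_split)
    n <- length(splits)
    g <- design$n_genes
    assign_factor <- function(levels) {
      out <- character(n)
      for (s in unique(splits)) {
        idx <- which(splits == s)
        # every level represented where the split is big enough
        lab <- rep_len(levels, length(idx))
        out[idx] <- sample(lab)
      }
      out
    }
    ann <- data.frame(
      sample_id = sprintf("D%04d", seq_len(n)),
      disease = assign_factor(design$disease_levels),
      ethnicity = assign_factor(design$ethnicity_levels),
      sex = assign_factor(design$sex_levels),
      split = splits,
      stringsAsFactors = FALSE
    )
    mat <- matrix(stats::rnorm(g * n, design$baseline_mean, design$noise_sd),
                  nrow = g, ncol = n)
    for (m in design$marker_specs) {
      hit <- rep(TRUE, n)
      if (!is.null(m$disease)) hit <- hit & ann$disease %in% m$disease
      if (!is.null(m$ethnicity)) hit <- hit & ann$ethnicity %in% m$ethnicity
      if (!is.null(m$sex)) hit <- hit & ann$sex %in% m$sex
      mat[m$gene_index, hit] <- mat[m$gene_index, hit] + m$shift
    }
    rownames(mat) <- sprintf("gene%04d", seq_len(g))
    colnames(mat) <- ann$sample_id
    list(matrix = mat, annotations = ann)
  })
}

#' Add per-batch additive shifts to an expression matrix
#'
#' @param matrix Genes x samples numeric matrix.
#' @param annotations Sample annotations with `dataset_id` batch labels.
#' @param shifts Named numeric vector of log2 offsets, one per batch label.
#' @return A new matrix; the input is not modified.
#' @export
add_batch_effect <- function(matrix, annotations, shifts) {
  check_matrix_annotations(matrix, annotations)
  ann <- align_annotations(matrix, annotations)
  batch <- as.character(ann$dataset_id)
  unknown <- setdiff(unique(batch), names(shifts))
  if (length(unknown)) {
    stop_radage("no shift entry for batch: ", paste(unknown, collapse = ", "))
  }
  sweep(matrix, 2, shifts[batch], "+")
}

#' Write expression and annotation tables
#'
#' Expression goes out as tab-delimited text with the gene id in the first
#' column and sample ids as the header; annotations as a tab-delimited sheet.
#'
#' @param matrix Genes x samples matrix.
#' @param path Output file path.
#' @export
write_expression_table <- function(matrix, path) {
  df <- data.frame(gene_id = rownames(matrix), matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_table
#' @param annotations Sample annotation data.frame.
#' @export
write_annotation_table <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Emit a miniature multi-cohort fixture layout
#'
#' Writes a small five-cohort directory (two age cohorts, three radiation
#' cohorts) of paired expression/annotation tables, mirroring the combined
#' study structure the pipeline ingests: ages 21-69, dose levels
#' 0/0.1/0.2/0.5/2 Gy, per-cohort batch shifts.
#'
#' @param dir Output directory (created if missing).
#' @param n_genes Genes per cohort.
#' @param seed Integer seed.
#' @return Invisibly, a data.frame manifest of the files written.
#' @export
write_cohort_fixture <- function(dir, n_genes = 50, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  layouts <- list(
    cohortA1 = list(n = 20, doses = 0),
    cohortA2 = list(n = 30, doses = 0),
    cohortR1 = list(n = 8, doses = c(0, 0.2, 2)),
    cohortB1 = list(n = 12, doses = c(0, 0.5)),
    cohortB2 = list(n = 16, doses = c(0, 0.1, 0.5, 2))
  )
  manifest <- data.frame(cohort = character(), expression = character(),
                         annotations = character(), stringsAsFactors = FALSE)
  for (i in seq_along(layouts)) {
    nm <- names(layouts)[i]
    ly <- layouts[[i]]
    des <- cohort_design(ly$n, n_genes, dose_levels = ly$doses,
                         batch_shifts = (i - 3) / 2, noise_sd = 0.8)
    sim <- simulate_cohort(des, seed = derive_seed(seed, i))
    sim$annotations$dataset_id <- nm
    sim$annotations$sample_id <- paste0(nm, "_", sim$annotations$sample_id)
    colnames(sim$matrix) <- sim$annotations$sample_id
    ep <- file.path(dir, paste0(nm, "_expression.tsv"))
    ap <- file.path(dir, paste0(nm, "_annotations.tsv"))
    write_expression_table(sim$matrix, ep)
    write_annotation_table(sim$annotations, ap)
    manifest <- rbind(manifest, data.frame(cohort = nm, expression = ep,
                                           annotations = ap))
  }
  invisible(manifest)
}
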