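# Build a battery of fake one-vs-rest tables from a per-gene profile matrix:
# profiles[[split]][gene, case] = c(p, log2FC) encoded as list entries.
fake_table <- function(genes, p, fc) {
  data.frame(gene = genes, t_statistic = 0, p_value = p, fdr_q = p,
             log2FC = fc, n_A = 5, n_B = 20, contrast = "x",
             stringsAsFactors = FALSE)
}

test_that("one-vs-rest tables cover testable levels and mirror two-level factors", {
  des <- disease_design(n_genes = 30, noise_sd = 0.5)
  sim <- simulate_disease_cohort(des, seed = 5)
  tabs <- one_vs_rest_tables(sim$matrix, sim$annotations, "sex", "train")
  expect_length(tabs, 1L)  # female-vs-rest mirrors male-vs-rest
  expect_equal(names(tabs), "sex.female_vs_rest")

  dtabs <- one_vs_rest_tables(sim$matrix, sim$annotations, "disease", "train")
  expect_gte(length(dtabs), 4L)
  expect_error(one_vs_rest_tables(sim$matrix, sim$annotations, "nope", "train"),
               "absent")
  expect_error(one_vs_rest_tables(sim$matrix, sim$annotations, "sex", "bogus"),
               "bogus")
})

test_that("a constructed marker passes one-vs-rest in every split", {
  des <- disease_design(
    n_genes = 15,
    marker_specs = disease_marker(7, disease = "lung_cancer", shift = 3),
    noise_sd = 0.3
  )
  sim <- simulate_disease_cohort(des, seed = 8)
  for (s in c("train", "test", "validation")) {
    tabs <- one_vs_rest_tables(sim$matrix, sim$annotations, "disease", s)
    tb <- tabs[["disease.lung_cancer_vs_rest"]]
    row <- tb[tb$gene == "gene0007", ]
    expect_lt(row$p_value, 0.05)
    expect_gt(row$log2FC, 2)
  }
})

test_that("null one-vs-rest significant fractions stay near alpha", {
  des <- disease_design(n_genes = 600, noise_sd = 1)
  sim <- simulate_disease_cohort(des, seed = 12)
  tabs <- one_vs_rest_tables(sim$matrix, sim$annotations, "ethnicity", "test")
  for (tb in tabs) {
    expect_lt(abs(mean(tb$p_value < 0.05) - 0.05),
              3 * sqrt(0.05 * 0.95 / 600) + 0.01)
  }
})

test_that("the candidate filter enforces the all-splits, two-case, fold-change rule", {
  genes <- sprintf("g%02d", 1:10)
  # gene profiles: g01 passes 2 cases everywhere; g02 passes 2 in train/test
  # but 1 in validation; g03 has p ok but |fc| <= 2 everywhere; g04 passes 3
  # cases everywhere; others null
  mk_split <- function(p1, f1, p2, f2, p3, f3) {
    list(
      case1 = fake_table(genes, p = p1, fc = f1),
      case2 = fake_table(genes, p = p2, fc = f2),
      case3 = fake_table(genes, p = p3, fc = f3)
    )
  }
  base_p <- rep(0.8, 10); base_f <- rep(0.1, 10)
  pr <- function(hits) replace(base_p, hits, 0.01)
  fc <- function(hits, v = 3) replace(base_f, hits, v)
  tables <- list(
    train = mk_split(pr(c(1, 2, 4)), fc(c(1, 2, 4)),
                     pr(c(1, 2, 4)), fc(c(1, 2, 4)),
                     pr(c(3, 4)), fc(4)),
    test = mk_split(pr(c(1, 2, 4)), fc(c(1, 2, 4)),
                    pr(c(1, 2, 4)), fc(c(1, 2, 4)),
                    pr(c(3, 4)), fc(4)),
    validation = mk_split(pr(c(1, 4)), fc(c(1, 4)),
                          pr(c(1, 2, 4)), fc(c(1, 4)),
                          pr(c(3, 4)), fc(4))
  )
  # g03's p hits carry no fold change; in validation g02's second case has
  # p < .05 but fc below the gate
  got <- filter_candidates(genes, tables, candidate_filter_config())

  # brute-force oracle of the written rule
  oracle <- Filter(function(g) {
    all(vapply(names(tables), function(s) {
      hits <- vapply(tables[[s]], function(tb) {
        row <- tb[tb$gene == g, ]
        row$p_value < 0.05 && abs(row$log2FC) > 2
      }, logical(1))
      sum(hits) >= 2
    }, logical(1)))
  }, genes)
  expect_equal(as.character(got), sort(as.character(oracle)))
  expect_equal(as.character(got), c("g01", "g04"))

  # monotonicity: relaxing thresholds never shrinks the set
  relaxed <- filter_candidates(genes, tables,
                               candidate_filter_config(alpha = 0.2,
                                                       fc_threshold = 1))
  expect_true(all(got %in% relaxed))

  # absent genes are dropped with a warning and counted
  expect_warning(
    w <- filter_candidates(c(genes, "missing"), tables,
                           candidate_filter_config()),
    "absent"
  )
  expect_equal(attr(w, "n_missing"), 1L)
})

test_that("three-way interaction nulls are calibrated", {
  withr::with_seed(14, {
    n <- 120
    d <- sample(c("control", "TB", "cancer"), n, replace = TRUE)
    e <- sample(c("A", "B"), n, replace = TRUE)
    s <- sample(c("m", "f"), n, replace = TRUE)
    hits <- vapply(1:400, function(i) {
      y <- 8 + 0.5 * (d == "TB") + 0.3 * (e == "A") + 0.2 * (s == "m") + rnorm(n)
      fit_three_way(y, d, e, s)$p_three_way < 0.05
    }, logical(1))
    expect_lt(abs(mean(hits) - 0.05), 0.035)
  })
})

test_that("a pure three-way cell offset is detected with exact cell recovery", {
  # balanced noiseless-ish 2x2x2 design with an offset in one cell
  grid <- expand.grid(d = c("a", "b"), e = c("x", "y"), s = c("m", "f"),
                      rep = 1:5)
  withr::with_seed(16, {
    y <- rnorm(nrow(grid), 8, 1e-6)
    cell <- grid$d == "b" & grid$e == "y" & grid$s == "f"
    y[cell] <- y[cell] + 2
    fit <- fit_three_way(y, grid$d, grid$e, grid$s)
    expect_lt(fit$p_three_way, 1e-10)

    # cell-means oracle for the 2x2x2 three-way contrast
    cm <- tapply(y, list(grid$d, grid$e, grid$s), mean)
    contrast <- (cm["b", "y", "f"] - cm["a", "y", "f"] -
                 cm["b", "x", "f"] + cm["a", "x", "f"]) -
                (cm["b", "y", "m"] - cm["a", "y", "m"] -
                 cm["b", "x", "m"] + cm["a", "x", "m"])
    expect_equal(contrast, 2, tolerance = 1e-4)

    # partial F equals the squared t of the single three-way coefficient here
    dat <- data.frame(y = y, d = grid$d, e = grid$e, s = grid$s)
    full <- lm(y ~ d * e * s, data = dat)
    tval <- summary(full)$coefficients["db:ey:sf", 3]
    f_from_anova <- anova(lm(y ~ (d + e + s)^2, data = dat), full)[2, "F"]
    expect_equal(f_from_anova, tval^2, tolerance = 1e-8)
  })
})

test_that("three-way fitting validates factors and saturation", {
  y <- rnorm(12)
  expect_error(fit_three_way(y, rep("a", 12), rep(c("x", "y"), 6),
                             rep(c("m", "f"), 6)), "2 levels")
  grid <- expand.grid(d = c("a", "b"), e = c("x", "y"), s = c("m", "f"))
  expect_error(fit_three_way(rnorm(8), grid$d, grid$e, grid$s), "saturated")
})

test_that("clinical genes tier by deepest significant interaction", {
  withr::with_seed(18, {
    grid <- expand.grid(d = c("a", "b"), e = c("x", "y"), s = c("m", "f"),
                        rep = 1:8)
    n <- nrow(grid)
    three <- rnorm(n, 8, 0.2) +
      3 * (grid$d == "b" & grid$e == "y" & grid$s == "f")
    twow <- rnorm(n, 8, 0.2) + 2 * (grid$d == "b" & grid$s == "f")
    mains <- rnorm(n, 8, 0.2) + 1.5 * (grid$d == "b")
    nul <- rnorm(n, 8, 0.2)
    m <- rbind(gThree = three, gTwo = twow, gMain = mains, gNull = nul)
    colnames(m) <- sprintf("s%03d", 1:n)
    ann <- data.frame(sample_id = colnames(m), disease = grid$d,
                      ethnicity = grid$e, sex = grid$s)
    tw <- three_way_table(m, ann)
    rk <- rank_clinical_genes(tw, alpha = 0.05)
    expect_equal(rk$tier[rk$gene == "gThree"], 1L)
    expect_equal(rk$tier[rk$gene == "gTwo"], 2L)
    expect_equal(rk$tier[rk$gene == "gMain"], 3L)
    expect_equal(rk$gene[1], "gThree")

    # empty tiers are a valid report
    rk0 <- rank_clinical_genes(tw[tw$gene == "gNull", ], alpha = 1e-6)
    expect_true(is.na(rk0$tier))
  })
})

test_that("rare factor levels merge into 'other' before testing", {
  ann <- data.frame(
    sample_id = sprintf("s%02d", 1:30),
    ethnicity = c(rep("Caucasian", 24), rep("CentralAsia", 2),
                  rep("MiddleEast", 4)),
    split = rep(c("train", "test", "validation"), 10)
  )
  merged <- merge_rare_levels(ann, "ethnicity", min_n = 4)
  expect_setequal(unique(merged$ethnicity), c("Caucasian", "other"))
  expect_equal(sum(merged$ethnicity == "other"), 6L)
})
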