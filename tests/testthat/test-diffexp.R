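# Independent Welch-formula oracle for a single gene.
welch_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- var(a); vb <- var(b)
  se <- sqrt(va / na + vb / nb)
  t <- (mean(a) - mean(b)) / se
  df <- (va / na + vb / nb)^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, p = 2 * pt(-abs(t), df))
}

# Brute-force BH step-up by definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(m * p[o][i:m] / (i:m)))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

test_that("Welch t-statistics match the formula oracle and t.test", {
  withr::with_seed(5, {
    m <- toy_matrix(rnorm(10 * 12, 8), sprintf("g%02d", 1:10),
                    sprintf("s%02d", 1:12))
    de <- two_group_de(m, colnames(m)[1:5], colnames(m)[6:12])
    for (g in c(1, 4, 10)) {
      orc <- welch_oracle(m[g, 1:5], m[g, 6:12])
      expect_equal(de$t_statistic[g], orc$t, tolerance = 1e-10)
      expect_equal(de$p_value[g], orc$p, tolerance = 1e-10)
      tt <- t.test(m[g, 1:5], m[g, 6:12])
      expect_equal(de$p_value[g], tt$p.value, tolerance = 1e-10)
    }
  })
  # hand vectors
  m2 <- toy_matrix(c(1, 2, 3, 4, 5, 6), "g1", paste0("s", 1:6))
  de2 <- two_group_de(rbind(m2, g2 = m2[1, ]), paste0("s", 1:3), paste0("s", 4:6))
  orc2 <- welch_oracle(c(1, 2, 3), c(4, 5, 6))
  expect_equal(de2$t_statistic[1], orc2$t, tolerance = 1e-12)
  expect_equal(de2$p_value[1], orc2$p, tolerance = 1e-12)
})

test_that("a pure additive shift yields exactly that log2FC", {
  base <- rnorm(8, 8)
  m <- toy_matrix(c(base + 2, base), "g1", paste0("s", 1:16))
  m <- m[1, , drop = FALSE]
  de <- two_group_de(rbind(m, m), paste0("s", 1:8), paste0("s", 9:16))
  expect_equal(de$log2FC[1], 2, tolerance = 1e-12)
})

test_that("group order flips t and log2FC but not p or q", {
  withr::with_seed(9, {
    m <- toy_matrix(rnorm(20 * 10, 8), sprintf("g%02d", 1:20), paste0("s", 1:10))
    ab <- two_group_de(m, paste0("s", 1:4), paste0("s", 5:10))
    ba <- two_group_de(m, paste0("s", 5:10), paste0("s", 1:4))
    expect_equal(ab$t_statistic, -ba$t_statistic)
    expect_equal(ab$log2FC, -ba$log2FC)
    expect_equal(ab$p_value, ba$p_value)
    expect_equal(ab$fdr_q, ba$fdr_q)
  })
})

test_that("two_group_de validates groups and handles zero variance", {
  m <- toy_matrix(rep(1, 8), "g1", paste0("s", 1:8))
  expect_error(two_group_de(m, paste0("s", 1:4), paste0("s", 4:8)), "overlap")
  expect_error(two_group_de(m, "s1", paste0("s", 2:8)), "at least 2")
  expect_warning(de <- two_group_de(m, paste0("s", 1:4), paste0("s", 5:8)),
                 "zero variance")
  expect_equal(de$t_statistic, 0)
  expect_equal(de$p_value, 1)
})

test_that("BH adjustment matches a brute-force step-up oracle", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  withr::with_seed(11, {
    for (i in 1:50) {
      p <- runif(sample(1:40, 1))^sample(1:3, 1)
      q <- bh_adjust(p)
      expect_equal(q, bh_oracle(p), tolerance = 1e-12)
      expect_true(all(q >= p - 1e-15))
      expect_true(all(diff(q[order(p)]) >= -1e-15))
    }
  })
})

test_that("the default contrast battery yields six tables on full annotations", {
  des <- cohort_design(120, 30, dose_levels = c(0, 0.1, 0.5, 2),
                       noise_sd = 0.8)
  sim <- simulate_cohort(des, seed = 6)
  ann <- annotate_classes(sim$annotations, 29)
  de <- run_contrasts(sim$matrix, ann)
  expect_named(de, c("control_vs_any_radiation", "control_vs_low",
                     "low_vs_medium", "medium_vs_high", "young_vs_old",
                     "male_vs_female"))
  expect_true(all(vapply(de, nrow, 1L) == 30))
})

test_that("an underpopulated contrast is skipped with a warning", {
  des <- cohort_design(40, 10, dose_levels = c(0, 2))  # no low/medium doses
  sim <- simulate_cohort(des, seed = 6)
  ann <- annotate_classes(sim$annotations)
  ws <- capture_warnings(de <- run_contrasts(sim$matrix, ann))
  expect_true(any(grepl("skipped", ws)))
  expect_true("low_vs_medium" %in% attr(de, "skipped"))
  expect_false("low_vs_medium" %in% names(de))
})

test_that("a dose-responsive gene reaches FDR significance in control-vs-any", {
  des <- cohort_design(120, 200, dose_levels = c(0, 0.1, 0.5, 2),
                       dose_weights = c(0.5, 0.17, 0.17, 0.16), noise_sd = 0.8)
  eff <- list(effect_spec(1, "none", dose_effect = 1))
  sim <- simulate_cohort(des, eff, seed = 14)
  ann <- annotate_classes(sim$annotations)
  de <- run_contrasts(sim$matrix, ann)$control_vs_any_radiation
  expect_lt(de$fdr_q[de$gene == "gene0001"], 0.05)
})

test_that("null data rarely yields any FDR-significant gene", {
  bad <- 0L
  for (seed in 1:8) {
    sim <- null_cohort(n = 60, g = 500, seed = seed)
    ids <- sim$annotations$sample_id
    de <- two_group_de(sim$matrix, ids[1:30], ids[31:60])
    if (any(de$fdr_q < 0.05)) bad <- bad + 1L
  }
  expect_lte(bad, 1L)
})

test_that("intersection counts follow UpSet semantics and a brute-force oracle", {
  mk <- function(sig, all_genes) {
    data.frame(gene = all_genes, t_statistic = 0,
               p_value = ifelse(all_genes %in% sig, 0.001, 0.9),
               fdr_q = ifelse(all_genes %in% sig, 0.001, 0.9),
               log2FC = 0, n_A = 5, n_B = 5, contrast = "x")
  }
  genes <- letters[1:10]
  tabs <- list(t1 = mk(c("a", "b", "c"), genes),
               t2 = mk(c("b", "c", "d"), genes),
               t3 = mk(c("c", "e"), genes))
  got <- intersect_significant(tabs, alpha = 0.05)

  # brute-force enumeration over every gene's exact membership pattern
  sets <- list(t1 = c("a", "b", "c"), t2 = c("b", "c", "d"), t3 = c("c", "e"))
  uni <- unique(unlist(sets))
  for (r in seq_len(nrow(got))) {
    pat <- unlist(got[r, c("t1", "t2", "t3")])
    expected <- sum(vapply(uni, function(g) {
      all(vapply(names(sets), function(s) (g %in% sets[[s]]) == pat[[s]],
                 logical(1)))
    }, logical(1)))
    expect_equal(got$count[r], expected)
  }
  # counts over all subsets sum to the union size
  expect_equal(sum(got$count), length(uni))

  # identical tables concentrate in the 'both' cell
  two <- intersect_significant(tabs[c(1, 1)], alpha = 0.05)
  expect_equal(two$count[two[[1]] & two[[2]]], 3L)
  expect_equal(sum(two$count), 3L)

  # disjoint sets have an empty intersection cell
  dis <- intersect_significant(list(x = mk("a", genes), y = mk("b", genes)))
  expect_equal(dis$count[dis$x & dis$y], 0L)
})

test_that("dose-trend profiles report the sign of successive bin means", {
  doses <- rep(c(0, 0.2, 0.7, 2), each = 5)
  bins <- assign_radiation_bin(doses)
  ann <- data.frame(sample_id = paste0("s", 1:20), dataset_id = "b1",
                    age = 30, dose_Gy = doses, radiation_bin = bins$label,
                    rad_code = bins$code)
  m <- rbind(
    up = bins$code + 0,                       # (+,+,+) by construction
    flat = rep(1, 20),                        # (0,0,0)
    dip = c(rep(2, 5), rep(1, 5), rep(2, 5), rep(3, 5))  # (-,+,+)
  )
  colnames(m) <- ann$sample_id
  got <- dose_trend(m, ann)
  expect_equal(got$profile, c("(+,+,+)", "(0,0,0)", "(-,+,+)"))

  ann2 <- ann[ann$radiation_bin != "low", ]
  expect_error(dose_trend(m[, ann2$sample_id], ann2), "low")
})
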