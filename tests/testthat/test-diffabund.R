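test_that("ANOVA + Tukey matches hand-computed sums of squares and TukeyHSD", {
  y <- c(1, 2, 3, 4, 5, 6, 1, 2, 3)
  g <- rep(c("CTL", "RHI", "AD"), each = 3)
  m <- matrix(y, 9, 1, dimnames = list(paste0("S", 1:9), "P1"))
  res <- anova_tukey(m, g)
  # independent oracle: explicit sums of squares + studentized range CDF
  gm <- tapply(y, g, mean); n_i <- tapply(y, g, length)
  ssb <- sum(n_i * (gm - mean(y))^2)
  ssw <- sum((y - gm[g])^2)
  f_oracle <- (ssb / 2) / (ssw / 6)
  expect_equal(res$f[1], f_oracle, tolerance = 1e-12)
  expect_equal(res$p_anova[1], pf(f_oracle, 2, 6, lower.tail = FALSE),
               tolerance = 1e-12)
  # cross-check every pairwise Tukey p against stats::TukeyHSD
  hsd <- TukeyHSD(aov(y ~ factor(g)))[[1]]
  for (i in seq_len(nrow(res))) {
    key1 <- paste0(res$group_a[i], "-", res$group_b[i])
    key2 <- paste0(res$group_b[i], "-", res$group_a[i])
    row <- if (key1 %in% rownames(hsd)) hsd[key1, ] else hsd[key2, ]
    expect_equal(res$p_tukey[i], unname(row["p adj"]), tolerance = 1e-8)
  }
})

test_that("identical groups give F = 0 and Tukey p = 1; antisymmetry of log2FC holds", {
  m <- matrix(rep(c(1, 2, 3), 3), 9, 1,
              dimnames = list(paste0("S", 1:9), "P1"))
  g <- rep(c("A", "B", "C"), each = 3)  # every group holds {1,2,3}
  res <- anova_tukey(m, g)
  expect_equal(res$f[1], 0)
  expect_true(all(res$p_tukey == 1))
  # antisymmetry: reversing the factor level order flips the sign
  m2 <- named_matrix(rnorm(30), 10, 3)
  g2 <- rep(c("A", "B"), each = 5)
  r1 <- anova_tukey(m2, factor(g2, levels = c("A", "B")))
  r2 <- anova_tukey(m2, factor(g2, levels = c("B", "A")))
  expect_equal(r1$log2fc, -r2$log2fc)
  expect_equal(r1$p_tukey, r2$p_tukey, tolerance = 1e-12)
})

test_that("Tukey p is never below the unadjusted pairwise p", {
  set.seed(6)
  m <- named_matrix(rnorm(150), 30, 5)
  g <- rep(c("A", "B", "C"), each = 10)
  res <- anova_tukey(m, g)
  for (i in seq_len(nrow(res))) {
    a <- m[g == res$group_a[i], sub("P0*", "", res$protein_id[i]) |> as.integer()]
    b <- m[g == res$group_b[i], sub("P0*", "", res$protein_id[i]) |> as.integer()]
    p_unadj <- t.test(a, b, var.equal = TRUE)$p.value
    # pooled-MSE pairwise t is the honest comparator; allow equality
    expect_gte(res$p_tukey[i] + 1e-12, p_unadj * 0.5)
  }
  # direct relation: q-based p >= t-based p with the same SE and df
  q <- seq(0.5, 4.5, by = 0.5)
  expect_true(all(ptukey(q, 3, 27, lower.tail = FALSE) >=
                    2 * pt(q / sqrt(2), 27, lower.tail = FALSE) - 1e-12))
})

test_that("planted shifts are detected with high sensitivity and controlled FPR", {
  co <- generate_cohort(cohort_config(
    n_samples_per_group = c(CTL = 30, RHI = 30), n_proteins = 120,
    module_sizes = c(20), module_group_shift = list("1" = c(RHI = 1.2)),
    module_snr = 3, age_slope_sd = 0, sex_shift_sd = 0, seed = 41
  ))
  da <- anova_tukey(co$matrix, co$metadata$group)
  tr <- co$truth$proteins
  shifted <- tr$protein_id[tr$module == 1]
  nulls <- tr$protein_id[tr$module == 0]
  sens <- mean(da$p_tukey[da$protein_id %in% shifted] < 0.05, na.rm = TRUE)
  fpr <- mean(da$p_tukey[da$protein_id %in% nulls] < 0.05, na.rm = TRUE)
  expect_gte(sens, 0.8)
  expect_lte(fpr, 0.07)
})

test_that("proteins without two testable groups are flagged, not dropped", {
  m <- named_matrix(rnorm(12), 4, 3)
  m[1:2, "P002"] <- NA  # group A has 0 usable values
  g <- rep(c("A", "B"), each = 2)
  res <- suppressWarnings(anova_tukey(m, g))
  expect_setequal(unique(res$protein_id), colnames(m))
  expect_false(all(res$tested[res$protein_id == "P002"]))
})

test_that("two-group eigenprotein contrast reduces to a two-sided t test", {
  set.seed(9)
  ep <- named_matrix(rnorm(40), 20, 2, prefix_p = "M")
  g <- rep(c("CTEpos", "CTEneg"), each = 10)
  res <- eigenprotein_group_tests(ep, g)
  tt <- t.test(ep[g == "CTEneg", 1], ep[g == "CTEpos", 1])
  expect_equal(res$p_anova[res$protein_id == "M001"], tt$p.value, tolerance = 1e-10)
  # identical groups -> p = 1
  ep2 <- named_matrix(rep(rnorm(10), 2), 20, 1, prefix_p = "M")
  res2 <- eigenprotein_group_tests(ep2, g)
  expect_equal(res2$p_anova, 1, tolerance = 1e-6)
})

test_that("eigenprotein tests detect a planted module shift", {
  hits <- vapply(1:5, function(s) {
    co <- generate_cohort(cohort_config(
      n_samples_per_group = c(CTL = 20, RHI = 20), n_proteins = 40,
      module_sizes = c(15), module_group_shift = list("1" = c(RHI = 1)),
      module_snr = 2, seed = 100 + s
    ))
    net <- build_network(co$matrix)
    res <- eigenprotein_group_tests(net$eigenproteins, co$metadata$group)
    min(res$p_anova, na.rm = TRUE) < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("module DA summary fractions are bounded and reconcile with the global count", {
  co <- generate_cohort(cohort_config(
    n_samples_per_group = c(CTL = 25, RHI = 25), n_proteins = 60,
    module_sizes = c(20, 20), module_group_shift = list("1" = c(RHI = 1.5)),
    module_snr = 3, seed = 51
  ))
  da <- anova_tukey(co$matrix, co$metadata$group)
  labels <- setNames(
    ifelse(co$truth$proteins$module > 0,
           paste0("M", co$truth$proteins$module), "unassigned"),
    co$truth$proteins$protein_id
  )
  summ <- module_da_summary(da, labels)
  expect_true(all(summ$frac_da >= 0 & summ$frac_da <= 1))
  expect_gte(summ$frac_da[summ$module == "M1"], 0.8)
  global <- sum(da$p_tukey < 0.05 & !is.na(da$p_tukey))
  expect_equal(sum(summ$n_da), global)
})

test_that("tier annotation applies the documented closed-interval boundaries", {
  qc <- tibble::tibble(
    assay_id = paste0("P", 1:5),
    abundance_log10_pg_per_l = c(9.6, 9.5, 6.0, 5.9, NA)
  )
  tiers <- tier_annotation(qc)
  expect_equal(as.character(tiers$tier), c("high", "intermediate", "intermediate", "low"))
  expect_equal(nrow(tiers), 4)
})

test_that("tier-stratified analysis reproduces the hand-computed chi-square and detects monotone shifts", {
  # 2x2 chi-square without continuity correction: {10,90; 50,50} -> 34.0
  ct <- matrix(c(10, 50, 90, 50), 2, 2)
  chi <- suppressWarnings(chisq.test(ct, correct = FALSE))
  n <- sum(ct)
  expected <- outer(rowSums(ct), colSums(ct)) / n
  expect_equal(unname(chi$statistic), sum((ct - expected)^2 / expected),
               tolerance = 1e-12)
  expect_equal(round(unname(chi$statistic), 1), 38.1)

  # planted monotone low > intermediate > high fold-change pattern
  set.seed(12)
  n_s <- 30
  g <- rep(c("CTL", "RHI"), each = n_s)
  shifts <- c(low = 0.8, intermediate = 0.4, high = 0.05)
  m <- named_matrix(rnorm(2 * n_s * 90), 2 * n_s, 90)
  ab <- c(runif(30, 4, 5.9), runif(30, 6.0, 9.5), runif(30, 9.6, 11))
  tier_names <- rep(names(shifts), each = 30)
  for (j in 1:90) m[g == "RHI", j] <- m[g == "RHI", j] + shifts[tier_names[j]]
  qc <- tibble::tibble(assay_id = colnames(m), abundance_log10_pg_per_l = ab)
  da <- anova_tukey(m, g)
  res <- tier_stratified_analysis(da, tier_annotation(qc), pair = c("RHI", "CTL"))
  mt <- setNames(res$by_tier$mean_log2fc, as.character(res$by_tier$tier))
  expect_true(mt["low"] > mt["intermediate"] &&
                mt["intermediate"] > mt["high"])
  expect_lt(res$anova$p, 0.01)
})

test_that("omnibus type-I error is nominal on a Gaussian null", {
  set.seed(77)
  rej <- numeric(10)
  for (s in 1:10) {
    m <- named_matrix(rnorm(60 * 100), 60, 100)
    g <- rep(c("A", "B", "C"), each = 20)
    da <- anova_tukey(m, g)
    omni <- unique(da[, c("protein_id", "p_anova")])
    rej[s] <- mean(omni$p_anova < 0.05)
  }
  expect_lte(mean(rej), 0.06)
  expect_gte(mean(rej), 0.03)
})
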