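make_qc <- function(ids, med, sd_ = 0.5, uniprot = NULL, warn = FALSE) {
  tibble::tibble(
    assay_id = ids, uniprot_id = uniprot %||% paste0("U", ids),
    buffer_median = med, buffer_sd = sd_, qc_warning = warn,
    abundance_log10_pg_per_l = NA_real_
  )
}

test_that("LOD masking censors strictly below median + 3 SD", {
  m <- named_matrix(c(6.4, 6.6, 6.5, 7.0), 2, 2)
  qc <- make_qc(colnames(m), med = 5, sd_ = 0.5)  # LOD = 6.5
  out <- apply_lod_mask(m, qc)
  expect_true(is.na(out["S001", "P001"]))   # 6.4 < 6.5
  expect_equal(out["S002", "P001"], 6.6)
  expect_equal(out["S001", "P002"], 6.5)    # equality kept
  # zero SD: LOD = median, equality retained
  qc0 <- make_qc(colnames(m), med = 6.5, sd_ = 0)
  out0 <- apply_lod_mask(m, qc0)
  expect_equal(out0["S001", "P002"], 6.5)
  expect_true(is.na(out0["S001", "P001"]))
  qc_missing <- qc[1, ]
  expect_error(apply_lod_mask(m, qc_missing), "P002")
})

test_that("protein filtering drops warnings, duplicates and high missingness with the documented tie-break", {
  set.seed(1)
  m <- named_matrix(rnorm(40), 10, 4)
  m[1:6, "P002"] <- NA            # 60% missing -> dropped
  m[1:5, "P003"] <- NA            # exactly 50% -> retained
  qc <- make_qc(colnames(m), med = -10)
  qc$uniprot_id[4] <- qc$uniprot_id[1]   # P004 duplicates P001
  m[1:2, "P001"] <- NA                   # P001 has higher missingness than P004
  res <- filter_proteins(m, qc)
  expect_setequal(colnames(res$matrix), c("P003", "P004"))
  expect_true("P001" %in% res$report$removed$duplicate_uniprot)
  expect_true("P002" %in% res$report$removed$high_missingness)
  # accounting reconciles
  expect_equal(ncol(m), ncol(res$matrix) +
                 length(res$report$removed$qc_warning) +
                 length(res$report$removed$duplicate_uniprot) +
                 length(res$report$removed$high_missingness))
  # flip the missingness: the other duplicate goes
  m2 <- named_matrix(rnorm(40), 10, 4)
  m2[1:6, "P002"] <- NA; m2[1:5, "P003"] <- NA
  m2[1:2, "P004"] <- NA
  res2 <- filter_proteins(m2, qc)
  expect_true("P004" %in% res2$report$removed$duplicate_uniprot)
  expect_true("P001" %in% colnames(res2$matrix))
})

test_that("sample connectivity is standardized and flags the decorrelated sample", {
  set.seed(5)
  base <- rnorm(20)
  m <- named_matrix(NA_real_, 5, 20)
  for (i in 1:4) m[i, ] <- base + rnorm(20, sd = 0.3)
  m[5, ] <- rnorm(20)             # pure noise sample
  z <- sample_connectivity(m)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(names(which.min(z)), "S005")
  # brute-force oracle for k
  cors <- sapply(1:5, function(i) sapply(1:5, function(j) {
    if (i == j) 0 else bicor(m[i, ], m[j, ])
  }))
  k <- colSums(cors)
  expect_equal(unname(z), unname((k - mean(k)) / sd(k)), tolerance = 1e-10)
})

test_that("identical samples give zero Z with a warning", {
  m <- named_matrix(rep(rnorm(10), each = 3), 3, 10)
  expect_warning(z <- sample_connectivity(m), "equal")
  expect_equal(unname(z), rep(0, 3))
})

test_that("outlier removal is one-sided, single-pass, and guarded", {
  set.seed(8)
  co <- generate_cohort(cohort_config(
    n_samples_per_group = c(CTL = 44, RHI = 22, AD = 39),
    n_proteins = 200, module_sizes = rep(30, 4),
    n_outlier_samples = 3, outlier_groups = c("CTL", "CTL", "RHI"),
    outlier_noise_multiplier = 5, seed = 17
  ))
  res <- remove_outlier_samples(co$matrix)
  planted <- co$truth$samples$sample_id[co$truth$samples$outlier]
  expect_setequal(res$report$removed$outlier_samples, planted)
  expect_equal(nrow(res$matrix), 105)
  # no outliers -> unchanged
  clean <- co$matrix[setdiff(rownames(co$matrix), planted), ]
  res2 <- remove_outlier_samples(clean)
  expect_identical(res2$matrix, clean)
  expect_error(remove_outlier_samples(clean, z_cutoff = 0), "positive")
})

test_that("bootstrap adjustment with one unresampled replicate equals closed-form OLS", {
  co <- quick_cohort(seed = 3, age_slope_sd = 0.05, sex_shift_sd = 0.3)
  adj <- adjust_covariates(co$matrix, co$metadata, n_boot = 1, seed = 1,
                           resample = FALSE)
  grp <- factor(co$metadata$group)
  for (j in c(1, 10, 40)) {
    fit <- lm(co$matrix[, j] ~ co$metadata$age + co$metadata$sex + grp)
    expect_equal(adj$coefficients$beta_age[j], unname(coef(fit)[2]), tolerance = 1e-10)
    expect_equal(adj$coefficients$beta_sex[j], unname(coef(fit)[3]), tolerance = 1e-10)
  }
})

test_that("adjustment is deterministic, preserves missingness, and nulls covariate signal", {
  co <- generate_cohort(cohort_config(
    n_samples_per_group = c(CTL = 50, RHI = 50), n_proteins = 40,
    module_sizes = c(10), age_slope_sd = 0.1, sex_shift_sd = 0,
    n_low_abundance_proteins = 5, lod_quantile = 0.2,
    orthogonalize_factors = TRUE, seed = 23
  ))
  a1 <- adjust_covariates(co$matrix, co$metadata, n_boot = 50, seed = 7)
  a2 <- adjust_covariates(co$matrix, co$metadata, n_boot = 50, seed = 7)
  expect_identical(a1$matrix, a2$matrix)
  expect_identical(is.na(a1$matrix), is.na(co$matrix))
  # residual age correlation among proteins with big planted slopes
  big <- which(abs(co$truth$proteins$beta_age) > 0.05)
  for (j in head(big, 5)) {
    expect_lt(abs(cor(a1$matrix[, j], co$metadata$age, use = "complete.obs")), 0.15)
  }
})

test_that("zero planted covariate effects leave the matrix nearly unchanged", {
  co <- generate_cohort(cohort_config(
    n_samples_per_group = c(CTL = 40, RHI = 40), n_proteins = 30,
    module_sizes = c(10), age_slope_sd = 0, sex_shift_sd = 0,
    orthogonalize_factors = TRUE, seed = 29
  ))
  adj <- adjust_covariates(co$matrix, co$metadata, n_boot = 100, seed = 2)
  # subtracting beta-hat * age moves levels by a near-constant amount, so
  # compare column-centered values; the residual perturbation is the
  # coefficient sampling noise times the covariate spread
  cen <- function(m) sweep(m, 2, colMeans(m))
  delta <- abs(cen(adj$matrix) - cen(co$matrix))
  # scale of the perturbation: coefficient sampling noise (se ~ 0.015 for
  # age, ~0.22 for binary sex at n = 80) times mean covariate deviations
  expect_lt(mean(delta), 0.25)
  for (j in c(1, 15, 30)) {
    expect_gt(cor(adj$matrix[, j], co$matrix[, j]), 0.97)
  }
})

test_that("full qc pipeline reconciles dimensions in fixed order", {
  co <- generate_cohort(cohort_config(
    n_samples_per_group = c(CTL = 25, RHI = 25), n_proteins = 80,
    module_sizes = c(15), n_duplicate_assays = 3, n_high_missing_proteins = 4,
    n_low_abundance_proteins = 5, n_outlier_samples = 2,
    outlier_noise_multiplier = 5, seed = 19
  ))
  res <- qc_pipeline(co$matrix, co$qc, co$metadata, n_boot = 25, seed = 1)
  expect_equal(ncol(res$matrix), 80 - 3 - 4)
  expect_equal(nrow(res$matrix), 50)
  rep_p <- res$reports$proteins
  expect_equal(rep_p$input_dims[2],
               rep_p$retained_dims[2] + length(rep_p$removed$qc_warning) +
                 length(rep_p$removed$duplicate_uniprot) +
                 length(rep_p$removed$high_missingness))
})
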