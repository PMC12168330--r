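#' Configuration for a synthetic plasma-proteomic cohort
#'
#' Builds and validates the parameter set for [generate_cohort()]. The
#' defaults mirror the structure of a three-group clinical cohort profiled
#' on a multiplex proximity-extension assay: 44 controls (CTL), 22
#' repetitive-head-impact (RHI) cases and 39 Alzheimer's disease (AD)
#' cases, with group-specific age and sex distributions, planted
#' co-expression modules driven by single latent factors, per-protein age
#' and sex effects, limit-of-detection censoring in low-abundance assays,
#' duplicate assays sharing a UniProt accession, and aberrant samples
#' whose residual noise is inflated so that they decorrelate from the
#' rest of the cohort.
#'
#' @param n_samples_per_group Named integer vector, samples per group.
#' @param n_proteins Total assay count (duplicate assays included).
#' @param module_sizes Integer vector of planted module sizes (each at
#'   least 10, the default minimum module size downstream); proteins not
#'   in any module are uncorrelated background.
#' @param module_group_shift List indexed by module giving a named vector
#'   of per-group mean shifts of the module factor (log2 units); protein
#'   level shifts are the factor shift scaled by that protein's loading.
#' @param module_snr Ratio of module-factor SD (1) to residual SD; 0
#'   disables module structure entirely.
#' @param age_slope_sd,sex_shift_sd SDs of per-protein age (log2/year)
#'   and sex coefficients.
#' @param n_duplicate_assays Assays that are re-noised copies of another
#'   assay and share its UniProt ID.
#' @param n_high_missing_proteins Proteins censored below their 60%
#'   quantile, i.e. guaranteed more than 50% missingness after masking.
#' @param n_low_abundance_proteins Proteins annotated as low-abundance and
#'   censored at `lod_quantile`.
#' @param lod_quantile Fraction of values censored in low-abundance
#'   proteins (deterministic empirical-quantile threshold).
#' @param n_outlier_samples Aberrant-connectivity samples appended to the
#'   cohort.
#' @param outlier_noise_multiplier Residual-SD inflation factor for
#'   outlier samples (at least 3).
#' @param outlier_groups Group labels for the outlier samples (recycled
#'   over group names when `NULL`).
#' @param trait_loadings Named list: trait -> named vector of target
#'   correlations with module factors (names are module indices).
#' @param age_mean,age_sd,sex_prop_male Named vectors per group; groups
#'   absent from the names fall back to 65/10/0.5.
#' @param orthogonalize_factors When `TRUE`, module factors are
#'   residualized on age and sex within each group (and re-scaled)
#'   before group shifts are applied, so planted covariate effects are
#'   identifiable without leakage from latent-factor/covariate sampling
#'   correlation, and the realized group shift equals the nominal one.
#'   Default `FALSE` (factors drawn independently of the demographics,
#'   sampling correlation and all).
#' @param n_qc_warning_assays Assays flagged with a QC warning.
#' @param seed Integer seed; the same config is byte-reproducible.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_samples_per_group = c(CTL = 44, RHI = 22, AD = 39),
                          n_proteins = 300,
                          module_sizes = rep(30L, 5),
                          module_group_shift = list(),
                          module_snr = 2,
                          age_slope_sd = 0.01,
                          sex_shift_sd = 0.1,
                          n_duplicate_assays = 0,
                          n_high_missing_proteins = 0,
                          n_low_abundance_proteins = 0,
                          lod_quantile = 0.2,
                          n_outlier_samples = 0,
                          outlier_noise_multiplier = 5,
                          outlier_groups = NULL,
                          trait_loadings = NULL,
                          age_mean = c(CTL = 70.6, RHI = 57.8, AD = 67.6),
                          age_sd = c(CTL = 7.2, RHI = 12.1, AD = 9.8),
                          sex_prop_male = c(CTL = 0.64, RHI = 1.0, AD = 0.44),
                          n_qc_warning_assays = 0,
                          orthogonalize_factors = FALSE,
                          seed = 1L) {
  cfg <- list(
    n_samples_per_group = n_samples_per_group, n_proteins = as.integer(n_proteins),
    module_sizes = as.integer(module_sizes), module_group_shift = module_group_shift,
    module_snr = module_snr, age_slope_sd = age_slope_sd, sex_shift_sd = sex_shift_sd,
    n_duplicate_assays = as.integer(n_duplicate_assays),
    n_high_missing_proteins = as.integer(n_high_missing_proteins),
    n_low_abundance_proteins = as.integer(n_low_abundance_proteins),
    lod_quantile = lod_quantile,
    n_outlier_samples = as.integer(n_outlier_samples),
    outlier_noise_multiplier = outlier_noise_multiplier,
    outlier_groups = outlier_groups, trait_loadings = trait_loadings,
    age_mean = age_mean, age_sd = age_sd, sex_prop_male = sex_prop_male,
    n_qc_warning_assays = as.integer(n_qc_warning_assays),
    orthogonalize_factors = isTRUE(orthogonalize_factors),
    seed = as.integer(seed)
  )
  # default: global cognition loads negatively on the second-largest
  # planted module (mirroring an immunovascular module tracking
  # cognition), when one exists
  if (is.null(trait_loadings)) {
    cfg$trait_loadings <- if (length(cfg$module_sizes) >= 2) {
      list(global_cognition_z = c("2" = -0.6))
    } else if (length(cfg$module_sizes) == 1) {
      list(global_cognition_z = c("1" = -0.6))
    } else list()
  }
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  if (is.null(names(cfg$n_samples_per_group)) ||
      any(cfg$n_samples_per_group < 1)) {
    config_error("n_samples_per_group must be a named vector of positive counts")
  }
  if (length(cfg$module_sizes) > 0 && any(cfg$module_sizes < 10)) {
    config_error("module_sizes must each be >= 10 (the downstream minimum module size)")
  }
  n_special <- sum(cfg$module_sizes) + cfg$n_duplicate_assays +
    cfg$n_high_missing_proteins + cfg$n_low_abundance_proteins +
    cfg$n_qc_warning_assays
  if (n_special > cfg$n_proteins) {
    config_error("module, duplicate, low-abundance and QC-warning protein counts exceed n_proteins")
  }
  if (cfg$n_duplicate_assays + cfg$n_high_missing_proteins >= cfg$n_proteins) {
    config_error("n_duplicate_assays + n_high_missing_proteins must be < n_proteins")
  }
  if (cfg$lod_quantile < 0 || cfg$lod_quantile >= 1) {
    config_error("lod_quantile must be in [0, 1)")
  }
  if (cfg$n_outlier_samples > 0 && cfg$outlier_noise_multiplier < 3) {
    config_error("outlier_noise_multiplier must be >= 3")
  }
  if (cfg$module_snr < 0) config_error("module_snr must be >= 0")
  invisible(cfg)
}

lookup_or <- function(v, key, default) {
  if (!is.null(names(v)) && key %in% names(v)) unname(v[[key]]) else default
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Draws a full synthetic data set under `config`: a samples x proteins
#' log2 abundance matrix with LOD-censored cells coded `NA`, per-sample
#' metadata, a per-assay QC table whose buffer statistics reproduce the
#' planted LOD thresholds exactly, a trait table generated from the
#' planted module factors, and a ground-truth record of every planted
#' effect for downstream validation.
#'
#' Module member proteins are `loading x factor + noise` with loadings
#' uniform on \[0.5, 1\] and standard-normal per-sample factors; group
#' shifts are applied to the factors, so the planted protein-level shift
#' between two groups is `loading * (shift_a - shift_b)`. Outlier samples
#' carry no factor structure: independent noise inflated by
#' `outlier_noise_multiplier` times each protein's marginal SD.
#'
#' @param config A [cohort_config()].
#' @return A list of class `plasma_cohort` with elements `matrix`
#'   (numeric samples x proteins), `metadata`, `qc`, `traits` (tibbles)
#'   and `truth` (list of tibbles: `proteins`, `shifts`, `samples`,
#'   `trait_loadings`, plus the realized `factors` matrix).
#' @examples
#' cohort <- generate_cohort(cohort_config(
#'   n_samples_per_group = c(CTL = 15, RHI = 15),
#'   n_proteins = 80, module_sizes = c(20, 20), seed = 7
#' ))
#' dim(cohort$matrix)
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  set.seed(config$seed)

  groups <- rep(names(config$n_samples_per_group), config$n_samples_per_group)
  n_clean <- length(groups)
  n_out <- config$n_outlier_samples
  out_groups <- config$outlier_groups %||%
    rep(names(config$n_samples_per_group), length.out = max(n_out, 1))[seq_len(n_out)]
  all_groups <- c(groups, out_groups)
  n <- n_clean + n_out
  sample_ids <- sprintf("S%03d", seq_len(n))
  outlier <- c(rep(FALSE, n_clean), rep(TRUE, n_out))

  age <- vapply(seq_len(n), function(i) {
    g <- all_groups[i]
    rnorm(1, lookup_or(config$age_mean, g, 65), lookup_or(config$age_sd, g, 10))
  }, numeric(1))
  sex <- vapply(seq_len(n), function(i) {
    rbinom(1, 1, lookup_or(config$sex_prop_male, all_groups[i], 0.5))
  }, numeric(1))

  p <- config$n_proteins
  n_mod <- length(config$module_sizes)
  protein_ids <- sprintf("P%04d", seq_len(p))
  uniprot <- sprintf("U%05d", seq_len(p))

  module_of <- rep(0L, p)
  idx <- 1L
  for (m in seq_len(n_mod)) {
    module_of[idx:(idx + config$module_sizes[m] - 1L)] <- m
    idx <- idx + config$module_sizes[m]
  }
  background <- which(module_of == 0L)

  # special background proteins: duplicates (filled later), high-missing, low-abundance, qc-warning
  take <- function(pool, k) if (k > 0) pool[seq_len(k)] else integer(0)
  dup_idx <- take(background, config$n_duplicate_assays)
  background <- setdiff(background, dup_idx)
  hm_idx <- take(background, config$n_high_missing_proteins)
  background <- setdiff(background, hm_idx)
  low_idx <- take(background, config$n_low_abundance_proteins)
  background <- setdiff(background, low_idx)
  qcw_idx <- take(background, config$n_qc_warning_assays)

  mu <- rnorm(p, mean = 3, sd = 1)
  loading <- runif(p, 0.5, 1)
  beta_age <- rnorm(p, 0, config$age_slope_sd)
  beta_sex <- rnorm(p, 0, config$sex_shift_sd)
  sigma <- if (config$module_snr > 0) 1 / config$module_snr else 1

  # latent factors for clean samples, with per-group mean shifts
  factors <- matrix(rnorm(n_clean * max(n_mod, 1)), n_clean, max(n_mod, 1))
  if (config$orthogonalize_factors && n_mod > 0) {
    clean_grp <- all_groups[seq_len(n_clean)]
    for (g in unique(clean_grp)) {
      ix <- which(clean_grp == g)
      Xg <- cbind(1, age[ix], sex[ix])
      for (m in seq_len(n_mod)) {
        fit <- stats::lm.fit(Xg, factors[ix, m])
        factors[ix, m] <- fit$residuals
      }
    }
    factors <- apply(factors, 2, function(f) f / max(sd(f), 1e-12))
    if (!is.matrix(factors)) factors <- matrix(factors, n_clean)
  }
  shift_of <- matrix(0, n_mod, n)  # factor-level shift applied per sample
  for (m in seq_len(n_mod)) {
    sh <- if (as.character(m) %in% names(config$module_group_shift)) {
      config$module_group_shift[[as.character(m)]]
    } else if (is.null(names(config$module_group_shift)) &&
               m <= length(config$module_group_shift)) {
      config$module_group_shift[[m]]
    } else numeric(0)
    for (g in names(sh)) shift_of[m, all_groups == g] <- sh[[g]]
  }
  if (n_mod > 0) {
    factors <- factors + t(shift_of[, seq_len(n_clean), drop = FALSE])
  }

  x <- matrix(NA_real_, n, p, dimnames = list(sample_ids, protein_ids))
  for (j in seq_len(p)) {
    m <- module_of[j]
    if (m > 0L && config$module_snr > 0) {
      signal <- loading[j] * factors[, m]
      x[seq_len(n_clean), j] <- mu[j] + signal +
        beta_age[j] * age[seq_len(n_clean)] + beta_sex[j] * sex[seq_len(n_clean)] +
        rnorm(n_clean, 0, sigma)
    } else {
      x[seq_len(n_clean), j] <- mu[j] +
        beta_age[j] * age[seq_len(n_clean)] + beta_sex[j] * sex[seq_len(n_clean)] +
        rnorm(n_clean, 0, 1)
    }
  }
  # outliers: independent noise at multiplier x the protein's marginal SD
  if (n_out > 0) {
    marg_sd <- vapply(seq_len(p), function(j) {
      if (module_of[j] > 0L && config$module_snr > 0)
        sqrt(loading[j]^2 + sigma^2) else 1
    }, numeric(1))
    for (j in seq_len(p)) {
      x[n_clean + seq_len(n_out), j] <-
        mu[j] + rnorm(n_out, 0, config$outlier_noise_multiplier * marg_sd[j])
    }
  }

  # duplicate assays: re-noised copies sharing the source UniProt ID
  dup_of <- rep(NA_character_, p)
  if (length(dup_idx) > 0) {
    src_pool <- setdiff(which(module_of == 0L), c(dup_idx, hm_idx, low_idx, qcw_idx))
    if (length(src_pool) < length(dup_idx)) src_pool <- setdiff(seq_len(p), dup_idx)
    src <- src_pool[seq_along(dup_idx)]
    for (k in seq_along(dup_idx)) {
      j <- dup_idx[k]
      x[, j] <- x[, src[k]] + rnorm(n, 0, 0.1)
      uniprot[j] <- uniprot[src[k]]
      dup_of[j] <- protein_ids[src[k]]
    }
  }

  # LOD censoring: deterministic empirical-quantile threshold per protein
  lod <- rep(-Inf, p)
  cens_frac <- rep(0, p)
  cens_frac[low_idx] <- config$lod_quantile
  cens_frac[hm_idx] <- max(0.6, config$lod_quantile)
  n_censored <- integer(p)
  for (j in which(cens_frac > 0)) {
    thr <- quantile(x[, j], cens_frac[j], names = FALSE, type = 1)
    below <- x[, j] < thr
    n_censored[j] <- sum(below)
    x[below, j] <- NA_real_
    lod[j] <- thr
  }

  buffer_sd <- rep(0.2, p)
  buffer_median <- ifelse(is.finite(lod), lod - 3 * buffer_sd,
                          apply(x, 2, min, na.rm = TRUE) - 3 - 3 * buffer_sd)
  abundance <- runif(p, 6.05, 10.5)
  abundance[c(low_idx, hm_idx)] <- runif(length(low_idx) + length(hm_idx), 4, 5.9)

  qc <- tibble(
    assay_id = protein_ids, uniprot_id = uniprot,
    buffer_median = buffer_median, buffer_sd = buffer_sd,
    qc_warning = seq_len(p) %in% qcw_idx,
    abundance_log10_pg_per_l = abundance
  )

  metadata <- tibble(
    sample_id = sample_ids, group = all_groups, age = age, sex = sex
  )

  # traits from standardized realized factors, calibrated by analytic scaling
  traits <- tibble(sample_id = sample_ids)
  trait_truth <- list()
  for (tr in names(config$trait_loadings)) {
    lo <- config$trait_loadings[[tr]]
    mods <- as.integer(names(lo))
    if (any(mods < 1 | mods > n_mod)) config_error("trait loading names a missing module")
    tot <- sum(lo^2)
    if (tot > 1) config_error("sum of squared trait loadings exceeds 1")
    val <- rnorm(n, 0, sqrt(1 - tot))
    for (k in seq_along(mods)) {
      f_std <- as.numeric(scale(factors[, mods[k]]))
      val[seq_len(n_clean)] <- val[seq_len(n_clean)] + lo[k] * f_std
    }
    traits[[tr]] <- val
    trait_truth[[tr]] <- tibble(trait = tr, module = mods, loading = unname(lo))
  }
  traits$sample_to_death_years <- runif(n, 1, 10)

  group_names <- names(config$n_samples_per_group)
  shifts <- list()
  if (n_mod > 0 && length(group_names) >= 2) {
    pairs <- utils::combn(group_names, 2)
    clean_groups <- all_groups[seq_len(n_clean)]
    for (cidx in seq_len(ncol(pairs))) {
      ga <- pairs[1, cidx]; gb <- pairs[2, cidx]
      fs <- vapply(seq_len(n_mod), function(m) {
        sa <- shift_of[m, match(ga, all_groups)]
        sb <- shift_of[m, match(gb, all_groups)]
        sa - sb
      }, numeric(1))
      # realized shift: the factor group-mean difference actually drawn,
      # so recovery checks are not blurred by shared factor sampling noise
      fr <- vapply(seq_len(n_mod), function(m) {
        mean(factors[clean_groups == ga, m]) - mean(factors[clean_groups == gb, m])
      }, numeric(1))
      planted <- module_of > 0L & config$module_snr > 0
      shifts[[cidx]] <- tibble(
        protein_id = protein_ids,
        group_a = ga, group_b = gb,
        log2_shift = ifelse(planted, loading * fs[pmax(module_of, 1L)], 0),
        log2_shift_realized = ifelse(planted, loading * fr[pmax(module_of, 1L)], 0)
      )
    }
  }

  truth <- list(
    proteins = tibble(
      protein_id = protein_ids, uniprot_id = uniprot, module = module_of,
      loading = ifelse(module_of > 0L, loading, NA_real_),
      beta_age = beta_age, beta_sex = beta_sex,
      is_duplicate = !is.na(dup_of), dup_of = dup_of,
      low_abundance = seq_len(p) %in% c(low_idx, hm_idx),
      high_missing = seq_len(p) %in% hm_idx,
      censored_fraction = n_censored / n
    ),
    shifts = if (length(shifts)) bind_rows(shifts) else
      tibble(protein_id = character(), group_a = character(),
             group_b = character(), log2_shift = numeric(),
             log2_shift_realized = numeric()),
    samples = tibble(sample_id = sample_ids, group = all_groups, outlier = outlier),
    trait_loadings = if (length(trait_truth)) bind_rows(trait_truth) else
      tibble(trait = character(), module = integer(), loading = numeric()),
    factors = factors
  )

  structure(
    list(matrix = x, metadata = metadata, qc = qc, traits = traits,
         truth = truth, config = config),
    class = "plasma_cohort"
  )
}

#' @export
print.plasma_cohort <- function(x, ...) {
  cat(sprintf(
    "<plasma_cohort> %d samples x %d assays (%d planted modules, %d outlier samples)\n",
    nrow(x$matrix), ncol(x$matrix), length(x$config$module_sizes),
    x$config$n_outlier_samples
  ))
  invisible(x)
}

#' Simulate an assay panel with planted QC removals
#'
#' Fixture generator for exercising the protein-level QC chain at a known
#' answer: exactly `n_duplicates` assays repeat an existing UniProt ID and
#' exactly `n_high_missing` assays exceed 50% missingness once the LOD
#' mask is applied, so the full chain retains
#' `n_assays - n_duplicates - n_high_missing` proteins.
#'
#' @param n_assays Total assay count.
#' @param n_duplicates Duplicate-UniProt assays.
#' @param n_high_missing Assays censored past 50% missingness.
#' @param n_samples Samples to draw (default 105).
#' @param seed Integer seed.
#' @return List with `matrix` (unmasked) and `qc` (tibble).
#' @examples
#' panel <- simulate_assay_panel(100, 5, 10, seed = 1)
#' @export
simulate_assay_panel <- function(n_assays, n_duplicates, n_high_missing,
                                 n_samples = 105, seed = 1L) {
  if (n_duplicates + n_high_missing >= n_assays) {
    config_error("n_duplicates + n_high_missing must be < n_assays")
  }
  set.seed(as.integer(seed))
  n <- n_samples; p <- n_assays
  sample_ids <- sprintf("S%03d", seq_len(n))
  protein_ids <- sprintf("P%04d", seq_len(p))
  uniprot <- sprintf("U%05d", seq_len(p))
  mu <- rnorm(p, 3, 1)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(sample_ids, protein_ids))
  x <- sweep(x, 2, mu, "+")

  hm_idx <- if (n_high_missing > 0) seq_len(n_high_missing) else integer(0)
  dup_idx <- if (n_duplicates > 0) n_high_missing + seq_len(n_duplicates) else integer(0)
  src_pool <- setdiff(seq_len(p), c(hm_idx, dup_idx))
  src <- src_pool[seq_along(dup_idx)]
  for (k in seq_along(dup_idx)) {
    x[, dup_idx[k]] <- x[, src[k]] + rnorm(n, 0, 0.1)
    uniprot[dup_idx[k]] <- uniprot[src[k]]
  }

  # LOD at the 60% empirical quantile for high-missing assays (> 50% after
  # strict-less masking), far below the data for everything else
  buffer_sd <- rep(0.2, p)
  lod <- apply(x, 2, min) - 3
  if (length(hm_idx)) {
    lod[hm_idx] <- apply(x[, hm_idx, drop = FALSE], 2, quantile, probs = 0.6,
                         names = FALSE, type = 1)
  }
  qc <- tibble(
    assay_id = protein_ids, uniprot_id = uniprot,
    buffer_median = lod - 3 * buffer_sd, buffer_sd = buffer_sd,
    qc_warning = FALSE,
    abundance_log10_pg_per_l = runif(p, 4, 10.5)
  )
  list(matrix = x, qc = qc)
}

#' Correlated companion measurement for a protein vector
#'
#' Emits `affine(x) + noise` calibrated so that the population Pearson
#' correlation with `x` equals `target_r`; used to emulate an orthogonal
#' immunoassay of an analyte also captured on the multiplex panel.
#'
#' @param x Numeric vector (missing allowed; propagated).
#' @param target_r Target correlation in (0, 1\].
#' @param seed Integer seed.
#' @return Numeric vector of the same length.
#' @export
simulate_immunoassay <- function(x, target_r, seed = 1L) {
  stopifnot(target_r > 0, target_r <= 1)
  set.seed(as.integer(seed))
  z <- as.numeric(scale(x))
  noise_sd <- sqrt(1 / target_r^2 - 1)
  z + rnorm(length(x), 0, noise_sd)
}

#' Semi-quantitative neuropathology ratings coupled to a latent severity
#'
#' Generates ordinal 0-3 regional proteinopathy ratings from a latent
#' Gaussian severity per (sample, proteinopathy): the latent score is
#' `loading x driver + noise` and is cut at fixed quantile thresholds, so
#' planted correlations between burden sums and the driver are
#' well-defined targets.
#'
#' @param driver Numeric latent severity per sample (e.g. a planted module
#'   factor); names taken as sample ids if present.
#' @param loadings Named numeric vector: proteinopathy -> correlation of
#'   its latent severity with `driver`.
#' @param regions Character vector of region names (defaults to the six
#'   medial-temporal-lobe regions of interest).
#' @param seed Integer seed.
#' @return Long tibble (sample_id, region, proteinopathy, rating).
#' @export
simulate_neuropath_ratings <- function(driver,
                                       loadings = c(tau = 0.6, `TDP-43` = 0.6,
                                                    `beta-amyloid` = 0,
                                                    `alpha-synuclein` = 0,
                                                    neurodegeneration = 0.6),
                                       regions = mtl_regions(),
                                       seed = 1L) {
  set.seed(as.integer(seed))
  n <- length(driver)
  ids <- names(driver) %||% sprintf("S%03d", seq_len(n))
  d <- as.numeric(scale(driver))
  cuts <- qnorm(c(0.4, 0.7, 0.9))  # latent quantiles for ratings 1..3
  out <- list()
  for (p_name in names(loadings)) {
    lo <- loadings[[p_name]]
    for (rg in regions) {
      latent <- lo * d + sqrt(1 - lo^2) * rnorm(n)
      rating <- findInterval(latent, cuts)
      out[[length(out) + 1L]] <- tibble(
        sample_id = ids, region = rg, proteinopathy = p_name, rating = rating
      )
    }
  }
  bind_rows(out)
}

#' Medial temporal lobe regions of interest
#'
#' The six regions whose summed semi-quantitative ratings form the MTL
#' burden composite.
#' @return Character vector of region names.
#' @export
mtl_regions <- function() {
  c("dentate gyrus", "CA1/subiculum", "CA2", "CA3/CA4",
    "entorhinal cortex", "amygdala")
}
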