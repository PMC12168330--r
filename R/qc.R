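#' Mask values below the assay limit of detection
#'
#' The LOD of each assay is its median log2 buffer signal plus three
#' buffer standard deviations; cells strictly below the LOD are coded
#' missing, everything else (equality included) is unchanged.
#'
#' @param matrix Numeric samples x proteins matrix.
#' @param qc Per-assay QC tibble with `assay_id`, `buffer_median`,
#'   `buffer_sd` (see [simulate_assay_panel()] for the schema).
#' @return The matrix with sub-LOD cells set to `NA`.
#' @export
apply_lod_mask <- function(matrix, qc) {
  assert_matrix(matrix, "matrix")
  missing_qc <- setdiff(colnames(matrix), qc$assay_id)
  if (length(missing_qc) > 0) {
    abort(paste0("no QC row for protein(s): ",
                 paste(head(missing_qc, 5), collapse = ", ")))
  }
  if (any(qc$buffer_sd < 0, na.rm = TRUE)) abort("buffer_sd must be >= 0")
  lod <- setNames(qc$buffer_median + 3 * qc$buffer_sd, qc$assay_id)
  out <- matrix
  for (j in colnames(out)) {
    below <- !is.na(out[, j]) & out[, j] < lod[[j]]
    out[below, j] <- NA_real_
  }
  out
}

#' Filter assays: QC warnings, duplicate UniProt IDs, high missingness
#'
#' Applies, in order: (1) removal of assays flagged with a QC warning;
#' (2) among assays sharing a UniProt accession, retention of exactly one
#' (lowest missingness, then highest variance, then lexicographically
#' smallest assay id); (3) removal of proteins whose missing fraction is
#' strictly greater than `missing_threshold`. Expects the LOD mask to
#' have been applied already.
#'
#' @param matrix Numeric samples x proteins matrix (LOD-masked).
#' @param qc Per-assay QC tibble.
#' @param missing_threshold Maximum tolerated missing fraction (default
#'   0.5; exactly 50% missing is retained).
#' @return List with `matrix` (filtered) and `report` (a `qc_report`).
#' @export
filter_proteins <- function(matrix, qc, missing_threshold = 0.5) {
  assert_matrix(matrix, "matrix")
  qc <- qc[match(colnames(matrix), qc$assay_id), ]

  warn_drop <- qc$assay_id[which(qc$qc_warning)]
  keep <- setdiff(colnames(matrix), warn_drop)

  miss_frac <- colMeans(is.na(matrix[, keep, drop = FALSE]))
  variance <- apply(matrix[, keep, drop = FALSE], 2, var, na.rm = TRUE)
  uni <- setNames(qc$uniprot_id, qc$assay_id)[keep]

  dup_drop <- character(0)
  for (u in unique(uni[duplicated(uni)])) {
    members <- keep[uni == u]
    ord <- order(miss_frac[members], -variance[members], members)
    dup_drop <- c(dup_drop, members[ord[-1]])
  }
  keep <- setdiff(keep, dup_drop)

  hm_drop <- keep[miss_frac[keep] > missing_threshold]
  keep <- setdiff(keep, hm_drop)

  if (length(keep) == 0) abort("no proteins remain after filtering")
  out <- matrix[, keep, drop = FALSE]
  report <- new_qc_report(
    stage = "filter_proteins",
    input_dims = dim(matrix),
    retained_dims = dim(out),
    removed = list(
      qc_warning = warn_drop, duplicate_uniprot = dup_drop,
      high_missingness = hm_drop
    )
  )
  list(matrix = out, report = report)
}

new_qc_report <- function(stage, input_dims, retained_dims, removed,
                          extra = list()) {
  structure(
    c(list(stage = stage, input_dims = input_dims,
           retained_dims = retained_dims, removed = removed), extra),
    class = "qc_report"
  )
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report:%s> %dx%d -> %dx%d\n", x$stage,
              x$input_dims[1], x$input_dims[2],
              x$retained_dims[1], x$retained_dims[2]))
  for (nm in names(x$removed)) {
    cat(sprintf("  removed %-20s %d\n", nm, length(x$removed[[nm]])))
  }
  invisible(x)
}

#' Z-transformed sample connectivity
#'
#' For each sample `i`, connectivity is the sum over other samples of the
#' inter-sample correlation (biweight midcorrelation by default) computed
#' across pairwise-complete proteins; the vector of connectivities is
#' then standardized to Z scores. Decorrelated (aberrant) samples have
#' strongly negative Z.
#'
#' @param matrix Numeric samples x proteins matrix.
#' @param method `"bicor"` (default) or `"pearson"`.
#' @return Named numeric vector of per-sample Z scores.
#' @export
sample_connectivity <- function(matrix, method = c("bicor", "pearson")) {
  method <- match.arg(method)
  assert_matrix(matrix, "matrix")
  if (nrow(matrix) < 3 || ncol(matrix) < 2) {
    abort("connectivity needs at least 3 samples and 2 proteins")
  }
  obs <- !is.na(matrix)
  pair_counts <- tcrossprod(obs * 1)
  diag(pair_counts) <- Inf
  if (any(pair_counts < 2)) {
    bad <- rownames(matrix)[which(apply(pair_counts < 2, 1, any))]
    abort(paste0("sample(s) with < 2 pairwise-complete proteins: ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  cors <- bicor_matrix(t(matrix), method = method)
  diag(cors) <- 0
  k <- rowSums(cors, na.rm = TRUE)
  s <- sd(k)
  if (!is.finite(s) || s == 0) {
    warn("all sample connectivities equal; returning zero Z scores")
    return(setNames(rep(0, nrow(matrix)), rownames(matrix)))
  }
  setNames((k - mean(k)) / s, rownames(matrix))
}

#' Remove aberrant-connectivity outlier samples
#'
#' Single-pass removal of samples whose connectivity Z score is below
#' `-z_cutoff` (low connectivity only: a decorrelated sample can only
#' lose connectivity).
#'
#' @param matrix Numeric samples x proteins matrix.
#' @param z_cutoff Positive Z threshold (default 3, the three-fold SD
#'   rule).
#' @param method Correlation passed to [sample_connectivity()].
#' @return List with `matrix` (outliers dropped) and `report`
#'   (a `qc_report` carrying the removed ids and all Z scores).
#' @export
remove_outlier_samples <- function(matrix, z_cutoff = 3.0,
                                   method = c("bicor", "pearson")) {
  if (z_cutoff <= 0) abort("z_cutoff must be positive")
  z <- sample_connectivity(matrix, method = match.arg(method))
  flagged <- names(z)[z < -z_cutoff]
  if (length(flagged) == nrow(matrix)) abort("all samples flagged as outliers")
  out <- matrix[setdiff(rownames(matrix), flagged), , drop = FALSE]
  report <- new_qc_report(
    stage = "remove_outlier_samples",
    input_dims = dim(matrix), retained_dims = dim(out),
    removed = list(outlier_samples = flagged),
    extra = list(connectivity_z = z)
  )
  list(matrix = out, report = report)
}

#' Case-protected bootstrap covariate adjustment
#'
#' Removes the effects of age and sex from every protein while protecting
#' case-related variance: each bootstrap replicate resamples samples with
#' replacement (stratified by group so group indicators stay estimable)
#' and fits, per protein, an ordinary least squares model
#' `protein ~ age + sex + group` on the non-missing cells. The
#' element-wise median over replicates of the age and sex coefficients is
#' multiplied by each participant's raw age and sex and subtracted from
#' their protein values. Missing cells stay missing; group coefficients
#' are estimated but never subtracted.
#'
#' @param matrix Numeric samples x proteins matrix.
#' @param meta Tibble with `sample_id`, `group`, `age`, `sex`.
#' @param n_boot Bootstrap replicates (default 1000). `n_boot = 1` with
#'   `resample = FALSE` reduces to a single OLS fit on the observed data.
#' @param seed Integer seed for the resampling stream.
#' @param resample Set `FALSE` to skip resampling (oracle mode).
#' @param max_retries Redraws allowed when a replicate's design matrix is
#'   singular (e.g. a resample missing one sex).
#' @return List with `matrix` (adjusted), `coefficients` (tibble:
#'   protein_id, beta_age, beta_sex) and `n_boot`.
#' @export
adjust_covariates <- function(matrix, meta, n_boot = 1000, seed = 1L,
                              resample = TRUE, max_retries = 25L) {
  assert_matrix(matrix, "matrix")
  meta <- meta[match(rownames(matrix), meta$sample_id), ]
  if (anyNA(meta$sample_id)) abort("metadata missing for some samples")
  if (sd(meta$age) == 0 || sd(meta$sex) == 0) {
    abort("covariates must be non-constant across the cohort")
  }
  grp <- groups_as_factor(meta$group)
  if (any(table(grp) < 2)) abort("each group needs at least 2 samples")

  design <- stats::model.matrix(~ age + sex + group,
                                data = data.frame(age = meta$age, sex = meta$sex,
                                                  group = grp))
  n <- nrow(matrix); p <- ncol(matrix)
  idx_by_group <- split(seq_len(n), grp)

  set.seed(as.integer(seed))
  beta_age <- matrix(NA_real_, n_boot, p)
  beta_sex <- matrix(NA_real_, n_boot, p)
  has_na <- anyNA(matrix)
  na_mask <- is.na(matrix)

  for (b in seq_len(n_boot)) {
    tries <- 0L
    repeat {
      rows <- if (resample) {
        unlist(lapply(idx_by_group, function(ix) sample(ix, length(ix), replace = TRUE)),
               use.names = FALSE)
      } else seq_len(n)
      Xb <- design[rows, , drop = FALSE]
      if (qr(Xb)$rank == ncol(Xb)) break
      tries <- tries + 1L
      if (tries > max_retries) abort("singular bootstrap design after max_retries redraws")
    }
    Yb <- matrix[rows, , drop = FALSE]
    if (!has_na) {
      coefs <- qr.coef(qr(Xb), Yb)
      beta_age[b, ] <- coefs["age", ]
      beta_sex[b, ] <- coefs["sex", ]
    } else {
      # complete columns in one solve, columns with missing cells individually
      complete_cols <- which(!apply(na_mask[rows, , drop = FALSE], 2, any))
      if (length(complete_cols) > 0) {
        coefs <- qr.coef(qr(Xb), Yb[, complete_cols, drop = FALSE])
        beta_age[b, complete_cols] <- coefs["age", ]
        beta_sex[b, complete_cols] <- coefs["sex", ]
      }
      for (j in setdiff(seq_len(p), complete_cols)) {
        ok <- !is.na(Yb[, j])
        if (sum(ok) <= ncol(Xb)) next
        Xo <- Xb[ok, , drop = FALSE]
        if (qr(Xo)$rank < ncol(Xo)) next
        cf <- qr.coef(qr(Xo), Yb[ok, j])
        beta_age[b, j] <- cf[["age"]]
        beta_sex[b, j] <- cf[["sex"]]
      }
    }
  }

  med_age <- apply(beta_age, 2, median, na.rm = TRUE)
  med_sex <- apply(beta_sex, 2, median, na.rm = TRUE)
  med_age[!is.finite(med_age)] <- 0
  med_sex[!is.finite(med_sex)] <- 0

  adjusted <- matrix -
    outer(meta$age, med_age) -
    outer(meta$sex, med_sex)
  adjusted[na_mask] <- NA_real_

  list(
    matrix = adjusted,
    coefficients = tibble(protein_id = colnames(matrix),
                          beta_age = med_age, beta_sex = med_sex),
    n_boot = n_boot
  )
}

#' Run the full sample/protein QC chain
#'
#' Fixed-order pipeline: LOD mask, protein filters, connectivity outlier
#' removal, bootstrap covariate adjustment.
#'
#' @inheritParams filter_proteins
#' @inheritParams adjust_covariates
#' @inheritParams remove_outlier_samples
#' @param adjust Set `FALSE` to skip covariate adjustment.
#' @return List with `matrix`, `reports` (list of `qc_report`s),
#'   `coefficients` (or `NULL`).
#' @export
qc_pipeline <- function(matrix, qc, meta, missing_threshold = 0.5,
                        z_cutoff = 3.0, n_boot = 1000, seed = 1L,
                        adjust = TRUE) {
  masked <- apply_lod_mask(matrix, qc)
  filt <- filter_proteins(masked, qc, missing_threshold)
  outl <- remove_outlier_samples(filt$matrix, z_cutoff)
  coefs <- NULL
  mat <- outl$matrix
  if (adjust) {
    adj <- adjust_covariates(mat, meta, n_boot = n_boot,
                             seed = stage_seed(seed, "boot"))
    mat <- adj$matrix
    coefs <- adj$coefficients
  }
  list(matrix = mat,
       reports = list(proteins = filt$report, samples = outl$report),
       coefficients = coefs)
}
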