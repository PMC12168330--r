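#' Global cognitive composite
#'
#' Mean of the episodic-memory and executive-function composite
#' z-scores; if one domain is missing the composite equals the other,
#' and it is missing only when both are.
#'
#' @param memory_z,executive_z Numeric domain z-scores (NA allowed).
#' @return Numeric global cognition z-scores.
#' @examples
#' cognitive_composite(c(-1, 0, NA), c(-3, 0, -2))
#' @export
cognitive_composite <- function(memory_z, executive_z) {
  stopifnot(length(memory_z) == length(executive_z))
  rowMeans(cbind(memory_z, executive_z), na.rm = TRUE) |>
    (\(x) ifelse(is.nan(x), NA_real_, x))()
}

#' Declared neuropathology region vocabulary
#'
#' The medial-temporal-lobe regions of interest plus the other cortical
#' and subcortical regions sampled in standard protocols.
#' @return Character vector.
#' @export
neuropath_regions <- function() {
  c(mtl_regions(),
    "middle frontal cortex", "orbitofrontal cortex",
    "superior/middle temporal cortex", "cingulate cortex",
    "inferior parietal cortex", "occipital cortex",
    "striatum", "thalamus", "substantia nigra", "locus coeruleus",
    "cerebellum")
}

#' Semi-quantitative neuropathology burden composites
#'
#' Sums ordinal 0-3 ratings over the chosen regions, separately per
#' proteinopathy (and neurodegeneration), per sample.
#'
#' @param ratings Long tibble (sample_id, region, proteinopathy, rating)
#'   with integer ratings in 0..3 and regions from
#'   [neuropath_regions()].
#' @param roi `"all"`, `"mtl"` or an explicit character vector of
#'   regions.
#' @return Wide tibble: sample_id plus one burden column per
#'   proteinopathy.
#' @export
neuropath_composites <- function(ratings, roi = "all") {
  bad_region <- setdiff(unique(ratings$region), neuropath_regions())
  if (length(bad_region) > 0) {
    abort(paste0("unknown region name(s): ", paste(bad_region, collapse = ", ")))
  }
  if (!all(ratings$rating %in% 0:3)) abort("ratings must be integers in 0..3")
  regions <- if (identical(roi, "all")) unique(ratings$region)
    else if (identical(roi, "mtl")) mtl_regions()
    else roi
  ratings |>
    filter(.data$region %in% regions) |>
    group_by(.data$sample_id, .data$proteinopathy) |>
    summarise(burden = sum(.data$rating), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "proteinopathy", values_from = "burden")
}

#' Subregion contributions to a burden composite
#'
#' Percentage of the summed composite accounted for by each region,
#' pooled over samples; percentages sum to 100 whenever the total
#' burden is positive.
#'
#' @param ratings Long ratings tibble (see [neuropath_composites()]).
#' @param proteinopathy Which proteinopathy to decompose.
#' @param roi Regions forming the composite (default the MTL set).
#' @return Tibble (region, burden, pct).
#' @export
subregion_contributions <- function(ratings, proteinopathy, roi = mtl_regions()) {
  d <- ratings |>
    filter(.data$proteinopathy == !!proteinopathy, .data$region %in% roi) |>
    group_by(.data$region) |>
    summarise(burden = sum(.data$rating), .groups = "drop")
  total <- sum(d$burden)
  mutate(d, pct = if (total > 0) 100 * .data$burden / total else 0)
}

# one correlation cell with method dispatch and the >= 5 pair guard
cor_cell <- function(x, y, method) {
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < 5 || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
    return(tibble(estimate = NA_real_, p = NA_real_, n = n, tested = FALSE))
  }
  r <- switch(method,
    spearman = cor(rank(x[ok]), rank(y[ok])),
    bicor = bicor(x[ok], y[ok]),
    pearson = cor(x[ok], y[ok])
  )
  tibble(estimate = r, p = cor_p_value(r, n), n = n, tested = TRUE)
}

#' Module eigenprotein-trait correlations
#'
#' Correlates each eigenprotein with each trait, pooled and within each
#' group, using Spearman's rho (tie-corrected midranks, t approximation
#' for p) or the biweight midcorrelation (t approximation on n-2 df).
#' Cells with fewer than 5 complete pairs or a zero-variance trait are
#' marked untested.
#'
#' @param eigenproteins Samples x modules matrix.
#' @param traits Tibble with `sample_id` and trait columns.
#' @param groups Optional group label per sample (adds per-group rows).
#' @param method `"spearman"` (default), `"bicor"` or `"pearson"`.
#' @return Tibble (module, trait, group, estimate, p, n, tested) where
#'   group `"pooled"` uses all samples.
#' @export
module_trait_correlations <- function(eigenproteins, traits, groups = NULL,
                                      method = c("spearman", "bicor", "pearson")) {
  method <- match.arg(method)
  traits <- traits[match(rownames(eigenproteins), traits$sample_id), ]
  trait_cols <- setdiff(names(traits), "sample_id")
  strata <- list(pooled = seq_len(nrow(eigenproteins)))
  if (!is.null(groups)) {
    grp <- groups_as_factor(groups)
    for (g in levels(grp)) strata[[g]] <- which(grp == g)
  }
  rows <- list()
  for (m in colnames(eigenproteins)) {
    for (tr in trait_cols) {
      for (g in names(strata)) {
        ix <- strata[[g]]
        cell <- cor_cell(eigenproteins[ix, m], traits[[tr]][ix], method)
        rows[[length(rows) + 1L]] <-
          mutate(cell, module = m, trait = tr, group = g, .before = 1)
      }
    }
  }
  out <- bind_rows(rows)
  if (any(!out$tested)) warn("some module-trait cells were untested (too few pairs or zero variance)")
  out
}

#' Per-protein differential correlation with a trait
#'
#' Spearman correlation of every protein with the trait within a sample
#' subset, with a per-module summary (fraction of members nominally
#' significant and mean coefficient) when module labels are supplied.
#'
#' @param matrix Numeric samples x proteins matrix.
#' @param trait Named (or matrix-aligned) numeric trait vector.
#' @param subset Optional logical/character/integer sample selector.
#' @param labels Optional named protein -> module vector.
#' @param alpha Nominal significance threshold for the module summary.
#' @return List with `proteins` (tibble: protein_id, rho, p, n, tested)
#'   and `modules` (tibble or NULL).
#' @export
protein_trait_differential_correlation <- function(matrix, trait, subset = NULL,
                                                   labels = NULL, alpha = 0.05) {
  if (!is.null(subset)) {
    matrix <- matrix[subset, , drop = FALSE]
    trait <- if (!is.null(names(trait))) trait[rownames(matrix)] else trait[subset]
  }
  if (sum(is.finite(trait)) < 5) abort("subset needs at least 5 samples with the trait")
  if (!anyNA(matrix) && all(is.finite(trait))) {
    # complete data: one ranked crossproduct instead of a per-protein loop
    R <- apply(matrix, 2, rank)
    rho <- as.numeric(cor(R, rank(trait)))
    sds <- apply(R, 2, sd)
    rho[sds == 0] <- NA
    n <- nrow(matrix)
    prot <- tibble(
      protein_id = colnames(matrix), rho = rho,
      p = ifelse(is.na(rho), NA_real_, cor_p_value(rho, n)),
      n = n, tested = !is.na(rho)
    )
  } else {
    prot <- bind_rows(lapply(colnames(matrix), function(p_id) {
      cell <- cor_cell(matrix[, p_id], trait, "spearman")
      mutate(cell, protein_id = p_id, .before = 1)
    }))
    prot <- dplyr::rename(prot, rho = "estimate")
    prot <- prot[, c("protein_id", "rho", "p", "n", "tested")]
  }
  modules <- NULL
  if (!is.null(labels)) {
    modules <- prot |>
      mutate(module = unname(labels[.data$protein_id])) |>
      filter(!is.na(.data$module), .data$module != "unassigned") |>
      group_by(.data$module) |>
      summarise(
        n = n(),
        frac_significant = mean(.data$p < alpha, na.rm = TRUE),
        mean_rho = mean(.data$rho, na.rm = TRUE),
        .groups = "drop"
      )
  }
  list(proteins = prot, modules = modules)
}

#' Cross-platform agreement between a panel assay and an immunoassay
#'
#' Pearson and Spearman correlations over paired, non-missing values.
#'
#' @param olink_values,immunoassay_values Paired numeric vectors.
#' @return One-row tibble (pearson, spearman, n, tested); untested with
#'   a warning below 5 pairs.
#' @export
cross_platform_check <- function(olink_values, immunoassay_values) {
  ok <- is.finite(olink_values) & is.finite(immunoassay_values)
  n <- sum(ok)
  if (n < 5) {
    warn("fewer than 5 paired values; cross-platform check untested")
    return(tibble(pearson = NA_real_, spearman = NA_real_, n = n, tested = FALSE))
  }
  tibble(
    pearson = cor(olink_values[ok], immunoassay_values[ok]),
    spearman = cor(olink_values[ok], immunoassay_values[ok], method = "spearman"),
    n = n, tested = TRUE
  )
}

#' Sampling-to-death interval confound check
#'
#' Biweight midcorrelation of every module eigenprotein with the
#' sampling-to-death interval, plus a two-sided t test of the interval
#' between the two groups.
#'
#' @param eigenproteins Samples x modules matrix (autopsy subset).
#' @param interval Numeric interval (years) per sample.
#' @param group Two-level group label per sample (e.g. CTE status).
#' @return List with `correlations` (one row per module: estimate, p, n)
#'   and `group_test` (tibble: t, p).
#' @export
interval_confound_check <- function(eigenproteins, interval, group) {
  if (sum(is.finite(interval)) < 5) {
    warn("fewer than 5 intervals; confound check untested")
    return(list(
      correlations = tibble(module = colnames(eigenproteins),
                            estimate = NA_real_, p = NA_real_,
                            n = sum(is.finite(interval)), tested = FALSE),
      group_test = tibble(t = NA_real_, p = NA_real_)
    ))
  }
  cors <- bind_rows(lapply(colnames(eigenproteins), function(m) {
    mutate(cor_cell(eigenproteins[, m], interval, "bicor"),
           module = m, .before = 1)
  }))
  grp <- droplevels(as.factor(group))
  gt <- if (nlevels(grp) == 2) {
    a <- interval[grp == levels(grp)[1]]
    b <- interval[grp == levels(grp)[2]]
    if (isTRUE(all.equal(var(c(a, b)), 0))) {
      tibble(t = 0, p = 1)
    } else {
      tt <- stats::t.test(a, b)
      tibble(t = unname(tt$statistic), p = tt$p.value)
    }
  } else tibble(t = NA_real_, p = NA_real_)
  list(correlations = cors, group_test = gt)
}

#' Heatmap of module-trait correlations
#'
#' @param cor_table Output of [module_trait_correlations()].
#' @param group Which stratum to show (default `"pooled"`).
#' @return A ggplot.
#' @export
plot_module_trait_heatmap <- function(cor_table, group = "pooled") {
  d <- filter(cor_table, .data$group == !!group, .data$tested)
  ggplot(d, aes(x = .data$trait, y = .data$module, fill = .data$estimate)) +
    geom_tile() +
    scale_fill_gradient2(limits = c(-1, 1)) +
    labs(fill = "correlation",
         title = sprintf("Module-trait correlations (%s)", group)) +
    theme_minimal()
}
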