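#' Per-protein one-way ANOVA with Tukey-Kramer post hoc comparisons
#'
#' For every protein, a fixed-effects one-way ANOVA on the non-missing
#' cells across groups, followed by Tukey-Kramer honestly-significant-
#' difference p-values for every group pair (studentized-range
#' distribution with the Kramer adjustment for unequal group sizes).
#' Log2 fold changes are differences of group means (the data are
#' log2-scale). Proteins with fewer than two groups holding two or more
#' non-missing values are reported as not tested rather than dropped.
#'
#' @param matrix Numeric samples x proteins matrix (log2 abundance).
#' @param groups Group label per sample (factor or character).
#' @return A tibble with one row per (protein, group pair): group means,
#'   omnibus `f` and `p_anova`, `log2fc` (mean of `group_a` minus mean of
#'   `group_b`), `p_tukey`, `tested`.
#' @examples
#' m <- matrix(rnorm(60), 20, 3,
#'             dimnames = list(paste0("S", 1:20), paste0("P", 1:3)))
#' anova_tukey(m, rep(c("CTL", "RHI"), each = 10))
#' @export
anova_tukey <- function(matrix, groups) {
  assert_matrix(matrix, "matrix")
  grp <- groups_as_factor(groups)
  stopifnot(length(grp) == nrow(matrix))
  lev <- levels(grp)
  if (length(lev) < 2) abort("need at least 2 groups")
  pairs <- utils::combn(lev, 2)

  rows <- vector("list", ncol(matrix))
  for (j in seq_len(ncol(matrix))) {
    y <- matrix[, j]
    ok <- !is.na(y)
    counts <- tapply(ok, grp, sum)
    counts[is.na(counts)] <- 0
    usable <- sum(counts >= 2)
    means <- tapply(y[ok], grp[ok], mean)

    if (usable < 2) {
      rows[[j]] <- tibble(
        protein_id = colnames(matrix)[j],
        group_a = pairs[1, ], group_b = pairs[2, ],
        mean_a = unname(means[pairs[1, ]]), mean_b = unname(means[pairs[2, ]]),
        f = NA_real_, p_anova = NA_real_,
        log2fc = NA_real_, p_tukey = NA_real_, tested = FALSE
      )
      next
    }
    yy <- y[ok]; gg <- droplevels(grp[ok])
    ni <- table(gg)
    k <- length(ni)
    n <- sum(ni)
    gm <- tapply(yy, gg, mean)
    ssb <- sum(ni * (gm - mean(yy))^2)
    ssw <- sum((yy - gm[gg])^2)
    df1 <- k - 1; df2 <- n - k
    mse <- ssw / df2
    f <- if (mse > 0) (ssb / df1) / mse else if (ssb > 0) Inf else 0
    p_anova <- pf(f, df1, df2, lower.tail = FALSE)
    if (mse == 0 && ssb == 0) p_anova <- 1

    fc <- p_tk <- rep(NA_real_, ncol(pairs))
    for (cpair in seq_len(ncol(pairs))) {
      a <- pairs[1, cpair]; b <- pairs[2, cpair]
      if (!a %in% names(gm) || !b %in% names(gm) ||
          ni[a] < 2 || ni[b] < 2) next
      fc[cpair] <- gm[[a]] - gm[[b]]
      se <- sqrt(mse / 2 * (1 / ni[[a]] + 1 / ni[[b]]))
      if (se == 0) {
        p_tk[cpair] <- if (fc[cpair] == 0) 1 else 0
      } else {
        q <- abs(fc[cpair]) / se
        p_tk[cpair] <- ptukey(q, nmeans = k, df = df2, lower.tail = FALSE)
      }
    }
    rows[[j]] <- tibble(
      protein_id = colnames(matrix)[j],
      group_a = pairs[1, ], group_b = pairs[2, ],
      mean_a = unname(means[pairs[1, ]]), mean_b = unname(means[pairs[2, ]]),
      f = f, p_anova = p_anova, log2fc = fc, p_tukey = p_tk, tested = TRUE
    )
  }
  bind_rows(rows)
}

#' Group tests on module eigenproteins
#'
#' Applies the ANOVA + Tukey-Kramer machinery to each eigenprotein
#' column; with exactly two groups a two-sided Welch t test is reported
#' instead (`p_anova` = `p_tukey` = the t-test p).
#'
#' @param eigenproteins Samples x modules eigenprotein matrix.
#' @param groups Group label per sample.
#' @return Tibble as in [anova_tukey()], with `protein_id` holding the
#'   module name and, for two-group designs, a `t` column.
#' @export
eigenprotein_group_tests <- function(eigenproteins, groups) {
  grp <- groups_as_factor(groups)
  lev <- levels(grp)
  if (length(lev) == 2) {
    rows <- lapply(colnames(eigenproteins), function(m) {
      a <- eigenproteins[grp == lev[1], m]
      b <- eigenproteins[grp == lev[2], m]
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      tt <- tryCatch(stats::t.test(a, b), error = function(e) NULL)
      tibble(
        protein_id = m, group_a = lev[1], group_b = lev[2],
        mean_a = mean(a), mean_b = mean(b),
        t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
        f = NA_real_,
        p_anova = if (is.null(tt)) NA_real_ else tt$p.value,
        log2fc = mean(a) - mean(b),
        p_tukey = if (is.null(tt)) NA_real_ else tt$p.value,
        tested = !is.null(tt)
      )
    })
    return(bind_rows(rows))
  }
  anova_tukey(eigenproteins, grp)
}

#' Per-module differential abundance summary
#'
#' For every module and group pair: the fraction of member proteins with
#' Tukey p below `alpha`, and the members' mean log2 fold change.
#'
#' @param diff Output of [anova_tukey()].
#' @param labels Named character vector protein -> module (e.g.
#'   `tidy(net)` columns).
#' @param alpha Significance threshold on the Tukey p (default 0.05).
#' @return Tibble (module, group_a, group_b, n, n_da, frac_da,
#'   mean_log2fc).
#' @export
module_da_summary <- function(diff, labels, alpha = 0.05) {
  diff |>
    mutate(module = unname(labels[.data$protein_id])) |>
    filter(!is.na(.data$module)) |>
    group_by(.data$module, .data$group_a, .data$group_b) |>
    summarise(
      n = n(),
      n_da = sum(.data$p_tukey < alpha, na.rm = TRUE),
      frac_da = .data$n_da / .data$n,
      mean_log2fc = mean(.data$log2fc, na.rm = TRUE),
      .groups = "drop"
    )
}

#' Absolute-abundance tier annotation
#'
#' Bins proteins into plasma abundance tiers from absolute concentration
#' annotations: high above 9.5 log10 pg/L, intermediate in \[6.0, 9.5\]
#' (boundaries inclusive), low below 6.0.
#'
#' @param qc Per-assay QC tibble with `assay_id` and
#'   `abundance_log10_pg_per_l`.
#' @return Tibble (protein_id, abundance_log10_pg_per_l, tier) with tier
#'   an ordered factor low < intermediate < high; proteins without an
#'   annotation are dropped.
#' @export
tier_annotation <- function(qc) {
  ab <- qc$abundance_log10_pg_per_l
  keep <- !is.na(ab)
  tier <- ifelse(ab > 9.5, "high", ifelse(ab >= 6.0, "intermediate", "low"))
  tibble(
    protein_id = qc$assay_id[keep],
    abundance_log10_pg_per_l = ab[keep],
    tier = factor(tier[keep], levels = c("low", "intermediate", "high"),
                  ordered = TRUE)
  )
}

#' Abundance-tier stratified differential-abundance analysis
#'
#' For one group pair: a one-way ANOVA of the signed per-protein log2
#' fold changes across abundance tiers, and a chi-square test of
#' independence (no continuity correction) on the tier x
#' (differentially upregulated vs not) contingency table, plus per-tier
#' means and percentages.
#'
#' @param diff Output of [anova_tukey()].
#' @param tiers Output of [tier_annotation()].
#' @param pair Character vector of the two group labels to analyse.
#' @param alpha Tukey-p threshold defining differential upregulation.
#' @return List with `anova` (tibble: f, p), `chisq` (tibble: statistic,
#'   p), and `by_tier` (tibble: tier, n, mean_log2fc, pct_da_up).
#' @export
tier_stratified_analysis <- function(diff, tiers, pair, alpha = 0.05) {
  d <- diff |>
    filter(.data$group_a %in% pair, .data$group_b %in% pair,
           .data$group_a != .data$group_b, .data$tested) |>
    mutate(log2fc = ifelse(.data$group_a == pair[1], .data$log2fc, -.data$log2fc)) |>
    left_join(tiers, by = "protein_id") |>
    filter(!is.na(.data$tier)) |>
    mutate(tier = droplevels(.data$tier),
           da_up = .data$p_tukey < alpha & .data$log2fc > 0)
  counts <- table(d$tier)
  if (sum(counts >= 2) < 2) abort("need at least 2 tiers with 2+ proteins")
  if (any(counts == 0)) {
    warn("empty abundance tier excluded")
    d <- filter(d, .data$tier %in% names(counts)[counts > 0])
    d$tier <- droplevels(d$tier)
  }
  av <- stats::oneway.test(log2fc ~ tier, data = d, var.equal = TRUE)
  ct <- table(d$tier, d$da_up)
  chi <- suppressWarnings(chisq.test(ct, correct = FALSE))
  by_tier <- d |>
    group_by(.data$tier) |>
    summarise(n = n(), mean_log2fc = mean(.data$log2fc),
              pct_da_up = 100 * mean(.data$da_up), .groups = "drop")
  list(
    anova = tibble(f = unname(av$statistic), p = av$p.value),
    chisq = tibble(statistic = unname(chi$statistic), p = chi$p.value),
    by_tier = by_tier
  )
}

#' Volcano plot of pairwise differential abundance
#'
#' @param diff Output of [anova_tukey()].
#' @param pair Two group labels; the log2 fold change is oriented as
#'   `pair[1] - pair[2]`.
#' @param labels Optional named module labels for colouring.
#' @param alpha Tukey-p significance line.
#' @return A ggplot.
#' @export
plot_volcano <- function(diff, pair, labels = NULL, alpha = 0.05) {
  d <- diff |>
    filter(.data$group_a %in% pair, .data$group_b %in% pair,
           .data$group_a != .data$group_b, .data$tested) |>
    mutate(log2fc = ifelse(.data$group_a == pair[1], .data$log2fc, -.data$log2fc))
  if (!is.null(labels)) d$module <- unname(labels[d$protein_id])
  p <- ggplot(d, aes(x = .data$log2fc, y = -log10(.data$p_tukey))) +
    geom_hline(yintercept = -log10(alpha), linetype = "dotted") +
    geom_vline(xintercept = 0, linetype = "dotted") +
    labs(x = sprintf("log2 fold change (%s - %s)", pair[1], pair[2]),
         y = "-log10 Tukey p") +
    theme_minimal()
  if (!is.null(labels)) p + geom_point(aes(colour = .data$module), alpha = 0.7)
  else p + geom_point(alpha = 0.7)
}
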