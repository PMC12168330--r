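#' Fisher exact gene-set enrichment with z transformation
#'
#' One-tailed hypergeometric test of the overlap between a hit list and a
#' gene set within a background universe. The p-value is transformed to a
#' signed z score: `z = qnorm(1 - p)` on the enrichment side when the
#' overlap exceeds its expectation, and `z = -qnorm(1 - p_depletion)`
#' when it falls short; p is clamped to \[1e-300, 1 - 1e-16\] before
#' inversion. Symbols are harmonized case-insensitively.
#'
#' @param hit_list Character vector of hits (subset of the universe).
#' @param gene_set Character vector of set members.
#' @param universe Character background vector.
#' @return One-row tibble: n_hits, n_set, n_universe, overlap, expected,
#'   p (one-tailed enrichment), z.
#' @examples
#' fisher_enrichment(paste0("g", 1:10), paste0("g", 6:40), paste0("g", 1:100))
#' @export
fisher_enrichment <- function(hit_list, gene_set, universe) {
  if (length(hit_list) == 0 || length(gene_set) == 0 || length(universe) == 0) {
    abort("hit list, gene set and universe must all be non-empty")
  }
  u <- unique(toupper(universe))
  hits <- unique(toupper(hit_list))
  set <- intersect(unique(toupper(gene_set)), u)
  if (!all(hits %in% u)) abort("hit list contains symbols outside the universe")
  if (length(set) == 0) abort("gene set has no members in the universe")

  n_u <- length(u); n_h <- length(hits); n_s <- length(set)
  ov <- length(intersect(hits, set))
  expected <- n_h * n_s / n_u

  # white = set members, black = rest; draw = hit list
  p_enrich <- phyper(ov - 1, n_s, n_u - n_s, n_h, lower.tail = FALSE)
  p_deplete <- phyper(ov, n_s, n_u - n_s, n_h, lower.tail = TRUE)
  clamp <- function(p) min(max(p, 1e-300), 1 - 1e-16)
  z <- if (ov >= expected) qnorm(1 - clamp(p_enrich)) else -qnorm(1 - clamp(p_deplete))
  tibble(
    n_hits = n_h, n_set = n_s, n_universe = n_u,
    overlap = ov, expected = expected, p = p_enrich, z = z
  )
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up q-values; `NaN`/`NA` p-values are propagated and excluded from
#' the ranking.
#'
#' @param pvals Numeric p-values in \[0, 1\] (NA allowed).
#' @return q-values of the same length.
#' @export
bh_fdr <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]")
  }
  out <- rep(NA_real_, length(pvals))
  ok <- !is.na(pvals)
  out[ok] <- p.adjust(pvals[ok], method = "BH")
  out
}

#' Enrichment of every gene set in a collection
#'
#' Runs [fisher_enrichment()] for each set against one hit list and
#' attaches BH-FDR q-values across the sets.
#'
#' @param hit_list Character hits.
#' @param gene_sets Named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param universe Character background.
#' @return Tibble, one row per set, sorted by decreasing z.
#' @export
enrich_gene_sets <- function(hit_list, gene_sets, universe) {
  rows <- lapply(names(gene_sets), function(nm) {
    res <- tryCatch(fisher_enrichment(hit_list, gene_sets[[nm]], universe),
                    error = function(e) NULL)
    if (is.null(res)) return(NULL)
    mutate(res, set = nm, .before = 1)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) abort("no gene set overlapped the universe")
  out$q <- bh_fdr(out$p)
  arrange(out, dplyr::desc(.data$z))
}

#' Module-wise overrepresentation of trait-correlated proteins
#'
#' The hit list is the set of proteins whose trait correlation is
#' nominally significant (`p < alpha`) in the stated direction; each
#' module is tested for overrepresentation of hits by a one-tailed
#' Fisher exact test against the universe of all tested proteins, with
#' BH-FDR across modules.
#'
#' @param protein_trait Tibble with `protein_id`, `rho` (or `estimate`)
#'   and `p` columns (e.g. from
#'   [protein_trait_differential_correlation()]).
#' @param labels Named character protein -> module vector.
#' @param direction `"positive"` or `"negative"` association.
#' @param alpha Nominal significance threshold for hit membership.
#' @return Tibble, one row per module, with overlap counts, Fisher `p`,
#'   `z` and `q`.
#' @export
module_overrepresentation <- function(protein_trait, labels,
                                      direction = c("negative", "positive"),
                                      alpha = 0.05) {
  direction <- match.arg(direction)
  est <- protein_trait$rho %||% protein_trait$estimate
  tested <- !is.na(protein_trait$p)
  universe <- protein_trait$protein_id[tested]
  sign_ok <- if (direction == "positive") est > 0 else est < 0
  hits <- protein_trait$protein_id[tested & protein_trait$p < alpha & sign_ok]

  mods <- sort(setdiff(unique(labels[universe]), c(NA, "unassigned")))
  if (length(hits) == 0) {
    warn("no trait-correlated hits at the nominal threshold")
    return(tibble(module = mods, overlap = 0L, n_set = NA_integer_,
                  p = 1, z = NA_real_, q = 1))
  }
  rows <- lapply(mods, function(m) {
    members <- universe[!is.na(labels[universe]) & labels[universe] == m]
    res <- fisher_enrichment(hits, members, universe)
    mutate(res, module = m, .before = 1)
  })
  out <- bind_rows(rows)
  out$q <- bh_fdr(out$p)
  out
}

#' Read a GMT gene-set file
#'
#' Standard tab-delimited format: set name, description, then members.
#' Trailing tabs and empty member fields are tolerated.
#'
#' @param path Path to a `.gmt` file.
#' @return Named list of character member vectors; the description is
#'   kept in the `"description"` attribute of each element.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) abort(sprintf("malformed GMT line: %s", substr(ln, 1, 40)))
    members <- parts[-(1:2)]
    members <- members[nzchar(members)]
    if (length(members) == 0) abort(sprintf("empty gene set: %s", parts[1]))
    s <- members
    attr(s, "description") <- parts[2]
    sets[[parts[1]]] <- s
  }
  sets
}
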