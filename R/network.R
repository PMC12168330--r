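#' Parameters of the signed weighted co-expression network
#'
#' Defaults follow the published analysis configuration for plasma
#' proximity-extension-assay data: soft-threshold power 7.5, biweight
#' midcorrelation, signed adjacency, mean-denominator topological
#' overlap, dynamic hybrid tree cut at the most sensitive split level
#' with a PAM stage, minimum module size 10 and eigenprotein merge height
#' 0.07.
#'
#' @param power Soft-threshold exponent (> 0; non-integer allowed).
#' @param deep_split Split sensitivity 0-4 (4 = most sensitive).
#' @param min_module_size Minimum proteins per module.
#' @param merge_cut_height Eigenprotein dissimilarity below which modules
#'   merge (in \[0, 1)).
#' @param tom_denom `"mean"` or `"min"` connectivity denominator.
#' @param correlation `"bicor"` or `"pearson"`.
#' @param signed Signed adjacency (anti-correlated proteins unconnected).
#' @param pam_stage Assign leftover proteins to the nearest module.
#' @param pam_respects_dendro Restrict PAM candidates to modules within
#'   the protein's dendrogram branch.
#' @param min_kme Membership threshold for kME-consistency enforcement.
#' @return A `network_params` list.
#' @export
network_params <- function(power = 7.5, deep_split = 4, min_module_size = 10,
                           merge_cut_height = 0.07,
                           tom_denom = c("mean", "min"),
                           correlation = c("bicor", "pearson"),
                           signed = TRUE, pam_stage = TRUE,
                           pam_respects_dendro = TRUE, min_kme = 0.30) {
  if (power <= 0) abort("power must be > 0")
  if (merge_cut_height < 0 || merge_cut_height >= 1) {
    abort("merge_cut_height must be in [0, 1)")
  }
  if (min_module_size < 2) abort("min_module_size must be >= 2")
  if (!deep_split %in% 0:4) abort("deep_split must be an integer in 0..4")
  structure(list(
    power = power, deep_split = as.integer(deep_split),
    min_module_size = as.integer(min_module_size),
    merge_cut_height = merge_cut_height,
    tom_denom = match.arg(tom_denom),
    correlation = match.arg(correlation),
    signed = signed, pam_stage = pam_stage,
    pam_respects_dendro = pam_respects_dendro, min_kme = min_kme
  ), class = "network_params")
}

#' Signed soft-threshold adjacency
#'
#' Maps a correlation matrix to \eqn{a_{ij} = ((1 + c_{ij})/2)^\beta}
#' (signed: correlation -1 maps to 0, +1 to 1) or
#' \eqn{|c_{ij}|^\beta} (unsigned). The diagonal is forced to 1.
#'
#' @param C Symmetric correlation matrix with entries in \[-1, 1\].
#' @param power Soft-threshold exponent.
#' @param signed Use the signed transform (default).
#' @return Adjacency matrix with entries in \[0, 1\].
#' @export
signed_adjacency <- function(C, power = 7.5, signed = TRUE) {
  C <- as.matrix(C)
  if (!isSymmetric(unname(C), tol = 1e-8)) abort("correlation matrix must be symmetric")
  if (any(C < -1 - 1e-8 | C > 1 + 1e-8, na.rm = TRUE)) {
    abort("correlation entries must lie in [-1, 1]")
  }
  A <- if (signed) ((1 + C) / 2)^power else abs(C)^power
  diag(A) <- 1
  A
}

#' Topological overlap similarity
#'
#' \deqn{TOM_{ij} = \frac{\ell_{ij} + a_{ij}}{D_{ij} + 1 - a_{ij}}}
#' with \eqn{\ell_{ij} = \sum_{u \ne i,j} a_{iu} a_{uj}}, node
#' connectivity \eqn{k_i = \sum_{u \ne i} a_{iu}}, and denominator
#' \eqn{D_{ij} = (k_i + k_j)/2} (`"mean"`) or \eqn{\min(k_i, k_j)}
#' (`"min"`). The diagonal is 1.
#'
#' @param A Symmetric adjacency with entries in \[0, 1\] and unit
#'   diagonal.
#' @param denom `"mean"` or `"min"`.
#' @return TOM similarity matrix; `1 - tom_similarity(A)` is the
#'   dissimilarity used for clustering.
#' @export
tom_similarity <- function(A, denom = c("mean", "min")) {
  denom <- match.arg(denom)
  A <- as.matrix(A)
  if (any(A < 0 | A > 1)) abort("adjacency entries must lie in [0, 1]")
  if (!isSymmetric(unname(A), tol = 1e-8)) abort("adjacency must be symmetric")
  diag(A) <- 0
  k <- rowSums(A)
  # with zero diagonal, (A %*% A)_ij = sum_{u != i,j} a_iu a_uj exactly
  L <- A %*% A
  D <- if (denom == "mean") outer(k, k, "+") / 2 else outer(k, k, pmin)
  tom <- (L + A) / (D + 1 - A)
  diag(tom) <- 1
  pmin(pmax(tom, 0), 1)
}

# deepSplit 0..4 -> (maxCoreScatter, minGap) on the normalized height scale
deep_split_grid <- function(deep_split) {
  msc <- c(0.64, 0.73, 0.82, 0.91, 0.95)[deep_split + 1]
  list(max_core_scatter = msc, min_gap = (1 - msc) * 3 / 4)
}

#' Dynamic hybrid module detection on a dissimilarity matrix
#'
#' Average-linkage hierarchical clustering followed by an adaptive
#' (variable-height) tree cut: a static cut at 99% of the joining-height
#' range above its 5th percentile defines the top branches, and each
#' branch is recursively subdivided while both candidate sub-clusters
#' have at least `min_module_size` members, a core scatter (mean internal
#' joining height) below the deep-split threshold, and a separating gap
#' above it. Clusters below the minimum size dissolve to "unassigned". A
#' PAM stage then assigns unassigned proteins to the module with the
#' smallest average dissimilarity, restricted (when
#' `pam_respects_dendro`) to modules inside the protein's static-cut
#' branch.
#'
#' @param dissimilarity Square symmetric matrix with zero diagonal
#'   (typically `1 - tom_similarity(A)`).
#' @param params A [network_params()].
#' @return List with `labels` (integer per protein, 0 = unassigned) and
#'   `dendrogram` (the `hclust` object).
#' @export
cut_modules <- function(dissimilarity, params = network_params()) {
  D <- as.matrix(dissimilarity)
  if (!isSymmetric(unname(D), tol = 1e-8) || any(abs(diag(D)) > 1e-8)) {
    abort("dissimilarity must be symmetric with zero diagonal")
  }
  n <- nrow(D)
  ids <- colnames(D) %||% as.character(seq_len(n))
  min_size <- params$min_module_size
  hc <- hclust(stats::as.dist(D), method = "average")
  if (n < 2 * min_size) {
    warn("fewer proteins than twice the minimum module size; all unassigned")
    return(list(labels = setNames(rep(0L, n), ids), dendrogram = hc))
  }

  h <- hc$height
  ref <- quantile(h, 0.05, names = FALSE)
  cut_height <- ref + 0.99 * (max(h) - ref)
  rng <- max(cut_height - ref, .Machine$double.eps)
  grid <- deep_split_grid(params$deep_split)
  msc_abs <- ref + grid$max_core_scatter * rng
  gap_abs <- grid$min_gap * rng

  # per internal node: leaves, height, sorted internal heights
  merge <- hc$merge
  leaves <- vector("list", n - 1)
  internal_h <- vector("list", n - 1)
  node_leaves <- function(k) if (k < 0) -k else leaves[[k]]
  for (k in seq_len(n - 1)) {
    a <- merge[k, 1]; b <- merge[k, 2]
    leaves[[k]] <- c(node_leaves(a), node_leaves(b))
    internal_h[[k]] <- c(
      if (a > 0) internal_h[[a]] else numeric(0),
      if (b > 0) internal_h[[b]] else numeric(0),
      h[k]
    )
  }
  node_size <- function(k) if (k < 0) 1L else length(leaves[[k]])
  node_height <- function(k) if (k < 0) ref else h[k]
  core_scatter <- function(k) {
    if (k < 0) return(ref)
    hs <- sort(internal_h[[k]])
    core <- head(hs, max(min_size - 1L, 1L))
    mean(core)
  }
  qualifies <- function(k, parent_h) {
    node_size(k) >= min_size &&
      core_scatter(k) <= msc_abs &&
      (parent_h - node_height(k)) >= gap_abs
  }

  labels <- rep(0L, n)
  next_label <- 0L
  assign_cluster <- function(k) {
    next_label <<- next_label + 1L
    labels[node_leaves(k)] <<- next_label
  }
  process <- function(k, parent_h) {
    if (node_size(k) < min_size) return(invisible())
    is_cluster <- core_scatter(k) <= msc_abs &&
      (parent_h - node_height(k)) >= gap_abs
    if (!is_cluster) {
      process(merge[k, 1], node_height(k))
      process(merge[k, 2], node_height(k))
      return(invisible())
    }
    a <- merge[k, 1]; b <- merge[k, 2]
    if (qualifies(a, node_height(k)) && qualifies(b, node_height(k))) {
      process(a, node_height(k))
      process(b, node_height(k))
    } else {
      assign_cluster(k)
    }
  }

  branches <- cutree(hc, h = cut_height)
  top_nodes <- which(vapply(seq_len(n - 1), function(k) h[k] <= cut_height &&
                              (k == n - 1 || h[find_parent(merge, k)] > cut_height),
                            logical(1)))
  for (k in top_nodes) process(k, cut_height)

  # PAM stage: rescue unassigned proteins
  if (params$pam_stage && any(labels > 0L) && any(labels == 0L)) {
    mods <- sort(unique(labels[labels > 0L]))
    avg_d <- vapply(mods, function(m) {
      rowMeans(D[, labels == m, drop = FALSE])
    }, numeric(n))
    if (is.null(dim(avg_d))) avg_d <- matrix(avg_d, nrow = n)
    for (i in which(labels == 0L)) {
      cand <- seq_along(mods)
      if (params$pam_respects_dendro) {
        same_branch <- which(branches == branches[i] & labels > 0L)
        cand <- which(mods %in% unique(labels[same_branch]))
        if (length(cand) == 0) next
      }
      d_i <- avg_d[i, cand]
      best <- cand[which.min(d_i)]
      if (min(d_i) <= cut_height) labels[i] <- mods[best]
    }
  }
  # dissolve modules that ended below minimum size
  tab <- table(labels[labels > 0L])
  small <- as.integer(names(tab)[tab < min_size])
  labels[labels %in% small] <- 0L

  list(labels = setNames(labels, ids), dendrogram = hc)
}

find_parent <- function(merge, k) {
  hit <- which(merge == k, arr.ind = TRUE)
  if (nrow(hit) == 0) 0L else hit[1, 1]
}

#' Module eigenprotein
#'
#' First principal component of the column-standardized member
#' submatrix. Missing cells are imputed by the protein's median for this
#' computation only; zero-variance members are dropped with a warning.
#' The score is standardized to unit variance and its sign is flipped so
#' that its mean correlation with the members is positive.
#'
#' @param matrix Numeric samples x proteins matrix.
#' @param members Character vector of member protein ids (>= 2).
#' @return List with `score` (named per-sample vector, unit variance) and
#'   `variance_explained` (fraction of member variance on the first
#'   component).
#' @export
module_eigenprotein <- function(matrix, members) {
  if (length(members) < 2) abort("a module needs at least 2 members")
  if (nrow(matrix) < 3) abort("eigenprotein needs at least 3 samples")
  sub <- matrix[, members, drop = FALSE]
  v <- apply(sub, 2, var, na.rm = TRUE)
  drop <- !is.finite(v) | v == 0
  if (any(drop)) {
    warn(sprintf("dropping %d zero-variance member(s) from eigenprotein", sum(drop)))
    sub <- sub[, !drop, drop = FALSE]
  }
  if (ncol(sub) < 2) abort("fewer than 2 usable members for eigenprotein")
  z <- scale_cols(sub)
  for (j in seq_len(ncol(z))) {
    nas <- is.na(z[, j])
    if (any(nas)) z[nas, j] <- median(z[, j], na.rm = TRUE)
  }
  sv <- svd(z, nu = 1, nv = 0)
  score <- sv$u[, 1]
  ve <- sv$d[1]^2 / sum(sv$d^2)
  if (mean(cor(score, z)) < 0) score <- -score
  score <- as.numeric(scale(score))
  list(score = setNames(score, rownames(matrix)), variance_explained = ve)
}

compute_eigenproteins <- function(matrix, labels) {
  mods <- sort(unique(labels[labels > 0L]))
  if (length(mods) == 0) {
    return(list(eigen = NULL, variance_explained = numeric(0)))
  }
  scores <- matrix(NA_real_, nrow(matrix), length(mods),
                   dimnames = list(rownames(matrix), paste0("M", mods)))
  ve <- setNames(numeric(length(mods)), paste0("M", mods))
  for (i in seq_along(mods)) {
    me <- module_eigenprotein(matrix, names(labels)[labels == mods[i]])
    scores[, i] <- me$score
    ve[i] <- me$variance_explained
  }
  list(eigen = scores, variance_explained = ve)
}

#' Merge modules with similar eigenproteins
#'
#' Iteratively merges the closest pair of modules whose eigenprotein
#' dissimilarity `1 - cor(ME_a, ME_b)` is below `merge_cut_height`,
#' recomputing eigenproteins after every merge, until no pair qualifies.
#'
#' @param matrix Numeric samples x proteins matrix.
#' @param labels Named integer label vector (0 = unassigned).
#' @param merge_cut_height Dissimilarity threshold (default 0.07).
#' @return Updated named integer label vector.
#' @export
merge_close_modules <- function(matrix, labels, merge_cut_height = 0.07) {
  repeat {
    mods <- sort(unique(labels[labels > 0L]))
    if (length(mods) < 2) return(labels)
    ep <- compute_eigenproteins(matrix, labels)$eigen
    cc <- cor(ep, use = "pairwise.complete.obs")
    diss <- 1 - cc
    diag(diss) <- Inf
    if (min(diss) >= merge_cut_height) return(labels)
    ij <- which(diss == min(diss), arr.ind = TRUE)[1, ]
    keep <- mods[min(ij)]; gone <- mods[max(ij)]
    labels[labels == gone] <- keep
  }
}

#' kME table: protein-eigenprotein correlations
#'
#' `kme[p, m]` is the biweight midcorrelation (or Pearson) of protein `p`
#' with module eigenprotein `m` over pairwise-complete samples.
#'
#' @param matrix Numeric samples x proteins matrix.
#' @param eigenproteins Samples x modules eigenprotein matrix.
#' @param method `"bicor"` or `"pearson"`.
#' @return Proteins x modules matrix of correlations in \[-1, 1\].
#' @export
kme_table <- function(matrix, eigenproteins, method = c("bicor", "pearson")) {
  method <- match.arg(method)
  bicor_matrix(matrix, eigenproteins, method = method)
}

#' Enforce kME-consistent module membership
#'
#' Iterates to a fixed point (or `max_iter`): a protein whose largest kME
#' belongs to a module other than its own is reassigned to that module; a
#' protein whose own-module kME falls below `min_kme` becomes
#' unassigned; modules dropping below the minimum size are dissolved.
#' Eigenproteins and the kME table are recomputed every iteration.
#'
#' @param matrix Numeric samples x proteins matrix.
#' @param labels Named integer label vector (0 = unassigned).
#' @param params A [network_params()].
#' @param max_iter Iteration cap (default 30).
#' @return List with `labels`, `eigenproteins`, `kme`,
#'   `variance_explained`, `converged`, `n_iter`.
#' @export
enforce_kme_consistency <- function(matrix, labels, params = network_params(),
                                    max_iter = 30L) {
  converged <- FALSE
  iter <- 0L
  ep <- compute_eigenproteins(matrix, labels)
  while (iter < max_iter) {
    iter <- iter + 1L
    if (is.null(ep$eigen)) break
    kme <- kme_table(matrix, ep$eigen, method = params$correlation)
    mods <- as.integer(sub("^M", "", colnames(ep$eigen)))
    new_labels <- labels
    for (i in seq_along(labels)) {
      ks <- kme[i, ]
      if (all(is.na(ks))) next
      best <- which.max(ks)
      if (labels[i] > 0L) {
        own <- match(labels[i], mods)
        if (!is.na(own) && !is.na(ks[own]) && ks[own] < params$min_kme) {
          new_labels[i] <- 0L
        } else if (!is.na(own) && best != own && ks[best] > ks[own]) {
          new_labels[i] <- mods[best]
        }
      } else if (params$pam_stage && ks[best] >= params$min_kme) {
        # unassigned proteins with clear membership rejoin their module
        new_labels[i] <- mods[best]
      }
    }
    tab <- table(new_labels[new_labels > 0L])
    small <- as.integer(names(tab)[tab < params$min_module_size])
    new_labels[new_labels %in% small] <- 0L
    if (identical(new_labels, labels)) {
      converged <- TRUE
      break
    }
    labels <- new_labels
    ep <- compute_eigenproteins(matrix, labels)
  }
  if (!converged && iter >= max_iter) {
    warn("kME consistency did not reach a fixed point within max_iter")
  }
  kme <- if (!is.null(ep$eigen)) {
    kme_table(matrix, ep$eigen, method = params$correlation)
  } else NULL
  list(labels = labels, eigenproteins = ep$eigen, kme = kme,
       variance_explained = ep$variance_explained,
       converged = converged, n_iter = iter)
}

#' Build the full signed co-expression network
#'
#' Runs the complete pipeline on a QC'd, covariate-adjusted abundance
#' matrix: correlation, signed soft-threshold adjacency, topological
#' overlap, average-linkage clustering with the dynamic hybrid cut and
#' PAM stage, eigenproteins, eigenprotein-similarity module merging, and
#' iterative kME-consistency reassignment. Final modules are renumbered
#' by decreasing size (M1 largest).
#'
#' @param matrix Numeric samples x proteins matrix.
#' @param params A [network_params()].
#' @return A `plasma_network` object: `params`, `dendrogram`, `labels`
#'   (named character, `"M1"`... or `"unassigned"`), `eigenproteins`
#'   (samples x modules), `kme` (proteins x modules),
#'   `variance_explained`, `converged`.
#' @examples
#' cohort <- generate_cohort(cohort_config(
#'   n_samples_per_group = c(CTL = 20, RHI = 20),
#'   n_proteins = 100, module_sizes = c(25, 25), seed = 3
#' ))
#' net <- build_network(cohort$matrix)
#' glance(net)
#' @export
build_network <- function(matrix, params = network_params()) {
  assert_matrix(matrix, "matrix")
  C <- bicor_matrix(matrix, method = params$correlation)
  A <- signed_adjacency(C, power = params$power, signed = params$signed)
  tom <- tom_similarity(A, denom = params$tom_denom)
  cut <- cut_modules(1 - tom, params)
  labels <- merge_close_modules(matrix, cut$labels, params$merge_cut_height)
  enforced <- enforce_kme_consistency(matrix, labels, params)
  labels <- relabel_by_size(enforced$labels)
  ep <- compute_eigenproteins(matrix, labels)
  kme <- if (!is.null(ep$eigen)) {
    kme_table(matrix, ep$eigen, method = params$correlation)
  } else NULL
  structure(list(
    params = params, dendrogram = cut$dendrogram,
    labels = module_label_names(labels),
    eigenproteins = ep$eigen, kme = kme,
    variance_explained = ep$variance_explained,
    converged = enforced$converged
  ), class = "plasma_network")
}

# renumber modules by decreasing size: 1 = largest
relabel_by_size <- function(labels) {
  tab <- sort(table(labels[labels > 0L]), decreasing = TRUE)
  map <- setNames(seq_along(tab), names(tab))
  out <- labels
  out[labels > 0L] <- map[as.character(labels[labels > 0L])]
  storage.mode(out) <- "integer"
  out
}

module_label_names <- function(labels) {
  out <- ifelse(labels > 0L, paste0("M", labels), "unassigned")
  setNames(out, names(labels))
}

#' @export
print.plasma_network <- function(x, ...) {
  nmod <- sum(grepl("^M", unique(x$labels)))
  cat(sprintf("<plasma_network> %d proteins, %d modules, %d unassigned\n",
              length(x$labels), nmod, sum(x$labels == "unassigned")))
  invisible(x)
}

#' @describeIn build_network Per-protein module assignment and own-module
#'   kME as a tibble.
#' @param x A `plasma_network`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.plasma_network <- function(x, ...) {
  own_kme <- vapply(seq_along(x$labels), function(i) {
    m <- x$labels[i]
    if (m == "unassigned" || is.null(x$kme)) return(NA_real_)
    x$kme[i, m]
  }, numeric(1))
  tibble(protein_id = names(x$labels), module = unname(x$labels),
         kme = own_kme)
}

#' @describeIn build_network One-row network summary.
#' @exportS3Method generics::glance
glance.plasma_network <- function(x, ...) {
  mods <- grep("^M", unique(x$labels), value = TRUE)
  tibble(
    n_proteins = length(x$labels), n_modules = length(mods),
    n_unassigned = sum(x$labels == "unassigned"),
    median_variance_explained = if (length(x$variance_explained)) {
      median(x$variance_explained)
    } else NA_real_,
    power = x$params$power, converged = x$converged
  )
}

#' @describeIn build_network Bar chart of module sizes shaded by the
#'   variance explained by each eigenprotein.
#' @param object A `plasma_network`.
#' @exportS3Method ggplot2::autoplot
autoplot.plasma_network <- function(object, ...) {
  td <- tidy(object)
  sizes <- td |>
    filter(.data$module != "unassigned") |>
    group_by(.data$module) |>
    summarise(n = n(), .groups = "drop") |>
    mutate(variance_explained =
             unname(object$variance_explained[.data$module]))
  ggplot(sizes, aes(x = stats::reorder(.data$module, -.data$n), y = .data$n,
                    fill = .data$variance_explained)) +
    geom_col() +
    labs(x = "module", y = "proteins",
         fill = "var. explained",
         title = "Co-expression module sizes") +
    theme_minimal()
}
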