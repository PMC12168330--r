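# Shared fixture builders. Everything is generated in code at test time.

named_matrix <- function(data, n, p, prefix_s = "S", prefix_p = "P") {
  matrix(data, n, p, dimnames = list(sprintf("%s%03d", prefix_s, seq_len(n)),
                                     sprintf("%s%03d", prefix_p, seq_len(p))))
}

# brute-force biweight midcorrelation straight from the defining formula
oracle_bicor <- function(x, y) {
  g <- function(v) {
    med <- median(v)
    madv <- median(abs(v - med))
    u <- (v - med) / (9 * madv)
    w <- (1 - u^2)^2 * (abs(u) < 1)
    (v - med) * w
  }
  gx <- g(x); gy <- g(y)
  sum(gx * gy) / sqrt(sum(gx^2) * sum(gy^2))
}

# O(n^3) topological overlap oracle
oracle_tom <- function(A, denom = "mean") {
  n <- nrow(A)
  A <- as.matrix(A); diag(A) <- 0
  k <- rowSums(A)
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + A[i, u] * A[u, j]
    D <- if (denom == "mean") (k[i] + k[j]) / 2 else min(k[i], k[j])
    out[i, j] <- (l + A[i, j]) / (D + 1 - A[i, j])
  }
  out
}

# exhaustive hypergeometric upper tail
oracle_hyper_upper <- function(overlap, n_set, n_universe, n_hits) {
  kk <- overlap:min(n_set, n_hits)
  sum(choose(n_set, kk) * choose(n_universe - n_set, n_hits - kk)) /
    choose(n_universe, n_hits)
}

# exhaustive pairwise AUC with half-credit ties
oracle_auc <- function(scores, y) {
  y <- as.factor(y)
  pos <- scores[y == levels(y)[2]]
  neg <- scores[y == levels(y)[1]]
  tot <- 0
  for (p_s in pos) for (n_s in neg) {
    tot <- tot + (p_s > n_s) + 0.5 * (p_s == n_s)
  }
  tot / (length(pos) * length(neg))
}

quick_cohort <- function(seed = 1, ...) {
  generate_cohort(cohort_config(
    n_samples_per_group = c(CTL = 15, RHI = 15),
    n_proteins = 60, module_sizes = c(15, 15), seed = seed, ...
  ))
}
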