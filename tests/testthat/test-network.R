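test_that("signed adjacency maps correlation endpoints and preserves order", {
  C <- matrix(c(1, 0, -1, 0, 1, 0.5, -1, 0.5, 1), 3, 3)
  A <- signed_adjacency(C, power = 7.5)
  expect_equal(A[1, 3], 0)
  expect_equal(diag(A), rep(1, 3))
  expect_equal(signed_adjacency(matrix(c(1, 0, 0, 1), 2), 7.5)[1, 2], 2^-7.5)
  # strictly increasing map
  cs <- seq(-0.9, 0.9, by = 0.2)
  as_ <- ((1 + cs) / 2)^7.5
  expect_true(all(diff(as_) > 0))
  expect_error(signed_adjacency(matrix(c(1, 0.2, 0.5, 1), 2), 7.5), "symmetric")
})

test_that("TOM matches the cubic brute-force oracle for both denominators", {
  set.seed(21)
  for (rep in 1:8) {
    n <- sample(3:8, 1)
    C <- cor(matrix(rnorm(20 * n), 20, n))
    A <- signed_adjacency(C, power = 3)
    for (dn in c("mean", "min")) {
      expect_equal(unname(tom_similarity(A, dn)), unname(oracle_tom(A, dn)),
                   tolerance = 1e-12)
    }
  }
})

test_that("TOM is symmetric, bounded, and maximal for identical fully-linked nodes", {
  set.seed(5)
  A <- signed_adjacency(cor(matrix(rnorm(200), 20, 10)), 4)
  tom <- tom_similarity(A)
  expect_true(isSymmetric(unname(tom)))
  expect_true(all(tom >= 0 & tom <= 1))
  # two nodes with identical 0/1 neighbourhoods and a_ij = 1 overlap fully
  set.seed(9)
  A2 <- matrix(rbinom(64, 1, 0.5), 8, 8)
  A2 <- 1 * ((A2 + t(A2)) > 0)
  A2[2, ] <- A2[1, ]; A2[, 2] <- A2[, 1]; A2[1, 2] <- A2[2, 1] <- 1
  diag(A2) <- 1
  expect_equal(tom_similarity(A2)[1, 2], 1, tolerance = 1e-12)
  expect_error(tom_similarity(A * 2), "\\[0, 1\\]")
})

test_that("two planted blocks are cut into two pure modules", {
  set.seed(13)
  n <- 50
  f1 <- rnorm(n); f2 <- rnorm(n)
  m <- cbind(
    sapply(1:30, function(i) f1 + rnorm(n, sd = 0.65)),
    sapply(1:30, function(i) f2 + rnorm(n, sd = 0.65))
  )
  dimnames(m) <- list(sprintf("S%02d", 1:n), sprintf("P%02d", 1:60))
  A <- signed_adjacency(bicor_matrix(m), 7.5)
  cut <- cut_modules(1 - tom_similarity(A))
  expect_equal(length(setdiff(unique(cut$labels), 0L)), 2)
  truth <- rep(1:2, each = 30)
  expect_gte(mclust::adjustedRandIndex(truth, cut$labels), 0.95)
})

test_that("tiny inputs yield a single unassigned labeling with warning", {
  D <- 1 - diag(5)
  dimnames(D) <- list(paste0("P", 1:5), paste0("P", 1:5))
  expect_warning(res <- cut_modules(D), "unassigned")
  expect_true(all(res$labels == 0L))
})

test_that("eigenprotein matches the SVD oracle and its sign convention", {
  set.seed(8)
  m <- named_matrix(rnorm(20), 5, 4)
  me <- module_eigenprotein(m, colnames(m))
  z <- scale(m)
  sv <- svd(z)
  oracle <- sv$u[, 1] / sd(sv$u[, 1])
  expect_equal(abs(unname(me$score)), abs(oracle), tolerance = 1e-8)
  expect_equal(me$variance_explained, sv$d[1]^2 / sum(sv$d^2), tolerance = 1e-10)
  expect_gt(mean(cor(me$score, z)), 0)
})

test_that("a module of identical proteins has eigenprotein = the protein, variance 1", {
  set.seed(2)
  v <- rnorm(12)
  m <- named_matrix(rep(v, 3), 12, 3)
  me <- module_eigenprotein(m, colnames(m))
  expect_equal(me$variance_explained, 1)
  expect_equal(unname(me$score), as.numeric(scale(v)), tolerance = 1e-10)
})

test_that("modules driven by one factor merge; distant modules do not", {
  set.seed(4)
  n <- 40
  f <- rnorm(n); g <- rnorm(n)
  m <- cbind(
    sapply(1:12, function(i) f + rnorm(n, sd = 0.3)),
    sapply(1:12, function(i) f + rnorm(n, sd = 0.3)),
    sapply(1:12, function(i) g + rnorm(n, sd = 0.3))
  )
  dimnames(m) <- list(sprintf("S%02d", 1:n), sprintf("P%02d", 1:36))
  labels <- setNames(rep(1:3, each = 12), colnames(m))
  merged <- merge_close_modules(m, labels, 0.07)
  expect_equal(length(unique(merged[1:24])), 1)
  expect_equal(length(unique(merged)), 2)
  # far-apart eigenproteins stay unmerged
  merged2 <- merge_close_modules(m, setNames(rep(c(1, 3), each = 12),
                                             colnames(m)[c(1:12, 25:36)])[colnames(m)[c(1:12, 25:36)]],
                                 0.07)
  expect_equal(length(unique(merged2)), 2)
})

test_that("kME table is bounded with kME = 1 for the eigenprotein itself", {
  co <- quick_cohort(seed = 12)
  net <- build_network(co$matrix)
  expect_true(all(net$kme >= -1 & net$kme <= 1))
  ep <- net$eigenproteins
  m_aug <- cbind(co$matrix, EPCOPY = ep[, 1])
  kme <- kme_table(m_aug, ep)
  expect_equal(kme["EPCOPY", 1], 1, tolerance = 1e-10)
})

test_that("hub proteins with the largest planted loadings have top own-module kME", {
  co <- generate_cohort(cohort_config(
    n_samples_per_group = c(CTL = 40, RHI = 40), n_proteins = 70,
    module_sizes = c(30, 30), module_snr = 3, seed = 18
  ))
  net <- build_network(co$matrix)
  td <- tidy(net)
  tr <- co$truth$proteins
  m1 <- tr[tr$module == 1, ]
  det_mod <- names(sort(table(td$module[match(m1$protein_id, td$protein_id)]),
                        decreasing = TRUE))[1]
  members <- td[td$module == det_mod, ]
  members$loading <- tr$loading[match(members$protein_id, tr$protein_id)]
  expect_gt(cor(members$kme, members$loading, use = "complete.obs"), 0.5)
})

test_that("kME consistency reaches a fixed point and honors its postcondition", {
  co <- quick_cohort(seed = 14)
  net <- build_network(co$matrix)
  labels_int <- setNames(rep(0L, length(net$labels)), names(net$labels))
  assigned <- net$labels != "unassigned"
  labels_int[assigned] <- as.integer(sub("^M", "", net$labels[assigned]))
  again <- enforce_kme_consistency(co$matrix, labels_int, network_params())
  expect_true(again$converged)
  expect_lte(again$n_iter, 2)
  kme <- again$kme
  for (i in seq_along(again$labels)) {
    if (again$labels[i] > 0L) {
      own <- match(paste0("M", again$labels[i]), colnames(kme))
      expect_gte(kme[i, own], network_params()$min_kme)
      expect_equal(kme[i, own], max(kme[i, ]), tolerance = 1e-10)
    }
  }
})

test_that("a protein planted in module A but generated from factor B ends in B", {
  set.seed(3)
  n <- 60
  f1 <- rnorm(n); f2 <- rnorm(n)
  m <- cbind(
    sapply(1:15, function(i) f1 + rnorm(n, sd = 0.5)),
    sapply(1:15, function(i) f2 + rnorm(n, sd = 0.5))
  )
  dimnames(m) <- list(sprintf("S%02d", 1:n), sprintf("P%02d", 1:30))
  labels <- setNames(rep(1:2, each = 15), colnames(m))
  labels["P16"] <- 1L  # generated from f2, mislabeled into module 1
  res <- enforce_kme_consistency(m, labels, network_params())
  expect_equal(unname(res$labels["P16"]), 2L)
})

test_that("pipeline on permuted protein order yields the same partition", {
  co <- quick_cohort(seed = 25)
  net1 <- build_network(co$matrix)
  set.seed(1)
  perm <- sample(ncol(co$matrix))
  net2 <- build_network(co$matrix[, perm])
  l1 <- tidy(net1); l2 <- tidy(net2)
  l2 <- l2[match(l1$protein_id, l2$protein_id), ]
  expect_equal(mclust::adjustedRandIndex(l1$module, l2$module), 1)
})

test_that("noise matrices end mostly unassigned after the kME stage", {
  fr <- vapply(1:6, function(s) {
    set.seed(s)
    m <- named_matrix(rnorm(105 * 100), 105, 100)
    net <- suppressWarnings(build_network(m))
    mean(net$labels != "unassigned")
  }, numeric(1))
  expect_lte(mean(fr), 0.2)
})

test_that("network accessors: tidy covers all proteins, glance counts modules", {
  co <- quick_cohort(seed = 33)
  net <- build_network(co$matrix)
  td <- tidy(net)
  expect_equal(nrow(td), ncol(co$matrix))
  g <- glance(net)
  expect_equal(g$n_modules, length(grep("^M", unique(td$module))))
  expect_s3_class(autoplot(net), "ggplot")
})
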