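# Internal helpers shared across stages.

# Stop with a classed condition so callers/tests can distinguish config errors.
config_error <- function(msg) {
  abort(msg, class = "plasmanet_config_error")
}

assert_matrix <- function(x, arg = "x") {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(sprintf("`%s` must be a numeric matrix (samples x proteins)", arg))
  }
  if (any(is.infinite(x))) {
    abort(sprintf("`%s` contains non-finite (infinite) values", arg))
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    abort(sprintf("`%s` must carry sample rownames and protein colnames", arg))
  }
  if (anyDuplicated(rownames(x))) abort("duplicate sample ids in matrix")
  if (anyDuplicated(colnames(x))) abort("duplicate protein ids in matrix")
  invisible(x)
}

# Deterministic per-stage substreams derived from one user seed: a stage
# re-run in isolation with the same top-level seed reproduces its stream.
stage_seed <- function(seed, stage) {
  offsets <- c(
    simulate = 11L, qc = 23L, network = 37L, da = 47L,
    enrich = 59L, panel = 67L, traits = 79L, boot = 97L
  )
  off <- offsets[[stage]]
  (as.integer(seed) * 101L + off) %% 2147483587L
}

# Column standardisation that tolerates missing values; zero-variance
# columns come back as all-zero rather than NaN.
scale_cols <- function(x) {
  mu <- colMeans(x, na.rm = TRUE)
  sdev <- apply(x, 2, sd, na.rm = TRUE)
  sdev[!is.finite(sdev) | sdev == 0] <- 1
  sweep(sweep(x, 2, mu, "-"), 2, sdev, "/")
}

groups_as_factor <- function(groups) {
  if (is.factor(groups)) droplevels(groups) else factor(groups)
}
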