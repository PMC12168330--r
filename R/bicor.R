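#' Biweight midcorrelation
#'
#' Robust correlation based on Tukey's biweight. Each vector is centred on
#' its median and observations are down-weighted by
#' \eqn{w = (1 - u^2)^2} for \eqn{|u| < 1} (zero otherwise), where
#' \eqn{u = (x - \mathrm{med}(x)) / (9\,\mathrm{MAD}(x))} and MAD is the
#' unscaled median absolute deviation. A vector whose MAD is zero (more
#' than half its values tied) falls back to Pearson weighting for that
#' vector, with a warning.
#'
#' Missing values are dropped pairwise; medians and MADs are computed on
#' the complete pairs actually used.
#'
#' @param x,y Numeric vectors of equal length.
#' @return A correlation in \[-1, 1\].
#' @examples
#' x <- rnorm(30)
#' bicor(x, x + rnorm(30, sd = 0.2))
#' @export
bicor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) {
    abort("bicor needs at least 3 pairwise-complete observations")
  }
  gx <- bicor_transform(x)
  gy <- bicor_transform(y)
  denom <- sqrt(sum(gx^2) * sum(gy^2))
  if (denom == 0) return(NA_real_)
  r <- sum(gx * gy) / denom
  max(-1, min(1, r))
}

# Median-centred, biweight-weighted version of a vector; Pearson (mean
# centring, unit weights) when MAD = 0.
bicor_transform <- function(x) {
  med <- median(x)
  madx <- median(abs(x - med))
  if (madx == 0) {
    warn("zero MAD; falling back to Pearson weighting for one vector",
         .frequency = "once", .frequency_id = "plasmanet_bicor_mad0")
    return(x - mean(x))
  }
  u <- (x - med) / (9 * madx)
  w <- (1 - u^2)^2 * (abs(u) < 1)
  (x - med) * w
}

#' Biweight midcorrelation matrix
#'
#' Correlation matrix between the columns of `x` (optionally against the
#' columns of `y`). With complete data this is exactly [bicor()] applied
#' to every pair. With missing values, per-column medians, MADs and
#' weights are computed on each column's observed values and products are
#' accumulated over pairwise-complete observations - the standard fast
#' approximation to fully pairwise recomputation.
#'
#' @param x Numeric matrix (observations x variables).
#' @param y Optional second matrix with the same number of rows.
#' @param method `"bicor"` (default) or `"pearson"`.
#' @return Matrix of correlations, `ncol(x)` by `ncol(y %||% x)`.
#' @export
bicor_matrix <- function(x, y = NULL, method = c("bicor", "pearson")) {
  method <- match.arg(method)
  x <- as.matrix(x)
  gx <- if (method == "bicor") apply_bicor_transform(x) else center_cols(x)
  if (is.null(y)) gy <- gx else {
    y <- as.matrix(y)
    stopifnot(nrow(y) == nrow(x))
    gy <- if (method == "bicor") apply_bicor_transform(y) else center_cols(y)
  }
  if (!anyNA(gx) && !anyNA(gy)) {
    nx <- sqrt(colSums(gx^2)); ny <- sqrt(colSums(gy^2))
    nx[nx == 0] <- 1; ny[ny == 0] <- 1
    r <- crossprod(sweep(gx, 2, nx, "/"), sweep(gy, 2, ny, "/"))
  } else {
    mx <- !is.na(gx); my <- !is.na(gy)
    gx0 <- gx; gx0[!mx] <- 0
    gy0 <- gy; gy0[!my] <- 0
    num <- crossprod(gx0, gy0)
    # sum over pairwise-complete k of gx_ik^2 (resp. gy_jk^2)
    sx <- crossprod(gx0^2, my * 1)
    sy <- crossprod(mx * 1, gy0^2)
    denom <- sqrt(sx * sy)
    denom[denom == 0] <- NA
    r <- num / denom
  }
  pmin(pmax(r, -1), 1)
}

apply_bicor_transform <- function(x) {
  out <- x
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    obs <- is.finite(v)
    if (sum(obs) >= 2) out[obs, j] <- bicor_transform_quiet(v[obs])
    out[!obs, j] <- NA
  }
  out
}

bicor_transform_quiet <- function(x) {
  med <- median(x)
  madx <- median(abs(x - med))
  if (madx == 0) return(x - mean(x))
  u <- (x - med) / (9 * madx)
  (x - med) * (1 - u^2)^2 * (abs(u) < 1)
}

center_cols <- function(x) {
  sweep(x, 2, colMeans(x, na.rm = TRUE), "-")
}

#' Correlation p-value via the Student-t approximation
#'
#' Two-sided p for a correlation coefficient on `n` pairs using
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on `n - 2` degrees of freedom.
#'
#' @param r Correlation coefficient(s).
#' @param n Number of complete pairs.
#' @return Two-sided p-value(s).
#' @export
cor_p_value <- function(r, n) {
  r <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
}
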