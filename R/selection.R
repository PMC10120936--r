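#' Feature screening by Gaussian distribution overlap
#'
#' Candidate features are screened by modeling their pre- and post-surgery
#' distributions as Gaussians and computing the overlapping coefficient
#' (the integral of the pointwise minimum of the two densities): a small
#' overlap means the feature separates the two states well. Redundancy
#' among retained features is quantified with the bias-corrected distance
#' correlation.
#'
#' @name selection
NULL

#' Overlapping coefficient of two Gaussian fits
#'
#' Fits a Gaussian to each group by sample mean and standard deviation and
#' integrates the pointwise minimum of the two densities. The equal-variance
#' case uses the closed form `2 * pnorm(-|mu1 - mu2| / (2 * sigma))`;
#' otherwise adaptive quadrature over the union of the two mu +/- 8 sigma
#' envelopes is used.
#'
#' @param pre_values,post_values Numeric vectors (>= 3 values each, nonzero
#'   variance).
#' @param feature_name Optional label carried into the result.
#' @return List with `feature_name`, `mu_pre`, `sigma_pre`, `mu_post`,
#'   `sigma_post` and `overlap` in `[0, 1]`.
#' @export
gaussian_overlap <- function(pre_values, post_values, feature_name = NA_character_) {
  stopifnot(length(pre_values) >= 3, length(post_values) >= 3)
  m1 <- mean(pre_values); s1 <- stats::sd(pre_values)
  m2 <- mean(post_values); s2 <- stats::sd(post_values)
  if (!is.finite(s1) || !is.finite(s2) || s1 <= 0 || s2 <= 0)
    stop("degenerate group variance: overlap undefined")
  overlap <- gaussian_overlap_coef(m1, s1, m2, s2)
  list(feature_name = feature_name, mu_pre = m1, sigma_pre = s1,
       mu_post = m2, sigma_post = s2, overlap = overlap)
}

#' @rdname gaussian_overlap
#' @param mu1,sigma1,mu2,sigma2 Parameters of the two Gaussian densities.
#' @export
gaussian_overlap_coef <- function(mu1, sigma1, mu2, sigma2) {
  if (isTRUE(all.equal(sigma1, sigma2))) {
    return(2 * stats::pnorm(-abs(mu1 - mu2) / (2 * sigma1)))
  }
  lo <- min(mu1 - 8 * sigma1, mu2 - 8 * sigma2)
  hi <- max(mu1 + 8 * sigma1, mu2 + 8 * sigma2)
  f <- function(x) pmin(stats::dnorm(x, mu1, sigma1), stats::dnorm(x, mu2, sigma2))
  val <- stats::integrate(f, lo, hi, rel.tol = 1e-10, abs.tol = 1e-10,
                          subdivisions = 500L)$value
  min(max(val, 0), 1)
}

#' Rank features by pre/post Gaussian overlap
#'
#' @param feature_table Data frame with one row per squeal.
#' @param features Character vector of feature column names to screen.
#' @param pre_mask,post_mask Logical vectors selecting the two groups'
#'   rows.
#' @param k Optional count: keep only the `k` most discriminative features.
#' @param max_overlap Optional ceiling: keep only features with overlap at
#'   or below this value.
#' @return Data frame sorted ascending by overlap (most discriminative
#'   first) with columns `feature_name`, `mu_pre`, `sigma_pre`, `mu_post`,
#'   `sigma_post`, `overlap`.
#' @export
rank_features <- function(feature_table, features, pre_mask, post_mask,
                          k = NULL, max_overlap = NULL) {
  if (!any(pre_mask) || !any(post_mask))
    stop("both phases must be present in the feature table")
  res <- lapply(features, function(f) {
    as.data.frame(gaussian_overlap(feature_table[[f]][pre_mask],
                                   feature_table[[f]][post_mask],
                                   feature_name = f))
  })
  out <- do.call(rbind, res)
  out <- out[order(out$overlap), , drop = FALSE]
  if (!is.null(max_overlap)) out <- out[out$overlap <= max_overlap, , drop = FALSE]
  if (!is.null(k)) out <- utils::head(out, k)
  rownames(out) <- NULL
  out
}

# --- distance correlation ---------------------------------------------------

dist_matrix <- function(x) {
  x <- as.numeric(x)
  abs(outer(x, x, "-"))
}

#' Distance correlation between two samples
#'
#' Energy-statistics measure of general (not just linear) dependence. The
#' biased variant double-centers the pairwise distance matrices; the
#' bias-corrected variant (the default, following Szekely and Rizzo)
#' U-centers them, and its value can be slightly negative under
#' independence.
#'
#' @param x,y Equal-length numeric vectors (n >= 4 for the bias-corrected
#'   variant).
#' @param bias_corrected Use the U-centered unbiased estimator
#'   (default TRUE).
#' @return Scalar; in `[0, 1]` for the biased variant.
#' @export
distance_correlation <- function(x, y, bias_corrected = TRUE) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("constant input vector: distance correlation undefined")
  A <- dist_matrix(x)
  B <- dist_matrix(y)
  if (bias_corrected) {
    if (n < 4) stop("bias-corrected variant needs n >= 4")
    Au <- u_center(A)
    Bu <- u_center(B)
    denom <- n * (n - 3)
    dcov2 <- sum(Au * Bu) / denom
    vx <- sum(Au * Au) / denom
    vy <- sum(Bu * Bu) / denom
    if (vx <= 0 || vy <= 0) return(0)
    dcov2 / sqrt(vx * vy)
  } else {
    Ac <- sweep(sweep(A, 1, rowMeans(A)), 2, colMeans(A)) + mean(A)
    Bc <- sweep(sweep(B, 1, rowMeans(B)), 2, colMeans(B)) + mean(B)
    dcov2 <- mean(Ac * Bc)
    vx <- mean(Ac * Ac)
    vy <- mean(Bc * Bc)
    if (vx <= 0 || vy <= 0) return(0)
    sqrt(dcov2 / sqrt(vx * vy))
  }
}

# U-centering per Szekely-Rizzo: row/column means exclude the diagonal,
# the grand mean uses (n-1)(n-2); the diagonal of the result is zero.
u_center <- function(D) {
  n <- nrow(D)
  rm <- rowSums(D) / (n - 2)
  cm <- colSums(D) / (n - 2)
  gm <- sum(D) / ((n - 1) * (n - 2))
  U <- D - outer(rm, rep(1, n)) - outer(rep(1, n), cm) + gm
  diag(U) <- 0
  U
}

#' Pairwise distance-correlation matrix
#'
#' @param feature_table Data frame with one row per squeal.
#' @param features Character vector of >= 2 feature column names.
#' @param bias_corrected Use the U-centered estimator (default TRUE).
#' @return Symmetric matrix with unit diagonal.
#' @export
correlation_matrix <- function(feature_table, features, bias_corrected = TRUE) {
  p <- length(features)
  stopifnot(p >= 2)
  M <- diag(1, p)
  dimnames(M) <- list(features, features)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      v <- distance_correlation(feature_table[[features[i]]],
                                feature_table[[features[j]]],
                                bias_corrected = bias_corrected)
      M[i, j] <- v
      M[j, i] <- v
    }
  }
  M
}
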