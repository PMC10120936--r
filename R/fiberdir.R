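#' Fiber directionality from two-channel microscopy mosaics
#'
#' The collagen (second-harmonic) and elastin (autofluorescence) channels
#' of a lamina-propria mosaic are processed independently through a fixed
#' chain: median filtering (2-pixel radius), intensity normalization, an
#' optional saturated-pixel contrast stretch, Otsu thresholding ignoring
#' black areas, removal of particles below 50 square micrometers, mean
#' filtering (3-pixel radius) and per-pixel local gradient orientation.
#' Pixel orientations are tallied into a directionality histogram over
#' [0, 180) degrees; a normal curve with constant baseline is fitted in two
#' passes to extract alignment (peak position), dispersion (fitted sigma in
#' degrees) and a goodness of fit in [0, 1]. The alignment difference
#' between the two channels measures collagen-elastin co-alignment.
#'
#' Images are numeric matrices; the first index is the image row (y), the
#' second the column (x). Orientations are measured from the image x-axis,
#' counter-clockwise, folded into [0, 180).
#'
#' @name fiberdir
NULL

#' Read a single-channel fiber image
#'
#' @param path TIFF or PNG file (8/16-bit grayscale; multi-channel images
#'   are averaged to one channel).
#' @return Numeric intensity matrix scaled to [0, 1].
#' @export
read_fiber_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format: .", ext)
  )
  if (length(dim(img)) == 3) img <- apply(img, c(1, 2), mean)
  img
}

#' Write a single-channel image
#'
#' @param image Numeric matrix; values are clipped to [0, 1].
#' @param path Output path (.tif/.tiff or .png).
#' @return `path`, invisibly.
#' @export
write_fiber_image <- function(image, path) {
  img <- pmin(pmax(image, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = tiff::writeTIFF(img, path, bits.per.sample = 16L),
    png = png::writePNG(img, path),
    stop("unsupported image format: .", ext)
  )
  invisible(path)
}

#' Median filter (ImageJ radius convention)
#'
#' Per-pixel median over the (2 * width + 1)^2 square neighbourhood,
#' truncated at the image borders.
#'
#' @param image Numeric matrix.
#' @param width Neighbourhood radius in pixels (default 2).
#' @return Filtered matrix, same shape.
#' @export
median_filter <- function(image, width = 2) {
  stopifnot(width >= 1)
  .median_filter_cpp(image, as.integer(width))
}

#' Mean (box) filter
#'
#' Per-pixel mean over the (2 * width + 1)^2 neighbourhood via an integral
#' image; borders use the truncated neighbourhood. Applied to a binary mask
#' this produces the graded edges from which gradient orientations are
#' estimated.
#'
#' @param image Numeric matrix (logical masks are coerced to 0/1).
#' @param width Neighbourhood radius in pixels (default 3).
#' @return Filtered numeric matrix.
#' @export
mean_filter <- function(image, width = 3) {
  stopifnot(width >= 1)
  x <- image * 1
  nr <- nrow(x); nc <- ncol(x)
  # integral image with zero padding row/col
  S <- matrix(0, nr + 1, nc + 1)
  cs <- apply(x, 2, cumsum)               # cumulative down rows
  S[-1, -1] <- t(apply(cs, 1, cumsum))    # then across columns
  i0 <- pmax(seq_len(nr) - width, 1L); i1 <- pmin(seq_len(nr) + width, nr)
  j0 <- pmax(seq_len(nc) - width, 1L); j1 <- pmin(seq_len(nc) + width, nc)
  sums <- S[i1 + 1, j1 + 1, drop = FALSE] - S[i0, j1 + 1, drop = FALSE] -
    S[i1 + 1, j0, drop = FALSE] + S[i0, j0, drop = FALSE]
  area <- outer(i1 - i0 + 1L, j1 - j0 + 1L)
  sums / area
}

#' Normalize intensity across a set of images
#'
#' Each image is linearly rescaled so that a common reference statistic
#' (default: its 99.5th intensity percentile) maps to full scale, making
#' brightness comparable across mosaics acquired at different gains.
#'
#' @param images List of numeric matrices.
#' @param probs Reference percentile in (0, 1] (default 0.995).
#' @param full_scale Target value for the reference percentile (default 1).
#' @return List of rescaled matrices.
#' @export
normalize_intensity <- function(images, probs = 0.995, full_scale = 1) {
  if (!is.list(images)) images <- list(images)
  lapply(images, function(img) {
    ref <- stats::quantile(img, probs, names = FALSE)
    if (ref <= 0) stop("zero dynamic range: cannot normalize")
    img * (full_scale / ref)
  })
}

#' Saturated-pixel contrast stretch
#'
#' Linear stretch mapping the `saturated_fraction/2` and
#' `1 - saturated_fraction/2` intensity quantiles to 0 and full scale and
#' clipping beyond them, so about `saturated_fraction` of the pixels
#' saturate (ImageJ "saturated pixels" semantics). Used to brighten
#' low-intensity control mosaics before thresholding.
#'
#' @param image Numeric matrix.
#' @param saturated_fraction Fraction of pixels driven to the scale limits
#'   (default 0.04).
#' @param full_scale Upper limit of the output scale (default 1).
#' @return Stretched matrix.
#' @export
saturate_stretch <- function(image, saturated_fraction = 0.04, full_scale = 1) {
  stopifnot(saturated_fraction >= 0, saturated_fraction < 1)
  qs <- stats::quantile(image, c(saturated_fraction / 2,
                                 1 - saturated_fraction / 2), names = FALSE)
  if (qs[2] <= qs[1]) stop("constant image: cannot stretch")
  out <- (image - qs[1]) / (qs[2] - qs[1]) * full_scale
  pmin(full_scale, pmax(0, out))
}

#' Otsu threshold mask, ignoring black areas
#'
#' Between-class-variance maximization on a 256-level histogram. With
#' `ignore_black` (the default), zero-intensity pixels -- the empty mosaic
#' background -- are excluded from the histogram so they cannot drag the
#' threshold down; they are always classified as background.
#'
#' @param image Numeric matrix in [0, 1].
#' @param ignore_black Exclude exact zeros from the histogram
#'   (default TRUE).
#' @param levels Histogram resolution (default 256).
#' @return List with `mask` (logical matrix, TRUE = fiber foreground) and
#'   `threshold` (on the intensity scale of the input).
#' @export
otsu_threshold <- function(image, ignore_black = TRUE, levels = 256L) {
  vals <- as.vector(image)
  considered <- if (ignore_black) vals[vals > 0] else vals
  if (length(unique(considered)) < 2)
    stop("degenerate histogram: need >= 2 distinct intensities")
  lo <- min(considered); hi <- max(considered)
  bin <- pmin(levels - 1L, floor((considered - lo) / (hi - lo) * levels))
  h <- tabulate(bin + 1L, nbins = levels)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (seq_len(levels) - 1))
  mu_t <- mu[levels]
  sigma_b2 <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b2[!is.finite(sigma_b2)] <- -Inf
  k <- which.max(sigma_b2)  # threshold between bin k-1 and k
  thr <- lo + k / levels * (hi - lo)
  mask <- image > thr
  if (ignore_black) mask[image <= 0] <- FALSE
  list(mask = mask, threshold = thr)
}

#' Remove small particles from a binary mask
#'
#' Connected components (8-connectivity) with an area below
#' `min_area_um2` square micrometers are deleted; components at exactly
#' the threshold area are retained.
#'
#' @param mask Logical matrix.
#' @param min_area_um2 Area threshold in square micrometers (default 50).
#' @param pixel_size_um Edge length of one pixel in micrometers
#'   (mandatory; areas convert via its square).
#' @return Logical matrix with small components removed.
#' @export
remove_small_particles <- function(mask, min_area_um2 = 50, pixel_size_um) {
  stopifnot(min_area_um2 >= 0, pixel_size_um > 0)
  lab <- .label_components_cpp(mask)
  if (max(lab) == 0L) return(mask)
  areas_px <- tabulate(lab[lab > 0])
  min_px <- min_area_um2 / pixel_size_um^2
  keep <- which(areas_px >= min_px)
  out <- matrix(lab %in% keep & mask, nrow(mask), ncol(mask))
  out
}

#' Per-pixel local gradient orientation
#'
#' The local intensity gradient is estimated either with
#' derivative-of-Gaussian filters (the default: separable Gaussian
#' smoothing in one direction, its derivative in the other, which gives
#' orientation estimates free of the 45-degree quantization that 3x3
#' stencils impose on thin structures) or with the classic Sobel 3x3
#' stencil. Borders are replicated. The structure (fiber) orientation is
#' the gradient direction rotated by 90 degrees and folded into [0, 180).
#' Pixels whose gradient magnitude falls below `magnitude_floor` times the
#' maximum magnitude are returned as `NA` (undefined orientation, e.g.
#' flat background).
#'
#' @param image Numeric matrix (>= 3x3).
#' @param magnitude_floor Relative magnitude cutoff (default 0.05).
#' @param gradient `"gaussian"` (derivative of Gaussian, default) or
#'   `"sobel"`.
#' @param gaussian_sigma Scale of the Gaussian derivative in pixels
#'   (default 1.5; ignored for Sobel).
#' @param coherence_floor Minimum structure-tensor coherence in [0, 1] for
#'   a pixel to receive an orientation (default 0: no gating). Pixels
#'   whose neighbourhood mixes several orientations -- fiber ends,
#'   crossings, mask corners -- have low coherence and are marked
#'   undefined, so only pixels whose neighbouring structure agrees on a
#'   direction vote.
#' @param coherence_sigma Gaussian scale (pixels) for smoothing the
#'   structure-tensor products (default 2).
#' @return List with `orientation_deg` (matrix, degrees in [0, 180) or
#'   `NA`), `magnitude` and (when gated) `coherence`.
#' @export
local_gradient_orientation <- function(image, magnitude_floor = 0.05,
                                       gradient = c("gaussian", "sobel"),
                                       gaussian_sigma = 1.5,
                                       coherence_floor = 0,
                                       coherence_sigma = 2) {
  gradient <- match.arg(gradient)
  stopifnot(nrow(image) >= 3, ncol(image) >= 3)
  if (gradient == "sobel") {
    pad <- function(m) {  # replicate borders
      m <- rbind(m[1, ], m, m[nrow(m), ])
      cbind(m[, 1], m, m[, ncol(m)])
    }
    P <- pad(image)
    nr <- nrow(image); nc <- ncol(image)
    sh <- function(di, dj) P[(2 + di):(nr + 1 + di), (2 + dj):(nc + 1 + dj)]
    # x = column direction, y = row direction
    gx <- (sh(-1, 1) + 2 * sh(0, 1) + sh(1, 1)) -
          (sh(-1, -1) + 2 * sh(0, -1) + sh(1, -1))
    gy <- (sh(1, -1) + 2 * sh(1, 0) + sh(1, 1)) -
          (sh(-1, -1) + 2 * sh(-1, 0) + sh(-1, 1))
  } else {
    s <- gaussian_sigma
    r <- ceiling(3 * s)
    xs <- -r:r
    g <- exp(-xs^2 / (2 * s^2)); g <- g / sum(g)
    dg <- -xs / s^2 * exp(-xs^2 / (2 * s^2))
    gy <- conv_separable(image, dg, g)   # derivative along rows (y)
    gx <- conv_separable(image, g, dg)   # derivative along columns (x)
  }
  mag <- sqrt(gx^2 + gy^2)
  if (diff(range(image)) == 0 || max(mag) == 0)
    stop("flat image: all orientations undefined")
  # structure direction: gradient direction + 90 degrees, folded to [0,180)
  theta <- (atan2(gy, gx) * 180 / pi + 90) %% 180
  theta[mag < magnitude_floor * max(mag)] <- NA_real_
  coh <- NULL
  if (coherence_floor > 0) {
    s <- coherence_sigma
    r <- ceiling(3 * s)
    xs <- -r:r
    g <- exp(-xs^2 / (2 * s^2)); g <- g / sum(g)
    jxx <- conv_separable(gx * gx, g, g)
    jyy <- conv_separable(gy * gy, g, g)
    jxy <- conv_separable(gx * gy, g, g)
    coh <- sqrt((jxx - jyy)^2 + 4 * jxy^2) / (jxx + jyy + 1e-12)
    theta[coh < coherence_floor] <- NA_real_
  }
  list(orientation_deg = theta, magnitude = mag, coherence = coh)
}

# separable convolution with replicated borders; kr acts along rows,
# kc along columns (both odd-length, centered)
conv_separable <- function(m, kr, kc) {
  nr <- nrow(m); nc <- ncol(m)
  rr <- (length(kr) - 1) / 2
  mp <- m[pmin(pmax(seq(1 - rr, nr + rr), 1), nr), , drop = FALSE]
  out <- matrix(0, nr, nc)
  for (k in seq_along(kr))
    out <- out + kr[k] * mp[seq_len(nr) + (k - 1), , drop = FALSE]
  rc <- (length(kc) - 1) / 2
  mp <- out[, pmin(pmax(seq(1 - rc, nc + rc), 1), nc), drop = FALSE]
  out <- matrix(0, nr, nc)
  for (k in seq_along(kc))
    out <- out + kc[k] * mp[, seq_len(nc) + (k - 1), drop = FALSE]
  out
}

#' Directionality histogram
#'
#' Counts of defined pixel orientations in uniform bins over [0, 180).
#'
#' @param orientations Orientation matrix from
#'   [local_gradient_orientation()] (degrees, `NA` = undefined).
#' @param mask Optional logical matrix restricting which pixels vote.
#' @param bin_width_deg Bin width in degrees (default 2).
#' @return List with `bin_centers` (degrees) and `counts`.
#' @export
directionality_histogram <- function(orientations, mask = NULL,
                                     bin_width_deg = 2) {
  th <- if (is.null(mask)) orientations else {
    stopifnot(identical(dim(mask), dim(orientations)))
    orientations[mask]
  }
  th <- th[!is.na(th)]
  if (length(th) == 0) stop("no defined orientations under the mask")
  n_bins <- round(180 / bin_width_deg)
  idx <- pmin(n_bins - 1L, floor(th / bin_width_deg))
  list(bin_centers = (seq_len(n_bins) - 0.5) * bin_width_deg,
       counts = tabulate(idx + 1L, nbins = n_bins))
}

circ_diff180 <- function(a, b) {
  d <- (a - b) %% 180
  ifelse(d > 90, d - 180, d)  # signed difference in [-90, 90)
}

#' Fit a normal curve to a directionality histogram
#'
#' Two-pass procedure: (1) a wrapped Gaussian (periodic images at multiples
#' of 180 degrees) with constant baseline is fitted by nonlinear least
#' squares to locate the peak; (2) the histogram is rotated so the peak
#' sits at 0 degrees (wrap-around preserved) and re-fitted, avoiding
#' artifacts away from the peak. Alignment is the final peak position,
#' dispersion the fitted sigma of the second pass, and GoF the coefficient
#' of determination of the second fit clamped to [0, 1].
#'
#' @param histogram A [directionality_histogram()].
#' @return List with `alignment_deg` in [0, 180), `dispersion_deg`, `gof`,
#'   `amplitude` and `baseline`.
#' @export
fit_normal <- function(histogram) {
  x <- histogram$bin_centers
  y <- as.numeric(histogram$counts)
  if (sum(y > 0) < 5) stop("histogram too sparse for a normal fit")

  # normal curve on the 180-degree periodic domain: the Gaussian is wrapped
  # (images at +/- 180 k) so broad distributions keep their mass
  wrapped_gauss <- function(x, A, mu, sigma, b) {
    v <- 0
    for (k in -2:2) v <- v + exp(-0.5 * ((x - mu + 180 * k) / sigma)^2)
    b + A * v
  }

  fit_pass <- function(xv, mu0, sigma0) {
    # several starting widths guard against a degenerate first guess
    for (s0 in unique(pmin(pmax(c(sigma0, 10, 20, 45), 1), 90))) {
      fit <- tryCatch(
        minpack.lm::nlsLM(
          y ~ wrapped_gauss(x, A, mu, sigma, b),
          data = data.frame(x = xv, y = y),
          start = list(A = max(y) - min(y), mu = mu0, sigma = s0,
                       b = min(y)),
          lower = c(A = 0, mu = mu0 - 90, sigma = 0.5, b = 0),
          upper = c(A = Inf, mu = mu0 + 90, sigma = 120, b = Inf),
          control = minpack.lm::nls.lm.control(maxiter = 200)
        ),
        error = function(e) NULL
      )
      if (!is.null(fit)) return(fit)
    }
    stop("directionality fit did not converge")
  }

  mu0 <- x[which.max(mean_smooth_circular(y, 2))]
  f1 <- fit_pass(x, mu0, 20)
  mu1 <- stats::coef(f1)[["mu"]] %% 180

  # second pass: rotate the histogram so the peak sits at 0 degrees
  x_shift <- circ_diff180(x, mu1)
  f2 <- fit_pass(x_shift, 0, stats::coef(f1)[["sigma"]])
  co <- stats::coef(f2)
  resid <- y - stats::predict(f2)
  ss_res <- sum(resid^2)
  ss_tot <- sum((y - mean(y))^2)
  gof <- if (ss_tot > 0) 1 - ss_res / ss_tot else 0
  list(
    alignment_deg = (mu1 + co[["mu"]]) %% 180,
    dispersion_deg = co[["sigma"]],
    gof = min(1, max(0, gof)),
    amplitude = co[["A"]],
    baseline = co[["b"]]
  )
}

# light circular moving average used only to pick a robust peak start
mean_smooth_circular <- function(y, half_width) {
  n <- length(y)
  idx <- outer(seq_len(n), -half_width:half_width, function(i, d) ((i - 1 + d) %% n) + 1)
  rowMeans(matrix(y[idx], nrow = n))
}

#' Alignment difference between two fits
#'
#' Circular distance between two peak alignments on the 180-degree
#' periodic orientation domain, in [0, 90].
#'
#' @param fit_a,fit_b [fit_normal()] results (or numbers, taken as degrees).
#' @return Degrees in [0, 90].
#' @export
alignment_difference <- function(fit_a, fit_b) {
  a <- if (is.list(fit_a)) fit_a$alignment_deg else fit_a
  b <- if (is.list(fit_b)) fit_b$alignment_deg else fit_b
  d <- abs(a - b) %% 180
  min(d, 180 - d)
}

#' Default image-analysis configuration
#'
#' @param median_width Median filter radius in pixels (default 2).
#' @param mean_width Mean filter radius in pixels (default 3).
#' @param min_area_um2 Particle-removal area threshold (default 50).
#' @param bin_width_deg Histogram bin width (default 2).
#' @param magnitude_floor Gradient magnitude floor (default 0.2).
#' @param gradient Gradient estimator for
#'   [local_gradient_orientation()] (default `"gaussian"`).
#' @param gaussian_sigma Derivative-of-Gaussian scale in pixels.
#' @param coherence_floor Structure-tensor coherence gate (default 0.9;
#'   see [local_gradient_orientation()]).
#' @param coherence_sigma Structure-tensor smoothing scale in pixels.
#' @param saturate Apply the 4% saturated-pixel stretch (default FALSE;
#'   used for low-intensity control mosaics).
#' @param saturated_fraction Stretch fraction when `saturate` is TRUE.
#' @return Named list of settings.
#' @export
fiber_config <- function(median_width = 2, mean_width = 3, min_area_um2 = 50,
                         bin_width_deg = 2, magnitude_floor = 0.2,
                         gradient = "gaussian", gaussian_sigma = 1.5,
                         coherence_floor = 0.9, coherence_sigma = 2,
                         saturate = FALSE, saturated_fraction = 0.04) {
  list(median_width = median_width, mean_width = mean_width,
       min_area_um2 = min_area_um2, bin_width_deg = bin_width_deg,
       magnitude_floor = magnitude_floor, gradient = gradient,
       gaussian_sigma = gaussian_sigma, coherence_floor = coherence_floor,
       coherence_sigma = coherence_sigma, saturate = saturate,
       saturated_fraction = saturated_fraction)
}

#' Directionality analysis of one channel
#'
#' Runs the full preprocessing chain (median filter, normalization,
#' optional stretch, Otsu mask ignoring black, particle removal, mean
#' filter, local gradient orientation) and fits the directionality
#' histogram.
#'
#' @param image Numeric intensity matrix in [0, 1].
#' @param pixel_size_um Micrometers per pixel edge (mandatory).
#' @param roi_mask Optional logical matrix restricting analysis to a
#'   region of interest.
#' @param config A [fiber_config()].
#' @return List with `fit` ([fit_normal()] result), `histogram`, `mask`
#'   (final binary mask) and `n_pixels` (orientation votes).
#' @export
analyze_channel <- function(image, pixel_size_um, roi_mask = NULL,
                            config = fiber_config()) {
  img <- median_filter(image, config$median_width)
  img <- normalize_intensity(img)[[1]]
  if (isTRUE(config$saturate))
    img <- saturate_stretch(img, config$saturated_fraction,
                            full_scale = max(img))
  if (!is.null(roi_mask)) img[!roi_mask] <- 0
  ot <- otsu_threshold(img, ignore_black = TRUE)
  mask <- remove_small_particles(ot$mask, config$min_area_um2, pixel_size_um)
  # particle-cleaned grayscale image: intensities under the mask, black
  # elsewhere; orientations come from its smoothed gradients
  cleaned <- img
  cleaned[!mask] <- 0
  smooth <- mean_filter(cleaned, config$mean_width)
  lgo <- local_gradient_orientation(smooth, config$magnitude_floor,
                                    gradient = config$gradient,
                                    gaussian_sigma = config$gaussian_sigma,
                                    coherence_floor = config$coherence_floor,
                                    coherence_sigma = config$coherence_sigma)
  vote_mask <- mask
  if (!is.null(roi_mask)) vote_mask <- vote_mask & roi_mask
  hist <- directionality_histogram(lgo$orientation_deg, vote_mask,
                                   config$bin_width_deg)
  list(fit = fit_normal(hist), histogram = hist, mask = mask,
       n_pixels = sum(hist$counts))
}

#' Full two-channel fiber analysis of one sample
#'
#' Runs [analyze_channel()] on the collagen and elastin channels and
#' reports the standard parameter triple: collagen-elastin alignment
#' difference, per-channel goodness of fit and per-channel dispersion.
#'
#' @param collagen_image,elastin_image Co-registered numeric matrices.
#' @param pixel_size_um Micrometers per pixel edge.
#' @param roi_mask Optional logical region-of-interest matrix.
#' @param config A [fiber_config()].
#' @param sample_id Identifier carried into the result.
#' @return List with `summary` (one-row data frame: `sample_id`,
#'   `alignment_difference_deg`, `gof_collagen`, `gof_elastin`,
#'   `dispersion_collagen`, `dispersion_elastin`) and the per-channel
#'   analysis results (`collagen`, `elastin`).
#' @export
analyze_sample <- function(collagen_image, elastin_image, pixel_size_um,
                           roi_mask = NULL, config = fiber_config(),
                           sample_id = "sample") {
  stopifnot(identical(dim(collagen_image), dim(elastin_image)))
  res_c <- tryCatch(
    analyze_channel(collagen_image, pixel_size_um, roi_mask, config),
    error = function(e) stop("collagen channel: ", conditionMessage(e)))
  res_e <- tryCatch(
    analyze_channel(elastin_image, pixel_size_um, roi_mask, config),
    error = function(e) stop("elastin channel: ", conditionMessage(e)))
  list(
    summary = data.frame(
      sample_id = sample_id,
      alignment_difference_deg = alignment_difference(res_c$fit, res_e$fit),
      gof_collagen = res_c$fit$gof,
      gof_elastin = res_e$fit$gof,
      dispersion_collagen = res_c$fit$dispersion_deg,
      dispersion_elastin = res_e$fit$dispersion_deg,
      stringsAsFactors = FALSE
    ),
    collagen = res_c,
    elastin = res_e
  )
}
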