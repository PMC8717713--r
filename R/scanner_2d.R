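# 2-D attenuated parallel-beam Radon scanner with Poisson counts and
# ramp-filter FBP reconstruction.
#
# The image domain is the square [-1, 1]^2 discretized to n x n pixels; the
# projection domain is [-sqrt(2), sqrt(2)] x [0, pi) discretized to
# n_dist x n_angle bins (183 x 181 at the reference 128 x 128 resolution).
# Projection is pixel-driven with linear interpolation between the two
# nearest distance bins, scaled so that a projection approximates the line
# integral (pixel area / distance-bin width); the backprojector is the
# exact transpose of the interpolation.

#' 2-D sinogram geometry and system matrix
#'
#' @param n image side (pixels; image = `[-1,1]^2`).
#' @param n_dist number of distance bins over `[-sqrt(2), sqrt(2)]`
#'   (default scales the reference 183-at-128 ratio).
#' @param n_angle number of angles over `[0, pi)` (default scales
#'   181-at-128).
#' @return object of class `sinogram_geometry`: the interpolation matrix
#'   `P` (rays x pixels, sparse), line-integral scale `scale`, bin width
#'   `ds`, angles, distances.
#' @export
sinogram_geometry <- function(n,
                              n_dist = round(183 * n / 128),
                              n_angle = round(181 * n / 128)) {
  n <- as.integer(n)
  px <- 2 / n
  centers <- seq(-1 + px / 2, 1 - px / 2, length.out = n)
  xy <- expand.grid(x = centers, y = centers)   # x fastest: voxel-major
  angles <- seq(0, pi, length.out = n_angle + 1L)[seq_len(n_angle)]
  smax <- sqrt(2)
  ds <- 2 * smax / (n_dist - 1L)
  dists <- seq(-smax, smax, length.out = n_dist)

  n_pix <- n * n
  ii <- vector("list", n_angle); vv <- vector("list", n_angle)
  pix <- seq_len(n_pix)
  for (a in seq_len(n_angle)) {
    s <- xy$x * cos(angles[a]) + xy$y * sin(angles[a])
    t <- (s - dists[1]) / ds
    i0 <- pmax(pmin(floor(t), n_dist - 2), 0)
    w <- t - i0
    row0 <- (a - 1L) * n_dist + as.integer(i0) + 1L
    ii[[a]] <- c(row0, row0 + 1L)
    vv[[a]] <- c(1 - w, w)
  }
  P <- Matrix::sparseMatrix(i = unlist(ii), j = rep(c(pix, pix), n_angle),
                            x = unlist(vv),
                            dims = c(n_dist * n_angle, n_pix))
  structure(list(n = n, n_dist = n_dist, n_angle = n_angle,
                 P = P, Pt = Matrix::t(P),
                 scale = px^2 / ds, ds = ds,
                 angles = angles, dists = dists),
            class = "sinogram_geometry")
}

#' Attenuated parallel-beam projection
#'
#' Line-integral projection of one image (or each column of an N x T
#' matrix), multiplied per ray by `exp(-line integral of the attenuation
#' map)` when an attenuation map is supplied.
#'
#' @param image length-N pixel vector, n x n matrix, or N x T multi-frame
#'   matrix.
#' @param geom a [sinogram_geometry()].
#' @param attenuation optional attenuation coefficient map (same pixel
#'   layout), in units of 1/(image length).
#' @return sinogram vector (n_dist*n_angle) or matrix (rays x T).
#'   The per-ray attenuation factors are available via
#'   [attenuation_factors()].
#' @export
radon_project <- function(image, geom, attenuation = NULL) {
  A <- function(v) as.numeric(geom$P %*% v) * geom$scale
  att <- if (is.null(attenuation)) 1 else
    attenuation_factors(attenuation, geom)
  if (is.matrix(image) && ncol(image) > 1L &&
      nrow(image) == geom$n^2) {
    out <- as.matrix(geom$P %*% image) * geom$scale
    out * att
  } else {
    A(as.numeric(image)) * att
  }
}

#' Per-ray attenuation factors
#'
#' @param attenuation attenuation coefficient map (1/(image length)).
#' @param geom a [sinogram_geometry()].
#' @return vector of factors in (0, 1], one per sinogram bin.
#' @export
attenuation_factors <- function(attenuation, geom) {
  exp(-as.numeric(geom$P %*% as.numeric(attenuation)) * geom$scale)
}

#' Adjoint (backprojection) of the projector
#'
#' Exact transpose of [radon_project()] without attenuation, so that
#' `<A x, y> == <x, radon_backproject(y)>` to rounding error.
#'
#' @param sino sinogram vector (or rays x T matrix).
#' @param geom a [sinogram_geometry()].
#' @return pixel vector (or N x T matrix).
#' @export
radon_backproject <- function(sino, geom) {
  out <- geom$Pt %*% sino * geom$scale
  if (is.matrix(sino)) as.matrix(out) else as.numeric(out)
}

ramp_filter <- function(sino_mat, geom) {
  # sino_mat: n_dist x n_angle; frequency-domain ramp with 2x zero-padding
  n_pad <- 2^ceiling(log2(2 * geom$n_dist))
  freq <- c(0:(n_pad / 2), -(n_pad / 2 - 1):-1) / (n_pad * geom$ds)
  ramp <- abs(freq)
  padded <- rbind(sino_mat, matrix(0, n_pad - geom$n_dist, geom$n_angle))
  filt <- Re(stats::mvfft(stats::mvfft(padded) * ramp, inverse = TRUE)) /
    n_pad
  filt[seq_len(geom$n_dist), , drop = FALSE]
}

gaussian_smooth_2d <- function(img_vec, n, h) {
  if (h <= 0) return(img_vec)
  mult1 <- gaussian_multiplier_1d(n, h)
  mult <- outer(mult1, mult1)
  a <- matrix(img_vec, n, n)
  Re(stats::fft(stats::fft(a) * mult, inverse = TRUE)) / (n * n)
}

#' Filtered backprojection reconstruction
#'
#' Per frame: divide counts by `tau`, frame duration and the per-ray
#' attenuation factors, ramp-filter along distance in the frequency domain
#' (2x zero padding), backproject with the transpose operator and the
#' `pi / n_angle` angular quadrature, then smooth with a common Gaussian
#' bandwidth (pixels) on the periodic image grid.
#'
#' @param counts rays x T count matrix (or vector for one frame).
#' @param geom a [sinogram_geometry()].
#' @param att_factors per-ray attenuation factors (1 = none).
#' @param tau dose scale.
#' @param bandwidth Gaussian bandwidth in pixels.
#' @param frame_durations per-frame durations if counts were accumulated
#'   over frames of unequal length (default 1).
#' @return N x T matrix of reconstructed activity (N = n^2).
#' @export
fbp_reconstruct_2d <- function(counts, geom, att_factors = 1, tau = 1,
                               bandwidth = 0, frame_durations = 1) {
  cnt <- as.matrix(counts)
  T_ <- ncol(cnt)
  dur <- rep_len(frame_durations, T_)
  out <- matrix(0, geom$n^2, T_)
  for (j in seq_len(T_)) {
    y <- cnt[, j] / (tau * dur[j] * att_factors)
    sino <- matrix(y, geom$n_dist, geom$n_angle)
    filt <- ramp_filter(sino, geom)
    bp <- as.numeric(geom$Pt %*% as.numeric(filt)) * (pi / geom$n_angle)
    out[, j] <- as.numeric(gaussian_smooth_2d(bp, geom$n, bandwidth))
  }
  out
}
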