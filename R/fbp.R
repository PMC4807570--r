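#' @title Parallel-beam projection / filtered back projection
#' @name fbp
#' @description Optional stage of the phantom generator: a
#'   forward-projection / FBP round trip over 180 degrees imparts
#'   realistic reconstruction texture to a transverse slice, emulating
#'   the beamline's Fourier-method reconstruction from 512
#'   projections.
NULL

# bilinear sampling of a 2D matrix at fractional (row, col) coords;
# outside the grid reads 0
bilinear <- function(img, yi, xi) {
  d <- dim(img)
  y0 <- floor(yi); x0 <- floor(xi)
  fy <- yi - y0; fx <- xi - x0
  out <- numeric(length(yi))
  gather <- function(y, x) {
    ok <- y >= 1 & y <= d[1] & x >= 1 & x <= d[2]
    v <- numeric(length(y))
    v[ok] <- img[(x[ok] - 1) * d[1] + y[ok]]
    v
  }
  out <- (1 - fy) * (1 - fx) * gather(y0, x0) +
         (1 - fy) * fx * gather(y0, x0 + 1) +
         fy * (1 - fx) * gather(y0 + 1, x0) +
         fy * fx * gather(y0 + 1, x0 + 1)
  out
}

#' Parallel-beam forward projection (Radon transform)
#'
#' Line integrals (in pixel units) of a square slice along the ray
#' direction of each angle; detector spacing equals the pixel spacing.
#'
#' @param slice square numeric matrix.
#' @param angles_deg projection angles in degrees.
#' @return sinogram matrix, `n x length(angles_deg)`.
#' @export
radon_forward <- function(slice, angles_deg) {
  stopifnot(is.matrix(slice), nrow(slice) == ncol(slice))
  n <- nrow(slice)
  ctr <- (n + 1) / 2
  g <- expand.grid(u = seq_len(n) - ctr, s = seq_len(n) - ctr,
                   KEEP.OUT.ATTRS = FALSE)
  sino <- matrix(0, n, length(angles_deg))
  for (a in seq_along(angles_deg)) {
    th <- angles_deg[a] * pi / 180
    src_y <- ctr + cos(th) * g$u - sin(th) * g$s
    src_x <- ctr + sin(th) * g$u + cos(th) * g$s
    rot <- matrix(bilinear(slice, src_y, src_x), n, n)
    sino[, a] <- colSums(rot)
  }
  sino
}

#' Filtered back projection of a sinogram
#'
#' Ram-Lak (ramp) filtering via zero-padded FFT followed by linear
#' back projection; scaling matches the forward convention so a
#' uniform disk reconstructs to its true attenuation value.
#'
#' @param sinogram matrix from [radon_forward()] (`n` detector bins x
#'   angles).
#' @param angles_deg the projection angles used.
#' @return reconstructed `n x n` matrix.
#' @export
fbp_reconstruct <- function(sinogram, angles_deg) {
  n <- nrow(sinogram)
  na <- length(angles_deg)
  stopifnot(ncol(sinogram) == na)
  m <- 2^ceiling(log2(2 * n))
  # Ram-Lak filter from its real-space kernel (correct DC behaviour):
  # h(0) = 1/4, h(k) = -1/(pi k)^2 for odd lags, 0 for even lags
  lag <- c(0:(m / 2), (m / 2 - 1):1)
  h <- numeric(m)
  h[1] <- 0.25
  odd <- lag %% 2 == 1
  h[odd] <- -1 / (pi * lag[odd])^2
  ramp <- 2 * Re(fft(h))
  filt <- matrix(0, n, na)
  for (a in seq_len(na)) {
    p <- c(sinogram[, a], rep(0, m - n))
    filt[, a] <- Re(fft(fft(p) * ramp, inverse = TRUE) / m)[seq_len(n)]
  }
  ctr <- (n + 1) / 2
  g <- expand.grid(y = seq_len(n) - ctr, x = seq_len(n) - ctr,
                   KEEP.OUT.ATTRS = FALSE)
  recon <- numeric(n * n)
  for (a in seq_len(na)) {
    th <- angles_deg[a] * pi / 180
    t <- ctr - sin(th) * g$y + cos(th) * g$x
    t0 <- floor(t); ft <- t - t0
    ok0 <- t0 >= 1 & t0 <= n
    ok1 <- t0 + 1 >= 1 & t0 + 1 <= n
    v <- numeric(length(t))
    v[ok0] <- v[ok0] + (1 - ft[ok0]) * filt[t0[ok0], a]
    v[ok1] <- v[ok1] + ft[ok1] * filt[t0[ok1] + 1, a]
    recon <- recon + v
  }
  matrix(recon * pi / (2 * na), n, n)
}

#' Projection/reconstruction round trip of a slice
#'
#' @param slice square numeric matrix (a transverse phantom slice).
#' @param n_projections number of projections (>= 8), default 512.
#' @param angular_range_deg total rotation, default 180.
#' @return reconstructed slice, same shape.
#' @export
fbp_roundtrip <- function(slice, n_projections = 512,
                          angular_range_deg = 180) {
  if (!is.matrix(slice) || nrow(slice) != ncol(slice))
    stop("'slice' must be a square matrix")
  if (n_projections < 8) stop("'n_projections' must be >= 8")
  angles <- angular_range_deg * (seq_len(n_projections) - 1) / n_projections
  fbp_reconstruct(radon_forward(slice, angles), angles)
}
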