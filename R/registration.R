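#' @title Volumetric registration by phase correlation
#' @name registration
#' @description The two scans of a dual-energy pair are acquired
#'   minutes apart; radiation-induced shrinkage and stage drift shift
#'   the second scan slightly.  Registration aligns the below-edge
#'   volume onto the above-edge frame before subtraction.  Because the
#'   two volumes image the same object with monotonically related
#'   contrast, normalized spectral phase correlation suffices for
#'   translation; a coarse search over a global scale factor is
#'   optionally available.
NULL

#' Rigid translation + per-axis scale transform
#'
#' Describes a motion of image content: a point `p` (voxel
#' coordinates, axis order z,y,x) maps to
#' `scale * (p - center) + center + translation`, with `center` the
#' volume center.  [apply_shrinkage()] moves content forward under the
#' transform; [resample_volume()] undoes it (pulls content back), so
#' `resample_volume(apply_shrinkage(v, t), t)` is the identity up to
#' interpolation.
#'
#' @param translation numeric length-3, voxels (z, y, x).
#' @param scale numeric length-3 (or 1, recycled) per-axis scale,
#'   each in (0.8, 1.2).
#' @return object of class `rigid_scale_transform`.
#' @export
rigid_scale_transform <- function(translation = c(0, 0, 0), scale = 1) {
  translation <- as.numeric(translation)
  scale <- rep(as.numeric(scale), length.out = 3L)
  stopifnot(length(translation) == 3L, all(is.finite(translation)),
            all(scale > 0.8 & scale < 1.2))
  structure(list(translation = translation, scale = scale),
            class = "rigid_scale_transform")
}

#' @export
print.rigid_scale_transform <- function(x, ...) {
  cat(sprintf("<rigid_scale_transform> t = (%s) voxels, s = (%s)\n",
              paste(signif(x$translation, 4), collapse = ", "),
              paste(signif(x$scale, 5), collapse = ", ")))
  invisible(x)
}

#' Invert a transform
#' @param transform a [rigid_scale_transform()].
#' @return the inverse transform.
#' @export
invert_transform <- function(transform) {
  rigid_scale_transform(-transform$translation / transform$scale,
                        1 / transform$scale)
}

# trilinear sampling of vol at fractional voxel coords (vectors zi, yi, xi);
# coordinates outside the grid read as 0
trilinear <- function(vol, zi, yi, xi) {
  d <- dim(vol)
  z0 <- floor(zi); y0 <- floor(yi); x0 <- floor(xi)
  fz <- zi - z0; fy <- yi - y0; fx <- xi - x0
  out <- numeric(length(zi))
  gather <- function(z, y, x) {
    ok <- z >= 1 & z <= d[1] & y >= 1 & y <= d[2] & x >= 1 & x <= d[3]
    v <- numeric(length(z))
    idx <- ((x[ok] - 1) * d[2] + (y[ok] - 1)) * d[1] + z[ok]
    v[ok] <- vol[idx]
    v
  }
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    w <- (if (dz) fz else 1 - fz) * (if (dy) fy else 1 - fy) *
         (if (dx) fx else 1 - fx)
    nz <- w != 0
    if (any(nz))
      out[nz] <- out[nz] +
        w[nz] * gather(z0[nz] + dz, y0[nz] + dy, x0[nz] + dx)
  }
  out
}

transform_coords <- function(transform, d) {
  ctr <- (d + 1) / 2
  zi <- seq_len(d[1]); yi <- seq_len(d[2]); xi <- seq_len(d[3])
  s <- transform$scale; t <- transform$translation
  list(z = s[1] * (zi - ctr[1]) + ctr[1] + t[1],
       y = s[2] * (yi - ctr[2]) + ctr[2] + t[2],
       x = s[3] * (xi - ctr[3]) + ctr[3] + t[3])
}

#' Resample a volume under a transform (pull content back)
#'
#' Samples the input at the transform-mapped coordinates, i.e. undoes
#' the content motion the transform describes:
#' `resample_volume(moving, estimate_transform(moving, fixed))` aligns
#' `moving` onto `fixed`.  Trilinear interpolation; out-of-field
#' voxels are 0.  Exact for integer translations.
#'
#' @param volume numeric 3D array.
#' @param transform a [rigid_scale_transform()].
#' @return resampled array, same shape.
#' @export
resample_volume <- function(volume, transform) {
  stopifnot_volume(volume)
  d <- dim(volume)
  if (all(transform$translation == 0) && all(transform$scale == 1))
    return(volume)
  cc <- transform_coords(transform, d)
  # integer shift, unit scale: exact index shuffle
  if (all(transform$scale == 1) &&
      all(abs(transform$translation - round(transform$translation)) == 0)) {
    t <- as.integer(round(transform$translation))
    out <- array(0, dim = d)
    src <- lapply(1:3, function(a) {
      i <- seq_len(d[a]) + t[a]
      i[i < 1L | i > d[a]] <- NA_integer_
      i
    })
    ok <- lapply(src, function(i) which(!is.na(i)))
    out[ok[[1]], ok[[2]], ok[[3]]] <-
      volume[src[[1]][ok[[1]]], src[[2]][ok[[2]]], src[[3]][ok[[3]]]]
    return(out)
  }
  g <- expand.grid(z = cc$z, y = cc$y, x = cc$x, KEEP.OUT.ATTRS = FALSE)
  array(trilinear(volume, g$z, g$y, g$x), dim = d)
}

# wrap DFT peak index to a signed lag
wrap_lag <- function(i, n) ifelse(i - 1 > n / 2, i - 1 - n, i - 1)

phase_correlate <- function(moving, fixed) {
  d <- dim(fixed)
  Ff <- fft(fixed); Fm <- fft(moving)
  q <- Ff * Conj(Fm)
  q <- q / pmax(Mod(q), .Machine$double.eps)
  r <- Re(fft(q, inverse = TRUE)) / length(q)
  pk <- arrayInd(which.max(r), d)
  # parabolic (3-point) sub-voxel refinement per axis, wrapped
  sub <- numeric(3)
  for (a in 1:3) {
    i <- pk[a]; n <- d[a]
    if (n < 3) next
    im <- if (i == 1) n else i - 1L
    ip <- if (i == n) 1L else i + 1L
    idx <- pk; v0 <- r[matrix(idx, 1)]
    idx[a] <- im; vm <- r[matrix(idx, 1)]
    idx[a] <- ip; vp <- r[matrix(idx, 1)]
    den <- vm - 2 * v0 + vp
    if (is.finite(den) && den < 0) {
      off <- 0.5 * (vm - vp) / den
      if (abs(off) < 1) sub[a] <- off
    }
  }
  lag <- vapply(1:3, function(a) wrap_lag(pk[a], d[a]), numeric(1)) + sub
  -lag  # peak at -t for content moved by +t
}

ncc <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  s <- sqrt(sum(a^2) * sum(b^2))
  if (s == 0) return(0)
  sum(a * b) / s
}

#' Estimate the inter-scan transform
#'
#' Returns the content motion of `moving` relative to `fixed` (the
#' transform that, applied forward to `fixed`, would produce `moving`),
#' so that [resample_volume()] with the estimate aligns `moving` onto
#' `fixed`.  Translation comes from normalized phase correlation with
#' parabolic sub-voxel refinement (exact for integer shifts); when
#' `estimate_scale = TRUE` a coarse search over a global scale factor
#' is wrapped around it, scored by normalized cross-correlation.
#'
#' @param moving,fixed numeric 3D arrays of identical shape with
#'   non-constant content.
#' @param estimate_scale also search a global (isotropic) scale.
#' @param scales candidate scale factors for the coarse search.
#' @return a [rigid_scale_transform()].
#' @export
estimate_transform <- function(moving, fixed, estimate_scale = FALSE,
                               scales = seq(0.99, 1.01, by = 0.0025)) {
  stopifnot_volume(moving); stopifnot_volume(fixed)
  same_shape(moving, fixed)
  if (sd(moving) == 0 || sd(fixed) == 0)
    stop("cannot register constant volumes (no structure)")
  if (!estimate_scale)
    return(rigid_scale_transform(phase_correlate(moving, fixed)))
  best <- NULL; best_score <- -Inf
  for (s in scales) {
    undo <- rigid_scale_transform(c(0, 0, 0), s)
    cand_moving <- resample_volume(moving, undo)
    t <- phase_correlate(cand_moving, fixed)
    aligned <- resample_volume(cand_moving, rigid_scale_transform(t))
    score <- ncc(aligned, fixed)
    if (score > best_score) {
      best_score <- score
      # content motion: scale s then the residual translation, expressed
      # as a single forward transform (t measured after unscaling)
      best <- rigid_scale_transform(t * s, s)
    }
  }
  best
}
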