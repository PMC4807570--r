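#' @title Synthetic dual-energy root phantoms
#' @name phantom
#' @description Generates paired reconstructed volumes (16.5 / 17.2
#'   keV) of a root-like object with known ground truth: organic
#'   tissue whose attenuation decreases slightly with energy, high-Z
#'   mineral inclusions in the vascular core (also decreasing), and
#'   yttria aggregates -- whose attenuation jumps by the K-edge factor
#'   of ~5 -- placed preferentially at the primary/lateral root
#'   junction and along the outer epidermis.  Inter-scan motion is
#'   emulated by a shrinkage transform applied to the below-edge
#'   volume (the second scan), optionally followed by noise.
NULL

#' Nanoparticle size population (TEM statistics)
#'
#' Default parameters are the measured size statistics of the imaged
#' particles: nanotubes of diameter 31.3 +/- 8.6 nm and length 206.3
#' +/- 77.3 nm, irregular particles of size 64.9 +/- 16.9 nm; all
#' normal, truncated at zero.
#'
#' @param diameter_mean,diameter_sd nanotube diameter (nm).
#' @param length_mean,length_sd nanotube length (nm).
#' @param size_mean,size_sd irregular particle size (nm).
#' @param nanotube_fraction mixing fraction of nanotubes in \[0, 1\].
#' @return object of class `particle_population`.
#' @export
particle_population <- function(diameter_mean = 31.3, diameter_sd = 8.6,
                                length_mean = 206.3, length_sd = 77.3,
                                size_mean = 64.9, size_sd = 16.9,
                                nanotube_fraction = 0.5) {
  stopifnot(diameter_mean > 0, length_mean > 0, size_mean > 0,
            diameter_sd >= 0, length_sd >= 0, size_sd >= 0,
            nanotube_fraction >= 0, nanotube_fraction <= 1)
  structure(list(diameter_mean = diameter_mean, diameter_sd = diameter_sd,
                 length_mean = length_mean, length_sd = length_sd,
                 size_mean = size_mean, size_sd = size_sd,
                 nanotube_fraction = nanotube_fraction),
            class = "particle_population")
}

# N(mean, sd) truncated at > 0 by rejection (negligible rejection rate
# for the default populations)
rtruncnorm_pos <- function(n, mean, sd) {
  x <- rnorm(n, mean, sd)
  bad <- which(x <= 0)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= 0]
  }
  x
}

#' Sample particle dimensions
#'
#' @param n number of particles (>= 1).
#' @param pop a [particle_population()].
#' @param seed integer seed (sampling is reproducible and leaves the
#'   caller's RNG state untouched).
#' @param type `"mixed"` draws the particle type per
#'   `nanotube_fraction`; `"nanotube"` / `"irregular"` force one type.
#' @return data.frame with `type` and, per type, `diameter_nm` +
#'   `length_nm` (nanotubes) or `size_nm` (irregular); unused fields
#'   are `NA`.
#' @export
sample_particles <- function(n, pop = particle_population(), seed = NULL,
                             type = c("mixed", "nanotube", "irregular")) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("'n' must be a count >= 1")
  n <- as.integer(n)
  type <- match.arg(type)
  stopifnot(inherits(pop, "particle_population"))
  with_seed(seed, {
    is_tube <- switch(type,
                      mixed = rbinom(n, 1L, pop$nanotube_fraction) == 1L,
                      nanotube = rep(TRUE, n),
                      irregular = rep(FALSE, n))
    out <- data.frame(type = ifelse(is_tube, "nanotube", "irregular"),
                      diameter_nm = NA_real_, length_nm = NA_real_,
                      size_nm = NA_real_)
    nt <- sum(is_tube)
    if (nt) {
      out$diameter_nm[is_tube] <- rtruncnorm_pos(nt, pop$diameter_mean,
                                                 pop$diameter_sd)
      out$length_nm[is_tube] <- rtruncnorm_pos(nt, pop$length_mean,
                                               pop$length_sd)
    }
    if (n - nt)
      out$size_nm[!is_tube] <- rtruncnorm_pos(n - nt, pop$size_mean,
                                              pop$size_sd)
    out
  })
}

#' Phantom specification
#'
#' The defaults describe the imaged scenario at desk scale: a
#' 64x256x256 grid at the acquisition's 0.00319 mm voxels, tissue
#' attenuation inside the published display window, mineral
#' inclusions at/above the high-Z threshold of 12 cm^-1, yttria
#' aggregate concentrations spanning the published display window of
#' 44.12--132.35 mg/cc (the protocol's high-Z exclusion B only admits
#' yttria with above-edge attenuation below 12 cm^-1, i.e.
#' concentrations up to about 136 mg/cc; see the methods vignette),
#' and a small inter-scan shrinkage.
#'
#' @param shape grid `(nz, ny, nx)` in voxels.
#' @param voxel_size_mm isotropic voxel edge (mm).
#' @param tissue_mu range of tissue linear attenuation at 17.2 keV
#'   (cm^-1).
#' @param mineral_mu mineral attenuation at 17.2 keV (cm^-1), >= 12.
#' @param concentration_range yttria aggregate concentrations (mg/cc).
#' @param n_yttria_blobs,n_mineral_blobs inclusion counts (may be 0).
#' @param shrinkage a [rigid_scale_transform()] applied to the
#'   below-edge volume (scale factors in (0.9, 1.1)); identity to
#'   disable.
#' @param noise list: `model` one of `"none"`, `"gaussian"`,
#'   `"poisson"`; `sigma` (cm^-1, gaussian); `I0` and `path_cm`
#'   (poisson).
#' @param seed integer; all phantom randomness flows from it.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 256, 256),
                         voxel_size_mm = 0.00319,
                         tissue_mu = c(0.5, 1.2),
                         mineral_mu = 13,
                         concentration_range = c(44.12, 132.35),
                         n_yttria_blobs = 6,
                         n_mineral_blobs = 3,
                         shrinkage = rigid_scale_transform(
                           c(0.2, 0.5, -0.3), 0.998),
                         noise = list(model = "none", sigma = 0.05,
                                      I0 = 1e5, path_cm = 0.13),
                         seed = 42) {
  stopifnot(length(shape) == 3L, all(shape >= 8),
            voxel_size_mm > 0,
            length(tissue_mu) == 2L, tissue_mu[1] > 0,
            tissue_mu[1] < tissue_mu[2],
            mineral_mu >= 12,
            length(concentration_range) == 2L,
            all(concentration_range > 0),
            concentration_range[1] <= concentration_range[2],
            inherits(shrinkage, "rigid_scale_transform"),
            all(shrinkage$scale > 0.9 & shrinkage$scale < 1.1))
  noise$model <- noise$model %||% "none"
  if (!noise$model %in% c("none", "gaussian", "poisson"))
    stop("unknown noise model: ", noise$model)
  structure(list(shape = as.integer(shape), voxel_size_mm = voxel_size_mm,
                 tissue_mu = tissue_mu, mineral_mu = mineral_mu,
                 concentration_range = concentration_range,
                 n_yttria_blobs = as.integer(n_yttria_blobs),
                 n_mineral_blobs = as.integer(n_mineral_blobs),
                 shrinkage = shrinkage, noise = noise,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Apply inter-scan shrinkage/shift to a volume
#'
#' Moves the content forward under the transform (translation `t`
#' shifts content by `+t` voxels; scale contracts/expands about the
#' volume center).  Linear interpolation, exact for integer
#' translations; out-of-field voxels are 0.
#'
#' @param volume numeric 3D array.
#' @param transform a [rigid_scale_transform()].
#' @return transformed array, same shape.
#' @export
apply_shrinkage <- function(volume, transform)
  resample_volume(volume, invert_transform(transform))

#' Add measurement noise to a reconstructed volume
#'
#' `"gaussian"` adds i.i.d. N(0, sigma) per voxel.  `"poisson"` is a
#' count-statistics proxy: each voxel value is converted to a
#' transmitted intensity over a representative path length,
#' Poisson-resampled at incident intensity `I0`, and converted back
#' to an attenuation coefficient.
#'
#' @param volume numeric 3D array (cm^-1).
#' @param model `"none"`, `"gaussian"` or `"poisson"`.
#' @param seed integer seed; RNG state of the caller is preserved.
#' @param sigma gaussian standard deviation (cm^-1).
#' @param I0 incident photon count per detector element.
#' @param path_cm representative path length (cm) for the poisson
#'   proxy.
#' @return noisy array, same shape.
#' @export
add_noise <- function(volume, model = c("none", "gaussian", "poisson"),
                      seed = NULL, sigma = 0.05, I0 = 1e5,
                      path_cm = 0.13) {
  stopifnot_volume(volume)
  model <- match.arg(model)
  if (model == "none") return(volume)
  with_seed(seed, {
    if (model == "gaussian") {
      if (sigma < 0) stop("'sigma' must be >= 0")
      if (sigma == 0) return(volume)
      volume + array(rnorm(length(volume), 0, sigma), dim(volume))
    } else {
      stopifnot(I0 > 0, path_cm > 0)
      tr <- exp(-pmax(volume, 0) * path_cm)
      counts <- pmax(rpois(length(volume), I0 * tr), 1)
      array(-log(counts / I0) / path_cm, dim(volume))
    }
  })
}

# sphere membership mask indices for a center and radius (clipped)
sphere_voxels <- function(d, center, radius) {
  zr <- max(1, floor(center[1] - radius)):min(d[1], ceiling(center[1] + radius))
  yr <- max(1, floor(center[2] - radius)):min(d[2], ceiling(center[2] + radius))
  xr <- max(1, floor(center[3] - radius)):min(d[3], ceiling(center[3] + radius))
  g <- expand.grid(z = zr, y = yr, x = xr, KEEP.OUT.ATTRS = FALSE)
  keep <- (g$z - center[1])^2 + (g$y - center[2])^2 + (g$x - center[3])^2 <=
    radius^2
  g <- g[keep, , drop = FALSE]
  ((g$x - 1) * d[2] + (g$y - 1)) * d[1] + g$z
}

#' Build a dual-energy root phantom with ground truth
#'
#' Constructs a primary root (epidermis ring, ground tissue, vascular
#' core) with one lateral root branch, drops mineral ellipsoids into
#' the vascular core and yttria aggregates at the root junction and
#' along the outer epidermis, then derives the two energy volumes.
#' On yttria voxels the construction identity
#' `above - below = concentration * delta_mu_rho / 1000` holds exactly
#' before shrinkage/noise; everywhere else the attenuation decreases
#' slightly with energy (so `above <= below`).  Aggregate radii derive
#' from [sample_particles()] sizes scaled by `aggregate_scale`
#' particles across a diameter.
#'
#' @param spec a [phantom_spec()].
#' @param pop a [particle_population()].
#' @param delta_mu_rho K-edge jump used for the construction identity
#'   (cm^2/g), default the source-implied 68.0.
#' @param edge_ratio above/below attenuation ratio of pure yttria;
#'   default the embedded-table ratio (about 5.6).
#' @param aggregate_scale particles across an aggregate diameter.
#' @return object of class `dual_energy_phantom`: `above`, `below`
#'   (numeric arrays, cm^-1), `truth` (masks `yttria`, `mineral`,
#'   `tissue`; `concentration` in mg/cc; `transform`), plus the spec
#'   and constants used.
#' @export
build_root_phantom <- function(spec = phantom_spec(),
                               pop = particle_population(),
                               delta_mu_rho = kedge_delta_mu_rho(),
                               edge_ratio = NULL,
                               aggregate_scale = 500) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.null(edge_ratio)) {
    mr <- mass_attenuation(yttria_compound(), c(16.5, 17.2))
    edge_ratio <- mr[2] / mr[1]
  }
  stopifnot(edge_ratio > 1, delta_mu_rho > 0)
  mu_rho_above_eff <- delta_mu_rho * edge_ratio / (edge_ratio - 1)
  mu_rho_below_eff <- delta_mu_rho / (edge_ratio - 1)
  # weakest admissible aggregate must sit inside the display window
  if (spec$concentration_range[1] / 1000 * mu_rho_above_eff < 0.2)
    stop("configuration error: weakest yttria aggregate falls below the ",
         "0.2 cm^-1 display window; raise 'concentration_range'")

  d <- spec$shape; nz <- d[1]; ny <- d[2]; nx <- d[3]
  cy <- (ny + 1) / 2; cx <- (nx + 1) / 2
  R <- 0.32 * min(ny, nx) / 2
  if (R < 4) stop("grid too small to contain a root cylinder")
  zi <- slice.index(array(0, d), 1)
  yi <- slice.index(array(0, d), 2)
  xi <- slice.index(array(0, d), 3)
  r2 <- (yi - cy)^2 + (xi - cx)^2
  primary <- r2 <= R^2
  zj <- round(nz / 2)
  Rl <- max(3, round(R / 4))
  lateral <- ((zi - zj)^2 + (yi - cy)^2 <= Rl^2) & (xi >= cx)
  root <- primary | lateral
  epidermis <- primary & r2 > (R - 3)^2
  vascular <- r2 <= (R / 3)^2

  # tissue attenuation at 17.2 keV, with a smooth texture so the
  # registration has structure to lock onto
  t_lo <- spec$tissue_mu[1]; t_hi <- spec$tissue_mu[2]
  mu_t <- array(0, d)
  mu_t[root] <- t_lo + 0.25 * (t_hi - t_lo)
  mu_t[lateral] <- t_lo + 0.40 * (t_hi - t_lo)
  mu_t[epidermis] <- t_lo + 0.60 * (t_hi - t_lo)
  mu_t[vascular] <- t_hi
  texture <- 1 + 0.05 * sin(2 * pi * 3 * xi / nx) *
    cos(2 * pi * 2 * yi / ny) * cos(2 * pi * zi / nz)
  mu_t <- mu_t * texture

  # energy dependence of non-edge materials, from the embedded table
  wtr <- compound_spec(c(H = 2, O = 1), 1.0)
  tissue_ratio <- mass_attenuation(wtr, 16.5) / mass_attenuation(wtr, 17.2)
  ca <- compound_spec(c(Ca = 1), 1.55)
  mineral_ratio <- mass_attenuation(ca, 16.5) / mass_attenuation(ca, 17.2)

  with_seed(spec$seed, {
    mineral <- array(FALSE, d)
    if (spec$n_mineral_blobs > 0) {
      for (b in seq_len(spec$n_mineral_blobs)) {
        ctr <- c(runif(1, 4, nz - 3),
                 cy + runif(1, -R / 4, R / 4),
                 cx + runif(1, -R / 4, R / 4))
        mineral[sphere_voxels(d, ctr, runif(1, 2, 4))] <- TRUE
      }
      mineral <- mineral & root
    }

    yttria <- array(FALSE, d)
    conc <- array(0, d)
    if (spec$n_yttria_blobs > 0) {
      sizes <- sample_particles(spec$n_yttria_blobs, pop,
                                type = "irregular")$size_nm
      radii <- pmax(2, sizes * aggregate_scale /
                         (spec$voxel_size_mm * 1e6) / 2)
      n_junction <- ceiling(spec$n_yttria_blobs / 2)
      for (b in seq_len(spec$n_yttria_blobs)) {
        if (b <= n_junction) {      # primary/lateral junction cluster
          ctr <- c(zj + runif(1, -Rl, Rl),
                   cy + runif(1, -Rl, Rl),
                   cx + R + runif(1, -2, 2))
        } else {                    # outer epidermis accumulation
          phi <- runif(1, 0, 2 * pi)
          ctr <- c(runif(1, 4, nz - 3),
                   cy + (R - 1.5) * sin(phi),
                   cx + (R - 1.5) * cos(phi))
        }
        vox <- sphere_voxels(d, ctr, radii[b])
        vox <- vox[!mineral[vox]]
        yttria[vox] <- TRUE
        conc[vox] <- runif(1, spec$concentration_range[1],
                           spec$concentration_range[2])
      }
    }

    above <- mu_t
    below <- mu_t * tissue_ratio
    above[mineral] <- spec$mineral_mu
    below[mineral] <- spec$mineral_mu * mineral_ratio
    # yttria voxels: energy-independent tissue base + edge-jumping term,
    # so the construction identity is exact
    base <- mu_t[yttria]
    above[yttria] <- base + conc[yttria] / 1000 * mu_rho_above_eff
    below[yttria] <- base + conc[yttria] / 1000 * mu_rho_below_eff

    tissue_mask <- root & !mineral & !yttria
    truth <- list(
      yttria = new_mask(array(yttria, d), "truth_yttria"),
      mineral = new_mask(array(mineral, d), "truth_mineral"),
      tissue = new_mask(array(tissue_mask, d), "truth_tissue"),
      concentration = conc,
      transform = spec$shrinkage)

    below <- apply_shrinkage(below, spec$shrinkage)
    if (spec$noise$model != "none") {
      above <- add_noise(above, spec$noise$model, seed = spec$seed + 1L,
                         sigma = spec$noise$sigma %||% 0.05,
                         I0 = spec$noise$I0 %||% 1e5,
                         path_cm = spec$noise$path_cm %||% 0.13)
      below <- add_noise(below, spec$noise$model, seed = spec$seed + 2L,
                         sigma = spec$noise$sigma %||% 0.05,
                         I0 = spec$noise$I0 %||% 1e5,
                         path_cm = spec$noise$path_cm %||% 0.13)
    }
    structure(list(above = above, below = below, truth = truth,
                   spec = spec, delta_mu_rho = delta_mu_rho,
                   edge_ratio = edge_ratio),
              class = "dual_energy_phantom")
  })
}

#' @export
print.dual_energy_phantom <- function(x, ...) {
  cat(sprintf(paste0("<dual_energy_phantom> %s voxels, %d yttria / %d ",
                     "mineral voxels, noise '%s'\n"),
              paste(dim(x$above), collapse = "x"),
              sum(x$truth$yttria), sum(x$truth$mineral),
              x$spec$noise$model))
  invisible(x)
}

#' Write a phantom pair (and truth) to a directory
#'
#' Writes `above.tif` / `below.tif` (float32), truth masks (uint8),
#' the concentration field (float32) and a YAML sidecar with the
#' spec, seed and applied transform.
#'
#' @param phantom a `dual_energy_phantom`.
#' @param dir output directory (created if needed).
#' @param truth also write ground-truth volumes.
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir, truth = TRUE) {
  stopifnot(inherits(phantom, "dual_energy_phantom"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_stack(phantom$above, file.path(dir, "above.tif"))
  write_stack(phantom$below, file.path(dir, "below.tif"))
  if (truth) {
    write_stack(array(as.numeric(phantom$truth$yttria), dim(phantom$above)),
                file.path(dir, "truth_yttria.tif"), "uint8")
    write_stack(array(as.numeric(phantom$truth$mineral), dim(phantom$above)),
                file.path(dir, "truth_mineral.tif"), "uint8")
    write_stack(phantom$truth$concentration,
                file.path(dir, "truth_concentration.tif"))
  }
  sc <- phantom$spec
  sidecar <- list(
    shape = as.integer(sc$shape), voxel_size_mm = sc$voxel_size_mm,
    tissue_mu = sc$tissue_mu, mineral_mu = sc$mineral_mu,
    concentration_range = sc$concentration_range,
    n_yttria_blobs = sc$n_yttria_blobs,
    n_mineral_blobs = sc$n_mineral_blobs,
    shrinkage = list(translation = sc$shrinkage$translation,
                     scale = sc$shrinkage$scale),
    noise = sc$noise, seed = sc$seed,
    delta_mu_rho = phantom$delta_mu_rho, edge_ratio = phantom$edge_ratio)
  yaml::write_yaml(sidecar, file.path(dir, "phantom.yaml"))
  invisible(dir)
}
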