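# Field-free-point MPI image formation.
#
# The operating-field model follows the saturation/selection scheme: a uniform
# background field magnetically saturates all particles except those near the
# field-free point (FFP), where the oppositely directed selection field cancels
# it. The net field magnitude grows linearly with distance from the FFP at the
# selection gradient; voxels whose net field stays inside the linear zone
# (|H| <= half-width) respond, all others are saturated and excluded. Each
# image pixel is the density-weighted relative magnetization (S ~ M_rel)
# aggregated over the linear zone around its FFP position — not a harmonic-
# space reconstruction, which the underlying proportionality does not specify.

#' MPI scan configuration
#'
#' Operating-point and acquisition settings: background field (default 500 Oe,
#' enough to saturate particles with ~100 Oe coercivity), opposed selection
#' field (default -500 Oe) with a +/- 50 Oe linear zone, selection gradient
#' (default 25 Oe/mm = 2.5 T/m, a typical MPI gradient), drive frequency,
#' additive Gaussian noise level, and the seed recorded into every output.
#'
#' @param background_Oe saturating background field, Oe (> 0).
#' @param selection_Oe selection field at the FFP, Oe (opposed to background).
#' @param linear_halfwidth_Oe half-width of the unsaturated linear zone, Oe.
#' @param gradient_Oe_mm selection-field gradient, Oe/mm (> 0).
#' @param drive_frequency_Hz imaging drive frequency, Hz.
#' @param noise_sd additive Gaussian noise, in raw signal units (>= 0).
#' @param seed integer seed for the noise draw.
#' @return object of class `scan_config`.
#' @export
scan_config <- function(background_Oe = 500, selection_Oe = -500,
                        linear_halfwidth_Oe = 50, gradient_Oe_mm = 25,
                        drive_frequency_Hz = 1e4, noise_sd = 0, seed = 1L) {
  stopifnot(background_Oe > 0, linear_halfwidth_Oe > 0, gradient_Oe_mm > 0,
            drive_frequency_Hz >= 0)
  if (noise_sd < 0) stop("configuration error: noise_sd must be non-negative")
  structure(list(
    background_Oe = background_Oe,
    selection_Oe = selection_Oe,
    linear_halfwidth_Oe = linear_halfwidth_Oe,
    gradient_Oe_mm = gradient_Oe_mm,
    drive_frequency_Hz = drive_frequency_Hz,
    noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "scan_config")
}

#' @export
print.scan_config <- function(x, ...) {
  cat(sprintf("<scan_config> H0 = %g Oe, selection %g +/- %g Oe, G = %g Oe/mm,\n",
              x$background_Oe, x$selection_Oe, x$linear_halfwidth_Oe, x$gradient_Oe_mm))
  cat(sprintf("  f = %g Hz, noise_sd = %g, seed = %d\n",
              x$drive_frequency_Hz, x$noise_sd, x$seed))
  invisible(x)
}

#' Net operating field at a position relative to the field-free point
#'
#' Magnitude of background plus selection field: exactly zero at the FFP,
#' growing linearly with distance at the selection gradient, and capped at the
#' background field far away (fully saturating). Positions mirror-symmetric
#' about the FFP see equal magnitudes.
#'
#' @param position_mm position(s), mm: length-3 vector or n x 3 matrix.
#' @param config a `scan_config`.
#' @param ffp_mm field-free-point position, mm (length 3).
#' @return net field magnitude(s), Oe.
#' @export
local_operating_field <- function(position_mm, config, ffp_mm) {
  stopifnot(inherits(config, "scan_config"), length(ffp_mm) == 3L)
  p <- if (is.matrix(position_mm)) position_mm else matrix(position_mm, ncol = 3)
  d <- sqrt(rowSums((p - matrix(ffp_mm, nrow(p), 3, byrow = TRUE))^2))
  pmin(config$gradient_Oe_mm * d, config$background_Oe)
}

#' Per-voxel MPI signal
#'
#' The signal a voxel contributes is its particle density times the relative
#' magnetization at its local operating field: `density * M_rel`, with the
#' plain Langevin `M_rel` for MN particles and the electric-field-shifted
#' `M_rel` for MENs. MN output is independent of the electric field by
#' construction.
#'
#' @param number_density_cm3 particle density, per cm^3 (>= 0).
#' @param H_Oe local operating field, Oe.
#' @param E_Vm local electric field, V/m.
#' @param spec a `particle_spec`.
#' @param mode `"MN"` or `"MEN"`.
#' @return signal (density-weighted relative magnetization).
#' @export
voxel_signal <- function(number_density_cm3, H_Oe, E_Vm, spec,
                         mode = c("MEN", "MN")) {
  mode <- match.arg(mode)
  stopifnot(all(number_density_cm3 >= 0))
  mrel <- if (mode == "MN") langevin_mrel(H_Oe, spec)
          else men_mrel(H_Oe, E_Vm, spec)
  number_density_cm3 * mrel
}

# Kernel of in-zone offsets for FFP aggregation: integer voxel offsets whose
# world distance keeps the net field inside the (broadened) linear zone, with
# the Langevin weight evaluated at that field.
.zone_kernel <- function(voxel_size_mm, config, spec, halfwidth_Oe) {
  r_mm <- halfwidth_Oe / config$gradient_Oe_mm
  nmax <- pmax(floor(r_mm / voxel_size_mm), 0)
  off <- expand.grid(i = -nmax[1]:nmax[1], j = -nmax[2]:nmax[2], k = -nmax[3]:nmax[3])
  dist <- sqrt((off$i * voxel_size_mm[1])^2 + (off$j * voxel_size_mm[2])^2 +
               (off$k * voxel_size_mm[3])^2)
  keep <- config$gradient_Oe_mm * dist <= halfwidth_Oe
  off <- off[keep, , drop = FALSE]
  H <- config$gradient_Oe_mm * dist[keep]
  list(offsets = as.matrix(off), H_Oe = H,
       weight = langevin_mrel(H, spec))
}

# Sum arr over kernel offsets: out(p) = sum_o w_o * arr(p + o), zero padding.
.kernel_sum <- function(arr, offsets, weights) {
  d <- dim(arr)
  out <- array(0, dim = d)
  for (r in seq_len(nrow(offsets))) {
    o <- offsets[r, ]
    src <- mapply(function(n, s) max(1, 1 + s):min(n, n + s), d, o, SIMPLIFY = FALSE)
    dst <- mapply(function(n, s) max(1, 1 - s):min(n, n - s), d, o, SIMPLIFY = FALSE)
    block <- do.call(`[`, c(list(arr), src, list(drop = FALSE)))
    cur <- do.call(`[`, c(list(out), dst, list(drop = FALSE)))
    out <- do.call(`[<-`, c(list(out), dst, list(cur + weights[r] * block)))
  }
  out
}

# run expr with a private RNG stream, restoring the caller's state
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Form an MPI image of the particle-loaded phantom
#'
#' Rasters the field-free point over the phantom grid. At each FFP position
#' the raw signal is the density-weighted relative magnetization summed over
#' the voxels inside the linear zone (all others are saturated and excluded);
#' for MENs the magnetization includes the electric-field shift. The
#' collective dipole field at the mean particle density broadens the effective
#' linear-zone width. Gaussian noise of `noise_sd` is added under the given
#' seed, negative values are clipped, and the image is normalized to its
#' maximum. Deterministic for a fixed seed.
#'
#' @param phantom a `tissue_phantom`.
#' @param density_map 3-D array of particle number density, per cm^3, on the
#'   phantom grid.
#' @param efield an `efield_map` on the phantom grid, or `NULL` for no field
#'   (pre-firing snapshot).
#' @param config a `scan_config`.
#' @param spec a `particle_spec`; for `mode = "MN"` its ME coupling is ignored.
#' @param mode `"MEN"` or `"MN"`.
#' @param seed overrides `config$seed` for the noise draw.
#' @return object of class `mpi_image`: normalized `signal` in `[0, 1]`,
#'   `norm_const` (raw maximum), `mode`, `mrel_baseline` (zone-mean Langevin
#'   magnetization), `h_operating_Oe` (field whose Langevin magnetization
#'   equals that baseline), `config`, `seed`, `config_hash`.
#' @export
mpi_scan <- function(phantom, density_map, efield, config, spec,
                     mode = c("MEN", "MN"), seed = config$seed) {
  mode <- match.arg(mode)
  validate_phantom(phantom)
  stopifnot(inherits(config, "scan_config"), inherits(spec, "particle_spec"))
  d <- dim(phantom$labels)
  if (!identical(dim(density_map), d))
    stop("shape error: density map grid does not match phantom grid")
  E <- if (is.null(efield)) array(0, dim = d) else efield$magnitude
  if (!identical(dim(E), d))
    stop("shape error: electric-field grid does not match phantom grid")
  if (any(density_map < 0)) stop("negative particle density")

  eff_spec <- if (mode == "MN") as_mn(spec) else spec
  dens_pos <- density_map[density_map > 0]
  mean_density <- if (length(dens_pos)) mean(dens_pos) else 0
  halfwidth_eff <- config$linear_halfwidth_Oe +
    dipole_mean_field(mean_density, eff_spec)
  kern <- .zone_kernel(phantom$voxel_size_mm, config, eff_spec, halfwidth_eff)

  raw <- .kernel_sum(density_map, kern$offsets, kern$weight)
  if (eff_spec$alpha_G_cm_V > 0) {
    shift <- density_map *
      (me_magnetization_shift(E, eff_spec) / eff_spec$Ms_emu_cc)
    raw <- raw + .kernel_sum(shift, kern$offsets, rep(1, nrow(kern$offsets)))
  }
  if (config$noise_sd > 0)
    raw <- raw + .with_seed(seed, array(stats::rnorm(length(raw), 0, config$noise_sd), dim = d))
  raw[raw < 0] <- 0
  norm_const <- max(raw)
  signal <- if (norm_const > 0) raw / norm_const else raw

  mrel_baseline <- mean(kern$weight)
  h_op <- .invert_langevin(mrel_baseline, eff_spec)
  structure(list(
    signal = signal, norm_const = norm_const, mode = mode,
    mrel_baseline = mrel_baseline, h_operating_Oe = h_op,
    config = config, seed = as.integer(seed),
    config_hash = config_hash(config)
  ), class = "mpi_image")
}

# field whose Langevin magnetization equals the target (0 <= target < 1)
.invert_langevin <- function(target, spec) {
  if (target <= 0) return(0)
  f <- function(H) langevin_mrel(H, spec) - target
  hi <- 1
  while (f(hi) < 0 && hi < 1e9) hi <- hi * 10
  stats::uniroot(f, c(0, hi), tol = 1e-10)$root
}

#' @export
print.mpi_image <- function(x, ...) {
  d <- dim(x$signal)
  cat(sprintf("<mpi_image> %s mode, %d x %d x %d, norm const %.4g, seed %d\n",
              x$mode, d[1], d[2], d[3], x$norm_const, x$seed))
  cat(sprintf("  zone-mean M_rel baseline %.4g (H_op = %.3g Oe)\n",
              x$mrel_baseline, x$h_operating_Oe))
  invisible(x)
}

#' Region of interest around a firing spot
#'
#' Voxel mask of the firing source sphere dilated by a margin (default one
#' voxel): the region used for firing-contrast metrics.
#'
#' @param phantom a `tissue_phantom`.
#' @param firing a `firing_source`.
#' @param dilate_voxels dilation of the sphere radius, in voxels.
#' @return logical 3-D array.
#' @export
firing_roi_mask <- function(phantom, firing, dilate_voxels = 1) {
  radius <- firing$diameter_mm / 2 +
    dilate_voxels * max(phantom$voxel_size_mm)
  .sphere_mask(phantom, firing$center_mm, radius) & phantom$labels > 0L
}

#' Firing-contrast ratio between two images
#'
#' Mean raw (de-normalized) signal in the ROI of the post-firing image divided
#' by the same mean in the pre-firing image.
#'
#' @param img_post,img_pre `mpi_image`s on the same grid.
#' @param roi logical ROI mask.
#' @return scalar ratio.
#' @export
roi_contrast <- function(img_post, img_pre, roi) {
  stopifnot(inherits(img_post, "mpi_image"), inherits(img_pre, "mpi_image"),
            identical(dim(img_post$signal), dim(img_pre$signal)))
  post <- mean(img_post$signal[roi] * img_post$norm_const)
  pre <- mean(img_pre$signal[roi] * img_pre$norm_const)
  post / pre
}

#' Signal and resolution versus particle density
#'
#' For each density, images a point-like density impulse and reports the peak
#' signal and the spatial resolution. The point response of the zone-sum model
#' is spherically symmetric, so it is evaluated on a fine radial profile of
#' FFP offsets built from the same operating-field and voxel-signal
#' primitives: `s(r) = density * M_rel(G r)` for `r` inside the (broadened)
#' linear zone and zero outside. The collective dipole field at that density
#' widens the zone, so resolution degrades at high densities while the peak
#' signal keeps growing — the density/resolution trade-off. Resolution is
#' quoted as the full width of the half-maximum region of the response (its
#' outer diameter; the response is shell-like under the signal-follows-
#' magnetization model).
#'
#' @param densities_cm3 ascending vector of particle densities, per cm^3.
#' @param spec a `particle_spec`.
#' @param config a `scan_config`.
#' @param dr_mm radial step of the profile, mm.
#' @return `data.frame` with columns `density_cm3`, `peak_signal`, `fwhm_mm`
#'   (NA for zero density), `dipole_field_Oe`.
#' @export
psf_density_study <- function(densities_cm3, spec, config, dr_mm = 0.005) {
  if (!length(densities_cm3)) stop("configuration error: empty density list")
  if (is.unsorted(densities_cm3)) stop("densities must be sorted ascending")
  stopifnot(inherits(spec, "particle_spec"), inherits(config, "scan_config"))
  rows <- lapply(densities_cm3, function(dens) {
    if (dens == 0)
      return(data.frame(density_cm3 = 0, peak_signal = 0, fwhm_mm = NA_real_,
                        dipole_field_Oe = 0))
    hdip <- dipole_mean_field(dens, spec)
    hw <- config$linear_halfwidth_Oe + hdip
    r_zone <- hw / config$gradient_Oe_mm
    r <- seq(0, r_zone, by = dr_mm)
    ffp <- cbind(r, 0, 0)
    H <- local_operating_field(ffp, config, c(0, 0, 0))
    s <- voxel_signal(dens, H, 0, spec, mode = spec$mode)
    s[H > hw] <- 0  # saturated: outside the broadened zone
    peak <- max(s)
    above <- which(s >= peak / 2)
    fwhm <- 2 * r[max(above)]  # outer diameter of the half-max region
    data.frame(density_cm3 = dens, peak_signal = peak, fwhm_mm = fwhm,
               dipole_field_Oe = hdip)
  })
  do.call(rbind, rows)
}
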