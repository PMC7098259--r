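# Nanoparticle magnetics: Langevin superparamagnetism, magnetoelectric shift,
# hysteresis dissipation and dipole-interaction broadening.
#
# Internal unit system is CGS-Gaussian for all magnetic quantities (Oe, emu/cc,
# erg), because the source literature for magnetoelectric nanoparticles quotes
# them that way; electric fields are SI (V/m) and are converted to V/cm only
# inside the magnetoelectric coupling (1 G cm/V * 1 V/cm = 1 G = 1 emu/cc).

#' Boltzmann constant in CGS units (erg/K)
#' @keywords internal
.kB_erg_K <- 1.38065e-16

#' Describe one nanoparticle species
#'
#' Constructs a `particle_spec`, the physical description of a single
#' nanoparticle species used throughout the simulator. Two species matter in
#' practice: magnetoelectric nanoparticles (MENs), whose magnetization shifts
#' linearly with the local electric field through the magnetoelectric (ME)
#' coefficient `alpha`, and conventional magnetic nanoparticles (MNs, e.g.
#' SPIONs) for which `alpha = 0`. The particle mode is therefore derived from
#' `alpha`: a spec is an MN exactly when `alpha == 0`.
#'
#' @param diameter_nm particle diameter in nm (spheres assumed).
#' @param Ms_emu_cc saturation magnetization in emu per cm^3 of particle
#'   material. Give either this or `Ms_emu_g`.
#' @param alpha_G_cm_V isotropic ME coefficient in G cm/V; `0` for MNs.
#' @param Hc_Oe coercivity in Oe; used only for hysteresis-loss accounting
#'   (imaging curves are computed without hysteresis).
#' @param mass_density_g_cc material mass density in g/cm^3.
#' @param temperature_K absolute temperature in K.
#' @param Ms_emu_g alternative unit for the saturation magnetization
#'   (emu per gram); converted with `mass_density_g_cc`.
#' @return An object of class `particle_spec` with fields `diameter_nm`,
#'   `Ms_emu_cc`, `alpha_G_cm_V`, `Hc_Oe`, `mass_density_g_cc`,
#'   `temperature_K` and derived `mode` (`"MEN"` or `"MN"`).
#' @seealso [men_spec()], [mn_spec()], [as_mn()]
#' @examples
#' men <- men_spec()
#' particle_volume_and_moment(men)
#' @export
particle_spec <- function(diameter_nm = 50, Ms_emu_cc = NULL,
                          alpha_G_cm_V = 0, Hc_Oe = 100,
                          mass_density_g_cc = 5, temperature_K = 300,
                          Ms_emu_g = NULL) {
  if (is.null(Ms_emu_cc) && is.null(Ms_emu_g))
    stop("give the saturation magnetization as Ms_emu_cc or Ms_emu_g")
  if (!is.null(Ms_emu_cc) && !is.null(Ms_emu_g))
    stop("give only one of Ms_emu_cc and Ms_emu_g")
  if (is.null(Ms_emu_cc)) Ms_emu_cc <- Ms_emu_g * mass_density_g_cc
  stopifnot(diameter_nm > 0, Ms_emu_cc >= 0, alpha_G_cm_V >= 0,
            Hc_Oe >= 0, mass_density_g_cc > 0, temperature_K > 0)
  structure(list(
    diameter_nm = diameter_nm,
    Ms_emu_cc = Ms_emu_cc,
    alpha_G_cm_V = alpha_G_cm_V,
    Hc_Oe = Hc_Oe,
    mass_density_g_cc = mass_density_g_cc,
    temperature_K = temperature_K,
    mode = if (alpha_G_cm_V > 0) "MEN" else "MN"
  ), class = "particle_spec")
}

#' Default magnetoelectric nanoparticle (50 nm BaTiO3-CoFe2O4 core-shell class)
#' @param ... overrides passed to [particle_spec()].
#' @return a `particle_spec` with `mode == "MEN"`.
#' @export
men_spec <- function(...) {
  args <- utils::modifyList(
    list(diameter_nm = 50, Ms_emu_cc = 10, alpha_G_cm_V = 0.1,
         Hc_Oe = 100, mass_density_g_cc = 5, temperature_K = 300),
    list(...))
  do.call(particle_spec, args)
}

#' Default conventional magnetic nanoparticle (SPION-like, alpha = 0)
#' @param ... overrides passed to [particle_spec()].
#' @return a `particle_spec` with `mode == "MN"`.
#' @export
mn_spec <- function(...) {
  args <- utils::modifyList(
    list(diameter_nm = 50, Ms_emu_cc = 100, alpha_G_cm_V = 0,
         Hc_Oe = 100, mass_density_g_cc = 5, temperature_K = 300),
    list(...))
  do.call(particle_spec, args)
}

#' Magnetically equivalent MN for a given MEN
#'
#' Returns a copy of `spec` with the ME coupling switched off. This is the
#' "equivalent MN" used as the structural reference in demodulation: identical
#' size, saturation magnetization and temperature, so the purely magnetic part
#' of its image matches the MEN image exactly and divides out.
#'
#' @param spec a `particle_spec`.
#' @return a `particle_spec` with `alpha_G_cm_V = 0`, `mode == "MN"`.
#' @export
as_mn <- function(spec) {
  stopifnot(inherits(spec, "particle_spec"))
  spec$alpha_G_cm_V <- 0
  spec$mode <- "MN"
  spec
}

#' @export
print.particle_spec <- function(x, ...) {
  cat(sprintf("<particle_spec> %s: d = %g nm, Ms = %g emu/cc, alpha = %g G cm/V,\n",
              x$mode, x$diameter_nm, x$Ms_emu_cc, x$alpha_G_cm_V))
  cat(sprintf("  Hc = %g Oe, density = %g g/cc, T = %g K\n",
              x$Hc_Oe, x$mass_density_g_cc, x$temperature_K))
  invisible(x)
}

#' Particle volume and magnetic moment
#'
#' Sphere volume `V = pi d^3 / 6` (cm^3) and saturation moment `m = Ms * V`
#' (emu), the product of saturation magnetization and volume.
#'
#' @param spec a `particle_spec`.
#' @return list with `V_cm3` and `m_emu`.
#' @examples
#' particle_volume_and_moment(men_spec())  # V ~ 6.545e-17 cm^3, m ~ 6.545e-16 emu
#' @export
particle_volume_and_moment <- function(spec) {
  stopifnot(inherits(spec, "particle_spec"))
  d_cm <- spec$diameter_nm * 1e-7
  V <- pi * d_cm^3 / 6
  list(V_cm3 = V, m_emu = spec$Ms_emu_cc * V)
}

# Numerically stable Langevin function L(x) = coth(x) - 1/x.
# Series for small |x| avoids catastrophic cancellation.
.langevin <- function(x) {
  out <- numeric(length(x))
  small <- abs(x) < 1e-3
  xs <- x[small]
  out[small] <- xs / 3 - xs^3 / 45
  xl <- x[!small]
  out[!small] <- 1 / tanh(xl) - 1 / xl
  out
}

#' Relative magnetization of a thermal superparamagnetic moment
#'
#' Mean-field (paramagnetic-gas) relative magnetization
#' `M_rel = M/Ms = L(xi)` with the Langevin function `L(xi) = coth(xi) - 1/xi`
#' and Langevin parameter `xi = m H / (kB T)`, where `m = Ms V` is the particle
#' moment. Odd in `H`, bounded by (-1, 1) for finite fields, `0` exactly at
#' `H = 0`. No hysteresis enters these curves.
#'
#' @param H_Oe applied field, Oe (vectorized).
#' @param spec a `particle_spec`.
#' @return `M_rel` in `[-1, 1]`, same length as `H_Oe`.
#' @examples
#' langevin_mrel(500, men_spec())  # ~0.873 at 500 Oe, 300 K
#' @export
langevin_mrel <- function(H_Oe, spec) {
  stopifnot(inherits(spec, "particle_spec"), all(is.finite(H_Oe)))
  m <- particle_volume_and_moment(spec)$m_emu
  if (m == 0) return(numeric(length(H_Oe)))
  xi <- m * H_Oe / (.kB_erg_K * spec$temperature_K)
  .langevin(xi)
}

#' Magnetoelectric magnetization shift
#'
#' The induced magnetization change of a magnetoelectric particle is linear in
#' the local electric field: `dM = alpha * E`, with `alpha` in G cm/V and `E`
#' converted from V/m to V/cm (factor 1/100); 1 G of magnetization is 1 emu/cc.
#'
#' @param E_Vm local electric field, V/m (vectorized; sign preserved).
#' @param spec a `particle_spec`.
#' @return `dM` in emu/cc.
#' @seealso [me_moment_shift()] for the per-particle moment form `dm = dM * V`.
#' @examples
#' me_magnetization_shift(100, men_spec())  # 0.1 emu/cc at 1 V/cm
#' @export
me_magnetization_shift <- function(E_Vm, spec) {
  stopifnot(inherits(spec, "particle_spec"), all(is.finite(E_Vm)))
  spec$alpha_G_cm_V * (E_Vm / 100)
}

#' Magnetoelectric moment shift per particle
#'
#' Per-particle form of the ME coupling, `dm = alpha * E * V` (emu), identical
#' to `me_magnetization_shift(E, spec) * V` by construction.
#'
#' @inheritParams me_magnetization_shift
#' @return `dm` in emu.
#' @export
me_moment_shift <- function(E_Vm, spec) {
  V <- particle_volume_and_moment(spec)$V_cm3
  me_magnetization_shift(E_Vm, spec) * V
}

#' Relative magnetization of a MEN in a magnetic and electric field
#'
#' Adds the ME magnetization shift to the Langevin term and clips to the
#' physical range: `M_rel = clip(L(xi) + dM(E)/Ms, -1, 1)`. Reduces exactly to
#' [langevin_mrel()] when `alpha = 0` or `E = 0`.
#'
#' @param H_Oe applied field, Oe.
#' @param E_Vm local electric field, V/m.
#' @param spec a `particle_spec` (needs `Ms > 0` whenever `E != 0`).
#' @return `M_rel` in `[-1, 1]`; `H_Oe` and `E_Vm` are recycled to a common
#'   length.
#' @examples
#' men_mrel(0, 100, men_spec())  # 0.01: 0.1 emu/cc shift over Ms = 10 emu/cc
#' @export
men_mrel <- function(H_Oe, E_Vm, spec) {
  stopifnot(inherits(spec, "particle_spec"))
  if (spec$Ms_emu_cc == 0 && any(E_Vm != 0))
    stop("Ms = 0 with a nonzero electric field: relative ME shift undefined")
  base <- langevin_mrel(H_Oe, spec)
  if (spec$Ms_emu_cc == 0) return(base)
  shift <- me_magnetization_shift(E_Vm, spec) / spec$Ms_emu_cc
  pmin(pmax(base + shift, -1), 1)
}

#' Hysteresis energy dissipated per field cycle
#'
#' Order-of-magnitude estimator of the heat released by a particle ensemble in
#' one full M-H cycle, from the hysteresis-loop area per unit material volume:
#' `4 Hc Ms` erg/cc for a rectangular loop (default) or `pi Hc Ms` erg/cc for
#' an elliptical loop. The ensemble volume is `total_mass / mass_density`.
#'
#' @param spec a `particle_spec`.
#' @param total_mass_g administered particle mass, g.
#' @param loop_model `"rectangular"` or `"elliptical"`.
#' @return energy per cycle in J (1 erg = 1e-7 J).
#' @examples
#' # 2.5 g at 5 g/cc, Ms = 10 emu/cc, Hc = 100 Oe -> 2e-4 J per cycle
#' hysteresis_energy_per_cycle(men_spec(), 2.5)
#' @export
hysteresis_energy_per_cycle <- function(spec, total_mass_g,
                                        loop_model = c("rectangular", "elliptical")) {
  stopifnot(inherits(spec, "particle_spec"), total_mass_g >= 0)
  loop_model <- match.arg(loop_model)
  V_tot_cc <- total_mass_g / spec$mass_density_g_cc
  area_factor <- switch(loop_model, rectangular = 4, elliptical = pi)
  erg <- area_factor * spec$Hc_Oe * spec$Ms_emu_cc * V_tot_cc
  erg * 1e-7
}

#' Mean dipole-interaction field at a given particle density
#'
#' Nearest-neighbour axial dipole field `2 m / r^3` (Oe, Gaussian units) at the
#' mean inter-particle spacing `r = density^(-1/3)`. Used as a scalar
#' field-broadening scale for the collective dipole-dipole interaction at high
#' densities; monotone non-decreasing in density. Spacings below 5 nm are
#' outside the classical-dipole regime and raise a warning.
#'
#' @param number_density_cm3 particles per cm^3 (vectorized, >= 0).
#' @param spec a `particle_spec`.
#' @return dipole field in Oe.
#' @examples
#' dipole_mean_field(1e12, men_spec())  # ~1.31e-3 Oe at 1 um spacing
#' @export
dipole_mean_field <- function(number_density_cm3, spec) {
  stopifnot(inherits(spec, "particle_spec"), all(number_density_cm3 >= 0))
  m <- particle_volume_and_moment(spec)$m_emu
  # 2 m / r^3 with r = n^(-1/3) collapses to 2 m n
  H <- 2 * m * number_density_cm3
  spacing_cm <- ifelse(number_density_cm3 > 0, number_density_cm3^(-1 / 3), Inf)
  if (any(spacing_cm < 5e-7))
    warning("mean particle spacing below 5 nm: classical dipole model invalid ",
            "(quantum-mechanical interaction regime)")
  H
}

#' Field-dependent magnetization curve families
#'
#' Tabulates `M_rel(H; E)` for a particle over a grid of magnetic fields and
#' (for MENs) electric fields, in long format suitable for CSV export or
#' plotting — the field-response curve family of the forward model.
#'
#' @param spec a `particle_spec`.
#' @param H_Oe vector of fields, Oe.
#' @param E_Vm vector of electric fields, V/m (one curve per value).
#' @return `data.frame` with columns `H_Oe`, `E_Vm`, `M_rel`.
#' @export
mrel_curves <- function(spec, H_Oe = seq(-500, 500, by = 5), E_Vm = 0) {
  stopifnot(inherits(spec, "particle_spec"))
  grid <- expand.grid(H_Oe = H_Oe, E_Vm = E_Vm)
  grid$M_rel <- men_mrel(grid$H_Oe, grid$E_Vm, spec)
  grid
}
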