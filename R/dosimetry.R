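# Dose-to-particle bookkeeping and thermal-safety accounting.

#' Molar mass of one BaTiO3 + CoFe2O4 formula-unit pair (g/mol)
#'
#' Convention for the core-shell composition: one barium-titanate unit
#' (233.19 g/mol) plus one cobalt-ferrite unit (234.62 g/mol).
#'
#' @export
MOLAR_MASS_BTO_CFO <- 467.8

#' Administered dose to particle mass
#'
#' `mass (g) = dose (mmol/kg) * bodyweight (kg) * molar mass (g/mol) / 1000`.
#' With the default BaTiO3-CoFe2O4 formula-unit molar mass, the reference dose
#' of 0.1 mmol/kg for a 50 kg subject gives about 2.3 g.
#'
#' @param dose_mmol_kg dose, mmol per kg bodyweight (>= 0).
#' @param bodyweight_kg subject weight, kg (>= 0).
#' @param molar_mass_g_mol particle molar mass, g/mol.
#' @return mass in g.
#' @examples
#' dose_to_mass(0.1, 50)  # ~2.34 g
#' @export
dose_to_mass <- function(dose_mmol_kg, bodyweight_kg,
                         molar_mass_g_mol = MOLAR_MASS_BTO_CFO) {
  stopifnot(dose_mmol_kg >= 0, bodyweight_kg >= 0, molar_mass_g_mol >= 0)
  dose_mmol_kg * bodyweight_kg * molar_mass_g_mol / 1000
}

#' Particle count and number density from administered mass
#'
#' Per-particle mass is `mass_density * V` with the sphere volume from the
#' spec; the count is `mass / per-particle mass`, and the mean number density
#' spreads that count uniformly over the target volume.
#'
#' @param mass_g total particle mass, g.
#' @param spec a `particle_spec`.
#' @param target_volume_cm3 volume over which particles distribute, cm^3 (> 0).
#' @return list with `count`, `number_density_cm3` and `particle_mass_g`.
#' @examples
#' mass_to_count_and_density(2.34, men_spec(), 1200)
#' @export
mass_to_count_and_density <- function(mass_g, spec, target_volume_cm3) {
  stopifnot(inherits(spec, "particle_spec"), mass_g >= 0, target_volume_cm3 > 0)
  V <- particle_volume_and_moment(spec)$V_cm3
  if (V <= 0) stop("configuration error: zero particle volume")
  pm <- spec$mass_density_g_cc * V
  count <- mass_g / pm
  list(count = count, number_density_cm3 = count / target_volume_cm3,
       particle_mass_g = pm)
}

#' Dissipated power and thermal-safety flag
#'
#' `power = energy per cycle * drive frequency`; the run is flagged safe when
#' the power does not exceed the safety limit (default 50 W, the budget below
#' which the brain's thermal transport keeps steady-state heating under ~2 K).
#'
#' @param energy_per_cycle_J hysteresis energy per M-H cycle, J (>= 0).
#' @param frequency_Hz imaging drive frequency, Hz (>= 0).
#' @param safety_limit_W acceptable dissipation, W.
#' @return list with `power_W` and logical `safe`.
#' @examples
#' dissipated_power(1e-4, 1e4)  # 1 W, safe
#' @export
dissipated_power <- function(energy_per_cycle_J, frequency_Hz,
                             safety_limit_W = 50) {
  stopifnot(energy_per_cycle_J >= 0, frequency_Hz >= 0, safety_limit_W >= 0)
  p <- energy_per_cycle_J * frequency_Hz
  list(power_W = p, safe = p <= safety_limit_W)
}

#' Full dose report
#'
#' Assembles the complete dosimetry chain: dose -> administered mass ->
#' particle count and mean number density over the target volume ->
#' hysteresis energy per cycle -> dissipated power and safety flag.
#'
#' @param dose_mmol_kg dose, mmol/kg.
#' @param bodyweight_kg subject weight, kg.
#' @param spec a `particle_spec`.
#' @param target_volume_cm3 tissue volume receiving the particles, cm^3.
#' @param molar_mass_g_mol particle molar mass, g/mol.
#' @param frequency_Hz imaging drive frequency, Hz.
#' @param loop_model hysteresis loop model, `"rectangular"` or `"elliptical"`.
#' @param safety_limit_W dissipation limit, W.
#' @return object of class `dose_report` (a named list of all quantities).
#' @export
dose_report <- function(dose_mmol_kg, bodyweight_kg, spec, target_volume_cm3,
                        molar_mass_g_mol = MOLAR_MASS_BTO_CFO,
                        frequency_Hz = 1e4,
                        loop_model = c("rectangular", "elliptical"),
                        safety_limit_W = 50) {
  loop_model <- match.arg(loop_model)
  mass <- dose_to_mass(dose_mmol_kg, bodyweight_kg, molar_mass_g_mol)
  cd <- mass_to_count_and_density(mass, spec, target_volume_cm3)
  energy <- hysteresis_energy_per_cycle(spec, mass, loop_model)
  pw <- dissipated_power(energy, frequency_Hz, safety_limit_W)
  structure(list(
    dose_mmol_kg = dose_mmol_kg,
    bodyweight_kg = bodyweight_kg,
    molar_mass_g_mol = molar_mass_g_mol,
    total_mass_g = mass,
    particle_count = cd$count,
    mean_number_density_cm3 = cd$number_density_cm3,
    target_volume_cm3 = target_volume_cm3,
    loop_model = loop_model,
    energy_per_cycle_J = energy,
    frequency_Hz = frequency_Hz,
    dissipated_power_W = pw$power_W,
    safety_limit_W = safety_limit_W,
    safe = pw$safe
  ), class = "dose_report")
}

#' @export
print.dose_report <- function(x, ...) {
  cat("<dose_report>\n")
  cat(sprintf("  dose %.3g mmol/kg x %.3g kg (M = %.1f g/mol) -> %.3g g\n",
              x$dose_mmol_kg, x$bodyweight_kg, x$molar_mass_g_mol, x$total_mass_g))
  cat(sprintf("  %.3g particles, mean density %.3g /cm^3 over %.3g cm^3\n",
              x$particle_count, x$mean_number_density_cm3, x$target_volume_cm3))
  cat(sprintf("  %s loop: %.3g J/cycle x %.3g Hz = %.3g W (limit %.3g W, %s)\n",
              x$loop_model, x$energy_per_cycle_J, x$frequency_Hz,
              x$dissipated_power_W, x$safety_limit_W,
              if (x$safe) "safe" else "UNSAFE"))
  invisible(x)
}

#' @export
as.data.frame.dose_report <- function(x, ...) {
  as.data.frame(unclass(x), stringsAsFactors = FALSE)
}
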