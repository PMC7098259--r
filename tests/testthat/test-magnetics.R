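# Nanoparticle physics: Langevin curves, magnetoelectric shift, dissipation,
# dipole broadening.

kB <- 1.38065e-16

test_that("sphere volume and saturation moment follow the spec geometry", {
  men <- men_spec()
  vm <- particle_volume_and_moment(men)
  expect_equal(vm$V_cm3, pi * (5e-6)^3 / 6)            # 6.545e-17 cm^3
  expect_equal(vm$V_cm3, 6.545e-17, tolerance = 1e-4)
  expect_equal(vm$m_emu, 10 * vm$V_cm3)                # m = Ms V
  expect_equal(particle_volume_and_moment(men_spec(Ms_emu_cc = 0))$m_emu, 0)
  # emu/g input converts through the mass density
  spec_g <- men_spec(Ms_emu_cc = NULL, Ms_emu_g = 2)
  expect_equal(spec_g$Ms_emu_cc, 10)
})

test_that("Langevin magnetization is odd, increasing, bounded, and correct at 500 Oe", {
  men <- men_spec()
  H <- c(0.1, 1, 5, 20, 100, 300, 500, 2000)
  L <- langevin_mrel(H, men)
  expect_equal(langevin_mrel(0, men), 0)
  expect_equal(langevin_mrel(-H, men), -L)          # odd
  expect_true(all(diff(langevin_mrel(seq(-600, 600, 10), men)) > 0))
  expect_true(all(abs(L) < 1))
  # frozen from direct evaluation: xi = mH/kBT = 7.9009 at 500 Oe, 300 K
  expect_equal(langevin_mrel(500, men), 0.87343, tolerance = 1e-4)
})

test_that("Langevin limits: small-field slope m/3kBT and saturation 1 - 1/xi within 1%", {
  men <- men_spec()
  m <- particle_volume_and_moment(men)$m_emu
  xi_per_Oe <- m / (kB * men$temperature_K)
  # slope regime xi < 0.1
  H_small <- 0.05 / xi_per_Oe
  expect_equal(langevin_mrel(H_small, men) / H_small, m / (3 * kB * 300),
               tolerance = 0.01)
  # saturation regime xi > 20
  for (xi in c(25, 50, 200)) {
    H <- xi / xi_per_Oe
    expect_equal(langevin_mrel(H, men), 1 - 1 / xi, tolerance = 0.01)
  }
  # series branch joins the exact formula smoothly at the switch point
  # (the 0.2% argument step itself changes L by 0.2%; no extra jump allowed)
  expect_equal(langevin_mrel(0.999e-3 / xi_per_Oe, men),
               langevin_mrel(1.001e-3 / xi_per_Oe, men), tolerance = 0.005)
})

test_that("magnetoelectric shift is the literal linear coupling in V/cm", {
  men <- men_spec()
  expect_equal(me_magnetization_shift(0, men), 0)
  expect_equal(me_magnetization_shift(100, men), 0.1)   # 0.1 G cm/V x 1 V/cm
  E <- c(5, 10, 20, 40, 100)
  expect_equal(me_magnetization_shift(2 * E, men),
               2 * me_magnetization_shift(E, men))       # linear
  expect_equal(me_magnetization_shift(-50, men), -me_magnetization_shift(50, men))
  # per-cc and per-particle routes agree to machine precision
  V <- particle_volume_and_moment(men)$V_cm3
  expect_equal(me_moment_shift(E, men), me_magnetization_shift(E, men) * V)
})

test_that("MEN magnetization adds the field shift and clips at saturation", {
  men <- men_spec()
  H <- seq(-500, 500, 25)
  expect_equal(men_mrel(H, 0, men), langevin_mrel(H, men))  # null shift
  expect_equal(men_mrel(0, 100, men), 0.01)                 # 0.1 / 10
  # exact additive linearity wherever unclipped
  for (E in c(5, 40, 100))
    expect_equal(men_mrel(H, E, men) - men_mrel(H, 0, men),
                 rep(men$alpha_G_cm_V * E / (100 * men$Ms_emu_cc), length(H)))
  expect_equal(men_mrel(0, 1e7, men), 1)                    # clipped
  expect_error(men_mrel(0, 10, men_spec(Ms_emu_cc = 1e-300 * 0, alpha_G_cm_V = 0.1)),
               "Ms = 0")
})

test_that("MN and MEN particle models are indistinguishable when alpha = 0", {
  a <- mn_spec()
  b <- as_mn(men_spec(Ms_emu_cc = 100))
  H <- seq(-500, 500, 50)
  for (E in c(0, 40, 100))
    expect_identical(men_mrel(H, E, a), men_mrel(H, E, b))
  expect_identical(a$mode, "MN")
  expect_identical(men_spec()$mode, "MEN")
})

test_that("hysteresis loss per cycle matches the loop-area formulas", {
  men <- men_spec()   # Ms 10 emu/cc, Hc 100 Oe, 5 g/cc
  expect_equal(hysteresis_energy_per_cycle(men_spec(Hc_Oe = 0), 2.5), 0)
  # 2.5 g -> 0.5 cc; rectangular 4 Hc Ms V = 2000 erg = 2e-4 J
  expect_equal(hysteresis_energy_per_cycle(men, 2.5), 2e-4)
  expect_equal(hysteresis_energy_per_cycle(men, 2.5, "elliptical"),
               pi * 100 * 10 * 0.5 * 1e-7)
  expect_error(hysteresis_energy_per_cycle(men, 2.5, "square"))
})

test_that("dipole interaction field scales linearly with number density", {
  men <- men_spec()
  expect_equal(dipole_mean_field(0, men), 0)
  # 1 um spacing: 2m/r^3 = 2 * 6.545e-16 / 1e-12
  expect_equal(dipole_mean_field(1e12, men), 1.309e-3, tolerance = 1e-3)
  expect_equal(dipole_mean_field(8e12, men), 8 * dipole_mean_field(1e12, men))
  d <- 10^seq(10, 17)
  expect_true(all(diff(dipole_mean_field(d, men)) > 0))
  expect_warning(dipole_mean_field(1e19, men), "5 nm")
})

test_that("magnetization curve families are tabulated per electric field", {
  men <- men_spec()
  tab <- mrel_curves(men, H_Oe = seq(-500, 500, 100), E_Vm = c(5, 10, 20, 40, 100))
  expect_named(tab, c("H_Oe", "E_Vm", "M_rel"))
  expect_equal(nrow(tab), 11 * 5)
  # each curve is the E = 0 curve shifted up by alpha E / (100 Ms)
  for (E in c(5, 100)) {
    cur <- tab[tab$E_Vm == E, ]
    expect_equal(cur$M_rel, langevin_mrel(cur$H_Oe, men) + 0.1 * E / (100 * 10))
  }
})

test_that("particle spec rejects unphysical values", {
  expect_error(particle_spec(diameter_nm = -1, Ms_emu_cc = 10))
  expect_error(particle_spec(Ms_emu_cc = 10, temperature_K = 0))
  expect_error(particle_spec())                         # no Ms given
  expect_error(particle_spec(Ms_emu_cc = 10, Ms_emu_g = 2))
})
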