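# Conduction solve: source discretization, potential solve against the
# closed-form image-lattice oracle, field differentiation, refinement.

test_that("firing source discretizes to a balanced volumetric current", {
  sc <- small_firing_scenario()
  src <- firing_to_source(sc$firing, sc$phantom)
  # 70 pA/pF x 1e4 pF/mm^3 = 7e5 pA/mm^3 = 700 A/m^3 inside the spot
  expect_equal(max(src$J_A_m3), 700)
  # exact source/sink balance
  vox_m3 <- prod(sc$phantom$voxel_size_mm) * 1e-9
  tot <- sum(src$J_A_m3) * vox_m3
  expect_lt(abs(tot), 1e-12 * sum(abs(src$J_A_m3)) * vox_m3)
  # null source
  fr0 <- firing_source(sc$firing$center_mm, rate_pA_per_pF = 0)
  expect_true(all(firing_to_source(fr0, sc$phantom)$J_A_m3 == 0))
  # spot entirely outside tissue
  fr_out <- firing_source(c(1, 1, 1), diameter_mm = 1)
  expect_error(firing_to_source(fr_out, sc$phantom), "geometry error")
})

test_that("zero source gives zero potential; solver is linear and superposable", {
  ph <- make_uniform_block(16, 2)
  z <- solve_potential(ph, array(0, dim = c(16, 16, 16)))
  expect_true(all(z$phi_V == 0))

  J1 <- array(0, dim = c(16, 16, 16)); J1[5, 8, 8] <- 1; J1[12, 8, 8] <- -1
  J2 <- array(0, dim = c(16, 16, 16)); J2[8, 5, 8] <- 2; J2[8, 12, 8] <- -2
  p1 <- solve_potential(ph, J1, tol = 1e-12)
  p2 <- solve_potential(ph, J2, tol = 1e-12)
  p12 <- solve_potential(ph, J1 + J2, tol = 1e-12)
  pd <- solve_potential(ph, 2 * J1, tol = 1e-12)
  scale <- max(abs(p12$phi_V))
  expect_lt(max(abs(p12$phi_V - p1$phi_V - p2$phi_V)) / scale, 1e-8)
  expect_lt(max(abs(pd$phi_V - 2 * p1$phi_V)) / scale, 1e-10)
})

test_that("an unbalanced source under insulating boundaries is rejected", {
  ph <- make_uniform_block(16, 2)
  J <- array(0, dim = c(16, 16, 16)); J[8, 8, 8] <- 1
  expect_error(solve_potential(ph, J), "unbalanced")
  expect_error(solve_potential(ph, array(0, dim = c(8, 8, 8))), "shape error")
})

test_that("discrete current conservation holds at every interior voxel", {
  sc <- small_firing_scenario()
  src <- firing_to_source(sc$firing, sc$phantom)
  pot <- solve_potential(sc$phantom, src, tol = 1e-10)
  expect_lt(conservation_residual(sc$phantom, src, pot), 1e-8)
})

test_that("solved potential matches the closed-form two-monopole solution within 5%", {
  n <- 48
  ph <- make_uniform_block(n, 1)
  d3 <- dim(ph$labels)
  c1 <- c(24, 24, 19); c2 <- c(24, 24, 29)
  rp <- voxel_distance(d3, 1, c1); rm <- voxel_distance(d3, 1, c2)
  I <- 1e-6; vol_m3 <- 1e-9
  mp <- rp <= 2; mm <- rm <= 2   # small spherical electrodes
  J <- array(0, dim = d3)
  J[mp] <- I / (sum(mp) * vol_m3); J[mm] <- -I / (sum(mm) * vol_m3)
  pot <- solve_potential(ph, J, tol = 1e-10)

  ax <- (1:n) - 0.5
  g <- expand.grid(x = ax, y = ax, z = ax)
  sigma <- 0.33
  phi_an <- phi_box_images(g$x, g$y, g$z,
                           list(list(q = I, at = c1), list(q = -I, at = c2)),
                           rep(n, 3), sigma)
  phi_an <- phi_an - mean(phi_an)
  num <- as.vector(pot$phi_V)
  # >= 3 voxels from the source regions, >= 5 voxels from the boundary,
  # excluding the thin null surface where the reference potential vanishes
  # (relative error is undefined as the reference crosses zero)
  el <- pmin(as.vector(rp), as.vector(rm)) >= 5 &
    g$x > 5 & g$x < n - 5 & g$y > 5 & g$y < n - 5 & g$z > 5 & g$z < n - 5
  pk <- max(abs(phi_an[el]))
  sel <- el & abs(phi_an) >= 0.02 * pk
  expect_gt(sum(sel), 2e4)
  expect_lt(max(abs(num[sel] - phi_an[sel]) / abs(phi_an[sel])), 0.05)
  # and the absolute mismatch is small everywhere eligible, null surface included
  expect_lt(max(abs(num[el] - phi_an[el])) / pk, 0.02)
})

test_that("field differentiation recovers linear and constant potentials", {
  n <- 12
  lab <- array(1L, dim = c(n, n, n))
  tissue <- lab > 0L
  ax <- ((1:n) - 0.5) * 1e-3  # m
  phi <- array(rep(ax, times = n * n), dim = c(n, n, n))  # phi = x, 1 V/m slope
  pot <- structure(list(phi_V = phi, tissue = tissue), class = "potential_map")
  ef <- efield_from_potential(pot, 1)
  expect_equal(max(abs(ef$Ex + 1)), 0, tolerance = 1e-12)  # E = (-1, 0, 0)
  expect_equal(max(abs(ef$Ey)), 0)
  expect_equal(max(abs(ef$Ez)), 0)
  expect_lt(max(abs(ef$magnitude - 1)), 1e-12)

  pot0 <- structure(list(phi_V = array(3.7, dim = c(n, n, n)), tissue = tissue),
                    class = "potential_map")
  ef0 <- efield_from_potential(pot0, 1)
  expect_true(all(ef0$magnitude == 0))
  expect_error(efield_from_potential(pot, 0), "voxel size")
})

test_that("field magnitude decays as 1/r^2 from a monopole electrode", {
  n <- 48
  ph <- make_uniform_block(n, 1)
  J <- array(0, dim = c(n, n, n)); vol_m3 <- 1e-9; I <- 1e-6
  J[14, 24, 24] <- I / vol_m3; J[34, 24, 24] <- -I / vol_m3
  pot <- solve_potential(ph, J, tol = 1e-10)
  ef <- efield_from_potential(pot, 1)
  r <- voxel_distance(dim(ph$labels), 1, c(13.5, 23.5, 23.5))
  sel <- r >= 2.5 & r <= 7
  xmask <- array(rep((1:n) - 0.5, times = n * n), dim = c(n, n, n)) < 23
  sel <- sel & xmask  # near-source half, away from the sink
  fit <- stats::lm(log(ef$magnitude[sel]) ~ log(r[sel]))
  expect_equal(unname(coef(fit)[2]), -2, tolerance = 0.1 / 2)
})

test_that("refinement reduces the potential change at fixed world probes (order >= 1)", {
  probe_phi <- function(h) {
    m <- round(24 / h)
    ph <- make_uniform_block(m, h)
    d3 <- dim(ph$labels)
    rp <- voxel_distance(d3, h, c(12, 12, 8))
    rm <- voxel_distance(d3, h, c(12, 12, 16))
    mp <- rp <= 2.2; mm <- rm <= 2.2
    J <- array(0, dim = d3); vol_m3 <- (h * 1e-3)^3
    J[mp] <- 1e-6 / (sum(mp) * vol_m3); J[mm] <- -1e-6 / (sum(mm) * vol_m3)
    pot <- solve_potential(ph, J, tol = 1e-11)
    sapply(list(c(12, 12, 4), c(12, 12, 20), c(9, 12, 6), c(15, 12, 18)),
           function(p) {
             ball <- voxel_distance(d3, h, p) <= 2
             mean(pot$phi_V[ball])
           })
  }
  v <- lapply(c(2, 1, 0.5), probe_phi)
  d1 <- sqrt(sum((v[[1]] - v[[2]])^2))
  d2 <- sqrt(sum((v[[2]] - v[[3]])^2))
  expect_lt(d2, d1)
  expect_gt(log2(d1 / d2), 1)
})

test_that("calibration scales the source so the peak field hits its target", {
  sc <- small_firing_scenario()
  cal <- calibrate_firing(sc$firing, sc$phantom, target_peak_Vm = 100)
  expect_equal(max(cal$efield$magnitude), 100)
  expect_equal(cal$firing$capacitance_density_pF_mm3,
               sc$firing$capacitance_density_pF_mm3 * cal$scale)
  # default working range: peak within 5..100 V/m band by construction
  expect_true(max(cal$efield$magnitude) <= 100 + 1e-9)
})
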