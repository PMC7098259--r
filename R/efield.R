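# Quasi-static current conduction: div(sigma grad phi) = -J_v on the voxel
# grid, discretized by finite volumes with harmonic-mean face conductivities
# (the standard choice for discontinuous sigma), insulating boundary at the
# tissue/background interface, mean-zero potential gauge, and a
# Jacobi-preconditioned conjugate-gradient solve on the tissue voxels.

#' Describe a localized neuronal firing source
#'
#' A firing event is modeled as an instantaneous volumetric current source: a
#' spherical spot of diameter `diameter_mm` injecting current at
#' `rate_pA_per_pF` per unit membrane capacitance, converted to a volume
#' density through `capacitance_density_pF_mm3` (membrane capacitance per mm^3
#' of tissue — an explicit calibration constant, see [calibrate_firing()]),
#' balanced by an equal-and-opposite sink sphere offset by `sink_offset_mm`
#' so the net injected current is zero (offset monopole pair).
#'
#' @param center_mm world coordinates of the spot center, mm.
#' @param diameter_mm spot diameter, mm (> 0).
#' @param rate_pA_per_pF current density per capacitance, pA/pF (>= 0).
#' @param capacitance_density_pF_mm3 membrane capacitance per tissue volume,
#'   pF/mm^3.
#' @param sink_offset_mm offset of the sink sphere relative to the source, mm
#'   (length 3); default `NULL` means one voxel along +z, resolved when the
#'   source is discretized on a grid.
#' @return object of class `firing_source`.
#' @export
firing_source <- function(center_mm, diameter_mm = 2, rate_pA_per_pF = 70,
                          capacitance_density_pF_mm3 = 1e4,
                          sink_offset_mm = NULL) {
  stopifnot(length(center_mm) == 3L, diameter_mm > 0, rate_pA_per_pF >= 0,
            capacitance_density_pF_mm3 > 0)
  structure(list(
    center_mm = as.numeric(center_mm),
    diameter_mm = diameter_mm,
    rate_pA_per_pF = rate_pA_per_pF,
    capacitance_density_pF_mm3 = capacitance_density_pF_mm3,
    sink_offset_mm = if (is.null(sink_offset_mm)) NULL else as.numeric(sink_offset_mm)
  ), class = "firing_source")
}

#' @export
print.firing_source <- function(x, ...) {
  cat(sprintf("<firing_source> center (%s) mm, d = %g mm, %g pA/pF x %g pF/mm^3\n",
              paste(signif(x$center_mm, 4), collapse = ", "),
              x$diameter_mm, x$rate_pA_per_pF, x$capacitance_density_pF_mm3))
  invisible(x)
}

# distance of every voxel center from a world point
voxel_distance_internal <- function(phantom, center_mm) {
  ax <- voxel_center_axes(phantom)
  d <- dim(phantom$labels)
  u <- outer((ax[[1]] - center_mm[1])^2, (ax[[2]] - center_mm[2])^2, "+")
  q <- outer(as.vector(u), (ax[[3]] - center_mm[3])^2, "+")
  dim(q) <- d
  sqrt(q)
}

# logical mask of voxels whose centers lie within radius of center
.sphere_mask <- function(phantom, center_mm, radius_mm) {
  voxel_distance_internal(phantom, center_mm) <= radius_mm
}

#' Discretize a firing source into a balanced volumetric current map
#'
#' Converts the firing description to a per-voxel volumetric current density
#' `J_v` in A/m^3: `J_v = rate_pA_per_pF * capacitance_density` inside the
#' source sphere (70 pA/pF at 1e4 pF/mm^3 is 7e5 pA/mm^3 = 700 A/m^3), an
#' equal-and-opposite density over the sink sphere, zero elsewhere. The sink
#' density is scaled by the discrete source/sink voxel counts so the total
#' injected current sums to zero exactly.
#'
#' @param firing a `firing_source`.
#' @param phantom a `tissue_phantom` (conductivity not required yet).
#' @return object of class `current_source_map`: list with `J_A_m3` (3-D
#'   array), `source_mask`, `sink_mask`, `total_current_A`.
#' @export
firing_to_source <- function(firing, phantom) {
  stopifnot(inherits(firing, "firing_source"))
  validate_phantom(phantom)
  tissue <- phantom$labels > 0L
  radius <- firing$diameter_mm / 2
  # spots smaller than a voxel snap to the nearest tissue voxel
  spot_mask <- function(center) {
    msk <- .sphere_mask(phantom, center, radius) & tissue
    if (!any(msk)) {
      d <- voxel_distance_internal(phantom, center)
      d[!tissue] <- Inf
      near <- which(d == min(d), arr.ind = FALSE)[1]
      if (d[near] > radius + max(phantom$voxel_size_mm)) return(msk)
      msk[near] <- TRUE
    }
    msk
  }
  src <- spot_mask(firing$center_mm)
  if (!any(src))
    stop("geometry error: firing spot does not intersect tissue")
  offset <- firing$sink_offset_mm
  if (is.null(offset)) offset <- c(0, 0, phantom$voxel_size_mm[3])
  snk <- spot_mask(firing$center_mm + offset)
  if (!any(snk))
    stop("geometry error: sink spot does not intersect tissue")

  # pA/pF * pF/mm^3 = pA/mm^3 = 1e-12 A / 1e-9 m^3 = 1e-3 A/m^3
  J_src <- firing$rate_pA_per_pF * firing$capacitance_density_pF_mm3 * 1e-3
  J <- array(0, dim = dim(phantom$labels))
  J[src] <- J[src] + J_src
  J[snk] <- J[snk] - J_src * sum(src) / sum(snk)
  structure(list(
    J_A_m3 = J,
    source_mask = src,
    sink_mask = snk,
    total_current_A = J_src * sum(src) * prod(phantom$voxel_size_mm) * 1e-9
  ), class = "current_source_map")
}

# Jacobi-preconditioned conjugate gradients for the (singular, consistent)
# conduction system; iterates are kept mean-free over the tissue DOFs.
.cg_solve <- function(A, b, tol = 1e-8, maxit = 10000L) {
  n <- length(b)
  b <- b - mean(b)
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0) return(list(x = numeric(n), iterations = 0L, residual = 0))
  Minv <- 1 / Matrix::diag(A)
  x <- numeric(n)
  r <- b
  z <- Minv * r
  p <- z
  rz <- sum(r * z)
  for (it in seq_len(maxit)) {
    Ap <- as.numeric(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    res <- sqrt(sum(r^2)) / bnorm
    if (res < tol) {
      x <- x - mean(x)
      return(list(x = x, iterations = it, residual = res))
    }
    z <- Minv * r
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  stop(sprintf(
    "solver error: conjugate gradients did not converge in %d iterations (relative residual %.3e)",
    maxit, res))
}

# Assemble the finite-volume operator over tissue voxels.
# Returns dof index array, sparse SPD matrix A (S), and geometry factors.
.assemble_conduction <- function(phantom) {
  sigma <- phantom$conductivity_S_m
  if (is.null(sigma)) stop("assign conductivities before solving")
  d <- dim(phantom$labels)
  tissue <- phantom$labels > 0L
  n <- sum(tissue)
  idx <- array(0L, dim = d)
  idx[tissue] <- seq_len(n)
  h <- phantom$voxel_size_mm * 1e-3  # m
  face_area <- c(h[2] * h[3], h[1] * h[3], h[1] * h[2])

  ii <- list(); jj <- list(); gg <- list()
  for (axis in 1:3) {
    take <- function(arr, drop_last) {
      ind <- lapply(d, seq_len)
      ind[[axis]] <- if (drop_last) seq_len(d[axis] - 1L) else 2L:d[axis]
      do.call(`[`, c(list(arr), ind, list(drop = FALSE)))
    }
    ia <- take(idx, TRUE); ib <- take(idx, FALSE)
    sa <- take(sigma, TRUE); sb <- take(sigma, FALSE)
    keep <- ia > 0L & ib > 0L
    sa <- sa[keep]; sb <- sb[keep]
    g <- 2 * sa * sb / (sa + sb) * face_area[axis] / h[axis]  # S (harmonic mean)
    ii[[axis]] <- ia[keep]; jj[[axis]] <- ib[keep]; gg[[axis]] <- g
  }
  i <- unlist(ii); j <- unlist(jj); g <- unlist(gg)
  A <- Matrix::sparseMatrix(i = c(i, j, i, j), j = c(j, i, i, j),
                            x = c(-g, -g, g, g), dims = c(n, n))
  list(idx = idx, tissue = tissue, A = A,
       voxel_volume_m3 = prod(h))
}

#' Solve the conduction problem for the electric potential
#'
#' Solves the discrete conservation law `div(sigma grad phi) = -J_v` on the
#' tissue voxels by finite volumes (harmonic-mean face conductivities), with an
#' insulating (zero normal current) boundary at the tissue/background interface
#' and the gauge fixed by a mean-zero potential over tissue. The source must be
#' balanced (net current zero) for a solution to exist under insulating
#' boundaries.
#'
#' @param phantom a `tissue_phantom` with conductivities assigned.
#' @param source a `current_source_map` from [firing_to_source()], or a 3-D
#'   array of volumetric current density (A/m^3).
#' @param tol relative residual tolerance of the iterative solve.
#' @param maxit iteration cap.
#' @return object of class `potential_map`: list with `phi_V` (3-D array, V;
#'   0 on background by convention), `tissue` mask, `iterations`, `residual`.
#' @export
solve_potential <- function(phantom, source, tol = 1e-8, maxit = 10000L) {
  validate_phantom(phantom)
  J <- if (inherits(source, "current_source_map")) source$J_A_m3 else source
  if (!identical(dim(J), dim(phantom$labels)))
    stop("shape error: source grid does not match phantom grid")
  sys <- .assemble_conduction(phantom)
  b <- J[sys$tissue] * sys$voxel_volume_m3  # injected current per voxel, A
  scale_b <- sum(abs(b))
  if (scale_b > 0 && abs(sum(b)) > 1e-9 * scale_b)
    stop("no-solution error: unbalanced source under insulating boundaries ",
         sprintf("(net current %.3e of total %.3e A)", sum(b), scale_b))
  sol <- .cg_solve(sys$A, b, tol = tol, maxit = maxit)
  phi <- array(0, dim = dim(phantom$labels))
  phi[sys$tissue] <- sol$x
  structure(list(phi_V = phi, tissue = sys$tissue,
                 iterations = sol$iterations, residual = sol$residual),
            class = "potential_map")
}

#' Residual of the discrete conservation law
#'
#' Recomputes `A phi - b` voxelwise; the maximum absolute residual relative to
#' the source scale quantifies how well discrete current conservation holds at
#' every interior voxel.
#'
#' @param phantom phantom used for the solve.
#' @param source source used for the solve.
#' @param potential the returned `potential_map`.
#' @return maximum per-voxel residual divided by `max(abs(b))` (dimensionless).
#' @export
conservation_residual <- function(phantom, source, potential) {
  J <- if (inherits(source, "current_source_map")) source$J_A_m3 else source
  sys <- .assemble_conduction(phantom)
  b <- J[sys$tissue] * sys$voxel_volume_m3
  r <- as.numeric(sys$A %*% potential$phi_V[sys$tissue]) - (b - mean(b))
  max(abs(r)) / max(abs(b))
}

#' Electric field from the potential
#'
#' `E = -grad(phi)` by central differences on interior tissue voxels and
#' one-sided differences at the tissue boundary; `E = 0` on background by
#' convention. Potentials are in V and voxel sizes in mm, so fields come out
#' in V/m after the mm-to-m conversion.
#'
#' @param potential a `potential_map`.
#' @param voxel_size_mm voxel size, mm (scalar or length 3).
#' @return object of class `efield_map`: list of 3-D arrays `Ex`, `Ey`, `Ez`,
#'   `magnitude` (V/m) plus the `tissue` mask.
#' @export
efield_from_potential <- function(potential, voxel_size_mm) {
  stopifnot(inherits(potential, "potential_map"))
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3)
  if (any(voxel_size_mm <= 0)) stop("configuration error: voxel size must be positive")
  phi <- potential$phi_V
  tissue <- potential$tissue
  d <- dim(phi)
  h_m <- voxel_size_mm * 1e-3
  shift <- function(arr, axis, by) {
    out <- array(NA_real_, dim = d)
    from <- lapply(d, seq_len); to <- lapply(d, seq_len)
    if (by > 0) { from[[axis]] <- (1 + by):d[axis]; to[[axis]] <- 1:(d[axis] - by) }
    else if (by < 0) { from[[axis]] <- 1:(d[axis] + by); to[[axis]] <- (1 - by):d[axis] }
    out <- do.call(`[<-`, c(list(out), to, list(do.call(`[`, c(list(arr), from, list(drop = FALSE))))))
    out
  }
  comp <- vector("list", 3)
  for (axis in 1:3) {
    tp <- shift(tissue, axis, 1); tp[is.na(tp)] <- FALSE
    tm <- shift(tissue, axis, -1); tm[is.na(tm)] <- FALSE
    pp <- shift(phi, axis, 1); pm <- shift(phi, axis, -1)
    g <- array(0, dim = d)
    both <- tissue & tp & tm
    fwd <- tissue & tp & !tm
    bwd <- tissue & !tp & tm
    g[both] <- (pp[both] - pm[both]) / (2 * h_m[axis])
    g[fwd] <- (pp[fwd] - phi[fwd]) / h_m[axis]
    g[bwd] <- (phi[bwd] - pm[bwd]) / h_m[axis]
    comp[[axis]] <- -g
  }
  mag <- sqrt(comp[[1]]^2 + comp[[2]]^2 + comp[[3]]^2)
  structure(list(Ex = comp[[1]], Ey = comp[[2]], Ez = comp[[3]],
                 magnitude = mag, tissue = tissue),
            class = "efield_map")
}

#' Calibrate the firing source to a target peak field
#'
#' The conduction problem is linear in the source, so the membrane-capacitance
#' calibration constant can be fixed by one solve: the source is discretized
#' and solved once, and `capacitance_density_pF_mm3` (and the solved maps) are
#' scaled so the peak field magnitude equals `target_peak_Vm`. This pins the
#' otherwise unconstrained capacitance-per-volume factor to a physiologically
#' stated working field.
#'
#' @param firing a `firing_source`.
#' @param phantom a `tissue_phantom` with conductivities.
#' @param target_peak_Vm desired peak `|E|`, V/m (default 100, the top of the
#'   5–100 V/m working range).
#' @param tol,maxit passed to [solve_potential()].
#' @return list with the rescaled `firing`, the scaled `potential` and
#'   `efield`, the discretized `source`, and `scale` applied.
#' @export
calibrate_firing <- function(firing, phantom, target_peak_Vm = 100,
                             tol = 1e-8, maxit = 10000L) {
  src <- firing_to_source(firing, phantom)
  pot <- solve_potential(phantom, src, tol = tol, maxit = maxit)
  ef <- efield_from_potential(pot, phantom$voxel_size_mm)
  peak <- max(ef$magnitude)
  if (peak <= 0) stop("zero field: cannot calibrate a null source")
  s <- target_peak_Vm / peak
  firing$capacitance_density_pF_mm3 <- firing$capacitance_density_pF_mm3 * s
  src$J_A_m3 <- src$J_A_m3 * s
  src$total_current_A <- src$total_current_A * s
  pot$phi_V <- pot$phi_V * s
  ef$Ex <- ef$Ex * s; ef$Ey <- ef$Ey * s; ef$Ez <- ef$Ez * s
  ef$magnitude <- ef$magnitude * s
  list(firing = firing, source = src, potential = pot, efield = ef, scale = s)
}
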