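# Shared fixtures and independent oracles, built in code at test time.

# Uniform single-tissue block phantom filling the whole grid (label 2 = GM).
make_uniform_block <- function(n, voxel_mm = 1, label = 2L) {
  assign_conductivities(tissue_phantom(array(label, dim = c(n, n, n)), voxel_mm))
}

# Wrap a magnitude array as an efield_map (synthetic ground-truth field).
synthetic_efield <- function(magnitude, tissue) {
  structure(list(Ex = NULL, Ey = NULL, Ez = NULL,
                 magnitude = magnitude, tissue = tissue),
            class = "efield_map")
}

# Distance of every voxel center from a world point, as an array.
voxel_distance <- function(dim3, voxel_mm, center_mm) {
  ax <- lapply(1:3, function(a) (seq_len(dim3[a]) - 0.5) * voxel_mm)
  u <- outer((ax[[1]] - center_mm[1])^2, (ax[[2]] - center_mm[2])^2, "+")
  q <- outer(as.vector(u), (ax[[3]] - center_mm[3])^2, "+")
  dim(q) <- dim3
  sqrt(q)
}

# Independent closed-form oracle for the conduction solve: the potential of
# point currents in a box with insulating (Neumann) walls is the superposition
# of free-space monopole potentials I/(4 pi sigma r) over the mirror-image
# lattice of the box. `charges` is a list of list(q = current A, at = mm).
# K reflections per axis; K = 2 keeps the truncation error well below the
# discretization error at these box sizes.
phi_box_images <- function(x, y, z, charges, box_mm, sigma, K = 2) {
  phi <- 0
  for (ch in charges) {
    for (kx in -K:K) for (ky in -K:K) for (kz in -K:K) {
      for (sx in c(1, -1)) for (sy in c(1, -1)) for (sz in c(1, -1)) {
        # image positions 2 k L +/- x0 along each axis; loop over all sign
        # combinations but halve duplicates when x0 mirrors onto itself
        px <- 2 * kx * box_mm[1] + sx * ch$at[1]
        py <- 2 * ky * box_mm[2] + sy * ch$at[2]
        pz <- 2 * kz * box_mm[3] + sz * ch$at[3]
        r_m <- sqrt((x - px)^2 + (y - py)^2 + (z - pz)^2) * 1e-3
        phi <- phi + ch$q / (4 * pi * sigma) / r_m
      }
    }
  }
  phi
}

# Shared small firing scenario on a layered phantom (fast conduction solve).
small_firing_scenario <- function() {
  ph <- make_layered_phantom(32, 1.5, c(14, 17.5, 20))
  ph <- assign_conductivities(ph)
  ctr <- dim(ph$labels) * ph$voxel_size_mm / 2
  fr <- firing_source(ctr + c(16, 0, 0), diameter_mm = 3)
  list(phantom = ph, firing = fr)
}
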