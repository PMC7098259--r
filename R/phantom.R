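# Segmented head phantoms on a structured voxel grid.
#
# Labels: 0 = background, 1 = white matter (WM), 2 = grey matter (GM),
# 3 = cerebrospinal fluid (CSF). World coordinates are 0-based: the center of
# voxel (i, j, k) (1-based R indices) sits at (i - 0.5) * voxel_size + origin,
# in mm.

.TISSUE_LABELS <- c(background = 0L, WM = 1L, GM = 2L, CSF = 3L)

#' Default tissue conductivity table (S/m)
#'
#' Uniform isotropic conductivities for the three brain compartments:
#' WM 0.14, GM 0.33, CSF 1.79 S/m.
#'
#' @return named numeric vector (names `WM`, `GM`, `CSF`).
#' @export
default_conductivities <- function() c(WM = 0.14, GM = 0.33, CSF = 1.79)

#' Construct a tissue phantom
#'
#' Low-level constructor for a `tissue_phantom`: a 3-D integer label grid plus
#' voxel geometry and (optionally) a per-voxel conductivity map. Prefer
#' [make_layered_phantom()] for the nested WM/GM/CSF head model.
#'
#' @param labels 3-D integer array with values in `{0, 1, 2, 3}`
#'   (background/WM/GM/CSF); at least 8 voxels per axis.
#' @param voxel_size_mm voxel edge lengths in mm (length 1 or 3, > 0).
#' @param conductivity_S_m optional 3-D numeric array, S/m; must be positive
#'   on tissue and zero on background.
#' @param origin_mm world-coordinate of the grid corner, mm (length 3).
#' @return object of class `tissue_phantom` with fields `labels`,
#'   `voxel_size_mm`, `conductivity_S_m` (or `NULL`), `origin_mm`.
#' @export
tissue_phantom <- function(labels, voxel_size_mm = 1,
                           conductivity_S_m = NULL, origin_mm = c(0, 0, 0)) {
  if (length(dim(labels)) != 3L)
    stop("labels must be a 3-D array")
  storage.mode(labels) <- "integer"
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3)
  phantom <- structure(list(
    labels = labels,
    voxel_size_mm = as.numeric(voxel_size_mm),
    conductivity_S_m = conductivity_S_m,
    origin_mm = as.numeric(origin_mm)
  ), class = "tissue_phantom")
  validate_phantom(phantom)
  phantom
}

#' Validate tissue-phantom invariants
#'
#' Checks the class invariants: labels restricted to the background/WM/GM/CSF
#' set, at least 8 voxels per axis, positive voxel sizes, and (if present)
#' conductivity positive exactly on tissue and zero on background. Called by
#' every constructor; exported for use on volumes read from disk.
#'
#' @param phantom a `tissue_phantom`.
#' @return the phantom, invisibly; errors on violation.
#' @export
validate_phantom <- function(phantom) {
  stopifnot(inherits(phantom, "tissue_phantom"))
  lab <- phantom$labels
  if (length(dim(lab)) != 3L) stop("labels must be 3-D")
  if (any(dim(lab) < 8L)) stop("grid must have at least 8 voxels per axis")
  bad <- setdiff(unique(as.vector(lab)), .TISSUE_LABELS)
  if (length(bad))
    stop("unknown label value(s): ", paste(sort(bad), collapse = ", "))
  if (length(phantom$voxel_size_mm) != 3L || any(phantom$voxel_size_mm <= 0))
    stop("voxel_size_mm must be 3 positive values")
  sig <- phantom$conductivity_S_m
  if (!is.null(sig)) {
    if (!identical(dim(sig), dim(lab)))
      stop("conductivity grid does not match label grid")
    if (any(sig[lab > 0L] <= 0))
      stop("conductivity must be positive on tissue voxels")
    if (any(sig[lab == 0L] != 0))
      stop("conductivity must be zero on background voxels")
  }
  invisible(phantom)
}

#' @export
print.tissue_phantom <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<tissue_phantom> %d x %d x %d voxels @ %s mm\n", d[1], d[2], d[3],
              paste(signif(x$voxel_size_mm, 3), collapse = " x ")))
  counts <- table(factor(as.vector(x$labels), levels = .TISSUE_LABELS,
                         labels = names(.TISSUE_LABELS)))
  cat("  voxels:", paste(sprintf("%s=%d", names(counts), counts), collapse = ", "), "\n")
  cat("  conductivity:", if (is.null(x$conductivity_S_m)) "unassigned" else "assigned", "\n")
  invisible(x)
}

#' World coordinates of all voxel centers
#' @param phantom a `tissue_phantom`.
#' @return list of 3 vectors (`x`, `y`, `z`) of per-axis center coordinates, mm.
#' @keywords internal
voxel_center_axes <- function(phantom) {
  d <- dim(phantom$labels)
  lapply(1:3, function(ax)
    (seq_len(d[ax]) - 0.5) * phantom$voxel_size_mm[ax] + phantom$origin_mm[ax])
}

#' Generate a nested-ellipsoid segmented head phantom
#'
#' Builds the synthetic stand-in for a segmented head: three nested ellipsoidal
#' compartments, innermost WM, a GM shell around it and a CSF shell outside,
#' with background beyond. Deterministic for fixed inputs.
#'
#' @param shape grid dimensions (length 3, or scalar for a cube).
#' @param voxel_size_mm voxel edge length, mm (scalar or length 3).
#' @param radii_mm semi-axes of the WM/GM/CSF ellipsoids: either a length-3
#'   vector (spherical shells, strictly increasing) or a 3 x 3 matrix with one
#'   row per shell (WM, GM, CSF) and one column per axis, strictly increasing
#'   down every column.
#' @param center_mm world coordinates of the common center, mm; defaults to the
#'   grid center.
#' @return a `tissue_phantom` (conductivity unassigned).
#' @examples
#' ph <- make_layered_phantom(32, 1, c(10, 12, 14))
#' table(ph$labels)
#' @export
make_layered_phantom <- function(shape, voxel_size_mm = 1,
                                 radii_mm = c(20, 25, 28), center_mm = NULL) {
  if (length(shape) == 1L) shape <- rep(shape, 3)
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3)
  stopifnot(length(shape) == 3L, all(shape >= 8), all(voxel_size_mm > 0))
  if (is.matrix(radii_mm)) {
    if (!all(dim(radii_mm) == c(3, 3)))
      stop("radii_mm matrix must be 3 x 3 (shells x axes)")
    R <- radii_mm
  } else {
    stopifnot(length(radii_mm) == 3L)
    R <- matrix(rep(radii_mm, 3), nrow = 3)  # rows: shells, cols: axes
  }
  if (any(diff(R) <= 0))
    stop("invalid geometry: shell radii must be strictly increasing (WM < GM < CSF)")
  extent <- shape * voxel_size_mm
  if (is.null(center_mm)) center_mm <- extent / 2
  if (any(center_mm - R[3, ] < 0) || any(center_mm + R[3, ] > extent))
    stop("out of bounds: outermost (CSF) ellipsoid does not fit inside the grid")

  ax <- lapply(1:3, function(a) (seq_len(shape[a]) - 0.5) * voxel_size_mm[a])
  # squared normalized radius per shell, built axis-separably
  labels <- array(0L, dim = shape)
  for (shell in 3:1) {  # fill outermost first, overwrite inwards
    u <- outer(((ax[[1]] - center_mm[1]) / R[shell, 1])^2,
               ((ax[[2]] - center_mm[2]) / R[shell, 2])^2, "+")
    q <- outer(as.vector(u), ((ax[[3]] - center_mm[3]) / R[shell, 3])^2, "+")
    dim(q) <- shape
    labels[q <= 1] <- .TISSUE_LABELS[[c("WM", "GM", "CSF")[shell]]]
  }
  tissue_phantom(labels, voxel_size_mm)
}

#' Assign tissue conductivities to a phantom
#'
#' Fills the per-voxel conductivity map by table lookup on the tissue label.
#' The default table is WM 0.14, GM 0.33, CSF 1.79 S/m; background stays at
#' exactly 0 (no-current convention).
#'
#' @param phantom a `tissue_phantom`.
#' @param table named numeric vector mapping labels to S/m; names may be tissue
#'   names (`"WM"`, `"GM"`, `"CSF"`) or label digits (`"1"`..`"3"`). Must cover
#'   every nonzero label present in the phantom.
#' @return the phantom with `conductivity_S_m` filled.
#' @examples
#' ph <- assign_conductivities(make_layered_phantom(32, 1, c(10, 12, 14)))
#' range(ph$conductivity_S_m[ph$labels == 1])  # 0.14 S/m in WM
#' @export
assign_conductivities <- function(phantom, table = default_conductivities()) {
  validate_phantom(phantom)
  if (is.null(names(table)) || any(!nzchar(names(table))))
    stop("conductivity table must be a named vector")
  if (any(table <= 0)) stop("conductivities must be positive")
  nm <- names(table)
  named <- nm %in% names(.TISSUE_LABELS)
  lab_of <- integer(length(table))
  lab_of[named] <- .TISSUE_LABELS[nm[named]]
  lab_of[!named] <- suppressWarnings(as.integer(nm[!named]))
  if (any(is.na(lab_of)))
    stop("unrecognized conductivity table name(s): ",
         paste(nm[is.na(lab_of)], collapse = ", "))
  present <- setdiff(sort(unique(as.vector(phantom$labels))), 0L)
  missing <- setdiff(present, lab_of)
  if (length(missing)) {
    miss_names <- names(.TISSUE_LABELS)[match(missing, .TISSUE_LABELS)]
    stop("phantom.conductivities: no conductivity given for label(s) ",
         paste(sprintf("%d (%s)", missing, miss_names), collapse = ", "))
  }
  sigma <- array(0, dim = dim(phantom$labels))
  for (i in seq_along(table))
    sigma[phantom$labels == lab_of[i]] <- table[[i]]
  phantom$conductivity_S_m <- sigma
  validate_phantom(phantom)
  phantom
}

#' Analytic compartment volumes of a layered phantom
#'
#' Exact ellipsoid-shell volumes (mm^3) for the geometry handed to
#' [make_layered_phantom()]; the voxelized tissue volumes converge to these as
#' the voxel size shrinks.
#'
#' @inheritParams make_layered_phantom
#' @return named vector of volumes (mm^3) for `WM`, `GM`, `CSF`.
#' @export
analytic_shell_volumes <- function(radii_mm) {
  R <- if (is.matrix(radii_mm)) radii_mm else matrix(rep(radii_mm, 3), nrow = 3)
  vol <- 4 / 3 * pi * apply(R, 1, prod)
  c(WM = vol[1], GM = vol[2] - vol[1], CSF = vol[3] - vol[2])
}

#' Write a 3-D volume to NIfTI-1
#'
#' Writes labels (integer) or maps (double) losslessly: integer data as INT16,
#' floating-point data as FLOAT64, with the voxel size in the pixdim header.
#'
#' @param volume 3-D array, or a `tissue_phantom` (its labels are written).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxel_size_mm voxel size, mm; taken from the phantom if one is given.
#' @return the path, invisibly.
#' @export
write_volume_nifti <- function(volume, path, voxel_size_mm = 1) {
  if (inherits(volume, "tissue_phantom")) {
    voxel_size_mm <- volume$voxel_size_mm
    volume <- volume$labels
  }
  if (length(dim(volume)) != 3L) stop("format error: volume must be 3-D")
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3)
  dtype <- if (is.integer(volume)) "int16" else "double"
  img <- RNifti::asNifti(volume)
  RNifti::pixdim(img) <- voxel_size_mm
  RNifti::writeNifti(img, path, datatype = dtype)
  invisible(path)
}

#' Read a label volume from NIfTI-1 into a tissue phantom
#'
#' Reads a 3-D integer label volume, validates the label set
#' (`{0, 1, 2, 3}`) and returns a `tissue_phantom` (conductivity unassigned).
#'
#' @param path a `.nii`/`.nii.gz` file with a 3-D integer volume.
#' @return a `tissue_phantom`.
#' @export
read_labels_nifti <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("format error: expected a 3-D volume, got ", length(dim(img)), "-D")
  vox <- RNifti::pixdim(img)[1:3]
  data <- as.array(img)
  if (any(data != round(data)))
    stop("format error: label volume contains non-integer values")
  bad <- setdiff(unique(as.vector(data)), .TISSUE_LABELS)
  if (length(bad))
    stop("validation error: unknown label value(s): ",
         paste(sort(bad), collapse = ", "))
  tissue_phantom(array(as.integer(data), dim = dim(data)), vox)
}

#' Read a floating-point 3-D map from NIfTI-1
#' @param path a `.nii`/`.nii.gz` file with a 3-D volume.
#' @return list with `data` (3-D array) and `voxel_size_mm`.
#' @export
read_map_nifti <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("format error: expected a 3-D volume, got ", length(dim(img)), "-D")
  list(data = as.array(img), voxel_size_mm = RNifti::pixdim(img)[1:3])
}
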