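#' Specify a geometric phantom
#'
#' A phantom is a set of simple solids (cuboid, ellipsoid, cylinder)
#' voxelized onto a regular grid, used to validate voxel-count volumetry
#' and principal-axis length computation against closed-form ground truth.
#'
#' @param grid Integer length-3: grid shape in voxels.
#' @param spacing Numeric length-3: voxel spacing in mm.
#' @param shapes List of shapes from [phantom_shape()].
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid, spacing, shapes) {
  stopifnot(length(grid) == 3, all(grid >= 1))
  if (any(spacing <= 0)) stop("spacing must be strictly positive")
  labs <- vapply(shapes, `[[`, numeric(1), "label")
  if (anyDuplicated(labs)) stop("shapes must carry distinct labels")
  structure(list(grid = as.integer(grid), spacing = as.numeric(spacing),
                 shapes = shapes), class = "phantom_spec")
}

#' Define one phantom shape
#'
#' @param type `"cuboid"`, `"ellipsoid"` or `"cylinder"`.
#' @param label Positive integer label id.
#' @param code Structure code (e.g. `"SOL"` or `"tibia"`).
#' @param kind `"muscle"` or `"bone"`.
#' @param center Physical centre in mm (length 3).
#' @param dim Shape dimensions in mm: cuboid edge lengths (length 3);
#'   ellipsoid semi-axes (length 3); cylinder `c(radius, length)`, with
#'   the cylinder axis along the local z before rotation.
#' @param angles Rotation angles in radians about the x, y then z axes
#'   mapping the shape's local frame into the grid frame.
#' @return A list describing the shape, with its analytic volume (cm^3)
#'   and analytic principal-axis extent (cm) attached.
#' @export
phantom_shape <- function(type = c("cuboid", "ellipsoid", "cylinder"),
                          label, code, kind = "muscle",
                          center, dim, angles = c(0, 0, 0)) {
  type <- match.arg(type)
  if (label <= 0) stop("label must be a positive integer")
  analytic <- switch(type,
    cuboid = list(vol = prod(dim), len = max(dim)),
    ellipsoid = list(vol = 4 * pi * prod(dim) / 3, len = 2 * max(dim)),
    cylinder = list(vol = pi * dim[1]^2 * dim[2], len = max(dim[2], 2 * dim[1]))
  )
  list(type = type, label = as.integer(label), code = code, kind = kind,
       center = center, dim = dim, R = euler_rotation(angles),
       analytic_volume_cm3 = analytic$vol / 1000,
       analytic_length_cm = analytic$len / 10)
}

euler_rotation <- function(angles) {
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Voxelize a phantom into a label volume
#'
#' Each voxel is assigned the label of the shape containing its centre.
#' Overlapping shapes with different labels are an error. The analytic
#' ground truth (volume and principal-axis extent per shape) is attached
#' as the `ground_truth` attribute of the result.
#'
#' @param spec A [phantom_spec()].
#' @param seed Unused; accepted for interface symmetry with the other
#'   generators (voxelization is deterministic).
#' @return A [as_label_volume()] object.
#' @export
make_phantom <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- spec$grid; sp <- spec$spacing
  centers <- list(( seq_len(g[1]) - 0.5) * sp[1],
                  ( seq_len(g[2]) - 0.5) * sp[2],
                  ( seq_len(g[3]) - 0.5) * sp[3])
  coords <- as.matrix(expand.grid(x = centers[[1]], y = centers[[2]], z = centers[[3]]))
  arr <- array(0L, dim = g)
  for (sh in spec$shapes) {
    u <- (coords - matrix(sh$center, nrow(coords), 3, byrow = TRUE)) %*% sh$R
    inside <- switch(sh$type,
      cuboid = abs(u[, 1]) <= sh$dim[1] / 2 & abs(u[, 2]) <= sh$dim[2] / 2 &
               abs(u[, 3]) <= sh$dim[3] / 2,
      ellipsoid = (u[, 1] / sh$dim[1])^2 + (u[, 2] / sh$dim[2])^2 +
                  (u[, 3] / sh$dim[3])^2 <= 1,
      cylinder = u[, 1]^2 + u[, 2]^2 <= sh$dim[1]^2 & abs(u[, 3]) <= sh$dim[2] / 2
    )
    clash <- inside & as.vector(arr) != 0L
    if (any(clash)) {
      stop("overlap error: shape with label ", sh$label,
           " intersects an already-voxelized shape")
    }
    arr[inside] <- sh$label
  }
  labels <- data.frame(
    label = vapply(spec$shapes, `[[`, integer(1), "label"),
    code = vapply(spec$shapes, `[[`, character(1), "code"),
    kind = vapply(spec$shapes, `[[`, character(1), "kind"),
    stringsAsFactors = FALSE
  )
  lv <- as_label_volume(arr, sp, labels)
  attr(lv, "ground_truth") <- data.frame(
    label = labels$label, code = labels$code,
    analytic_volume_cm3 = vapply(spec$shapes, `[[`, numeric(1), "analytic_volume_cm3"),
    analytic_length_cm = vapply(spec$shapes, `[[`, numeric(1), "analytic_length_cm"),
    stringsAsFactors = FALSE
  )
  lv
}
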