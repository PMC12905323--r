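# Voxelized 3-channel state over a 120 mm cube at 4 mm resolution.
# Channels: 0 target, 1 bone, 2 insonified. Voxels are half-open 4 mm
# cells; inclusion is by voxel-center test; indices are 0-based in the
# lattice convention (R arrays remain 1-based internally).

GRID_EDGE_MM <- 120
GRID_RES_MM <- 4

#' Virtual probe model
#'
#' A linear transducer whose elements emit parallel rays along the probe
#' centerline from points spaced along the long axis.
#'
#' @param footprint_length Transducer footprint (mm, default 40).
#' @param ray_spacing Element spacing (mm, default 2; must be at most half
#'   the voxel resolution so every traversed voxel column is sampled).
#' @param imaging_depth Ray length (mm, default 120, clipped to the grid).
#' @return An object of class `probe_model`.
#' @export
probe_model <- function(footprint_length = 40, ray_spacing = 2,
                        imaging_depth = 120) {
  stopifnot(footprint_length > 0,
            ray_spacing <= GRID_RES_MM / 2, ray_spacing > 0,
            imaging_depth > 0)
  structure(list(footprint_length = footprint_length,
                 ray_spacing = ray_spacing, imaging_depth = imaging_depth),
            class = "probe_model")
}

# volume-weighted centroid of the scene's targets
target_centroid <- function(scene) {
  ctrs <- t(vapply(scene$targets, function(s) {
    if (inherits(s, "ellipsoid")) s$center else colMeans(shape_bbox(s))
  }, numeric(3)))
  w <- vapply(scene$targets, shape_volume, numeric(1))
  colSums(ctrs * w) / sum(w)
}

#' Voxelize a scene around a center point
#'
#' Fills the target and bone channels of a 30x30x30 lattice covering the
#' 120 mm cube centered at `center` (default: the volume-weighted centroid
#' of the union of targets). A warning is recorded when a target extends
#' beyond the cube; voxels outside are not counted in `N`.
#'
#' @param scene An [anatomy_scene()].
#' @param center Length-3 cube center (mm); default target centroid.
#' @return An object of class `voxel_grid` with fields `origin`, `res`,
#'   `dims`, logical arrays `target`, `bone`, `ins`, and `N` (total target
#'   voxels).
#' @export
voxelize <- function(scene, center = NULL) {
  if (is.null(center)) center <- target_centroid(scene)
  dims <- rep(GRID_EDGE_MM / GRID_RES_MM, 3L)
  origin <- center - GRID_EDGE_MM / 2
  ax <- origin[1L] + (seq_len(dims[1L]) - 0.5) * GRID_RES_MM
  ay <- origin[2L] + (seq_len(dims[2L]) - 0.5) * GRID_RES_MM
  az <- origin[3L] + (seq_len(dims[3L]) - 0.5) * GRID_RES_MM
  centers <- as.matrix(expand.grid(x = ax, y = ay, z = az))
  tgt <- rep(FALSE, nrow(centers))
  for (s in scene$targets) tgt <- tgt | shape_inside(s, centers)
  bone <- rep(FALSE, nrow(centers))
  for (s in scene$bones) bone <- bone | shape_inside(s, centers)
  for (s in scene$targets) {
    bb <- shape_bbox(s)
    if (any(bb[1L, ] < origin) || any(bb[2L, ] > origin + GRID_EDGE_MM))
      warning("target extends beyond the 120 mm state cube; ",
              "outside voxels are not counted")
  }
  structure(list(origin = origin, res = GRID_RES_MM, dims = as.integer(dims),
                 target = array(tgt, dims), bone = array(bone, dims),
                 ins = array(FALSE, dims), N = sum(tgt)),
            class = "voxel_grid")
}

#' Cast probe rays through the lattice
#'
#' Each element's ray is traversed voxel-by-voxel from the probe face to
#' the imaging depth. Voxels before the first bone voxel on a ray are
#' insonified; the first bone voxel and those behind it are shadowed. A
#' voxel reached unblocked by any ray counts as insonified, not shadowed;
#' each lattice cell counts once per step.
#'
#' @param pose A `probe_pose`.
#' @param grid A `voxel_grid`.
#' @param probe A [probe_model()].
#' @return List with logical arrays `ins` and `shadow` (disjoint), counts
#'   `n_ins`, `n_shadow`, `N_t` (= `n_ins + n_shadow`, the total scanned
#'   volume), and `covered` (logical array: insonified target voxels).
#' @export
cast_rays <- function(pose, grid, probe = probe_model()) {
  offs <- seq(-probe$footprint_length / 2, probe$footprint_length / 2,
              by = probe$ray_spacing)
  origins <- matrix(pose$contact_point, length(offs), 3L, byrow = TRUE) +
    outer(offs, pose$long_axis)
  res <- cast_rays_cpp(origins, pose$centerline, grid$origin, grid$res,
                       grid$dims, as.integer(grid$bone), probe$imaging_depth)
  ins <- array(res$ins == 1L, grid$dims)
  shadow <- array(res$shadow == 1L, grid$dims) & !ins
  n_ins <- sum(ins)
  n_shadow <- sum(shadow)
  list(ins = ins, shadow = shadow, n_ins = n_ins, n_shadow = n_shadow,
       N_t = n_ins + n_shadow, covered = ins & grid$target)
}

#' Stack the three most recent grids into the 9-channel state tensor
#'
#' @param history List of 3 `voxel_grid`s, oldest first.
#' @return Binary array of dimension 9 x 30 x 30 x 30 (channel order:
#'   target, bone, insonified per time slot, oldest first).
#' @export
state_tensor <- function(history) {
  stopifnot(length(history) == 3L)
  d <- history[[1L]]$dims
  out <- array(0L, c(9L, d))
  for (s in 1:3) {
    g <- history[[s]]
    out[3L * s - 2L, , , ] <- g$target
    out[3L * s - 1L, , , ] <- g$bone
    out[3L * s, , , ] <- g$ins
  }
  out
}
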