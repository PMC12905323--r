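# Synthetic thoracic phantoms and ingestion of segmented anatomy.
#
# An AnatomyScene holds the three structures the planner needs: the skin
# surface (probe placement), the rib cage (acoustic obstacles) and one or
# more target volumes. Synthetic phantoms model the ribs as capsules swept
# along partial circular arcs around the torso axis, which makes the
# intercostal gap width an exact, configurable quantity.

# evaluate expr under a fixed seed without disturbing the caller's RNG
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Construct an anatomy scene
#'
#' @param skin A shape with a closed surface (skin).
#' @param bones List of bone shapes.
#' @param targets List of target shapes.
#' @param frame_id Text label for the world frame.
#' @param provenance List describing origin (seed record or file paths).
#' @return An object of class `anatomy_scene`.
#' @export
anatomy_scene <- function(skin, bones, targets, frame_id = "world",
                          provenance = list()) {
  structure(list(skin = skin, bones = bones, targets = targets,
                 frame_id = frame_id, provenance = provenance),
            class = "anatomy_scene")
}

#' @export
print.anatomy_scene <- function(x, ...) {
  cat("<anatomy_scene>", x$frame_id, "\n",
      " bones:", length(x$bones), "\n",
      " targets:", length(x$targets),
      sprintf("(%.2f cm^3 total)\n",
              sum(vapply(x$targets, shape_volume, numeric(1)))))
  invisible(x)
}

#' Phantom configuration
#'
#' Geometry of the synthetic thorax. The intercostal gap is the bone-free
#' distance between the surfaces of adjacent ribs, so rib centerlines are
#' spaced `intercostal_gap + 2 * rib_radius` apart.
#'
#' @param n_ribs Number of ribs.
#' @param rib_radius Rib half-thickness (mm).
#' @param intercostal_gap Bone-free gap between adjacent rib surfaces (mm);
#'   anatomically down to 10 mm.
#' @param torso_radius Radius of the rib-centerline cylinder (mm).
#' @param torso_height Axial extent of the phantom (mm).
#' @param skin_offset Skin stand-off above the outer rib surface (mm).
#' @param rib_span Angular span of each rib arc in degrees
#'   (0 = anterior midline, increasing to the patient's left).
#' @param n_targets Number of targets, 1-3.
#' @param size_class One of "small", "medium", "large", or NULL when
#'   `volume_range` is given.
#' @param volume_range Optional explicit target-volume range (cm^3).
#' @param seed Integer seed; the generator is deterministic given the config.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(n_ribs = 5L, rib_radius = 5, intercostal_gap = 20,
                           torso_radius = 80, torso_height = 170,
                           skin_offset = 10, rib_span = c(-80, 80),
                           n_targets = 1L, size_class = "medium",
                           volume_range = NULL, seed = 1L) {
  stopifnot(intercostal_gap > 0, n_targets %in% 1:3, n_ribs >= 2L,
            rib_radius > 0, torso_radius > rib_radius, skin_offset > 0)
  if (is.null(volume_range)) {
    stopifnot(size_class %in% c("small", "medium", "large"))
    volume_range <- switch(size_class,
                           small = c(1.5, 3.9),
                           medium = c(4, 13.5),
                           large = c(13.5, 25))
  }
  structure(list(n_ribs = as.integer(n_ribs), rib_radius = rib_radius,
                 intercostal_gap = intercostal_gap,
                 torso_radius = torso_radius, torso_height = torso_height,
                 skin_offset = skin_offset, rib_span = rib_span,
                 n_targets = as.integer(n_targets), size_class = size_class,
                 volume_range = volume_range, seed = as.integer(seed)),
            class = "phantom_config")
}

# deterministic interior samples of an ellipsoid (for intersection tests)
.ellipsoid_samples <- function(e, n = 400L) {
  i <- seq_len(n)
  # Fibonacci sphere directions; radii stratified as u^(1/3) with a
  # golden-ratio scramble so radius is decorrelated from direction
  phi <- (1 + sqrt(5)) / 2
  z <- 1 - 2 * (i - 0.5) / n
  r <- sqrt(pmax(0, 1 - z^2))
  th <- 2 * pi * i / phi
  dirs <- cbind(r * cos(th), r * sin(th), z)
  rad <- ((i / phi) %% 1)^(1 / 3)
  rad[n] <- 1                              # guarantee surface coverage
  loc <- dirs * rad
  sweep(loc %*% diag(e$semi) %*% t(e$rot), 2L, e$center, "+")
}

.point_in_bones <- function(bones, pts) {
  inside <- rep(FALSE, nrow(pts))
  for (b in bones) inside <- inside | shape_inside(b, pts)
  inside
}

.random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to a proper rotation
  m <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(m)
  q <- qr.Q(qr_)
  q <- q %*% diag(sign(diag(qr.R(qr_))))
  if (det(q) < 0) q[, 3] <- -q[, 3]
  q
}

.sample_ellipsoid_target <- function(volume_range, region, bones, skin,
                                     existing = list(), max_attempts = 1000L) {
  for (attempt in seq_len(max_attempts)) {
    vol <- runif(1, volume_range[1L], volume_range[2L])        # cm^3
    r0 <- (3 * vol * 1000 / (4 * pi))^(1 / 3)                  # mm
    f <- runif(3, 0.7, 1.3)
    f <- f / prod(f)^(1 / 3)                                   # product 1
    semi <- r0 * f
    rot <- .random_rotation()
    rho <- runif(1, region$rho_range[1L], region$rho_range[2L])
    th <- runif(1, region$theta_range[1L], region$theta_range[2L]) * pi / 180
    z <- runif(1, region$z_range[1L], region$z_range[2L])
    center <- c(region$cx + rho * cos(th), region$cy + rho * sin(th), z)
    e <- ellipsoid(center, semi, rot)
    pts <- .ellipsoid_samples(e)
    if (any(.point_in_bones(bones, pts))) next
    if (!all(shape_inside(skin, pts))) next
    clash <- FALSE
    for (t2 in existing) {
      if (any(shape_inside(t2, pts)) ||
          any(shape_inside(e, .ellipsoid_samples(t2)))) { clash <- TRUE; break }
    }
    if (clash) next
    return(e)
  }
  stop("target placement failed after ", max_attempts,
       " rejection-sampling attempts; target cannot fit")
}

# region beneath the ribs in which target centers are sampled
.phantom_region <- function(config) {
  spacing <- config$intercostal_gap + 2 * config$rib_radius
  z0 <- (config$torso_height - spacing * (config$n_ribs - 1L)) / 2
  z1 <- z0 + spacing * (config$n_ribs - 1L)
  inner <- config$torso_radius - config$rib_radius
  list(cx = 0, cy = 0,
       rho_range = c(0.25, 0.72) * inner,
       theta_range = config$rib_span + c(15, -15),
       z_range = c(z0, z1),
       rib_z = seq(z0, z1, by = spacing))
}

#' Generate a synthetic thoracic phantom
#'
#' Builds a partial rib cage (capsule arcs around the torso axis at the
#' configured gap width), an enclosing cylindrical skin, and 1-3 ellipsoidal
#' targets beneath the ribs, rejection-sampled to intersect no bone.
#' Deterministic for a fixed config (including seed).
#'
#' @param config A [phantom_config()].
#' @return An [anatomy_scene()].
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  region <- .phantom_region(config)
  bones <- lapply(region$rib_z, function(z)
    rib_arc(0, 0, z, config$torso_radius, config$rib_radius,
            config$rib_span))
  skin <- cylinder_skin(0, 0,
                        config$torso_radius + config$rib_radius +
                          config$skin_offset,
                        c(0, config$torso_height))
  targets <- with_seed(config$seed, {
    out <- list()
    for (i in seq_len(config$n_targets))
      out[[i]] <- .sample_ellipsoid_target(config$volume_range, region,
                                           bones, skin, existing = out)
    out
  })
  anatomy_scene(skin, bones, targets, frame_id = "phantom",
                provenance = list(kind = "synthetic", config = unclass(config)))
}

#' Re-place targets in an existing scene
#'
#' Returns a copy of the scene whose targets are replaced by `n` freshly
#' sampled ellipsoids beneath the ribs (no bone intersection, pairwise
#' disjoint). This is what an episode reset calls when target randomization
#' is requested.
#'
#' @param scene An [anatomy_scene()].
#' @param n Number of targets (1-3).
#' @param size_class "small", "medium" or "large".
#' @param seed Integer seed.
#' @param volume_range Optional explicit volume range (cm^3), overrides
#'   `size_class`.
#' @return A new [anatomy_scene()].
#' @export
place_targets <- function(scene, n, size_class = "medium", seed = 1L,
                          volume_range = NULL) {
  stopifnot(inherits(scene, "anatomy_scene"), n %in% 1:3)
  if (is.null(volume_range))
    volume_range <- switch(size_class, small = c(1.5, 3.9),
                           medium = c(4, 13.5), large = c(13.5, 25),
                           stop("unknown size class: ", size_class))
  cfg <- scene$provenance$config
  region <- if (!is.null(cfg)) .phantom_region(do.call(phantom_config, cfg[
    setdiff(names(cfg), c("n_targets", "size_class", "volume_range"))]))
  else {
    bb <- Reduce(function(a, b) rbind(pmin(a[1, ], b[1, ]),
                                      pmax(a[2, ], b[2, ])),
                 lapply(scene$bones, shape_bbox))
    ctr <- colMeans(bb)
    list(cx = ctr[1L], cy = ctr[2L],
         rho_range = c(0.1, 0.6) * max(bb[2, 1:2] - ctr[1:2]),
         theta_range = c(-180, 180),
         z_range = bb[, 3L] + c(0.15, -0.15) * diff(bb[, 3L]))
  }
  targets <- with_seed(seed, {
    out <- list()
    for (i in seq_len(n))
      out[[i]] <- .sample_ellipsoid_target(volume_range, region,
                                           scene$bones, scene$skin,
                                           existing = out)
    out
  })
  prov <- scene$provenance
  prov$placement <- list(seed = seed, n = n, size_class = size_class)
  anatomy_scene(scene$skin, scene$bones, targets, scene$frame_id, prov)
}

# --- scene ingestion --------------------------------------------------------

.read_mesh_checked <- function(path, role) {
  m <- switch(tolower(tools::file_ext(path)),
              stl = read_stl(path),
              ply = read_ply(path),
              stop("unsupported mesh format for ", role, ": ", path))
  if (!mesh_is_watertight(m))
    stop("surface mesh is not watertight: ", m$name, " (", role, ")")
  m
}

#' Load a scene from segmentation files
#'
#' Either watertight STL/PLY surface meshes for the skin, bones and each
#' target, or a single NIfTI label map (then pass `label_map` and `labels`).
#' All inputs must be in millimetres.
#'
#' @param skin_path Skin surface mesh path (ignored when `label_map` given).
#' @param bone_path Path(s) to bone surface meshes.
#' @param target_paths Character vector of target mesh paths.
#' @param label_map Optional path to a NIfTI label volume.
#' @param labels Named integer vector with entries `skin`, `bone`, `target`
#'   giving label values in the map.
#' @return An [anatomy_scene()].
#' @export
load_scene <- function(skin_path = NULL, bone_path = NULL,
                       target_paths = NULL, label_map = NULL,
                       labels = c(skin = 1L, bone = 2L, target = 3L)) {
  if (!is.null(label_map)) {
    return(.load_scene_nifti(label_map, labels))
  }
  skin <- .read_mesh_checked(skin_path, "skin")
  bones <- lapply(bone_path, .read_mesh_checked, role = "bone")
  targets <- lapply(target_paths, .read_mesh_checked, role = "target")
  anatomy_scene(skin, bones, targets, frame_id = "loaded",
                provenance = list(kind = "files", skin = skin_path,
                                  bones = bone_path, targets = target_paths))
}

# occupancy-predicate shape over a NIfTI label volume
label_shape <- function(arr, voxdim, origin, label, name = "label") {
  structure(list(arr = arr, voxdim = voxdim, origin = origin,
                 label = as.integer(label), name = name),
            class = c("label_shape", "icuplan_shape"))
}

#' @export
shape_inside.label_shape <- function(shape, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3L)
  idx <- sweep(sweep(pts, 2L, shape$origin), 2L, shape$voxdim, "/")
  ijk <- floor(idx) + 1L
  d <- dim(shape$arr)
  ok <- ijk[, 1L] >= 1 & ijk[, 1L] <= d[1L] &
    ijk[, 2L] >= 1 & ijk[, 2L] <= d[2L] &
    ijk[, 3L] >= 1 & ijk[, 3L] <= d[3L]
  out <- rep(FALSE, nrow(pts))
  if (any(ok))
    out[ok] <- shape$arr[cbind(ijk[ok, 1L], ijk[ok, 2L], ijk[ok, 3L])] ==
      shape$label
  out
}

#' @export
shape_volume.label_shape <- function(shape) {
  sum(shape$arr == shape$label) * prod(shape$voxdim) / 1000
}

#' @export
shape_bbox.label_shape <- function(shape) {
  w <- which(shape$arr == shape$label, arr.ind = TRUE)
  if (!nrow(w)) stop("label ", shape$label, " absent from volume")
  lo <- shape$origin + (apply(w, 2L, min) - 1L) * shape$voxdim
  hi <- shape$origin + apply(w, 2L, max) * shape$voxdim
  rbind(lo, hi)
}

#' @export
shape_ray.label_shape <- function(shape, origin, dir) {
  d <- .unit(dir)
  step <- min(shape$voxdim) / 4
  tmax <- sqrt(sum((dim(shape$arr) * shape$voxdim)^2)) +
    sqrt(sum((origin - shape$origin)^2))
  ts <- seq(0, tmax, by = step)
  pts <- matrix(origin, length(ts), 3L, byrow = TRUE) + outer(ts, d)
  ins <- shape_inside(shape, pts)
  i <- which(ins)[1L]
  if (is.na(i) || i == 1L) return(NULL)
  t0 <- ts[i]
  p <- origin + t0 * d
  # normal from the local occupancy gradient
  h <- min(shape$voxdim)
  g <- vapply(1:3, function(k) {
    e <- numeric(3); e[k] <- h
    mean(shape_inside(shape, rbind(p + e))) -
      mean(shape_inside(shape, rbind(p - e)))
  }, numeric(1))
  n <- if (sqrt(sum(g^2)) < 1e-9) -d else -.unit(g)
  if (sum(n * d) > 0) n <- -n
  list(t = t0, point = p, normal = n)
}

.load_scene_nifti <- function(label_map, labels) {
  img <- RNifti::readNifti(label_map)
  hdr <- RNifti::niftiHeader(img)
  if (bitwAnd(hdr$xyzt_units, 7L) == 1L)
    stop("NIfTI spatial units are metres; inputs must be millimetres: ",
         label_map)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) stop("label map must be a 3D volume")
  voxdim <- abs(hdr$pixdim[2:4])
  origin <- c(0, 0, 0)  # voxel (1,1,1) corner at the world origin
  mk <- function(role) label_shape(arr, voxdim, origin, labels[[role]],
                                   name = paste0(role, ":", label_map))
  targets <- list(mk("target"))
  anatomy_scene(mk("skin"), list(mk("bone")), targets,
                frame_id = "nifti",
                provenance = list(kind = "nifti", path = label_map,
                                  labels = as.list(labels)))
}

#' Write a reproducibility manifest for a scene
#'
#' Records provenance (generator config and seed, or source files with MD5
#' hashes) so the scene can be regenerated or re-loaded exactly.
#'
#' @param scene An [anatomy_scene()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_scene_manifest <- function(scene, path) {
  prov <- scene$provenance
  if (identical(prov$kind, "files")) {
    files <- unlist(prov[c("skin", "bones", "targets")])
    prov$md5 <- as.list(tools::md5sum(files))
  }
  man <- list(frame_id = scene$frame_id,
              n_bones = length(scene$bones),
              n_targets = length(scene$targets),
              target_volumes_cm3 = vapply(scene$targets, shape_volume,
                                          numeric(1)),
              provenance = prov)
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# dense point sample of the bone surfaces/volumes (cylinder fitting input)
scene_bone_points <- function(scene, n_per_bone = 200L) {
  do.call(rbind, lapply(scene$bones, function(b) {
    if (inherits(b, "rib_arc")) {
      th <- seq(b$theta_range[1L], b$theta_range[2L], length.out = n_per_bone)
      r_out <- b$arc_radius + b$tube_radius
      cbind(b$cx + r_out * cos(th * pi / 180),
            b$cy + r_out * sin(th * pi / 180), b$z)
    } else if (inherits(b, "mesh_shape")) {
      v <- b$vertices
      v[seq(1L, nrow(v), length.out = min(nrow(v), n_per_bone)), ,
        drop = FALSE]
    } else if (inherits(b, "label_shape")) {
      w <- which(b$arr == b$label, arr.ind = TRUE)
      w <- w[seq(1L, nrow(w), length.out = min(nrow(w), n_per_bone)), ,
             drop = FALSE]
      sweep((w - 0.5) %*% diag(b$voxdim), 2L, b$origin, "+")
    } else stop("cannot sample points from bone of class ", class(b)[1L])
  }))
}
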