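# Cylindrical probe coordinates. A minimum bounding cylinder is fitted to
# the rib cage with its axis fixed to the longitudinal body axis (patients
# lie supine; the cylinder of interest is axis-aligned). Probe surface
# coordinates are (h, theta): height along and angle around that axis,
# theta = 0 at the anterior midline increasing towards the patient's left.
# Inter-patient size differences are removed by an anisotropic affine map
# onto a generic cylinder (radius/height below); trajectories map back via
# the exact inverse.

GENERIC_RADIUS <- 100   # mm, generic cylinder radius
GENERIC_HEIGHT <- 200   # mm, generic cylinder height

# --- minimal enclosing circle (Welzl, move-to-front) ------------------------

.circ_contains <- function(circ, p, tol = 1e-7) {
  sqrt(sum((p - circ$center)^2)) <= circ$r * (1 + tol) + tol
}

.circ2 <- function(a, b) list(center = (a + b) / 2,
                              r = sqrt(sum((a - b)^2)) / 2)

.circ3 <- function(a, b, c) {
  d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) +
              c[1] * (a[2] - b[2]))
  if (abs(d) < 1e-12) {
    # collinear: fall back to the widest 2-point circle
    cands <- list(.circ2(a, b), .circ2(a, c), .circ2(b, c))
    return(cands[[which.max(vapply(cands, `[[`, numeric(1), "r"))]])
  }
  ux <- (sum(a^2) * (b[2] - c[2]) + sum(b^2) * (c[2] - a[2]) +
           sum(c^2) * (a[2] - b[2])) / d
  uy <- (sum(a^2) * (c[1] - b[1]) + sum(b^2) * (a[1] - c[1]) +
           sum(c^2) * (b[1] - a[1])) / d
  ctr <- c(ux, uy)
  list(center = ctr, r = sqrt(sum((a - ctr)^2)))
}

minimal_enclosing_circle <- function(P) {
  P <- P[with_seed(7L, sample(nrow(P))), , drop = FALSE]
  n <- nrow(P)
  circ <- list(center = P[1L, ], r = 0)
  for (i in seq_len(n)) {
    if (.circ_contains(circ, P[i, ])) next
    circ <- list(center = P[i, ], r = 0)
    for (j in seq_len(i - 1L)) {
      if (.circ_contains(circ, P[j, ])) next
      circ <- .circ2(P[i, ], P[j, ])
      for (k in seq_len(j - 1L)) {
        if (.circ_contains(circ, P[k, ])) next
        circ <- .circ3(P[i, ], P[j, ], P[k, ])
      }
    }
  }
  circ
}

# --- cylindrical frame ------------------------------------------------------

#' Fit the bounding cylinder of the rib cage
#'
#' The cylinder axis is fixed to `axis_dir` (the longitudinal body axis);
#' the radius is the minimal enclosing circle of the bone points projected
#' onto the plane normal to the axis, and the height range spans their
#' projected extent.
#'
#' @param bone_points n x 3 matrix of points on the rib cage (mm), n >= 10.
#' @param axis_dir Cylinder axis direction (default +z, cranio-caudal).
#' @param generic_radius,generic_height Generic cylinder dimensions (mm)
#'   used by [to_generic()].
#' @return An object of class `cyl_frame` with fields `axis_point`,
#'   `axis_dir`, `u`, `v` (in-plane basis, `u` anterior), `R_c`, `h_range`.
#' @export
fit_cylinder <- function(bone_points, axis_dir = c(0, 0, 1),
                         generic_radius = GENERIC_RADIUS,
                         generic_height = GENERIC_HEIGHT) {
  stopifnot(is.matrix(bone_points), ncol(bone_points) == 3L,
            nrow(bone_points) >= 10L)
  a <- .unit(axis_dir)
  # in-plane orthonormal basis; u is the anterior (+x) direction projected
  u0 <- c(1, 0, 0) - sum(c(1, 0, 0) * a) * a
  if (sqrt(sum(u0^2)) < 1e-9) u0 <- c(0, 1, 0) - sum(c(0, 1, 0) * a) * a
  u <- .unit(u0)
  v <- c(a[2] * u[3] - a[3] * u[2], a[3] * u[1] - a[1] * u[3],
         a[1] * u[2] - a[2] * u[1])   # v = a x u, right-handed (u, v, a)
  P <- cbind(bone_points %*% u, bone_points %*% v)
  h <- as.numeric(bone_points %*% a)
  if (max(apply(P, 2L, function(x) diff(range(x)))) < 1e-9)
    stop("degenerate bone points: all on the cylinder axis")
  circ <- minimal_enclosing_circle(P)
  if (circ$r <= 0) stop("degenerate bone points: zero enclosing radius")
  axis_point <- circ$center[1L] * u + circ$center[2L] * v
  structure(list(axis_point = as.numeric(axis_point), axis_dir = a,
                 u = u, v = as.numeric(v), R_c = circ$r,
                 h_range = range(h),
                 generic_radius = generic_radius,
                 generic_height = generic_height),
            class = "cyl_frame")
}

.radial_dir <- function(frame, theta_deg) {
  th <- theta_deg * pi / 180
  cos(th) * frame$u + sin(th) * frame$v
}

#' Map points or poses to the generic cylinder scale
#'
#' Anisotropic affine: radial components scale by
#' `generic_radius / R_c`, axial by `generic_height / diff(h_range)`, with
#' `h = h_range[1]` mapped to generic height 0. Output coordinates are in
#' the generic frame (axis through the origin along +z).
#'
#' @param frame A `cyl_frame`.
#' @param x Either an n x 3 point matrix (mm, world frame) or a list/pose
#'   with fields `h` and `theta`.
#' @return Same kind as `x`, in generic scale.
#' @export
to_generic <- function(frame, x) {
  s_r <- frame$generic_radius / frame$R_c
  s_h <- frame$generic_height / diff(frame$h_range)
  if (is.matrix(x)) {
    rel <- sweep(x, 2L, frame$axis_point)
    h <- as.numeric(rel %*% frame$axis_dir)
    cbind((rel %*% frame$u) * s_r, (rel %*% frame$v) * s_r,
          (h - frame$h_range[1L]) * s_h)
  } else if (is.list(x) && !is.null(x$h)) {
    x$h <- (x$h - frame$h_range[1L]) * s_h
    x
  } else stop("to_generic: unsupported input")
}

#' Inverse of [to_generic()]
#' @inheritParams to_generic
#' @return Same kind as `x`, in patient scale (world frame for points).
#' @export
from_generic <- function(frame, x) {
  s_r <- frame$generic_radius / frame$R_c
  s_h <- frame$generic_height / diff(frame$h_range)
  if (is.matrix(x)) {
    h <- x[, 3L] / s_h + frame$h_range[1L]
    matrix(frame$axis_point, nrow(x), 3L, byrow = TRUE) +
      outer(x[, 1L] / s_r, frame$u) + outer(x[, 2L] / s_r, frame$v) +
      outer(h, frame$axis_dir)
  } else if (is.list(x) && !is.null(x$h)) {
    x$h <- x$h / s_h + frame$h_range[1L]
    x
  } else stop("from_generic: unsupported input")
}

#' Project a cylinder-surface coordinate onto the skin
#'
#' Casts the inward radial ray from cylinder point (h, theta) and returns
#' the first skin intersection and its outward normal. A miss (probe off
#' the body) returns `NULL`; the environment treats that action as invalid.
#'
#' @param h Height along the cylinder axis (mm, patient scale).
#' @param theta Angle around the axis (degrees).
#' @param frame A `cyl_frame`.
#' @param skin Skin shape.
#' @return List with `contact_point`, `skin_normal`, or `NULL` off-surface.
#' @export
surface_project <- function(h, theta, frame, skin) {
  rhat <- .radial_dir(frame, theta)
  bb <- shape_bbox(skin)
  r_start <- max(frame$R_c, max(abs(bb))) * 2 + 10
  origin <- frame$axis_point + h * frame$axis_dir + r_start * rhat
  hit <- shape_ray(skin, origin, -rhat)
  if (is.null(hit)) return(NULL)
  list(contact_point = as.numeric(hit$point),
       skin_normal = as.numeric(hit$normal))
}

#' Construct a probe pose
#'
#' The probe centerline starts at the inward skin normal; the long axis
#' starts along the circumferential tangent of the cylinder. `phi` rotates
#' the long axis about the skin normal, then `psi` tilts the centerline
#' about the rotated long axis. The tilt angle (centerline vs inward
#' normal) is evaluated in patient space; poses beyond `tilt_limit` are
#' flagged terminal.
#'
#' @param h,theta,phi,psi Pose coordinates (mm, degrees).
#' @param frame A `cyl_frame`.
#' @param skin Skin shape.
#' @param adj Readjusting-mode flag carried on the pose.
#' @param tilt_limit Maximum tilt in degrees (default 20).
#' @return A `probe_pose`, or `NULL` when (h, theta) is off the surface.
#' @export
build_pose <- function(h, theta, phi = 0, psi = 0, frame, skin,
                       adj = FALSE, tilt_limit = 20) {
  proj <- surface_project(h, theta, frame, skin)
  if (is.null(proj)) return(NULL)
  n_out <- proj$skin_normal
  center0 <- -n_out
  # circumferential tangent, projected into the plane normal to center0
  that <- -sin(theta * pi / 180) * frame$u + cos(theta * pi / 180) * frame$v
  long0 <- that - sum(that * center0) * center0
  if (sqrt(sum(long0^2)) < 1e-9) long0 <- frame$axis_dir
  long0 <- .unit(long0)
  long1 <- as.numeric(rotation_about(n_out, phi) %*% long0)
  center1 <- as.numeric(rotation_about(long1, psi) %*% center0)
  tilt <- acos(pmin(1, pmax(-1, sum(center1 * center0)))) * 180 / pi
  structure(list(h = h, theta = theta, phi = phi, psi = psi, adj = adj,
                 contact_point = proj$contact_point,
                 centerline = center1, long_axis = long1,
                 skin_normal = n_out, tilt = tilt,
                 terminal_tilt = tilt > tilt_limit + 1e-9),
            class = "probe_pose")
}

#' 4x4 world transform of a probe pose
#'
#' Columns: long axis, short axis (centerline x long axis), centerline,
#' contact point.
#' @param pose A `probe_pose`.
#' @return 4x4 numeric matrix.
#' @export
pose_transform <- function(pose) {
  short <- c(pose$centerline[2] * pose$long_axis[3] -
               pose$centerline[3] * pose$long_axis[2],
             pose$centerline[3] * pose$long_axis[1] -
               pose$centerline[1] * pose$long_axis[3],
             pose$centerline[1] * pose$long_axis[2] -
               pose$centerline[2] * pose$long_axis[1])
  m <- diag(4)
  m[1:3, 1L] <- pose$long_axis
  m[1:3, 2L] <- short
  m[1:3, 3L] <- pose$centerline
  m[1:3, 4L] <- pose$contact_point
  m
}

#' Serialize a pose to a JSON record
#' @param pose A `probe_pose`.
#' @return JSON string.
#' @export
pose_to_json <- function(pose) {
  jsonlite::toJSON(list(h = pose$h, theta = pose$theta, phi = pose$phi,
                        psi = pose$psi, adj = pose$adj,
                        transform = pose_transform(pose)),
                   auto_unbox = TRUE, digits = NA)
}
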