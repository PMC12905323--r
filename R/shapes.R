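#' @useDynLib icuplan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rnorm sd setNames
#' @importFrom utils head tail modifyList read.csv write.csv
NULL

# ---------------------------------------------------------------------------
# Geometric primitives. All coordinates are millimetres in a right-handed
# world frame: +z cranio-caudal (the torso axis), +x anterior. Volumes are
# reported in cm^3 (1 mm^3 = 1e-3 cm^3). Shapes expose four generics:
# inside-test, exact volume, first-hit ray intersection, and bounding box.
# ---------------------------------------------------------------------------

#' Point-inclusion test for a shape
#'
#' @param shape A shape object (`ellipsoid`, `rib_arc`, `cylinder_skin`,
#'   `mesh_shape`).
#' @param pts Numeric matrix with one point per row (x, y, z in mm), or a
#'   single point as a length-3 vector.
#' @return Logical vector, one entry per point.
#' @export
shape_inside <- function(shape, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3L)
  stopifnot(ncol(pts) == 3L)
  UseMethod("shape_inside")
}

#' Exact volume of a shape in cm^3
#' @param shape A shape object.
#' @return Volume in cm^3.
#' @export
shape_volume <- function(shape) UseMethod("shape_volume")

#' First intersection of a ray with a shape's surface
#'
#' @param shape A shape object.
#' @param origin Ray origin (mm).
#' @param dir Ray direction (normalized internally).
#' @return `NULL` if the ray misses, else a list with `t` (distance in mm),
#'   `point` (hit location) and `normal` (outward unit surface normal).
#' @export
shape_ray <- function(shape, origin, dir) UseMethod("shape_ray")

#' Axis-aligned bounding box of a shape
#' @param shape A shape object.
#' @return 2 x 3 matrix: rows are (min, max), columns (x, y, z) in mm.
#' @export
shape_bbox <- function(shape) UseMethod("shape_bbox")

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("zero-length vector cannot be normalized")
  v / n
}

# Rodrigues rotation matrix: rotate about unit axis by angle in degrees.
rotation_about <- function(axis, deg) {
  a <- .unit(axis)
  th <- deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# --- ellipsoid --------------------------------------------------------------

#' Ellipsoidal target volume
#'
#' The canonical synthetic scanning target: closed-form volume and inside
#' test. `rot` maps local (principal-axis) coordinates to world coordinates.
#'
#' @param center Length-3 center (mm).
#' @param semi Length-3 semi-axes (mm).
#' @param rot 3x3 rotation matrix (world from local). Default identity.
#' @return An object of class `ellipsoid`.
#' @export
ellipsoid <- function(center, semi, rot = diag(3)) {
  stopifnot(length(center) == 3L, length(semi) == 3L, all(semi > 0))
  structure(list(center = as.numeric(center), semi = as.numeric(semi),
                 rot = rot), class = c("ellipsoid", "icuplan_shape"))
}

#' @export
shape_inside.ellipsoid <- function(shape, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3L)
  d <- sweep(pts, 2L, shape$center)
  loc <- d %*% shape$rot            # rows: t(rot) %*% d
  q <- sweep(loc, 2L, shape$semi, "/")
  rowSums(q^2) <= 1
}

#' @export
shape_volume.ellipsoid <- function(shape) {
  (4 / 3) * pi * prod(shape$semi) / 1000
}

#' @export
shape_bbox.ellipsoid <- function(shape) {
  # extent along world axis i: sqrt(sum_j (R[i,j] * s_j)^2)
  ext <- sqrt(rowSums(sweep(shape$rot, 2L, shape$semi, "*")^2))
  rbind(shape$center - ext, shape$center + ext)
}

#' @export
shape_ray.ellipsoid <- function(shape, origin, dir) {
  # map the ray into the unit-sphere frame
  d <- .unit(dir)
  o <- as.numeric((origin - shape$center) %*% shape$rot) / shape$semi
  v <- as.numeric(d %*% shape$rot) / shape$semi
  a <- sum(v^2); b <- 2 * sum(o * v); cc <- sum(o^2) - 1
  disc <- b^2 - 4 * a * cc
  if (disc < 0) return(NULL)
  ts <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  ts <- ts[ts > 1e-9]
  if (!length(ts)) return(NULL)
  t0 <- min(ts)
  p <- origin + t0 * d
  loc <- as.numeric((p - shape$center) %*% shape$rot)
  n <- .unit(shape$rot %*% (loc / shape$semi^2))
  list(t = t0, point = p, normal = as.numeric(n))
}

# --- rib arc (capsule swept along a circular arc) ---------------------------

#' Rib modelled as a capsule swept along a circular arc
#'
#' A tube of radius `tube_radius` whose centerline is the circular arc of
#' radius `arc_radius` around the vertical axis through `(cx, cy)`, at height
#' `z`, spanning `theta_range` degrees (theta = 0 anterior, i.e. +x,
#' increasing towards +y). The swept capsule has rounded ends.
#'
#' @param cx,cy Axis position (mm).
#' @param z Height of the arc plane (mm).
#' @param arc_radius Radius of the centerline arc (mm).
#' @param tube_radius Rib half-thickness (mm).
#' @param theta_range Length-2 angular span in degrees, width < 360.
#' @return An object of class `rib_arc`.
#' @export
rib_arc <- function(cx, cy, z, arc_radius, tube_radius,
                    theta_range = c(-80, 80)) {
  stopifnot(arc_radius > 0, tube_radius > 0,
            diff(theta_range) > 0, diff(theta_range) < 360)
  structure(list(cx = cx, cy = cy, z = z, arc_radius = arc_radius,
                 tube_radius = tube_radius, theta_range = theta_range),
            class = c("rib_arc", "icuplan_shape"))
}

# distance from points to the centerline arc
.arc_dist <- function(shape, pts) {
  dx <- pts[, 1L] - shape$cx
  dy <- pts[, 2L] - shape$cy
  th <- atan2(dy, dx) * 180 / pi
  t0 <- shape$theta_range[1L]; t1 <- shape$theta_range[2L]
  # wrap th into [t0 - 180, t0 + 180) relative window, then clamp
  rel <- (th - t0) %% 360
  rel[rel > 180 + (t1 - t0) / 2] <- rel[rel > 180 + (t1 - t0) / 2] - 360
  thc <- pmin(pmax(rel, 0), t1 - t0) + t0
  ax <- shape$cx + shape$arc_radius * cos(thc * pi / 180)
  ay <- shape$cy + shape$arc_radius * sin(thc * pi / 180)
  sqrt((pts[, 1L] - ax)^2 + (pts[, 2L] - ay)^2 + (pts[, 3L] - shape$z)^2)
}

#' @export
shape_inside.rib_arc <- function(shape, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3L)
  .arc_dist(shape, pts) <= shape$tube_radius
}

#' @export
shape_volume.rib_arc <- function(shape) {
  # torus segment + two hemispherical caps (exact for arc_radius > tube_radius)
  frac <- diff(shape$theta_range) / 360
  torus <- 2 * pi^2 * shape$arc_radius * shape$tube_radius^2 * frac
  caps <- (4 / 3) * pi * shape$tube_radius^3
  (torus + caps) / 1000
}

#' @export
shape_bbox.rib_arc <- function(shape) {
  r <- shape$arc_radius + shape$tube_radius
  rbind(c(shape$cx - r, shape$cy - r, shape$z - shape$tube_radius),
        c(shape$cx + r, shape$cy + r, shape$z + shape$tube_radius))
}

#' @export
shape_ray.rib_arc <- function(shape, origin, dir) {
  # bisection along the ray on the signed distance; adequate for the thin
  # tubes used here (rays that matter approach roughly radially)
  d <- .unit(dir)
  tmax <- 2 * (shape$arc_radius + shape$tube_radius) + 50
  ts <- seq(0, tmax, by = shape$tube_radius / 4)
  pts <- matrix(origin, nrow = length(ts), ncol = 3L, byrow = TRUE) +
    outer(ts, d)
  f <- .arc_dist(shape, pts) - shape$tube_radius
  idx <- which(f[-1L] <= 0 & f[-length(f)] > 0)
  if (!length(idx)) return(NULL)
  lo <- ts[idx[1L]]; hi <- ts[idx[1L] + 1L]
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    fm <- .arc_dist(shape, matrix(origin + mid * d, ncol = 3L)) -
      shape$tube_radius
    if (fm > 0) lo <- mid else hi <- mid
  }
  t0 <- (lo + hi) / 2
  p <- origin + t0 * d
  eps <- 1e-4
  g <- vapply(1:3, function(k) {
    e <- numeric(3); e[k] <- eps
    (.arc_dist(shape, matrix(p + e, ncol = 3L)) -
       .arc_dist(shape, matrix(p - e, ncol = 3L))) / (2 * eps)
  }, numeric(1))
  list(t = t0, point = p, normal = .unit(g))
}

# --- cylindrical skin -------------------------------------------------------

#' Closed cylindrical skin surface
#'
#' Analytic skin for synthetic phantoms: a capped cylinder around the
#' vertical axis through `(cx, cy)`.
#'
#' @param cx,cy Axis position (mm).
#' @param radius Skin radius (mm).
#' @param z_range Length-2 axial extent (mm).
#' @return An object of class `cylinder_skin`.
#' @export
cylinder_skin <- function(cx, cy, radius, z_range) {
  stopifnot(radius > 0, diff(z_range) > 0)
  structure(list(cx = cx, cy = cy, radius = radius,
                 z_range = as.numeric(z_range)),
            class = c("cylinder_skin", "icuplan_shape"))
}

#' @export
shape_inside.cylinder_skin <- function(shape, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3L)
  rho2 <- (pts[, 1L] - shape$cx)^2 + (pts[, 2L] - shape$cy)^2
  rho2 <= shape$radius^2 &
    pts[, 3L] >= shape$z_range[1L] & pts[, 3L] <= shape$z_range[2L]
}

#' @export
shape_volume.cylinder_skin <- function(shape) {
  pi * shape$radius^2 * diff(shape$z_range) / 1000
}

#' @export
shape_bbox.cylinder_skin <- function(shape) {
  r <- shape$radius
  rbind(c(shape$cx - r, shape$cy - r, shape$z_range[1L]),
        c(shape$cx + r, shape$cy + r, shape$z_range[2L]))
}

#' @export
shape_ray.cylinder_skin <- function(shape, origin, dir) {
  d <- .unit(dir)
  hits <- list()
  # lateral surface
  ox <- origin[1L] - shape$cx; oy <- origin[2L] - shape$cy
  a <- d[1L]^2 + d[2L]^2
  if (a > 1e-14) {
    b <- 2 * (ox * d[1L] + oy * d[2L])
    cc <- ox^2 + oy^2 - shape$radius^2
    disc <- b^2 - 4 * a * cc
    if (disc >= 0) {
      for (t0 in (-b + c(-1, 1) * sqrt(disc)) / (2 * a)) {
        if (t0 > 1e-9) {
          p <- origin + t0 * d
          if (p[3L] >= shape$z_range[1L] && p[3L] <= shape$z_range[2L]) {
            n <- .unit(c(p[1L] - shape$cx, p[2L] - shape$cy, 0))
            hits[[length(hits) + 1L]] <- list(t = t0, point = p, normal = n)
          }
        }
      }
    }
  }
  # caps
  for (i in 1:2) {
    zc <- shape$z_range[i]
    if (abs(d[3L]) > 1e-14) {
      t0 <- (zc - origin[3L]) / d[3L]
      if (t0 > 1e-9) {
        p <- origin + t0 * d
        if ((p[1L] - shape$cx)^2 + (p[2L] - shape$cy)^2 <= shape$radius^2) {
          n <- c(0, 0, if (i == 1L) -1 else 1)
          hits[[length(hits) + 1L]] <- list(t = t0, point = p, normal = n)
        }
      }
    }
  }
  if (!length(hits)) return(NULL)
  hits[[which.min(vapply(hits, `[[`, numeric(1), "t"))]]
}

# --- triangulated mesh ------------------------------------------------------

#' Triangulated surface mesh shape
#'
#' @param vertices n x 3 numeric matrix (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices; triangles
#'   should be consistently oriented with outward normals.
#' @param name Label used in error messages.
#' @return An object of class `mesh_shape`.
#' @export
mesh_shape <- function(vertices, faces, name = "mesh") {
  stopifnot(ncol(vertices) == 3L, ncol(faces) == 3L)
  storage.mode(faces) <- "integer"
  structure(list(vertices = vertices, faces = faces, name = name),
            class = c("mesh_shape", "icuplan_shape"))
}

#' Check that a mesh is watertight (closed, edge-manifold)
#'
#' Every undirected edge must be used by exactly two triangles.
#' @param mesh A `mesh_shape`.
#' @return TRUE/FALSE.
#' @export
mesh_is_watertight <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

#' @export
shape_volume.mesh_shape <- function(shape) {
  v <- shape$vertices; f <- shape$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  cc <- v[f[, 3L], , drop = FALSE]
  # signed tetrahedron volumes against the origin
  cr <- cbind(b[, 2] * cc[, 3] - b[, 3] * cc[, 2],
              b[, 3] * cc[, 1] - b[, 1] * cc[, 3],
              b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  abs(sum(rowSums(a * cr)) / 6) / 1000
}

#' @export
shape_bbox.mesh_shape <- function(shape) {
  rbind(apply(shape$vertices, 2L, min), apply(shape$vertices, 2L, max))
}

# Moeller-Trumbore over all faces; returns t values (NA where no hit).
.tri_ray_t <- function(shape, origin, d) {
  v <- shape$vertices; f <- shape$faces
  p0 <- v[f[, 1L], , drop = FALSE]
  e1 <- v[f[, 2L], , drop = FALSE] - p0
  e2 <- v[f[, 3L], , drop = FALSE] - p0
  h <- cbind(d[2] * e2[, 3] - d[3] * e2[, 2],
             d[3] * e2[, 1] - d[1] * e2[, 3],
             d[1] * e2[, 2] - d[2] * e2[, 1])
  a <- rowSums(e1 * h)
  ok <- abs(a) > 1e-12
  s <- -sweep(p0, 2L, origin)  # origin - p0
  u <- rowSums(s * h) / a
  q <- cbind(s[, 2] * e1[, 3] - s[, 3] * e1[, 2],
             s[, 3] * e1[, 1] - s[, 1] * e1[, 3],
             s[, 1] * e1[, 2] - s[, 2] * e1[, 1])
  vv <- (q[, 1] * d[1] + q[, 2] * d[2] + q[, 3] * d[3]) / a
  t0 <- rowSums(e2 * q) / a
  hit <- ok & u >= -1e-9 & vv >= -1e-9 & (u + vv) <= 1 + 1e-9 & t0 > 1e-9
  t0[!hit] <- NA_real_
  t0
}

#' @export
shape_ray.mesh_shape <- function(shape, origin, dir) {
  d <- .unit(dir)
  tt <- .tri_ray_t(shape, origin, d)
  if (all(is.na(tt))) return(NULL)
  i <- which.min(tt)
  v <- shape$vertices; f <- shape$faces
  e1 <- v[f[i, 2L], ] - v[f[i, 1L], ]
  e2 <- v[f[i, 3L], ] - v[f[i, 1L], ]
  n <- .unit(c(e1[2] * e2[3] - e1[3] * e2[2],
               e1[3] * e2[1] - e1[1] * e2[3],
               e1[1] * e2[2] - e1[2] * e2[1]))
  if (sum(n * d) > 0) n <- -n   # outward: against the incoming ray
  list(t = tt[i], point = origin + tt[i] * d, normal = n)
}

#' @export
shape_inside.mesh_shape <- function(shape, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3L)
  # parity of crossings along a fixed irrational direction
  d <- .unit(c(0.577215, 0.301029, 0.754877))
  apply(pts, 1L, function(p) {
    tt <- .tri_ray_t(shape, p, d)
    sum(!is.na(tt)) %% 2L == 1L
  })
}
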