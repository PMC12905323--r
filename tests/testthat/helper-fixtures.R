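# Shared fixtures: small meshes, canonical phantoms/scenes, scripted
# policies, and independent oracles used across the suite.

# axis-aligned box as a watertight 12-triangle mesh
box_mesh <- function(lo, hi, name = "box") {
  v <- as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                             z = c(lo[3], hi[3])))
  # vertex order: (x fastest) 1:(---) 2:(+--) 3:(-+-) 4:(++-)
  #               5:(--+) 6:(+-+) 7:(-++) 8:(+++)
  f <- rbind(c(1, 3, 2), c(2, 3, 4),    # bottom  (z-)
             c(5, 6, 7), c(6, 8, 7),    # top     (z+)
             c(1, 2, 5), c(2, 6, 5),    # front   (y-)
             c(3, 7, 4), c(4, 7, 8),    # back    (y+)
             c(1, 5, 3), c(3, 5, 7),    # left    (x-)
             c(2, 4, 6), c(4, 8, 6))    # right   (x+)
  mesh_shape(v, f, name = name)
}

# the single-gap phantom used for scaled learning checks: two ribs, one
# 30 mm intercostal gap, one small target beneath it
trivial_phantom <- function(seed = 3L) {
  phantom_config(seed = seed, n_ribs = 2L, intercostal_gap = 30,
                 size_class = "small", torso_height = 170)
}

# bone-free easy scene: cylindrical skin, one out-of-the-way rib (the
# frame fit needs bones), and one target near the skin under theta = 0
easy_scene <- function(target_center = c(55, 0, 85), semi = c(9, 9, 9)) {
  bones <- list(rib_arc(0, 0, 20, 80, 4, c(-80, 80)),
                rib_arc(0, 0, 150, 80, 4, c(-80, 80)))
  skin <- cylinder_skin(0, 0, 95, c(0, 170))
  anatomy_scene(skin, bones, list(ellipsoid(target_center, semi)),
                frame_id = "easy")
}

# scripted navigator: align theta to the target, descend below it, then
# sweep h upward; succeeds on open scenes within the step budget
make_sweeper <- function() {
  last_step <- Inf
  phase <- 1L
  h_lo <- NA_real_
  function(env) {
    if (env$steps < last_step) {
      phase <<- 1L
      h_lo <<- NA_real_
    }
    last_step <<- env$steps
    ctr <- env$centroid
    th_t <- atan2(ctr[2] - env$frame$axis_point[2],
                  ctr[1] - env$frame$axis_point[1]) * 180 / pi
    p <- env$pose
    dth <- ((th_t - p$theta + 180) %% 360) - 180
    if (phase == 1L) {
      if (abs(dth) > 2) return(if (dth > 0) 3L else 4L)
      phase <<- 2L
      h_lo <<- ctr[3] - 12
    }
    if (phase == 2L) {
      if (p$h > h_lo + env$h_step / 2) return(2L)
      phase <<- 3L
    }
    1L
  }
}

# a bare probe pose for direct ray-casting tests (bypasses the skin)
fake_pose <- function(contact, centerline, long_axis) {
  structure(list(h = NA, theta = NA, phi = 0, psi = 0, adj = FALSE,
                 contact_point = contact, centerline = .unit_v(centerline),
                 long_axis = .unit_v(long_axis), tilt = 0,
                 terminal_tilt = FALSE),
            class = "probe_pose")
}

.unit_v <- function(v) v / sqrt(sum(v^2))

# Independent ray-cast oracle: per-voxel slab intersection intervals.
# For each ray the entry/exit parameters against every voxel box are
# computed in closed form; voxels with positive chord within the imaging
# depth are ordered by entry, split at the first bone voxel.
oracle_cast <- function(pose, grid, probe) {
  dims <- grid$dims
  ncell <- prod(dims)
  ijk <- as.matrix(expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]),
                               k = seq_len(dims[3])))
  lo <- sweep((ijk - 1) * grid$res, 2, grid$origin, "+")
  hi <- lo + grid$res
  d <- .unit_v(pose$centerline)
  offs <- seq(-probe$footprint_length / 2, probe$footprint_length / 2,
              by = probe$ray_spacing)
  ins <- logical(ncell)
  shadow <- logical(ncell)
  bone <- as.logical(grid$bone)
  for (o in offs) {
    orig <- pose$contact_point + o * pose$long_axis
    tmin <- rep(0, ncell)
    tmax <- rep(probe$imaging_depth, ncell)
    ok <- rep(TRUE, ncell)
    for (k in 1:3) {
      if (abs(d[k]) < 1e-12) {
        # half-open cells: a ray on a boundary plane belongs to the
        # upper cell, matching the floor() voxel convention
        ok <- ok & orig[k] >= lo[, k] & orig[k] < hi[, k]
      } else {
        t1 <- (lo[, k] - orig[k]) / d[k]
        t2 <- (hi[, k] - orig[k]) / d[k]
        tmin <- pmax(tmin, pmin(t1, t2))
        tmax <- pmin(tmax, pmax(t1, t2))
      }
    }
    vis <- ok & (tmax - tmin > 1e-9)
    if (!any(vis)) next
    vi <- which(vis)
    ord <- vi[order(tmin[vi])]
    bpos <- which(bone[ord])[1]
    if (is.na(bpos)) {
      ins[ord] <- TRUE
    } else {
      t_block <- tmin[ord[bpos]]
      before <- tmin[ord] < t_block - 1e-12
      ins[ord[before]] <- TRUE
      shadow[ord[!before]] <- TRUE
    }
  }
  shadow <- shadow & !ins
  list(ins = array(ins, dims), shadow = array(shadow, dims),
       n_ins = sum(ins), n_shadow = sum(shadow))
}

# brute-force minimal enclosing circle over <= 50 points: try all pair
# and triple circles, keep the smallest that contains every point
oracle_mec <- function(P) {
  n <- nrow(P)
  best <- NULL
  contains_all <- function(ctr, r) all(sqrt((P[, 1] - ctr[1])^2 +
                                              (P[, 2] - ctr[2])^2) <=
                                         r + 1e-9)
  consider <- function(ctr, r) {
    if (contains_all(ctr, r) && (is.null(best) || r < best$r))
      best <<- list(center = ctr, r = r)
  }
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    ctr <- (P[i, ] + P[j, ]) / 2
    consider(ctr, sqrt(sum((P[i, ] - P[j, ])^2)) / 2)
  }
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    a <- P[i, ]; b <- P[j, ]; cc <- P[k, ]
    dd <- 2 * (a[1] * (b[2] - cc[2]) + b[1] * (cc[2] - a[2]) +
                 cc[1] * (a[2] - b[2]))
    if (abs(dd) < 1e-12) next
    ux <- (sum(a^2) * (b[2] - cc[2]) + sum(b^2) * (cc[2] - a[2]) +
             sum(cc^2) * (a[2] - b[2])) / dd
    uy <- (sum(a^2) * (cc[1] - b[1]) + sum(b^2) * (a[1] - cc[1]) +
             sum(cc^2) * (b[1] - a[1])) / dd
    consider(c(ux, uy), sqrt(sum((a - c(ux, uy))^2)))
  }
  best
}
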