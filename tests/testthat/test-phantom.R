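# Synthetic phantom generation and scene ingestion.

test_that("generation is deterministic for a fixed config", {
  cfg <- phantom_config(seed = 11, size_class = "medium")
  s1 <- generate_phantom(cfg)
  s2 <- generate_phantom(cfg)
  summ <- function(s) list(
    centers = lapply(s$targets, `[[`, "center"),
    vols = vapply(s$targets, shape_volume, numeric(1)),
    n_bones = length(s$bones))
  expect_identical(summ(s1), summ(s2))
})

test_that("target volumes respect the configured size class", {
  for (sd in 1:4) {
    small <- generate_phantom(phantom_config(seed = sd,
                                             size_class = "small"))
    vol <- shape_volume(small$targets[[1]])
    expect_lt(vol, 4)
    expect_identical(classify_size(vol), "small")
  }
  med <- generate_phantom(phantom_config(seed = 5, size_class = "medium"))
  v <- shape_volume(med$targets[[1]])
  expect_gte(v, 4)
  expect_lte(v, 13.5)
})

test_that("intercostal gap width is honoured (distance-transform sweep)", {
  cfg <- phantom_config(seed = 2, intercostal_gap = 10, n_ribs = 3L)
  sc <- generate_phantom(cfg)
  # march along the axial direction on the rib-centerline cylinder at the
  # anterior midline; the bone-free run between adjacent rib surfaces is
  # the gap
  dz <- 0.05
  z <- seq(0, cfg$torso_height, by = dz)
  pts <- cbind(cfg$torso_radius, 0, z)
  occ <- rep(FALSE, length(z))
  for (b in sc$bones) occ <- occ | shape_inside(b, pts)
  r <- rle(occ)
  runs <- r$lengths[!r$values]
  gaps <- runs[-c(1, length(runs))] * dz    # interior bone-free runs
  expect_equal(length(gaps), 2L)            # 3 ribs -> 2 gaps
  expect_true(all(abs(gaps - 10) <= 2 * dz))
})

test_that("targets are disjoint from bones and from each other", {
  cfg <- phantom_config(seed = 7, n_targets = 3L, size_class = "small")
  sc <- generate_phantom(cfg)
  expect_length(sc$targets, 3L)
  # 1 mm rasterization over each target's bounding box: no voxel flagged
  # as both target and bone, and no voxel in two targets
  for (i in seq_along(sc$targets)) {
    bb <- shape_bbox(sc$targets[[i]])
    g <- as.matrix(expand.grid(x = seq(bb[1, 1], bb[2, 1], by = 1),
                               y = seq(bb[1, 2], bb[2, 2], by = 1),
                               z = seq(bb[1, 3], bb[2, 3], by = 1)))
    inside_t <- shape_inside(sc$targets[[i]], g)
    inside_b <- rep(FALSE, nrow(g))
    for (b in sc$bones) inside_b <- inside_b | shape_inside(b, g)
    expect_equal(sum(inside_t & inside_b), 0L)
    for (j in seq_along(sc$targets)) {
      if (j == i) next
      expect_equal(sum(inside_t & shape_inside(sc$targets[[j]], g)), 0L)
    }
  }
})

test_that("placement is reproducible and bounded rejection errors", {
  base <- generate_phantom(phantom_config(seed = 1))
  a <- place_targets(base, 1L, "small", seed = 99)
  b <- place_targets(base, 1L, "small", seed = 99)
  expect_identical(a$targets[[1]]$center, b$targets[[1]]$center)
  expect_error(place_targets(base, 1L, seed = 1,
                             volume_range = c(3000, 3200)),
               "rejection")
})

test_that("mesh scenes load with unit and watertightness contracts", {
  dir <- tempdir()
  skin_f <- file.path(dir, "skin.stl")
  bone_f <- file.path(dir, "bone.stl")
  tgt_f <- file.path(dir, "target.stl")
  write_stl(box_mesh(c(-60, -60, -60), c(60, 60, 60), "skin"), skin_f)
  write_stl(box_mesh(c(20, -5, -5), c(30, 5, 5), "bone"), bone_f)
  write_stl(box_mesh(c(0, 0, 0), c(1, 1, 1), "target"), tgt_f)
  sc <- load_scene(skin_f, bone_f, tgt_f)
  expect_equal(shape_volume(sc$targets[[1]]), 0.001)  # unit cube in mm
  expect_true(shape_inside(sc$bones[[1]], c(25, 0, 0)))
  # non-watertight skin is refused by name
  open <- box_mesh(c(-60, -60, -60), c(60, 60, 60), "openskin")
  open$faces <- open$faces[-1, ]
  open_f <- file.path(dir, "open.stl")
  write_stl(open, open_f)
  expect_error(load_scene(open_f, bone_f, tgt_f), "watertight")
})

test_that("NIfTI label maps become occupancy predicates with unit checks", {
  arr <- array(0L, c(8, 8, 8))
  arr[arr > -1] <- 1L                      # skin everywhere
  arr[4, 4, 4] <- 2L                       # one bone voxel
  arr[6, 6, 6] <- 3L                       # one target voxel
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(4, 4, 4)
  RNifti::pixunits(img) <- c("mm", "s")
  f <- tempfile(fileext = ".nii")
  RNifti::writeNifti(img, f)
  sc <- load_scene(label_map = f)
  # voxel (4,4,4) covers [12,16)^3 mm; its center is at 14 mm
  expect_true(shape_inside(sc$bones[[1]], c(14, 14, 14)))
  expect_false(shape_inside(sc$bones[[1]], c(18, 14, 14)))
  expect_equal(shape_volume(sc$targets[[1]]), 4^3 / 1000)
  RNifti::pixunits(img) <- c("m", "s")
  RNifti::writeNifti(img, f)
  expect_error(load_scene(label_map = f), "metres")
})

test_that("scene manifests record provenance", {
  sc <- generate_phantom(phantom_config(seed = 8))
  f <- tempfile(fileext = ".json")
  write_scene_manifest(sc, f)
  man <- jsonlite::read_json(f)
  expect_equal(man$provenance$kind, "synthetic")
  expect_equal(man$provenance$config$seed, 8)
  expect_equal(man$n_targets, 1L)
})
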