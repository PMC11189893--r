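test_that("make_disks is deterministic and places the requested regions", {
  spec <- scene_spec(height = 128, width = 128, n_regions = 10,
                     radius_range = c(6, 10))
  s1 <- make_disks(spec, seed = 3)
  s2 <- make_disks(spec, seed = 3)
  expect_identical(s1, s2)
  expect_false(identical(s1$image, make_disks(spec, seed = 4)$image))
  expect_equal(dim(s1$image), dim(s1$labels))
  expect_equal(sort(unique(s1$labels[s1$labels > 0])), 1:10)
  expect_true(all(s1$image >= 0 & s1$image <= 1))
})

test_that("a clean flat disk's image support equals its label support", {
  spec <- scene_spec(height = 64, width = 64, n_regions = 1,
                     radius_range = c(8, 8), texture = "flat",
                     illumination = 0, blur_sigma = 0, noise_sigma = 0)
  s <- make_disks(spec, seed = 5)
  expect_identical(s$image > min(s$image), s$labels > 0)
})

test_that("overcrowded scenes fail with the achieved count", {
  spec <- scene_spec(height = 64, width = 64, n_regions = 500,
                     radius_range = c(10, 12), max_overlap = 0)
  expect_error(make_disks(spec, seed = 1), "could only place")
})

test_that("disk fixtures contain touching contacts with distance valleys", {
  spec <- scene_spec() # 256x256, 30 disks, touching allowed
  s <- make_disks(spec, seed = 1)
  ids <- s$labels
  H <- nrow(ids)
  # find 4-adjacent pixel pairs with different positive labels
  right <- ids[, -1]; left <- ids[, -ncol(ids)]
  down <- ids[-1, ]; up <- ids[-nrow(ids), ]
  hpair <- left > 0 & right > 0 & left != right
  vpair <- up > 0 & down > 0 & up != down
  expect_gt(sum(hpair) + sum(vpair), 0) # regions really are in contact
  contact <- matrix(FALSE, nrow(ids), ncol(ids))
  contact[, -ncol(ids)] <- contact[, -ncol(ids)] | hpair
  contact[, -1] <- contact[, -1] | hpair
  contact[-nrow(ids), ] <- contact[-nrow(ids), ] | vpair
  contact[-1, ] <- contact[-1, ] | vpair
  d <- edge_distance(ids, 10)
  expect_true(all(d[contact] <= 1)) # valley on both sides of every contact
})

test_that("make_lattice responds to the deletion rate", {
  spec0 <- scene_spec(height = 160, width = 160, deletion_rate = 0,
                      noise_sigma = 0)
  l0 <- make_lattice(spec0, seed = 2)
  # full grid: every horizontal strut row is fully present in the mask
  expect_true(all(l0$mask[seq(1, 160, 32), 1:129]))
  counts <- vapply(c(0, 0.2, 0.5, 0.9), function(rate) {
    sp <- scene_spec(height = 160, width = 160, deletion_rate = rate,
                     noise_sigma = 0)
    sum(make_lattice(sp, seed = 2)$mask)
  }, numeric(1))
  expect_true(all(diff(counts) < 0)) # monotone decrease, same seed
  expect_identical(make_lattice(spec0, seed = 2), l0) # deterministic
})

test_that("fixture projects are ready to train", {
  root <- file.path(withr::local_tempdir(), "fx")
  spec <- scene_spec(height = 48, width = 48, n_regions = 3,
                     radius_range = c(5, 7))
  make_fixture_project(root, "disks", spec, seed = 2)
  expect_true(file.exists(file.path(root, "params.txt")))
  expect_true(file.exists(file.path(root, "train_images", "scene001.tif")))
  expect_true(file.exists(file.path(root, "train_masks", "scene001.tif")))
  expect_true(file.exists(file.path(root, "test_images", "scene002.tif")))
  expect_true(file.exists(file.path(root, "test_masks", "scene002.tif")))
  # masks hold the generated labels exactly
  m <- read_label_raster(file.path(root, "train_masks", "scene001.tif"))
  expect_identical(m, make_disks(spec, seed = 2)$labels)
})
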