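test_that("create_project lays out the tree and refuses to overwrite", {
  root <- withr::local_tempdir()
  proj <- create_project(file.path(root, "p1"))
  for (d in c("train_images", "train_masks", "test_images", "aoi",
              "outputs", "models"))
    expect_true(dir.exists(file.path(root, "p1", d)))
  expect_true(file.exists(proj$param_file))
  lines <- readLines(proj$param_file)
  expect_true("dist_cap=10" %in% lines)
  expect_true("learning_rate=0.001" %in% lines)
  # second call: error, disk unchanged
  before <- list.files(file.path(root, "p1"), recursive = TRUE)
  expect_error(create_project(file.path(root, "p1")), "already exists")
  expect_identical(list.files(file.path(root, "p1"), recursive = TRUE),
                   before)
})

test_that("load_params fills defaults and validates ranges", {
  f <- withr::local_tempfile(lines = character(0))
  p <- load_params(f) # empty file -> all defaults
  expect_identical(p, default_params())

  f2 <- withr::local_tempfile(lines = c("# a comment", "fraction=0.01"))
  expect_equal(load_params(f2)$fraction, 0.01)

  f3 <- withr::local_tempfile(lines = c("epochs=2", "fraction=1"))
  p3 <- load_params(f3)
  expect_equal(p3$epochs, 2L)
  expect_equal(p3$fraction, 1)

  f4 <- withr::local_tempfile(lines = "fraction=0")
  expect_error(load_params(f4), "fraction")
  f5 <- withr::local_tempfile(lines = "fraction=1.5")
  expect_error(load_params(f5), "fraction")
  f6 <- withr::local_tempfile(lines = "no_such_key=3")
  expect_error(load_params(f6), "no_such_key")
  # keys are case-insensitive
  f7 <- withr::local_tempfile(lines = "EPOCHS=7")
  expect_equal(load_params(f7)$epochs, 7L)
})

test_that("parameter serialization round-trips random valid sets", {
  set.seed(101)
  for (i in 1:25) {
    p <- default_params()
    p$scales <- sort(sample(1:30, sample(1:5, 1)))
    p$patch_side <- c(15L, 25L, 35L)[sample(3, 1)]
    p$dist_cap <- sample(1:30, 1)
    p$fraction <- runif(1, .Machine$double.eps, 1)
    p$epochs <- sample(1:10, 1)
    p$balance_classes <- sample(c(TRUE, FALSE), 1)
    p$augment <- sample(c(TRUE, FALSE), 1)
    p$learning_rate <- 10^runif(1, -5, -1)
    p$prob_threshold <- runif(1, 0.01, 0.99)
    p$min_region_px <- sample(0:100, 1)
    p$seed <- sample(1:10^6, 1)
    p$batch_size <- sample(1:512, 1)
    p$marker_level <- if (runif(1) < 0.5) "auto" else runif(1, 0.5, 20)
    p$rgb_mode <- sample(c("luma", "keep3"), 1)
    f <- tempfile()
    write_params(p, f)
    expect_identical(load_params(f), p)
    unlink(f)
  }
})

test_that("label rasters round-trip exactly and reject RGB", {
  set.seed(7)
  lab <- matrix(sample(0:65535, 100 * 80, TRUE), 100, 80)
  f <- withr::local_tempfile(fileext = ".tif")
  write_label_raster(lab, f)
  expect_identical(read_label_raster(f), matrix(as.integer(lab), 100, 80))

  # PNG labels read back as integers
  f2 <- withr::local_tempfile(fileext = ".png")
  small <- matrix(sample(0:2, 60, TRUE), 10, 6)
  png::writePNG(small / 255, f2)
  got <- read_label_raster(f2)
  expect_identical(got, matrix(as.integer(small), 10, 6))
  expect_equal(sort(unique(got[got > 0])), sort(unique(small[small > 0])))

  # RGB where labels expected -> error (ambiguous IDs)
  f3 <- withr::local_tempfile(fileext = ".png")
  png::writePNG(array(runif(60), c(5, 4, 3)), f3)
  expect_error(read_label_raster(f3), "single-channel")
})

test_that("float rasters survive the round trip at float32 precision", {
  set.seed(8)
  m <- matrix(runif(100 * 80) * 10, 100, 80)
  m[1, 1] <- 10 # cap value must survive
  f <- withr::local_tempfile(fileext = ".tif")
  write_float_raster(m, f)
  r1 <- read_float_raster(f)
  expect_lt(max(abs(r1 - m)), 1e-5) # float32 rounding only
  expect_equal(r1[1, 1], 10)
  # second trip is bit-exact: values are already float32-representable
  write_float_raster(r1, f)
  expect_identical(read_float_raster(f), r1)
})
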