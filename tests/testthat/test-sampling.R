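test_that("normalize_image gives zero mean, unit sd, affine invariance", {
  expect_equal(normalize_image(matrix(3.7, 10, 10)), matrix(0, 10, 10))
  set.seed(1)
  img <- matrix(runif(400, 0, 255), 20, 20)
  n <- normalize_image(img)
  expect_lt(abs(mean(n)), 1e-9)
  expect_lt(abs(sd(as.vector(n)) - 1), 1e-6)
  # invariant to affine intensity changes with positive gain
  expect_equal(normalize_image(3.2 * img + 17), n, tolerance = 1e-9)
})

test_that("extract_stacks produces the documented window content", {
  set.seed(2)
  img <- matrix(runif(60 * 50), 60, 50)
  # scale-1 channel is the literal 25x25 window (direct indexing oracle)
  st <- extract_stack(img, c(30, 25), c(1L, 3L), 25)
  expect_equal(st[, , 1], img[18:42, 13:37], tolerance = 1e-12)
  # constant image -> every channel constant
  stc <- extract_stack(matrix(2, 60, 50), c(10, 10), c(1L, 3L, 9L), 25)
  expect_true(all(stc == 2))
  # scales [1,3,9,27] -> 4 channels
  st4 <- extract_stack(img, c(30, 25), c(1L, 3L, 9L, 27L), 25)
  expect_equal(dim(st4), c(25, 25, 4))
  # block averaging: scale-3 center block equals mean of the 3x3 around center
  st3 <- extract_stack(img, c(30, 25), c(3L), 25)
  expect_equal(st3[13, 13, 1], mean(img[29:31, 24:26]), tolerance = 1e-12)
  expect_error(extract_stacks(img, cbind(0, 5), c(1L), 25), "inside")
  expect_error(extract_stacks(img, cbind(5, 5), c(0L), 25), "scales")
})

test_that("out-of-bounds patch content is edge-replicated", {
  img <- matrix(rep(1:6, each = 6), 6, 6) # columns ramp 1..6
  st <- extract_stack(img, c(1, 1), c(1L), 5)
  # rows above the image replicate row 1; columns left replicate column 1
  expect_equal(st[1, 3, 1], img[1, 1])
  expect_equal(st[3, 3, 1], img[1, 1])
  expect_equal(st[5, 5, 1], img[3, 3])
})

test_that("dihedral is the full symmetry group of the square", {
  set.seed(3)
  patch <- array(runif(25 * 25 * 2), c(25, 25, 2))
  expect_identical(dihedral(patch, 0), patch)
  # 90-degree rotation applied four times is the identity
  r <- patch
  for (i in 1:4) r <- dihedral(r, 1)
  expect_equal(r, patch)
  # the 8 outputs of an asymmetric patch are pairwise distinct
  outs <- lapply(0:7, function(k) dihedral(patch, k))
  for (a in 1:7) for (b in (a + 1):8)
    expect_false(isTRUE(all.equal(outs[[a]], outs[[b]])))
  # every channel transformed identically
  expect_equal(dihedral(patch, 3)[, , 2], dihedral(patch[, , 2], 3))
})

test_that("draw_samples honors fraction, balance, AOI and seeding", {
  # F=1, balance off: every AOI pixel exactly once
  ids <- matrix(0L, 20, 20)
  ids[4:9, 4:9] <- 1L
  p <- default_params()
  p$balance_classes <- FALSE
  d <- draw_samples(list(ids), NULL, p, seed = 5)
  expect_equal(nrow(d$samples), 400)
  key <- paste(d$samples$row, d$samples$col)
  expect_equal(sort(key), sort(paste(row(ids), col(ids))))
  expect_equal(d$budget$T, p$epochs * 400)

  # F=0.5, balance on, 1000 eligible (900 outie / 100 innie)
  ids2 <- matrix(0L, 25, 40)
  ids2[1:4, 1:25] <- 1L
  stopifnot(sum(ids2 > 0) == 100, length(ids2) == 1000)
  p2 <- default_params()
  p2$fraction <- 0.5
  d2 <- draw_samples(list(ids2), NULL, p2, seed = 6)
  expect_equal(nrow(d2$samples), 500)
  expect_lte(abs(sum(d2$samples$class == 1) - sum(d2$samples$class == 0)), 1)

  # AOI excluding the left half: no sample center there
  aoi <- matrix(TRUE, 25, 40)
  aoi[, 1:20] <- FALSE
  d3 <- draw_samples(list(ids2), list(aoi), p2, seed = 7)
  expect_true(all(d3$samples$col > 20))

  # same seed -> identical stream; different seed -> different order
  d4 <- draw_samples(list(ids2), NULL, p2, seed = 6)
  expect_identical(d2$samples, d4$samples)
  d5 <- draw_samples(list(ids2), NULL, p2, seed = 8)
  expect_false(identical(d2$samples, d5$samples))
})

test_that("sample distance labels obey the class contract", {
  set.seed(9)
  ids <- random_label_map(20, 20, 3)
  p <- default_params()
  d <- draw_samples(list(ids), NULL, p, seed = 1)
  s <- d$samples
  expect_true(all(s$dist[s$class == 0] == 0))
  expect_true(all(s$dist >= 0 & s$dist <= p$dist_cap))
  # labels match a direct lookup
  dmap <- edge_distance(ids, p$dist_cap)
  expect_equal(s$dist, dmap[cbind(s$row, s$col)])
  expect_equal(s$class, as.integer(ids[cbind(s$row, s$col)] > 0))
})

test_that("the training budget identity holds across (E, F, M) grids", {
  for (E in c(1L, 2L, 3L)) {
    for (frac in c(0.01, 0.2, 1)) {
      for (Hw in list(c(20, 50), c(32, 32))) {
        ids <- matrix(0L, Hw[1], Hw[2])
        ids[2:10, 2:10] <- 1L
        M <- prod(Hw)
        p <- default_params()
        p$epochs <- E
        p$fraction <- frac
        d <- draw_samples(list(ids), NULL, p, seed = 3)
        expect_equal(d$budget$M, M)
        expect_equal(d$budget$T, E * round(frac * M))
        expect_lte(abs(d$budget$T - E * frac * M), E / 2)
        # the collapse variable EF = T/M is recoverable to rounding
        expect_lte(abs(d$budget$T / d$budget$M - E * frac),
                   E / (2 * M) + 1e-12)
      }
    }
  }
})
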