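test_that("binarize applies the >= tie rule and conserves counts", {
  set.seed(30)
  pmap <- matrix(runif(100), 10, 10)
  pmap[3, 3] <- 0.5
  b <- binarize(pmap, 0.5)
  expect_true(b[3, 3]) # ties pass
  expect_equal(sum(b), sum(pmap >= 0.5))
  expect_true(all(binarize(matrix(1, 4, 4), 0.5)))
  expect_error(binarize(pmap, 0), "threshold")
})

test_that("watershed with an ideal distance map splits touching disks", {
  # two disks touching along a line
  H <- 60; W <- 60
  ids <- matrix(0L, H, W)
  mk <- function(ctr, r, k) {
    d2 <- (row(ids) - ctr[1])^2 + (col(ids) - ctr[2])^2
    ids[d2 <= r^2 & ids == 0] <<- k
  }
  mk(c(30, 20), 10, 1L)
  mk(c(30, 40), 10, 2L) # centers 20 apart, radius 10: tangent contact
  dmap <- edge_distance(ids, 10)
  p <- default_params()
  p$min_region_px <- 0L
  seg <- watershed_split(ids > 0, dmap, p)
  expect_equal(max(seg$labels), 2)
  # per-pixel agreement away from the 1-px contact band
  contact <- which(vapply(seq_along(ids), function(i) {
    if (ids[i] == 0) return(FALSE)
    r <- ((i - 1) %% H) + 1; c <- ((i - 1) %/% H) + 1
    nb <- ids[max(1, r - 1):min(H, r + 1), max(1, c - 1):min(W, c + 1)]
    any(nb > 0 & nb != ids[i])
  }, logical(1)))
  res <- seg_score(ids, seg$labels)
  expect_equal(res$seg, 1, tolerance = 0.02)
  relabel <- c(res$rows$pred_id)[match(ids[ids > 0], res$rows$true_id)]
  mismatch <- which(ids > 0)[seg$labels[ids > 0] != relabel]
  expect_true(all(mismatch %in% contact))
})

test_that("watershed covers the foreground and filters speckle", {
  # single isolated blob -> one region covering exactly the blob
  ids <- matrix(0L, 20, 20)
  ids[5:12, 6:14] <- 1L
  dmap <- edge_distance(ids, 4)
  p <- default_params()
  p$marker_level <- 2
  p$min_region_px <- 0L
  seg <- watershed_split(ids > 0, dmap, p)
  expect_equal(max(seg$labels), 1)
  expect_identical(seg$labels > 0, ids > 0)
  # partition: every foreground pixel is labeled or removed by min_region_px
  p$min_region_px <- 200L
  seg2 <- watershed_split(ids > 0, dmap, p)
  expect_equal(max(seg2$labels), 0) # 72 px blob removed
  # no markers at all -> empty segmentation with a warning
  p$marker_level <- 99
  expect_warning(watershed_split(ids > 0, dmap, p), "marker")
})

test_that("watershed output is deterministic and its labels well-ordered", {
  set.seed(31)
  ids <- random_label_map(30, 30, 4)
  dmap <- edge_distance(ids, 6)
  p <- default_params()
  p$marker_level <- 3
  p$min_region_px <- 2L
  s1 <- watershed_split(ids > 0, dmap, p)
  s2 <- watershed_split(ids > 0, dmap, p)
  expect_identical(s1$labels, s2$labels)
  if (max(s1$labels) > 0) {
    present <- sort(unique(s1$labels[s1$labels > 0]))
    expect_equal(present, seq_along(present)) # renumbered 1..K
  }
})

test_that("region_table reports areas, centroids and boxes", {
  expect_equal(nrow(region_table(matrix(0L, 5, 5))), 0)
  lab <- matrix(0L, 20, 20)
  lab[2:5, 3:4] <- 1L
  # symmetric disk: centroid at its center
  d2 <- (row(lab) - 13)^2 + (col(lab) - 12)^2
  lab[d2 <= 16] <- 2L
  tab <- region_table(lab)
  expect_equal(nrow(tab), 2)
  expect_equal(sum(tab$area), sum(lab > 0))
  expect_equal(tab$area[1], 8)
  expect_lt(abs(tab$centroid_r[2] - 13), 0.5)
  expect_lt(abs(tab$centroid_c[2] - 12), 0.5)
  expect_equal(unlist(tab[1, c("rmin", "rmax", "cmin", "cmax")]),
               c(rmin = 2, rmax = 5, cmin = 3, cmax = 4))
})

test_that("predict_maps equals a per-pixel loop and respects the AOI", {
  set.seed(33)
  net <- pseudo_trained_net(tiny_spec(2L))
  img <- matrix(runif(32 * 32), 32, 32)
  p <- default_params()
  p$scales <- c(1L, 3L)
  aoi <- matrix(TRUE, 32, 32)
  aoi[1:3, ] <- FALSE # exclude the top border
  maps <- predict_maps(net, img, aoi, p, batch = 64)
  expect_equal(dim(maps$prob), c(32, 32))
  expect_true(all(maps$prob[1:3, ] == 0))
  expect_true(all(maps$dist[1:3, ] == 0))
  expect_true(all(maps$prob >= 0 & maps$prob <= 1))
  expect_true(all(maps$dist <= p$dist_cap))
  # naive per-pixel loop oracle on a band of pixels
  norm <- normalize_image(img)
  for (px in list(c(10, 10), c(4, 1), c(32, 32), c(17, 25))) {
    st <- extract_stack(norm, px, p$scales, p$patch_side)
    one <- net_forward(net, st, d_max = p$dist_cap)
    expect_equal(maps$prob[px[1], px[2]], one$prob, tolerance = 1e-10)
    expect_equal(maps$dist[px[1], px[2]], one$dist, tolerance = 1e-10)
  }
  # untrained network refuses
  un <- build_network(tiny_spec(2L), seed = 1)
  expect_error(predict_maps(un, img, NULL, p), "trained")
})
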