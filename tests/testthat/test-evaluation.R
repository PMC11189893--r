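test_that("jaccard matches counting on drawn toy sets", {
  A <- matrix(FALSE, 6, 6); A[2:3, 2:5] <- TRUE # 8 px
  expect_equal(jaccard(A, A), 1)
  B <- matrix(FALSE, 6, 6); B[5:6, 1:2] <- TRUE
  expect_equal(jaccard(A, B), 0)
  # |A|=8, |A∩B|=6, |B|=8 -> 6/10
  C <- matrix(FALSE, 6, 6); C[2:3, 3:6] <- TRUE
  expect_equal(sum(A & C), 6)
  expect_equal(jaccard(A, C), 0.6)
  expect_error(jaccard(matrix(FALSE, 2, 2), B[1:2, 1:2]), "empty")
})

test_that("seg_score implements matching, half-overlap rule and pooling", {
  # perfect prediction under relabeling scores 1
  set.seed(40)
  truth <- random_label_map(16, 16, 3)
  if (!any(truth > 0)) truth[2:4, 2:4] <- 1L
  relab <- truth
  ids <- sort(unique(truth[truth > 0]))
  for (i in seq_along(ids)) relab[truth == ids[i]] <- 100L + i
  expect_equal(seg_score(truth, relab)$seg, 1)
  # all-background prediction scores 0
  expect_equal(seg_score(truth, matrix(0L, 16, 16))$seg, 0)

  # drawn 12x8 toy: two 4x4 squares, one exact, the other covered 7/16
  tr <- matrix(0L, 8, 12)
  tr[3:6, 2:5] <- 1L
  tr[3:6, 8:11] <- 2L
  pr <- matrix(0L, 8, 12)
  pr[3:6, 2:5] <- 5L            # exact match
  pr[3:6, 8:9] <- 6L            # 8 px of region 2 ... start from 8 px
  pr[6, 9] <- 0L                # now 7 of 16 px covered
  r <- seg_score(tr, pr)
  expect_equal(r$rows$score, c(1, 0))
  expect_equal(r$seg, 0.5)
  expect_true(is.na(r$rows$pred_id[2]))
})

test_that("the half-overlap boundary follows the chosen convention", {
  tr <- matrix(0L, 6, 6)
  tr[1:4, 1:4] <- 1L # 16 px
  pr <- matrix(0L, 6, 6)
  pr[1:2, 1:4] <- 1L # exactly half: 8 px
  # at-least-half rule: scores the jaccard
  expect_equal(seg_score(tr, pr)$seg, 8 / 16)
  # strict rule zeroes the exact-half case
  expect_equal(seg_score(tr, pr, strict_half = TRUE)$seg, 0)
})

test_that("SEG is invariant under ID permutations and monotone on nesting", {
  set.seed(41)
  for (i in 1:10) {
    truth <- random_label_map(20, 20, 3)
    pred <- random_label_map(20, 20, 3)
    if (!any(truth > 0)) truth[2:4, 2:4] <- 1L
    base <- seg_score(truth, pred)$seg
    # permute predicted IDs
    pids <- unique(pred[pred > 0])
    if (length(pids) > 1) {
      prm <- pred
      shuffled <- sample(pids)
      for (j in seq_along(pids)) prm[pred == pids[j]] <- 1000L + shuffled[j]
      expect_equal(seg_score(truth, prm)$seg, base)
    }
  }
  # shrinking a matched prediction inside the true region lowers its jaccard
  tr <- matrix(0L, 10, 10); tr[2:9, 2:9] <- 1L
  pr1 <- tr
  pr2 <- matrix(0L, 10, 10); pr2[3:8, 3:8] <- 1L
  expect_gt(seg_score(tr, pr1)$seg, seg_score(tr, pr2)$seg)
})

test_that("seg_score agrees with the all-pairs brute force on random maps", {
  set.seed(42)
  for (i in 1:40) {
    truth <- random_label_map(18, 18, sample(1:4, 1))
    pred <- random_label_map(18, 18, sample(0:4, 1))
    if (!any(truth > 0)) truth[2:3, 2:3] <- 1L
    expect_equal(seg_score(truth, pred)$seg,
                 brute_seg_score(truth, pred),
                 tolerance = 1e-12)
  }
})

test_that("pooling averages over regions, not images", {
  tr1 <- matrix(0L, 6, 6); tr1[1:3, 1:3] <- 1L
  tr2 <- matrix(0L, 6, 6); tr2[1:3, 1:3] <- 1L; tr2[5:6, 5:6] <- 2L
  r1 <- seg_score(tr1, tr1)                  # one region, score 1
  r2 <- seg_score(tr2, matrix(0L, 6, 6))     # two regions, scores 0
  pooled <- seg_pool(list(r1, r2))
  expect_equal(pooled$seg, 1 / 3)            # mean over 3 regions
  expect_equal(nrow(pooled$rows), 3)
})
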