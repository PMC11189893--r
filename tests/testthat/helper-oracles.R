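# Independent brute-force oracles. These deliberately share no code with the
# package internals: distances by exhaustive pairwise minima, SEG by full
# overlap enumeration.

# O(N^2) capped distance to the nearest differently-labeled pixel
brute_edge_distance <- function(ids, d_max) {
  rs <- row(ids); cs <- col(ids)
  out <- matrix(0, nrow(ids), ncol(ids))
  for (i in which(ids > 0)) {
    diff <- ids != ids[i]
    if (!any(diff)) {
      out[i] <- d_max
    } else {
      d <- sqrt((rs[diff] - rs[i])^2 + (cs[diff] - cs[i])^2)
      out[i] <- min(d_max, min(d))
    }
  }
  out
}

# all-pairs-overlap SEG with the half-overlap zero rule
brute_seg_score <- function(truth, pred, aoi = NULL, strict = FALSE) {
  if (!is.null(aoi)) {
    truth[!aoi] <- 0L
    pred[!aoi] <- 0L
  }
  tids <- sort(unique(truth[truth > 0]))
  stopifnot(length(tids) > 0)
  scores <- vapply(tids, function(tid) {
    R <- truth == tid
    pids <- sort(unique(pred[pred > 0]))
    if (length(pids) == 0) return(0)
    inter <- vapply(pids, function(p) sum(R & pred == p), numeric(1))
    best <- max(inter)
    if (best == 0) return(0)
    cand <- pids[inter == best]
    jac <- max(vapply(cand, function(p) sum(R & pred == p) / sum(R | pred == p),
                      numeric(1)))
    ok <- if (strict) best > sum(R) / 2 else best >= sum(R) / 2
    if (ok) jac else 0
  }, numeric(1))
  mean(scores)
}

# random label map: a few rectangles (possibly touching/overwriting) on a
# small canvas; returns an integer matrix
random_label_map <- function(H = 24, W = 24, n = sample(1:4, 1)) {
  ids <- matrix(0L, H, W)
  for (k in seq_len(n)) {
    h <- sample(2:max(2, H %/% 2), 1)
    w <- sample(2:max(2, W %/% 2), 1)
    r0 <- sample(1:(H - h + 1), 1)
    c0 <- sample(1:(W - w + 1), 1)
    ids[r0:(r0 + h - 1), c0:(c0 + w - 1)] <- k
  }
  ids
}

# tiny network spec used where architecture size is irrelevant
tiny_spec <- function(n_channels = 1L) {
  network_spec(25L, n_channels, c(2L, 3L, 4L), c(8L, 6L, 5L, 4L))
}

# a "trained" network for pure-inference tests (weights are random; only the
# forward pass semantics are exercised)
pseudo_trained_net <- function(spec = tiny_spec(), seed = 11L) {
  net <- build_network(spec, seed = seed)
  net$trained <- TRUE
  net
}
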