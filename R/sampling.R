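# Training-set construction: image normalization, multi-scale patch stacks,
# dihedral augmentation, and the class-balanced fractional pixel draw.

#' Normalize image brightness
#'
#' Affine per-image rescale to zero mean and unit (sample) standard
#' deviation, so the network sees comparable intensities across images. A
#' constant image maps to all zeros. RGB arrays are normalized by their
#' global mean/sd, preserving relative channel contrast.
#'
#' @param img A `bb_image`, numeric matrix or H x W x 3 array.
#' @return A numeric matrix/array of the same shape.
#' @export
normalize_image <- function(img) {
  px <- if (inherits(img, "bb_image")) img$pixels else img
  mu <- mean(px)
  s <- stats::sd(as.vector(px))
  if (!is.finite(s) || s == 0) return(px * 0)
  (px - mu) / s
}

#' Convert RGB to single-channel luma
#'
#' Rec. 601 luma weights (0.299, 0.587, 0.114). Grayscale input is returned
#' unchanged.
#'
#' @param px Numeric matrix or H x W x 3 array.
#' @return Numeric matrix.
#' @export
rgb_to_luma <- function(px) {
  if (is.matrix(px)) return(px)
  stopifnot(length(dim(px)) == 3, dim(px)[3] == 3)
  0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
}

# replicate-pad a matrix by `pad` pixels on every side
pad_replicate <- function(m, pad) {
  if (pad == 0) return(m)
  ri <- c(rep(1L, pad), seq_len(nrow(m)), rep(nrow(m), pad))
  ci <- c(rep(1L, pad), seq_len(ncol(m)), rep(ncol(m), pad))
  m[ri, ci]
}

# summed-area table with a leading zero row/column:
# SA[i+1, j+1] = sum(m[1:i, 1:j])
integral_image <- function(m) {
  sa <- matrix(0, nrow(m) + 1, ncol(m) + 1)
  sa[-1, -1] <- apply(apply(m, 2, cumsum), 1, cumsum) |> t()
  sa
}

# padding needed so every block of every scale falls inside the padded image
stack_pad <- function(scales, patch_side) {
  max(vapply(scales, function(s) {
    a <- (patch_side * s - 1) %/% 2
    max(a, patch_side * s - 1 - a)
  }, numeric(1)))
}

#' Extract multi-scale patch stacks
#'
#' For each center pixel and each scale `s`, takes the
#' `(patch_side * s)`-square window centered on the pixel (edge-replicated
#' beyond the image), block-averages it `s x s` down to
#' `patch_side x patch_side`, and stacks the scales as channels. Multi-channel
#' images contribute `length(scales) * C` channels, ordered channel-within-
#' scale.
#'
#' @param img Normalized numeric matrix (or H x W x C array).
#' @param centers Integer matrix with one `(row, col)` center per row.
#' @param scales Integer vector of window scales (1 = native resolution).
#' @param patch_side Odd patch side in pixels.
#' @return A numeric matrix with `patch_side^2 * n_channels` rows and one
#'   column per center, ordered `(row, col, channel)` column-major, channels
#'   grouped as scale-major.
#' @export
extract_stacks <- function(img, centers, scales, patch_side) {
  if (any(scales < 1)) stop("scales must be >= 1")
  if (is.matrix(centers) == FALSE) centers <- matrix(centers, nrow = 1)
  chans <- if (is.matrix(img)) list(img) else
    lapply(seq_len(dim(img)[3]), function(i) img[, , i])
  H <- nrow(chans[[1]]); W <- ncol(chans[[1]])
  if (any(centers[, 1] < 1 | centers[, 1] > H |
          centers[, 2] < 1 | centers[, 2] > W))
    stop("patch centers must lie inside the image")
  p <- patch_side
  pad <- stack_pad(scales, p)
  sas <- lapply(chans, function(ch) integral_image(pad_replicate(ch, pad)))
  n <- nrow(centers)
  nc_img <- length(chans)
  out <- matrix(0, p * p * length(scales) * nc_img, n)
  Hp1 <- H + 2 * pad + 1 # rows of the integral image
  rpad <- centers[, 1] + pad
  cpad <- centers[, 2] + pad
  js <- 0:(p - 1)
  for (si in seq_along(scales)) {
    s <- scales[si]
    a <- (p * s - 1) %/% 2
    r_starts <- rpad - a # start row (1-based, padded coords) of block j = 0
    c_starts <- cpad - a
    for (jc in js) {
      c0 <- c_starts + jc * s # block columns c0 .. c0+s-1
      for (jr in js) {
        r0 <- r_starts + jr * s
        # integral-image block sum; SA indices: [r0, c0] is the corner above-left
        i11 <- (c0 + s - 1) * Hp1 + (r0 + s)
        i00 <- (c0 - 1) * Hp1 + r0
        i10 <- (c0 - 1) * Hp1 + (r0 + s)
        i01 <- (c0 + s - 1) * Hp1 + r0
        for (ci in seq_len(nc_img)) {
          sa <- sas[[ci]]
          vals <- (sa[i11] + sa[i00] - sa[i10] - sa[i01]) / (s * s)
          row <- ((si - 1) * nc_img + (ci - 1)) * p * p + jc * p + jr + 1
          out[row, ] <- vals
        }
      }
    }
  }
  out
}

#' Extract one patch stack as an array
#'
#' Convenience wrapper around [extract_stacks()] for a single center.
#'
#' @inheritParams extract_stacks
#' @param center Length-2 integer vector `(row, col)`.
#' @return A `patch_side x patch_side x n_channels` array.
#' @export
extract_stack <- function(img, center, scales, patch_side) {
  v <- extract_stacks(img, matrix(center, nrow = 1), scales, patch_side)
  nc <- length(v) / (patch_side^2)
  array(v, dim = c(patch_side, patch_side, nc))
}

#' Dihedral symmetry of a patch stack
#'
#' Applies the `k`-th element of the dihedral group of the square (k = 0..3:
#' rotation by 90 degrees counter-clockwise k times; k = 4..7: horizontal
#' flip followed by the same rotations) identically to every channel.
#'
#' @param stack A `p x p x C` array (or `p x p` matrix).
#' @param k Integer in 0..7.
#' @return Transformed array of the same shape.
#' @export
dihedral <- function(stack, k) {
  stopifnot(k %in% 0:7)
  m <- if (is.matrix(stack)) array(stack, c(dim(stack), 1)) else stack
  p <- dim(m)[1]
  stopifnot(dim(m)[2] == p)
  perm <- dihedral_perm(p, k)
  out <- m
  for (ch in seq_len(dim(m)[3])) {
    sl <- m[, , ch]
    out[, , ch] <- matrix(sl[perm], p, p)
  }
  if (is.matrix(stack)) out[, , 1] else out
}

# index permutation on the p x p grid implementing dihedral element k:
# result[i] = original[perm[i]]
dihedral_perm <- function(p, k) {
  idx <- matrix(seq_len(p * p), p, p)
  rot <- function(m) t(m)[p:1, , drop = FALSE] # 90 degrees CCW
  if (k >= 4) idx <- idx[, p:1, drop = FALSE]  # horizontal flip
  r <- k %% 4
  for (i in seq_len(r)) idx <- rot(idx)
  as.vector(idx)
}

# full-row permutation for stacked (p^2 * C) x n matrices
dihedral_row_perm <- function(p, n_channels, k) {
  base <- dihedral_perm(p, k)
  as.vector(outer(base, (seq_len(n_channels) - 1) * p * p, `+`))
}

#' Draw the training-pixel stream
#'
#' Selects training pixels from the area of interest of each labeled image.
#' A fraction `F` of the `M` eligible pixels is drawn; with class balancing
#' on, innies and outies are drawn in equal numbers (within one), sampling
#' with replacement from the minority class if it is exhausted; with
#' balancing off, the native class ratio of a plain uniform draw is kept
#' (and `F = 1` yields every eligible pixel exactly once). The stream order
#' is a seeded permutation.
#'
#' @param label_maps List of integer label matrices, one per training image.
#' @param aois List of logical AOI matrices (or `NULL` entries for all-true).
#' @param params A `bb_params` list (`fraction`, `epochs`, `balance_classes`,
#'   `dist_cap`, `seed` are used).
#' @param seed RNG seed; defaults to `params$seed`.
#' @return A list with `samples` (data.frame: `img`, `row`, `col`, `class`,
#'   `dist`) and `budget` (list `M`, `F`, `E`, `T` with
#'   `T = E * round(F * M)` sample presentations).
#' @export
draw_samples <- function(label_maps, aois = NULL, params = default_params(),
                         seed = params$seed) {
  stopifnot(length(label_maps) >= 1)
  if (is.null(aois)) aois <- vector("list", length(label_maps))
  if (length(aois) < length(label_maps))
    length(aois) <- length(label_maps)
  set.seed(seed)
  per_img <- lapply(seq_along(label_maps), function(i) {
    map <- label_maps[[i]]
    keep <- aoi_or_default(aois[[i]], dim(map))
    idx <- which(keep)
    if (length(idx) == 0) return(NULL)
    dmap <- edge_distance(map, params$dist_cap)
    data.frame(img = i,
               row = ((idx - 1) %% nrow(map)) + 1,
               col = ((idx - 1) %/% nrow(map)) + 1,
               class = as.integer(map[idx] > 0),
               dist = dmap[idx])
  })
  all <- do.call(rbind, per_img)
  if (is.null(all) || nrow(all) == 0)
    stop("no eligible pixels: the AOI excludes everything")
  M <- nrow(all)
  frac <- params$fraction
  E <- params$epochs
  n_draw <- round(frac * M)
  if (n_draw < 1) stop("fraction too small: no pixels drawn")
  if (isTRUE(params$balance_classes)) {
    innies <- which(all$class == 1)
    outies <- which(all$class == 0)
    if (length(innies) == 0 || length(outies) == 0)
      stop("class balancing requires both innie and outie pixels in the AOI")
    n_in <- n_draw %/% 2
    n_out <- n_draw - n_in
    pick_in <- sample(innies, n_in, replace = n_in > length(innies))
    pick_out <- sample(outies, n_out, replace = n_out > length(outies))
    picked <- c(pick_in, pick_out)
  } else {
    picked <- sample.int(M, n_draw, replace = FALSE)
  }
  picked <- picked[sample.int(length(picked))]
  samples <- all[picked, , drop = FALSE]
  rownames(samples) <- NULL
  budget <- list(M = M, F = frac, E = E, T = E * n_draw)
  list(samples = samples, budget = budget)
}
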