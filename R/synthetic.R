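# Synthetic scene generators: textured touching disks (granular packings,
# bubbles) and thin fracturing lattices. These provide image/label pairs
# with the structural features the method targets — regions in contact,
# per-region texture, uneven illumination, blur and noise — with clean
# labels, so every pipeline stage is testable without external data.

#' Scene specification for synthetic fixtures
#'
#' @param height,width Canvas size in pixels.
#' @param n_regions Number of disks (or lattice cells across).
#' @param radius_range Disk radius range in pixels (min 3).
#' @param max_overlap Maximum allowed overlap (px) between two disks;
#'   touching is allowed whenever `max_overlap >= 0`.
#' @param texture One of `"flat"`, `"radial"`, `"birefringence"` (a
#'   four-lobed angular intensity pattern plus a radial ramp, emulating
#'   stress-fringe-like per-particle texture without modeling
#'   photoelasticity).
#' @param illumination Amplitude of a linear illumination gradient.
#' @param blur_sigma Gaussian blur sigma in pixels.
#' @param noise_sigma Additive Gaussian noise sigma (intensity units, image
#'   scale is 0..1).
#' @param deletion_rate Fraction of lattice struts removed (lattice preset).
#' @return A list of class `bb_scene_spec`.
#' @export
scene_spec <- function(height = 256L, width = 256L, n_regions = 30L,
                       radius_range = c(8, 14), max_overlap = 2,
                       texture = c("birefringence", "radial", "flat"),
                       illumination = 0.15, blur_sigma = 1,
                       noise_sigma = 0.03, deletion_rate = 0.15) {
  texture <- match.arg(texture)
  stopifnot(radius_range[1] >= 3, radius_range[2] >= radius_range[1])
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_regions = as.integer(n_regions),
                 radius_range = radius_range, max_overlap = max_overlap,
                 texture = texture, illumination = illumination,
                 blur_sigma = blur_sigma, noise_sigma = noise_sigma,
                 deletion_rate = deletion_rate),
            class = "bb_scene_spec")
}

gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  rad <- max(1L, ceiling(3 * sigma))
  x <- (-rad):rad
  k <- exp(-x^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad <- pad_replicate(m, rad)
  # separable convolution: rows then columns
  h <- nrow(m); w <- ncol(m)
  tmp <- matrix(0, h, ncol(pad))
  for (i in seq_along(x))
    tmp <- tmp + k[i] * pad[rad + (1:h) + x[i], ]
  out <- matrix(0, h, w)
  for (i in seq_along(x))
    out <- out + k[i] * tmp[, rad + (1:w) + x[i]]
  out
}

#' Generate a textured touching-disks scene
#'
#' Disks are placed by rejection sampling honoring the overlap allowance
#' (touching pairs permitted and common); contested pixels in slight
#' overlaps go to the disk whose rim is farthest. Texture, illumination
#' gradient, blur and noise act on the image only; labels stay clean.
#'
#' @param spec A `bb_scene_spec`.
#' @param seed RNG seed; the same seed reproduces the scene exactly.
#' @return A list with `image` (numeric matrix, 0..1) and `labels` (integer
#'   matrix with one positive ID per disk).
#' @export
make_disks <- function(spec = scene_spec(), seed = 1L) {
  set.seed(seed)
  H <- spec$height; W <- spec$width
  n <- spec$n_regions
  centers <- matrix(0, 0, 3) # r, c, radius
  attempts <- 0L
  max_attempts <- 400L * n
  while (nrow(centers) < n && attempts < max_attempts) {
    attempts <- attempts + 1L
    rad <- runif(1, spec$radius_range[1], spec$radius_range[2])
    r <- runif(1, rad + 1, H - rad)
    c <- runif(1, rad + 1, W - rad)
    ok <- TRUE
    if (nrow(centers) > 0) {
      d <- sqrt((centers[, 1] - r)^2 + (centers[, 2] - c)^2)
      if (any(d < centers[, 3] + rad - spec$max_overlap)) ok <- FALSE
    }
    if (ok) centers <- rbind(centers, c(r, c, rad))
  }
  if (nrow(centers) < n)
    stop("could only place ", nrow(centers), " of ", n,
         " disks within the attempt budget")

  labels <- matrix(0L, H, W)
  depth <- matrix(-Inf, H, W) # signed depth inside a disk: radius - dist
  img <- matrix(0.08, H, W)   # background level
  phases <- runif(n, 0, pi)
  for (i in seq_len(n)) {
    r0 <- centers[i, 1]; c0 <- centers[i, 2]; rad <- centers[i, 3]
    rr <- max(1L, floor(r0 - rad)):min(H, ceiling(r0 + rad))
    cc <- max(1L, floor(c0 - rad)):min(W, ceiling(c0 + rad))
    dr <- outer(rr - r0, rep(1, length(cc)))
    dc <- outer(rep(1, length(rr)), cc - c0)
    dist <- sqrt(dr^2 + dc^2)
    inside <- dist <= rad
    dpt <- rad - dist
    sub_depth <- depth[rr, cc]
    win <- inside & (dpt > sub_depth)
    if (!any(win)) next
    sub_lab <- labels[rr, cc]
    sub_lab[win] <- i
    labels[rr, cc] <- sub_lab
    sub_depth[win] <- dpt[win]
    depth[rr, cc] <- sub_depth
    tex <- switch(spec$texture,
      flat = matrix(0.7, length(rr), length(cc)),
      radial = 0.9 - 0.5 * dist / rad,
      birefringence = {
        th <- atan2(dr, dc)
        0.35 + 0.4 * cos(2 * th + phases[i])^2 + 0.2 * (1 - dist / rad)
      })
    sub_img <- img[rr, cc]
    sub_img[win] <- tex[win]
    img[rr, cc] <- sub_img
  }
  if (spec$illumination != 0) {
    ramp <- outer(seq(-0.5, 0.5, length.out = H),
                  seq(-0.5, 0.5, length.out = W), `+`)
    img <- img * (1 + spec$illumination * ramp)
  }
  img <- gaussian_blur(img, spec$blur_sigma)
  if (spec$noise_sigma > 0)
    img <- img + matrix(rnorm(H * W, sd = spec$noise_sigma), H, W)
  img <- pmin(pmax(img, 0), 1)
  list(image = img, labels = labels)
}

#' Generate a thin-lattice scene with fractured struts
#'
#' A regular grid of thin bright struts on a dark background; a random
#' subset of struts is deleted ("fractures"), each surviving strut gets its
#' own brightness, and noise is added. The returned mask is binary (no
#' regions in contact are distinguished).
#'
#' @param spec A `bb_scene_spec` (`deletion_rate`, `noise_sigma`,
#'   `blur_sigma` are used).
#' @param seed RNG seed.
#' @param pitch Lattice pitch in pixels.
#' @param strut_width Strut thickness in pixels.
#' @return A list with `image` (numeric matrix 0..1) and `mask` (logical
#'   strut-pixel matrix).
#' @export
make_lattice <- function(spec = scene_spec(), seed = 1L, pitch = 32L,
                         strut_width = 3L) {
  set.seed(seed)
  H <- spec$height; W <- spec$width
  img <- matrix(0.05, H, W)
  mask <- matrix(FALSE, H, W)
  nodes_r <- seq(1L, H, by = pitch)
  nodes_c <- seq(1L, W, by = pitch)
  half <- strut_width %/% 2
  add_strut <- function(r1, c1, r2, c2) {
    rr <- max(1L, min(r1, r2) - half):min(H, max(r1, r2) + half)
    cc <- max(1L, min(c1, c2) - half):min(W, max(c1, c2) + half)
    bright <- runif(1, 0.5, 0.9)
    img[rr, cc] <<- pmax(img[rr, cc], bright)
    mask[rr, cc] <<- TRUE
  }
  for (r in nodes_r) for (ci in seq_along(nodes_c[-length(nodes_c)])) {
    if (runif(1) >= spec$deletion_rate)
      add_strut(r, nodes_c[ci], r, nodes_c[ci + 1])
  }
  for (c in nodes_c) for (ri in seq_along(nodes_r[-length(nodes_r)])) {
    if (runif(1) >= spec$deletion_rate)
      add_strut(nodes_r[ri], c, nodes_r[ri + 1], c)
  }
  img <- gaussian_blur(img, spec$blur_sigma)
  if (spec$noise_sigma > 0)
    img <- img + matrix(rnorm(H * W, sd = spec$noise_sigma), H, W)
  img <- pmin(pmax(img, 0), 1)
  list(image = img, mask = mask)
}

#' Write a ready-to-train synthetic project
#'
#' Creates a project tree ([create_project()]) and fills it with generated
#' training and test scenes: one labeled training scene and one test scene
#' from the same spec under different seeds, with test ground truth under
#' `test_masks/` for evaluation.
#'
#' @param root Project directory to create.
#' @param preset `"disks"` or `"lattice"`.
#' @param spec A `bb_scene_spec`.
#' @param seed Base RNG seed (the test scene uses `seed + 1`).
#' @param params Optional `bb_params` overriding the defaults written to
#'   the parameter file.
#' @return The `bb_project` layout, invisibly.
#' @export
make_fixture_project <- function(root, preset = c("disks", "lattice"),
                                 spec = scene_spec(), seed = 1L,
                                 params = NULL) {
  preset <- match.arg(preset)
  layout <- create_project(root)
  dir.create(file.path(root, "test_masks"), showWarnings = FALSE)
  gen <- function(s) {
    if (preset == "disks") make_disks(spec, seed = s)
    else { sc <- make_lattice(spec, seed = s)
           list(image = sc$image, labels = matrix(as.integer(sc$mask),
                                                  nrow(sc$mask))) }
  }
  train <- gen(seed)
  test <- gen(seed + 1L)
  tiff::writeTIFF(train$image, file.path(root, "train_images", "scene001.tif"),
                  bits.per.sample = 16, compression = "none")
  write_label_raster(train$labels,
                     file.path(root, "train_masks", "scene001.tif"))
  tiff::writeTIFF(test$image, file.path(root, "test_images", "scene002.tif"),
                  bits.per.sample = 16, compression = "none")
  write_label_raster(test$labels,
                     file.path(root, "test_masks", "scene002.tif"))
  if (!is.null(params)) write_params(params, layout$param_file)
  invisible(layout)
}
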