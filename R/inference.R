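# Whole-image prediction and assembly: batched per-pixel forward passes
# produce a probability map and a distance map; thresholding the first and
# watershedding the second splits the foreground into labeled regions, in
# particular separating regions in contact at the distance valleys.

#' Per-pixel probability and distance maps
#'
#' Runs one forward pass per AOI pixel (batched) over the normalized image.
#' The distance output is clipped to `[0, dist_cap]`; pixels outside the AOI
#' are 0 in both maps.
#'
#' @param net A trained `bb_network`.
#' @param image A `bb_image`, numeric matrix, or H x W x 3 array.
#' @param aoi Logical AOI matrix or `NULL`.
#' @param params A `bb_params` list (`scales`, `patch_side`, `dist_cap`,
#'   `rgb_mode` are used).
#' @param batch Pixels per forward batch.
#' @return A list with numeric matrices `prob` and `dist` of the image's
#'   dimensions.
#' @export
predict_maps <- function(net, image, aoi = NULL, params = default_params(),
                         batch = 128L) {
  if (!isTRUE(net$trained)) stop("the network has not been trained")
  px <- if (inherits(image, "bb_image")) image$pixels else image
  if (!is.matrix(px) && identical(params$rgb_mode, "luma"))
    px <- rgb_to_luma(px)
  norm <- normalize_image(px)
  dims <- if (is.matrix(norm)) dim(norm) else dim(norm)[1:2]
  keep <- aoi_or_default(aoi, dims)
  prob <- matrix(0, dims[1], dims[2])
  dist <- matrix(0, dims[1], dims[2])
  idx <- which(keep)
  if (length(idx) == 0) return(list(prob = prob, dist = dist))
  centers <- cbind(((idx - 1) %% dims[1]) + 1, ((idx - 1) %/% dims[1]) + 1)
  for (start in seq(1, length(idx), by = batch)) {
    sel <- start:min(start + batch - 1, length(idx))
    X <- extract_stacks(norm, centers[sel, , drop = FALSE],
                        params$scales, params$patch_side)
    r <- net_forward(net, X, clip = TRUE, d_max = params$dist_cap)
    prob[idx[sel]] <- r$prob
    dist[idx[sel]] <- r$dist
  }
  list(prob = prob, dist = dist)
}

#' Threshold a probability map
#'
#' @param pmap Numeric probability matrix.
#' @param threshold Threshold in (0, 1); pixels with `p >= threshold` are
#'   foreground (ties pass).
#' @return Logical matrix.
#' @export
binarize <- function(pmap, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  pmap >= threshold
}

#' Split the foreground into labeled regions by seeded watershed
#'
#' Markers are the 8-connected components of the high-distance plateau
#' (`dist >= marker_level`) inside the foreground; every foreground pixel is
#' then assigned to a marker basin by flooding the inverted distance map
#' (high distances first, ties to the earlier-queued basin). Basins smaller
#' than `min_region_px` are removed; the survivors are renumbered 1..K in
#' raster-scan order of their first pixel.
#'
#' @param binary Logical foreground matrix.
#' @param dmap Numeric distance matrix of the same shape.
#' @param params A `bb_params` list (`marker_level`, `min_region_px`).
#' @return A list of class `bb_segmentation` with `labels` (integer matrix)
#'   and `regions` (the [region_table()] data.frame).
#' @export
watershed_split <- function(binary, dmap, params = default_params()) {
  stopifnot(all(dim(binary) == dim(dmap)))
  lev <- effective_marker_level(params)
  if (any(binary) && !any(binary & dmap >= lev))
    warning("no watershed markers found (no distance plateau >= ",
            lev, "); returning an empty segmentation")
  lab <- cpp_watershed(binary, dmap, lev, params$min_region_px)
  structure(list(labels = lab, regions = region_table(lab)),
            class = "bb_segmentation")
}

#' Region summary table
#'
#' @param seg A `bb_segmentation` or an integer label matrix.
#' @return A data.frame with one row per region: `id`, `area`, `centroid_r`,
#'   `centroid_c`, `rmin`, `rmax`, `cmin`, `cmax`.
#' @export
region_table <- function(seg) {
  lab <- if (inherits(seg, "bb_segmentation")) seg$labels else seg
  idx <- which(lab > 0)
  if (length(idx) == 0)
    return(data.frame(id = integer(0), area = integer(0),
                      centroid_r = numeric(0), centroid_c = numeric(0),
                      rmin = integer(0), rmax = integer(0),
                      cmin = integer(0), cmax = integer(0)))
  ids <- lab[idx]
  r <- ((idx - 1) %% nrow(lab)) + 1
  c <- ((idx - 1) %/% nrow(lab)) + 1
  sp <- split(seq_along(idx), ids)
  out <- do.call(rbind, lapply(names(sp), function(k) {
    i <- sp[[k]]
    data.frame(id = as.integer(k), area = length(i),
               centroid_r = mean(r[i]), centroid_c = mean(c[i]),
               rmin = min(r[i]), rmax = max(r[i]),
               cmin = min(c[i]), cmax = max(c[i]))
  }))
  out[order(out$id), , drop = FALSE]
}

#' Segment one image end to end
#'
#' [predict_maps()], [binarize()] and [watershed_split()] in sequence.
#'
#' @inheritParams predict_maps
#' @return A list with `prob`, `dist`, `binary` and `seg`
#'   (a `bb_segmentation`).
#' @export
segment_image <- function(net, image, aoi = NULL, params = default_params(),
                          batch = 128L) {
  maps <- predict_maps(net, image, aoi, params, batch = batch)
  bin <- binarize(maps$prob, params$prob_threshold)
  keep <- aoi_or_default(aoi, dim(maps$prob))
  bin <- bin & keep
  seg <- watershed_split(bin, maps$dist, params)
  list(prob = maps$prob, dist = maps$dist, binary = bin, seg = seg)
}
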