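# Training-target construction: each labeled pixel gets a binary class
# ("innie" = inside any region) and a capped Euclidean distance to the
# nearest region edge. An edge pixel is the nearest pixel carrying a
# *different* ID — background or another region — so touching regions carry
# a distance valley on both sides of their contact, which is what lets the
# watershed separate them later.

#' Binary innie/outie target from a label map
#'
#' @param map Integer label matrix (0 = background).
#' @return Logical matrix, `TRUE` exactly where `map > 0`.
#' @export
binarize_labels <- function(map) {
  stopifnot(is.matrix(map))
  map > 0
}

#' Capped distance-to-edge target from a label map
#'
#' For every pixel inside region `k`, the Euclidean (center-to-center)
#' distance to the nearest pixel whose ID differs from `k`, capped at
#' `d_max`; 0 on background. A solid region wider than `2 * d_max` has an
#' interior plateau equal to `d_max` exactly.
#'
#' @param map Integer label matrix.
#' @param d_max Positive distance cap in pixels.
#' @return Numeric matrix of distances in `[0, d_max]`.
#' @export
edge_distance <- function(map, d_max) {
  stopifnot(is.matrix(map), d_max >= 1)
  storage.mode(map) <- "integer"
  cpp_edge_distance(map, as.numeric(d_max))
}

#' Resolve an area-of-interest mask
#'
#' @param aoi Logical matrix, or `NULL` for all-true.
#' @param dim Image dimensions `c(H, W)` used when `aoi` is `NULL`.
#' @return Logical H x W matrix.
#' @export
aoi_or_default <- function(aoi, dim) {
  if (is.null(aoi)) return(matrix(TRUE, dim[1], dim[2]))
  stopifnot(is.logical(aoi), all(dim(aoi) == dim))
  aoi
}
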