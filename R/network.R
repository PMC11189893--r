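# The dual-output CNN. Fifteen counted layers: six 3x3 convolutions, three
# 2x2 max-pooling layers, four dense layers, and two single-unit heads
# (sigmoid class probability, linear edge distance). Blocks 2 and 3 carry an
# additive skip connection from their input, projected by a 1x1 convolution
# plus pooling where shapes differ. With the default 25-pixel patches the
# tensor entering the flatten is 2 x 2 x 96.

#' Network architecture specification
#'
#' @param patch_side Input patch side in pixels (odd; default 25).
#' @param n_channels Number of input channels (one per scale, times image
#'   channels).
#' @param conv_widths Filter counts of the three convolutional blocks.
#' @param dense_widths Widths of the four dense layers.
#' @return A list of class `bb_net_spec`.
#' @export
network_spec <- function(patch_side = 25L, n_channels = 4L,
                         conv_widths = c(24L, 48L, 96L),
                         dense_widths = c(384L, 96L, 48L, 16L)) {
  stopifnot(length(conv_widths) == 3, length(dense_widths) == 4,
            n_channels >= 1)
  spec <- structure(
    list(patch_side = as.integer(patch_side),
         n_channels = as.integer(n_channels),
         conv_widths = as.integer(conv_widths),
         dense_widths = as.integer(dense_widths),
         activation = "relu",
         heads = c(class = "sigmoid", dist = "linear")),
    class = "bb_net_spec")
  shape_plan(spec) # validates
  spec
}

#' Spatial shape plan of the network
#'
#' Traces the feature-map side through the three blocks
#' (`patch_side -> pool -> pool -> valid conv -> pool`) and errors, naming
#' the offending block, if the plan cannot reach a consistent final map.
#'
#' @param spec A `bb_net_spec`.
#' @return A list with per-stage spatial sides and `final` `(h, h, w3)`.
#' @export
shape_plan <- function(spec) {
  p <- spec$patch_side
  h1 <- p %/% 2
  h2 <- h1 %/% 2
  h3 <- h2 - 2
  if (h3 < 1)
    stop("shape plan fails in block 3: valid 3x3 convolution needs a ",
         "feature map of side >= 3, got ", h2)
  h4 <- h3 %/% 2
  if (h2 %% 3 != 0 || h2 %/% 3 != h4)
    stop("shape plan fails in block 3: skip pooling (3x3, stride 3) of side ",
         h2, " does not match the main path side ", h4)
  flat <- h4 * h4 * spec$conv_widths[3]
  list(block1 = c(p, h1), block2 = c(h1, h2), block3 = c(h2, h3, h4),
       final = c(h4, h4, spec$conv_widths[3]), flatten = flat)
}

#' Count the network's layers
#'
#' Six convolutional layers, three max-pooling layers, four dense layers and
#' two output heads; skip projections are not counted.
#'
#' @param spec A `bb_net_spec`.
#' @return Integer layer count (15 for the default family).
#' @export
count_layers <- function(spec) {
  6L + 3L + length(spec$dense_widths) + length(spec$heads)
}

he_init <- function(nout, nin, fan_in) {
  matrix(stats::rnorm(nout * nin, sd = sqrt(2 / fan_in)), nout, nin)
}

#' Build an (untrained) network
#'
#' Initializes all weights (He-normal scaled by fan-in, zero biases) from
#' the given seed. Two builds with the same spec and seed are identical.
#'
#' @param spec A `bb_net_spec`.
#' @param seed RNG seed for the initialization.
#' @return A list of class `bb_network` with fields `spec`, `weights`,
#'   `trained`, `provenance`.
#' @export
build_network <- function(spec, seed = 1L) {
  plan <- shape_plan(spec)
  set.seed(seed)
  S <- spec$n_channels
  w <- spec$conv_widths
  d <- spec$dense_widths
  flat <- plan$flatten
  if (d[1] <= 0) stop("dense widths must be positive")
  W <- list(
    c1a_W = he_init(w[1], S * 9, S * 9),    c1a_b = numeric(w[1]),
    c1b_W = he_init(w[1], w[1] * 9, w[1] * 9), c1b_b = numeric(w[1]),
    c2a_W = he_init(w[2], w[1] * 9, w[1] * 9), c2a_b = numeric(w[2]),
    c2b_W = he_init(w[2], w[2] * 9, w[2] * 9), c2b_b = numeric(w[2]),
    s2_W  = he_init(w[2], w[1], w[1]),      s2_b = numeric(w[2]),
    c3a_W = he_init(w[3], w[2] * 9, w[2] * 9), c3a_b = numeric(w[3]),
    c3b_W = he_init(w[3], w[3] * 9, w[3] * 9), c3b_b = numeric(w[3]),
    s3_W  = he_init(w[3], w[2], w[2]),      s3_b = numeric(w[3]),
    d1_W = he_init(d[1], flat, flat),       d1_b = numeric(d[1]),
    d2_W = he_init(d[2], d[1], d[1]),       d2_b = numeric(d[2]),
    d3_W = he_init(d[3], d[2], d[2]),       d3_b = numeric(d[3]),
    d4_W = he_init(d[4], d[3], d[3]),       d4_b = numeric(d[4]),
    hc_W = he_init(1, d[4], d[4]),          hc_b = numeric(1),
    hd_W = he_init(1, d[4], d[4]),          hd_b = numeric(1)
  )
  structure(list(spec = spec, weights = W, trained = FALSE,
                 provenance = list(init_seed = seed)),
            class = "bb_network")
}

#' Number of trainable parameters
#'
#' @param net A `bb_network`.
#' @return Integer parameter count.
#' @export
n_params <- function(net) {
  sum(vapply(net$weights, length, numeric(1)))
}

#' Forward pass
#'
#' Computes the class probability and edge-distance output for a batch of
#' patch stacks. The pass is deterministic: repeated calls on the same
#' weights and input agree exactly.
#'
#' @param net A `bb_network`.
#' @param stacks A `patch_side^2 * n_channels` x B matrix (one stack per
#'   column, as produced by [extract_stacks()]), or a single stack array.
#' @param clip If `TRUE` (default), the distance output is clipped to
#'   `[0, d_max]`.
#' @param d_max Upper clip value (default `Inf`, i.e. clip at 0 only).
#' @return A list with numeric vectors `prob` (in `[0, 1]`) and `dist`.
#' @export
net_forward <- function(net, stacks, clip = TRUE, d_max = Inf) {
  if (is.array(stacks) && length(dim(stacks)) == 3)
    stacks <- matrix(stacks, ncol = 1)
  if (is.vector(stacks)) stacks <- matrix(stacks, ncol = 1)
  spec <- net$spec
  if (nrow(stacks) != spec$patch_side^2 * spec$n_channels)
    stop("stack shape does not match the network input: expected ",
         spec$patch_side^2 * spec$n_channels, " rows, got ", nrow(stacks))
  r <- cpp_net_pass(net$weights, stacks, spec$patch_side, spec$n_channels,
                    spec$conv_widths[1], spec$conv_widths[2],
                    spec$conv_widths[3],
                    numeric(0), numeric(0), FALSE)
  dist <- as.vector(r$dist)
  if (clip) dist <- pmin(pmax(dist, 0), d_max)
  list(prob = as.vector(r$prob), dist = dist)
}
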