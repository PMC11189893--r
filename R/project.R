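# No-code project workflow. A project is a folder tree plus a plain-text
# parameter file; the train/predict/eval verbs operate on it without any
# further configuration.

project_subdirs <- c("train_images", "train_masks", "test_images", "aoi",
                     "outputs", "models")

#' Create a segmentation project
#'
#' Lays out the project folder structure (`train_images/`, `train_masks/`,
#' `test_images/`, `aoi/`, `outputs/`, `models/`) and writes `params.txt`
#' with every parameter at its default. Refuses to touch a directory that
#' already contains a project.
#'
#' @param root Project directory (created if missing).
#' @return A list of class `bb_project` with `root`, the subdirectory paths
#'   and `param_file`.
#' @export
create_project <- function(root) {
  pf <- file.path(root, "params.txt")
  if (file.exists(pf))
    stop("a project already exists at ", root,
         " (found params.txt); refusing to overwrite")
  if (!dir.exists(root) &&
      !dir.create(root, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create project directory ", root)
  for (d in project_subdirs)
    dir.create(file.path(root, d), showWarnings = FALSE)
  write_params(default_params(), pf)
  layout <- c(list(root = root),
              stats::setNames(as.list(file.path(root, project_subdirs)),
                              project_subdirs),
              list(param_file = pf))
  structure(layout, class = "bb_project")
}

open_project <- function(root) {
  pf <- file.path(root, "params.txt")
  if (!file.exists(pf)) stop("no project found at ", root)
  structure(c(list(root = root),
              stats::setNames(as.list(file.path(root, project_subdirs)),
                              project_subdirs),
              list(param_file = pf)),
            class = "bb_project")
}

load_image_for_net <- function(path, params) {
  img <- read_raster(path)
  px <- img$pixels
  if (!is.matrix(px) && identical(params$rgb_mode, "luma"))
    px <- rgb_to_luma(px)
  list(name = img$name, pixels = px)
}

read_optional_aoi <- function(aoi_dir, name, dims) {
  p <- find_raster(aoi_dir, name)
  if (is.null(p)) return(NULL)
  m <- read_label_raster(p)
  if (!all(dim(m) == dims))
    stop("AOI mask ", p, " does not match the image dimensions")
  m > 0
}

net_channels <- function(params, image_px) {
  per_scale <- if (is.matrix(image_px) ||
                   identical(params$rgb_mode, "luma")) 1L else 3L
  length(params$scales) * per_scale
}

#' Train a project's network
#'
#' Reads the parameter file, pairs every training image with its same-named
#' mask (an error if one is missing), derives the per-pixel class and
#' capped-distance targets, draws the class-balanced fractional pixel
#' sample, trains the network, and saves the model plus a training log.
#'
#' @param root Project directory.
#' @return Invisibly, a list with `net`, `log` and `budget`.
#' @export
train_project <- function(root) {
  proj <- open_project(root)
  params <- load_params(proj$param_file)
  files <- list_rasters(proj$train_images)
  if (length(files) == 0) stop("no training images in ", proj$train_images)
  imgs <- list(); maps <- list(); aois <- list()
  for (i in seq_along(files)) {
    im <- load_image_for_net(file.path(proj$train_images, files[i]), params)
    mp <- find_raster(proj$train_masks, im$name)
    if (is.null(mp))
      stop("training image '", im$name, "' has no mask in ",
           proj$train_masks)
    mask <- read_label_raster(mp)
    if (!all(dim(mask) == dim(im$pixels)[1:2]))
      stop("mask for '", im$name, "' does not match the image dimensions")
    imgs[[i]] <- im
    maps[[i]] <- mask
    aois[i] <- list(read_optional_aoi(proj$aoi, im$name, dim(mask)))
  }
  draw <- draw_samples(maps, aois, params, seed = params$seed)
  samples <- draw$samples
  # materialize patch stacks image by image
  X <- matrix(0, params$patch_side^2 * net_channels(params, imgs[[1]]$pixels),
              nrow(samples))
  for (i in seq_along(imgs)) {
    sel <- which(samples$img == i)
    if (length(sel) == 0) next
    norm <- normalize_image(imgs[[i]]$pixels)
    X[, sel] <- extract_stacks(norm,
                               cbind(samples$row[sel], samples$col[sel]),
                               params$scales, params$patch_side)
  }
  spec <- network_spec(patch_side = params$patch_side,
                       n_channels = nrow(X) / params$patch_side^2)
  net <- build_network(spec, seed = params$seed)
  fit <- fit_network(net, X, samples$class, samples$dist, params,
                     seed = params$seed, checkpoint_dir = proj$models)
  fit$net$provenance$params <- params
  fit$net$provenance$budget <- draw$budget
  saveRDS(fit$net, file.path(proj$models, "model.rds"))
  write.csv(fit$log, file.path(proj$outputs, "train_log.csv"),
            row.names = FALSE)
  invisible(list(net = fit$net, log = fit$log, budget = draw$budget))
}

#' Segment a project's test images
#'
#' Loads the trained model and segments every image in `test_images/`,
#' writing `<name>_seg.tif` (16-bit labels) and `<name>_regions.csv` to
#' `outputs/`, plus optional probability / distance / binary rasters
#' according to the save flags in the parameter file.
#'
#' @param root Project directory.
#' @return Invisibly, a named list of `bb_segmentation` objects.
#' @export
predict_project <- function(root) {
  proj <- open_project(root)
  params <- load_params(proj$param_file)
  model_path <- file.path(proj$models, "model.rds")
  if (!file.exists(model_path))
    stop("no trained model found; run train_project() first")
  net <- readRDS(model_path)
  files <- list_rasters(proj$test_images)
  if (length(files) == 0) stop("no test images in ", proj$test_images)
  out <- list()
  for (f in files) {
    im <- load_image_for_net(file.path(proj$test_images, f), params)
    aoi <- read_optional_aoi(proj$aoi, im$name, dim(im$pixels)[1:2])
    res <- segment_image(net, im$pixels, aoi, params)
    base <- file.path(proj$outputs, im$name)
    write_label_raster(res$seg$labels, paste0(base, "_seg.tif"))
    write.csv(res$seg$regions, paste0(base, "_regions.csv"),
              row.names = FALSE)
    if (isTRUE(params$save_prob_map))
      write_float_raster(res$prob, paste0(base, "_prob.tif"))
    if (isTRUE(params$save_dist_map))
      write_float_raster(res$dist, paste0(base, "_dist.tif"))
    if (isTRUE(params$save_binary))
      write_label_raster(matrix(as.integer(res$binary), nrow(res$binary)),
                         paste0(base, "_bin.tif"))
    out[[im$name]] <- res$seg
  }
  invisible(out)
}

#' Evaluate a project's segmentations
#'
#' Scores every written segmentation in `outputs/` against ground-truth
#' label maps found in `root/truth_dir/` and writes per-region and summary
#' CSVs. The dataset SEG pools regions across images.
#'
#' @param root Project directory.
#' @param truth_dir Subdirectory of `root` holding the ground-truth label
#'   maps (same base names as the test images).
#' @return Invisibly, a list with `per_image` (named numeric), `seg`
#'   (pooled) and `rows`.
#' @export
eval_project <- function(root, truth_dir = "test_masks") {
  proj <- open_project(root)
  params <- load_params(proj$param_file)
  tdir <- file.path(root, truth_dir)
  if (!dir.exists(tdir)) stop("truth directory not found: ", tdir)
  segs <- list.files(proj$outputs, pattern = "_seg\\.(tif|tiff)$")
  if (length(segs) == 0)
    stop("no segmentations in ", proj$outputs, "; run predict_project() first")
  results <- list(); names_out <- character(0)
  for (f in segs) {
    name <- sub("_seg\\.(tif|tiff)$", "", f)
    tp <- find_raster(tdir, name)
    if (is.null(tp)) stop("no ground truth for '", name, "' in ", tdir)
    truth <- read_label_raster(tp)
    pred <- read_label_raster(file.path(proj$outputs, f))
    aoi <- read_optional_aoi(proj$aoi, name, dim(truth))
    results[[length(results) + 1]] <-
      seg_score(truth, pred, aoi, strict_half = isTRUE(params$seg_strict_half))
    names_out <- c(names_out, name)
  }
  pooled <- seg_pool(results)
  per_image <- stats::setNames(
    vapply(results, function(r) r$seg, numeric(1)), names_out)
  pooled$rows$image <- names_out[pooled$rows$image]
  write.csv(pooled$rows, file.path(proj$outputs, "seg_regions.csv"),
            row.names = FALSE)
  write.csv(data.frame(image = c(names_out, "POOLED"),
                       seg = c(per_image, pooled$seg)),
            file.path(proj$outputs, "seg_scores.csv"), row.names = FALSE)
  invisible(list(per_image = per_image, seg = pooled$seg,
                 rows = pooled$rows))
}
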