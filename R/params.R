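# Parameter file handling: key=value lines, "#" comments, case-insensitive
# keys. Every run of the workflow is driven by one of these files so that no
# code needs to be edited.

bb_param_defs <- function() {
  list(
    scales = list(
      default = c(1L, 3L, 9L, 27L), kind = "int_vec",
      check = function(v) length(v) >= 1 && all(v >= 1),
      msg = "must be one or more positive integers"),
    patch_side = list(
      default = 25L, kind = "int",
      check = function(v) v >= 1 && v %% 2 == 1,
      msg = "must be an odd positive integer"),
    dist_cap = list(
      default = 10L, kind = "int",
      check = function(v) v >= 1,
      msg = "must be a positive integer (pixels)"),
    fraction = list(
      default = 1, kind = "real",
      check = function(v) v > 0 && v <= 1,
      msg = "must lie in (0, 1]"),
    epochs = list(
      default = 2L, kind = "int",
      check = function(v) v >= 1,
      msg = "must be a positive integer"),
    balance_classes = list(default = TRUE, kind = "flag"),
    augment = list(default = TRUE, kind = "flag"),
    learning_rate = list(
      default = 0.001, kind = "real",
      check = function(v) v > 0,
      msg = "must be a positive real"),
    prob_threshold = list(
      default = 0.5, kind = "real",
      check = function(v) v > 0 && v < 1,
      msg = "must lie in (0, 1)"),
    min_region_px = list(
      default = 10L, kind = "int",
      check = function(v) v >= 0,
      msg = "must be a non-negative integer"),
    seed = list(default = 1L, kind = "int",
      check = function(v) TRUE, msg = ""),
    batch_size = list(
      default = 64L, kind = "int",
      check = function(v) v >= 1,
      msg = "must be a positive integer"),
    marker_level = list(
      default = "auto", kind = "auto_real",
      check = function(v) identical(v, "auto") || (is.numeric(v) && v > 0),
      msg = "must be 'auto' or a positive real (pixels)"),
    rgb_mode = list(
      default = "luma", kind = "choice", choices = c("luma", "keep3")),
    seg_strict_half = list(default = FALSE, kind = "flag"),
    save_prob_map = list(default = FALSE, kind = "flag"),
    save_dist_map = list(default = FALSE, kind = "flag"),
    save_binary = list(default = FALSE, kind = "flag")
  )
}

#' Default parameter set
#'
#' Returns the full parameter set at its default values. Defaults follow the
#' published workflow: four context scales (1, 3, 9, 27), 25-pixel patches, a
#' 10-pixel distance cap, Adam learning rate 0.001, two epochs, class
#' balancing and dihedral augmentation on.
#'
#' @return A named list of class `bb_params`.
#' @export
default_params <- function() {
  p <- lapply(bb_param_defs(), function(d) d$default)
  structure(p, class = "bb_params")
}

check_param <- function(key, value) {
  defs <- bb_param_defs()
  d <- defs[[key]]
  if (is.null(d)) stop("unknown parameter '", key, "'", call. = FALSE)
  if (identical(d$kind, "choice")) {
    if (!value %in% d$choices)
      stop("parameter '", key, "' must be one of: ",
           paste(d$choices, collapse = ", "), call. = FALSE)
  } else if (!is.null(d$check) && !d$check(value)) {
    stop("parameter '", key, "' ", d$msg, call. = FALSE)
  }
  invisible(TRUE)
}

#' Validate a parameter set
#'
#' Checks every field against its allowed range, naming the offending key on
#' failure.
#'
#' @param params A `bb_params` list.
#' @return The validated parameter set, invisibly.
#' @export
validate_params <- function(params) {
  defs <- bb_param_defs()
  unknown <- setdiff(names(params), names(defs))
  if (length(unknown) > 0)
    stop("unknown parameter '", unknown[1], "'", call. = FALSE)
  missing <- setdiff(names(defs), names(params))
  if (length(missing) > 0)
    stop("missing parameter '", missing[1], "'", call. = FALSE)
  for (key in names(defs)) check_param(key, params[[key]])
  invisible(params)
}

# shortest decimal representation that parses back to exactly x
fmt_real <- function(x) {
  for (d in 1:17) {
    s <- formatC(x, digits = d, format = "g")
    if (as.numeric(s) == x) return(s)
  }
  s
}

fmt_value <- function(key, value, defs = bb_param_defs()) {
  kind <- defs[[key]]$kind
  switch(kind,
    int_vec = paste(value, collapse = ","),
    int = as.character(value),
    real = fmt_real(value),
    flag = if (isTRUE(value)) "1" else "0",
    auto_real = if (identical(value, "auto")) "auto" else fmt_real(value),
    choice = value
  )
}

parse_value <- function(key, text, defs = bb_param_defs()) {
  d <- defs[[key]]
  if (is.null(d)) stop("unknown parameter '", key, "'", call. = FALSE)
  text <- trimws(text)
  bad <- function() stop("parameter '", key, "' has unreadable value '", text,
                         "'", call. = FALSE)
  out <- switch(d$kind,
    int_vec = {
      parts <- trimws(strsplit(text, ",", fixed = TRUE)[[1]])
      v <- suppressWarnings(as.numeric(parts))
      if (length(v) == 0 || anyNA(v) || any(v != round(v))) bad()
      as.integer(v)
    },
    int = {
      v <- suppressWarnings(as.numeric(text))
      if (is.na(v) || v != round(v)) bad()
      as.integer(v)
    },
    real = {
      v <- suppressWarnings(as.numeric(text))
      if (is.na(v)) bad()
      v
    },
    flag = {
      lv <- tolower(text)
      if (lv %in% c("1", "true", "yes", "on")) TRUE
      else if (lv %in% c("0", "false", "no", "off")) FALSE
      else bad()
    },
    auto_real = {
      if (tolower(text) == "auto") "auto"
      else {
        v <- suppressWarnings(as.numeric(text))
        if (is.na(v)) bad()
        v
      }
    },
    choice = tolower(text)
  )
  check_param(key, out)
  out
}

#' Read a parameter file
#'
#' Parses a `key=value` parameter file. Keys are case-insensitive, blank
#' lines and `#` comments are ignored, omitted keys take their defaults, and
#' unknown keys or out-of-range values raise an error naming the key.
#'
#' @param file Path to the parameter file.
#' @return A validated `bb_params` list.
#' @export
load_params <- function(file) {
  if (!file.exists(file)) stop("parameter file not found: ", file)
  lines <- readLines(file, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  p <- default_params()
  defs <- bb_param_defs()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop("cannot parse parameter line: '", ln, "'", call. = FALSE)
    key <- tolower(trimws(sub("=.*$", "", ln)))
    val <- sub("^[^=]*=", "", ln)
    if (!key %in% names(defs))
      stop("unknown parameter '", key, "'", call. = FALSE)
    p[[key]] <- parse_value(key, val, defs)
  }
  validate_params(p)
  p
}

#' Write a parameter file
#'
#' Serializes a parameter set as `key=value` lines. `load_params()` of the
#' written file reproduces the parameter set exactly.
#'
#' @param params A `bb_params` list.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_params <- function(params, file) {
  validate_params(params)
  defs <- bb_param_defs()
  lines <- c("# segmentation project parameters",
             vapply(names(defs),
                    function(k) paste0(k, "=", fmt_value(k, params[[k]], defs)),
                    character(1)))
  writeLines(lines, file)
  invisible(file)
}

# marker_level resolves to dist_cap - 2 when "auto": markers are the high
# plateau of the distance map, well clear of regression noise at edges.
effective_marker_level <- function(params) {
  if (identical(params$marker_level, "auto")) params$dist_cap - 2
  else params$marker_level
}
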