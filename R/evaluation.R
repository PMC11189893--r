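# SEG scoring: each true region is matched to the predicted region of
# highest overlap and scored by their Jaccard index, zeroed when the
# intersection covers less than half of the true region; SEG is the mean
# over true regions.

#' Jaccard index of two pixel sets
#'
#' @param A,B Logical matrices of the same shape (A must be non-empty).
#' @return `|A intersect B| / |A union B|`; 0 when `B` is empty.
#' @export
jaccard <- function(A, B) {
  stopifnot(all(dim(A) == dim(B)))
  if (!any(A)) stop("jaccard is undefined for an empty reference set")
  inter <- sum(A & B)
  uni <- sum(A | B)
  inter / uni
}

#' SEG score of a predicted segmentation against ground truth
#'
#' For each true region, the predicted region with the largest intersection
#' is selected (ties broken by larger Jaccard, then lower predicted ID). The
#' region scores its Jaccard index if the intersection covers at least half
#' of the true region's area, else 0; SEG is the mean score over true
#' regions. Pixels outside the AOI are excluded from all counts.
#'
#' @param truth Integer true label matrix (>= 1 region inside the AOI).
#' @param pred Integer predicted label matrix (or `bb_segmentation`).
#' @param aoi Logical AOI matrix or `NULL`.
#' @param strict_half If `TRUE`, require the intersection to *exceed* half
#'   the true area (the Cell Tracking Challenge convention) instead of the
#'   default at-least-half rule.
#' @return A list of class `bb_seg_result` with `rows` (per-true-region
#'   data.frame: `true_id`, `pred_id`, `intersection`, `union`, `jaccard`,
#'   `score`) and `seg` (the mean score).
#' @export
seg_score <- function(truth, pred, aoi = NULL, strict_half = FALSE) {
  if (inherits(pred, "bb_segmentation")) pred <- pred$labels
  if (!all(dim(truth) == dim(pred)))
    stop("truth and prediction have different shapes")
  keep <- aoi_or_default(aoi, dim(truth))
  tr <- truth; tr[!keep] <- 0L
  pr <- pred; pr[!keep] <- 0L
  true_ids <- sort(unique(tr[tr > 0]))
  if (length(true_ids) == 0)
    stop("the ground truth has no region inside the AOI")
  pred_areas <- table(pr[pr > 0])
  fg <- tr > 0
  rows <- do.call(rbind, lapply(true_ids, function(tid) {
    mask_t <- tr == tid
    area_t <- sum(mask_t)
    ov <- table(pr[mask_t & pr > 0])
    if (length(ov) == 0)
      return(data.frame(true_id = tid, pred_id = NA_integer_,
                        intersection = 0L, union = area_t,
                        jaccard = 0, score = 0))
    cand <- data.frame(pid = as.integer(names(ov)),
                       inter = as.integer(ov))
    cand$union <- area_t +
      as.integer(pred_areas[as.character(cand$pid)]) - cand$inter
    cand$jac <- cand$inter / cand$union
    cand <- cand[order(-cand$inter, -cand$jac, cand$pid), , drop = FALSE]
    best <- cand[1, ]
    pass <- if (strict_half) best$inter > area_t / 2
            else best$inter >= area_t / 2
    data.frame(true_id = tid,
               pred_id = if (pass) best$pid else NA_integer_,
               intersection = best$inter, union = best$union,
               jaccard = best$jac,
               score = if (pass) best$jac else 0)
  }))
  rownames(rows) <- NULL
  structure(list(rows = rows, seg = mean(rows$score)),
            class = "bb_seg_result")
}

#' Pool SEG results across images
#'
#' SEG for a dataset is the mean over *all* true regions of the per-region
#' scores, pooled across images (each region counts once, regardless of
#' which image it came from).
#'
#' @param results A list of `bb_seg_result` objects.
#' @return A list with `rows` (all per-region rows, with an `image` column)
#'   and `seg` (the pooled mean).
#' @export
seg_pool <- function(results) {
  stopifnot(length(results) >= 1)
  rows <- do.call(rbind, lapply(seq_along(results), function(i) {
    r <- results[[i]]$rows
    r$image <- i
    r
  }))
  list(rows = rows, seg = mean(rows$score))
}
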