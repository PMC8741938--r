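#' Detection evaluation dataset
#'
#' Bundles, per image, the ground-truth cell instance mask (NULL or all-zero
#' for benign images), a benign flag, and the detections (points with
#' confidences) reported for that image. Benign images must carry zero
#' ground-truth instances; they are what the false-positive operating points
#' of the FROC are measured on.
#'
#' @param gt_masks named list of integer label matrices (or NULL entries for
#'   benign images).
#' @param detections data.frame with columns image_id, row, col, confidence
#'   (confidences in [0, 1]; image_id must name an entry of `gt_masks`).
#' @param benign character vector of benign image ids (subset of
#'   `names(gt_masks)`).
#' @return object of class `eval_dataset`.
#' @export
eval_dataset <- function(gt_masks, detections, benign = character(0)) {
  stopifnot(is.list(gt_masks), !is.null(names(gt_masks)))
  ids <- names(gt_masks)
  if (anyDuplicated(ids)) stop("eval_dataset: duplicate image ids")
  if (!all(benign %in% ids))
    stop("eval_dataset: benign ids not in gt_masks: ",
         paste(setdiff(benign, ids), collapse = ", "))
  need <- c("image_id", "row", "col", "confidence")
  stopifnot(all(need %in% names(detections)))
  if (nrow(detections) &&
      (any(detections$confidence < 0) || any(detections$confidence > 1)))
    stop("eval_dataset: confidences outside [0, 1]")
  if (nrow(detections) && !all(detections$image_id %in% ids))
    stop("eval_dataset: detections reference unknown images")
  n_gt <- vapply(ids, function(i) {
    m <- gt_masks[[i]]
    if (is.null(m)) 0L else length(unique(m[m > 0L]))
  }, integer(1))
  if (any(n_gt[benign] > 0L))
    stop("eval_dataset: benign images must have zero ground-truth instances")
  structure(list(gt_masks = gt_masks, detections = detections,
                 benign = benign, n_gt = n_gt), class = "eval_dataset")
}

#' Match point detections to ground-truth instances
#'
#' Greedy matching in descending confidence order (ties broken by row then
#' column) under the default "center-in-mask" criterion: a detection is a
#' true positive if its (row, col) falls inside a ground-truth instance that
#' no higher-confidence detection has already claimed; every other detection
#' is a false positive. Each instance is claimed at most once. Because
#' claiming follows confidence order, the matching at any confidence
#' threshold is the prefix of this one.
#'
#' @param gt_mask integer label matrix (may be NULL / all zero).
#' @param detections data.frame with row, col, confidence for one image.
#' @param criterion matching rule; only "center_in_mask" is implemented
#'   (detections are points).
#' @return list with `tp` (logical per detection, input order), `gt_hit`
#'   (logical per instance label), `n_gt`.
#' @export
match_detections <- function(gt_mask, detections,
                             criterion = c("center_in_mask")) {
  criterion <- match.arg(criterion)
  n <- nrow(detections)
  labs <- if (is.null(gt_mask)) integer(0) else unique(gt_mask[gt_mask > 0L])
  nlab <- if (length(labs)) max(labs) else 0L
  claimed <- logical(nlab)
  tp <- logical(n)
  if (n) {
    ord <- order(-detections$confidence, detections$row, detections$col)
    for (i in ord) {
      r <- as.integer(round(detections$row[i]))
      cc <- as.integer(round(detections$col[i]))
      lab <- if (is.null(gt_mask) || r < 1 || cc < 1 || r > nrow(gt_mask) ||
                 cc > ncol(gt_mask)) 0L else gt_mask[r, cc]
      if (lab > 0L && !claimed[lab]) {
        claimed[lab] <- TRUE
        tp[i] <- TRUE
      }
    }
  }
  list(tp = tp, gt_hit = claimed, n_gt = length(labs))
}

#' FROC curve and score over fixed false-positive operating points
#'
#' Sweeps the confidence threshold over all distinct detection confidences
#' (plus the empty operating point). At each threshold the instance-level
#' recall (over all images) and the mean false-positive count per benign
#' image are computed; for each target f in `fp_targets` the operating
#' point with the largest recall among those with mean benign FPs <= f is
#' chosen (at equal recall, the higher threshold). The FROC score is the
#' mean of the per-target recalls. Recalls are non-decreasing and
#' thresholds non-increasing in the target; if even threshold 0 stays below
#' a target, that target reuses the threshold-0 recall.
#'
#' @param dataset an [eval_dataset]; needs >= 1 benign image and >= 1
#'   ground-truth instance.
#' @param fp_targets false-positive operating points (mean FPs per benign
#'   image).
#' @return object of class `froc_result`: list with `points` (data.frame:
#'   fp_target, threshold, recall, mean_fps) and `froc`.
#' @export
froc_curve <- function(dataset, fp_targets = c(1, 2, 4, 8, 16, 32)) {
  stopifnot(inherits(dataset, "eval_dataset"))
  if (!length(dataset$benign))
    stop("froc_curve: needs at least one benign image to count normal-region FPs")
  total_gt <- sum(dataset$n_gt)
  if (total_gt == 0L)
    stop("froc_curve: no ground-truth instances in the dataset")
  n_benign <- length(dataset$benign)
  det <- dataset$detections
  conf_tp <- numeric(0)
  conf_fp_benign <- numeric(0)
  for (id in names(dataset$gt_masks)) {
    d <- det[det$image_id == id, , drop = FALSE]
    if (!nrow(d)) next
    m <- match_detections(dataset$gt_masks[[id]], d)
    conf_tp <- c(conf_tp, d$confidence[m$tp])
    if (id %in% dataset$benign)
      conf_fp_benign <- c(conf_fp_benign, d$confidence[!m$tp])
  }
  thresholds <- c(Inf, sort(unique(det$confidence), decreasing = TRUE))
  recall_at <- vapply(thresholds, function(t)
    sum(conf_tp >= t) / total_gt, numeric(1))
  fps_at <- vapply(thresholds, function(t)
    sum(conf_fp_benign >= t) / n_benign, numeric(1))
  pts <- lapply(fp_targets, function(f) {
    feas <- which(fps_at <= f)
    best_recall <- max(recall_at[feas])
    pick <- feas[recall_at[feas] == best_recall]
    pick <- pick[which.max(thresholds[pick])]
    data.frame(fp_target = f, threshold = thresholds[pick],
               recall = recall_at[pick], mean_fps = fps_at[pick])
  })
  pts <- do.call(rbind, pts)
  structure(list(points = pts, froc = mean(pts$recall)),
            class = "froc_result")
}

#' @export
print.froc_result <- function(x, ...) {
  cat("FROC operating points (mean FPs per benign image):\n")
  print(x$points, row.names = FALSE)
  cat(sprintf("FROC score (mean recall): %.4f\n", x$froc))
  invisible(x)
}

#' Write a FROC result as CSV + JSON summary
#'
#' @param result a [froc_result].
#' @param csv_path per-operating-point CSV destination.
#' @param json_path summary JSON destination (froc, n targets).
#' @export
write_froc <- function(result, csv_path, json_path = NULL) {
  stopifnot(inherits(result, "froc_result"))
  utils::write.csv(result$points, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(froc = result$froc,
                              n_targets = nrow(result$points)),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}
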