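# Detection metrics: confusion counts, precision / recall / F1, average
# precision by all-point PR interpolation, and mAP over IoU 0.5:0.95.

#' Corner-box IoU between one box and a matrix of boxes
#' @param box numeric length-4 `(x1, y1, x2, y2)`
#' @param boxes n x 4 matrix
#' @return numeric vector of IoUs
#' @export
box_iou <- function(box, boxes) iou_corners(box, boxes)

norm_to_corners <- function(boxes, width = 1, height = 1) {
  cbind(x1 = (boxes$cx - boxes$w / 2) * width,
        y1 = (boxes$cy - boxes$h / 2) * height,
        x2 = (boxes$cx + boxes$w / 2) * width,
        y2 = (boxes$cy + boxes$h / 2) * height)
}

#' Match detections to ground truth (one image)
#'
#' Greedy one-to-one matching in confidence order: each detection is a TP if
#' its best IoU over still-unmatched ground-truth boxes reaches the
#' threshold, otherwise an FP; leftover ground truth are FN. Detections are
#' sorted by descending confidence internally, so `TP + FN` always equals
#' the number of ground-truth boxes.
#'
#' @param detections data.frame with `x1, y1, x2, y2, conf`
#' @param gt n x 4 matrix (or data.frame) of ground-truth corner boxes
#' @param iou_thr IoU threshold
#' @return `confusion_counts`: list(TP, FP, FN) plus per-detection logical
#'   `tp` (in the sorted order) and the sorted confidences `conf`
#' @export
match_detections <- function(detections, gt, iou_thr = 0.5) {
  gt <- as.matrix(gt)
  nd <- nrow(detections)
  ng <- nrow(gt)
  if (nd > 1) detections <- detections[order(-detections$conf), , drop = FALSE]
  used <- logical(ng)
  tp <- logical(nd)
  for (i in seq_len(nd)) {
    if (!ng) break
    ious <- iou_corners(as.numeric(detections[i, c("x1", "y1", "x2", "y2")]),
                        gt)
    ious[used] <- -1
    j <- which.max(ious)
    if (length(j) && ious[j] >= iou_thr) {
      tp[i] <- TRUE
      used[j] <- TRUE
    }
  }
  structure(list(TP = sum(tp), FP = sum(!tp), FN = ng - sum(tp),
                 tp = tp, conf = if (nd) detections$conf else numeric(0)),
            class = "confusion_counts")
}

#' Precision, recall and F1 from confusion counts
#'
#' `P = TP / (TP + FP)`, `R = TP / (TP + FN)`, `F1 = 2PR / (P + R)`.
#' Zero-denominator conventions: P = 0 with no detections, R = 0 with no
#' ground truth, F1 = 0 when P + R = 0.
#' @param counts a `confusion_counts` (or list with TP/FP/FN)
#' @return list(precision, recall, f1)
#' @export
precision_recall_f1 <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; FN <- counts$FN
  p <- if (TP + FP > 0) TP / (TP + FP) else 0
  r <- if (TP + FN > 0) TP / (TP + FN) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  list(precision = p, recall = r, f1 = f1)
}

#' Average precision from ranked detections
#'
#' Sweeps the confidence ranking, accumulates the precision-recall curve and
#' integrates it. Default integration is all-point interpolation: precision
#' is replaced by its monotone (right-to-left maximum) envelope and the area
#' is the sum of recall-step rectangles. `interp = "101"` evaluates the
#' envelope on the 101-point recall grid instead.
#'
#' @param tp logical vector, TP flag per detection
#' @param conf confidences (same length; detections are ranked by it)
#' @param n_gt number of ground-truth boxes (> 0)
#' @param interp `"all"` (default) or `"101"`
#' @return AP in `[0, 1]`
#' @export
ap_from_pr <- function(tp, conf, n_gt, interp = c("all", "101")) {
  interp <- match.arg(interp)
  if (n_gt <= 0) stop("AP undefined: no ground-truth boxes")
  if (!length(tp)) return(0)
  ord <- order(-conf)
  tp <- tp[ord]
  ctp <- cumsum(tp)
  prec <- ctp / seq_along(tp)
  rec <- ctp / n_gt
  mrec <- c(0, rec)
  mpre <- c(1, prec)
  mpre <- rev(cummax(rev(mpre)))
  if (interp == "101") {
    grid <- seq(0, 1, by = 0.01)
    pr <- vapply(grid, function(g) {
      i <- which(mrec >= g)
      if (length(i)) mpre[min(i)] else 0
    }, numeric(1))
    return(mean(pr))
  }
  sum(diff(mrec) * mpre[-1])
}

#' Mean AP over IoU thresholds 0.5 to 0.95
#'
#' Arithmetic mean of the ten APs; with one class the mAP at a threshold
#' equals the AP at that threshold.
#' @param aps numeric vector of 10 APs (IoU 0.5, 0.55, ..., 0.95)
#' @return mean AP
#' @export
map50_95 <- function(aps) {
  if (length(aps) != 10 || anyNA(aps))
    stop("need exactly 10 AP values (IoU 0.50 to 0.95 in steps of 0.05)")
  mean(aps)
}

#' Evaluate a detector on a dataset
#'
#' Runs decode -> match -> metrics. The PR sweep uses a low confidence floor
#' (0.001) so the AP integral sees the full ranking; precision / recall / F1
#' are reported at the operating threshold `conf_thr` (default from the
#' model config, 0.25) and IoU `iou_thr` (0.5). Deterministic for fixed
#' weights and data.
#'
#' @param model an `ayolo_model`
#' @param dataset list of samples (`image` in `[0,255]`, `boxes`), e.g. from
#'   [load_yolo_dataset()] or built in memory; alternatively a list of
#'   pre-computed detection data.frames via `detections =`
#' @param conf_thr,iou_thr operating thresholds
#' @param detections optional list (parallel to dataset) of detection
#'   data.frames replacing the model forward pass (used by oracle tests)
#' @return `metrics_report`: list(precision, recall, f1, ap50, map50_95,
#'   per_iou, n_images, n_gt)
#' @export
evaluate_model <- function(model = NULL, dataset, conf_thr = NULL,
                           iou_thr = NULL, detections = NULL) {
  if (!length(dataset)) stop("empty dataset")
  conf_thr <- conf_thr %||% (if (!is.null(model)) model$config$conf_thr else 0.25)
  iou_thr <- iou_thr %||% (if (!is.null(model)) model$config$iou_thr else 0.5)
  if (is.null(detections)) {
    detections <- lapply(dataset, function(s) {
      img <- s$image / 255
      detect_image(model, img, conf_thr = 0.001, iou_thr = iou_thr)
    })
  }
  gts <- lapply(dataset, function(s) {
    d <- dim(s$image)
    norm_to_corners(s$boxes, d[2], d[1])
  })
  n_gt <- sum(vapply(gts, nrow, numeric(1)))
  thrs <- seq(0.5, 0.95, by = 0.05)
  aps <- vapply(thrs, function(t) {
    tp <- logical(0); conf <- numeric(0)
    for (i in seq_along(detections)) {
      m <- match_detections(detections[[i]], gts[[i]], t)
      tp <- c(tp, m$tp); conf <- c(conf, m$conf)
    }
    if (n_gt == 0) stop("AP undefined: dataset has no ground-truth boxes")
    ap_from_pr(tp, conf, n_gt)
  }, numeric(1))
  # operating-point P/R/F1
  tot <- list(TP = 0, FP = 0, FN = 0)
  for (i in seq_along(detections)) {
    di <- detections[[i]]
    di <- di[di$conf >= conf_thr, , drop = FALSE]
    m <- match_detections(di, gts[[i]], iou_thr)
    tot$TP <- tot$TP + m$TP; tot$FP <- tot$FP + m$FP; tot$FN <- tot$FN + m$FN
  }
  prf <- precision_recall_f1(tot)
  structure(list(precision = prf$precision, recall = prf$recall,
                 f1 = prf$f1, ap50 = aps[1], map50_95 = mean(aps),
                 per_iou = setNames(aps, sprintf("%.2f", thrs)),
                 n_images = length(dataset), n_gt = n_gt,
                 counts = tot),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("<metrics_report> P=%.4f R=%.4f F1=%.4f AP50=%.4f ",
                     "mAP50:95=%.4f (%d images, %d GT)\n"),
              x$precision, x$recall, x$f1, x$ap50, x$map50_95,
              x$n_images, x$n_gt))
  invisible(x)
}
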