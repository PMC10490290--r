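# Dataset splitting and k-means anchor generation.

#' Split items into train/validation/test sets
#'
#' Sizes are `round(n * r / sum(r))` for validation and test with the
#' remainder going to train (so 2700 items at 8:1:1 give 2160/270/270).
#' Items are sorted before the seeded shuffle, making the split invariant to
#' input order. The three sets are disjoint and exhaustive.
#'
#' @param items character (or other atomic) vector
#' @param ratios positive length-3 vector (train, val, test)
#' @param seed shuffle seed
#' @return list with `train`, `val`, `test`
#' @export
split_dataset <- function(items, ratios = c(8, 1, 1), seed = 0L) {
  stopifnot(length(ratios) == 3, all(ratios > 0))
  n <- length(items)
  if (n < 3) stop("fewer items (", n, ") than parts (3)")
  s <- sum(ratios)
  n_val <- round(n * ratios[2] / s)
  n_test <- round(n * ratios[3] / s)
  n_train <- n - n_val - n_test
  if (n_train < 1 || n_val < 1 || n_test < 1)
    stop("split produces an empty part for n = ", n)
  perm <- with_seed(seed, function() sample.int(n))
  shuffled <- sort(items)[perm]
  list(train = shuffled[seq_len(n_train)],
       val = shuffled[n_train + seq_len(n_val)],
       test = shuffled[n_train + n_val + seq_len(n_test)])
}

# IoU between (w, h) shape pairs (boxes anchored at a common corner).
wh_iou <- function(wh, centroids) {
  iw <- outer(wh[, 1], centroids[, 1], pmin)
  ih <- outer(wh[, 2], centroids[, 2], pmin)
  inter <- iw * ih
  a1 <- wh[, 1] * wh[, 2]
  a2 <- centroids[, 1] * centroids[, 2]
  inter / (outer(a1, a2, `+`) - inter)
}

#' k-means anchor generation
#'
#' Lloyd's algorithm on pixel `(w, h)` box shapes under the shape-aware
#' `1 - IoU` distance, seeded initialization from k distinct boxes, iterated
#' to an assignment fixpoint (or `max_iter`). Centroids are sorted ascending
#' by area and grouped 3 per detection scale.
#'
#' @param boxes a [norm_box()] table
#' @param k number of anchors (default 9)
#' @param img_size pixel scale at which anchors are expressed
#' @param seed initialization seed
#' @param max_iter iteration cap per restart (default 300)
#' @param n_init seeded restarts; the lowest-cost solution wins (Lloyd's
#'   algorithm is sensitive to initialization, so a handful of restarts make
#'   the result effectively deterministic in the global optimum on separable
#'   data)
#' @return `anchor_set`: k x 2 matrix (w, h) with attribute `groups`
#'   (area-tertile scale assignment)
#' @export
kmeans_anchors <- function(boxes, k = 9L, img_size = 640L, seed = 0L,
                           max_iter = 300L, n_init = 10L) {
  wh <- cbind(boxes$w, boxes$h) * img_size
  if (nrow(wh) < k) stop("need at least k = ", k, " boxes, got ", nrow(wh))
  uniq <- unique(wh)
  if (nrow(uniq) < k)
    warning("fewer than k distinct box shapes; duplicated centroids allowed")
  run_once <- function(s) {
    cent <- with_seed(s, function() {
      pool <- if (nrow(uniq) >= k) uniq else wh
      pool[sample.int(nrow(pool), k, replace = nrow(pool) < k), ,
           drop = FALSE]
    })
    assign_prev <- rep(0L, nrow(wh))
    for (it in seq_len(max_iter)) {
      iou <- wh_iou(wh, cent)
      asg <- max.col(iou, ties.method = "first")
      if (identical(asg, assign_prev)) break
      assign_prev <- asg
      for (j in seq_len(k)) {
        sel <- asg == j
        if (any(sel)) cent[j, ] <- colMeans(wh[sel, , drop = FALSE])
      }
    }
    cent
  }
  best <- NULL; best_cost <- Inf
  for (r in seq_len(n_init)) {
    cent <- run_once(derive_seed(seed, r))
    cost <- anchor_cost(wh, cent)
    if (cost < best_cost) { best <- cent; best_cost <- cost }
  }
  cent <- best
  ord <- order(cent[, 1] * cent[, 2])
  cent <- cent[ord, , drop = FALSE]
  structure(cent, groups = rep(seq_len(ceiling(k / 3)), each = 3)[seq_len(k)],
            class = "anchor_set")
}

# Total within-cluster 1-IoU cost of an anchor set (used by tests/oracles).
anchor_cost <- function(wh, cent) {
  iou <- wh_iou(wh, cent)
  sum(1 - iou[cbind(seq_len(nrow(wh)), max.col(iou, ties.method = "first"))])
}
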