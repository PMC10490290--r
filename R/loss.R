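# Training loss: CIoU box regression + BCE objectness/classification, and
# the anchor-based target assignment.

#' Complete-IoU loss between boxes
#'
#' Boxes are in center/size form `(cx, cy, w, h)`. The loss is
#' `1 - CIoU` with `CIoU = IoU - rho^2 / c^2 - alpha * v`, where `rho` is the
#' center distance, `c` the diagonal of the smallest enclosing box,
#' `v = 4/pi^2 * (atan(w_t/h_t) - atan(w_p/h_p))^2` the aspect-ratio penalty
#' and `alpha = v / (1 - IoU + v)` (treated as a constant in gradients, per
#' the usual formulation). Zero exactly when the boxes coincide; the three
#' terms are bounded so the loss is always below 3.
#'
#' @param pred,target length-4 vectors or n x 4 matrices
#' @return numeric vector of losses (>= 0)
#' @export
ciou_loss <- function(pred, target) 1 - ciou(pred, target)

ciou <- function(pred, target) {
  p <- if (is.matrix(pred)) pred else matrix(pred, 1)
  t <- if (is.matrix(target)) target else matrix(target, 1)
  if (any(p[, 3] <= 0) || any(p[, 4] <= 0) || any(t[, 3] <= 0) ||
      any(t[, 4] <= 0))
    stop("ciou: zero- or negative-area box")
  px1 <- p[, 1] - p[, 3] / 2; px2 <- p[, 1] + p[, 3] / 2
  py1 <- p[, 2] - p[, 4] / 2; py2 <- p[, 2] + p[, 4] / 2
  tx1 <- t[, 1] - t[, 3] / 2; tx2 <- t[, 1] + t[, 3] / 2
  ty1 <- t[, 2] - t[, 4] / 2; ty2 <- t[, 2] + t[, 4] / 2
  iw <- pmax(0, pmin(px2, tx2) - pmax(px1, tx1))
  ih <- pmax(0, pmin(py2, ty2) - pmax(py1, ty1))
  inter <- iw * ih
  union <- p[, 3] * p[, 4] + t[, 3] * t[, 4] - inter
  iou <- inter / union
  rho2 <- (p[, 1] - t[, 1])^2 + (p[, 2] - t[, 2])^2
  cw <- pmax(px2, tx2) - pmin(px1, tx1)
  ch <- pmax(py2, ty2) - pmin(py1, ty1)
  c2 <- cw^2 + ch^2 + 1e-9
  v <- 4 / pi^2 * (atan(t[, 3] / t[, 4]) - atan(p[, 3] / p[, 4]))^2
  alpha <- v / (1 - iou + v + 1e-9)
  iou - rho2 / c2 - alpha * v
}

#' Assign ground-truth boxes to anchors and grid cells
#'
#' Stock anchor matching: a box matches an anchor when
#' `max(w/aw, aw/w, h/ah, ah/h) < 4`; each match is placed in its containing
#' grid cell plus up to two nearest neighbor cells (the ones whose center is
#' within half a cell of the box center).
#'
#' @param boxes a [norm_box()] table
#' @param anchors 9 x 2 pixel anchors (scale-major), e.g. `model$anchors`
#' @param img_h,img_w input size in pixels
#' @param strides per-scale strides (default 8/16/32)
#' @param ratio_thr anchor/box ratio gate (default 4)
#' @return list of 3 data.frames (one per scale) with columns
#'   `a` (anchor 1..3), `gi`, `gj` (0-based cell), `gx`, `gy`, `gw`, `gh`
#'   (grid units), `cls`
#' @export
build_targets <- function(boxes, anchors, img_h, img_w,
                          strides = c(8L, 16L, 32L), ratio_thr = 4) {
  out <- vector("list", 3)
  for (s in 1:3) {
    ngx <- img_w / strides[s]; ngy <- img_h / strides[s]
    an <- anchors[(s - 1L) * 3L + 1:3, , drop = FALSE] / strides[s]
    rows <- list()
    for (b in seq_len(nrow(boxes))) {
      gw <- boxes$w[b] * ngx; gh <- boxes$h[b] * ngy
      gx <- boxes$cx[b] * ngx; gy <- boxes$cy[b] * ngy
      for (a in 1:3) {
        r <- c(gw / an[a, 1], an[a, 1] / gw, gh / an[a, 2], an[a, 2] / gh)
        if (max(r) >= ratio_thr) next
        gi <- floor(gx); gj <- floor(gy)
        cells <- list(c(gi, gj))
        fx <- gx - gi; fy <- gy - gj
        if (fx < 0.5 && gx > 1) cells <- c(cells, list(c(gi - 1, gj)))
        if (fx > 0.5 && gx < ngx - 1) cells <- c(cells, list(c(gi + 1, gj)))
        if (fy < 0.5 && gy > 1) cells <- c(cells, list(c(gi, gj - 1)))
        if (fy > 0.5 && gy < ngy - 1) cells <- c(cells, list(c(gi, gj + 1)))
        for (cl in cells) {
          ci <- min(max(cl[1], 0), ngx - 1); cj <- min(max(cl[2], 0), ngy - 1)
          rows[[length(rows) + 1L]] <-
            data.frame(a = a, gi = ci, gj = cj, gx = gx, gy = gy,
                       gw = gw, gh = gh, cls = boxes$class_id[b])
        }
      }
    }
    out[[s]] <- if (length(rows)) unique(do.call(rbind, rows))
                else data.frame(a = integer(0), gi = numeric(0),
                                gj = numeric(0), gx = numeric(0),
                                gy = numeric(0), gw = numeric(0),
                                gh = numeric(0), cls = integer(0))
  }
  out
}

bce_logit <- function(t, y) pmax(t, 0) - t * y + log1p(exp(-abs(t)))

#' Loss weights
#' @param box,obj,cls term weights (stock balance)
#' @param balance per-scale objectness weights (P3, P4, P5)
#' @return list of weights
#' @export
loss_weights <- function(box = 0.05, obj = 1.0, cls = 0.5,
                         balance = c(4.0, 1.0, 0.4)) {
  list(box = box, obj = obj, cls = cls, balance = balance)
}

# decode box logits (lx, ly, lw, lh) at anchor an (grid units) into a
# cell-relative center/size box
decode_box_logits <- function(lx, ly, lw, lh, an) {
  cbind(2 * sigmoid(lx) - 0.5, 2 * sigmoid(ly) - 0.5,
        (2 * sigmoid(lw))^2 * an[, 1], (2 * sigmoid(lh))^2 * an[, 2])
}

#' Detection loss and its gradients
#'
#' Weighted sum of a CIoU box term over matched anchors, BCE objectness over
#' every cell (target = clamped CIoU of the matched box, 0 elsewhere) and
#' BCE classification over matched cells (retained also for `nc = 1`).
#' Per-scale means, summed over scales with the per-scale objectness
#' balance. Box-term gradients with respect to the four box logits are
#' computed by central finite differences of the CIoU (exact to O(eps^2);
#' matched anchors are few, so the extra evaluations are negligible), BCE
#' gradients analytically.
#'
#' @param model an `ayolo_model`
#' @param raw per-scale raw head outputs (from [forward_model()])
#' @param targets output of [build_targets()]
#' @param weights a [loss_weights()]
#' @param compute_grads also return d(loss)/d(raw) matrices
#' @return list: `loss` (total), components `box`, `obj`, `cls` (already
#'   weighted), and `grads` (list of 3 matrices) when requested
#' @export
detection_loss <- function(model, raw, targets, weights = loss_weights(),
                           compute_grads = TRUE) {
  nc <- model$nc
  no <- 5L + nc
  lbox <- 0; lobj <- 0; lcls <- 0
  grads <- if (compute_grads) vector("list", 3)
  eps <- 1e-4
  for (s in 1:3) {
    m <- raw[[s]]
    h <- attr(m, "h"); w <- attr(m, "w")
    ncell <- h * w
    G <- if (compute_grads) matrix(0, ncell, ncol(m))
    tobj <- matrix(0, ncell, 3)
    tg <- targets[[s]]
    nmatch <- nrow(tg)
    if (nmatch) {
      an <- model$anchors[(s - 1L) * 3L + 1:3, , drop = FALSE] /
            model$strides[s]
      r <- as.integer(tg$gj + tg$gi * h + 1)
      base <- (tg$a - 1L) * no
      li <- function(k) cbind(r, base + k)
      lx <- m[li(1)]; ly <- m[li(2)]; lw <- m[li(3)]; lh <- m[li(4)]
      tbox <- cbind(tg$gx - tg$gi, tg$gy - tg$gj, tg$gw, tg$gh)
      anm <- an[tg$a, , drop = FALSE]
      cio <- ciou(decode_box_logits(lx, ly, lw, lh, anm), tbox)
      lbox <- lbox + mean(1 - cio)
      if (compute_grads) {
        scale_g <- weights$box / nmatch
        logits <- list(lx, ly, lw, lh)
        for (k in 1:4) {
          lp <- logits; lp[[k]] <- lp[[k]] + eps
          lm_ <- logits; lm_[[k]] <- lm_[[k]] - eps
          cp <- ciou(decode_box_logits(lp[[1]], lp[[2]], lp[[3]], lp[[4]],
                                       anm), tbox)
          cm <- ciou(decode_box_logits(lm_[[1]], lm_[[2]], lm_[[3]], lm_[[4]],
                                       anm), tbox)
          dk <- -(cp - cm) / (2 * eps) * scale_g
          idx <- li(k)
          for (q in seq_len(nmatch))
            G[idx[q, 1], idx[q, 2]] <- G[idx[q, 1], idx[q, 2]] + dk[q]
        }
      }
      # objectness target: clamped detached CIoU, max over duplicates
      tv <- pmax(0, pmin(1, cio))
      key <- paste(r, tg$a)
      agg <- tapply(tv, key, max)
      kk <- strsplit(names(agg), " ")
      for (q in seq_along(agg)) {
        rr <- as.integer(kk[[q]][1]); aa <- as.integer(kk[[q]][2])
        tobj[rr, aa] <- agg[[q]]
      }
      # classification
      Lc <- matrix(m[cbind(rep(r, nc),
                           rep(base, nc) + 5L +
                             rep(seq_len(nc), each = nmatch))],
                   nmatch, nc)
      Yc <- matrix(0, nmatch, nc)
      Yc[cbind(seq_len(nmatch), tg$cls + 1L)] <- 1
      lcls <- lcls + mean(bce_logit(Lc, Yc))
      if (compute_grads) {
        dC <- (sigmoid(Lc) - Yc) * weights$cls / (nmatch * nc)
        for (j in seq_len(nc)) {
          idx <- cbind(r, base + 5L + j)
          for (q in seq_len(nmatch))
            G[idx[q, 1], idx[q, 2]] <- G[idx[q, 1], idx[q, 2]] + dC[q, j]
        }
      }
    }
    obj_cols <- (0:2) * no + 5L
    To <- m[, obj_cols, drop = FALSE]
    lobj <- lobj + weights$balance[s] * mean(bce_logit(To, tobj))
    if (compute_grads) {
      G[, obj_cols] <- G[, obj_cols] +
        (sigmoid(To) - tobj) * weights$obj * weights$balance[s] / (3 * ncell)
      grads[[s]] <- G
    }
  }
  box_c <- weights$box * lbox
  obj_c <- weights$obj * lobj
  cls_c <- weights$cls * lcls
  list(loss = box_c + obj_c + cls_c, box = box_c, obj = obj_c, cls = cls_c,
       grads = if (compute_grads) grads)
}
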