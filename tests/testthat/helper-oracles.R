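# Independent oracles, deliberately implemented by different routes than the
# package code they check.

# Direct nested-loop convolution on an h x w x cin array; weight indexed as
# Wk[ky, kx, ci, co]; same layout the package's im2col uses, but computed
# without im2col.
naive_conv <- function(a, Wk, stride = 1L, pad = NULL) {
  k <- dim(Wk)[1]; cin <- dim(Wk)[3]; cout <- dim(Wk)[4]
  if (is.null(pad)) pad <- k %/% 2L
  h <- dim(a)[1]; w <- dim(a)[2]
  ho <- (h + 2 * pad - k) %/% stride + 1L
  wo <- (w + 2 * pad - k) %/% stride + 1L
  out <- array(0, c(ho, wo, cout))
  for (co in 1:cout) for (yo in 1:ho) for (xo in 1:wo) {
    acc <- 0
    for (ci in 1:cin) for (ky in 1:k) for (kx in 1:k) {
      yi <- (yo - 1L) * stride - pad + ky
      xi <- (xo - 1L) * stride - pad + kx
      if (yi >= 1 && yi <= h && xi >= 1 && xi <= w)
        acc <- acc + a[yi, xi, ci] * Wk[ky, kx, ci, co]
    }
    out[yo, xo, co] <- acc
  }
  out
}

# package weight matrix (k*k*cin x cout) -> Wk[ky, kx, ci, co]
unpack_weight <- function(W, k, cin, cout) array(W, c(k, k, cin, cout))

# Parallel-pool spatial pyramid: naive max-pool (stride 1, same padding) at
# each size, concatenated with the input. Direct loops, no shared code.
naive_spp <- function(a, sizes = c(5, 9, 13)) {
  h <- dim(a)[1]; w <- dim(a)[2]; cc <- dim(a)[3]
  pool1 <- function(k) {
    r <- k %/% 2
    out <- array(-Inf, dim(a))
    for (ch in 1:cc) for (y in 1:h) for (x in 1:w) {
      ys <- max(1, y - r):min(h, y + r)
      xs <- max(1, x - r):min(w, x + r)
      out[y, x, ch] <- max(a[ys, xs, ch])
    }
    out
  }
  pools <- lapply(sizes, pool1)
  do.call(function(...) {
    arrs <- list(...)
    array(unlist(arrs), c(h, w, cc * length(arrs)))
  }, c(list(a), pools))
}

# Flatten-and-count parameter walker: inspects the node environments
# directly rather than going through node_learnables().
oracle_param_count <- function(graph) {
  tot <- 0
  for (nd in graph$nodes) {
    for (nm in ls(nd$par)) {
      if (grepl("^(g_|v_|bn_r)", nm)) next  # grads, velocities, buffers
      tot <- tot + length(get(nm, envir = nd$par))
    }
  }
  tot
}

# Brute-force AP: enumerate every confidence cut, build the exact PR
# staircase, integrate the monotone envelope rectangle by rectangle.
oracle_ap <- function(tp, conf, n_gt) {
  ord <- order(-conf)
  tp <- tp[ord]
  n <- length(tp)
  recs <- pres <- numeric(n)
  for (k in 1:n) {
    recs[k] <- sum(tp[1:k]) / n_gt
    pres[k] <- sum(tp[1:k]) / k
  }
  ap <- 0
  prev_r <- 0
  for (k in 1:n) {
    if (recs[k] > prev_r) {
      ap <- ap + (recs[k] - prev_r) * max(pres[k:n])
      prev_r <- recs[k]
    }
  }
  ap
}

# Independently transcribed complete-IoU closed form (center/size boxes).
oracle_ciou <- function(b1, b2) {
  a1 <- c(b1[1] - b1[3] / 2, b1[2] - b1[4] / 2,
          b1[1] + b1[3] / 2, b1[2] + b1[4] / 2)
  a2 <- c(b2[1] - b2[3] / 2, b2[2] - b2[4] / 2,
          b2[1] + b2[3] / 2, b2[2] + b2[4] / 2)
  iw <- min(a1[3], a2[3]) - max(a1[1], a2[1])
  ih <- min(a1[4], a2[4]) - max(a1[2], a2[2])
  inter <- max(0, iw) * max(0, ih)
  uni <- b1[3] * b1[4] + b2[3] * b2[4] - inter
  iou <- inter / uni
  rho2 <- (b1[1] - b2[1])^2 + (b1[2] - b2[2])^2
  cw <- max(a1[3], a2[3]) - min(a1[1], a2[1])
  ch <- max(a1[4], a2[4]) - min(a1[2], a2[2])
  v <- 4 / pi^2 * (atan(b2[3] / b2[4]) - atan(b1[3] / b1[4]))^2
  alpha <- v / (1 - iou + v + 1e-9)
  iou - rho2 / (cw^2 + ch^2 + 1e-9) - alpha * v
}

# Exhaustive anchor/cell matcher (loops over every anchor, cell and offset
# rule independently of build_targets).
oracle_match_count <- function(boxes, anchors, img_h, img_w,
                               strides = c(8, 16, 32)) {
  count <- 0
  for (s in 1:3) {
    ngx <- img_w / strides[s]; ngy <- img_h / strides[s]
    an <- anchors[(s - 1) * 3 + 1:3, , drop = FALSE] / strides[s]
    cells <- character(0)
    for (b in seq_len(nrow(boxes))) {
      gw <- boxes$w[b] * ngx; gh <- boxes$h[b] * ngy
      gx <- boxes$cx[b] * ngx; gy <- boxes$cy[b] * ngy
      for (a in 1:3) {
        if (max(gw / an[a, 1], an[a, 1] / gw,
                gh / an[a, 2], an[a, 2] / gh) >= 4) next
        gi <- floor(gx); gj <- floor(gy)
        cand <- list(c(gi, gj))
        if (gx - gi < 0.5 && gx > 1) cand <- append(cand, list(c(gi - 1, gj)))
        if (gx - gi > 0.5 && gx < ngx - 1) cand <- append(cand, list(c(gi + 1, gj)))
        if (gy - gj < 0.5 && gy > 1) cand <- append(cand, list(c(gi, gj - 1)))
        if (gy - gj > 0.5 && gy < ngy - 1) cand <- append(cand, list(c(gi, gj + 1)))
        for (cl in cand)
          cells <- c(cells, paste(s, a, cl[1], cl[2], b))
      }
    }
    count <- count + length(unique(cells))
  }
  count
}

# Multi-restart Lloyd k-means under 1-IoU distance; returns the best
# within-cluster cost over n_restarts seeded starts.
oracle_kmeans_cost <- function(wh, k, n_restarts = 30, iters = 300) {
  iou_m <- function(wh, ct) {
    iw <- outer(wh[, 1], ct[, 1], pmin); ih <- outer(wh[, 2], ct[, 2], pmin)
    inter <- iw * ih
    inter / (outer(wh[, 1] * wh[, 2], ct[, 1] * ct[, 2], `+`) - inter)
  }
  best <- Inf
  for (r in seq_len(n_restarts)) {
    set.seed(1000 + r)
    ct <- wh[sample.int(nrow(wh), k), , drop = FALSE]
    prev <- rep(0L, nrow(wh))
    for (it in seq_len(iters)) {
      asg <- max.col(iou_m(wh, ct), ties.method = "first")
      if (identical(asg, prev)) break
      prev <- asg
      for (j in seq_len(k)) if (any(asg == j))
        ct[j, ] <- colMeans(wh[asg == j, , drop = FALSE])
    }
    m <- iou_m(wh, ct)
    cost <- sum(1 - m[cbind(seq_len(nrow(wh)), max.col(m, "first"))])
    best <- min(best, cost)
  }
  best
}

# small deterministic random feature map helper
rand_fmap <- function(h, w, c, seed = 1) {
  set.seed(seed)
  array(rnorm(h * w * c), c(h, w, c))
}
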