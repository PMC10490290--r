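# Loss, target assignment, schedule, metrics, and small training mechanics.

test_that("CIoU loss: identity, oracle agreement, bounds, errors", {
  expect_equal(ciou_loss(c(1, 2, 3, 4), c(1, 2, 3, 4)), 0)

  # worked example against the independently transcribed closed form
  p <- c(0, 0, 2, 2); t <- c(2, 2, 2, 2)
  expect_equal(ciou_loss(p, t), 1 - oracle_ciou(p, t), tolerance = 1e-9)

  set.seed(12)
  for (i in 1:50) {
    b1 <- c(runif(2, -5, 5), runif(2, 0.1, 6))
    b2 <- c(runif(2, -5, 5), runif(2, 0.1, 6))
    l <- ciou_loss(b1, b2)
    expect_equal(l, 1 - oracle_ciou(b1, b2), tolerance = 1e-9)
    expect_gte(l, 0)
    expect_lt(l, 3)
  }
  expect_error(ciou_loss(c(0, 0, 0, 1), c(0, 0, 1, 1)), "zero")
})

test_that("target assignment: anchor gate, cell neighbors, oracle count", {
  anchors <- STOCK_ANCHORS
  # a box exactly equal to an anchor, centered in a cell -> assigned there
  b <- norm_box(0L, cx = (10 + 0.5) * 8 / 320, cy = (7 + 0.5) * 8 / 320,
                w = 10 / 320, h = 13 / 320)   # first stride-8 anchor
  tg <- build_targets(b, anchors, 320, 320)
  expect_true(any(tg[[1]]$a == 1 & tg[[1]]$gi == 10 & tg[[1]]$gj == 7))

  # a box 10x larger than every anchor gets no assignment
  giant <- norm_box(0L, 0.5, 0.5, 1.0, 1.0)
  tg2 <- build_targets(giant, matrix(rep(c(4, 4), 9), ncol = 2,
                                     byrow = TRUE), 320, 320)
  expect_equal(sum(vapply(tg2, nrow, numeric(1))), 0)

  # off-center boxes get the containing cell plus two neighbor cells
  # (per matched anchor)
  b3 <- norm_box(0L, 0.333, 0.666, 10 / 320, 13 / 320)
  tg3 <- build_targets(b3, anchors, 320, 320)
  expect_equal(sum(tg3[[1]]$a == 1), 3)

  # fixed toy scene: assignment count matches the exhaustive matcher
  set.seed(5)
  boxes <- norm_box(rep(0L, 6), runif(6, 0.2, 0.8), runif(6, 0.2, 0.8),
                    runif(6, 0.05, 0.35), runif(6, 0.05, 0.35))
  tg4 <- build_targets(boxes, anchors, 320, 320)
  expect_equal(sum(vapply(tg4, nrow, numeric(1))),
               oracle_match_count(boxes, anchors, 320, 320))
})

test_that("cosine schedule hits both printed endpoints and is monotone", {
  pp <- train_params()
  expect_equal(cosine_lr(0, pp), 0.01)
  expect_equal(cosine_lr(pp$epochs, pp), 0.0001)
  expect_equal(cosine_lr(pp$epochs / 2, pp), (0.01 + 0.0001) / 2)
  expect_equal(cosine_lr(pp$epochs / 2, pp), 0.00505)
  lrs <- cosine_lr(0:pp$epochs, pp)
  expect_true(all(diff(lrs) <= 0))
  expect_error(cosine_lr(pp$epochs + 1, pp), "range")
  expect_error(cosine_lr(-1, pp), "range")
})

test_that("match_detections implements greedy one-to-one matching", {
  gt <- matrix(c(0, 0, 10, 10), 1)
  d60 <- data.frame(x1 = 0, y1 = 0, x2 = 10, y2 = 6.1, conf = 0.9)
  m <- match_detections(d60, gt, 0.5)   # IoU 0.61
  expect_equal(c(m$TP, m$FP, m$FN), c(1, 0, 0))

  # duplicate second detection on the same GT is an FP
  d2 <- rbind(d60, data.frame(x1 = 0, y1 = 0, x2 = 10, y2 = 6, conf = 0.8))
  m2 <- match_detections(d2, gt, 0.5)
  expect_equal(c(m2$TP, m2$FP, m2$FN), c(1, 1, 0))

  # IoU 0.4 below threshold
  d40 <- data.frame(x1 = 0, y1 = 0, x2 = 10, y2 = 4, conf = 0.9)
  m3 <- match_detections(d40, gt, 0.5)
  expect_equal(c(m3$TP, m3$FP, m3$FN), c(0, 1, 1))

  # TP + FN equals the number of ground-truth boxes
  expect_equal(m2$TP + m2$FN, nrow(gt))
})

test_that("precision/recall/F1 formulas and reference-table consistency", {
  prf <- precision_recall_f1(list(TP = 9, FP = 1, FN = 0))
  expect_equal(prf$precision, 0.9)
  expect_equal(prf$recall, 1.0)
  expect_equal(prf$f1, 2 * 0.9 / 1.9, tolerance = 1e-9)

  # P == R implies F1 == P
  prf2 <- precision_recall_f1(list(TP = 3, FP = 1, FN = 1))
  expect_equal(prf2$f1, prf2$precision)

  # zero-denominator conventions
  expect_equal(precision_recall_f1(list(TP = 0, FP = 0, FN = 2))$precision, 0)
  expect_equal(precision_recall_f1(list(TP = 0, FP = 3, FN = 0))$recall, 0)

  # F1 recomputed from the printed precision/recall pair matches the printed
  # F1 within input rounding (+-0.02)
  f1 <- 2 * 97.81 * 97.32 / (97.81 + 97.32)
  expect_lt(abs(f1 - 97.55), 0.02)
})

test_that("AP: worked example, edge cases, brute-force oracle, monotonicity", {
  # 2 GT, ranking [TP, FP, TP] -> 0.5*1 + 0.5*(2/3)
  expect_equal(ap_from_pr(c(TRUE, FALSE, TRUE), c(0.9, 0.8, 0.7), 2),
               0.5 * 1 + 0.5 * (2 / 3), tolerance = 1e-12)
  expect_equal(ap_from_pr(rep(TRUE, 4), 4:1 / 4, 4), 1)
  expect_equal(ap_from_pr(rep(FALSE, 3), 3:1 / 3, 5), 0)
  expect_equal(ap_from_pr(logical(0), numeric(0), 3), 0)
  expect_error(ap_from_pr(TRUE, 0.9, 0), "no ground-truth")

  # oracle equivalence on 100 random detection sets
  set.seed(99)
  for (i in 1:100) {
    n <- sample(1:25, 1)
    tp <- runif(n) < 0.5
    conf <- runif(n)
    n_gt <- max(sum(tp), 1) + sample(0:3, 1)
    expect_equal(ap_from_pr(tp, conf, n_gt), oracle_ap(tp, conf, n_gt),
                 tolerance = 1e-12)
  }

  # adding a correct detection never decreases AP
  set.seed(42)
  for (i in 1:20) {
    n <- sample(2:12, 1)
    tp <- runif(n) < 0.5
    conf <- runif(n)
    n_gt <- sum(tp) + sample(1:3, 1)
    ap0 <- ap_from_pr(tp, conf, n_gt)
    ap1 <- ap_from_pr(c(tp, TRUE), c(conf, runif(1)), n_gt)
    expect_gte(ap1 + 1e-12, ap0)
  }

  # adding an FP never increases precision at any fixed recall level
  tp <- c(TRUE, TRUE, FALSE, TRUE)
  conf <- c(0.9, 0.8, 0.7, 0.6)
  prec_at <- function(tp, conf, n_gt, r) {
    ord <- order(-conf); tp <- tp[ord]
    ctp <- cumsum(tp); rec <- ctp / n_gt; prec <- ctp / seq_along(tp)
    ok <- rec >= r - 1e-12
    if (any(ok)) max(prec[ok]) else 0
  }
  for (r in c(0.25, 0.5, 0.75, 1)) {
    p0 <- prec_at(tp, conf, 4, r)
    p1 <- prec_at(c(tp, FALSE), c(conf, 0.85), 4, r)
    expect_lte(p1, p0 + 1e-12)
  }

  # 101-point variant stays within a step of the exact integral
  expect_equal(ap_from_pr(c(TRUE, FALSE, TRUE), c(0.9, 0.8, 0.7), 2,
                          interp = "101"),
               0.8333, tolerance = 0.02)
})

test_that("map50_95 averages ten thresholds; single class mAP == AP", {
  expect_equal(map50_95(rep(0.7, 10)), 0.7)
  expect_error(map50_95(rep(0.7, 9)), "10")
  # a perfect detector with exact boxes scores 1 at every threshold
  ds <- list(list(image = array(0, c(64, 64, 3)),
                  boxes = norm_box(0L, 0.5, 0.5, 0.25, 0.25)))
  det <- list(data.frame(x1 = 24, y1 = 24, x2 = 40, y2 = 40, conf = 1,
                         class_id = 0L))
  rep <- evaluate_model(dataset = ds, detections = det)
  expect_equal(rep$map50_95, 1)
  # one class: the mAP at IoU .5 is the AP at IoU .5
  expect_equal(rep$ap50, unname(rep$per_iou["0.50"]))
})

test_that("evaluate_model edge cases and determinism", {
  ds <- list(list(image = array(0, c(64, 64, 3)),
                  boxes = norm_box(0L, 0.5, 0.5, 0.25, 0.25)))
  empty <- list(data.frame(x1 = numeric(0), y1 = numeric(0),
                           x2 = numeric(0), y2 = numeric(0),
                           conf = numeric(0), class_id = integer(0)))
  rep0 <- evaluate_model(dataset = ds, detections = empty)
  expect_equal(rep0$precision, 0)
  expect_equal(rep0$recall, 0)
  expect_error(evaluate_model(dataset = list()), "empty")

  m <- build_model(model_config("cs", nc = 1, input_size = 64, seed = 3))
  sc <- generate_scene(scene_config(img_size = 64, n_apples = c(2, 2),
                                    radius = c(8, 12),
                                    occluder_density = 0), seed = 2)
  ds2 <- list(list(image = sc$image, boxes = sc$boxes))
  r1 <- evaluate_model(m, ds2)
  r2 <- evaluate_model(m, ds2)
  expect_identical(r1[c("precision", "recall", "ap50", "map50_95")],
                   r2[c("precision", "recall", "ap50", "map50_95")])
})

test_that("detection loss: asymptotics, hand-computed toy, linearity, grads", {
  m <- build_model(model_config("cs", nc = 1, input_size = 64, seed = 1))
  no <- 6L
  mk_raw <- function(fill) lapply(c(8, 4, 2), function(g)
    appleyolo:::fmap(matrix(fill, g * g, 3 * no), g, g))

  # no ground truth + objectness logits -> -inf limit: loss -> 0
  tg0 <- build_targets(norm_box(), m$anchors, 64, 64)
  l <- detection_loss(m, mk_raw(-30), tg0, compute_grads = FALSE)
  expect_lt(l$loss, 1e-8)
  expect_equal(l$box, 0)

  # one matched cell: components equal a hand computation
  b <- norm_box(0L, cx = 2.5 / 8, cy = 2.5 / 8,
                w = 10 / 64, h = 13 / 64)  # equals anchor 1 at stride 8
  tg <- build_targets(b, m$anchors, 64, 64)
  raw <- mk_raw(-30)
  # logits 0 at the matched location: pxy = 0.5 (correct), pwh = anchor
  i1 <- tg[[1]][tg[[1]]$a == 1 & tg[[1]]$gi == 2 & tg[[1]]$gj == 2, ]
  expect_equal(nrow(i1), 1)
  r <- 2 + 2 * 8 + 1
  raw[[1]][r, 1:6] <- 0
  w <- loss_weights()
  out <- detection_loss(m, raw, list(tg[[1]][tg[[1]]$gi == 2 &
                                             tg[[1]]$gj == 2 &
                                             tg[[1]]$a == 1, ],
                                     tg0[[2]], tg0[[3]]),
                        weights = w, compute_grads = FALSE)
  # box: pxy = 2*sig(0)-0.5 = 0.5 matches target offset 0.5; pwh = anchor =
  # gt -> ciou = 1, box loss 0
  expect_equal(out$box, 0, tolerance = 1e-9)
  # cls: single class, logit 0, target 1 -> BCE = log 2, weighted 0.5
  expect_equal(out$cls, w$cls * log(2), tolerance = 1e-9)
  # obj: matched cell has target 1 (ciou), logit 0 -> log 2; all other cells
  # logit -30, target 0 -> ~0; per-scale mean weighted by balance
  expect_equal(out$obj, w$balance[1] * log(2) / (3 * 64), tolerance = 1e-6)

  # doubling the box weight doubles the box component only
  b2 <- norm_box(0L, 0.4, 0.4, 0.2, 0.2)
  tgb <- build_targets(b2, m$anchors, 64, 64)
  raw2 <- lapply(c(8, 4, 2), function(g) {
    set.seed(g)
    appleyolo:::fmap(matrix(rnorm(g * g * 3 * no), g * g, 3 * no), g, g)
  })
  l1 <- detection_loss(m, raw2, tgb, loss_weights(box = 0.05),
                       compute_grads = FALSE)
  l2 <- detection_loss(m, raw2, tgb, loss_weights(box = 0.10),
                       compute_grads = FALSE)
  expect_equal(l2$box, 2 * l1$box, tolerance = 1e-12)
  expect_equal(l2$obj, l1$obj)
  expect_equal(l2$cls, l1$cls)

  # gradients match numeric differentiation of the total loss
  g <- detection_loss(m, raw2, tgb, compute_grads = TRUE)$grads
  set.seed(33)
  for (s in 1:3) {
    for (probe in 1:4) {
      i <- sample(nrow(raw2[[s]]), 1); j <- sample(ncol(raw2[[s]]), 1)
      eps <- 1e-5
      rp <- raw2; rp[[s]][i, j] <- rp[[s]][i, j] + eps
      rm_ <- raw2; rm_[[s]][i, j] <- rm_[[s]][i, j] - eps
      num <- (detection_loss(m, rp, tgb, compute_grads = FALSE)$loss -
              detection_loss(m, rm_, tgb, compute_grads = FALSE)$loss) /
             (2 * eps)
      expect_equal(g[[s]][i, j], num, tolerance = 1e-4)
    }
  }
})

test_that("short training run: determinism, learning signal, checkpointing", {
  cfg <- scene_config(img_size = 64, n_apples = c(1, 2), radius = c(8, 14),
                      occluder_density = 0, min_sep = 1.1)
  ds <- lapply(1:4, function(s) {
    sc <- generate_scene(cfg, seed = s)
    list(image = sc$image, boxes = sc$boxes)
  })
  pp <- train_params(batch = 4, epochs = 3, img_size = 64, nc = 1,
                     lr0 = 0.02, warmup_epochs = 1)
  m1 <- build_model(model_config("cs", nc = 1, input_size = 64, seed = 11))
  r1 <- train_model(m1, ds, pp, seed = 21)
  m2 <- build_model(model_config("cs", nc = 1, input_size = 64, seed = 11))
  r2 <- train_model(m2, ds, pp, seed = 21)
  # same seeds -> identical epoch-0 loss (and the whole log)
  expect_equal(r1$log$loss[1], r2$log$loss[1])
  expect_equal(r1$log, r2$log)
  expect_true(all(is.finite(r1$log$loss)))
  # three epochs of SGD on four images already reduce the loss
  expect_lt(tail(r1$log$loss, 1), r1$log$loss[1])

  # checkpoint save -> load gives identical validation metrics
  ck <- tempfile(fileext = ".ckpt")
  save_checkpoint(r1$model, ck)
  m3 <- load_checkpoint(ck)
  e1 <- evaluate_model(r1$model, ds)
  e3 <- evaluate_model(m3, ds)
  expect_identical(e1[c("precision", "recall", "ap50", "map50_95")],
                   e3[c("precision", "recall", "ap50", "map50_95")])
  unlink(ck)

  # nc mismatch and empty dataset are rejected
  expect_error(train_model(m1, list(), pp), "empty")
  expect_error(train_model(build_model(model_config("cs", nc = 2,
                                                    input_size = 64)),
                           ds, pp), "nc")
})
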