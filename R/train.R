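# Training loop: SGD with momentum and weight decay, cosine-annealed
# learning rate with a short linear warmup, seeded shuffling.

#' Training hyperparameters
#'
#' Defaults are the reference training configuration: initial learning rate
#' 0.01 annealed by cosine to a floor of 0.0001, weight decay 0.0001, batch
#' size 12, 200 epochs, 640 x 640 inputs, one class, confidence threshold
#' 0.25 and IoU threshold 0.5.
#'
#' @param lr0 initial learning rate
#' @param lr_floor cosine floor
#' @param weight_decay L2 decay on convolution weights (not BN/bias)
#' @param momentum SGD momentum
#' @param batch batch size
#' @param epochs training epochs
#' @param img_size square input size
#' @param nc class count
#' @param conf_thr,iou_thr evaluation thresholds
#' @param warmup_epochs linear warmup span (fraction of epochs allowed)
#' @param weights a [loss_weights()]
#' @param eval_every validate every this many epochs (0 = never)
#' @return `train_params` list
#' @export
train_params <- function(lr0 = 0.01, lr_floor = 0.0001, weight_decay = 0.0001,
                         momentum = 0.937, batch = 12L, epochs = 200L,
                         img_size = 640L, nc = 1L, conf_thr = 0.25,
                         iou_thr = 0.5, warmup_epochs = 2,
                         weights = loss_weights(), eval_every = 0L) {
  structure(list(lr0 = lr0, lr_floor = lr_floor,
                 weight_decay = weight_decay, momentum = momentum,
                 batch = as.integer(batch), epochs = as.integer(epochs),
                 img_size = as.integer(img_size), nc = as.integer(nc),
                 conf_thr = conf_thr, iou_thr = iou_thr,
                 warmup_epochs = warmup_epochs, weights = weights,
                 eval_every = as.integer(eval_every)),
            class = "train_params")
}

#' Cosine-annealed learning rate
#'
#' `lr(e) = lr_floor + (lr0 - lr_floor) * (1 + cos(pi * e / epochs)) / 2`:
#' equals `lr0` at epoch 0 and `lr_floor` at the final epoch, monotone
#' non-increasing in between.
#' @param epoch epoch in `[0, epochs]`
#' @param params a [train_params()]
#' @return learning rate
#' @export
cosine_lr <- function(epoch, params) {
  if (any(epoch < 0) || any(epoch > params$epochs))
    stop("epoch out of range [0, ", params$epochs, "]")
  params$lr_floor + (params$lr0 - params$lr_floor) *
    (1 + cos(pi * epoch / params$epochs)) / 2
}

sgd_step <- function(nodes, lr, momentum, wd, nacc) {
  for (nd in nodes) {
    for (nm in node_learnables(nd)) {
      gn <- paste0("g_", nm)
      if (!exists(gn, envir = nd$par, inherits = FALSE)) next
      g <- get(gn, envir = nd$par) / nacc
      wv <- get(nm, envir = nd$par)
      if (nm == "W") g <- g + wd * wv
      vn <- paste0("v_", nm)
      v <- if (exists(vn, envir = nd$par, inherits = FALSE))
        momentum * get(vn, envir = nd$par) + g else g
      assign(vn, v, envir = nd$par)
      assign(nm, wv - lr * v, envir = nd$par)
    }
  }
}

#' Train a detector
#'
#' SGD(momentum 0.937) with weight decay on convolution weights, cosine
#' learning-rate schedule with linear warmup over the first batches, seeded
#' shuffling, per-image gradient accumulation over each mini-batch. Emits a
#' per-epoch log of the (weighted) box/objectness/class loss components.
#' The model is updated in place and also returned. Pass `init_from` to
#' warm-start from a checkpoint (transfer-learning hook; no download is ever
#' performed).
#'
#' @param model an `ayolo_model` (its `nc` must match `params$nc`)
#' @param train_ds list of samples (`image` `[0,255]`, `boxes`), e.g. from
#'   [load_yolo_dataset()]
#' @param params a [train_params()]
#' @param val_ds optional validation samples, evaluated every
#'   `params$eval_every` epochs
#' @param seed shuffle seed
#' @param init_from optional checkpoint path for warm starting
#' @param verbose print per-epoch lines
#' @return list with `model` and `log` (data.frame: epoch, lr, loss, box,
#'   obj, cls, val_ap50)
#' @export
train_model <- function(model, train_ds, params = train_params(),
                        val_ds = NULL, seed = 0L, init_from = NULL,
                        verbose = FALSE) {
  if (!length(train_ds)) stop("empty training dataset")
  if (model$nc != params$nc)
    stop("model nc (", model$nc, ") != params nc (", params$nc, ")")
  if (!is.null(init_from)) {
    ck <- readRDS(init_from)
    restore_params(model, ck$pars)
  }
  prep <- lapply(train_ds, function(s) {
    d <- dim(s$image)
    list(x = fmap_from_array(s$image / 255),
         targets = build_targets(s$boxes, model$anchors, d[1], d[2]))
  })
  n <- length(prep)
  nb <- ceiling(n / params$batch)
  warm_iters <- max(1, round(params$warmup_epochs * nb))
  it <- 0L
  log_rows <- vector("list", params$epochs)
  nodes <- model$graph$nodes
  for (epoch in seq_len(params$epochs) - 1L) {
    lr_e <- cosine_lr(epoch, params)
    ord <- with_seed(derive_seed(seed, epoch), function() sample.int(n))
    comp <- c(loss = 0, box = 0, obj = 0, cls = 0)
    for (bi in seq_len(nb)) {
      idx <- ord[((bi - 1L) * params$batch + 1L):min(bi * params$batch, n)]
      zero_grads(nodes)
      for (ii in idx) {
        fw <- graph_forward(model$graph, prep[[ii]]$x, training = TRUE)
        ls <- detection_loss(model, fw$out, prep[[ii]]$targets,
                             params$weights)
        if (!is.finite(ls$loss))
          stop(sprintf(
            "NaN/Inf loss at epoch %d batch %d (box=%.4g obj=%.4g cls=%.4g)",
            epoch, bi, ls$box, ls$obj, ls$cls))
        graph_backward(model$graph, fw, ls$grads)
        comp <- comp + c(ls$loss, ls$box, ls$obj, ls$cls)
      }
      it <- it + 1L
      lr_i <- lr_e * min(1, it / warm_iters)
      # stock batch-loss convention: per-image scale-mean losses are SUMMED
      # over the mini-batch (loss x batch size), so gradients accumulate
      # without dividing by the batch count
      sgd_step(nodes, lr_i, params$momentum, params$weight_decay, 1L)
    }
    comp <- comp / n
    val_ap <- NA_real_
    if (!is.null(val_ds) && params$eval_every > 0 &&
        (epoch + 1L) %% params$eval_every == 0L) {
      val_ap <- evaluate_model(model, val_ds, params$conf_thr,
                               params$iou_thr)$ap50
    }
    log_rows[[epoch + 1L]] <- data.frame(epoch = epoch, lr = lr_e,
                                         loss = comp[1], box = comp[2],
                                         obj = comp[3], cls = comp[4],
                                         val_ap50 = val_ap)
    if (verbose)
      message(sprintf("epoch %3d lr %.5f loss %.4f (box %.4f obj %.4f cls %.4f)%s",
                      epoch, lr_e, comp[1], comp[2], comp[3], comp[4],
                      if (is.na(val_ap)) "" else sprintf(" val AP50 %.3f", val_ap)))
  }
  log <- do.call(rbind, log_rows)
  rownames(log) <- NULL
  list(model = model, log = log)
}
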