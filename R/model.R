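# Model assembly: the baseline one-stage detector (CSP backbone + SPPF,
# CSP-PAN neck, three-scale anchor head) and its lightweight variant in which
# every C3 becomes a C3-light (residual bottlenecks in the backbone, plain in
# the neck) and SimAM attention sits on the three neck outputs.

#' Stock three-scale anchor set
#'
#' The default 9 x 2 (w, h) pixel anchor priors for 640-pixel inputs,
#' scale-major (three per stride 8/16/32); replace with [kmeans_anchors()]
#' output for dataset-specific priors.
#' @format 9 x 2 numeric matrix
#' @export
STOCK_ANCHORS <- matrix(c(10, 13, 16, 30, 33, 23,
                          30, 61, 62, 45, 59, 119,
                          116, 90, 156, 198, 373, 326),
                        ncol = 2, byrow = TRUE)

#' Model configuration
#'
#' @param variant `"baseline"` (stock C3 blocks) or `"cs"` (C3-light blocks
#'   plus SimAM on the neck outputs; set `simam = FALSE` for the intermediate
#'   C3-light-only model)
#' @param nc number of classes (80 for the stock head used in the reference
#'   accounting; 1 for apple training)
#' @param depth_multiple,width_multiple block-repeat and channel-width scaling
#'   (0.33 / 0.25 is the nano preset)
#' @param anchors 9 x 2 matrix of anchor (w, h) pixel pairs, scale-major
#'   (3 per stride 8/16/32), e.g. from [kmeans_anchors()]
#' @param input_size nominal square input size in pixels (multiple of 32)
#' @param simam insert SimAM nodes (only meaningful for `variant = "cs"`)
#' @param lambda SimAM energy regularizer
#' @param conf_thr,iou_thr default decoding thresholds
#' @param seed weight-initialization seed
#' @return a `model_config` list
#' @export
model_config <- function(variant = c("baseline", "cs"), nc = 80L,
                         depth_multiple = 0.33, width_multiple = 0.25,
                         anchors = STOCK_ANCHORS, input_size = 640L,
                         simam = TRUE, lambda = 1e-4,
                         conf_thr = 0.25, iou_thr = 0.5, seed = 0L) {
  variant <- match.arg(variant)
  if (nc < 1) stop("nc must be a positive integer")
  anchors <- matrix(as.numeric(anchors), ncol = 2)
  stopifnot(nrow(anchors) == 9, all(anchors > 0), input_size %% 32 == 0)
  structure(list(variant = variant, nc = as.integer(nc),
                 depth_multiple = depth_multiple,
                 width_multiple = width_multiple, anchors = anchors,
                 input_size = as.integer(input_size), simam = simam,
                 lambda = lambda, conf_thr = conf_thr, iou_thr = iou_thr,
                 seed = as.integer(seed)),
            class = "model_config")
}

make_divisible <- function(x, div = 8L) as.integer(ceiling(x / div) * div)

#' Build a detector model
#'
#' Assembles the explicit layer graph: 6x6 stride-2 stem, four stride-2
#' stages with CSP bottlenecks, SPPF, a PAN neck with two upsample and two
#' downsample paths, and three 1x1 detection heads predicting
#' `3 * (5 + nc)` channels at strides 8/16/32. For `variant = "cs"` every C3
#' is replaced by a C3-light (residual form in the backbone, plain form in
#' the neck) and three SimAM nodes are inserted on the neck outputs.
#'
#' @param config a [model_config()]
#' @return an `ayolo_model`
#' @examples
#' m <- build_model(model_config("baseline", nc = 80))
#' n_params(m)  # 1872157, the stock nano accounting
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "model_config"))
  cw <- function(x) make_divisible(x * config$width_multiple)
  rd <- function(n) max(1L, as.integer(round(n * config$depth_multiple)))
  light <- config$variant == "cs"
  no <- 5L + config$nc

  with_seed(config$seed, function() {
    gb <- graph_builder()
    b <- integer(24)
    # backbone
    b[1] <- add_conv(gb, 0L, "model.0", 3L, cw(64), 6L, 2L, pad = 2L,
                     block_id = 0L)
    b[2] <- add_conv(gb, b[1], "model.1", cw(64), cw(128), 3L, 2L,
                     block_id = 1L)
    b[3] <- add_c3(gb, b[2], "model.2", cw(128), cw(128), rd(3), TRUE, light, 2L)
    b[4] <- add_conv(gb, b[3], "model.3", cw(128), cw(256), 3L, 2L,
                     block_id = 3L)
    b[5] <- add_c3(gb, b[4], "model.4", cw(256), cw(256), rd(6), TRUE, light, 4L)
    b[6] <- add_conv(gb, b[5], "model.5", cw(256), cw(512), 3L, 2L,
                     block_id = 5L)
    b[7] <- add_c3(gb, b[6], "model.6", cw(512), cw(512), rd(9), TRUE, light, 6L)
    b[8] <- add_conv(gb, b[7], "model.7", cw(512), cw(1024), 3L, 2L,
                     block_id = 7L)
    b[9] <- add_c3(gb, b[8], "model.8", cw(1024), cw(1024), rd(3), TRUE, light,
                   8L)
    b[10] <- add_sppf(gb, b[9], "model.9", cw(1024), cw(1024), 5L, 9L)
    # neck (PAN)
    b[11] <- add_conv(gb, b[10], "model.10", cw(1024), cw(512), 1L,
                      block_id = 10L)
    b[12] <- gb$add(node_simple("upsample", "model.11", cw(512), cw(512),
                                from = b[11], module = "Upsample",
                                block_id = 11L))
    b[13] <- gb$add(node_simple("concat", "model.12", 2L * cw(512), 2L * cw(512),
                                from = c(b[12], b[7]), module = "Concat",
                                block_id = 12L))
    b[14] <- add_c3(gb, b[13], "model.13", 2L * cw(512), cw(512), rd(3), FALSE,
                    light, 13L)
    b[15] <- add_conv(gb, b[14], "model.14", cw(512), cw(256), 1L,
                      block_id = 14L)
    b[16] <- gb$add(node_simple("upsample", "model.15", cw(256), cw(256),
                                from = b[15], module = "Upsample",
                                block_id = 15L))
    b[17] <- gb$add(node_simple("concat", "model.16", 2L * cw(256), 2L * cw(256),
                                from = c(b[16], b[5]), module = "Concat",
                                block_id = 16L))
    b[18] <- add_c3(gb, b[17], "model.17", 2L * cw(256), cw(256), rd(3), FALSE,
                    light, 17L)
    b[19] <- add_conv(gb, b[18], "model.18", cw(256), cw(256), 3L, 2L,
                      block_id = 18L)
    b[20] <- gb$add(node_simple("concat", "model.19", 2L * cw(256), 2L * cw(256),
                                from = c(b[19], b[15]), module = "Concat",
                                block_id = 19L))
    b[21] <- add_c3(gb, b[20], "model.20", 2L * cw(256), cw(512), rd(3), FALSE,
                    light, 20L)
    b[22] <- add_conv(gb, b[21], "model.21", cw(512), cw(512), 3L, 2L,
                      block_id = 21L)
    b[23] <- gb$add(node_simple("concat", "model.22", 2L * cw(512), 2L * cw(512),
                                from = c(b[22], b[11]), module = "Concat",
                                block_id = 22L))
    b[24] <- add_c3(gb, b[23], "model.23", 2L * cw(512), cw(1024), rd(3), FALSE,
                    light, 23L)

    p <- c(b[18], b[21], b[24])
    if (light && isTRUE(config$simam)) {
      p <- c(add_simam(gb, b[18], "model.17.simam", config$lambda, 17L),
             add_simam(gb, b[21], "model.20.simam", config$lambda, 20L),
             add_simam(gb, b[24], "model.23.simam", config$lambda, 23L))
    }
    strides <- c(8L, 16L, 32L)
    heads <- integer(3)
    head_cin <- c(cw(256), cw(512), cw(1024))
    for (s in 1:3) {
      heads[s] <- add_conv(gb, p[s], sprintf("model.24.m%d", s - 1L),
                           head_cin[s], 3L * no, 1L, bn = FALSE, act = "none",
                           bias = TRUE, module = "Detect", block_id = 24L)
      # prior-aware bias init: few objects per cell, near-certain class
      bias <- numeric(3L * no)
      for (a in 0:2) {
        bias[a * no + 5L] <- log(8 / (config$input_size / strides[s])^2)
        bias[a * no + 5L + seq_len(config$nc)] <-
          log(0.6 / (config$nc - 0.99999))
      }
      assign("b", bias, envir = gb$nodes[[heads[s]]]$par)
    }
    g <- graph_seal(gb$nodes, out = heads)
    graph_validate(g)
    structure(list(graph = g, config = config, nc = config$nc,
                   anchors = config$anchors, strides = strides,
                   head_idx = heads),
              class = "ayolo_model")
  })
}

#' Total learnable parameters of a model
#' @param model an `ayolo_model`
#' @return numeric count (conv weights/biases and BN affine pairs; BN running
#'   statistics excluded)
#' @export
n_params <- function(model) block_params(model$graph)

#' @export
print.ayolo_model <- function(x, ...) {
  cat(sprintf("<ayolo_model> variant=%s nc=%d nodes=%d params=%s\n",
              x$config$variant, x$nc, length(x$graph$nodes),
              format(n_params(x), big.mark = ",")))
  invisible(x)
}

#' Forward pass
#'
#' @param model an `ayolo_model`
#' @param image `h x w x 3` array with values in `[0, 1]`, or a feature-map
#'   matrix from [fmap_from_array()]
#' @param training TRUE caches activations for the backward pass and updates
#'   BN running buffers
#' @param bn batch-norm statistics at inference: `"batch"` (default;
#'   per-image statistics, the faithful analog of train-time normalization
#'   in this single-image engine) or `"running"` (EMA buffers, which fold to
#'   a fixed affine)
#' @param on_indivisible what to do when spatial dims are not multiples of
#'   32: `"fail"` (default) or `"resize"` (bilinear, to the nearest multiple)
#' @return a list with `arrays` (three arrays of shape
#'   `(3, h/s, w/s, 5 + nc)` for strides 8/16/32), `raw` (internal per-scale
#'   matrices), and `fwd` (caches when `training = TRUE`)
#' @export
forward_model <- function(model, image, training = FALSE,
                          on_indivisible = c("fail", "resize"),
                          bn = c("batch", "running")) {
  on_indivisible <- match.arg(on_indivisible)
  bn <- match.arg(bn)
  if (is.array(image) && length(dim(image)) == 3L) {
    d <- dim(image)
    if (any(d[1:2] %% 32 != 0)) {
      if (on_indivisible == "fail")
        stop("input dims ", d[1], "x", d[2], " are not divisible by 32 ",
             "(pass on_indivisible = \"resize\" to rescale)")
      image <- resize_image(image, 32 * round(d[1] / 32), 32 * round(d[2] / 32))
    }
    x <- fmap_from_array(image)
  } else x <- image
  fwd <- graph_forward(model$graph, x, training = training,
                       use_batch = training || bn == "batch")
  no <- 5L + model$nc
  arrays <- lapply(fwd$out, function(m) {
    h <- attr(m, "h"); w <- attr(m, "w")
    a <- as.numeric(m)
    dim(a) <- c(h, w, no, 3L)
    aperm(a, c(4L, 1L, 2L, 3L))
  })
  list(arrays = arrays, raw = fwd$out, fwd = if (training) fwd)
}

#' Decode raw head outputs to detections
#'
#' Applies the sigmoid/anchor decoding (`xy = (2*sig(t) - 0.5 + cell) * stride`,
#' `wh = (2*sig(t))^2 * anchor`), filters at the confidence threshold
#' (objectness times best class score), and runs greedy class-agnostic
#' non-maximum suppression, ties broken by lower box index.
#'
#' @param model an `ayolo_model`
#' @param raw the `raw` element returned by [forward_model()]
#' @param conf_thr,iou_thr thresholds in `[0, 1]`; default from the model
#'   config (0.25 / 0.5)
#' @return data.frame with columns `x1, y1, x2, y2, conf, class_id`, sorted
#'   by confidence descending (possibly 0 rows)
#' @export
decode_predictions <- function(model, raw, conf_thr = NULL, iou_thr = NULL) {
  conf_thr <- conf_thr %||% model$config$conf_thr
  iou_thr <- iou_thr %||% model$config$iou_thr
  stopifnot(conf_thr >= 0, conf_thr <= 1, iou_thr >= 0, iou_thr <= 1)
  no <- 5L + model$nc
  out <- list()
  for (s in 1:3) {
    m <- raw[[s]]
    h <- attr(m, "h"); w <- attr(m, "w")
    stride <- model$strides[s]
    r <- seq_len(h * w)
    gy <- (r - 1) %% h
    gx <- (r - 1) %/% h
    for (a in 1:3) {
      cols <- (a - 1L) * no + seq_len(no)
      t <- m[, cols, drop = FALSE]
      obj <- sigmoid(t[, 5])
      cls <- sigmoid(t[, 6:no, drop = FALSE])
      best <- max.col(cls, ties.method = "first")
      conf <- obj * cls[cbind(seq_along(best), best)]
      keep <- which(conf >= conf_thr)
      if (!length(keep)) next
      an <- model$anchors[(s - 1L) * 3L + a, ]
      px <- (2 * sigmoid(t[keep, 1]) - 0.5 + gx[keep]) * stride
      py <- (2 * sigmoid(t[keep, 2]) - 0.5 + gy[keep]) * stride
      pw <- (2 * sigmoid(t[keep, 3]))^2 * an[1]
      ph <- (2 * sigmoid(t[keep, 4]))^2 * an[2]
      out[[length(out) + 1L]] <-
        data.frame(x1 = px - pw / 2, y1 = py - ph / 2,
                   x2 = px + pw / 2, y2 = py + ph / 2,
                   conf = conf[keep], class_id = best[keep] - 1L)
    }
  }
  det <- if (length(out)) do.call(rbind, out)
         else data.frame(x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
                         y2 = numeric(0), conf = numeric(0),
                         class_id = integer(0))
  nms_greedy(det, iou_thr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

iou_corners <- function(box, boxes) {
  ix1 <- pmax(box[1], boxes[, 1]); iy1 <- pmax(box[2], boxes[, 2])
  ix2 <- pmin(box[3], boxes[, 3]); iy2 <- pmin(box[4], boxes[, 4])
  inter <- pmax(0, ix2 - ix1) * pmax(0, iy2 - iy1)
  a1 <- (box[3] - box[1]) * (box[4] - box[2])
  a2 <- (boxes[, 3] - boxes[, 1]) * (boxes[, 4] - boxes[, 2])
  inter / (a1 + a2 - inter)
}

nms_greedy <- function(det, iou_thr) {
  if (nrow(det) <= 1) return(det)
  ord <- order(-det$conf, seq_len(nrow(det)))
  det <- det[ord, , drop = FALSE]
  keep <- logical(nrow(det))
  alive <- rep(TRUE, nrow(det))
  for (i in seq_len(nrow(det))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    if (i < nrow(det)) {
      later <- which(alive & seq_len(nrow(det)) > i)
      if (length(later)) {
        ious <- iou_corners(as.numeric(det[i, 1:4]),
                            as.matrix(det[later, 1:4, drop = FALSE]))
        alive[later[ious > iou_thr]] <- FALSE
      }
    }
  }
  out <- det[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect objects in an image
#'
#' Convenience wrapper: forward + decode on one image.
#' @inheritParams forward_model
#' @inheritParams decode_predictions
#' @return detection data.frame (see [decode_predictions()])
#' @export
detect_image <- function(model, image, conf_thr = NULL, iou_thr = NULL,
                         on_indivisible = "fail", bn = "batch") {
  fw <- forward_model(model, image, on_indivisible = on_indivisible, bn = bn)
  decode_predictions(model, fw$raw, conf_thr, iou_thr)
}

# ---- checkpoints and config files ------------------------------------------

#' Save / load model checkpoints
#'
#' Checkpoints hold the model config plus every parameter and buffer array;
#' a save/load round trip restores the model bit-exactly.
#' @param model an `ayolo_model`
#' @param path file path (RDS serialization; a run-time artifact)
#' @export
save_checkpoint <- function(model, path) {
  pars <- lapply(model$graph$nodes, function(nd) {
    nms <- setdiff(ls(nd$par), grep("^g_", ls(nd$par), value = TRUE))
    mget(nms, envir = nd$par)
  })
  saveRDS(list(config = model$config, pars = pars), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint`: the restored `ayolo_model`
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_model(ck$config)
  restore_params(model, ck$pars)
  model
}

restore_params <- function(model, pars) {
  stopifnot(length(pars) == length(model$graph$nodes))
  for (i in seq_along(pars))
    for (nm in names(pars[[i]]))
      assign(nm, pars[[i]][[nm]], envir = model$graph$nodes[[i]]$par)
  invisible(model)
}

clone_model <- function(model) {
  pars <- lapply(model$graph$nodes, function(nd)
    mget(setdiff(ls(nd$par), grep("^g_", ls(nd$par), value = TRUE)),
         envir = nd$par))
  m2 <- build_model(model$config)
  restore_params(m2, pars)
  m2
}

#' Write / read a model configuration file
#'
#' A minimal flat `key: value` text dialect (anchors as nine `w,h` pairs on
#' one line). No YAML engine is available in the target environment, so the
#' parser accepts exactly what the writer emits.
#' @param config a [model_config()]
#' @param path file path
#' @export
write_model_config <- function(config, path) {
  lines <- c(
    paste0("variant: ", config$variant),
    paste0("nc: ", config$nc),
    paste0("depth_multiple: ", format(config$depth_multiple, digits = 15)),
    paste0("width_multiple: ", format(config$width_multiple, digits = 15)),
    paste0("input_size: ", config$input_size),
    paste0("simam: ", ifelse(config$simam, "true", "false")),
    paste0("lambda: ", format(config$lambda, digits = 15)),
    paste0("conf_thr: ", format(config$conf_thr, digits = 15)),
    paste0("iou_thr: ", format(config$iou_thr, digits = 15)),
    paste0("seed: ", config$seed),
    paste0("anchors: ", paste(apply(config$anchors, 1, paste,
                                    collapse = ","), collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  lines <- readLines(path)
  kv <- list()
  for (ln in lines) {
    if (!nzchar(trimws(ln)) || startsWith(trimws(ln), "#")) next
    m <- regmatches(ln, regexec("^([a-z_]+):\\s*(.*)$", ln))[[1]]
    if (length(m) != 3) stop("cannot parse config line: ", ln)
    kv[[m[2]]] <- m[3]
  }
  anchors <- do.call(rbind, lapply(strsplit(kv$anchors, " ")[[1]],
                                   function(p) as.numeric(strsplit(p, ",")[[1]])))
  model_config(variant = kv$variant, nc = as.integer(kv$nc),
               depth_multiple = as.numeric(kv$depth_multiple),
               width_multiple = as.numeric(kv$width_multiple),
               anchors = anchors, input_size = as.integer(kv$input_size),
               simam = identical(kv$simam, "true"),
               lambda = as.numeric(kv$lambda),
               conf_thr = as.numeric(kv$conf_thr),
               iou_thr = as.numeric(kv$iou_thr), seed = as.integer(kv$seed))
}
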