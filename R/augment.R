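# Eight-way augmentation pipeline. Parameter ranges follow the reference pipeline:
# GaussianBlur sigma (0.5, 3.0); AverageBlur k (2, 11); colorspace (hue
# shift, degrees) (10, 50); brightness (-50, 50) grey levels; Gaussian noise
# sigma = 3 grey levels; horizontal / vertical flip; resize factor
# (0.5, 0.8). Pixel transforms leave boxes untouched; flips remap box
# centers; resize changes pixels only (normalized boxes are scale-free).

AUG_METHODS <- c("gaussian_blur", "average_blur", "colorspace", "brightness",
                 "gaussian_noise", "hflip", "vflip", "resize")

AUG_DEFAULTS <- list(gaussian_blur = c(0.5, 3.0), average_blur = c(2, 11),
                     colorspace = c(10, 50), brightness = c(-50, 50),
                     gaussian_noise = 3, hflip = 1, vflip = 1,
                     resize = c(0.5, 0.8))

#' Augmentation specification
#'
#' @param method one of `r paste(AUG_METHODS, collapse = ", ")`
#' @param param parameter (range) for the method; defaults to the reference
#'   range for that method
#' @return an `augmentation_spec` list
#' @export
augmentation_spec <- function(method, param = NULL) {
  if (!method %in% AUG_METHODS)
    stop("unknown augmentation method '", method, "'")
  param <- param %||% AUG_DEFAULTS[[method]]
  lo <- AUG_DEFAULTS[[method]]
  if (length(lo) == 2 && (min(param) < lo[1] || max(param) > lo[2]))
    stop("parameter ", deparse(param), " outside the allowed range ",
         deparse(lo), " for ", method)
  structure(list(method = method, param = param), class = "augmentation_spec")
}

#' Default set of all eight augmentations
#' @return list of [augmentation_spec()]s
#' @export
default_augmentations <- function() lapply(AUG_METHODS, augmentation_spec)

rgb_to_hsv_arr <- function(img) {
  m <- rbind(as.vector(img[, , 1]), as.vector(img[, , 2]),
             as.vector(img[, , 3]))
  grDevices::rgb2hsv(m, maxColorValue = 255)
}

hsv_to_rgb_arr <- function(hsv, h, w) {
  hh <- hsv[1, ] * 6; s <- hsv[2, ]; v <- hsv[3, ]
  i <- floor(hh) %% 6
  f <- hh - floor(hh)
  p <- v * (1 - s); q <- v * (1 - f * s); t_ <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t_, v)))))
  g <- ifelse(i == 0, t_, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t_,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  array(c(r, g, b) * 255, c(h, w, 3))
}

clip255 <- function(img) {
  d <- dim(img)
  out <- pmax(0, pmin(255, img))
  dim(out) <- d
  out
}

#' Apply one augmentation to an image + labels pair
#'
#' Deterministic given `seed`. Blurs, colorspace, brightness and noise leave
#' the boxes bit-identical; `hflip` maps `cx -> 1 - cx`, `vflip` maps
#' `cy -> 1 - cy`; `resize` rescales the pixels while the normalized boxes
#' are unchanged.
#'
#' @param image `h x w x 3` array in `[0, 255]`
#' @param boxes a [norm_box()] table
#' @param spec an [augmentation_spec()]
#' @param seed RNG seed for the parameter draw
#' @return list with `image` and `boxes`
#' @export
augment_sample <- function(image, boxes, spec, seed = 0L) {
  stopifnot(inherits(spec, "augmentation_spec"))
  with_seed(seed, function() {
    d <- dim(image)
    p <- spec$param
    u <- function() if (length(p) == 2) runif(1, p[1], p[2]) else p[1]
    img <- switch(spec$method,
      gaussian_blur = blur_image(image, u()),
      average_blur = box_blur_image(image, as.integer(round(u()))),
      colorspace = {
        hsv <- rgb_to_hsv_arr(image)
        hsv[1, ] <- (hsv[1, ] + u() / 360) %% 1
        hsv_to_rgb_arr(hsv, d[1], d[2])
      },
      brightness = clip255(image + u()),
      gaussian_noise = clip255(image + array(rnorm(prod(d), sd = p[1]), d)),
      hflip = image[, d[2]:1, , drop = FALSE],
      vflip = image[d[1]:1, , , drop = FALSE],
      resize = {
        f <- u()
        resize_image(image, max(1, round(d[1] * f)), max(1, round(d[2] * f)))
      })
    bx <- boxes
    if (spec$method == "hflip" && nrow(bx)) bx$cx <- 1 - bx$cx
    if (spec$method == "vflip" && nrow(bx)) bx$cy <- 1 - bx$cy
    list(image = img, boxes = validate_norm_box(bx))
  })
}

# Cumulative-rounding schedule of augmented copies per original: the i-th
# original gets round(i*e) - round((i-1)*e) extras with e the mean extra
# count, so totals hit round(n * multiplier) exactly for any multiplier.
aug_schedule <- function(n, multiplier) {
  total_extra <- round(n * multiplier) - n
  diff(round(seq(0, n) / n * total_extra))
}

#' Expand a labeled image directory by augmentation
#'
#' Keeps every original and writes `multiplier - 1` augmented copies per
#' image on average; a non-integral multiplier is realized by a deterministic
#' cumulative-rounding schedule over the (sorted) originals so that the total
#' count equals `round(n * multiplier)` exactly (e.g. 500 originals at
#' multiplier 5.4 give 2700 images). Each copy samples one method from
#' `specs` and its parameters independently, seeded.
#'
#' @param in_dir directory of paired `.ppm` images and `.txt` YOLO labels
#' @param out_dir output directory (created; collision of names is an error)
#' @param multiplier target expansion factor (>= 1)
#' @param seed base seed
#' @param specs list of [augmentation_spec()]s to sample from
#' @return invisible data.frame manifest (file, source, method)
#' @export
build_augmented_dataset <- function(in_dir, out_dir, multiplier, seed = 0L,
                                    specs = default_augmentations()) {
  stopifnot(multiplier >= 1)
  imgs <- sort(list.files(in_dir, pattern = "\\.ppm$", full.names = TRUE))
  if (!length(imgs)) stop("no .ppm images in ", in_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(imgs)
  sched <- aug_schedule(n, multiplier)
  rows <- list()
  emit <- function(img, bx, stem, src, method) {
    ip <- file.path(out_dir, paste0(stem, ".ppm"))
    if (file.exists(ip)) stop("output name collision: ", ip)
    write_image(img, ip)
    write_yolo_txt(bx, file.path(out_dir, paste0(stem, ".txt")))
    rows[[length(rows) + 1L]] <<- data.frame(file = basename(ip),
                                             source = src, method = method)
  }
  for (i in seq_len(n)) {
    stem <- sub("\\.ppm$", "", basename(imgs[i]))
    img <- read_image(imgs[i])
    bx <- read_yolo_txt(file.path(in_dir, paste0(stem, ".txt")))
    emit(img, bx, stem, stem, "original")
    for (j in seq_len(sched[i])) {
      s <- derive_seed(seed, i * 1000L + j)
      k <- with_seed(s, function() sample.int(length(specs), 1))
      aug <- augment_sample(img, bx, specs[[k]], derive_seed(s, 1L))
      emit(aug$image, aug$boxes, sprintf("%s_aug%02d", stem, j), stem,
           specs[[k]]$method)
    }
  }
  invisible(do.call(rbind, rows))
}
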