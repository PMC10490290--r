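# Synthetic orchard scene generator.
#
# Scenes emulate the conditions an orchard camera sees: round/elliptical
# fruit at varying size, partial fruit-on-fruit overlap, branch and leaf
# occlusion, day / low-light / overexposed illumination, and optional motion
# blur. Apples are shaded radial-gradient ellipses with a specular spot;
# occluders are thick branch segments and leaf ellipses drawn on top. The
# generator tracks per-pixel ownership, so ground-truth boxes are tight
# around the *visible* part of each apple and boxes with visible fraction
# below a threshold are culled. Photorealism is a non-goal: the point is to
# exercise every pipeline stage with exact, programmatic ground truth.

#' Synthetic scene configuration
#'
#' @param img_size square image size in pixels
#' @param n_apples inclusive integer range of apple counts
#' @param radius inclusive pixel range of apple radii
#' @param occluder_density non-negative real; expected occluders = 10 x density
#' @param min_sep minimum apple center separation as a fraction of the
#'   radius sum (0.6 default allows partial fruit-on-fruit overlap; >= 1
#'   keeps apples disjoint)
#' @param lighting `"day"`, `"dark"` or `"overexposed"`
#' @param blur_sigma Gaussian blur applied to the final image (0 = none)
#' @param min_visible visible-area fraction below which a box is culled
#' @return a `scene_config` list
#' @export
scene_config <- function(img_size = 320L, n_apples = c(3L, 8L),
                         radius = c(12L, 36L), occluder_density = 0.3,
                         lighting = c("day", "dark", "overexposed"),
                         blur_sigma = 0, min_visible = 0.25, min_sep = 0.6) {
  lighting <- match.arg(lighting)
  stopifnot(length(n_apples) == 2, n_apples[1] <= n_apples[2],
            length(radius) == 2, radius[1] <= radius[2],
            occluder_density >= 0, min_visible > 0, min_visible <= 1)
  if (2 * radius[2] >= img_size)
    stop("config error: apple diameter ", 2 * radius[2],
         " exceeds image size ", img_size)
  structure(list(img_size = as.integer(img_size),
                 n_apples = as.integer(n_apples), radius = as.numeric(radius),
                 occluder_density = occluder_density, lighting = lighting,
                 blur_sigma = blur_sigma, min_visible = min_visible,
                 min_sep = min_sep),
            class = "scene_config")
}

# smooth low-frequency noise field in [-1, 1]
noise_field <- function(n, coarse = 8L) {
  g <- matrix(runif(coarse * coarse, -1, 1), coarse, coarse)
  resize_image(array(g, c(coarse, coarse, 1)), n, n)[, , 1]
}

#' Generate one synthetic orchard scene
#'
#' @param config a [scene_config()]
#' @param seed scene seed (fully determines the output)
#' @return list with `image` (`n x n x 3`, `[0, 255]`), `boxes` (a
#'   [norm_box()] table, tight around visible apple pixels) and `ownership`
#'   (integer matrix: 0 background, -1 occluder, i = apple i; used by
#'   pixel-level tests)
#' @export
generate_scene <- function(config, seed = 0L) {
  stopifnot(inherits(config, "scene_config"))
  with_seed(seed, function() {
    n <- config$img_size
    xs <- matrix(rep(seq_len(n), each = n), n, n)   # column index
    ys <- matrix(rep(seq_len(n), n), n, n)          # row index
    img <- array(0, c(n, n, 3))
    base <- c(58, 88, 42)
    f1 <- noise_field(n); f2 <- noise_field(n, 16L)
    for (ch in 1:3)
      img[, , ch] <- base[ch] * (1 + 0.25 * f1 + 0.12 * f2) +
                     rnorm(n * n, sd = 6)
    own <- matrix(0L, n, n)
    total_px <- integer(0)

    n_ap <- if (config$n_apples[1] == config$n_apples[2]) config$n_apples[1]
            else sample(config$n_apples[1]:config$n_apples[2], 1)
    apples <- list()
    for (i in seq_len(n_ap)) {
      for (try in 1:200) {
        r <- runif(1, config$radius[1], config$radius[2])
        cx <- runif(1, r + 1, n - r - 1)
        cy <- runif(1, r + 1, n - r - 1)
        ok <- TRUE
        for (ap in apples) {
          if (sqrt((cx - ap$cx)^2 + (cy - ap$cy)^2) <
              config$min_sep * (r + max(ap$rx, ap$ry))) { ok <- FALSE; break }
        }
        if (ok) break
      }
      apples[[i]] <- list(cx = cx, cy = cy, rx = r,
                          ry = r * runif(1, 0.85, 1.05))
    }
    for (i in seq_along(apples)) {
      ap <- apples[[i]]
      e <- ((xs - ap$cx) / ap$rx)^2 + ((ys - ap$cy) / ap$ry)^2
      mask <- e <= 1
      total_px[i] <- sum(mask)
      shade <- 1.05 - 0.45 * e[mask]
      yellow <- runif(1) < 0.25
      col <- if (yellow) c(205, 170, 40) + rnorm(3, sd = 10)
             else c(185, 40, 35) + rnorm(3, sd = c(25, 12, 8))
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[mask] <- pmax(0, col[ch] * shade)
        img[, , ch] <- plane
      }
      # specular highlight
      hx <- ap$cx - 0.35 * ap$rx; hy <- ap$cy - 0.35 * ap$ry
      hl <- exp(-(((xs - hx)^2 + (ys - hy)^2) / (0.12 * ap$rx^2 + 1e-9)))
      hl[!mask] <- 0
      for (ch in 1:3) img[, , ch] <- img[, , ch] + 90 * hl
      own[mask] <- i
    }

    n_occ <- round(10 * config$occluder_density)
    for (j in seq_len(n_occ)) {
      if (runif(1) < 0.6) {                         # branch segment
        x0 <- runif(1, 1, n); y0 <- runif(1, 1, n)
        ang <- runif(1, 0, pi); len <- runif(1, 0.3, 0.9) * n
        x1 <- x0 + cos(ang) * len; y1 <- y0 + sin(ang) * len
        wd <- runif(1, 2, 5)
        dx <- x1 - x0; dy <- y1 - y0
        tt <- pmin(1, pmax(0, ((xs - x0) * dx + (ys - y0) * dy) /
                                (dx * dx + dy * dy + 1e-9)))
        dist2 <- (xs - (x0 + tt * dx))^2 + (ys - (y0 + tt * dy))^2
        mask <- dist2 <= wd^2
        col <- c(82, 56, 30) + rnorm(3, sd = 6)
      } else {                                      # leaf
        lx <- runif(1, 1, n); ly <- runif(1, 1, n)
        lr <- runif(1, 6, 16)
        mask <- ((xs - lx) / lr)^2 + ((ys - ly) / (0.55 * lr))^2 <= 1
        col <- c(48, 110, 45) + rnorm(3, sd = 10)
      }
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[mask] <- col[ch]
        img[, , ch] <- plane
      }
      own[mask] <- -1L
    }

    img <- switch(config$lighting,
      day = img,
      dark = {
        img <- img * 0.32
        img[, , 3] <- img[, , 3] + 8
        img
      },
      overexposed = img * 1.8 + 30)
    if (config$blur_sigma > 0) img <- blur_image(img, config$blur_sigma)
    img <- clip255(img)

    boxes <- norm_box()
    for (i in seq_along(apples)) {
      vis <- which(own == i, arr.ind = TRUE)
      if (!nrow(vis)) next
      if (nrow(vis) / total_px[i] < config$min_visible) next
      y1 <- min(vis[, 1]) - 1; y2 <- max(vis[, 1])
      x1 <- min(vis[, 2]) - 1; x2 <- max(vis[, 2])
      boxes <- rbind(boxes,
                     data.frame(class_id = 0L, cx = (x1 + x2) / 2 / n,
                                cy = (y1 + y2) / 2 / n, w = (x2 - x1) / n,
                                h = (y2 - y1) / n))
    }
    list(image = img, boxes = validate_norm_box(boxes), ownership = own)
  })
}

#' Generate a labeled dataset on disk
#'
#' Writes `scene_%04d.ppm` with paired Pascal VOC XML and YOLO TXT labels
#' plus a JSON manifest recording per-scene seeds, so any scene can be
#' regenerated independently.
#'
#' @param n number of scenes
#' @param config a [scene_config()]
#' @param seed base seed; scene i uses `derive_seed(seed, i)`
#' @param out_dir output directory (created)
#' @return invisible manifest data.frame (file, seed, n_boxes)
#' @export
generate_dataset <- function(n, config, seed = 0L, out_dir) {
  stopifnot(n >= 1)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    si <- derive_seed(seed, i)
    sc <- generate_scene(config, si)
    stem <- sprintf("scene_%04d", i)
    write_image(sc$image, file.path(out_dir, paste0(stem, ".ppm")))
    write_yolo_txt(sc$boxes, file.path(out_dir, paste0(stem, ".txt")))
    write_voc_annotation(
      yolo_to_voc(sc$boxes, config$img_size, config$img_size,
                  filename = paste0(stem, ".ppm")),
      file.path(out_dir, paste0(stem, ".xml")))
    rows[[i]] <- data.frame(file = paste0(stem, ".ppm"), seed = si,
                            n_boxes = nrow(sc$boxes))
  }
  manifest <- do.call(rbind, rows)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  invisible(manifest)
}

#' Load a labeled dataset directory into memory
#'
#' Reads paired `.ppm` / `.txt` files (as produced by [generate_dataset()]
#' or [build_augmented_dataset()]), optionally resizing images to a square
#' model input size (normalized boxes are unchanged by resizing).
#' @param dir dataset directory
#' @param img_size optional square size to resize to
#' @return list of samples, each `list(image, boxes, file)`
#' @export
load_yolo_dataset <- function(dir, img_size = NULL) {
  imgs <- sort(list.files(dir, pattern = "\\.ppm$", full.names = TRUE))
  if (!length(imgs)) stop("no .ppm images found in ", dir)
  lapply(imgs, function(p) {
    img <- read_image(p)
    if (!is.null(img_size)) img <- resize_image(img, img_size, img_size)
    lp <- sub("\\.ppm$", ".txt", p)
    boxes <- if (file.exists(lp)) read_yolo_txt(lp) else norm_box()
    list(image = img, boxes = boxes, file = basename(p))
  })
}
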