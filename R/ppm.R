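# Netpbm image IO. No PNG/JPEG reader exists in the target environment, so
# images travel as PPM (color) / PGM (gray), P2/P3 ASCII or P5/P6 binary.
# In memory an image is an h x w x 3 double array with values in [0, 255].

#' Read / write Netpbm images
#'
#' @param path file path (`.ppm` / `.pgm`)
#' @return `read_image`: an `h x w x 3` array in `[0, 255]` (grayscale input
#'   is replicated across channels)
#' @export
read_image <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- character(0)
  # header tokens with '#' comment handling
  buf <- raw(0)
  read_tok <- function() {
    repeat {
      ch <- readBin(con, "raw", 1)
      if (!length(ch)) stop("unexpected end of file in header: ", path)
      c_ <- rawToChar(ch)
      if (c_ == "#") {
        repeat {
          ch <- readBin(con, "raw", 1)
          if (!length(ch) || rawToChar(ch) == "\n") break
        }
      } else if (grepl("[ \t\r\n]", c_)) {
        if (length(buf)) break
      } else buf <<- c(buf, ch)
    }
    t <- rawToChar(buf); buf <<- raw(0); t
  }
  magic <- read_tok()
  if (!magic %in% c("P2", "P3", "P5", "P6"))
    stop("unsupported Netpbm magic '", magic, "' in ", path)
  w <- as.integer(read_tok()); h <- as.integer(read_tok())
  maxval <- as.integer(read_tok())
  nch <- if (magic %in% c("P3", "P6")) 3L else 1L
  n <- as.double(w) * h * nch
  vals <- if (magic %in% c("P5", "P6")) {
    as.integer(readBin(con, "raw", n))
  } else {
    scan(con, what = integer(), n = n, quiet = TRUE)
  }
  if (length(vals) != n) stop("truncated pixel data in ", path)
  a <- array(0, c(h, w, 3))
  # file order: channel fastest, then x, then y
  px <- array(as.double(vals), c(nch, w, h))
  for (ch in 1:3) a[, , ch] <- t(px[min(ch, nch), , ])
  a * (255 / maxval)
}

#' @rdname read_image
#' @param img `h x w x 3` array in `[0, 255]` (or `h x w` matrix for PGM)
#' @param ascii write ASCII (P3/P2) instead of binary (P6/P5)
#' @export
write_image <- function(img, path, ascii = FALSE) {
  if (is.matrix(img)) {
    h <- nrow(img); w <- ncol(img)
    vals <- as.integer(pmax(0, pmin(255, round(t(img)))))
    magic <- if (ascii) "P2" else "P5"
  } else {
    stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
    h <- dim(img)[1]; w <- dim(img)[2]
    vals <- as.integer(pmax(0, pmin(255, round(aperm(img, c(3, 2, 1))))))
    magic <- if (ascii) "P3" else "P6"
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("%s\n%d %d\n255\n", magic, w, h), con, eos = NULL)
  if (ascii) writeChar(paste(vals, collapse = "\n"), con, eos = NULL)
  else writeBin(as.raw(vals), con)
  invisible(path)
}

#' Resize an image
#'
#' Bilinear interpolation with half-pixel centers; used by the resize
#' augmentation and by [forward_model()]'s optional input rescaling.
#' @param img `h x w x c` array
#' @param ho,wo output dims
#' @return resized array
#' @export
resize_image <- function(img, ho, wo) {
  d <- dim(img)
  h <- d[1]; w <- d[2]
  ys <- pmin(pmax((seq_len(ho) - 0.5) * h / ho - 0.5, 0), h - 1)
  xs <- pmin(pmax((seq_len(wo) - 0.5) * w / wo - 0.5, 0), w - 1)
  y0 <- pmin(floor(ys), h - 1); y1 <- pmin(y0 + 1, h - 1); fy <- ys - y0
  x0 <- pmin(floor(xs), w - 1); x1 <- pmin(x0 + 1, w - 1); fx <- xs - x0
  out <- array(0, c(ho, wo, d[3]))
  for (ch in seq_len(d[3])) {
    M <- img[, , ch]
    a <- M[y0 + 1, x0 + 1, drop = FALSE]; b <- M[y0 + 1, x1 + 1, drop = FALSE]
    cc <- M[y1 + 1, x0 + 1, drop = FALSE]; dd <- M[y1 + 1, x1 + 1, drop = FALSE]
    top <- a + sweep(b - a, 2, fx, `*`)
    bot <- cc + sweep(dd - cc, 2, fx, `*`)
    out[, , ch] <- top + sweep(bot - top, 1, fy, `*`)
  }
  out
}

# Separable Gaussian blur with edge replication.
blur_image <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2)); k <- k / sum(k)
  blur1 <- function(M) {
    h <- nrow(M)
    Mp <- M[c(rep(1, r), seq_len(h), rep(h, r)), , drop = FALSE]
    out <- matrix(0, h, ncol(M))
    for (i in seq_along(k))
      out <- out + k[i] * Mp[i:(i + h - 1), , drop = FALSE]
    out
  }
  for (ch in seq_len(dim(img)[3]))
    img[, , ch] <- t(blur1(t(blur1(img[, , ch]))))
  img
}

box_blur_image <- function(img, k) {
  r0 <- (k - 1L) %/% 2L; r1 <- k - 1L - r0
  blur1 <- function(M) {
    h <- nrow(M)
    Mp <- M[c(rep(1, r0), seq_len(h), rep(h, r1)), , drop = FALSE]
    out <- matrix(0, h, ncol(M))
    for (i in seq_len(k))
      out <- out + Mp[i:(i + h - 1), , drop = FALSE]
    out / k
  }
  for (ch in seq_len(dim(img)[3]))
    img[, , ch] <- t(blur1(t(blur1(img[, , ch]))))
  img
}
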