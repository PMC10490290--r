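#' Feature-map container
#'
#' Internally every feature map is a dense `(h*w) x c` double matrix in
#' column-major order with spatial index `y + (x-1)*h`, i.e. the matrix view
#' of an R array of dim `c(h, w, ch)`. These helpers convert between the two
#' representations. A batch is a plain list of feature maps; every block
#' operates image-by-image, so the batch axis is trivially preserved.
#'
#' @param a array of dim `c(h, w, ch)` (a 2-D matrix is treated as 1 channel)
#' @return `fmap_from_array`: a feature map matrix with attributes `h`, `w`;
#'   `fmap_to_array`: the corresponding `h x w x ch` array.
#' @export
fmap_from_array <- function(a) {
  if (is.matrix(a)) dim(a) <- c(dim(a), 1L)
  stopifnot(length(dim(a)) == 3L)
  d <- dim(a)
  m <- a
  dim(m) <- c(d[1] * d[2], d[3])
  structure(m, h = d[1], w = d[2])
}

#' @rdname fmap_from_array
#' @param x feature map matrix
#' @param h,w spatial dims (taken from attributes when missing)
#' @export
fmap_to_array <- function(x, h = attr(x, "h"), w = attr(x, "w")) {
  a <- as.numeric(x)
  dim(a) <- c(h, w, ncol(x))
  a
}

fmap <- function(m, h, w) structure(m, h = h, w = w)

sigmoid <- function(x) 1 / (1 + exp(-x))

silu <- function(x) x * sigmoid(x)

silu_grad <- function(x) {
  s <- sigmoid(x)
  s * (1 + x * (1 - s))
}

#' Deterministic child seed derivation
#'
#' Derives a reproducible 31-bit child seed from a base seed and an index so
#' that per-scene / per-epoch streams are independent but fully determined by
#' one user-facing seed.
#' @param seed base seed (integer)
#' @param i index (integer)
#' @return integer seed in `[0, 2^31)`
#' @export
derive_seed <- function(seed, i) {
  s <- (as.double(seed) %% 2147483647) + 1
  x <- (s * 48271 + i * 104729 + 12345) %% 2147483647
  as.integer(x)
}

# Evaluate fn with a locally seeded RNG, restoring global state afterwards.
with_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}
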