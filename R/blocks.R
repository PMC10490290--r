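# Composite blocks, flattened to primitive nodes through a small builder.

graph_builder <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- list()
  e$add <- function(node) {
    e$nodes[[length(e$nodes) + 1L]] <- node
    length(e$nodes)
  }
  e
}

add_conv <- function(gb, from, name, c_in, c_out, k = 1L, stride = 1L,
                     bn = TRUE, act = "silu", bias = !bn, pad = NULL,
                     module = "Conv", block_id = NA_integer_) {
  gb$add(node_conv(name, c_in, c_out, k, stride, bn = bn, act = act,
                   bias = bias, pad = pad, from = from, module = module,
                   block_id = block_id))
}

# Standard CSP bottleneck: 1x1 conv -> 3x3 conv (+ residual when shortcut).
# Light variant (partial-convolution bottleneck): PConv(3x3, c_p = c/4,
# weights only) -> 1x1 conv c->2c with BN+SiLU -> 1x1 conv 2c->c with neither
# BN nor bias (FasterNet-style pointwise mixing); residual kept in the
# backbone form (BottleNeck1) and dropped in the neck form (BottleNeck2).
# This layout is the one whose summed parameter counts reproduce the printed
# per-module totals of the reference accounting.
add_bottleneck <- function(gb, from, name, c, shortcut, light,
                           module, block_id) {
  if (!light) {
    a <- add_conv(gb, from, paste0(name, ".cv1"), c, c, 1L,
                  module = module, block_id = block_id)
    b <- add_conv(gb, a, paste0(name, ".cv2"), c, c, 3L,
                  module = module, block_id = block_id)
  } else {
    if (c %% 4L != 0L)
      stop("C3-light bottleneck requires channels divisible by 4, got ", c)
    a <- gb$add(node_pconv(paste0(name, ".pconv"), c, c %/% 4L, 3L,
                           from = from, module = module, block_id = block_id))
    m1 <- add_conv(gb, a, paste0(name, ".pw1"), c, 2L * c, 1L,
                   module = module, block_id = block_id)
    b <- add_conv(gb, m1, paste0(name, ".pw2"), 2L * c, c, 1L,
                  bn = FALSE, act = "none", bias = FALSE,
                  module = module, block_id = block_id)
  }
  if (shortcut)
    b <- gb$add(node_simple("add", paste0(name, ".add"), c, c,
                            from = c(from, b), module = module,
                            block_id = block_id))
  b
}

add_c3 <- function(gb, from, name, c1, c2, n, shortcut, light = FALSE,
                   block_id = NA_integer_) {
  module <- if (light) "C3-light" else "C3"
  c_ <- c2 %/% 2L
  cv1 <- add_conv(gb, from, paste0(name, ".cv1"), c1, c_, 1L,
                  module = module, block_id = block_id)
  y <- cv1
  for (i in seq_len(n))
    y <- add_bottleneck(gb, y, paste0(name, ".m", i - 1L), c_, shortcut,
                        light, module, block_id)
  cv2 <- add_conv(gb, from, paste0(name, ".cv2"), c1, c_, 1L,
                  module = module, block_id = block_id)
  cat_ <- gb$add(node_simple("concat", paste0(name, ".cat"), 2L * c_, 2L * c_,
                             from = c(y, cv2), module = module,
                             block_id = block_id))
  add_conv(gb, cat_, paste0(name, ".cv3"), 2L * c_, c2, 1L,
           module = module, block_id = block_id)
}

add_sppf <- function(gb, from, name, c1, c2, k = 5L,
                     block_id = NA_integer_) {
  if (k %% 2L == 0L) stop("sppf: pool size must be odd, got ", k)
  c_ <- c1 %/% 2L
  cv1 <- add_conv(gb, from, paste0(name, ".cv1"), c1, c_, 1L,
                  module = "SPPF", block_id = block_id)
  m1 <- gb$add(node_simple("maxpool", paste0(name, ".m1"), c_, c_, from = cv1,
                           module = "SPPF", block_id = block_id, k = k))
  m2 <- gb$add(node_simple("maxpool", paste0(name, ".m2"), c_, c_, from = m1,
                           module = "SPPF", block_id = block_id, k = k))
  m3 <- gb$add(node_simple("maxpool", paste0(name, ".m3"), c_, c_, from = m2,
                           module = "SPPF", block_id = block_id, k = k))
  cat_ <- gb$add(node_simple("concat", paste0(name, ".cat"), 4L * c_, 4L * c_,
                             from = c(cv1, m1, m2, m3), module = "SPPF",
                             block_id = block_id))
  add_conv(gb, cat_, paste0(name, ".cv2"), 4L * c_, c2, 1L,
           module = "SPPF", block_id = block_id)
}

add_simam <- function(gb, from, name, lambda, block_id = NA_integer_) {
  nd <- gb$nodes[[from]]
  gb$add(node_simple("simam", name, nd$c_out, nd$c_out, from = from,
                     module = "SimAM", block_id = block_id, lambda = lambda))
}

# ---- user-facing layer specs and single-block operations --------------------

#' Layer specifications
#'
#' Small record constructors describing the primitive blocks. A convolution
#' under batch normalization carries no bias, so its learnable parameter count
#' is `k^2 * c_in * c_out + 2 * c_out`; a partial convolution convolves only a
#' contiguous block of `c_p` channels (default partial ratio `c_p/c = 1/4`)
#' and passes the remaining `c - c_p` channels through untouched, which cuts
#' its multiply-accumulates to `(c_p/c)^2` of a full convolution; SimAM is a
#' parameter-free attention module whose only tunable is the energy
#' regularizer `lambda`.
#'
#' @param k kernel size (square)
#' @param c_in,c_out input/output channel counts
#' @param stride convolution stride
#' @param has_bn use batch normalization (implies no conv bias)
#' @param activation `"silu"` (default) or `"none"`
#' @return a spec list used by [conv_bn_act()], [pconv()], [simam()].
#' @export
conv_spec <- function(k, c_in, c_out, stride = 1L, has_bn = TRUE,
                      activation = "silu") {
  stopifnot(k >= 1, c_in >= 1, c_out >= 1, stride >= 1)
  list(k = as.integer(k), c_in = as.integer(c_in), c_out = as.integer(c_out),
       stride = as.integer(stride), has_bn = has_bn, activation = activation)
}

#' @rdname conv_spec
#' @param c total channels of a partial convolution
#' @param c_p convolved channels (default `c/4`)
#' @param slice_position which contiguous channel block is convolved
#' @export
pconv_spec <- function(c, c_p = max(1L, c %/% 4L), k = 3L,
                       slice_position = c("first", "last")) {
  slice_position <- match.arg(slice_position)
  if (c_p > c) stop("pconv configuration error: c_p (", c_p,
                    ") exceeds c (", c, ")")
  list(c = as.integer(c), c_p = as.integer(c_p), k = as.integer(k),
       slice_position = slice_position)
}

#' @rdname conv_spec
#' @param lambda positive energy regularizer (default `1e-4`, the value used
#'   by the original parameter-free attention formulation)
#' @export
simam_spec <- function(lambda = 1e-4) {
  stopifnot(lambda > 0)
  list(lambda = lambda)
}

#' Instantiate single blocks with seeded weights
#'
#' Constructors return a small sealed graph (weights initialized from `seed`)
#' that [block_forward()] runs on a feature map. They exist so that individual
#' blocks can be exercised and profiled outside a full model.
#'
#' @param spec a [conv_spec()] / [pconv_spec()]
#' @param seed RNG seed for weight initialization
#' @return an `ayolo_graph` object
#' @export
new_conv_layer <- function(spec, seed = 0L) {
  with_seed(seed, function() {
    gb <- graph_builder()
    add_conv(gb, 0L, "conv", spec$c_in, spec$c_out, spec$k, spec$stride,
             bn = spec$has_bn, act = spec$activation, bias = !spec$has_bn)
    graph_seal(gb$nodes)
  })
}

#' @rdname new_conv_layer
#' @export
new_pconv_layer <- function(spec, seed = 0L) {
  with_seed(seed, function() {
    gb <- graph_builder()
    gb$add(node_pconv("pconv", spec$c, spec$c_p, spec$k, spec$slice_position,
                      from = 0L))
    graph_seal(gb$nodes)
  })
}

#' @rdname new_conv_layer
#' @param c_in,c_out,n,shortcut CSP block configuration (`n` bottlenecks)
#' @export
new_c3_block <- function(c_in, c_out, n = 1L, shortcut = TRUE, seed = 0L) {
  with_seed(seed, function() {
    gb <- graph_builder()
    add_c3(gb, 0L, "c3", c_in, c_out, n, shortcut, light = FALSE)
    graph_seal(gb$nodes)
  })
}

#' @rdname new_conv_layer
#' @export
new_c3_light_block <- function(c_in, c_out, n = 1L, shortcut = TRUE,
                               seed = 0L) {
  with_seed(seed, function() {
    gb <- graph_builder()
    add_c3(gb, 0L, "c3l", c_in, c_out, n, shortcut, light = TRUE)
    graph_seal(gb$nodes)
  })
}

#' @rdname new_conv_layer
#' @param k pool size (odd) for the fast spatial-pyramid-pooling block
#' @export
new_sppf_block <- function(c_in, c_out, k = 5L, seed = 0L) {
  with_seed(seed, function() {
    gb <- graph_builder()
    add_sppf(gb, 0L, "sppf", c_in, c_out, k)
    graph_seal(gb$nodes)
  })
}

#' Run a block on a feature map
#'
#' @param block an `ayolo_graph` from one of the block constructors
#' @param x feature map (`(h*w) x c` matrix from [fmap_from_array()], or an
#'   `h x w x c` array)
#' @param training use batch statistics in BN (TRUE) or running stats (FALSE)
#' @return the block's output feature map (matrix with `h`, `w` attributes)
#' @export
block_forward <- function(block, x, training = FALSE) {
  if (is.array(x) && length(dim(x)) == 3L) x <- fmap_from_array(x)
  graph_forward(block, x, training = training)$out[[1]]
}

#' Count learnable parameters of a block or graph
#' @param block an `ayolo_graph`
#' @return integer parameter count (BN running statistics excluded)
#' @export
block_params <- function(block) {
  sum(vapply(block$nodes, node_n_params, numeric(1)))
}

#' Primitive block operations
#'
#' Functional forms of the building blocks: each applies a freshly
#' seed-initialized block to `x` (pass `block =` to reuse weights across
#' calls). `conv_bn_act` is convolution + batch norm + activation;
#' `pconv` convolves only the selected contiguous channel slice; `c3_block` /
#' `c3_light_block` are the CSP bottleneck stacks (`shortcut = TRUE` is the
#' residual backbone form, `FALSE` the neck form); `sppf` chains three k x k
#' max-pools and concatenates (element-wise equal to parallel spatial pyramid
#' pooling with sizes k, 2k-1, 3k-2); `simam` modulates `x` by its per-channel
#' energy-based attention and adds zero parameters.
#'
#' @param x feature map (matrix with `h`/`w` attributes, or `h x w x c` array)
#' @param spec layer spec from [conv_spec()] etc.
#' @param block optional pre-built block to reuse
#' @param seed weight-init seed when `block` is NULL
#' @param training BN statistics mode
#' @return output feature map
#' @export
conv_bn_act <- function(x, spec, block = NULL, seed = 0L, training = FALSE) {
  if (is.null(block)) block <- new_conv_layer(spec, seed)
  block_forward(block, x, training)
}

#' @rdname conv_bn_act
#' @export
pconv <- function(x, spec, block = NULL, seed = 0L) {
  if (is.null(block)) block <- new_pconv_layer(spec, seed)
  block_forward(block, x)
}

#' @rdname conv_bn_act
#' @param c_out output channels
#' @param n number of bottlenecks
#' @param shortcut residual adds in the bottlenecks
#' @export
c3_block <- function(x, c_out, n = 1L, shortcut = TRUE, block = NULL,
                     seed = 0L, training = FALSE) {
  if (is.array(x) && length(dim(x)) == 3L) x <- fmap_from_array(x)
  if (is.null(block)) block <- new_c3_block(ncol(x), c_out, n, shortcut, seed)
  block_forward(block, x, training)
}

#' @rdname conv_bn_act
#' @export
c3_light_block <- function(x, c_out, n = 1L, shortcut = TRUE, block = NULL,
                           seed = 0L, training = FALSE) {
  if (is.array(x) && length(dim(x)) == 3L) x <- fmap_from_array(x)
  if (is.null(block))
    block <- new_c3_light_block(ncol(x), c_out, n, shortcut, seed)
  block_forward(block, x, training)
}

#' @rdname conv_bn_act
#' @param k pool size (odd)
#' @export
sppf <- function(x, k = 5L, block = NULL, seed = 0L, training = FALSE) {
  if (is.array(x) && length(dim(x)) == 3L) x <- fmap_from_array(x)
  if (is.null(block)) block <- new_sppf_block(ncol(x), ncol(x), k, seed)
  block_forward(block, x, training)
}

#' @rdname conv_bn_act
#' @export
simam <- function(x, spec = simam_spec()) {
  if (is.array(x) && length(dim(x)) == 3L) x <- fmap_from_array(x)
  gb <- graph_builder()
  gb$add(node_simple("simam", "simam", ncol(x), ncol(x), from = 0L,
                     lambda = spec$lambda))
  block_forward(graph_seal(gb$nodes), x)
}
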