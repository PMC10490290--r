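# Graph-node engine.
#
# A model is a DAG of primitive nodes; every composite block (C3, C3-light,
# SPPF, ...) is flattened to primitives at build time so one forward/backward
# implementation serves the whole network. Learnable arrays live in a per-node
# environment (`par`) so the optimizer and the running-statistics update can
# mutate them in place; gradients accumulate into the same environment under
# `g_<name>`.
#
# Node types: conv (covers the detect heads: k=1, bias, no BN, no act),
# pconv, maxpool (stride 1, same pad), upsample (nearest x2), concat, add,
# simam.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

new_par_env <- function(lst) {
  e <- new.env(parent = emptyenv())
  for (nm in names(lst)) assign(nm, lst[[nm]], envir = e)
  e
}

kaiming_init <- function(nrow, ncol, fan_in) {
  matrix(rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

node_conv <- function(name, c_in, c_out, k = 1L, stride = 1L,
                      bn = TRUE, act = "silu", bias = !bn,
                      pad = NULL, from = NA_integer_,
                      module = "Conv", block_id = NA_integer_) {
  if (is.null(pad)) pad <- k %/% 2L
  par <- list(W = kaiming_init(k * k * c_in, c_out, k * k * c_in))
  if (bias) par$b <- numeric(c_out)
  if (bn) {
    par$bn_g <- rep(1, c_out); par$bn_b <- numeric(c_out)
    par$bn_rm <- numeric(c_out); par$bn_rv <- rep(1, c_out)
  }
  list(type = "conv", name = name, c_in = c_in, c_out = c_out, k = as.integer(k),
       stride = as.integer(stride), pad = as.integer(pad), bn = bn, act = act,
       bias = bias, from = from, module = module, block_id = block_id,
       par = new_par_env(par))
}

node_pconv <- function(name, c, c_p, k = 3L, slice = c("first", "last"),
                       from = NA_integer_, module = "C3-light",
                       block_id = NA_integer_) {
  slice <- match.arg(slice)
  if (c_p > c) stop("pconv configuration error in '", name, "': c_p > c")
  par <- list(W = kaiming_init(k * k * c_p, c_p, k * k * c_p))
  list(type = "pconv", name = name, c_in = c, c_out = c, c_p = as.integer(c_p),
       k = as.integer(k), slice = slice, from = from, module = module,
       block_id = block_id, par = new_par_env(list(W = par$W)))
}

node_simple <- function(type, name, c_in, c_out, from = NA_integer_,
                        module = type, block_id = NA_integer_, ...) {
  c(list(type = type, name = name, c_in = c_in, c_out = c_out, from = from,
         module = module, block_id = block_id, par = new_par_env(list())),
    list(...))
}

# Learnable array names per node (BN running stats are buffers, not counted).
node_learnables <- function(node) {
  switch(node$type,
    conv = c("W", if (node$bias) "b", if (node$bn) c("bn_g", "bn_b")),
    pconv = "W",
    character(0))
}

node_n_params <- function(node) {
  sum(vapply(node_learnables(node),
             function(nm) length(get(nm, envir = node$par)), numeric(1)))
}

# ---- forward ----------------------------------------------------------------

# column-broadcast helpers: much faster than sweep() in the hot path
colmul <- function(m, v) m * rep(v, each = nrow(m))
coladd <- function(m, v) m + rep(v, each = nrow(m))

conv_affine <- function(node, z, training, use_batch = training) {
  p <- node$par
  if (node$bias) z <- coladd(z, p$b)
  if (node$bn) {
    if (use_batch) {
      mu <- colMeans(z)
      zc <- coladd(z, -mu)
      v <- colMeans(zc * zc)
      istd <- 1 / sqrt(v + BN_EPS)
      xhat <- colmul(zc, istd)
      if (training) {
        assign("bn_rm", (1 - BN_MOMENTUM) * p$bn_rm + BN_MOMENTUM * mu,
               envir = p)
        assign("bn_rv", (1 - BN_MOMENTUM) * p$bn_rv + BN_MOMENTUM * v,
               envir = p)
      }
      return(list(y = coladd(colmul(xhat, p$bn_g), p$bn_b),
                  xhat = xhat, istd = istd))
    }
    istd <- 1 / sqrt(p$bn_rv + BN_EPS)
    # fold: y = z * (g*istd) + (b - rm*g*istd)
    sc <- p$bn_g * istd
    return(list(y = coladd(colmul(z, sc), p$bn_b - p$bn_rm * sc)))
  }
  list(y = z)
}

node_forward <- function(node, ins, training = FALSE,
                         use_batch = training) {
  x <- ins[[1]]
  h <- attr(x, "h"); w <- attr(x, "w")
  switch(node$type,
    conv = {
      if (ncol(x) != node$c_in)
        stop("configuration error in layer '", node$name, "': expected ",
             node$c_in, " input channels, got ", ncol(x))
      k1 <- node$k == 1L && node$stride == 1L && node$pad == 0L
      Xcol <- if (k1) x else im2col_cpp(x, h, w, node$k, node$stride, node$pad)
      ho <- (h + 2 * node$pad - node$k) %/% node$stride + 1L
      wo <- (w + 2 * node$pad - node$k) %/% node$stride + 1L
      z <- Xcol %*% node$par$W
      bn <- conv_affine(node, z, training, use_batch)
      y <- if (node$act == "silu") silu(bn$y) else bn$y
      cache <- if (training)
        list(Xcol = Xcol, h = h, w = w, xhat = bn$xhat, istd = bn$istd,
             z_act = if (node$act == "silu") bn$y)
      list(y = fmap(y, ho, wo), cache = cache)
    },
    pconv = {
      if (ncol(x) != node$c_in)
        stop("configuration error in layer '", node$name, "': expected ",
             node$c_in, " input channels, got ", ncol(x))
      cp <- node$c_p
      sel <- if (node$slice == "first") seq_len(cp)
             else (node$c_in - cp + 1L):node$c_in
      Xcol <- im2col_cpp(x[, sel, drop = FALSE], h, w, node$k, 1L, node$k %/% 2L)
      y <- x
      y[, sel] <- Xcol %*% node$par$W
      cache <- if (training) list(Xcol = Xcol, h = h, w = w, sel = sel)
      list(y = fmap(y, h, w), cache = cache)
    },
    maxpool = {
      r <- maxpool_same_cpp(x, h, w, node$k)
      list(y = fmap(r$y, h, w), cache = if (training) list(idx = r$idx, n = h * w))
    },
    upsample = {
      idx <- as.vector(outer(ceiling(seq_len(2 * h) / 2),
                             (ceiling(seq_len(2 * w) / 2) - 1L) * h, `+`))
      list(y = fmap(x[idx, , drop = FALSE], 2L * h, 2L * w),
           cache = if (training) list(idx = idx, n = h * w))
    },
    concat = {
      list(y = fmap(do.call(cbind, ins), h, w),
           cache = if (training) list(splits = vapply(ins, ncol, integer(1))))
    },
    add = list(y = fmap(ins[[1]] + ins[[2]], h, w), cache = NULL),
    simam = {
      n <- h * w
      if (n < 2) stop("simam: spatial map 1x1 has undefined variance in '",
                      node$name, "'")
      mu <- colMeans(x)
      t_ <- coladd(x, -mu)
      v <- colSums(t_ * t_) / (n - 1)
      A <- 1 / (4 * (v + node$lambda))
      E <- colmul(t_ * t_, A) + 0.5
      s <- sigmoid(E)
      list(y = fmap(x * s, h, w),
           cache = if (training) list(t_ = t_, A = A, s = s, x = x, n = n))
    },
    stop("unknown node type: ", node$type))
}

# ---- backward ---------------------------------------------------------------

accum_grad <- function(par, nm, g) {
  gn <- paste0("g_", nm)
  if (exists(gn, envir = par, inherits = FALSE))
    assign(gn, get(gn, envir = par) + g, envir = par)
  else assign(gn, g, envir = par)
}

node_backward <- function(node, dout, cache) {
  switch(node$type,
    conv = {
      dz <- if (node$act == "silu") dout * silu_grad(cache$z_act) else dout
      p <- node$par
      if (node$bn) {
        dxhat <- colmul(dz, p$bn_g)
        accum_grad(p, "bn_g", colSums(dz * cache$xhat))
        accum_grad(p, "bn_b", colSums(dz))
        n <- nrow(dz)
        s1 <- colSums(dxhat)
        s2 <- colSums(dxhat * cache$xhat)
        dz <- colmul(coladd(n * dxhat, -s1) - colmul(cache$xhat, s2),
                     cache$istd / n)
      }
      if (node$bias) accum_grad(p, "b", colSums(dz))
      accum_grad(p, "W", crossprod(cache$Xcol, dz))
      dcol <- dz %*% t(p$W)
      dx <- if (node$k == 1L && node$stride == 1L && node$pad == 0L) dcol
            else col2im_cpp(dcol, cache$h, cache$w, node$c_in, node$k,
                            node$stride, node$pad)
      list(dx)
    },
    pconv = {
      sel <- cache$sel
      dya <- dout[, sel, drop = FALSE]
      accum_grad(node$par, "W", crossprod(cache$Xcol, dya))
      dxa <- col2im_cpp(dya %*% t(node$par$W), cache$h, cache$w, node$c_p,
                        node$k, 1L, node$k %/% 2L)
      dx <- dout
      dx[, sel] <- dxa
      list(dx)
    },
    maxpool = list(maxpool_bwd_cpp(dout, cache$idx, cache$n)),
    upsample = {
      dx <- rowsum(dout, cache$idx)
      dimnames(dx) <- NULL
      list(dx)
    },
    concat = {
      ends <- cumsum(cache$splits)
      starts <- c(1L, head(ends, -1L) + 1L)
      lapply(seq_along(ends),
             function(i) dout[, starts[i]:ends[i], drop = FALSE])
    },
    add = list(dout, dout),
    simam = {
      with(cache, {
        P <- dout * x * s * (1 - s)
        dLdv <- colSums(P * t_ * t_) * (-4 * A * A)
        D <- colmul(P * t_, 2 * A) + colmul(t_, 2 * dLdv / (n - 1))
        list(dout * s + coladd(D, -colMeans(D)))
      })
    },
    stop("unknown node type: ", node$type))
}

zero_grads <- function(nodes) {
  for (nd in nodes) {
    gs <- grep("^g_", ls(nd$par), value = TRUE)
    if (length(gs)) rm(list = gs, envir = nd$par)
  }
  invisible(NULL)
}

# ---- graph execution --------------------------------------------------------

# `from` semantics: 0 refers to the graph input, i > 0 to node i's output;
# NA means "previous node" and is resolved at build time by graph_seal().
graph_seal <- function(nodes, out = length(nodes)) {
  for (i in seq_along(nodes)) {
    if (anyNA(nodes[[i]]$from)) nodes[[i]]$from <- i - 1L
  }
  structure(list(nodes = nodes, out = as.integer(out)), class = "ayolo_graph")
}

graph_forward <- function(graph, x, training = FALSE, keep_all = FALSE,
                          use_batch = training) {
  nodes <- graph$nodes
  vals <- vector("list", length(nodes))
  caches <- if (training) vector("list", length(nodes))
  fetch <- function(j) if (j == 0L) x else vals[[j]]
  for (i in seq_along(nodes)) {
    ins <- lapply(nodes[[i]]$from, fetch)
    r <- node_forward(nodes[[i]], ins, training, use_batch)
    vals[[i]] <- r$y
    if (training) caches[[i]] <- r$cache
  }
  list(out = vals[graph$out], vals = if (keep_all || training) vals,
       caches = caches)
}

# douts: list parallel to graph$out. Returns gradient w.r.t. the graph input;
# parameter gradients are accumulated in the node environments.
graph_backward <- function(graph, fwd, douts) {
  nodes <- graph$nodes
  d <- vector("list", length(nodes))
  dinput <- NULL
  for (k in seq_along(graph$out)) {
    i <- graph$out[k]
    d[[i]] <- if (is.null(d[[i]])) douts[[k]] else d[[i]] + douts[[k]]
  }
  for (i in rev(seq_along(nodes))) {
    if (is.null(d[[i]])) next
    dxs <- node_backward(nodes[[i]], d[[i]], fwd$caches[[i]])
    for (k in seq_along(nodes[[i]]$from)) {
      j <- nodes[[i]]$from[k]
      if (j == 0L) {
        dinput <- if (is.null(dinput)) dxs[[k]] else dinput + dxs[[k]]
      } else {
        d[[j]] <- if (is.null(d[[j]])) dxs[[k]] else d[[j]] + dxs[[k]]
      }
    }
    d[[i]] <- NULL
  }
  dinput
}

graph_validate <- function(graph) {
  nodes <- graph$nodes
  for (i in seq_along(nodes)) {
    nd <- nodes[[i]]
    if (any(nd$from >= i))
      stop("graph is not a DAG at node ", i, " ('", nd$name, "')")
    pc <- vapply(nd$from, function(j)
      if (j == 0L) NA_integer_ else nodes[[j]]$c_out, integer(1))
    cin <- if (nd$type == "concat") sum(pc)
           else if (all(is.na(pc))) NA_integer_ else unique(pc[!is.na(pc)])
    if (length(cin) != 1 || (!is.na(cin) && cin != nd$c_in))
      stop("channel mismatch at node '", nd$name, "': producers give ",
           paste(pc, collapse = "/"), ", node expects ", nd$c_in)
  }
  invisible(TRUE)
}
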