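# Building blocks: conv-BN-act, partial convolution, C3 / C3-light, SPPF,
# SimAM, and their exact parameter cost model.

test_that("conv_bn_act parameter count, identity case and stride arithmetic", {
  # k=3, c_in=2, c_out=4 under BN: 72 conv weights + 8 BN affine = 80
  blk <- new_conv_layer(conv_spec(3, 2, 4))
  expect_equal(block_params(blk), 80)

  # identity 1x1 conv with BN at identity -> output equals activation(x)
  spec <- conv_spec(1, 3, 3)
  blk <- new_conv_layer(spec)
  blk$nodes[[1]]$par$W <- diag(3)
  x <- fmap_from_array(rand_fmap(6, 5, 3))
  y <- block_forward(blk, x, training = FALSE)  # running stats at identity
  # BN eps (1e-5) scales by 1/sqrt(1 + eps), hence the loose tolerance
  expect_equal(as.numeric(y), as.numeric(x * appleyolo:::sigmoid(x)),
               tolerance = 1e-4)

  # stride 2 halves spatial dims
  blk2 <- new_conv_layer(conv_spec(3, 3, 8, stride = 2))
  y2 <- block_forward(blk2, fmap_from_array(rand_fmap(64, 64, 3)))
  expect_equal(c(attr(y2, "h"), attr(y2, "w")), c(32L, 32L))

  # channel mismatch is a configuration error naming the layer
  expect_error(block_forward(blk2, fmap_from_array(rand_fmap(8, 8, 5))),
               "configuration error")
})

test_that("conv forward matches a naive nested-loop oracle", {
  for (cse in list(c(k = 3, cin = 2, cout = 4, s = 1),
                   c(k = 1, cin = 5, cout = 3, s = 1),
                   c(k = 3, cin = 3, cout = 2, s = 2),
                   c(k = 5, cin = 2, cout = 2, s = 1))) {
    blk <- new_conv_layer(conv_spec(cse["k"], cse["cin"], cse["cout"],
                                    stride = cse["s"], has_bn = FALSE,
                                    activation = "none"),
                          seed = cse["k"] * 10)
    a <- rand_fmap(8, 9, cse["cin"], seed = cse["cin"])
    y <- block_forward(blk, fmap_from_array(a))
    Wk <- unpack_weight(blk$nodes[[1]]$par$W, cse["k"], cse["cin"],
                        cse["cout"])
    expect_equal(as.numeric(y),
                 as.numeric(fmap_from_array(
                   naive_conv(a, Wk, stride = cse["s"]))),
                 tolerance = 1e-12)
  }
})

test_that("pconv: passthrough, degenerate full ratio, zero kernel, errors", {
  x <- fmap_from_array(rand_fmap(8, 8, 16))

  # untouched channels are bitwise identical
  blk <- new_pconv_layer(pconv_spec(16))  # c_p = 4
  y <- pconv(x, NULL, block = blk)
  expect_identical(y[, 5:16], x[, 5:16])
  expect_false(isTRUE(all.equal(y[, 1:4], x[, 1:4])))

  # 'last' slice position convolves the trailing block
  blk_l <- new_pconv_layer(pconv_spec(16, slice_position = "last"))
  yl <- pconv(x, NULL, block = blk_l)
  expect_identical(yl[, 1:12], x[, 1:12])

  # c_p = c equals a regular conv with the same kernel (oracle)
  blk_full <- new_pconv_layer(pconv_spec(6, c_p = 6), seed = 3)
  a <- rand_fmap(7, 7, 6, seed = 5)
  yf <- pconv(fmap_from_array(a), NULL, block = blk_full)
  Wk <- unpack_weight(blk_full$nodes[[1]]$par$W, 3, 6, 6)
  expect_equal(as.numeric(yf), as.numeric(fmap_from_array(naive_conv(a, Wk))),
               tolerance = 1e-12)

  # zeroed kernel: selected block all zeros, rest untouched
  blk$nodes[[1]]$par$W[] <- 0
  y0 <- pconv(x, NULL, block = blk)
  expect_true(all(y0[, 1:4] == 0))
  expect_identical(y0[, 5:16], x[, 5:16])

  expect_error(pconv_spec(8, c_p = 9), "c_p")
})

test_that("pconv MAC count follows the (c_p/c)^2 law", {
  # h=w=8, k=3, c=16, c_p=4: 9216 MACs vs 147456, ratio 1/16
  nd <- appleyolo:::node_pconv("p", 16L, 4L, 3L)
  p <- appleyolo:::node_profile(nd, 8L, 8L)
  expect_equal(p$macs, 8 * 8 * 9 * 16)
  ndc <- appleyolo:::node_conv("c", 16L, 16L, 3L)
  pc <- appleyolo:::node_profile(ndc, 8L, 8L)
  expect_equal(pc$macs, 8 * 8 * 9 * 256)
  expect_equal(p$macs / pc$macs, 1 / 16)

  # property: ratio == (c_p/c)^2 exactly for 20 random tuples
  set.seed(11)
  for (i in 1:20) {
    c_ <- sample(4:32, 1)
    cp <- sample(seq_len(c_), 1)
    k <- sample(c(1, 3, 5), 1)
    h <- sample(4:12, 1); w <- sample(4:12, 1)
    mp <- appleyolo:::node_profile(
      appleyolo:::node_pconv("p", c_, cp, k), h, w)$macs
    mc <- appleyolo:::node_profile(
      appleyolo:::node_conv("c", c_, c_, k, bn = FALSE), h, w)$macs
    expect_equal(mp / mc, (cp / c_)^2)
  }
})

test_that("C3: residual zero-perturbation, hand-enumerated parameter count", {
  # zero-init bottleneck convs + BN at identity: bottleneck path outputs its
  # input, so the residual dominates
  blk <- new_c3_block(32, 32, n = 1, shortcut = TRUE)
  for (nd in blk$nodes) {
    if (nd$type == "conv" && grepl("m0", nd$name)) nd$par$W[] <- 0
  }
  x <- fmap_from_array(rand_fmap(6, 6, 32))
  fw <- appleyolo:::graph_forward(blk, x)
  # the add node output equals the cv1 output (bottleneck contributes
  # sigmoid-of-0-scaled zeros = 0 after silu(0)=0)
  add_i <- which(vapply(blk$nodes, function(n) n$type == "add", logical(1)))
  cv1_i <- which(vapply(blk$nodes, function(n) n$name == "c3.cv1",
                        logical(1)))
  fw2 <- appleyolo:::graph_forward(blk, x, keep_all = TRUE)
  expect_equal(as.numeric(fw2$vals[[add_i]]), as.numeric(fw2$vals[[cv1_i]]),
               tolerance = 1e-12)

  # parameter count equals independent hand enumeration:
  # C3(32->32, n=1): cv1/cv2 1x1 32->16 (544 each), cv3 1x1 32->32 (1088),
  # bottleneck 1x1 16->16 (288) + 3x3 16->16 (2336)
  expect_equal(block_params(new_c3_block(32, 32, 1, TRUE)),
               544 + 544 + 1088 + 288 + 2336)
  expect_equal(block_params(new_c3_block(32, 32, 1, TRUE)),
               oracle_param_count(new_c3_block(32, 32, 1, TRUE)))
})

test_that("C3-light: same interface, strictly fewer parameters", {
  x <- fmap_from_array(rand_fmap(8, 8, 64))
  y1 <- c3_block(x, 64, n = 2, shortcut = TRUE)
  y2 <- c3_light_block(x, 64, n = 2, shortcut = TRUE)
  expect_equal(dim(y1), dim(y2))
  expect_equal(attr(y1, "h"), attr(y2, "h"))

  for (cfg in list(c(32, 32, 1), c(64, 64, 2), c(256, 128, 1))) {
    expect_lt(block_params(new_c3_light_block(cfg[1], cfg[2], cfg[3])),
              block_params(new_c3_block(cfg[1], cfg[2], cfg[3])))
  }
})

test_that("SPPF equals parallel SPP(5, 9, 13) element-wise", {
  # constant feature map stays constant through the pooling stage
  blk <- new_sppf_block(4, 4)
  xconst <- fmap_from_array(array(2.5, c(8, 8, 4)))
  fw <- appleyolo:::graph_forward(blk, xconst, keep_all = TRUE)
  cat_i <- which(vapply(blk$nodes, function(n) n$type == "concat",
                        logical(1)))
  cv1_i <- 1L
  v1 <- fw$vals[[cv1_i]]
  expect_true(all(abs(fw$vals[[cat_i]] -
                      cbind(v1, v1, v1, v1)) < 1e-12))

  # chained 5x5 pools == parallel pools of 5, 9, 13 (oracle), incl. random
  # 4x8x8 example; tolerance 0 for max chains
  set.seed(21)
  for (i in 1:50) {
    h <- sample(6:12, 1); w <- sample(6:12, 1); cc <- sample(c(2, 4), 1)
    a <- array(rnorm(h * w * cc), c(h, w, cc))
    blk <- new_sppf_block(cc, cc, seed = i)
    fw <- appleyolo:::graph_forward(blk, fmap_from_array(a), keep_all = TRUE)
    cat_i <- which(vapply(blk$nodes, function(n) n$type == "concat",
                          logical(1)))
    cv1 <- fmap_to_array(fw$vals[[1L]])
    expect_identical(as.numeric(fw$vals[[cat_i]]),
                     as.numeric(fmap_from_array(naive_spp(cv1))))
  }

  expect_error(new_sppf_block(8, 8, k = 4), "odd")
})

test_that("SimAM: energy formula, zero parameters, shape preservation", {
  # constant channel: E = 0.5 everywhere, output = sigmoid(0.5) * x
  x <- fmap_from_array(array(3, c(5, 5, 2)))
  y <- simam(x)
  expect_equal(as.numeric(y), rep(3 * 1 / (1 + exp(-0.5)), 50),
               tolerance = 1e-12)
  expect_equal(unname(as.numeric(y[1, 1])), 3 * 0.6224593, tolerance = 1e-6)

  # hand-evaluated energy on a non-constant channel
  v <- c(1, 2, 3, 4, 5, 6)
  xa <- fmap_from_array(array(v, c(2, 3, 1)))
  lam <- 1e-4
  mu <- mean(v); vv <- sum((v - mu)^2) / (length(v) - 1)
  E <- (v - mu)^2 / (4 * (vv + lam)) + 0.5
  expect_equal(as.numeric(simam(xa)), v / (1 + exp(-E)), tolerance = 1e-12)

  # zero learnable parameters, shape preserved for all tested shapes
  for (d in list(c(4, 4, 3), c(40, 40, 256), c(2, 7, 1))) {
    xx <- fmap_from_array(array(rnorm(prod(d)), d))
    yy <- simam(xx)
    expect_equal(dim(yy), dim(xx))
    expect_equal(c(attr(yy, "h"), attr(yy, "w")), d[1:2])
  }
  gb <- appleyolo:::graph_builder()
  gb$add(appleyolo:::node_simple("simam", "s", 4L, 4L, from = 0L,
                                 lambda = 1e-4))
  expect_equal(block_params(appleyolo:::graph_seal(gb$nodes)), 0)

  # degenerate 1x1 spatial map raises
  expect_error(simam(fmap_from_array(array(1, c(1, 1, 3)))), "variance")
})

test_that("reference per-module parameter sums for C3 and C3-light", {
  mb <- build_model(model_config("baseline", nc = 80))
  mcs <- build_model(model_config("cs", nc = 80))
  sum_mod <- function(m, mod)
    sum(vapply(m$graph$nodes,
               function(nd) if (nd$module == mod)
                 appleyolo:::node_n_params(nd) else 0, numeric(1)))
  expect_equal(sum_mod(mb, "C3"), 972096)
  expect_equal(sum_mod(mcs, "C3-light"), 664464)
})

test_that("block parameter counts equal the independent walker everywhere", {
  blocks <- list(new_conv_layer(conv_spec(3, 4, 8)),
                 new_pconv_layer(pconv_spec(12)),
                 new_c3_block(16, 16, 2, TRUE),
                 new_c3_light_block(16, 16, 2, FALSE),
                 new_sppf_block(16, 16))
  for (b in blocks)
    expect_equal(block_params(b), oracle_param_count(b))
})
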