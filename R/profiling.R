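# Parameter and FLOP accounting.
#
# FLOP convention (fixed; the one under which the stock nano baseline prints
# 4.5 GFLOPs at 640 x 640 to one decimal):
#   * convolution / partial convolution / linear: 2 x multiply-accumulates,
#     plus 1 op per output element when a bias is present;
#   * batch norm (inference-time affine): 2 ops per element;
#   * SiLU: 4 ops per element (exp, add, divide, multiply);
#   * k x k max pool: k^2 - 1 comparisons per output element;
#   * residual add: 1 op per element;
#   * SimAM: 10 ops per element (energy terms, sigmoid, modulation,
#     reduction adds);
#   * nearest upsample and concatenation: 0 (memory copies).
# Parameters are independent of input size; MACs of conv nodes scale with
# the spatial extent.

SIMAM_OPS_PER_ELEM <- 10

node_profile <- function(nd, h, w) {
  params <- node_n_params(nd)
  macs <- 0; extra <- 0
  ho <- h; wo <- w
  if (nd$type == "conv") {
    ho <- (h + 2 * nd$pad - nd$k) %/% nd$stride + 1L
    wo <- (w + 2 * nd$pad - nd$k) %/% nd$stride + 1L
    e <- as.double(ho) * wo * nd$c_out
    macs <- e * nd$k^2 * nd$c_in
    extra <- (if (nd$bias) e else 0) + (if (nd$bn) 2 * e else 0) +
             (if (nd$act == "silu") 4 * e else 0)
  } else if (nd$type == "pconv") {
    macs <- as.double(h) * w * nd$k^2 * nd$c_p^2
  } else if (nd$type == "maxpool") {
    extra <- as.double(h) * w * nd$c_out * (nd$k^2 - 1)
  } else if (nd$type == "upsample") {
    ho <- 2L * h; wo <- 2L * w
  } else if (nd$type == "add") {
    extra <- as.double(h) * w * nd$c_out
  } else if (nd$type == "simam") {
    extra <- as.double(h) * w * nd$c_out * SIMAM_OPS_PER_ELEM
  }
  list(params = params, macs = macs, flops = 2 * macs + extra,
       ho = ho, wo = wo)
}

#' Profile a model: per-node parameters, MACs and FLOPs
#'
#' Walks the layer graph at a stated input size, propagating spatial shapes,
#' and reports per-node and total learnable parameters, multiply-accumulates
#' and FLOPs under the package's documented counting convention (see the
#' methods vignette).
#'
#' @param model an `ayolo_model` from [build_model()]
#' @param input_size square input size in pixels (default: the model
#'   config's; must be divisible by 32)
#' @return a `profile_report`: list with `nodes` (data.frame: name, module,
#'   block_id, params, macs, flops), `total_params`, `total_macs`,
#'   `total_flops`, `gflops` (= total_flops / 1e9) and `input_size`
#' @examples
#' pr <- profile_model(build_model(model_config("baseline", nc = 80)))
#' round(pr$gflops, 1)  # 4.5
#' @export
profile_model <- function(model, input_size = model$config$input_size) {
  if (input_size %% 32 != 0) stop("input_size must be divisible by 32")
  nodes <- model$graph$nodes
  H <- integer(length(nodes)); W <- integer(length(nodes))
  rows <- vector("list", length(nodes))
  for (i in seq_along(nodes)) {
    nd <- nodes[[i]]
    j <- nd$from[1]
    h <- if (j == 0L) input_size else H[j]
    w <- if (j == 0L) input_size else W[j]
    p <- node_profile(nd, h, w)
    H[i] <- p$ho; W[i] <- p$wo
    rows[[i]] <- data.frame(name = nd$name, module = nd$module,
                            block_id = nd$block_id, params = p$params,
                            macs = p$macs, flops = p$flops)
  }
  nodes_df <- do.call(rbind, rows)
  structure(list(nodes = nodes_df,
                 total_params = sum(nodes_df$params),
                 total_macs = sum(nodes_df$macs),
                 total_flops = sum(nodes_df$flops),
                 gflops = sum(nodes_df$flops) / 1e9,
                 input_size = input_size),
            class = "profile_report")
}

#' @export
print.profile_report <- function(x, ...) {
  cat(sprintf("<profile_report> params=%s  GFLOPs=%.3f @ %d\n",
              format(x$total_params, big.mark = ","), x$gflops, x$input_size))
  invisible(x)
}

#' Count learnable parameters
#'
#' Counts learnable arrays only: conv weights and biases, BN affine pairs;
#' BN running statistics are buffers and excluded. Parameter counts are
#' independent of the input size.
#' @param model an `ayolo_model` (an empty graph counts 0)
#' @return a `profile_report` (its `total_params` is the headline number)
#' @export
count_parameters <- function(model) profile_model(model)

#' Count FLOPs at a stated input size
#' @inheritParams profile_model
#' @return a `profile_report` (its `total_flops` / `gflops` are the headline
#'   numbers)
#' @export
count_flops <- function(model, input_size = model$config$input_size) {
  profile_model(model, input_size)
}

#' Per-module aggregation of a profile report
#'
#' Sums parameters and FLOPs over all instances of each module type
#' (`Conv`, `C3` or `C3-light`, `SPPF`, `SimAM`, `Detect`, ...), the
#' aggregation used by per-module accounting tables.
#' @param report a `profile_report`
#' @return data.frame with columns `module`, `params`, `gflops`
#' @export
profile_by_module <- function(report) {
  agg <- aggregate(cbind(params, flops) ~ module, data = report$nodes, sum)
  data.frame(module = agg$module, params = agg$params,
             gflops = agg$flops / 1e9)
}

#' Relative reduction / improvement between two measurements
#'
#' `reduction_pct = 100 * (a - b) / a` and `improvement_pct = 100 * (b - a) / a`,
#' rounded to two decimals for reporting; the denominator is always the first
#' (reference) value, so the function is not symmetric under exchange.
#' Accepts bare numbers (e.g. printed table values) or `profile_report`s
#' (compared on `total_params` unless `what = "gflops"`, in which case GFLOPs
#' are rounded to one decimal first, the precision at which headline
#' percentages are quoted).
#'
#' @param a reference value or report
#' @param b comparison value or report
#' @param what `"params"` or `"gflops"` when profiles are passed
#' @return list with `reduction_pct` and `improvement_pct`
#' @examples
#' summarize_reduction(4.5, 3.8)$reduction_pct    # 15.56
#' summarize_reduction(85.55, 97.81)$improvement_pct  # 14.33
#' @export
summarize_reduction <- function(a, b, what = c("params", "gflops")) {
  what <- match.arg(what)
  pick <- function(x) {
    if (inherits(x, "profile_report")) {
      if (what == "gflops") round(x$gflops, 1) else x$total_params
    } else as.numeric(x)
  }
  av <- pick(a); bv <- pick(b)
  if (av == 0) stop("reference value is zero; reduction undefined")
  list(reduction_pct = round(100 * (av - bv) / av, 2),
       improvement_pct = round(100 * (bv - av) / av, 2))
}
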