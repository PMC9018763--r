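# Lightweight volumetric encoder-decoder network engine.
#
# A small V-Net-style backbone: `levels` resolution scales with channel
# doubling, two 3x3x3 convolutions per stage, 2x average-pool downsampling,
# nearest-neighbor upsampling with skip concatenation, per-head 1x1x1 output
# convolutions, and an optional patch-level classifier (global average pool
# over the bottleneck followed by three fully-connected layers). Forward,
# backward and Adam updates are implemented here directly; the convolution
# kernels live in compiled code.

#' Network configuration
#'
#' @param in_channels number of input channels.
#' @param levels number of resolution scales (>= 2); the patch must be
#'   divisible by `2^(levels-1)` per axis.
#' @param base_channels channels at the finest scale; doubled per scale.
#' @param patch integer length-3 patch size (z, y, x).
#' @param heads list of head specs from [head_spec()]; names must be unique.
#' @param classifier optional `list(n_classes =, hidden =)` enabling the
#'   patch classifier (three fully-connected layers over the pooled
#'   bottleneck).
#' @param convs_per_stage convolutions per scale (default 2).
#' @return a `net_config` list.
#' @export
net_config <- function(in_channels, levels = 2L, base_channels = 4L,
                       patch = c(32L, 32L, 32L), heads,
                       classifier = NULL, convs_per_stage = 2L) {
  patch <- as.integer(patch)
  levels <- as.integer(levels)
  if (levels < 2L) stopf("net_config(): levels must be >= 2")
  div <- 2L^(levels - 1L)
  if (any(patch %% div != 0L))
    stopf("net_config(): patch must be divisible by %d per axis", div)
  nm <- vapply(heads, `[[`, "", "name")
  if (anyDuplicated(nm)) stopf("net_config(): head names must be unique")
  names(heads) <- nm
  if (!is.null(classifier)) classifier$hidden <- classifier$hidden %||% 32L
  structure(list(in_channels = as.integer(in_channels), levels = levels,
                 base_channels = as.integer(base_channels), patch = patch,
                 heads = heads, classifier = classifier,
                 convs_per_stage = as.integer(convs_per_stage)),
            class = "net_config")
}

#' @rdname net_config
#' @param name head name (e.g. "mask", "offset", "prob").
#' @param channels output channels.
#' @param activation `"sigmoid"`, `"softmax"` or `"linear"`.
#' @param loss `"bce"`, `"l2"` or `"ce"`; defaults to bce for sigmoid, l2 for
#'   linear, ce for softmax.
#' @param masked if `TRUE`, the L2 loss is averaged over foreground-mask
#'   voxels only (used for offset heads).
#' @param class_weights optional per-class weights for the softmax
#'   cross-entropy (counters class imbalance).
#' @export
head_spec <- function(name, channels, activation = c("sigmoid", "softmax", "linear"),
                      loss = NULL, masked = FALSE, class_weights = NULL) {
  activation <- match.arg(activation)
  loss <- loss %||% switch(activation, sigmoid = "bce", linear = "l2", softmax = "ce")
  list(name = name, channels = as.integer(channels), activation = activation,
       loss = loss, masked = isTRUE(masked), class_weights = class_weights)
}

net_channels <- function(cfg) cfg$base_channels * 2L^(seq_len(cfg$levels) - 1L)

he_init <- function(cout, cin, k) {
  sd <- sqrt(2 / (cin * k^3))
  list(w = array(stats::rnorm(cout * cin * k^3, sd = sd), c(cout, cin, k, k, k)),
       b = numeric(cout))
}

#' Build a segmentation network predictor
#'
#' Constructs the encoder-decoder with seeded parameter initialization and
#' wraps it as a predictor usable with [predict_patch()] /
#' [predict_patchwise()].
#'
#' @param cfg a [net_config()].
#' @param seed integer seed for parameter initialization.
#' @return a `net_predictor`.
#' @export
build_segnet <- function(cfg, seed = 0L) {
  stopifnot(inherits(cfg, "net_config"))
  ch <- net_channels(cfg)
  params <- with_seed(seed, {
    p <- list(enc = list(), dec = list(), heads = list(), cls = NULL)
    cin <- cfg$in_channels
    for (l in seq_len(cfg$levels)) {
      convs <- list()
      for (j in seq_len(cfg$convs_per_stage)) {
        convs[[j]] <- he_init(ch[l], cin, 3L)
        cin <- ch[l]
      }
      p$enc[[l]] <- convs
      if (l < cfg$levels) cin <- ch[l]
    }
    for (l in rev(seq_len(cfg$levels - 1L))) {
      convs <- list()
      cin <- ch[l + 1L] + ch[l]          # upsampled deeper + skip
      for (j in seq_len(cfg$convs_per_stage)) {
        convs[[j]] <- he_init(ch[l], cin, 3L)
        cin <- ch[l]
      }
      p$dec[[l]] <- convs
    }
    for (h in cfg$heads) p$heads[[h$name]] <- he_init(h$channels, ch[1], 1L)
    if (!is.null(cfg$classifier)) {
      hdim <- cfg$classifier$hidden
      K <- cfg$classifier$n_classes
      cb <- ch[cfg$levels]
      gl <- function(o, i) list(w = matrix(stats::rnorm(o * i, sd = sqrt(2 / i)), o, i),
                                b = numeric(o))
      p$cls <- list(gl(hdim, cb), gl(hdim, hdim), gl(K, hdim))
    }
    p
  })
  structure(list(cfg = cfg, params = params), class = c("net_predictor", "dent_predictor"))
}

# --- primitive ops -------------------------------------------------------

conv_fw <- function(x, layer, k) {
  d <- dim(x)
  conv3d_fw(x, layer$w, layer$b, d[1], dim(layer$w)[1], d[2], d[3], d[4], k)
}

avgpool2 <- function(x) {
  d <- dim(x)
  out <- array(0, c(d[1], d[2] / 2L, d[3] / 2L, d[4] / 2L))
  for (oz in 0:1) for (oy in 0:1) for (ox in 0:1)
    out <- out + x[, seq(1L + oz, d[2], 2L), seq(1L + oy, d[3], 2L),
                   seq(1L + ox, d[4], 2L), drop = FALSE]
  out / 8
}

avgpool2_bw <- function(g, din) {
  out <- array(0, din)
  for (oz in 0:1) for (oy in 0:1) for (ox in 0:1)
    out[, seq(1L + oz, din[2], 2L), seq(1L + oy, din[3], 2L),
        seq(1L + ox, din[4], 2L)] <- g / 8
  out
}

upsample2 <- function(x) {
  d <- dim(x)
  out <- array(0, c(d[1], 2L * d[2], 2L * d[3], 2L * d[4]))
  for (oz in 0:1) for (oy in 0:1) for (ox in 0:1)
    out[, seq(1L + oz, 2L * d[2], 2L), seq(1L + oy, 2L * d[3], 2L),
        seq(1L + ox, 2L * d[4], 2L)] <- x
  out
}

upsample2_bw <- function(g) {
  d <- dim(g)
  out <- array(0, c(d[1], d[2] / 2L, d[3] / 2L, d[4] / 2L))
  for (oz in 0:1) for (oy in 0:1) for (ox in 0:1)
    out <- out + g[, seq(1L + oz, d[2], 2L), seq(1L + oy, d[3], 2L),
                   seq(1L + ox, d[4], 2L), drop = FALSE]
  out
}

# Leaky rectifier (slope 0.1 for negative inputs): keeps gradient alive in
# tiny narrow networks where plain ReLU units can die irrecoverably.
LEAKY_SLOPE <- 0.1
leaky_relu <- function(x) pmax(x, 0) + LEAKY_SLOPE * pmin(x, 0)
leaky_grad <- function(out) (out > 0) + LEAKY_SLOPE * (out <= 0)

sigmoidf <- function(x) 1 / (1 + exp(-x))

softmax_ch <- function(x) {
  # softmax over the channel (first) dimension of a (C,D,H,W) array
  d <- dim(x)
  m <- apply(x, 2:4, max)
  e <- exp(x - rep(m, each = d[1]))
  s <- apply(e, 2:4, sum)
  e / rep(s, each = d[1])
}

apply_activation <- function(pre, activation) {
  switch(activation, sigmoid = sigmoidf(pre), softmax = softmax_ch(pre), linear = pre)
}

# --- forward / backward --------------------------------------------------

net_forward <- function(net, x, need_cache = FALSE) {
  cfg <- net$cfg
  p <- net$params
  cache <- list(conv_in = list(), relu_out = list())
  enc_out <- vector("list", cfg$levels)
  cur <- x
  ci <- list(); ro <- list()
  key <- function(l, j, part) paste(part, l, j, sep = ".")
  for (l in seq_len(cfg$levels)) {
    for (j in seq_len(cfg$convs_per_stage)) {
      if (need_cache) ci[[key(l, j, "enc")]] <- cur
      cur <- conv_fw(cur, p$enc[[l]][[j]], 3L)
      cur <- leaky_relu(cur)
      if (need_cache) ro[[key(l, j, "enc")]] <- cur
    }
    enc_out[[l]] <- cur
    if (l < cfg$levels) cur <- avgpool2(cur)
  }
  bottleneck <- enc_out[[cfg$levels]]
  cur <- bottleneck
  for (l in rev(seq_len(cfg$levels - 1L))) {
    up <- upsample2(cur)
    cur <- abind_ch(up, enc_out[[l]])
    for (j in seq_len(cfg$convs_per_stage)) {
      if (need_cache) ci[[key(l, j, "dec")]] <- cur
      cur <- conv_fw(cur, p$dec[[l]][[j]], 3L)
      cur <- leaky_relu(cur)
      if (need_cache) ro[[key(l, j, "dec")]] <- cur
    }
  }
  heads <- list()
  for (h in cfg$heads) {
    pre <- conv_fw(cur, p$heads[[h$name]], 1L)
    heads[[h$name]] <- list(pre = pre, act = apply_activation(pre, h$activation))
  }
  logits <- NULL; gap <- NULL
  if (!is.null(p$cls)) {
    gap <- rowMeans(matrix(bottleneck, nrow = dim(bottleneck)[1]))
    a1 <- leaky_relu(as.vector(p$cls[[1]]$w %*% gap + p$cls[[1]]$b))
    a2 <- leaky_relu(as.vector(p$cls[[2]]$w %*% a1 + p$cls[[2]]$b))
    logits <- as.vector(p$cls[[3]]$w %*% a2 + p$cls[[3]]$b)
    if (need_cache) cache$cls <- list(gap = gap, a1 = a1, a2 = a2)
  }
  if (need_cache) {
    cache$conv_in <- ci; cache$relu_out <- ro
    cache$final <- cur; cache$bottleneck_dim <- dim(bottleneck)
  }
  list(heads = heads, logits = logits, cache = if (need_cache) cache else NULL)
}

abind_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1] + db[1], da[2], da[3], da[4]))
  out[seq_len(da[1]), , , ] <- a
  out[da[1] + seq_len(db[1]), , , ] <- b
  out
}

# Backward pass. grad_heads: named list of gradients w.r.t. head
# *pre-activations*; grad_logits: gradient w.r.t. classifier logits.
# Returns gradients in the same nested structure as params.
net_backward <- function(net, fwd, grad_heads, grad_logits = NULL) {
  cfg <- net$cfg
  p <- net$params
  cache <- fwd$cache
  key <- function(l, j, part) paste(part, l, j, sep = ".")
  g <- list(enc = vector("list", cfg$levels),
            dec = vector("list", max(0L, cfg$levels - 1L)),
            heads = list(), cls = NULL)
  final <- cache$final
  df <- dim(final)
  gcur <- array(0, df)
  for (h in cfg$heads) {
    gh <- grad_heads[[h$name]]
    if (is.null(gh)) next
    bw <- conv3d_bw(final, p$heads[[h$name]]$w, gh,
                    df[1], dim(p$heads[[h$name]]$w)[1], df[2], df[3], df[4], 1L)
    g$heads[[h$name]] <- list(w = bw$gw, b = bw$gb)
    gcur <- gcur + bw$gx
  }
  gbottle_extra <- NULL
  if (!is.null(grad_logits) && !is.null(p$cls)) {
    cl <- cache$cls
    g3 <- list(w = outer(grad_logits, cl$a2), b = grad_logits)
    ga2 <- as.vector(t(p$cls[[3]]$w) %*% grad_logits) * leaky_grad(cl$a2)
    g2 <- list(w = outer(ga2, cl$a1), b = ga2)
    ga1 <- as.vector(t(p$cls[[2]]$w) %*% ga2) * leaky_grad(cl$a1)
    g1 <- list(w = outer(ga1, cl$gap), b = ga1)
    g$cls <- list(g1, g2, g3)
    ggap <- as.vector(t(p$cls[[1]]$w) %*% ga1)
    bd <- cache$bottleneck_dim
    nvox <- prod(bd[2:4])
    gbottle_extra <- array(rep(ggap / nvox, times = nvox), bd)
  }
  # decoder stages, fine-to-coarse input order is rev of forward
  gskip <- vector("list", cfg$levels)
  for (l in seq_len(cfg$levels - 1L)) {
    for (j in rev(seq_len(cfg$convs_per_stage))) {
      gcur <- gcur * leaky_grad(cache$relu_out[[key(l, j, "dec")]])
      xin <- cache$conv_in[[key(l, j, "dec")]]
      dxi <- dim(xin)
      bw <- conv3d_bw(xin, p$dec[[l]][[j]]$w, gcur,
                      dxi[1], dim(p$dec[[l]][[j]]$w)[1], dxi[2], dxi[3], dxi[4], 3L)
      if (is.null(g$dec[[l]])) g$dec[[l]] <- vector("list", cfg$convs_per_stage)
      g$dec[[l]][[j]] <- list(w = bw$gw, b = bw$gb)
      gcur <- bw$gx
    }
    ch_up <- dim(gcur)[1] - net_channels(cfg)[l]
    gup <- gcur[seq_len(ch_up), , , , drop = FALSE]
    gskip[[l]] <- gcur[ch_up + seq_len(dim(gcur)[1] - ch_up), , , , drop = FALSE]
    gcur <- upsample2_bw(gup)
  }
  # encoder, deepest stage first
  genc_in <- gcur                        # gradient flowing into bottleneck output
  if (!is.null(gbottle_extra)) genc_in <- genc_in + gbottle_extra
  for (l in rev(seq_len(cfg$levels))) {
    gl <- if (l == cfg$levels) genc_in else avgpool2_bw(gnext, dim(cache$relu_out[[key(l, cfg$convs_per_stage, "enc")]]))
    if (l < cfg$levels && !is.null(gskip[[l]])) gl <- gl + gskip[[l]]
    for (j in rev(seq_len(cfg$convs_per_stage))) {
      gl <- gl * leaky_grad(cache$relu_out[[key(l, j, "enc")]])
      xin <- cache$conv_in[[key(l, j, "enc")]]
      dxi <- dim(xin)
      bw <- conv3d_bw(xin, p$enc[[l]][[j]]$w, gl,
                      dxi[1], dim(p$enc[[l]][[j]]$w)[1], dxi[2], dxi[3], dxi[4], 3L)
      if (is.null(g$enc[[l]])) g$enc[[l]] <- vector("list", cfg$convs_per_stage)
      g$enc[[l]][[j]] <- list(w = bw$gw, b = bw$gb)
      gl <- bw$gx
    }
    gnext <- gl
  }
  g
}
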