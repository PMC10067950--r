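# Internal neural-network engine: layer forward/backward passes on [H, W, C]
# arrays. Convolutions dispatch to compiled code; everything else is
# vectorised R. All backward passes are hand-derived and verified against
# finite differences in the test suite.

NN_EPS <- 1e-5

# largest divisor of n_channels that is <= cap (group-norm group count)
gn_groups_for <- function(n_channels, cap = 8L) {
  g <- min(cap, n_channels)
  while (n_channels %% g != 0L) g <- g - 1L
  g
}

he_weights <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}

conv_fw <- function(x, w, b, stride) {
  kd <- dim(w)
  pad <- (kd[1] - 1L) %/% 2L
  conv2d_fw_cpp(x, as.numeric(w), as.numeric(b), kd[1], kd[2], stride, pad)
}

conv_bw <- function(x, w, dy, stride) {
  kd <- dim(w)
  pad <- (kd[1] - 1L) %/% 2L
  out <- conv2d_bw_cpp(x, as.numeric(w), dy, kd[1], kd[2], stride, pad)
  out$dw <- array(out$dw, dim = kd)
  out
}

# group normalisation over (H, W, C/g) per group; batch-size independent so
# the bilateral swap-equivariance property holds exactly in inference
gn_fw <- function(x, gamma, beta, groups, relu = FALSE) {
  out <- gn_fw_cpp(x, as.numeric(gamma), as.numeric(beta), groups, NN_EPS,
                   relu)
  list(y = out$y, cache = list(xhat = out$xhat, istd = out$istd,
                               gamma = gamma, groups = groups))
}

gn_bw <- function(dy, cache) {
  out <- gn_bw_cpp(dy, cache$xhat, cache$istd, as.numeric(cache$gamma),
                   cache$groups)
  list(dx = out$dx, dgamma = out$dgamma, dbeta = out$dbeta)
}

se_fw <- function(x, w1, b1, w2, b2) {
  d <- dim(x); hw <- d[1] * d[2]
  z <- .colMeans(x, hw, d[3])
  a_pre <- drop(w1 %*% z) + b1
  a <- pmax(a_pre, 0)
  s_pre <- drop(w2 %*% a) + b2
  s <- 1 / (1 + exp(-s_pre))
  y <- x * rep(s, each = hw)
  list(y = y, gate = s,
       cache = list(x = x, z = z, a_pre = a_pre, a = a, s = s,
                    w1 = w1, w2 = w2, hw = hw, dim = d))
}

se_bw <- function(dy, cache) {
  d <- cache$dim; hw <- cache$hw; C <- d[3]
  s <- cache$s
  ds <- .colSums(dy * cache$x, hw, C)
  dspre <- ds * s * (1 - s)
  dw2 <- dspre %o% cache$a
  db2 <- dspre
  da <- drop(t(cache$w2) %*% dspre) * (cache$a_pre > 0)
  dw1 <- da %o% cache$z
  db1 <- da
  dz <- drop(t(cache$w1) %*% da)
  dx <- dy * rep(s, each = hw) + rep(dz / hw, each = hw)
  list(dx = dx, dw1 = dw1, db1 = db1, dw2 = dw2, db2 = db2)
}

# pre-activation SE-residual block:
#   x -> GN -> ReLU -> conv3x3(stride) -> GN -> ReLU -> conv3x3 -> SE -> (+) -> y
# shortcut: identity, or 1x1 conv on the first pre-activation when the
# shape changes
block_fw <- function(x, p, bs) {
  g1 <- gn_fw(x, p$gn1.g, p$gn1.b, bs$groups_in, relu = TRUE)
  r1 <- g1$y                            # ReLU fused into the GN kernel
  c1 <- conv_fw(r1, p$conv1.w, p$conv1.b, bs$stride)
  g2 <- gn_fw(c1, p$gn2.g, p$gn2.b, bs$groups_out, relu = TRUE)
  r2 <- g2$y
  c2 <- conv_fw(r2, p$conv2.w, p$conv2.b, 1L)
  se <- se_fw(c2, p$se.w1, p$se.b1, p$se.w2, p$se.b2)
  if (bs$has_proj) {
    sc <- conv_fw(r1, p$proj.w, p$proj.b, bs$stride)
  } else {
    sc <- x
  }
  y <- se$y + sc
  list(y = y, cache = list(x = x, g1 = g1, r1 = r1, c1 = c1, g2 = g2,
                           r2 = r2, se = se))
}

block_bw <- function(dy, p, bs, cache) {
  gr <- list()
  seb <- se_bw(dy, cache$se$cache)
  gr$se.w1 <- seb$dw1; gr$se.b1 <- seb$db1
  gr$se.w2 <- seb$dw2; gr$se.b2 <- seb$db2
  cb2 <- conv_bw(cache$r2, p$conv2.w, seb$dx, 1L)
  gr$conv2.w <- cb2$dw; gr$conv2.b <- cb2$db
  da2 <- cb2$dx * (cache$g2$y > 0)
  gb2 <- gn_bw(da2, cache$g2$cache)
  gr$gn2.g <- gb2$dgamma; gr$gn2.b <- gb2$dbeta
  cb1 <- conv_bw(cache$r1, p$conv1.w, gb2$dx, bs$stride)
  gr$conv1.w <- cb1$dw; gr$conv1.b <- cb1$db
  dr1 <- cb1$dx
  if (bs$has_proj) {
    pb <- conv_bw(cache$r1, p$proj.w, dy, bs$stride)
    gr$proj.w <- pb$dw; gr$proj.b <- pb$db
    dr1 <- dr1 + pb$dx
  }
  da1 <- dr1 * (cache$g1$y > 0)
  gb1 <- gn_bw(da1, cache$g1$cache)
  gr$gn1.g <- gb1$dgamma; gr$gn1.b <- gb1$dbeta
  dx <- gb1$dx
  if (!bs$has_proj) dx <- dx + dy
  list(dx = dx, grads = gr)
}

block_param_init <- function(bs, se_reduction) {
  cin <- bs$cin; cout <- bs$cout
  cr <- max(1L, cout %/% se_reduction)
  p <- list(
    gn1.g = rep(1, cin), gn1.b = rep(0, cin),
    conv1.w = he_weights(c(3L, 3L, cin, cout), 9 * cin),
    conv1.b = rep(0, cout),
    gn2.g = rep(1, cout), gn2.b = rep(0, cout),
    conv2.w = he_weights(c(3L, 3L, cout, cout), 9 * cout),
    conv2.b = rep(0, cout),
    se.w1 = he_weights(c(cr, cout), cout), se.b1 = rep(0, cr),
    se.w2 = he_weights(c(cout, cr), cr), se.b2 = rep(0, cout)
  )
  if (bs$has_proj) {
    p$proj.w <- he_weights(c(1L, 1L, cin, cout), cin)
    p$proj.b <- rep(0, cout)
  }
  p
}

stream_blocks <- function(cfg) {
  n <- cfg$n_blocks
  cins <- c(1L, cfg$block_widths[-n])
  lapply(seq_len(n), function(i) {
    cin <- cins[i]; cout <- cfg$block_widths[i]; stride <- cfg$block_strides[i]
    has_proj <- (stride != 1L || cin != cout)
    short <- c("gn1.g", "gn1.b", "conv1.w", "conv1.b",
               "gn2.g", "gn2.b", "conv2.w", "conv2.b",
               "se.w1", "se.b1", "se.w2", "se.b2",
               if (has_proj) c("proj.w", "proj.b"))
    list(cin = cin, cout = cout, stride = stride,
         has_proj = has_proj,
         groups_in = gn_groups_for(cin), groups_out = gn_groups_for(cout),
         snames = short, pnames = paste0("b", i, ".", short))
  })
}

block_params <- function(params, bs) {
  p <- params[bs$pnames]
  names(p) <- bs$snames
  p
}

stream_param_init <- function(cfg) {
  blocks <- stream_blocks(cfg)
  params <- list()
  for (i in seq_along(blocks)) {
    bp <- block_param_init(blocks[[i]], cfg$se_reduction)
    names(bp) <- paste0("b", i, ".", names(bp))
    params <- c(params, bp)
  }
  cl <- cfg$block_widths[cfg$n_blocks]
  params$fin.gn.g <- rep(1, cl)
  params$fin.gn.b <- rep(0, cl)
  params$fin.conv.w <- he_weights(c(1L, 1L, cl, 3L), cl)
  params$fin.conv.b <- rep(0, 3)
  params
}

stream_fw_full <- function(params, cfg, x) {
  blocks <- stream_blocks(cfg)
  caches <- vector("list", length(blocks))
  h <- x
  for (i in seq_along(blocks)) {
    p <- block_params(params, blocks[[i]])
    out <- block_fw(h, p, blocks[[i]])
    caches[[i]] <- out$cache
    h <- out$y
  }
  gl <- gn_groups_for(dim(h)[3])
  gf <- gn_fw(h, params$fin.gn.g, params$fin.gn.b, gl, relu = TRUE)
  rf <- gf$y
  fm <- conv_fw(rf, params$fin.conv.w, params$fin.conv.b, 1L)
  list(fm = fm, caches = caches, gf = gf, rf = rf, blocks = blocks)
}

stream_bw_full <- function(params, cfg, fwd, dfm) {
  grads <- list()
  cbf <- conv_bw(fwd$rf, params$fin.conv.w, dfm, 1L)
  grads$fin.conv.w <- cbf$dw; grads$fin.conv.b <- cbf$db
  daf <- cbf$dx * (fwd$gf$y > 0)
  gbf <- gn_bw(daf, fwd$gf$cache)
  grads$fin.gn.g <- gbf$dgamma; grads$fin.gn.b <- gbf$dbeta
  dh <- gbf$dx
  for (i in rev(seq_along(fwd$blocks))) {
    bs <- fwd$blocks[[i]]
    p <- block_params(params, bs)
    out <- block_bw(dh, p, bs, fwd$caches[[i]])
    names(out$grads) <- paste0("b", i, ".",
                               names(out$grads))
    grads <- c(grads, out$grads)
    dh <- out$dx
  }
  grads
}

add_grads <- function(a, b) {
  for (nm in names(b)) {
    a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  }
  a
}

softmax <- function(logits) {
  m <- max(logits)
  e <- exp(logits - m)
  e / sum(e)
}
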