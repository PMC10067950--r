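#' Configuration for one CNN stream
#'
#' Describes the convolutional stream that maps a single-ear radiograph to a
#' spatial category-evidence grid (the category feature map). The default
#' stream takes a 384 x 256 input through six squeeze-and-excitation residual
#' blocks with a cumulative spatial reduction of 32x, followed by a 1 x 1
#' projection to one channel per mastoiditis category, yielding a 12 x 8 x 3
#' feature map.
#'
#' @param n_blocks number of SE-residual blocks (default 6).
#' @param block_strides integer strides per block; their product is the total
#'   spatial reduction (default `c(1, 2, 2, 2, 2, 2)`, i.e. 32x).
#' @param block_widths channel widths per block.
#' @param se_reduction squeeze-and-excitation bottleneck reduction ratio.
#' @param lse_r sharpness of Log-Sum-Exp pooling; larger values approach max
#'   pooling, smaller values approach mean pooling.
#' @param input_shape `c(rows, cols)` of a single-ear input image.
#' @param n_classes number of output evidence channels (3 mastoiditis
#'   categories).
#' @return an object of class `stream_config`.
#' @export
stream_config <- function(n_blocks = 6L,
                          block_strides = c(1L, 2L, 2L, 2L, 2L, 2L),
                          block_widths = c(16L, 32L, 64L, 128L, 256L, 256L),
                          se_reduction = 8L,
                          lse_r = 5,
                          input_shape = c(384L, 256L),
                          n_classes = 3L) {
  cfg <- list(n_blocks = as.integer(n_blocks),
              block_strides = as.integer(block_strides),
              block_widths = as.integer(block_widths),
              se_reduction = as.integer(se_reduction),
              lse_r = lse_r,
              input_shape = as.integer(input_shape),
              n_classes = as.integer(n_classes))
  class(cfg) <- "stream_config"
  validate_stream_config(cfg)
  cfg
}

validate_stream_config <- function(cfg) {
  if (length(cfg$block_strides) != cfg$n_blocks ||
      length(cfg$block_widths) != cfg$n_blocks) {
    stop("block_strides and block_widths must each have n_blocks entries")
  }
  if (cfg$lse_r <= 0) stop("lse_r must be positive")
  h <- cfg$input_shape[1]; w <- cfg$input_shape[2]
  for (s in cfg$block_strides) {
    if (h %% s != 0L || w %% s != 0L) {
      stop("stride schedule does not evenly divide the input shape")
    }
    h <- h %/% s; w <- w %/% s
  }
  cfg$feature_shape <- c(h, w)
  invisible(cfg)
}

feature_shape <- function(cfg) {
  red <- prod(cfg$block_strides)
  cfg$input_shape %/% red
}

#' Build a single CNN stream
#'
#' Constructs the weight set of one convolutional stream (He-initialised).
#' In the bilateral model both sides are processed by one such stream: the
#' twin streams share a single parameter set, which guarantees that
#' identical inputs produce identical feature maps on both sides.
#'
#' @param cfg a [stream_config()].
#' @param seed optional integer seed for reproducible initialisation.
#' @return an object of class `masto_stream` with elements `cfg` and
#'   `params`.
#' @export
build_stream <- function(cfg = stream_config(), seed = NULL) {
  validate_stream_config(cfg)
  fs <- feature_shape(cfg)
  if (cfg$n_classes != 3L) stop("streams emit 3 category channels")
  if (!is.null(seed)) set.seed(seed)
  obj <- list(cfg = cfg, params = stream_param_init(cfg))
  class(obj) <- "masto_stream"
  obj
}

#' Forward one image through a stream
#'
#' @param stream a `masto_stream` from [build_stream()].
#' @param image numeric matrix with dimensions `cfg$input_shape`, values in
#'   `[0, 1]`.
#' @return a `CategoryFeatureMap`: an `[h, w, 3]` array of real-valued class
#'   evidence (12 x 8 x 3 for the default configuration).
#' @export
forward_stream <- function(stream, image) {
  if (!identical(dim(image)[1:2], as.integer(stream$cfg$input_shape))) {
    stop("input shape does not match stream configuration: expected ",
         paste(stream$cfg$input_shape, collapse = "x"))
  }
  x <- array(image, dim = c(dim(image)[1:2], 1L))
  fwd <- stream_fw_full(stream$params, stream$cfg, x)
  structure(fwd$fm, class = "CategoryFeatureMap")
}

#' Squeeze-and-excitation channel recalibration
#'
#' Gates each channel of a feature array by a learned function of its global
#' average: global average pool, a bottleneck dense layer with ReLU, a second
#' dense layer with sigmoid, then channel-wise rescaling. Exposed standalone
#' for inspection; inside the network each residual block applies it with its
#' own learned weights.
#'
#' @param features `[H, W, C]` array.
#' @param w1,b1 bottleneck weights (`Cr x C`) and bias (`Cr`).
#' @param w2,b2 expansion weights (`C x Cr`) and bias (`C`).
#' @return list with `output` (`[H, W, C]`) and `gate` (length-`C` vector of
#'   sigmoid gates in `(0, 1)`).
#' @export
se_recalibrate <- function(features, w1, b1, w2, b2) {
  out <- se_fw(features, w1, b1, w2, b2)
  list(output = out$y, gate = out$gate)
}

#' Log-Sum-Exp pooling
#'
#' Smooth aggregation of a spatial map to a scalar,
#' `(1/r) * log(mean(exp(r * x)))`, computed with a max-shift for numerical
#' stability. Interpolates between mean pooling (`r -> 0`) and max pooling
#' (`r -> Inf`); always lies between the mean and the maximum of the map.
#'
#' @param map numeric matrix (one feature-map channel).
#' @param r positive sharpness parameter.
#' @return scalar pooled value.
#' @export
lse_pool <- function(map, r) {
  if (!all(is.finite(map))) stop("lse_pool: map contains non-finite values")
  if (r <= 0) stop("lse_pool: r must be positive")
  m <- max(map)
  m + log(mean(exp(r * (map - m)))) / r
}

lse_pool_bw <- function(map, r, dout) {
  w <- exp(r * (map - max(map)))
  dout * w / sum(w)
}

#' Mastoiditis classification head
#'
#' Pools each of the three category channels of a feature map with
#' Log-Sum-Exp pooling and applies softmax over the three pooled logits.
#'
#' @param fm `[h, w, 3]` category feature map.
#' @param r LSE sharpness.
#' @return length-3 probability vector over (normal, mild, severe).
#' @export
mastoiditis_head <- function(fm, r = 5) {
  logits <- vapply(1:3, function(c) lse_pool(fm[, , c], r), numeric(1))
  softmax(logits)
}

#' Symmetry evaluation layer
#'
#' Computes the element-wise absolute difference between the right and left
#' category feature maps, per category channel and pixel. The result is
#' symmetric in its arguments and zero wherever the two sides carry
#' identical evidence.
#'
#' @param right_fm,left_fm `[h, w, 3]` category feature maps.
#' @return `[h, w, 3]` non-negative difference map (`SymmetryDiffMap`).
#' @export
symmetry_eval <- function(right_fm, left_fm) {
  if (!identical(dim(right_fm), dim(left_fm))) {
    stop("feature map shapes differ")
  }
  structure(abs(right_fm - left_fm), class = "SymmetryDiffMap")
}

#' Symmetry classification head
#'
#' Maps the absolute-difference map to a 3-grade probability vector. With
#' `head = "linear"` (default) a learnable 1 x 1 channel map converts the
#' three category-difference channels into three grade channels before
#' per-channel LSE pooling and softmax; with `head = "direct"` the raw
#' difference channels are pooled without parameters.
#'
#' @param diff `[h, w, 3]` symmetry difference map.
#' @param r LSE sharpness.
#' @param head `"linear"` or `"direct"`.
#' @param sym_w,sym_b 3 x 3 weight matrix and length-3 bias of the linear
#'   grade map (ignored for `"direct"`).
#' @return length-3 probability vector over grades 0..2.
#' @export
symmetry_head <- function(diff, r = 5, head = c("linear", "direct"),
                          sym_w = NULL, sym_b = NULL) {
  head <- match.arg(head)
  if (head == "linear" && (is.null(sym_w) || is.null(sym_b))) {
    stop("the linear symmetry head needs sym_w (3x3) and sym_b (length 3)")
  }
  gm <- grade_map(diff, head, sym_w, sym_b)
  logits <- vapply(1:3, function(g) lse_pool(gm[, , g], r), numeric(1))
  softmax(logits)
}

grade_map <- function(diff, head, sym_w, sym_b) {
  if (head == "direct") return(diff)
  d <- dim(diff)
  flat <- matrix(diff, ncol = 3L)        # (h*w) x 3 category diffs
  gm <- flat %*% t(sym_w)                # (h*w) x 3 grade channels
  gm <- sweep(gm, 2L, sym_b, "+")
  array(gm, dim = d)
}

#' Build the bilateral symmetry model
#'
#' The main architecture: two weight-shared CNN streams (one per ear), a
#' mastoiditis classifier per side (LSE pooling + softmax), and an auxiliary
#' symmetry path that takes the absolute difference of the two feature maps
#' and predicts the symmetry grade (0, 1 or 2) through its own LSE-pooled
#' classifier.
#'
#' @param cfg a [stream_config()].
#' @param head symmetry head variant, `"linear"` (learnable 1 x 1 grade map,
#'   default) or `"direct"` (parameter-free pooling of the raw difference
#'   channels).
#' @param seed optional integer seed for reproducible He initialisation.
#' @return an object of class `masto_model` with `arch = "bilateral"`.
#' @export
build_bilateral <- function(cfg = stream_config(), head = c("linear", "direct"),
                            seed = NULL) {
  head <- match.arg(head)
  validate_stream_config(cfg)
  if (!is.null(seed)) set.seed(seed)
  params <- stream_param_init(cfg)
  if (head == "linear") {
    params$sym.w <- he_weights(c(3L, 3L), 3)
    params$sym.b <- rep(0, 3)
  }
  obj <- list(arch = "bilateral", cfg = cfg, head = head, params = params)
  class(obj) <- "masto_model"
  obj
}

#' Build the single-side baseline model
#'
#' The comparison architecture: one CNN stream and one mastoiditis
#' classifier, receiving a single-ear image; the contralateral stream and
#' the symmetry path are removed.
#'
#' @inheritParams build_bilateral
#' @return an object of class `masto_model` with `arch = "single"`.
#' @export
build_single_side <- function(cfg = stream_config(), seed = NULL) {
  validate_stream_config(cfg)
  if (!is.null(seed)) set.seed(seed)
  obj <- list(arch = "single", cfg = cfg, head = "none",
              params = stream_param_init(cfg))
  class(obj) <- "masto_model"
  obj
}

#' Number of parameters of a model or stream
#'
#' @param x a `masto_model` or `masto_stream`.
#' @return integer count of scalar parameters.
#' @export
n_params <- function(x) {
  sum(vapply(x$params, length, integer(1)))
}

as_input_array <- function(image, shape) {
  if (!identical(as.integer(dim(image)[1:2]), as.integer(shape))) {
    stop("input shape ", paste(dim(image)[1:2], collapse = "x"),
         " does not match configured ", paste(shape, collapse = "x"))
  }
  array(image, dim = c(shape, 1L))
}

# full forward pass with caches retained (used by training and CAM)
forward_bilateral_full <- function(model, right_image, left_image) {
  stopifnot(model$arch == "bilateral")
  xr <- as_input_array(right_image, model$cfg$input_shape)
  xl <- as_input_array(left_image, model$cfg$input_shape)
  fr <- stream_fw_full(model$params, model$cfg, xr)
  fl <- stream_fw_full(model$params, model$cfg, xl)
  diff <- abs(fr$fm - fl$fm)
  gm <- grade_map(diff, model$head, model$params$sym.w, model$params$sym.b)
  r <- model$cfg$lse_r
  logits_r <- vapply(1:3, function(c) lse_pool(fr$fm[, , c], r), numeric(1))
  logits_l <- vapply(1:3, function(c) lse_pool(fl$fm[, , c], r), numeric(1))
  logits_s <- vapply(1:3, function(g) lse_pool(gm[, , g], r), numeric(1))
  list(right_fm = fr$fm, left_fm = fl$fm, diff = diff, grade_map = gm,
       right_probs = softmax(logits_r), left_probs = softmax(logits_l),
       symmetry_probs = softmax(logits_s),
       fwd_r = fr, fwd_l = fl)
}

#' Forward a paired input through the bilateral model
#'
#' @param model a bilateral `masto_model`.
#' @param pair a `PairedInput` from [compose_pair()], or a list with
#'   `right_image` and `left_image` matrices of the configured input shape.
#' @return a `BilateralPrediction`: list with `right_probs`, `left_probs`
#'   (3-vectors over categories) and `symmetry_probs` (3-vector over grades).
#' @export
forward_bilateral <- function(model, pair) {
  out <- forward_bilateral_full(model, pair$right_image, pair$left_image)
  structure(list(right_probs = out$right_probs,
                 left_probs = out$left_probs,
                 symmetry_probs = out$symmetry_probs),
            class = "BilateralPrediction")
}

#' Forward a single-ear image through the single-side model
#'
#' @param model a single-side `masto_model`.
#' @param image matrix of the configured input shape (right-ear
#'   orientation; left ears must be flipped before prediction).
#' @return length-3 probability vector over categories.
#' @export
forward_single <- function(model, image) {
  stopifnot(model$arch == "single")
  x <- as_input_array(image, model$cfg$input_shape)
  fwd <- stream_fw_full(model$params, model$cfg, x)
  mastoiditis_head(fwd$fm, model$cfg$lse_r)
}
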