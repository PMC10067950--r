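# Loss composition, stratified dataset split, and the RMSprop training loop.

CE_FLOOR <- 1e-12

cross_entropy <- function(probs, target) {
  -log(max(probs[target + 1L], CE_FLOOR))
}

onehot3 <- function(k) {
  v <- numeric(3)
  v[k + 1L] <- 1
  v
}

#' Training configuration
#'
#' Defaults follow the published training recipe: RMSprop with initial
#' learning rate 1e-4, mini-batch size 4, He weight initialisation. The
#' epoch budget and early-stopping rule are package choices (the recipe
#' states none): early stopping on validation total loss.
#'
#' @param learning_rate initial learning rate (> 0).
#' @param batch_size mini-batch size (>= 1).
#' @param max_epochs maximum training epochs.
#' @param patience epochs without validation improvement before stopping.
#' @param seed integer seed controlling initialisation and batch order.
#' @param symmetry_weight weight of the symmetry loss added to each side's
#'   classifier loss (default 1, the literal composition).
#' @param rho,epsilon RMSprop decay and stabiliser.
#' @return a `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 4L,
                         max_epochs = 100L, patience = 10L, seed = 1L,
                         symmetry_weight = 1, rho = 0.9, epsilon = 1e-7) {
  stopifnot(learning_rate > 0, batch_size >= 1, max_epochs >= 1,
            patience >= 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 seed = as.integer(seed),
                 symmetry_weight = symmetry_weight,
                 rho = rho, epsilon = epsilon),
            class = "train_config")
}

#' Composite symmetry-augmented loss
#'
#' Three categorical cross-entropies are computed: one per mastoiditis
#' classifier and one for the symmetry classifier. The symmetry loss is
#' added to each side's classifier loss and the two sums are added, so
#' `total = ce_right + ce_left + 2 * ce_symmetry`.
#'
#' @param pred a `BilateralPrediction` (from [forward_bilateral()]).
#' @param label list or data.frame row with integer fields `right`, `left`
#'   (categories 0-2) and `grade`; excluded (category-3) labels are an
#'   error.
#' @param symmetry_weight weight applied to the symmetry loss per side.
#' @return a `LossBreakdown`: list with `ce_right`, `ce_left`,
#'   `ce_symmetry`, `total`.
#' @export
composite_loss <- function(pred, label, symmetry_weight = 1) {
  right <- label$right %||% label$right_cat
  left <- label$left %||% label$left_cat
  if (isTRUE(label$excluded) || right == 3L || left == 3L) {
    stop("excluded (postoperative) labels cannot be scored")
  }
  gr <- if (!is.null(label$grade) && !is.na(label$grade)) label$grade else
    abs(right - left)
  ce_r <- cross_entropy(pred$right_probs, right)
  ce_l <- cross_entropy(pred$left_probs, left)
  ce_s <- cross_entropy(pred$symmetry_probs, gr)
  # the symmetry loss is added to each side's loss and the two sums are
  # added; evaluated in the algebraically equivalent order so the
  # decomposition identity total == ce_r + ce_l + 2 w ce_s is exact
  list(ce_right = ce_r, ce_left = ce_l, ce_symmetry = ce_s,
       total = ce_r + ce_l + 2 * symmetry_weight * ce_s)
}

#' Single-side categorical cross-entropy loss
#'
#' @param probs length-3 category probability vector.
#' @param cat true category (0-2).
#' @return scalar loss.
#' @export
single_side_loss <- function(probs, cat) {
  if (cat == 3L) stop("excluded (postoperative) labels cannot be scored")
  cross_entropy(probs, check_category(cat))
}

#' Stratified train/validation split by symmetry grade
#'
#' Splits included subjects into training and validation sets at the given
#' ratio (default 5:1) with stratified random sampling on the symmetry
#' grade: within each grade stratum the validation fraction is
#' `ratio[2] / sum(ratio)`, rounded to the nearest subject. Deterministic
#' given `seed`.
#'
#' @param labels data.frame as returned by [read_label_table()] (columns
#'   `subject_id`, `grade`, `excluded`).
#' @param ratio length-2 positive numeric, train:validation (default
#'   `c(5, 1)`).
#' @param seed integer seed.
#' @return list with character vectors `train` and `validation`.
#' @export
stratified_split <- function(labels, ratio = c(5, 1), seed = 1L) {
  stopifnot(length(ratio) == 2, all(ratio > 0))
  inc <- labels[!labels$excluded, , drop = FALSE]
  if (nrow(inc) == 0) stop("no included subjects to split")
  frac <- ratio[2] / sum(ratio)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  val <- character(0)
  for (g in sort(unique(inc$grade))) {
    ids <- inc$subject_id[inc$grade == g]
    if (length(ids) < 6) {
      warning("degenerate stratum: grade ", g, " has only ", length(ids),
              " subjects")
    }
    n_val <- round(length(ids) * frac)
    if (n_val > 0) val <- c(val, ids[sample.int(length(ids), n_val)])
  }
  list(train = setdiff(inc$subject_id, val), validation = val)
}

init_model_params <- function(model) {
  params <- stream_param_init(model$cfg)
  if (model$arch == "bilateral" && model$head == "linear") {
    params$sym.w <- he_weights(c(3L, 3L), 3)
    params$sym.b <- rep(0, 3)
  }
  params
}

# loss + parameter gradients for one example (named grads matching params)
example_grad <- function(model, ex, symmetry_weight) {
  r <- model$cfg$lse_r
  if (model$arch == "bilateral") {
    fwd <- forward_bilateral_full(model, ex$right_image, ex$left_image)
    lb <- composite_loss(list(right_probs = fwd$right_probs,
                              left_probs = fwd$left_probs,
                              symmetry_probs = fwd$symmetry_probs),
                         ex, symmetry_weight)
    dlog_r <- fwd$right_probs - onehot3(ex$right %||% ex$right_cat)
    dlog_l <- fwd$left_probs - onehot3(ex$left %||% ex$left_cat)
    dlog_s <- 2 * symmetry_weight * (fwd$symmetry_probs - onehot3(ex$grade))
    d <- dim(fwd$right_fm)
    dfm_r <- array(0, d); dfm_l <- array(0, d); dgm <- array(0, d)
    for (c in 1:3) {
      dfm_r[, , c] <- lse_pool_bw(fwd$right_fm[, , c], r, dlog_r[c])
      dfm_l[, , c] <- lse_pool_bw(fwd$left_fm[, , c], r, dlog_l[c])
      dgm[, , c] <- lse_pool_bw(fwd$grade_map[, , c], r, dlog_s[c])
    }
    grads <- list()
    if (model$head == "linear") {
      flatd <- matrix(fwd$diff, ncol = 3L)
      flatg <- matrix(dgm, ncol = 3L)
      grads$sym.w <- t(flatg) %*% flatd
      grads$sym.b <- colSums(flatg)
      ddiff <- array(flatg %*% model$params$sym.w, dim = d)
    } else {
      ddiff <- dgm
    }
    sgn <- sign(fwd$right_fm - fwd$left_fm)
    dfm_r <- dfm_r + sgn * ddiff
    dfm_l <- dfm_l - sgn * ddiff
    grads <- add_grads(grads,
                       stream_bw_full(model$params, model$cfg, fwd$fwd_r, dfm_r))
    grads <- add_grads(grads,
                       stream_bw_full(model$params, model$cfg, fwd$fwd_l, dfm_l))
    list(loss = lb, grads = grads)
  } else {
    x <- as_input_array(ex$image, model$cfg$input_shape)
    fwd <- stream_fw_full(model$params, model$cfg, x)
    logits <- vapply(1:3, function(c) lse_pool(fwd$fm[, , c], r), numeric(1))
    probs <- softmax(logits)
    loss <- cross_entropy(probs, ex$cat)
    dlog <- probs - onehot3(ex$cat)
    dfm <- array(0, dim(fwd$fm))
    for (c in 1:3) dfm[, , c] <- lse_pool_bw(fwd$fm[, , c], r, dlog[c])
    list(loss = list(total = loss),
         grads = stream_bw_full(model$params, model$cfg, fwd, dfm))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

model_loss <- function(model, ex, symmetry_weight = 1) {
  if (model$arch == "bilateral") {
    pred <- forward_bilateral(model, ex)
    composite_loss(pred, ex, symmetry_weight)$total
  } else {
    single_side_loss(forward_single(model, ex$image), ex$cat)
  }
}

#' Train a model
#'
#' He-initialises the weights, then optimises the composite (bilateral) or
#' plain cross-entropy (single-side) loss with RMSprop mini-batches. Early
#' stopping monitors the mean validation total loss; the weights of the
#' best validation epoch are restored. Fully reproducible given
#' `cfg$seed`.
#'
#' @param model a `masto_model` from [build_bilateral()] or
#'   [build_single_side()].
#' @param train_set,val_set lists of examples. Bilateral examples carry
#'   `right_image`, `left_image`, `right_cat` (alias `right`), `left_cat`
#'   (alias `left`), `grade`; single-side examples carry `image`, `cat`.
#' @param cfg a [train_config()].
#' @param verbose print per-epoch losses.
#' @return the model with trained `params` and a `history` data.frame
#'   (epoch, mean loss components, validation total).
#' @export
train_model <- function(model, train_set, val_set, cfg = train_config(),
                        verbose = FALSE) {
  stopifnot(length(train_set) > 0, length(val_set) > 0)
  set.seed(cfg$seed)
  model$params <- init_model_params(model)
  vstate <- lapply(model$params, function(p) array(0, dim = dim(p) %||% length(p)))
  n <- length(train_set)
  best_val <- Inf; best_params <- model$params; best_epoch <- 0L
  hist <- list()
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = cfg$batch_size)
    ep_losses <- list()
    for (s in starts) {
      idx <- ord[s:min(s + cfg$batch_size - 1L, n)]
      bg <- NULL
      bl <- list()
      for (i in idx) {
        out <- example_grad(model, train_set[[i]], cfg$symmetry_weight)
        bg <- if (is.null(bg)) out$grads else add_grads(bg, out$grads)
        bl[[length(bl) + 1L]] <- out$loss
      }
      k <- length(idx)
      if (!all(vapply(bl, function(l) is.finite(l$total), logical(1)))) {
        stop("training diverged: non-finite loss at epoch ", epoch)
      }
      for (nm in names(bg)) {
        g <- bg[[nm]] / k
        vstate[[nm]] <- cfg$rho * vstate[[nm]] + (1 - cfg$rho) * g^2
        model$params[[nm]] <- model$params[[nm]] -
          cfg$learning_rate * g / (sqrt(vstate[[nm]]) + cfg$epsilon)
      }
      ep_losses <- c(ep_losses, bl)
    }
    mean_of <- function(field) {
      v <- vapply(ep_losses, function(l) l[[field]] %||% NA_real_, numeric(1))
      mean(v)
    }
    val_total <- mean(vapply(val_set, function(ex)
      model_loss(model, ex, cfg$symmetry_weight), numeric(1)))
    hist[[epoch]] <- data.frame(
      epoch = epoch,
      ce_right = mean_of("ce_right"), ce_left = mean_of("ce_left"),
      ce_symmetry = mean_of("ce_symmetry"), total = mean_of("total"),
      val_total = val_total)
    if (verbose) {
      message(sprintf("epoch %d: train %.4f val %.4f", epoch,
                      mean_of("total"), val_total))
    }
    if (val_total < best_val - 1e-9) {
      best_val <- val_total; best_params <- model$params; best_epoch <- epoch
    } else if (epoch - best_epoch >= cfg$patience) {
      break
    }
  }
  model$params <- best_params
  model$history <- do.call(rbind, hist)
  model$best_epoch <- best_epoch
  model
}
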