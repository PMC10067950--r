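# Class activation mapping: per-class spatial evidence from the pre-pooling
# feature maps, rectified and bilinearly upsampled to input resolution.

#' Class activation map for a mastoiditis category
#'
#' Takes the requested category channel of a side's feature map, applies
#' ReLU (regions that respond positively to the LSE pooling), and upsamples
#' bilinearly to the input image size.
#'
#' @param fm `[h, w, 3]` category feature map (one side).
#' @param class_index category 0 (normal), 1 (mild) or 2 (severe).
#' @param target `c(rows, cols)` output resolution (default 384 x 256).
#' @return an `ActivationMap`: non-negative matrix of size `target`.
#' @export
cam_category <- function(fm, class_index, target = c(384L, 256L)) {
  if (!(class_index %in% 0:2)) stop("class_index must be 0, 1 or 2")
  ch <- pmax(fm[, , class_index + 1L], 0)
  structure(resize_bilinear(ch, target[1], target[2]), class = "ActivationMap")
}

#' Class activation map for a symmetry grade
#'
#' Same construction applied to the symmetry path's pre-pooling grade map
#' (after the 1 x 1 grade mapping for the `linear` head, so channels
#' genuinely index grades 0-2; the raw absolute-difference channels for the
#' `direct` head).
#'
#' @param model a bilateral `masto_model`.
#' @param pair a `PairedInput` (or list with `right_image`, `left_image`).
#' @param grade_index symmetry grade 0, 1 or 2.
#' @param target `c(rows, cols)` output resolution.
#' @return an `ActivationMap`.
#' @export
cam_symmetry <- function(model, pair, grade_index, target = c(384L, 256L)) {
  if (!(grade_index %in% 0:2)) stop("grade_index must be 0, 1 or 2")
  fwd <- forward_bilateral_full(model, pair$right_image, pair$left_image)
  ch <- pmax(fwd$grade_map[, , grade_index + 1L], 0)
  structure(resize_bilinear(ch, target[1], target[2]), class = "ActivationMap")
}

# diverging palette: blue (unreacted) - white (intermediate) - red (strong),
# midpoint at half the panel maximum
cam_palette <- function(n = 64) {
  grDevices::colorRampPalette(c("#2166AC", "#FFFFFF", "#B2182B"))(n)
}

draw_panel <- function(img, title, zlim = NULL, palette = NULL) {
  if (is.null(palette)) palette <- grDevices::gray.colors(64, 0, 1)
  if (is.null(zlim)) zlim <- range(img)
  if (diff(zlim) == 0) zlim <- zlim + c(0, 1e-9)
  # image() draws x along rows; rotate so image rows run top-to-bottom
  graphics::image(t(img[nrow(img):1, , drop = FALSE]), col = palette,
                  zlim = zlim, axes = FALSE, asp = nrow(img) / ncol(img))
  graphics::title(main = title, cex.main = 0.8, line = 0.4)
}

#' Render the 12-subpanel class activation figure for one study
#'
#' Layout (3 rows x 4 columns): row 1 the right-ear input and its three
#' category CAMs; row 2 the left-ear input and its category CAMs; row 3 the
#' absolute-difference image and the three symmetry-grade CAMs. Each CAM is
#' annotated with its predicted probability. CAM panels use a diverging
#' blue-white-red palette with the midpoint at half the panel maximum.
#'
#' @param pair a `PairedInput` for the study.
#' @param model a trained bilateral `masto_model`.
#' @param file output PNG path.
#' @return invisibly, a list with the 12 panel descriptors (`kind`,
#'   `title`, `prob`) and the prediction used for annotation.
#' @export
render_cam_panel <- function(pair, model, file) {
  fwd <- forward_bilateral_full(model, pair$right_image, pair$left_image)
  target <- dim(pair$right_image)
  cams_r <- lapply(0:2, function(k) cam_category(fwd$right_fm, k, target))
  cams_l <- lapply(0:2, function(k) cam_category(fwd$left_fm, k, target))
  cams_s <- lapply(0:2, function(g) {
    structure(resize_bilinear(pmax(fwd$grade_map[, , g + 1L], 0),
                              target[1], target[2]),
              class = "ActivationMap")
  })
  diff_img <- abs(pair$right_image - pair$left_image)
  cat_names <- c("normal", "mild", "severe")
  panels <- list()
  add_panel <- function(kind, title, prob = NA_real_) {
    panels[[length(panels) + 1L]] <<- list(kind = kind, title = title,
                                           prob = prob)
  }
  grDevices::png(file, width = 1024, height = 1152)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(3, 4), mar = c(0.5, 0.5, 2, 0.5))
  draw_panel(pair$right_image, "right ear")
  add_panel("input", "right ear")
  for (k in 1:3) {
    p <- fwd$right_probs[k]
    ttl <- sprintf("R %s p=%.3f", cat_names[k], p)
    draw_panel(cams_r[[k]], ttl, zlim = c(0, max(cams_r[[k]], 1e-9) ),
               palette = cam_palette())
    add_panel("cam_category", ttl, p)
  }
  draw_panel(pair$left_image, "left ear")
  add_panel("input", "left ear")
  for (k in 1:3) {
    p <- fwd$left_probs[k]
    ttl <- sprintf("L %s p=%.3f", cat_names[k], p)
    draw_panel(cams_l[[k]], ttl, zlim = c(0, max(cams_l[[k]], 1e-9)),
               palette = cam_palette())
    add_panel("cam_category", ttl, p)
  }
  draw_panel(diff_img, "|right - left|")
  add_panel("input", "|right - left|")
  for (g in 1:3) {
    p <- fwd$symmetry_probs[g]
    ttl <- sprintf("grade %d p=%.3f", g - 1L, p)
    draw_panel(cams_s[[g]], ttl, zlim = c(0, max(cams_s[[g]], 1e-9)),
               palette = cam_palette())
    add_panel("cam_symmetry", ttl, p)
  }
  invisible(list(panels = panels,
                 prediction = list(right_probs = fwd$right_probs,
                                   left_probs = fwd$left_probs,
                                   symmetry_probs = fwd$symmetry_probs)))
}
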