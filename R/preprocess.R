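# Preprocessing geometry: physical-unit ear cropping from the AP view,
# left-ear flip, bilinear resize, paired-input composition.

CROP_HEIGHT_MM <- 180
CROP_WIDTH_MM <- 120
INPUT_ROWS <- 384L
INPUT_COLS <- 256L

#' Read an AP-view radiograph from a DICOM file
#'
#' Applies the rescale slope/intercept, fixes the photometric convention
#' (MONOCHROME1 images are inverted so that higher values are always
#' brighter: air cells dark, sclerotic bone bright), and reads the physical
#' pixel spacing.
#'
#' @param path DICOM file path.
#' @param fallback_spacing_mm optional numeric: spacing to assume when the
#'   file carries no PixelSpacing tag; without it a missing spacing is an
#'   error.
#' @return an `APView`: list with `pixels` (numeric matrix, rows =
#'   superior-inferior, columns = patient-right to patient-left),
#'   `row_spacing_mm`, `col_spacing_mm`, `photometric`.
#' @export
read_ap_view <- function(path, fallback_spacing_mm = NULL) {
  tags <- read_dicom(path)
  px <- tags[["7fe0,0010"]]
  if (is.null(px)) stop("DICOM file has no pixel data: ", path)
  slope <- if (is.null(tags[["0028,1053"]])) 1 else tags[["0028,1053"]]
  intercept <- if (is.null(tags[["0028,1052"]])) 0 else tags[["0028,1052"]]
  pixels <- px * slope + intercept
  photometric <- tags[["0028,0004"]]
  if (is.null(photometric)) photometric <- "MONOCHROME2"
  if (toupper(photometric) == "MONOCHROME1") {
    pixels <- max(pixels) + min(pixels) - pixels
  }
  spacing <- tags[["0028,0030"]]
  if (is.null(spacing)) {
    if (is.null(fallback_spacing_mm)) {
      stop("DICOM file has no PixelSpacing and no fallback spacing was supplied")
    }
    spacing <- rep(fallback_spacing_mm, 2L)
  }
  if (any(spacing <= 0)) stop("pixel spacing must be positive")
  structure(list(pixels = pixels,
                 row_spacing_mm = spacing[1], col_spacing_mm = spacing[2],
                 photometric = toupper(photometric)),
            class = "APView")
}

ap_view <- function(pixels, row_spacing_mm, col_spacing_mm,
                    photometric = "MONOCHROME2") {
  stopifnot(is.matrix(pixels), all(is.finite(pixels)),
            row_spacing_mm > 0, col_spacing_mm > 0)
  structure(list(pixels = pixels, row_spacing_mm = row_spacing_mm,
                 col_spacing_mm = col_spacing_mm, photometric = photometric),
            class = "APView")
}

# 1-based index range of length len whose centre sits at fractional
# coordinate `centre` (in pixels), clamped into [1, limit] when the overhang
# is at most `tol` * len
crop_range <- function(centre, len, limit, tol) {
  start <- floor(centre - len / 2) + 1L
  overhang <- max(0L, 1L - start, start + len - 1L - limit)
  if (overhang > tol * len) {
    stop("crop box exceeds image bounds by ", overhang,
         " px (more than the clamp tolerance)")
  }
  start <- min(max(start, 1L), limit - len + 1L)
  if (start < 1L) stop("image too small for the crop box")
  as.integer(start:(start + len - 1L))
}

#' Crop the two ear regions from an AP view
#'
#' The right-ear crop is a 180 mm x 120 mm box (rows x columns) centred at
#' (0.5 H, 0.25 W) in pixel units; the left-ear crop is the mirror
#' reflection of that box about the vertical midline (the symmetric point,
#' centred at (0.5 H, 0.75 W) within one pixel). Box size in pixels is
#' `round(180 / row_spacing) x round(120 / col_spacing)`. Boxes overhanging
#' the image by at most `clamp_tolerance` of their size are shifted inside;
#' larger overhangs are an error.
#'
#' @param view an `APView`.
#' @param clamp_tolerance maximum fractional overhang tolerated (default
#'   0.1).
#' @return list with elements `right` and `left`, each an `EarCrop`: list
#'   with `pixels`, `side`, `rows`, `cols` (source index ranges) and the
#'   spacings.
#' @export
crop_ears <- function(view, clamp_tolerance = 0.1) {
  H <- nrow(view$pixels); W <- ncol(view$pixels)
  h_px <- as.integer(round(CROP_HEIGHT_MM / view$row_spacing_mm))
  w_px <- as.integer(round(CROP_WIDTH_MM / view$col_spacing_mm))
  rows <- crop_range(0.5 * H, h_px, H, clamp_tolerance)
  cols_r <- crop_range(0.25 * W, w_px, W, clamp_tolerance)
  cols_l <- as.integer(sort(W + 1L - cols_r))
  mk <- function(side, cols) {
    structure(list(pixels = view$pixels[rows, cols, drop = FALSE],
                   side = side, rows = rows, cols = cols,
                   row_spacing_mm = view$row_spacing_mm,
                   col_spacing_mm = view$col_spacing_mm),
              class = "EarCrop")
  }
  list(right = mk("right", cols_r), left = mk("left", cols_l))
}

flip_horizontal <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]

resize_bilinear <- function(m, rows, cols) {
  if (identical(dim(m), as.integer(c(rows, cols)))) return(m)
  # EBImage maps `w` to the first array dimension
  as.matrix(EBImage::resize(m, w = rows, h = cols))
}

normalize_01 <- function(m) {
  rng <- range(m)
  if (diff(rng) == 0) {
    warning("degenerate crop with zero intensity range; normalized to zeros")
    return(matrix(0, nrow(m), ncol(m)))
  }
  (m - rng[1]) / diff(rng)
}

#' Compose the paired two-ear network input
#'
#' Flips the left-ear crop horizontally so both ears share the right-ear
#' orientation, resizes both crops bilinearly to the network input size,
#' normalizes each image to `[0, 1]` by its own min-max range, and
#' concatenates the two vertically (right ear on top). With a perfectly
#' mirror-symmetric subject the two halves are identical, which is the
#' spatial correspondence the symmetry evaluation layer exploits.
#'
#' @param right,left `EarCrop`s from [crop_ears()].
#' @param target `c(rows, cols)` single-ear input size (default 384 x 256).
#' @return a `PairedInput`: list with `right_image`, `left_image` (each
#'   `target`, values in `[0, 1]`) and `concatenated`
#'   (`2 * target[1] x target[2]`, right on top).
#' @export
compose_pair <- function(right, left, target = c(INPUT_ROWS, INPUT_COLS)) {
  stopifnot(inherits(right, "EarCrop"), inherits(left, "EarCrop"))
  ri <- normalize_01(resize_bilinear(right$pixels, target[1], target[2]))
  li <- normalize_01(resize_bilinear(flip_horizontal(left$pixels),
                                     target[1], target[2]))
  structure(list(right_image = ri, left_image = li,
                 concatenated = rbind(ri, li)),
            class = "PairedInput")
}
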