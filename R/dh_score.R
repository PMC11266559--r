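#' Immunostain image container
#'
#' @param rgb numeric array `height x width x 3` with values in `[0, 255]`
#'   (8-bit RGB).
#' @param roi_mask logical `height x width` matrix of the manually-drawn
#'   region of interest; defaults to the full frame.
#' @return A list of class `stain_image`.
#' @export
stain_image <- function(rgb, roi_mask = NULL) {
  if (length(dim(rgb)) != 3 || dim(rgb)[3] != 3)
    stop("`rgb` must be a height x width x 3 array")
  if (min(rgb) < 0 || max(rgb) > 255)
    stop("`rgb` must be 8-bit (values in [0, 255])")
  if (is.null(roi_mask)) roi_mask <- matrix(TRUE, dim(rgb)[1], dim(rgb)[2])
  if (!identical(dim(roi_mask), dim(rgb)[1:2]))
    stop("roi_mask dimensions must match the image")
  structure(list(rgb = rgb, roi_mask = roi_mask), class = "stain_image")
}

# Classical H-DAB stain vectors (Ruifrok & Johnston), unit-normalized rows:
# hematoxylin, DAB, and the residual third channel.
hdab_stain_matrix <- function() {
  m <- rbind(hematoxylin = c(0.650, 0.704, 0.286),
             dab = c(0.268, 0.570, 0.776),
             residual = c(0.7110, 0.4233, 0.5614))
  m / sqrt(rowSums(m^2))
}

#' Tissue area by global grayscale thresholding
#'
#' Counts ROI pixels whose Rec.601 luminance (`0.299 R + 0.587 G +
#' 0.114 B`) lies in `[0, 241]` (inclusive bounds); near-white background is
#' excluded.
#'
#' @param img a [stain_image()].
#' @param threshold upper luminance bound (default 241).
#' @return Pixel count.
#' @export
tissue_area <- function(img, threshold = 241) {
  luma <- luminance(img$rgb)
  sum(img$roi_mask & luma >= 0 & luma <= threshold)
}

luminance <- function(rgb) {
  0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
}

#' Color-deconvolve the DAB channel
#'
#' Optical densities (`-log10(I / 255)`, intensities clamped to `[1, 255]`)
#' are unmixed with the H-DAB stain matrix; the DAB concentration is mapped
#' back to an 8-bit intensity `255 * 10^(-c)` where 0 means maximal DAB and
#' 255 no stain.
#'
#' @param img a [stain_image()] or 8-bit RGB array.
#' @param stains 3 x 3 stain matrix (rows = stains), overriding the default
#'   H-DAB vectors.
#' @return Integer matrix (height x width) of DAB intensities in `[0, 255]`.
#' @export
deconvolve_dab <- function(img, stains = hdab_stain_matrix()) {
  rgb <- if (inherits(img, "stain_image")) img$rgb else img
  if (length(dim(rgb)) != 3 || min(rgb) < 0 || max(rgb) > 255)
    stop("input must be an 8-bit RGB image")
  dims <- dim(rgb)[1:2]
  flat <- matrix(rgb, ncol = 3)
  od <- -log10(pmin(pmax(flat, 1), 255) / 255)
  conc <- od %*% solve(stains)          # od = conc %*% stains
  dab <- 255 * 10^(-conc[, 2])
  matrix(as.integer(round(pmin(pmax(dab, 0), 255))), dims[1], dims[2])
}

#' Bin DAB intensities and compute the digital Histo-score
#'
#' Within ROI and tissue area, pixels are counted as strong (DAB in
#' `[0, 134]`), medium (`[135, 182]`) or weak (`[183, 203]`); intensities in
#' `(203, 255]` stay unscored. The DH-score is `3 n_strong + 2 n_medium +
#' n_weak`; `dh_per_area` divides by the tissue area.
#'
#' @param dab integer DAB-intensity matrix from [deconvolve_dab()].
#' @param img the corresponding [stain_image()].
#' @return A list of class `dh_result`: `tissue_area`, `n_strong`,
#'   `n_medium`, `n_weak`, `dh`, `dh_per_area`.
#' @export
bin_and_score <- function(dab, img) {
  luma <- luminance(img$rgb)
  tissue <- img$roi_mask & luma <= 241
  ta <- sum(tissue)
  n_strong <- as.integer(sum(tissue & dab <= 134))
  n_medium <- as.integer(sum(tissue & dab >= 135 & dab <= 182))
  n_weak <- as.integer(sum(tissue & dab >= 183 & dab <= 203))
  dh <- 3L * n_strong + 2L * n_medium + n_weak
  if (ta == 0) {
    warning("tissue area is 0; dh_per_area undefined")
    dpa <- NA_real_
  } else dpa <- dh / ta
  structure(list(tissue_area = ta, n_strong = n_strong, n_medium = n_medium,
                 n_weak = n_weak, dh = dh, dh_per_area = dpa),
            class = "dh_result")
}

#' @export
print.dh_result <- function(x, ...) {
  cat(sprintf("DH-score %d (strong %d, medium %d, weak %d; tissue %d px)\n",
              x$dh, x$n_strong, x$n_medium, x$n_weak, x$tissue_area))
  invisible(x)
}

#' One-call DH-score of an immunostain image
#'
#' @inheritParams bin_and_score
#' @inheritParams deconvolve_dab
#' @return A `dh_result`, see [bin_and_score()].
#' @export
dh_score <- function(img, stains = hdab_stain_matrix()) {
  bin_and_score(deconvolve_dab(img, stains), img)
}
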