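# Candidate pure-stain pixels whose deconvolved DAB intensity provably lands
# inside a requested bin after 8-bit rounding. Strong/medium/weak blobs are
# rendered as pure DAB, negative blobs as pure hematoxylin (DAB-free tissue).
.dab_bins <- list(strong = c(0, 134), medium = c(135, 182),
                  weak = c(183, 203), negative = c(204, 255))

stain_pixel_candidates <- function(bin, stains = hdab_stain_matrix()) {
  rng <- .dab_bins[[bin]]
  if (is.null(rng)) stop("unknown DAB bin: ", bin)
  cand <- list()
  if (bin == "negative") {
    # hematoxylin-only tissue pixels: recovered DAB stays ~255
    for (conc in seq(0.1, 1.2, by = 0.05)) {
      px <- round(255 * 10^(-conc * stains[1, ]))
      if (check_pixel(px, rng, stains)) cand[[length(cand) + 1]] <- px
    }
  } else {
    for (v in seq(max(rng[1], 2), rng[2], by = 1)) {
      conc <- log10(255 / v)
      px <- round(255 * 10^(-conc * stains[2, ]))
      if (check_pixel(px, rng, stains)) cand[[length(cand) + 1]] <- px
    }
  }
  if (length(cand) == 0)
    stop("bin '", bin, "' unreachable with the given stain vectors")
  do.call(rbind, cand)
}

check_pixel <- function(px, rng, stains) {
  if (any(px < 0 | px > 255)) return(FALSE)
  if (0.299 * px[1] + 0.587 * px[2] + 0.114 * px[3] > 241) return(FALSE)
  arr <- array(px, c(1, 1, 3))
  d <- deconvolve_dab(arr, stains)[1, 1]
  d >= rng[1] && d <= rng[2]
}

#' Render a synthetic DAB immunostain image with known bin counts
#'
#' Places blobs of pixels whose deconvolved DAB intensity lies strictly
#' inside the requested bin (`strong` `[0,134]`, `medium` `[135,182]`,
#' `weak` `[183,203]`, `negative` `(203,255]`) on a white background (which
#' the `[0, 241]` grayscale rule excludes from tissue). Blob pixels are
#' scattered at random positions.
#'
#' @param width,height image dimensions in pixels.
#' @param blobs list of `list(n_pixels =, bin =)` specifications.
#' @param seed integer RNG seed.
#' @param stains stain matrix, see [deconvolve_dab()].
#' @return A list: `image` (a [stain_image()] with full-frame ROI) and
#'   `truth` (named counts `strong`, `medium`, `weak`, `negative` and the
#'   implied `dh`).
#' @export
simulate_stain_image <- function(width, height, blobs = list(), seed = 1,
                                 stains = hdab_stain_matrix()) {
  total <- sum(vapply(blobs, function(b) b$n_pixels, 0))
  if (total > width * height) stop("total blob pixels exceed the image size")
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(seed)
  rgb <- array(255, c(height, width, 3))
  free <- sample.int(height * width)
  used <- 0L
  truth <- c(strong = 0L, medium = 0L, weak = 0L, negative = 0L)
  for (b in blobs) {
    if (b$n_pixels == 0) next
    cand <- stain_pixel_candidates(b$bin, stains)
    idx <- free[(used + 1):(used + b$n_pixels)]
    used <- used + b$n_pixels
    pick <- sample.int(nrow(cand), b$n_pixels, replace = TRUE)
    for (ch in 1:3) {
      plane <- rgb[, , ch]
      plane[idx] <- cand[pick, ch]
      rgb[, , ch] <- plane
    }
    truth[b$bin] <- truth[b$bin] + as.integer(b$n_pixels)
  }
  truth_dh <- 3L * truth[["strong"]] + 2L * truth[["medium"]] + truth[["weak"]]
  list(image = stain_image(rgb),
       truth = c(as.list(truth), dh = truth_dh))
}

#' Write / read a stain image as PNG
#'
#' @param img a [stain_image()].
#' @param path output path (`_mask.png` is appended for the ROI).
#' @return `write_stain_image` returns the paths invisibly;
#'   `read_stain_image` returns a [stain_image()].
#' @export
write_stain_image <- function(img, path) {
  arr <- img$rgb / 255
  png::writePNG(arr, path)
  mask_path <- sub("\\.png$", "_mask.png", path)
  png::writePNG(matrix(as.numeric(img$roi_mask), nrow(img$roi_mask)), mask_path)
  invisible(c(image = path, mask = mask_path))
}

#' @rdname write_stain_image
#' @param mask_path optional ROI mask PNG (white = inside).
#' @export
read_stain_image <- function(path, mask_path = NULL) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 2) arr <- array(rep(arr, 3), c(dim(arr), 3))
  if (dim(arr)[3] == 4) arr <- arr[, , 1:3]
  rgb <- round(arr * 255)
  mask <- NULL
  if (!is.null(mask_path)) {
    m <- png::readPNG(mask_path)
    if (length(dim(m)) == 3) m <- m[, , 1]
    mask <- m > 0.5
  }
  stain_image(rgb, mask)
}
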