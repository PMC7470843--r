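#' Average realigned images within a class
#'
#' Voxelwise arithmetic mean (and per-voxel variance) over realigned images
#' of one (stage x genotype) class. Images contribute raw intensities by
#' default; set `normalize_by` to divide each image by its own total in a
#' reference channel first.
#'
#' @param images list of `realigned_image`s sharing grid and channels.
#' @param class_key identifier carried on the result (e.g. "spindle/WT").
#' @param normalize_by optional channel name for per-image normalization.
#' @return a `class_average`: `mean_image` and `var_image` (per-channel
#'   grids), `n`, `class_key`, voxel sizes.
#' @export
average_class <- function(images, class_key = "", normalize_by = NULL) {
  if (length(images) == 0) stop("no images to average")
  d0 <- dim(images[[1]]$pixels[[1]])
  ch <- names(images[[1]]$pixels)
  for (im in images) {
    if (!identical(dim(im$pixels[[1]]), d0) ||
        !identical(names(im$pixels), ch))
      stop("images must share grid dimensions and channels")
  }
  if (!is.null(normalize_by)) {
    images <- lapply(images, function(im) {
      s <- sum(im$pixels[[normalize_by]])
      if (s <= 0) stop("non-positive normalization total")
      im$pixels <- lapply(im$pixels, function(a) a / s)
      im
    })
  }
  n <- length(images)
  mean_image <- stats::setNames(lapply(ch, function(cc) {
    acc <- array(0, d0)
    for (im in images) acc <- acc + im$pixels[[cc]]
    acc / n
  }), ch)
  var_image <- stats::setNames(lapply(ch, function(cc) {
    if (n == 1) return(array(0, d0))
    acc <- array(0, d0)
    for (im in images) acc <- acc + (im$pixels[[cc]] - mean_image[[cc]])^2
    acc / (n - 1)
  }), ch)
  structure(list(mean_image = mean_image, var_image = var_image, n = n,
                 class_key = class_key,
                 voxel_xy = images[[1]]$voxel_xy,
                 voxel_z = images[[1]]$voxel_z),
            class = "class_average")
}

# corner-aligned bilinear upscale of one matrix; reproduces affine
# intensity ramps exactly, including at the borders
.upscale_mat <- function(mat, factor) {
  d <- dim(mat)
  ox <- if (d[1] == 1) rep(1, factor) else
    1 + (seq_len(factor * d[1]) - 1) * (d[1] - 1) / (factor * d[1] - 1)
  oy <- if (d[2] == 1) rep(1, factor) else
    1 + (seq_len(factor * d[2]) - 1) * (d[2] - 1) / (factor * d[2] - 1)
  g <- expand.grid(x = ox, y = oy)
  matrix(bilinear(mat, g$x, g$y), factor * d[1], factor * d[2])
}

#' Upscale an image laterally for display
#'
#' Multiplies the lateral (x, y) dimensions by an integer factor using
#' bilinear interpolation, leaving z untouched; the display convention for
#' averaged panels (default 4 x 4).
#'
#' @param image an `image_stack`/`realigned_image`, a `projection_2d`, or a
#'   plain matrix.
#' @param factor integer >= 1.
#' @return same kind of object with lateral dimensions scaled.
#' @export
upscale_display <- function(image, factor = 4) {
  if (factor != round(factor) || factor < 1)
    stop("factor must be a positive integer")
  factor <- as.integer(factor)
  if (factor == 1L) return(image)
  if (is.matrix(image)) return(.upscale_mat(image, factor))
  if (inherits(image, "projection_2d")) {
    image$pixels <- lapply(image$pixels, .upscale_mat, factor = factor)
    image$voxel_xy <- image$voxel_xy / factor
    return(image)
  }
  image$pixels <- lapply(image$pixels, function(arr) {
    d <- dim(arr)
    out <- array(0, c(factor * d[1], factor * d[2], d[3]))
    for (k in seq_len(d[3])) out[, , k] <- .upscale_mat(arr[, , k], factor)
    out
  })
  image$voxel_xy <- image$voxel_xy / factor
  image
}

#' Convert an image to 8-bit display depth
#'
#' Linear mapping of `[low, high]` to 0..255 with clipping; use one shared
#' `low`/`high` across a figure set for consistent brightness and contrast.
#' The float originals are untouched.
#'
#' @param image matrix or array of intensities.
#' @param low,high display range (defaults: image min/max).
#' @return integer array of the same shape, values 0..255.
#' @export
to_display_8bit <- function(image, low = min(image), high = max(image)) {
  if (high <= low) stop("display range must have high > low")
  x <- (image - low) / (high - low)
  x[x < 0] <- 0; x[x > 1] <- 1
  storage <- round(x * 255)
  array(as.integer(storage), dim = if (is.null(dim(image))) length(image)
                                   else dim(image))
}
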