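#' Load an image or focal stack
#'
#' Reads a single- or multi-page TIFF (or PNG/JPEG-less PNG) into an ordered
#' stack of grayscale planes with intensities in `[0, 1]`. RGB input is
#' converted to luminance (ITU-R 601: `0.299 R + 0.587 G + 0.114 B`).
#'
#' @param path Path to a readable single- or multi-page TIFF or PNG file.
#' @param z_step Physical distance between consecutive planes in micrometers
#'   (default 8, the acquisition step used for brightfield multifocal stacks).
#' @return An object of class `image_stack`: a list with `planes` (list of
#'   numeric matrices) and `z_step`.
#' @export
load_stack <- function(path, z_step = 8) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop("unreadable file: ", path)
  if (!is.numeric(z_step) || z_step <= 0) stop("z_step must be > 0")
  ext <- tolower(tools::file_ext(path))
  planes <- if (ext %in% c("tif", "tiff")) {
    p <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(p)) list(p) else p
  } else if (ext == "png") {
    list(png::readPNG(path))
  } else stop("unsupported image format: .", ext)
  planes <- lapply(planes, to_gray)
  dims <- vapply(planes, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("planes of unequal size in ", path)
  new_image_stack(planes, z_step)
}

#' Construct an image stack from in-memory planes
#'
#' @param planes List of numeric matrices (grayscale, `[0, 1]`), identical
#'   dimensions, ordered bottom plane first.
#' @param z_step Plane spacing in micrometers (> 0).
#' @return An `image_stack` object.
#' @export
new_image_stack <- function(planes, z_step = 8) {
  if (!is.list(planes) || length(planes) < 1L) stop("need at least one plane")
  if (!is.numeric(z_step) || length(z_step) != 1L || z_step <= 0)
    stop("z_step must be a single value > 0")
  dims <- vapply(planes, function(p) {
    if (!is.matrix(p)) stop("planes must be 2D matrices")
    dim(p)
  }, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("planes of unequal size")
  structure(list(planes = planes, z_step = as.numeric(z_step)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$planes[[1]])
  cat(sprintf("<image_stack> %d plane(s), %d x %d px, z step %g um\n",
              length(x$planes), d[2], d[1], x$z_step))
  invisible(x)
}

# RGB(A) array -> luminance matrix; matrices pass through.
to_gray <- function(img) {
  if (is.matrix(img)) return(img)
  if (length(dim(img)) == 3L) {
    nc <- dim(img)[3]
    if (nc >= 3L)
      return(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3])
    return(img[, , 1])
  }
  stop("unsupported image array layout")
}

# Local variance of the Laplacian: the per-plane sharpness score.
sharpness_map <- function(plane, window) {
  lap <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  l <- as.matrix(EBImage::filter2(plane, lap, boundary = "replicate"))
  box <- matrix(1 / (window * window), window, window)
  m1 <- as.matrix(EBImage::filter2(l, box, boundary = "replicate"))
  m2 <- as.matrix(EBImage::filter2(l * l, box, boundary = "replicate"))
  pmax(m2 - m1 * m1, 0)
}

#' Assemble an all-in-focus image from a focal stack
#'
#' Depth-from-focus: per pixel, the plane maximizing a local sharpness score
#' (variance of the Laplacian within `window`) is selected; the depth map is
#' median-filtered with the same window before the image is assembled.
#'
#' @param stack An [image_stack][new_image_stack].
#' @param window Odd side length (pixels, >= 3) of the local sharpness and
#'   median-filter window. Default 9.
#' @param median_smooth Apply the median filter to the depth map (default
#'   `TRUE`). Disable to obtain the raw per-pixel argmax.
#' @return An object of class `focused_image`: list with `image` (matrix) and
#'   `depth_index` (integer matrix, 0-based plane of best focus per pixel).
#' @export
focus_stack <- function(stack, window = 9, median_smooth = TRUE) {
  stopifnot(inherits(stack, "image_stack"))
  if (window < 3 || window %% 2 != 1) stop("window must be odd and >= 3")
  d <- dim(stack$planes[[1]])
  if (window > min(d)) stop("window larger than image")
  np <- length(stack$planes)
  if (np == 1L) {
    return(structure(list(image = stack$planes[[1]],
                          depth_index = matrix(0L, d[1], d[2])),
                     class = "focused_image"))
  }
  best <- sharpness_map(stack$planes[[1]], window)
  depth <- matrix(1L, d[1], d[2])
  for (p in 2:np) {
    s <- sharpness_map(stack$planes[[p]], window)
    sel <- s > best
    best[sel] <- s[sel]
    depth[sel] <- p
  }
  if (median_smooth && np > 1L) {
    dn <- (depth - 1L) / (np - 1L)
    dn <- as.matrix(EBImage::medianFilter(dn, size = (window - 1L) %/% 2L))
    depth <- as.integer(round(dn * (np - 1L))) + 1L
    dim(depth) <- d
  }
  img <- matrix(0, d[1], d[2])
  for (p in seq_len(np)) {
    sel <- depth == p
    img[sel] <- stack$planes[[p]][sel]
  }
  structure(list(image = img, depth_index = depth - 1L),
            class = "focused_image")
}

#' @export
print.focused_image <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<focused_image> %d x %d px, depth range %d..%d\n",
              d[2], d[1], min(x$depth_index), max(x$depth_index)))
  invisible(x)
}

#' Convert a depth map to physical altitude
#'
#' Altitude in micrometers relative to the lowest focal plane actually used:
#' `(depth_index - min(depth_index)) * z_step`.
#'
#' @param focused A [focused_image][focus_stack].
#' @param z_step Plane spacing in micrometers.
#' @return Numeric matrix of altitudes (um); its minimum is 0.
#' @export
altitude_map <- function(focused, z_step = 8) {
  stopifnot(inherits(focused, "focused_image"))
  (focused$depth_index - min(focused$depth_index)) * z_step
}

#' Write a focused image and its depth map as 16-bit TIFFs
#'
#' @param focused A [focused_image][focus_stack].
#' @param prefix Output path prefix; writes `<prefix>_focused.tif` and
#'   `<prefix>_depth.tif`.
#' @return Invisibly, the two paths written.
#' @export
write_focused <- function(focused, prefix) {
  stopifnot(inherits(focused, "focused_image"))
  p1 <- paste0(prefix, "_focused.tif")
  p2 <- paste0(prefix, "_depth.tif")
  tiff::writeTIFF(pmin(pmax(focused$image, 0), 1), p1,
                  bits.per.sample = 16L, compression = "none")
  tiff::writeTIFF(focused$depth_index / 65535, p2,
                  bits.per.sample = 16L, compression = "none")
  invisible(c(p1, p2))
}
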