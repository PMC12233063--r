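#' Pixel feature recipe
#'
#' Deterministic multi-scale feature bank used by both pixel classifiers:
#' raw intensity plus, at each smoothing scale, the Gaussian blur, gradient
#' magnitude, Laplacian, the two Hessian eigenvalues and the local
#' (Gaussian-weighted) variance.
#'
#' @param sigmas Smoothing scales in pixels. Default `c(1, 2, 4, 8, 16)`.
#' @return A `feature_recipe` object.
#' @export
feature_recipe <- function(sigmas = c(1, 2, 4, 8, 16)) {
  stopifnot(is.numeric(sigmas), length(sigmas) >= 1, all(sigmas > 0))
  nms <- c("raw", as.vector(outer(
    c("gauss", "gradmag", "laplacian", "hess_hi", "hess_lo", "variance"),
    sigmas, function(f, s) paste0(f, "_s", s))))
  structure(list(sigmas = sigmas, feature_names = nms, version = 1L),
            class = "feature_recipe")
}

gblur_rep <- function(x, sigma) {
  # cap the kernel radius so small images remain filterable
  r <- min(2 * ceiling(3 * sigma) + 1, 2 * ((min(dim(x)) - 1) %/% 2) + 1)
  as.matrix(EBImage::gblur(x, sigma = sigma, radius = r,
                           boundary = "replicate"))
}

filt <- function(x, k) as.matrix(EBImage::filter2(x, k, boundary = "replicate"))

#' Compute the per-pixel feature stack
#'
#' @param image Numeric matrix, grayscale in `[0, 1]`.
#' @param recipe A [feature_recipe].
#' @return Numeric array `H x W x k`, third dimension named by feature.
#' @export
extract_features <- function(image, recipe = feature_recipe()) {
  stopifnot(is.matrix(image), inherits(recipe, "feature_recipe"))
  kx <- matrix(c(-0.5, 0, 0.5), 1, 3)          # d/dx (x = column)
  ky <- t(kx)                                  # d/dy
  kxx <- matrix(c(1, -2, 1), 1, 3)
  kyy <- t(kxx)
  kxy <- matrix(c(0.25, 0, -0.25, 0, 0, 0, -0.25, 0, 0.25), 3, 3)
  klap <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  out <- vector("list", length(recipe$feature_names))
  out[[1]] <- image
  i <- 2L
  for (s in recipe$sigmas) {
    g <- gblur_rep(image, s)
    gx <- filt(g, kx); gy <- filt(g, ky)
    fxx <- filt(g, kxx); fyy <- filt(g, kyy); fxy <- filt(g, kxy)
    tr <- fxx + fyy
    dd <- sqrt((fxx - fyy)^2 + 4 * fxy^2)
    v <- pmax(gblur_rep(image^2, s) - g^2, 0)
    out[[i]] <- g
    out[[i + 1L]] <- sqrt(gx^2 + gy^2)
    out[[i + 2L]] <- filt(g, klap)
    out[[i + 3L]] <- (tr + dd) / 2
    out[[i + 4L]] <- (tr - dd) / 2
    out[[i + 5L]] <- v
    i <- i + 6L
  }
  arr <- array(unlist(out, use.names = FALSE),
               dim = c(dim(image), length(out)),
               dimnames = list(NULL, NULL, recipe$feature_names))
  arr
}

#' Training annotation for the pixel classifiers
#'
#' Sparse manual annotation of one image: the compound-eye outline interior
#' and a set of labeled ommatidium (facet) masks sampled from several eye
#' regions. Boundary-class pixels are derived later as the morphological
#' gradient of the facet masks.
#'
#' @param image_id Identifier string.
#' @param eye_region Logical matrix: `TRUE` inside the delineated eye outline.
#' @param facet_label Integer matrix, 0 = unlabeled, k > 0 = annotated facet k.
#' @return A `training_annotation` object.
#' @export
training_annotation <- function(image_id, eye_region, facet_label) {
  stopifnot(is.matrix(eye_region), is.matrix(facet_label),
            all(dim(eye_region) == dim(facet_label)))
  eye_region <- eye_region > 0
  facet_label <- matrix(as.integer(facet_label), nrow(facet_label))
  if (!any(facet_label > 0L)) stop("annotation with empty facet class")
  if (any(facet_label > 0L & !eye_region))
    stop("facet annotations must lie inside the eye outline")
  structure(list(image_id = image_id, eye_region = eye_region,
                 facet_label = facet_label),
            class = "training_annotation")
}

#' Read a label-image annotation (0 = unlabeled, 1 = eye, 2 = facet)
#'
#' @param path PNG/TIFF label image; values 0, 1, 2 scaled to `[0,1]` or raw.
#' @param image_id Identifier; defaults to the file name.
#' @return A [training_annotation]. Facet regions are split into connected
#'   components to recover individual facet labels.
#' @export
read_annotation <- function(path, image_id = basename(path)) {
  ext <- tolower(tools::file_ext(path))
  lab <- if (ext == "png") png::readPNG(path) else tiff::readTIFF(path)
  lab <- to_gray(lab)
  # class ids 0 (unlabeled), 1 (eye), 2 (facet); accept raw ids or ids
  # stored in an integer image read back on the [0, 1] scale
  vals <- sort(unique(as.vector(lab)))
  if (length(vals) > 3)
    stop("annotation image must contain at most 3 label values (0, 1, 2)")
  lab <- matrix(match(lab, vals) - 1L, nrow(lab))
  facets <- as.matrix(EBImage::bwlabel(lab == 2L))
  training_annotation(image_id, eye_region = lab >= 1L, facet_label = facets)
}

# boundary class = morphological gradient (3 px box) of the facet masks
facet_boundary_mask <- function(facet_label) {
  bin <- facet_label > 0L
  k <- EBImage::makeBrush(3, shape = "box")
  dil <- as.matrix(EBImage::dilate(bin * 1, k)) > 0
  ero <- as.matrix(EBImage::erode(bin * 1, k)) > 0
  dil & !ero
}

sample_class <- function(idx, cap) {
  if (length(idx) <= cap) idx else sort(sample(idx, cap))
}

#' Train the eye-region and facet pixel classifiers
#'
#' Trains two 100-tree random forests on pixel features: one separating
#' eye from non-eye pixels, one separating facet-interior from facet-boundary
#' pixels. Per-class training pixels are capped by seeded subsampling.
#'
#' @param annotations List of [training_annotation] objects.
#' @param images Matching list of grayscale image matrices.
#' @param seed Integer RNG seed; training is reproducible given the seed.
#' @param recipe A [feature_recipe]; must match between training and use.
#' @param num_trees Trees per forest (default 100).
#' @param max_per_class Per-class training-pixel cap (default 50000).
#' @return List with elements `eye` and `facet`, each a `pixel_model`.
#' @export
train_models <- function(annotations, images, seed,
                         recipe = feature_recipe(), num_trees = 100,
                         max_per_class = 50000) {
  if (inherits(annotations, "training_annotation")) annotations <- list(annotations)
  if (is.matrix(images)) images <- list(images)
  stopifnot(length(annotations) >= 1, length(annotations) == length(images))
  eye_x <- list(); eye_y <- list(); fac_x <- list(); fac_y <- list()
  for (k in seq_along(annotations)) {
    ann <- annotations[[k]]
    stopifnot(inherits(ann, "training_annotation"),
              all(dim(images[[k]]) == dim(ann$eye_region)))
    fs <- extract_features(images[[k]], recipe)
    fm <- matrix(fs, ncol = dim(fs)[3],
                 dimnames = list(NULL, dimnames(fs)[[3]]))
    interior <- which(ann$facet_label > 0L)
    boundary <- which(facet_boundary_mask(ann$facet_label) & ann$facet_label == 0L)
    inside <- which(ann$eye_region)
    outside <- which(!ann$eye_region)
    if (!length(interior) || !length(boundary))
      stop("annotation with empty facet/boundary class: ", ann$image_id)
    if (!length(inside) || !length(outside))
      stop("annotation with empty eye/non-eye class: ", ann$image_id)
    with_seed(seed + k, {
      interior <- sample_class(interior, max_per_class)
      boundary <- sample_class(boundary, max_per_class)
      inside <- sample_class(inside, max_per_class)
      outside <- sample_class(outside, max_per_class)
    })
    eye_x[[k]] <- fm[c(inside, outside), , drop = FALSE]
    eye_y[[k]] <- rep(c("eye", "noneye"), c(length(inside), length(outside)))
    fac_x[[k]] <- fm[c(interior, boundary), , drop = FALSE]
    fac_y[[k]] <- rep(c("interior", "boundary"),
                      c(length(interior), length(boundary)))
  }
  fit <- function(x, y, task) {
    df <- as.data.frame(do.call(rbind, x))
    df$.class <- factor(unlist(y))
    forest <- ranger::ranger(dependent.variable.name = ".class", data = df,
                             num.trees = num_trees, probability = TRUE,
                             seed = seed, num.threads = 1)
    structure(list(task = task, forest = forest, recipe = recipe,
                   num_trees = num_trees, seed = seed),
              class = "pixel_model")
  }
  list(eye = fit(eye_x, eye_y, "eye"), facet = fit(fac_x, fac_y, "facet"))
}

#' @export
print.pixel_model <- function(x, ...) {
  cat(sprintf("<pixel_model> task '%s', %d trees, %d features\n",
              x$task, x$num_trees, length(x$recipe$feature_names)))
  invisible(x)
}

#' Predict eye and facet probability maps
#'
#' Applies the two trained pixel classifiers to an image and derives the
#' binary eye mask by Otsu thresholding of the eye probability map.
#'
#' @param image Grayscale matrix in `[0, 1]`.
#' @param eye_model,facet_model `pixel_model` objects from [train_models]
#'   sharing one feature recipe.
#' @return A `probability_maps` object: `eye_prob`, `facet_prob` (matrices in
#'   `[0, 1]`) and `eye_mask` (logical matrix).
#' @export
predict_maps <- function(image, eye_model, facet_model) {
  stopifnot(inherits(eye_model, "pixel_model"),
            inherits(facet_model, "pixel_model"))
  if (!identical(eye_model$recipe, facet_model$recipe))
    stop("feature recipe mismatch between models")
  fs <- extract_features(image, eye_model$recipe)
  df <- as.data.frame(matrix(fs, ncol = dim(fs)[3],
                             dimnames = list(NULL, dimnames(fs)[[3]])))
  pe <- predict(eye_model$forest, data = df, num.threads = 1)$predictions
  pf <- predict(facet_model$forest, data = df, num.threads = 1)$predictions
  eye_prob <- matrix(pe[, "eye"], nrow(image))
  facet_prob <- matrix(pf[, "interior"], nrow(image))
  probability_maps(eye_prob, facet_prob)
}

#' Construct a probability-maps object
#'
#' @param eye_prob,facet_prob Matrices in `[0, 1]`, same dimensions.
#' @param eye_mask Optional logical matrix; computed by [eye_mask_from_prob]
#'   when omitted.
#' @return A `probability_maps` object.
#' @export
probability_maps <- function(eye_prob, facet_prob, eye_mask = NULL) {
  stopifnot(is.matrix(eye_prob), is.matrix(facet_prob),
            all(dim(eye_prob) == dim(facet_prob)))
  if (is.null(eye_mask)) eye_mask <- eye_mask_from_prob(eye_prob)
  stopifnot(all(dim(eye_mask) == dim(eye_prob)))
  structure(list(eye_prob = eye_prob, facet_prob = facet_prob,
                 eye_mask = eye_mask > 0),
            class = "probability_maps")
}

#' @export
print.probability_maps <- function(x, ...) {
  cat(sprintf("<probability_maps> %d x %d px, eye mask area %d px\n",
              ncol(x$eye_prob), nrow(x$eye_prob), sum(x$eye_mask)))
  invisible(x)
}

#' Otsu threshold of a sample
#'
#' Histogram-based Otsu threshold: the cut maximizing the between-class
#' variance over all bin boundaries of a 256-bin histogram of the values.
#'
#' @param x Numeric vector (or matrix) of values; at least 2 distinct values.
#' @param n_bins Number of histogram bins (default 256).
#' @return The threshold value (a bin boundary strictly inside the data range).
#' @export
otsu_threshold <- function(x, n_bins = 256) {
  x <- as.vector(x)
  x <- x[is.finite(x)]
  r <- range(x)
  if (length(x) < 2 || r[1] == r[2])
    stop("otsu_threshold: constant input, no threshold exists")
  breaks <- seq(r[1], r[2], length.out = n_bins + 1)
  counts <- tabulate(pmin(pmax(findInterval(x, breaks, all.inside = TRUE), 1L),
                          n_bins), nbins = n_bins)
  mids <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  k <- otsu_split(counts, mids)
  breaks[k + 1L]
}

#' Otsu threshold of a histogram
#'
#' @param counts Non-negative bin counts.
#' @param mids Bin center values (same length, increasing).
#' @return Index `k` of the last bin of the lower class: the split maximizing
#'   the between-class variance puts bins `1..k` below and `k+1..n` above.
#' @export
otsu_split <- function(counts, mids = seq_along(counts)) {
  stopifnot(length(counts) == length(mids), length(counts) >= 2)
  counts <- as.numeric(counts)
  n <- sum(counts)
  if (n <= 0 || sum(counts > 0) < 2)
    stop("otsu_split: need mass in at least two bins")
  W0 <- cumsum(counts)[-length(counts)]
  M0 <- cumsum(counts * mids)[-length(counts)]
  W1 <- n - W0
  M1 <- sum(counts * mids) - M0
  # between-class variance, up to the constant factor 1/n^3:
  # w0*w1*(mu0-mu1)^2 = (M0*W1 - M1*W0)^2 / (W0*W1*n)
  bcv <- ifelse(W0 > 0 & W1 > 0, (M0 * W1 - M1 * W0)^2 / (W0 * W1), -Inf)
  which.max(bcv)  # ties: lowest split, deterministic
}

#' Binary eye mask from the eye probability map
#'
#' Thresholds the eye probability map with the Otsu algorithm, keeps the
#' largest connected component and fills interior holes.
#'
#' @param eye_prob Matrix in `[0, 1]`.
#' @return Logical matrix.
#' @export
eye_mask_from_prob <- function(eye_prob) {
  thr <- otsu_threshold(eye_prob)
  mask <- eye_prob >= thr
  if (!any(mask)) stop("empty eye mask after thresholding")
  lab <- as.matrix(EBImage::bwlabel(mask * 1))
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  mask <- lab == keep
  mask <- as.matrix(EBImage::fillHull(mask * 1)) > 0
  mask
}
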