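#' Build the three-circle ("Mickey") template
#'
#' An `m x m` template of three identical filled circles of radius `0.225*m`
#' whose centers form an equilateral triangle of side `0.5*m`: two "ears"
#' (the known adjacent ommatidia) and one "face" (the candidate). The binary
#' pattern is smoothed with a 2D Gaussian of `sigma = m/20`; pixels outside
#' the union of the circles dilated by `0.05*m` form an ignore region (NaN)
#' that is never scored, avoiding interference from surrounding ommatidia.
#'
#' @param m Template side length in pixels (>= 20 so that `sigma >= 1`).
#' @return A `mickey_template`: list with `m`, `image` (matrix with NaN
#'   ignore region), `anchors` (3 x 2 matrix, rows ear1, ear2, face, template
#'   pixel coordinates) and precomputed non-NaN pixel lists.
#' @export
build_mickey_template <- function(m) {
  m <- as.integer(round(m))
  if (m < 20) stop("m too small for sigma = m/20 smoothing (need m >= 20)")
  r <- 0.225 * m
  side <- 0.5 * m
  h <- side * sqrt(3) / 2
  margin <- (m - h - 2 * r) / 2
  ear_y <- margin + r
  face_y <- ear_y + h
  # x positions centered on the pixel-grid mirror axis (m - 1) / 2 so the
  # discrete template is exactly symmetric under swapping the two ears
  cx <- (m - 1) / 2
  anchors <- rbind(ear1 = c(cx - 0.25 * m, ear_y),
                   ear2 = c(cx + 0.25 * m, ear_y),
                   face = c(cx, face_y))
  xs <- matrix(rep(0:(m - 1), each = m), m)    # [row=y+1, col=x+1] -> x
  ys <- matrix(rep(0:(m - 1), times = m), m)   # -> y
  dmin <- matrix(Inf, m, m)
  inside <- matrix(FALSE, m, m)
  for (k in 1:3) {
    d <- sqrt((xs - anchors[k, 1])^2 + (ys - anchors[k, 2])^2)
    dmin <- pmin(dmin, d)
    inside <- inside | (d <= r)
  }
  img <- gblur_rep(inside * 1, m / 20)
  img[dmin > r + 0.05 * m] <- NA_real_
  keep <- which(!is.na(img))
  structure(list(m = m, image = img, anchors = anchors,
                 tx = xs[keep], ty = ys[keep], tvals = img[keep],
                 sum_t2 = sum(img[keep]^2)),
            class = "mickey_template")
}

#' @export
print.mickey_template <- function(x, ...) {
  cat(sprintf("<mickey_template> m = %d px, %d scored px (%.0f%% ignored)\n",
              x$m, length(x$tvals),
              100 * (1 - length(x$tvals) / x$m^2)))
  invisible(x)
}

#' Affine map from template anchors to image points
#'
#' The unique affine transform sending the template's three circle centers
#' exactly onto the given image positions; every non-NaN template pixel
#' `(i, j)` then maps to image coordinate `A %*% c(i, j) + b`.
#'
#' @param template A [mickey_template][build_mickey_template].
#' @param ear1,ear2,face Target image positions `c(x, y)`.
#' @return List with `A` (2 x 2 linear part), `b` (offset) and `slant`
#'   (apparent tilt in degrees from normal view, from the singular values of
#'   `A`).
#' @export
affine_from_anchors <- function(template, ear1, ear2, face) {
  stopifnot(inherits(template, "mickey_template"))
  tgt <- rbind(ear1, ear2, face)
  M <- cbind(template$anchors, 1)
  area2 <- abs((tgt[2, 1] - tgt[1, 1]) * (tgt[3, 2] - tgt[1, 2]) -
               (tgt[3, 1] - tgt[1, 1]) * (tgt[2, 2] - tgt[1, 2]))
  if (area2 < 1e-9) stop("collinear target points: singular transform")
  cf <- solve(M, tgt)  # 3 x 2 columns (x, y)
  A <- t(cf[1:2, ])
  b <- cf[3, ]
  list(A = A, b = b,
       slant = slant_from_linear(A[1, 1], A[1, 2], A[2, 1], A[2, 2]))
}

#' Apply an affine transform to points
#'
#' @param tr List with `A` and `b` from [affine_from_anchors].
#' @param pts n x 2 matrix (or length-2 vector) of template coordinates.
#' @return n x 2 matrix of image coordinates.
#' @export
apply_affine <- function(tr, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  t(tr$A %*% t(pts) + tr$b)
}

#' Template objective at a single pose
#'
#' The squared-error objective between the facet probability map and the
#' affinely transformed template,
#' `Delta = sum((I_prob(A(i,j)) - theta * I_mouse(i,j))^2)` over the non-NaN
#' template pixels, with the brightness parameter `theta` free. When `theta`
#' is `NULL` it is set to its closed-form least-squares optimum
#' `sum(p*t) / sum(t^2)`.
#'
#' @param facet_prob Facet probability map (matrix).
#' @param template A [mickey_template][build_mickey_template].
#' @param ear1,ear2,face Image positions `c(x, y)` the anchors map onto.
#' @param theta Brightness parameter; `NULL` for the closed-form optimum.
#' @return List with `delta`, `theta` and `slant`.
#' @export
mickey_objective <- function(facet_prob, template, ear1, ear2, face,
                             theta = NULL) {
  s <- cpp_mickey_sample(facet_prob, template$tvals, template$tx, template$ty,
                         template$anchors, as.numeric(ear1),
                         as.numeric(ear2), as.numeric(face))
  if (is.null(theta)) theta <- sum(s$p * s$t) / sum(s$t^2)
  list(delta = sum((s$p - theta * s$t)^2), theta = theta, slant = s$slant)
}

#' Configuration for candidate fitting and grid expansion
#'
#' @param theta_min Minimum closed-form brightness parameter for a candidate
#'   to count as a facet (rejects fits landing on near-empty probability
#'   regions). Default 0.1.
#' @param min_view_angle Minimum angle (degrees) between the viewing axis and
#'   the facet plane; candidates steeper than this (slant > 90 - 20 = 70 deg
#'   from normal) are rejected. Default 20.
#' @param slant_tol Maximum difference (degrees) between the candidate's
#'   slant and that of the mirrored ommatidium. Default 30.
#' @param search_frac Radius of the candidate search disk as a fraction of
#'   `L_grid` (the hard rejection distance). Default 0.3.
#' @param accept_frac Acceptance radius around the predicted position as a
#'   fraction of `L_grid`. Default 0.5.
#' @param max_add Cap on the number of ommatidia added by one expansion.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(theta_min = 0.1, min_view_angle = 20, slant_tol = 30,
                       search_frac = 0.3, accept_frac = 0.5, max_add = Inf) {
  structure(list(theta_min = theta_min, min_view_angle = min_view_angle,
                 slant_tol = slant_tol, search_frac = search_frac,
                 accept_frac = accept_frac, max_add = max_add),
            class = "fit_config")
}

as_pos <- function(p) {
  if (is.list(p) || is.data.frame(p)) c(p$x, p$y) else as.numeric(p)
}

rejected_fit <- function(predicted) {
  structure(list(pos = c(NA_real_, NA_real_), delta = Inf, theta = NA_real_,
                 slant = NA_real_, transform = NULL, predicted = predicted),
            class = "candidate_fit")
}

#' Fit a candidate ommatidium to the facet probability map
#'
#' Searches face positions on the integer pixel grid within a disk of radius
#' `search_frac * L_grid` around the mirror prediction, scoring each pose by
#' the template objective (closed-form brightness), then refines the best
#' pose to sub-pixel precision by parabolic interpolation. The fit is
#' rejected (`delta = Inf`) when the best pose is too dim
#' (`theta < theta_min`), too steep (less than `min_view_angle` degrees
#' between the viewing axis and the facet plane), or when its slant differs
#' from that of the mirrored ommatidium by more than `slant_tol`.
#'
#' @param facet_prob Facet probability map (matrix).
#' @param ear1,ear2 Known adjacent ommatidia (`c(x, y)` or rows with `x`,
#'   `y`): the template "ears".
#' @param predicted Mirror-predicted face position `c(x, y)`.
#' @param omtd1 The mirrored ommatidium (for the slant-difference constraint);
#'   may be `NULL` or have `slant = NA` to skip that constraint.
#' @param L_grid Current average grid edge length (px).
#' @param template Optional [mickey_template][build_mickey_template]; by
#'   default built with `m = max(20, round(2 * L_grid))` so the circle radius
#'   `0.225*m` matches the facet radius.
#' @param config A [fit_config].
#' @return A `candidate_fit`: list with `pos`, `delta`, `theta`, `slant`,
#'   `transform` and `predicted`.
#' @export
fit_candidate <- function(facet_prob, ear1, ear2, predicted, omtd1 = NULL,
                          L_grid, template = NULL, config = fit_config()) {
  predicted <- as.numeric(predicted)
  H <- nrow(facet_prob); W <- ncol(facet_prob)
  if (predicted[1] < 0 || predicted[1] > W - 1 ||
      predicted[2] < 0 || predicted[2] > H - 1)
    stop("predicted position outside image")
  if (is.null(template))
    template <- build_mickey_template(max(20, round(2 * L_grid)))
  e1 <- as_pos(ear1); e2 <- as_pos(ear2)
  rad <- config$search_frac * L_grid
  ir <- floor(rad)
  offs <- expand.grid(dx = -ir:ir, dy = -ir:ir)
  offs <- offs[offs$dx^2 + offs$dy^2 <= rad^2, , drop = FALSE]
  cx <- predicted[1] + offs$dx
  cy <- predicted[2] + offs$dy
  sc <- cpp_mickey_scan(facet_prob, template$tvals, template$tx, template$ty,
                        template$anchors, e1, e2, cx, cy)
  delta <- sc$delta
  delta[sc$theta < config$theta_min] <- Inf
  if (all(!is.finite(delta))) return(rejected_fit(predicted))
  k <- which.min(delta)
  # parabolic sub-pixel refinement along x and y using integer-grid neighbors
  refine <- function(dd) {
    num <- (dd[1] - dd[3]) / 2
    den <- dd[1] - 2 * dd[2] + dd[3]
    if (!all(is.finite(dd)) || den <= 0) 0 else max(-0.5, min(0.5, num / den))
  }
  find_off <- function(dx, dy) {
    j <- which(offs$dx == dx & offs$dy == dy)
    if (length(j) == 1) delta[j] else Inf
  }
  dx0 <- offs$dx[k]; dy0 <- offs$dy[k]
  sx <- refine(c(find_off(dx0 - 1, dy0), delta[k], find_off(dx0 + 1, dy0)))
  sy <- refine(c(find_off(dx0, dy0 - 1), delta[k], find_off(dx0, dy0 + 1)))
  best <- predicted + c(dx0 + sx, dy0 + sy)
  if (sqrt(sum((best - predicted)^2)) > rad)
    best <- predicted + c(dx0, dy0)
  ob <- mickey_objective(facet_prob, template, e1, e2, best)
  if (ob$delta > delta[k]) {  # refinement must not worsen the objective
    best <- predicted + c(dx0, dy0)
    ob <- list(delta = delta[k], theta = sc$theta[k], slant = sc$slant[k])
  }
  if (ob$theta < config$theta_min) return(rejected_fit(predicted))
  if ((90 - ob$slant) < config$min_view_angle) return(rejected_fit(predicted))
  s1 <- if (is.null(omtd1)) NA_real_ else
    (if (is.list(omtd1) || is.data.frame(omtd1)) omtd1$slant else NA_real_)
  if (is.finite(s1) && abs(ob$slant - s1) > config$slant_tol)
    return(rejected_fit(predicted))
  structure(list(pos = best, delta = ob$delta, theta = ob$theta,
                 slant = ob$slant,
                 transform = affine_from_anchors(template, e1, e2, best),
                 predicted = predicted),
            class = "candidate_fit")
}

#' @export
print.candidate_fit <- function(x, ...) {
  if (is.finite(x$delta))
    cat(sprintf("<candidate_fit> pos (%.2f, %.2f), delta %.4g, theta %.3f, slant %.1f deg\n",
                x$pos[1], x$pos[2], x$delta, x$theta, x$slant))
  else cat("<candidate_fit> rejected (delta = Inf)\n")
  invisible(x)
}
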