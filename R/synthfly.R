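#' Specification of a synthetic compound eye
#'
#' Parameters of the synthetic eye generator: a hexagonal facet lattice laid
#' on a spherical cap, orthographically projected to the image plane, with
#' optional planted spacing gradient (an "acute zone" of enlarged facets),
#' per-facet lens shading and specular reflection, inter-ommatidial
#' bristles, background texture, noise and (optionally) a multifocal stack.
#'
#' Defaults emulate a lateral brightfield macroscope view of a
#' *D. melanogaster* eye: ~800 facets of 16 um spacing at the apex, the
#' visible cap spanning 60 degrees from the apex, 1 um/px sampling and an
#' 8 um focal step.
#'
#' @param n_target Approximate facet count in `[7, 20000]`.
#' @param facet_spacing Facet center spacing at the eye apex (um).
#' @param cap_angle Angular radius of the visible cap (degrees, in (0, 90]).
#' @param sphere_radius Eye radius (um); derived from `n_target` when `NULL`.
#' @param spacing_gradient `NULL`, or a list with `amplitude` (fractional
#'   spacing increase at the zone center, e.g. 0.2), `width_frac` (Gaussian
#'   width as a fraction of the cap's geodesic radius), `offset_frac`
#'   (zone-center offset from the apex as a fraction of the geodesic radius)
#'   and `direction` (image-space unit vector from apex toward the zone).
#' @param bristle_density Fraction of eligible lattice vertices carrying a
#'   bristle (bristles sit at alternating vertices on the real eye).
#' @param bristle_length Bristle length in um.
#' @param reflection_strength Specular highlight amplitude (0 disables).
#' @param noise_sd Additive Gaussian noise sd.
#' @param px_size Pixel size (um/px).
#' @param n_planes Number of focal planes (0 = single SEM-like 2D image).
#' @param z_step Focal step (um).
#' @param jitter_sd Seeded positional jitter of the facet centers on the eye
#'   surface (um); models the small natural irregularity of the lattice.
#' @param slant_cutoff Facets tilted beyond this angle (degrees from normal
#'   view) are excluded from the ground truth as not visible.
#' @param anterior Image-space anterior direction (as in
#'   [recenter_and_orient]).
#' @param seed RNG seed for the stochastic rendering components.
#' @return A `synthetic_eye_spec` object.
#' @export
synthetic_eye_spec <- function(n_target = 800, facet_spacing = 16,
                               cap_angle = 60, sphere_radius = NULL,
                               spacing_gradient = NULL,
                               bristle_density = 0.5, bristle_length = 10,
                               reflection_strength = 0.3, noise_sd = 0.02,
                               px_size = 1, n_planes = 0, z_step = 8,
                               jitter_sd = 0.3, slant_cutoff = 75,
                               anterior = "right", seed = 1) {
  stopifnot(n_target >= 7, n_target <= 20000, facet_spacing > 0,
            cap_angle > 0, cap_angle <= 90, px_size > 0, z_step > 0,
            jitter_sd >= 0)
  if (is.null(sphere_radius)) {
    # the lattice is laid out in the equal-area azimuthal plane, so the facet
    # count is the number of lattice cells (area sqrt(3)/2 * s^2) in the
    # planar disc of radius 2 R sin(cap_angle / 2)
    tc <- min(cap_angle, slant_cutoff) * pi / 180
    sphere_radius <- facet_spacing *
      sqrt(n_target * (sqrt(3) / 2) / pi) / (2 * sin(tc / 2))
  }
  structure(list(n_target = n_target, facet_spacing = facet_spacing,
                 cap_angle = cap_angle, sphere_radius = sphere_radius,
                 spacing_gradient = spacing_gradient,
                 bristle_density = bristle_density,
                 bristle_length = bristle_length,
                 reflection_strength = reflection_strength,
                 noise_sd = noise_sd, px_size = px_size,
                 n_planes = n_planes, z_step = z_step,
                 jitter_sd = jitter_sd, slant_cutoff = slant_cutoff,
                 anterior = anterior, seed = seed),
            class = "synthetic_eye_spec")
}

dir_vec <- function(d) {
  dirs <- list(right = c(1, 0), left = c(-1, 0), up = c(0, -1), down = c(0, 1))
  v <- if (is.character(d)) dirs[[d]] else as.numeric(d)
  v / sqrt(sum(v^2))
}

erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1

#' Generate the ground-truth facet lattice of a synthetic eye
#'
#' Lays a hexagonal lattice (apex spacing `facet_spacing`, optionally warped
#' by the planted spacing gradient) on the spherical cap via the
#' azimuthal-equidistant surface parameterization and projects it
#' orthographically onto the image plane. Peripheral facets are foreshortened
#' (their projected spacing shrinks toward the rim) and facets tilted beyond
#' `slant_cutoff` are excluded.
#'
#' @param spec A [synthetic_eye_spec].
#' @return An `eye_truth` object: `centers` (n x 2 image positions, px),
#'   `hex` (n x 2 integer lattice coordinates), `z` (altitude, um, 0 at the
#'   lowest included facet), `slant` (degrees), `eye_mask` (logical matrix),
#'   `width`/`height` (px), `spacing_px`, `anterior`, `gradient_center`
#'   (image position of the planted spacing maximum, or `NULL`), `spec`.
#' @export
generate_lattice <- function(spec) {
  stopifnot(inherits(spec, "synthetic_eye_spec"))
  s <- spec$facet_spacing
  R <- spec$sphere_radius
  a_max <- min(spec$cap_angle, spec$slant_cutoff) * pi / 180
  # Lambert equal-area azimuthal parameterization of the cap: planar radius
  # u maps to polar angle alpha = 2 asin(u / 2R). Radial spacing is
  # stretched by 1/cos(alpha/2) and tangential spacing compressed by
  # cos(alpha/2), so the mean facet spacing on the surface stays nearly
  # uniform (a hexagonal lattice cannot be laid isometrically on a sphere).
  rg_max <- 2 * R * sin(a_max / 2)
  nring <- ceiling(rg_max / s * 1.4) + 2
  ij <- expand.grid(i = -nring:nring, j = -nring:nring)
  ux <- ij$i * s + ij$j * s / 2
  uy <- ij$j * s * sqrt(3) / 2
  grad_center <- NULL
  if (!is.null(spec$spacing_gradient)) {
    g <- spec$spacing_gradient
    dv <- dir_vec(g$direction %||% c(1, 1))
    c0 <- g$offset_frac * rg_max * dv
    w <- g$width_frac * rg_max
    rx <- ux - c0[1]; ry <- uy - c0[2]
    r <- sqrt(rx^2 + ry^2)
    h <- r + g$amplitude * w * sqrt(pi / 2) * erf(r / (sqrt(2) * w))
    f <- ifelse(r > 0, h / r, 1 + g$amplitude)
    ux <- c0[1] + rx * f
    uy <- c0[2] + ry * f
    grad_center <- c0
  }
  if (spec$jitter_sd > 0)
    with_seed(spec$seed, {
      ux <- ux + rnorm(length(ux), 0, spec$jitter_sd)
      uy <- uy + rnorm(length(uy), 0, spec$jitter_sd)
    })
  rg <- sqrt(ux^2 + uy^2)
  keep <- rg <= rg_max
  ij <- ij[keep, , drop = FALSE]
  ux <- ux[keep]; uy <- uy[keep]; rg <- rg[keep]
  if (nrow(ij) < 7) stop("specification yields fewer than 7 facets")
  alpha <- 2 * asin(pmin(1, rg / (2 * R)))
  phi <- atan2(uy, ux)
  rho <- R * sin(alpha)
  x3 <- rho * cos(phi); y3 <- rho * sin(phi); z3 <- R * cos(alpha)
  r_img <- R * sin(a_max) / spec$px_size
  pad <- ceiling(2 * s / spec$px_size)
  W <- 2L * (ceiling(r_img) + pad) + 1L
  cx <- (W - 1) / 2
  x <- x3 / spec$px_size + cx
  y <- y3 / spec$px_size + cx
  z <- z3 - min(z3)
  xs <- matrix(rep(0:(W - 1), each = W), W)
  ys <- matrix(rep(0:(W - 1), times = W), W)
  # eye region edge: the facet surface extends half a facet beyond the last
  # center ring on the sphere, foreshortened by the orthographic projection
  r_mask <- R * sin(min(a_max + 0.5 * s / R, pi / 2)) / spec$px_size
  mask <- (xs - cx)^2 + (ys - cx)^2 <= r_mask^2
  gc_img <- if (is.null(grad_center)) NULL else {
    gr <- sqrt(sum(grad_center^2))
    ga <- 2 * asin(min(1, gr / (2 * R)))
    gd <- if (gr > 0) grad_center / gr else c(0, 0)
    R * sin(ga) * gd / spec$px_size + cx
  }
  structure(list(centers = cbind(x = x, y = y),
                 hex = cbind(x_hex = as.integer(ij$i),
                             y_hex = as.integer(ij$j)),
                 z = z, slant = alpha * 180 / pi, eye_mask = mask,
                 width = W, height = W,
                 spacing_px = s / spec$px_size,
                 anterior = spec$anterior,
                 gradient_center = gc_img, spec = spec),
            class = "eye_truth")
}

#' @export
print.eye_truth <- function(x, ...) {
  cat(sprintf("<eye_truth> %d facets, %d x %d px, apex spacing %.1f px\n",
              nrow(x$centers), x$width, x$height, x$spacing_px))
  invisible(x)
}

#' Ground-truth lattice of a flat hexagonal patch
#'
#' A perfectly planar patch of `rings` concentric rings around a central
#' facet (`3*rings*(rings+1) + 1` facets in total), useful for exercising the
#' grid machinery without curvature.
#'
#' @param rings Number of rings (>= 1).
#' @param spacing_px Center spacing in pixels.
#' @param jitter_sd Positional jitter sd in pixels (default 0).
#' @param seed Seed for the jitter.
#' @return An `eye_truth` object (flat: `z = 0`, `slant = 0`).
#' @export
flat_patch_truth <- function(rings, spacing_px = 14, jitter_sd = 0, seed = 1) {
  ij <- expand.grid(i = -rings:rings, j = -rings:rings)
  ij <- ij[abs(ij$i + ij$j) <= rings & abs(ij$i) <= rings &
             abs(ij$j) <= rings, , drop = FALSE]
  s <- spacing_px
  x0 <- ij$i * s + ij$j * s / 2
  y0 <- ij$j * s * sqrt(3) / 2
  if (jitter_sd > 0)
    with_seed(seed, {
      x0 <- x0 + rnorm(length(x0), 0, jitter_sd)
      y0 <- y0 + rnorm(length(y0), 0, jitter_sd)
    })
  pad <- 2 * s
  W <- 2L * ceiling(max(abs(c(x0, y0))) + pad) + 1L
  cx <- (W - 1) / 2
  x <- x0 + cx; y <- y0 + cx
  xs <- matrix(rep(0:(W - 1), each = W), W)
  ys <- matrix(rep(0:(W - 1), times = W), W)
  r_mask <- max(sqrt(x0^2 + y0^2)) + 0.5 * s
  mask <- (xs - cx)^2 + (ys - cx)^2 <= r_mask^2
  structure(list(centers = cbind(x = x, y = y),
                 hex = cbind(x_hex = as.integer(ij$i),
                             y_hex = as.integer(ij$j)),
                 z = rep(0, nrow(ij)), slant = rep(0, nrow(ij)),
                 eye_mask = mask, width = W, height = W,
                 spacing_px = s, anterior = "right",
                 gradient_center = NULL,
                 spec = NULL),
            class = "eye_truth")
}

#' Convert a ground truth to a hexgrid
#'
#' @param gt An `eye_truth`.
#' @return A `hexgrid` carrying the true hex coordinates, positions,
#'   altitudes and slants (origin `"auto"`).
#' @export
truth_as_grid <- function(gt) {
  stopifnot(inherits(gt, "eye_truth"))
  g <- new_hexgrid(data.frame(
    id = seq_len(nrow(gt$centers)),
    x_hex = gt$hex[, 1], y_hex = gt$hex[, 2],
    x = gt$centers[, 1], y = gt$centers[, 2],
    z = gt$z, slant = gt$slant, origin = "auto",
    stringsAsFactors = FALSE))
  if (!is.null(gt$spec)) attr(g, "px_size") <- gt$spec$px_size
  g
}

# nearest-facet geometry of the canvas: label, distance to nearest and
# second-nearest center (cached on the truth object by callers if needed)
truth_geometry <- function(gt) {
  cpp_nearest2(gt$centers[, 1], gt$centers[, 2], gt$width, gt$height)
}

# interior indicator: within the facet disc and away from the Voronoi ridge
truth_interior <- function(gt, geom, halfwidth_frac = 0.12) {
  tt <- (geom$d2 - geom$d1) / 2
  (tt > halfwidth_frac * gt$spacing_px) & (geom$d1 < 0.45 * gt$spacing_px)
}

#' Ideal probability maps of a synthetic eye
#'
#' Noise-free stand-ins for the classifier output, used to exercise the grid
#' expansion in isolation: the facet probability map is a Gaussian-smoothed
#' indicator of the facet interiors (sigma = 0.1 x apex spacing), the eye
#' probability map a smoothed indicator of the eye region.
#'
#' @param gt An `eye_truth` from [generate_lattice] or [flat_patch_truth].
#' @return A [probability_maps] object (its mask is recomputed from the
#'   smoothed eye probability by [eye_mask_from_prob]).
#' @export
ideal_probability_maps <- function(gt) {
  stopifnot(inherits(gt, "eye_truth"))
  geom <- truth_geometry(gt)
  sig <- 0.1 * gt$spacing_px
  fp <- gblur_rep(truth_interior(gt, geom) * 1, sig)
  ep <- gblur_rep(gt$eye_mask * 1, sig)
  probability_maps(pmin(pmax(ep, 0), 1), pmin(pmax(fp, 0), 1))
}

#' Render a synthetic eye image (or focal stack)
#'
#' Facets are rendered as shaded convex domes separated by dark Voronoi
#' boundaries, with a slant-dependent specular highlight offset from each
#' facet center, dark inter-ommatidial bristles, textured background outside
#' the eye and additive Gaussian noise. With `n_planes > 0` a multifocal
#' stack is produced in which each pixel is defocus-blurred in proportion to
#' the distance between its facet's altitude and the focal plane.
#'
#' @param gt An `eye_truth`.
#' @param spec The generating [synthetic_eye_spec] (defaults to `gt$spec`).
#' @return A numeric image matrix, or an [image_stack][new_image_stack] when
#'   `spec$n_planes > 0`.
#' @export
render_image <- function(gt, spec = gt$spec) {
  stopifnot(inherits(gt, "eye_truth"), inherits(spec, "synthetic_eye_spec"))
  geom <- truth_geometry(gt)
  s_px <- gt$spacing_px
  W <- gt$width; H <- gt$height
  out <- NULL
  lab <- geom$label
  rho <- (geom$d1 + geom$d2) / 2
  tt <- (geom$d2 - geom$d1) / 2
  cosf <- cos(gt$slant * pi / 180)
  shade <- 0.5 + 0.5 * cosf[lab]
  dome <- pmax(0, 1 - (geom$d1 / pmax(rho, 1e-6))^2)
  img <- (0.35 + 0.45 * dome) * shade
  img <- img * pmin(1, tt / (0.12 * s_px))^0.7  # dark facet boundaries
  with_seed(spec$seed + 1, {
    if (spec$reflection_strength > 0) {
      # specular highlight displaced from the center along the local outward
      # radial direction, proportional to the facet tilt
      cx <- (W - 1) / 2
      n <- nrow(gt$centers)
      rad <- gt$centers - cx
      rn <- sqrt(rowSums(rad^2)); rn[rn == 0] <- 1
      hl <- gt$centers + rad / rn * (0.35 * s_px) * sin(gt$slant * pi / 180)
      dh2 <- (matrix(rep(0:(W - 1), each = H), H) - hl[lab, 1])^2 +
             (matrix(rep(0:(H - 1), times = W), H) - hl[lab, 2])^2
      img <- img + spec$reflection_strength *
        exp(-dh2 / (2 * (0.25 * pmax(rho, 1))^2))
    }
    if (spec$bristle_density > 0) {
      # bristles grow from alternating lattice vertices; approximate with one
      # bristle per selected facet, rooted at a Voronoi vertex
      alt <- (gt$hex[, 1] - gt$hex[, 2]) %% 2 == 0
      cand <- which(alt)
      nb <- max(0L, round(spec$bristle_density * length(cand)))
      pick <- if (nb >= length(cand)) cand else sort(sample(cand, nb))
      blen <- spec$bristle_length / spec$px_size
      for (f in pick) {
        az <- runif(1, 0, 2 * pi)
        base <- gt$centers[f, ] + 0.5 * s_px * c(cos(az), sin(az))
        ang <- az + runif(1, -0.5, 0.5)
        tseq <- seq(0, blen, by = 0.5)
        bx <- round(base[1] + tseq * cos(ang))
        by <- round(base[2] + tseq * sin(ang))
        ok <- bx >= 0 & bx < W & by >= 0 & by < H
        idx <- cbind(by[ok] + 1L, bx[ok] + 1L)
        img[idx] <- img[idx] * 0.3
      }
    }
    bg <- 0.3 + 0.15 * gblur_rep(matrix(runif(H * W), H), 6)
    img[!gt$eye_mask] <- bg[!gt$eye_mask]
    if (spec$noise_sd > 0) {
      if (spec$n_planes > 0) {
        noise_planes <- lapply(seq_len(spec$n_planes), function(k)
          matrix(rnorm(H * W, 0, spec$noise_sd), H))
      } else {
        img <- img + matrix(rnorm(H * W, 0, spec$noise_sd), H)
      }
    } else if (spec$n_planes > 0) {
      noise_planes <- lapply(seq_len(spec$n_planes), function(k)
        matrix(0, H, W))
    }
    img <- pmin(pmax(img, 0), 1)
    if (spec$n_planes > 0) {
      zmap <- gt$z[lab]
      zmap[!gt$eye_mask] <- 0
      planes <- vector("list", spec$n_planes)
      blur_cache <- list()
      for (k in seq_len(spec$n_planes)) {
        zk <- (k - 1) * spec$z_step
        lev <- pmin(8L, as.integer(round(abs(zmap - zk) / spec$z_step)))
        pk <- matrix(0, H, W)
        for (l in sort(unique(as.vector(lev)))) {
          key <- as.character(l)
          if (is.null(blur_cache[[key]]))
            blur_cache[[key]] <- if (l == 0) img else
              gblur_rep(img, 1.2 * l)
          sel <- lev == l
          pk[sel] <- blur_cache[[key]][sel]
        }
        planes[[k]] <- pmin(pmax(pk + noise_planes[[k]], 0), 1)
      }
      out <- new_image_stack(planes, spec$z_step)
    }
  })
  out %||% img
}

#' Derive a training annotation from a synthetic ground truth
#'
#' Emulates the manual training step: the eye outline plus a seeded sample of
#' facets (default 150, drawn across all eye regions) segmented as labeled
#' masks.
#'
#' @param gt An `eye_truth`.
#' @param n_facets Number of annotated facets.
#' @param seed Sampling seed.
#' @param image_id Identifier.
#' @return A [training_annotation].
#' @export
annotation_from_truth <- function(gt, n_facets = 150, seed = 1,
                                  image_id = "synthetic") {
  stopifnot(inherits(gt, "eye_truth"))
  geom <- truth_geometry(gt)
  interior <- truth_interior(gt, geom)
  n <- nrow(gt$centers)
  n_facets <- min(n_facets, n)
  # stratified over radial position so all eye regions are represented
  cx <- (gt$width - 1) / 2
  r <- sqrt((gt$centers[, 1] - cx)^2 + (gt$centers[, 2] - cx)^2)
  ord <- order(r)
  pick <- with_seed(seed, {
    strata <- split(ord, cut(seq_along(ord), breaks = 5, labels = FALSE))
    unlist(lapply(strata, function(s)
      sample(s, round(length(s) / length(ord) * n_facets))))
  })
  facet_label <- matrix(0L, gt$height, gt$width)
  sel <- interior & matrix(geom$label %in% pick, gt$height) & gt$eye_mask
  facet_label[sel] <- match(geom$label[sel], sort(unique(geom$label[sel])))
  training_annotation(image_id, eye_region = gt$eye_mask,
                      facet_label = facet_label)
}
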