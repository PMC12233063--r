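#' Assign altitudes to a grid from a depth-derived altitude map
#'
#' Each ommatidium's `z` (um) is read from the altitude map at its rounded
#' image position; the pixel size is recorded on the grid so that subsequent
#' 3D computations can convert `x`, `y` to micrometers.
#'
#' @param grid A `hexgrid`.
#' @param altitude Numeric matrix of altitudes in um (see [altitude_map]).
#' @param px_size Pixel size in um/px (no default: an acquisition property).
#' @return The grid with `z` filled in and attribute `px_size` set.
#' @export
assign_altitude <- function(grid, altitude, px_size) {
  stopifnot(inherits(grid, "hexgrid"), is.matrix(altitude),
            is.numeric(px_size), px_size > 0)
  xi <- as.integer(round(grid$omm$x)) + 1L
  yi <- as.integer(round(grid$omm$y)) + 1L
  if (any(xi < 1L | xi > ncol(altitude) | yi < 1L | yi > nrow(altitude)))
    stop("ommatidium position outside the altitude map")
  grid$omm$z <- altitude[cbind(yi, xi)]
  attr(grid, "px_size") <- px_size
  grid
}

#' Mean 3D spacing between each ommatidium and its hex-neighbors
#'
#' For every ommatidium, the mean Euclidean distance in 3D space (x, y scaled
#' by the pixel size; z in um) between its center and those of its
#' hex-adjacent neighbors. Because adjacent lenses are juxtaposed, this is a
#' proxy for the local ommatidial diameter.
#'
#' @param grid A `hexgrid`; `z` may be all zero/NA for a flat (2D) analysis.
#' @param px_size Pixel size in um/px; defaults to the grid's `px_size`
#'   attribute, or 1 (spacing then reported in pixel units).
#' @return A `spacing_map` data frame: `id`, `x_hex`, `y_hex`, `x`, `y`,
#'   `spacing` (um; NA for isolated ommatidia, which are flagged in the
#'   `isolated` column), `n_neighbors`.
#' @export
spacing_per_ommatidium <- function(grid, px_size = NULL) {
  stopifnot(inherits(grid, "hexgrid"))
  px_size <- px_size %||% attr(grid, "px_size") %||% 1
  omm <- grid$omm
  z <- ifelse(is.na(omm$z), 0, omm$z)
  idx <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(nrow(omm)))
    assign(hex_key(omm$x_hex[i], omm$y_hex[i]), i, envir = idx)
  spacing <- rep(NA_real_, nrow(omm))
  nn <- integer(nrow(omm))
  for (i in seq_len(nrow(omm))) {
    ds <- numeric(0)
    for (k in seq_len(nrow(HEX_OFFSETS))) {
      key <- hex_key(omm$x_hex[i] + HEX_OFFSETS[k, 1],
                     omm$y_hex[i] + HEX_OFFSETS[k, 2])
      if (exists(key, envir = idx, inherits = FALSE)) {
        j <- get(key, envir = idx)
        ds <- c(ds, sqrt(((omm$x[i] - omm$x[j]) * px_size)^2 +
                         ((omm$y[i] - omm$y[j]) * px_size)^2 +
                         (z[i] - z[j])^2))
      }
    }
    nn[i] <- length(ds)
    if (length(ds)) spacing[i] <- mean(ds)
  }
  out <- data.frame(id = omm$id, x_hex = omm$x_hex, y_hex = omm$y_hex,
                    x = omm$x, y = omm$y, spacing = spacing,
                    n_neighbors = nn, isolated = nn == 0L)
  class(out) <- c("spacing_map", class(out))
  out
}

#' Least-squares polynomial surface fit
#'
#' Fits a bivariate polynomial (default degree 3) to scattered values,
#' returning an evaluator, a rasterized map over the data's bounding box and
#' the location of the surface maximum within the convex hull of the data
#' (the zone of enlarged ommatidia when fitted to spacing values).
#'
#' @param positions n x 2 matrix of (x, y) positions.
#' @param values Numeric vector of length n.
#' @param degree Total polynomial degree (default 3).
#' @param raster_n Rasterization resolution per axis (default 101).
#' @return A `poly_surface`: list with `coef`, `degree`, `predict(x, y)`,
#'   `raster` (list `x`, `y`, `z`) and `peak` (`c(x, y)` of the in-hull
#'   maximum).
#' @export
fit_surface <- function(positions, values, degree = 3, raster_n = 101) {
  positions <- as.matrix(positions)
  keep <- is.finite(values) & is.finite(positions[, 1]) &
    is.finite(positions[, 2])
  positions <- positions[keep, , drop = FALSE]
  values <- values[keep]
  terms <- expand.grid(i = 0:degree, j = 0:degree)
  terms <- terms[terms$i + terms$j <= degree, , drop = FALSE]
  if (nrow(positions) < nrow(terms))
    stop("need at least ", nrow(terms), " points for degree ", degree)
  ctr <- colMeans(positions)
  scl <- max(apply(positions, 2, function(v) diff(range(v))), 1e-9) / 2
  design <- function(x, y) {
    u <- (x - ctr[1]) / scl; v <- (y - ctr[2]) / scl
    vapply(seq_len(nrow(terms)),
           function(k) u^terms$i[k] * v^terms$j[k], numeric(length(u)))
  }
  X <- design(positions[, 1], positions[, 2])
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("rank-deficient polynomial design")
  cf <- qr.coef(qrX, values)
  pred <- function(x, y) as.vector(design(x, y) %*% cf)
  rx <- seq(min(positions[, 1]), max(positions[, 1]), length.out = raster_n)
  ry <- seq(min(positions[, 2]), max(positions[, 2]), length.out = raster_n)
  gg <- expand.grid(x = rx, y = ry)
  zz <- pred(gg$x, gg$y)
  hull <- positions[chull(positions), , drop = FALSE]
  inh <- mgcv::in.out(rbind(hull, hull[1, ]), cbind(gg$x, gg$y))
  zin <- ifelse(inh, zz, -Inf)
  pk <- as.numeric(gg[which.max(zin), ])
  structure(list(coef = cf, degree = degree, predict = pred,
                 raster = list(x = rx, y = ry,
                               z = matrix(zz, raster_n, raster_n)),
                 peak = pk, residuals = values - pred(positions[, 1],
                                                      positions[, 2])),
            class = "poly_surface")
}

#' @export
print.poly_surface <- function(x, ...) {
  cat(sprintf("<poly_surface> degree %d, rms residual %.4g, peak (%.1f, %.1f)\n",
              x$degree, sqrt(mean(x$residuals^2)), x$peak[1], x$peak[2]))
  invisible(x)
}

# the 12 hex-lattice symmetries (6 rotations x optional axis swap), each a
# 2x2 integer matrix acting on (x_hex, y_hex) and preserving adjacency
hex_symmetries <- function() {
  rot <- matrix(c(0L, 1L, -1L, 1L), 2)  # (x, y) -> (-y, x + y), column-major
  out <- vector("list", 12)
  M <- diag(2L)
  for (k in 1:6) {
    out[[k]] <- M
    out[[k + 6]] <- M[, 2:1]  # followed by axis swap (reflection)
    M <- rot %*% M
  }
  out
}

#' Recenter the grid origin and orient the hexagonal axes
#'
#' Moves the hex origin to the center-most ommatidium (nearest the centroid
#' of all image positions) and applies the hex-lattice symmetry that makes
#' both hex coordinates of the most anterior ommatidium positive, so that the
#' column index `x_hex + y_hex` increases from posterior to anterior,
#' following the birth order of the R8 founder cells.
#'
#' @param grid A `hexgrid`.
#' @param anterior Image-space direction of the eye's anterior: one of
#'   `"right"`, `"left"`, `"up"`, `"down"` or a numeric `c(dx, dy)` vector
#'   (y axis points down).
#' @return The reindexed `hexgrid`, with attribute `orientation` recording
#'   the applied shift and symmetry.
#' @export
recenter_and_orient <- function(grid, anterior = "right") {
  stopifnot(inherits(grid, "hexgrid"), nrow(grid$omm) >= 1)
  dirs <- list(right = c(1, 0), left = c(-1, 0), up = c(0, -1),
               down = c(0, 1))
  avec <- if (is.character(anterior)) {
    if (!anterior %in% names(dirs)) stop("unknown anterior direction")
    dirs[[anterior]]
  } else as.numeric(anterior)
  omm <- grid$omm
  cen <- c(mean(omm$x), mean(omm$y))
  d2 <- (omm$x - cen[1])^2 + (omm$y - cen[2])^2
  ic <- which(d2 == min(d2))[1]
  h0 <- c(omm$x_hex[ic], omm$y_hex[ic])
  hx <- omm$x_hex - h0[1]
  hy <- omm$y_hex - h0[2]
  proj <- omm$x * avec[1] + omm$y * avec[2]
  ia <- which(proj == max(proj))[1]
  syms <- hex_symmetries()
  score <- vapply(syms, function(S) {
    h <- S %*% c(hx[ia], hy[ia])
    2 * (h[1] > 0 && h[2] > 0) + (h[1] >= 0 && h[2] >= 0)
  }, numeric(1))
  k <- which(score == max(score))[1]  # deterministic tie-break: fixed order
  S <- syms[[k]]
  hh <- S %*% rbind(hx, hy)
  omm$x_hex <- as.integer(hh[1, ])
  omm$y_hex <- as.integer(hh[2, ])
  out <- new_hexgrid(omm)
  attr(out, "px_size") <- attr(grid, "px_size")
  attr(out, "orientation") <- list(shift = h0, symmetry = S,
                                   anterior = avec, tie = sum(score == max(score)) > 1)
  out
}

#' Column profile of a reindexed grid
#'
#' The number of ommatidia in each column, where the column index
#' `x_hex + y_hex` reflects the birth order of ommatidial columns along the
#' anterior-posterior axis.
#'
#' @param grid A `hexgrid`, normally after [recenter_and_orient].
#' @return A `column_profile` data frame (`column_index`, `count`) with
#'   attributes `total` and `n_columns`.
#' @export
column_profile <- function(grid) {
  stopifnot(inherits(grid, "hexgrid"))
  ci <- grid$omm$x_hex + grid$omm$y_hex
  tb <- table(ci)
  out <- data.frame(column_index = as.integer(names(tb)),
                    count = as.integer(tb))
  out <- out[order(out$column_index), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("column_profile", class(out))
  attr(out, "total") <- nrow(grid$omm)
  attr(out, "n_columns") <- nrow(out)
  out
}

profile_as_vector <- function(p) {
  idx <- p$column_index
  v <- numeric(max(idx) - min(idx) + 1L)
  v[idx - min(idx) + 1L] <- p$count
  list(v = v, offset = min(idx))
}

ssd_at_shift <- function(a, b, s) {
  # sum of squared differences between a and b shifted by s, zero-padded
  lo <- min(0, s); hi <- max(length(a), length(b) + s)
  av <- numeric(hi - lo); bv <- numeric(hi - lo)
  av[(1 - lo):(length(a) - lo)] <- a
  bv[(1 + s - lo):(length(b) + s - lo)] <- b
  sum((av - bv)^2)
}

#' Align column profiles across eyes
#'
#' Aligns a set of column profiles by integer shifts minimizing each
#' profile's squared difference to the running mean (iterated to
#' convergence), then reports the per-column mean and standard deviation of
#' the aligned set.
#'
#' @param profiles List of [column_profile] objects (>= 2).
#' @param max_iter Maximum alignment sweeps (default 20).
#' @return A data frame `column` (aligned index, 0 at the first column of the
#'   first profile), `mean`, `sd`, `n` (profiles covering that column), with
#'   attribute `shifts`.
#' @export
align_profiles <- function(profiles, max_iter = 20) {
  stopifnot(length(profiles) >= 2)
  vs <- lapply(profiles, profile_as_vector)
  n <- length(vs)
  shifts <- integer(n)
  span <- max(vapply(vs, function(a) length(a$v), integer(1)))
  for (it in seq_len(max_iter)) {
    changed <- FALSE
    for (i in seq_len(n)) {
      others <- setdiff(seq_len(n), i)
      # running mean of the other profiles at their current shifts
      lo <- min(shifts[others]); hi <- max(shifts[others] +
        vapply(vs[others], function(a) length(a$v), integer(1)))
      acc <- numeric(hi - lo); cnt <- 0
      for (j in others) {
        vj <- numeric(hi - lo)
        vj[(shifts[j] - lo + 1):(shifts[j] - lo + length(vs[[j]]$v))] <- vs[[j]]$v
        acc <- acc + vj; cnt <- cnt + 1
      }
      mn <- acc / cnt
      cand <- (-span):(span)
      ss <- vapply(cand, function(s) ssd_at_shift(mn, vs[[i]]$v, s - lo),
                   numeric(1))
      s_new <- cand[which.min(ss)]
      if (s_new != shifts[i]) { shifts[i] <- s_new; changed <- TRUE }
    }
    if (!changed) break
  }
  shifts <- shifts - shifts[1]
  lo <- min(shifts); hi <- max(shifts + vapply(vs, function(a) length(a$v),
                                               integer(1)))
  M <- matrix(NA_real_, n, hi - lo)
  for (i in seq_len(n))
    M[i, (shifts[i] - lo + 1):(shifts[i] - lo + length(vs[[i]]$v))] <- vs[[i]]$v
  covered <- colSums(!is.na(M)) > 0
  if (!any(covered)) stop("profiles do not overlap after alignment")
  out <- data.frame(column = (seq_len(ncol(M)) + lo - 1)[covered],
                    mean = colMeans(M, na.rm = TRUE)[covered],
                    sd = apply(M, 2, sd, na.rm = TRUE)[covered],
                    n = colSums(!is.na(M))[covered])
  rownames(out) <- NULL
  attr(out, "shifts") <- shifts
  out
}

#' Average per-ommatidium spacing across eyes on the shared hex grid
#'
#' Accumulates spacing measurements from several reindexed eyes by their
#' unique hexagonal coordinate and projects the mean onto a reference eye's
#' image positions. Coordinates present in fewer than `coverage` of the eyes
#' are dropped (rim coordinates are unstable across individuals).
#'
#' @param grids List of reindexed `hexgrid`s (see [recenter_and_orient]).
#' @param reference One reindexed `hexgrid` supplying the projection
#'   positions.
#' @param px_sizes Pixel sizes (um/px) per grid, recycled; default from each
#'   grid's attribute or 1.
#' @param coverage Minimum fraction of eyes a coordinate must appear in
#'   (default 0.5).
#' @return Data frame `x_hex`, `y_hex`, `x`, `y` (reference positions),
#'   `mean_spacing`, `sd_spacing`, `n_eyes`.
#' @export
average_spacing_across_eyes <- function(grids, reference, px_sizes = NULL,
                                        coverage = 0.5) {
  stopifnot(length(grids) >= 1, inherits(reference, "hexgrid"))
  sps <- lapply(seq_along(grids), function(i)
    spacing_per_ommatidium(grids[[i]],
                           px_size = if (is.null(px_sizes)) NULL
                                     else px_sizes[[(i - 1) %% length(px_sizes) + 1]]))
  all_keys <- unlist(lapply(sps, function(s) hex_key(s$x_hex, s$y_hex)))
  tb <- table(all_keys)
  keep <- names(tb)[tb >= coverage * length(grids)]
  ref_keys <- hex_key(reference$omm$x_hex, reference$omm$y_hex)
  keep <- intersect(keep, ref_keys)
  if (!length(keep)) stop("no hexagonal coordinates shared with the reference")
  acc <- new.env(hash = TRUE, parent = emptyenv())
  for (s in sps) {
    ks <- hex_key(s$x_hex, s$y_hex)
    for (i in seq_len(nrow(s))) {
      if (!is.finite(s$spacing[i])) next
      assign(ks[i], c(get0(ks[i], envir = acc, ifnotfound = numeric(0)),
                      s$spacing[i]), envir = acc)
    }
  }
  ri <- match(keep, ref_keys)
  vals <- lapply(keep, function(k) get0(k, envir = acc,
                                        ifnotfound = numeric(0)))
  out <- data.frame(
    x_hex = reference$omm$x_hex[ri], y_hex = reference$omm$y_hex[ri],
    x = reference$omm$x[ri], y = reference$omm$y[ri],
    mean_spacing = vapply(vals, function(v) if (length(v)) mean(v) else NA_real_,
                          numeric(1)),
    sd_spacing = vapply(vals, function(v) if (length(v) > 1) sd(v) else NA_real_,
                        numeric(1)),
    n_eyes = vapply(vals, length, integer(1)))
  out[order(out$x_hex, out$y_hex), , drop = FALSE]
}
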