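#' The ommatidia hexagonal grid
#'
#' A `hexgrid` holds every registered ommatidium with its unique integer
#' hexagonal coordinate `(x_hex, y_hex)`, its continuous image position
#' `(x, y)` in pixels, optional altitude `z` (um), its apparent tilt
#' (`slant`, degrees from normal view) and a provenance flag
#' (`seed`, `auto`, `manual`). Two ommatidia are hex-neighbors iff their
#' coordinate difference is one of the six offsets
#' (1,0), (-1,0), (0,1), (0,-1), (1,-1), (-1,1).
#'
#' @param omm Data frame with columns `id`, `x_hex`, `y_hex`, `x`, `y`,
#'   `z`, `slant`, `origin`.
#' @return A `hexgrid` object.
#' @export
new_hexgrid <- function(omm) {
  need <- c("id", "x_hex", "y_hex", "x", "y", "z", "slant", "origin")
  stopifnot(is.data.frame(omm), all(need %in% names(omm)))
  keys <- hex_key(omm$x_hex, omm$y_hex)
  if (anyDuplicated(keys))
    stop("duplicate hexagonal coordinates: ",
         paste(unique(keys[duplicated(keys)]), collapse = "; "))
  omm$x_hex <- as.integer(omm$x_hex)
  omm$y_hex <- as.integer(omm$y_hex)
  rownames(omm) <- NULL
  structure(list(omm = omm), class = "hexgrid")
}

#' @export
print.hexgrid <- function(x, ...) {
  n <- nrow(x$omm)
  lg <- tryCatch(grid_edge_length(x), error = function(e) NA_real_)
  cat(sprintf("<hexgrid> %d ommatidia (%s), L_grid = %s px\n", n,
              paste(names(table(x$omm$origin)), table(x$omm$origin),
                    sep = ":", collapse = ", "),
              ifelse(is.na(lg), "NA", sprintf("%.2f", lg))))
  invisible(x)
}

#' @export
as.data.frame.hexgrid <- function(x, ...) x$omm

# apparent tilt of the local lattice plane: angle (deg, from normal view)
# derived from the singular values of a 2x2 linear map.
slant_from_linear <- function(a, b, c, d) {
  E <- (a + d) / 2; F <- (a - d) / 2
  G <- (c + b) / 2; H <- (c - b) / 2
  Q <- sqrt(E^2 + H^2); R <- sqrt(F^2 + G^2)
  smax <- Q + R; smin <- abs(Q - R)
  if (smax <= 0) return(90)
  acos(min(1, smin / smax)) * 180 / pi
}

#' Seed a hexagonal grid from three adjacent ommatidia
#'
#' The grid origin and orientation are fixed by three mutually adjacent
#' ommatidia picked at the eye center; they receive hexagonal coordinates
#' (0,0), (1,0) and (0,1).
#'
#' @param p0,p1,p2 Image positions `c(x, y)` in pixels of the three seeds.
#' @return A `hexgrid` with three seed ommatidia.
#' @export
seed_grid <- function(p0, p1, p2) {
  pts <- rbind(p0, p1, p2)
  stopifnot(ncol(pts) == 2, nrow(pts) == 3, all(is.finite(pts)))
  d <- c(sqrt(sum((p0 - p1)^2)), sqrt(sum((p0 - p2)^2)),
         sqrt(sum((p1 - p2)^2)))
  if (any(d == 0)) stop("seed points must be distinct")
  if (max(d) > 3 * median(d))
    stop("seed points are not mutually close (max pairwise distance exceeds ",
         "3x the median)")
  area <- abs((p1[1] - p0[1]) * (p2[2] - p0[2]) -
              (p2[1] - p0[1]) * (p1[2] - p0[2])) / 2
  if (area < 0.02 * max(d)^2)
    stop("degenerate (near-collinear) seed triplet")
  # tilt of the seed triangle relative to an equilateral reference
  L <- mean(d)
  ref <- rbind(c(0, 0), c(L, 0), c(L / 2, L * sqrt(3) / 2))
  M <- cbind(ref, 1)
  coef <- solve(M, pts)
  sl <- slant_from_linear(coef[1, 1], coef[2, 1], coef[1, 2], coef[2, 2])
  new_hexgrid(data.frame(
    id = 1:3, x_hex = c(0L, 1L, 0L), y_hex = c(0L, 0L, 1L),
    x = pts[, 1], y = pts[, 2], z = NA_real_, slant = sl,
    origin = "seed", stringsAsFactors = FALSE))
}

is_hex_adjacent <- function(h1, h2) {
  d <- c(h2[1] - h1[1], h2[2] - h1[2])
  any(HEX_OFFSETS[, 1] == d[1] & HEX_OFFSETS[, 2] == d[2])
}

#' Mirror prediction of a fourth ommatidium
#'
#' Given three mutually adjacent ommatidia, the fourth is spawned by mirroring
#' the first through the midpoint of the other two:
#' `hex4 = hex2 + hex3 - hex1` and `pos4 = pos2 + pos3 - pos1`.
#'
#' @param omtd1,omtd2,omtd3 Lists (or single data-frame rows) with fields
#'   `x_hex`, `y_hex`, `x`, `y`; `omtd2` and `omtd3` must be hex-neighbors of
#'   `omtd1` and of each other.
#' @return List with `hex` (integer pair) and `pos` (numeric pair).
#' @export
mirror_predict <- function(omtd1, omtd2, omtd3) {
  h1 <- c(omtd1$x_hex, omtd1$y_hex)
  h2 <- c(omtd2$x_hex, omtd2$y_hex)
  h3 <- c(omtd3$x_hex, omtd3$y_hex)
  if (!(is_hex_adjacent(h1, h2) && is_hex_adjacent(h1, h3) &&
        is_hex_adjacent(h2, h3)))
    stop("omtd1, omtd2, omtd3 must be mutually hex-adjacent")
  list(hex = as.integer(h2 + h3 - h1),
       pos = c(omtd2$x + omtd3$x - omtd1$x, omtd2$y + omtd3$y - omtd1$y))
}

# enumerate hex-adjacent index pairs (each once)
adjacent_pairs <- function(omm) {
  idx <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(nrow(omm)))
    assign(hex_key(omm$x_hex[i], omm$y_hex[i]), i, envir = idx)
  a <- integer(0); b <- integer(0)
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, -1L))) {
    k <- hex_key(omm$x_hex + off[1], omm$y_hex + off[2])
    hit <- vapply(k, function(kk) {
      if (exists(kk, envir = idx, inherits = FALSE))
        get(kk, envir = idx) else NA_integer_
    }, integer(1))
    sel <- !is.na(hit)
    a <- c(a, which(sel)); b <- c(b, hit[sel])
  }
  cbind(a, b)
}

#' Average hexagonal edge length of a grid
#'
#' `L_grid`: the mean Euclidean distance between the image positions of all
#' hex-adjacent ommatidium pairs. It sets the template scale and all search
#' radii during grid expansion.
#'
#' @param grid A `hexgrid`.
#' @return Average adjacent-pair spacing in pixels.
#' @export
grid_edge_length <- function(grid) {
  stopifnot(inherits(grid, "hexgrid"))
  pr <- adjacent_pairs(grid$omm)
  if (nrow(pr) == 0) stop("grid has no adjacent ommatidium pairs")
  mean(sqrt((grid$omm$x[pr[, 1]] - grid$omm$x[pr[, 2]])^2 +
            (grid$omm$y[pr[, 1]] - grid$omm$y[pr[, 2]])^2))
}

#' Remove an ommatidium from the grid
#'
#' @param grid A `hexgrid`.
#' @param hex Integer pair `c(x_hex, y_hex)`.
#' @return The grid without that ommatidium.
#' @export
remove_ommatidium <- function(grid, hex) {
  stopifnot(inherits(grid, "hexgrid"), length(hex) == 2)
  sel <- grid$omm$x_hex == hex[1] & grid$omm$y_hex == hex[2]
  if (!any(sel)) stop("no ommatidium at hex coordinate (", hex[1], ",",
                      hex[2], ")")
  new_hexgrid(grid$omm[!sel, , drop = FALSE])
}

#' Manually add an ommatidium at an image position
#'
#' The hexagonal coordinate is inferred automatically: the unoccupied mirror
#' slot (from any registered mutually adjacent triplet) whose predicted
#' position is nearest to `pos` is used if its prediction falls within
#' `L_grid` of `pos`; otherwise the open neighbor slot of the nearest
#' registered ommatidium minimizing the positional residual (predicted from a
#' local least-squares lattice fit) is used.
#'
#' @param grid A `hexgrid` with at least 3 ommatidia.
#' @param pos Image position `c(x, y)` in pixels.
#' @return The grid with the added ommatidium (origin `"manual"`).
#' @export
add_manual <- function(grid, pos) {
  stopifnot(inherits(grid, "hexgrid"), length(pos) == 2)
  omm <- grid$omm
  L <- grid_edge_length(grid)
  dmin <- min(sqrt((omm$x - pos[1])^2 + (omm$y - pos[2])^2))
  if (dmin < L / 2)
    stop("position duplicates an existing ommatidium (within L_grid/2)")
  occ <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(nrow(omm)))
    assign(hex_key(omm$x_hex[i], omm$y_hex[i]), i, envir = occ)
  best <- NULL
  for (tri in enumerate_triplets(omm)) {
    for (r in 1:3) {
      o1 <- tri[r]; rest <- tri[-r]
      mp <- mirror_predict(omm[o1, ], omm[rest[1], ], omm[rest[2], ])
      if (exists(hex_key(mp$hex[1], mp$hex[2]), envir = occ, inherits = FALSE))
        next
      d <- sqrt(sum((mp$pos - pos)^2))
      if (is.null(best) || d < best$d) best <- list(hex = mp$hex, d = d)
    }
  }
  if (is.null(best) || best$d > L) {
    # fall back: open neighbor slots of the nearest few ommatidia, positions
    # predicted from a local affine lattice fit
    near <- order((omm$x - pos[1])^2 + (omm$y - pos[2])^2)
    loc <- omm[head(near, 8), ]
    X <- cbind(loc$x_hex, loc$y_hex, 1)
    cf <- qr.solve(X, cbind(loc$x, loc$y))
    best <- NULL
    for (o in head(near, 4)) {
      for (k in seq_len(nrow(HEX_OFFSETS))) {
        hx <- omm$x_hex[o] + HEX_OFFSETS[k, 1]
        hy <- omm$y_hex[o] + HEX_OFFSETS[k, 2]
        if (exists(hex_key(hx, hy), envir = occ, inherits = FALSE)) next
        pred <- c(hx, hy, 1) %*% cf
        d <- sqrt(sum((pred - pos)^2))
        if (is.null(best) || d < best$d) best <- list(hex = c(hx, hy), d = d)
      }
    }
    if (is.null(best)) stop("no open hexagonal slot near position")
  }
  omm <- rbind(omm, data.frame(
    id = max(omm$id) + 1L, x_hex = best$hex[1], y_hex = best$hex[2],
    x = pos[1], y = pos[2], z = NA_real_, slant = NA_real_,
    origin = "manual", stringsAsFactors = FALSE))
  new_hexgrid(omm)
}

# all mutually adjacent index triplets (each triangle once, sorted indices)
enumerate_triplets <- function(omm) {
  pr <- adjacent_pairs(omm)
  if (nrow(pr) == 0) return(list())
  nb <- vector("list", nrow(omm))
  for (i in seq_len(nrow(pr))) {
    nb[[pr[i, 1]]] <- c(nb[[pr[i, 1]]], pr[i, 2])
    nb[[pr[i, 2]]] <- c(nb[[pr[i, 2]]], pr[i, 1])
  }
  out <- list()
  for (i in seq_len(nrow(omm))) {
    ns <- nb[[i]]
    ns <- ns[ns > i]
    if (length(ns) < 2) next
    for (a in seq_along(ns)) for (b in seq_along(ns)) {
      if (b <= a) next
      j <- ns[a]; k <- ns[b]
      if (is_hex_adjacent(c(omm$x_hex[j], omm$y_hex[j]),
                          c(omm$x_hex[k], omm$y_hex[k])))
        out[[length(out) + 1L]] <- c(i, j, k)
    }
  }
  out
}

#' Total ommatidia and column count
#'
#' @param grid A `hexgrid`.
#' @return Named numeric vector: `n` (grid size) and `columns` (number of
#'   occupied columns, i.e. distinct values of `x_hex + y_hex`).
#' @export
count_ommatidia <- function(grid) {
  stopifnot(inherits(grid, "hexgrid"))
  c(n = nrow(grid$omm),
    columns = length(unique(grid$omm$x_hex + grid$omm$y_hex)))
}
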