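#' Expand a seeded hexagonal grid over the facet probability map
#'
#' The core segmentation step. Starting from a seeded grid, every mutually
#' adjacent registered triplet proposes a new ommatidium at its mirror
#' position; each proposal is fitted to the facet probability map with the
#' three-circle template ([fit_candidate]) and pushed onto a global priority
#' queue ordered by the objective value. Proposals are accepted best-fit
#' first; an accepted ommatidium is always on the perimeter of the grid,
#' receives the mirror hex coordinate `hex2 + hex3 - hex1`, updates `L_grid`
#' (the running mean spacing over all registered adjacent pairs) and spawns
#' new proposals from the triangles it completes. A proposal is discarded
#' when its slot is already occupied, its fitted center lies outside the eye
#' mask, farther than `accept_frac * L_grid` from its prediction, or within
#' `L_grid / 2` of an already registered ommatidium. Expansion stops when the
#' queue holds no admissible candidate.
#'
#' @param grid A seeded `hexgrid` (see [seed_grid]).
#' @param maps A [probability_maps] object (`facet_prob` and `eye_mask` are
#'   used).
#' @param config A [fit_config].
#' @return The expanded `hexgrid`, with an attribute `stats` (list: ommatidia
#'   added, proposals rejected, template fits performed, final `L_grid`).
#' @export
expand_grid <- function(grid, maps, config = fit_config()) {
  stopifnot(inherits(grid, "hexgrid"), inherits(maps, "probability_maps"))
  prob <- maps$facet_prob
  mask <- maps$eye_mask
  H <- nrow(prob); W <- ncol(prob)

  n0 <- nrow(grid$omm)
  cap <- max(1024L, 4L * n0)
  st <- new.env(parent = emptyenv())
  st$n <- 0L
  st$hx <- integer(cap); st$hy <- integer(cap)
  st$x <- numeric(cap); st$y <- numeric(cap)
  st$slant <- numeric(cap); st$origin <- character(cap)
  st$pair_sum <- 0; st$pair_n <- 0L
  occ <- new.env(hash = TRUE, parent = emptyenv())
  tmpl_cache <- new.env(hash = TRUE, parent = emptyenv())
  seen <- new.env(hash = TRUE, parent = emptyenv())

  lgrid <- function() st$pair_sum / st$pair_n

  register <- function(hx, hy, x, y, slant, origin) {
    i <- st$n + 1L
    if (i > length(st$hx)) {  # grow
      for (f in c("hx", "hy", "x", "y", "slant", "origin"))
        st[[f]] <- c(st[[f]], vector(mode = mode(st[[f]]),
                                     length = length(st[[f]])))
    }
    st$n <- i
    st$hx[i] <- hx; st$hy[i] <- hy
    st$x[i] <- x; st$y[i] <- y
    st$slant[i] <- slant; st$origin[i] <- origin
    assign(hex_key(hx, hy), i, envir = occ)
    for (k in seq_len(nrow(HEX_OFFSETS))) {
      key <- hex_key(hx + HEX_OFFSETS[k, 1], hy + HEX_OFFSETS[k, 2])
      if (exists(key, envir = occ, inherits = FALSE)) {
        j <- get(key, envir = occ)
        st$pair_sum <- st$pair_sum + sqrt((st$x[i] - st$x[j])^2 +
                                          (st$y[i] - st$y[j])^2)
        st$pair_n <- st$pair_n + 1L
      }
    }
    i
  }

  in_mask <- function(x, y) {
    xi <- as.integer(round(x)) + 1L
    yi <- as.integer(round(y)) + 1L
    xi >= 1L && xi <= W && yi >= 1L && yi <= H && mask[yi, xi]
  }

  get_template <- function(L) {
    m <- max(20L, as.integer(round(2 * L)))
    key <- as.character(m)
    if (!exists(key, envir = tmpl_cache, inherits = FALSE))
      assign(key, build_mickey_template(m), envir = tmpl_cache)
    get(key, envir = tmpl_cache)
  }

  # priority queue on delta
  qcap <- 4096L
  qu <- new.env(parent = emptyenv())
  qu$n <- 0L
  for (f in c("delta", "px", "py", "theta", "slant", "predx", "predy"))
    qu[[f]] <- numeric(qcap)
  qu$hx <- integer(qcap); qu$hy <- integer(qcap)
  qu$active <- logical(qcap)
  n_fits <- 0L; n_rej <- 0L

  push <- function(hx, hy, fit) {
    i <- qu$n + 1L
    if (i > length(qu$delta)) {
      for (f in c("delta", "px", "py", "theta", "slant", "predx", "predy",
                  "hx", "hy", "active"))
        qu[[f]] <- c(qu[[f]], vector(mode = mode(qu[[f]]),
                                     length = length(qu[[f]])))
    }
    qu$n <- i
    qu$delta[i] <- fit$delta
    qu$px[i] <- fit$pos[1]; qu$py[i] <- fit$pos[2]
    qu$theta[i] <- fit$theta; qu$slant[i] <- fit$slant
    qu$predx[i] <- fit$predicted[1]; qu$predy[i] <- fit$predicted[2]
    qu$hx[i] <- hx; qu$hy[i] <- hy
    qu$active[i] <- TRUE
  }

  # propose the mirror slot of (o1 | o2, o3): fit and enqueue
  propose <- function(o1, o2, o3) {
    hx4 <- st$hx[o2] + st$hx[o3] - st$hx[o1]
    hy4 <- st$hy[o2] + st$hy[o3] - st$hy[o1]
    if (exists(hex_key(hx4, hy4), envir = occ, inherits = FALSE)) return()
    key <- paste(hx4, hy4, o1, sep = "|")
    if (exists(key, envir = seen, inherits = FALSE)) return()
    assign(key, TRUE, envir = seen)
    px4 <- st$x[o2] + st$x[o3] - st$x[o1]
    py4 <- st$y[o2] + st$y[o3] - st$y[o1]
    if (px4 < 1 || px4 > W - 2 || py4 < 1 || py4 > H - 2) return()
    if (!in_mask(px4, py4)) return()
    L <- lgrid()
    fit <- fit_candidate(prob, c(st$x[o2], st$y[o2]), c(st$x[o3], st$y[o3]),
                         c(px4, py4),
                         omtd1 = list(slant = st$slant[o1]), L_grid = L,
                         template = get_template(L), config = config)
    n_fits <<- n_fits + 1L
    if (is.finite(fit$delta)) push(hx4, hy4, fit)
  }

  # all triangles containing ommatidium i whose other vertices are registered
  propose_around <- function(i) {
    nbs <- integer(0)
    for (k in seq_len(nrow(HEX_OFFSETS))) {
      key <- hex_key(st$hx[i] + HEX_OFFSETS[k, 1], st$hy[i] + HEX_OFFSETS[k, 2])
      if (exists(key, envir = occ, inherits = FALSE))
        nbs <- c(nbs, get(key, envir = occ))
    }
    if (length(nbs) < 2) return()
    for (a in seq_along(nbs)) for (b in seq_along(nbs)) {
      if (b <= a) next
      j <- nbs[a]; k <- nbs[b]
      if (!is_hex_adjacent(c(st$hx[j], st$hy[j]), c(st$hx[k], st$hy[k]))) next
      propose(i, j, k)   # mirror i through (j, k)
      propose(j, i, k)   # mirror j through (i, k)
      propose(k, i, j)   # mirror k through (i, j)
    }
  }

  for (i in seq_len(n0))
    register(grid$omm$x_hex[i], grid$omm$y_hex[i], grid$omm$x[i],
             grid$omm$y[i], grid$omm$slant[i], grid$omm$origin[i])
  if (st$pair_n == 0L) stop("seed grid has no adjacent pairs")
  for (i in seq_len(n0)) propose_around(i)

  n_added <- 0L
  while (n_added < config$max_add) {
    act <- which(qu$active[seq_len(qu$n)])
    if (!length(act)) break
    d <- qu$delta[act]
    k <- act[d == min(d)]
    if (length(k) > 1L)  # deterministic tie-break: hex lexicographic
      k <- k[order(qu$hx[k], qu$hy[k])][1]
    qu$active[k] <- FALSE
    L <- lgrid()
    hx <- qu$hx[k]; hy <- qu$hy[k]
    px <- qu$px[k]; py <- qu$py[k]
    ok <- !exists(hex_key(hx, hy), envir = occ, inherits = FALSE) &&
      in_mask(px, py) &&
      sqrt((px - qu$predx[k])^2 + (py - qu$predy[k])^2) <=
        config$accept_frac * L &&
      cpp_min_dist(st$x[seq_len(st$n)], st$y[seq_len(st$n)], px, py) >= L / 2
    if (!ok) { n_rej <- n_rej + 1L; next }
    i <- register(hx, hy, px, py, qu$slant[k], "auto")
    n_added <- n_added + 1L
    propose_around(i)
  }

  n <- st$n
  omm <- data.frame(
    id = seq_len(n), x_hex = st$hx[seq_len(n)], y_hex = st$hy[seq_len(n)],
    x = st$x[seq_len(n)], y = st$y[seq_len(n)], z = NA_real_,
    slant = st$slant[seq_len(n)], origin = st$origin[seq_len(n)],
    stringsAsFactors = FALSE)
  # carry over altitudes of the input grid if present
  omm$z[seq_len(n0)] <- grid$omm$z
  out <- new_hexgrid(omm)
  attr(out, "stats") <- list(n_added = n_added, n_rejected = n_rej,
                             n_fits = n_fits, L_grid = lgrid())
  out
}

#' Automatically seed a grid from the facet probability map
#'
#' Replaces the interactive seed selection: thresholds the smoothed facet
#' probability map into facet-interior blobs (connected components), takes
#' the blob nearest the eye-mask centroid and its two nearest neighbor blobs
#' as the three seed ommatidia. Blob centroids are robust against plateau
#' maxima in classifier output.
#'
#' @param maps A [probability_maps].
#' @param min_prob Probability threshold defining facet-interior blobs.
#' @return A `hexgrid` of three seeds (see [seed_grid]).
#' @export
auto_seed <- function(maps, min_prob = 0.6) {
  stopifnot(inherits(maps, "probability_maps"))
  sm <- gblur_rep(maps$facet_prob, 1)
  blobs <- as.matrix(EBImage::bwlabel((sm >= min_prob & maps$eye_mask) * 1))
  nb <- max(blobs)
  if (nb < 3) stop("not enough facet blobs to auto-seed")
  sizes <- tabulate(blobs[blobs > 0], nbins = nb)
  # centroids (0-based pixel coordinates)
  idx <- which(blobs > 0)
  lab <- blobs[idx]
  yy <- (idx - 1) %% nrow(blobs)
  xx <- (idx - 1) %/% nrow(blobs)
  cx <- tapply(xx, lab, mean)
  cy <- tapply(yy, lab, mean)
  # drop speck blobs (below a tenth of the median blob area)
  keep <- sizes >= max(4, median(sizes) / 10)
  pk <- cbind(x = cx[keep], y = cy[keep])
  if (nrow(pk) < 3) stop("not enough in-mask facet blobs to auto-seed")
  mrow <- which(maps$eye_mask, arr.ind = TRUE)
  cen <- c(mean(mrow[, 2]) - 1, mean(mrow[, 1]) - 1)
  d0 <- sqrt((pk[, 1] - cen[1])^2 + (pk[, 2] - cen[2])^2)
  p0 <- pk[which.min(d0), ]
  rest <- pk[order(sqrt((pk[, 1] - p0[1])^2 + (pk[, 2] - p0[2])^2)), ,
             drop = FALSE]
  # rest[1] is p0 itself; among the nearest blobs pick the pair forming the
  # most equilateral triangle with p0 -- three mutually adjacent facets are
  # equidistant, whereas second-ring neighbors sit sqrt(3) spacings apart
  kmax <- min(9, nrow(rest))
  best <- NULL
  for (j in 2:(kmax - 1)) for (k in (j + 1):kmax) {
    d <- c(sqrt(sum((p0 - rest[j, ])^2)),
           sqrt(sum((p0 - rest[k, ])^2)),
           sqrt(sum((rest[j, ] - rest[k, ])^2)))
    ratio <- max(d) / min(d)
    if (ratio > 1.25) next
    g <- tryCatch(seed_grid(as.numeric(p0), as.numeric(rest[j, ]),
                            as.numeric(rest[k, ])),
                  error = function(e) NULL)
    # among near-equilateral triangles take the smallest: mutually adjacent
    # facets are a factor sqrt(3) closer than the second-ring triangle
    if (!is.null(g) && (is.null(best) || mean(d) < best$size))
      best <- list(grid = g, size = mean(d))
  }
  if (is.null(best))
    stop("could not form a near-equilateral seed triplet from facet blobs")
  best$grid
}
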