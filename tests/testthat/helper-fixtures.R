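# Fixtures shared across test files; everything is generated in code.

# a jittered hexagonal patch as a hexgrid (flat, z = 0)
jittered_grid <- function(rings = 3, spacing = 12, jitter_sd = 1, seed = 1) {
  truth_as_grid(flat_patch_truth(rings, spacing_px = spacing,
                                 jitter_sd = jitter_sd, seed = seed))
}

# random subset of a jittered patch (keeps the grid non-degenerate)
random_grid <- function(seed, rings = 4, keep_frac = 0.8) {
  g <- jittered_grid(rings = rings, seed = seed)
  withr::with_seed(seed, {
    n <- nrow(g$omm)
    idx <- sort(sample(n, max(3, round(keep_frac * n))))
    new_hexgrid(g$omm[idx, , drop = FALSE])
  })
}

# seed grid at the three ground-truth facets nearest the eye apex;
# returns the grid and the truth hex of the (0,0) seed for hex comparison
seed_from_truth <- function(gt) {
  cx <- (gt$width - 1) / 2
  r <- sqrt((gt$centers[, 1] - cx)^2 + (gt$centers[, 2] - cx)^2)
  i0 <- which.min(r)
  h0 <- gt$hex[i0, ]
  i1 <- which(gt$hex[, 1] == h0[1] + 1 & gt$hex[, 2] == h0[2])
  i2 <- which(gt$hex[, 1] == h0[1] & gt$hex[, 2] == h0[2] + 1)
  stopifnot(length(i1) == 1, length(i2) == 1)
  list(grid = seed_grid(gt$centers[i0, ], gt$centers[i1, ],
                        gt$centers[i2, ]),
       h0 = h0)
}

# the six neighbor directions in angular order: consecutive pairs are
# mutually adjacent, so (h, h + dirs[k], h + dirs[k+1]) is a valid triplet
hex_dirs_ordered <- function() {
  rbind(c(1, 0), c(0, 1), c(-1, 1), c(-1, 0), c(0, -1), c(1, -1))
}

# random valid mutually adjacent triplet with lattice-consistent positions
random_triplet <- function(L = 10) {
  dirs <- hex_dirs_ordered()
  h1 <- sample(-20:20, 2)
  k <- sample(6, 1)
  h2 <- h1 + dirs[k, ]
  h3 <- h1 + dirs[k %% 6 + 1, ]
  e1 <- c(L, 0) + rnorm(2, 0, 0.5)
  e2 <- c(L / 2, L * sqrt(3) / 2) + rnorm(2, 0, 0.5)
  org <- runif(2, 0, 100)
  pos <- function(h) org + h[1] * e1 + h[2] * e2 + rnorm(2, 0, 0.3)
  mk <- function(h) {
    p <- pos(h)
    list(x_hex = h[1], y_hex = h[2], x = p[1], y = p[2])
  }
  list(o1 = mk(h1), o2 = mk(h2), o3 = mk(h3))
}

# smooth random probability-like image in [0, 1]
smooth_prob_image <- function(n = 80, sigma = 3, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(runif(n * n), n)
    m <- as.matrix(EBImage::gblur(m, sigma))
    (m - min(m)) / (max(m) - min(m))
  })
}
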