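test_that("altitude assignment reads the map at ommatidium positions", {
  g <- jittered_grid(rings = 2, spacing = 10, jitter_sd = 0)
  flat <- matrix(0, 90, 90)
  ga <- assign_altitude(g, flat, px_size = 1.5)
  expect_true(all(ga$omm$z == 0))
  expect_equal(attr(ga, "px_size"), 1.5)

  # quantized altitudes from a 12-plane stack
  alt <- matrix(rep(seq(0, 88, by = 8), length.out = 90 * 90), 90)
  gq <- assign_altitude(g, alt, px_size = 1)
  expect_true(all(gq$omm$z %in% seq(0, 88, by = 8)))

  small <- matrix(0, 5, 5)
  expect_error(assign_altitude(g, small, px_size = 1), "outside")
})

test_that("hemisphere altitude decreases from center to rim along hex rays", {
  gt <- generate_lattice(synthetic_eye_spec(n_target = 250, jitter_sd = 0,
                                            seed = 2))
  g <- truth_as_grid(gt)
  omm <- g$omm
  for (dir in list(c(1L, 0L), c(0L, 1L), c(-1L, 1L))) {
    sel <- omm[omm$x_hex * dir[2] == omm$y_hex * dir[1], ]
    tt <- if (dir[1] != 0) sel$x_hex / dir[1] else sel$y_hex / dir[2]
    ray <- sel[tt >= 0, ][order(tt[tt >= 0]), ]
    if (nrow(ray) > 2) expect_true(all(diff(ray$z) < 0))
  }
})

test_that("per-ommatidium spacing equals the neighbor-distance oracle", {
  # uniform flat lattice: every interior value equals the spacing
  g <- jittered_grid(rings = 3, spacing = 12, jitter_sd = 0)
  sp <- spacing_per_ommatidium(g)
  interior <- sp$n_neighbors == 6
  expect_true(all(abs(sp$spacing[interior] - 12) < 1e-9))

  # 3-4-12 triple: Euclidean distance 13 in 3D
  two <- new_hexgrid(data.frame(id = 1:2, x_hex = c(0L, 1L),
                                y_hex = c(0L, 0L), x = c(0, 3), y = c(0, 4),
                                z = c(0, 12), slant = NA_real_,
                                origin = "manual"))
  expect_equal(spacing_per_ommatidium(two, px_size = 1)$spacing, c(13, 13))

  # jittered grid vs brute-force enumeration
  gj <- jittered_grid(rings = 3, spacing = 11, jitter_sd = 1.2, seed = 5)
  gj$omm$z <- withr::with_seed(6, runif(nrow(gj$omm), 0, 10))
  sp2 <- spacing_per_ommatidium(gj, px_size = 2)
  omm <- gj$omm
  dirs <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1), c(1, -1), c(-1, 1))
  for (i in seq_len(nrow(omm))) {
    ds <- c()
    for (k in 1:6) {
      j <- which(omm$x_hex == omm$x_hex[i] + dirs[k, 1] &
                 omm$y_hex == omm$y_hex[i] + dirs[k, 2])
      if (length(j))
        ds <- c(ds, sqrt((2 * (omm$x[i] - omm$x[j]))^2 +
                         (2 * (omm$y[i] - omm$y[j]))^2 +
                         (omm$z[i] - omm$z[j])^2))
    }
    expect_equal(sp2$spacing[i], mean(ds))
  }

  # isolated ommatidium is flagged, not an error
  iso <- new_hexgrid(rbind(omm, data.frame(
    id = 999L, x_hex = 50L, y_hex = 50L, x = 1, y = 1, z = 0,
    slant = NA_real_, origin = "manual")))
  spi <- spacing_per_ommatidium(iso)
  expect_true(spi$isolated[spi$id == 999])
  expect_true(is.na(spi$spacing[spi$id == 999]))
})

test_that("polynomial surfaces recover nested models and planted peaks", {
  withr::with_seed(8, {
    pos <- cbind(runif(80, 0, 100), runif(80, 0, 100))
    vals <- 2 + 0.03 * pos[, 1] - 0.01 * pos[, 2] +
      4e-4 * pos[, 1] * pos[, 2] - 3e-4 * pos[, 1]^2
    fit <- fit_surface(pos, vals, degree = 3)
    expect_lt(max(abs(fit$residuals)), 1e-8)

    cf <- fit_surface(pos, rep(7, 80), degree = 2)
    expect_lt(max(abs(cf$residuals)), 1e-8)
    expect_equal(unname(cf$predict(50, 50)), 7, tolerance = 1e-8)

    # radial bump: the raster argmax lands near the true peak
    peak <- c(60, 45)
    vb <- 1 + exp(-((pos[, 1] - peak[1])^2 + (pos[, 2] - peak[2])^2) / 800)
    fb <- fit_surface(pos, vb, degree = 3)
    expect_lt(sqrt(sum((fb$peak - peak)^2)), 10)
  })
  expect_error(fit_surface(cbind(1:3, 1:3), 1:3, degree = 3), "at least")
})

test_that("recentering and reorientation preserve adjacency and direct columns", {
  g <- jittered_grid(rings = 3, spacing = 12, jitter_sd = 0.5, seed = 12)
  gr <- recenter_and_orient(g, anterior = "right")
  # symmetric grid already centered: origin ommatidium keeps hex (0, 0)
  i0 <- which(g$omm$x_hex == 0 & g$omm$y_hex == 0)
  j0 <- which(gr$omm$x_hex == 0 & gr$omm$y_hex == 0)
  expect_equal(c(gr$omm$x[j0], gr$omm$y[j0]), c(g$omm$x[i0], g$omm$y[i0]))

  # adjacency is preserved by the lattice symmetry
  pairs_of <- function(gg) {
    omm <- gg$omm
    dirs <- rbind(c(1, 0), c(0, 1), c(1, -1))
    n <- 0
    for (k in 1:3)
      n <- n + sum(paste(omm$x_hex + dirs[k, 1], omm$y_hex + dirs[k, 2]) %in%
                     paste(omm$x_hex, omm$y_hex))
    n
  }
  expect_equal(pairs_of(gr), pairs_of(g))

  # the most anterior ommatidium gets positive hex coordinates, so the
  # column index increases from posterior to anterior
  ia <- which.max(gr$omm$x)
  expect_gte(gr$omm$x_hex[ia], 0)
  expect_gte(gr$omm$y_hex[ia], 0)
  expect_gt(gr$omm$x_hex[ia] + gr$omm$y_hex[ia], 0)
  expect_gt(cor(gr$omm$x, gr$omm$x_hex + gr$omm$y_hex), 0.8)
})

test_that("column profiles count ommatidia per x_hex + y_hex", {
  gs <- seed_grid(c(0, 0), c(10, 0), c(5, 8.66))
  pr <- column_profile(gs)
  expect_equal(pr$column_index, c(0L, 1L))
  expect_equal(pr$count, c(1L, 2L))

  # 1-ring hexagon: brute-force enumeration over the patch
  g1 <- jittered_grid(rings = 1, jitter_sd = 0)
  p1 <- column_profile(g1)
  brute <- table(g1$omm$x_hex + g1$omm$y_hex)
  expect_equal(p1$count, as.integer(brute))
  expect_equal(sum(p1$count), 7)
  expect_equal(attr(p1, "total"), 7)
})

test_that("profile alignment recovers pure shifts and averages", {
  base <- column_profile(jittered_grid(rings = 3, jitter_sd = 0))
  shifted <- base
  shifted$column_index <- shifted$column_index + 3L
  al <- align_profiles(list(base, shifted, base))
  expect_true(all(al$sd[al$n == 3] == 0))
  expect_equal(attr(al, "shifts")[1], 0)
  expect_equal(sum(al$mean * al$n) / 3, sum(base$count), tolerance = 1e-9)

  # a noisy copy: the aligned mean is closer to the clean profile than the
  # noisy one is (in SSD)
  noisy <- base
  noisy$count <- noisy$count + c(1L, -1L, rep(0L, nrow(noisy) - 2))
  al2 <- align_profiles(list(base, noisy))
  common <- al2$n == 2
  ssd_mean <- sum((al2$mean[common] - base$count)^2)
  ssd_noisy <- sum((noisy$count - base$count)^2)
  expect_lt(ssd_mean, ssd_noisy)
})

test_that("cross-eye spacing averages respect coverage and idempotence", {
  g <- jittered_grid(rings = 2, spacing = 12, jitter_sd = 0)
  avg <- average_spacing_across_eyes(list(g, g), reference = g)
  sp <- spacing_per_ommatidium(g)
  expect_equal(avg$mean_spacing, sp$spacing[match(hexeye:::hex_key(avg$x_hex, avg$y_hex),
                                                  hexeye:::hex_key(sp$x_hex, sp$y_hex))])
  # a coordinate present in only 1 of 4 eyes is dropped
  g_extra <- add_manual(g, c(max(g$omm$x) + 12, mean(g$omm$y)))
  avg4 <- average_spacing_across_eyes(list(g_extra, g, g, g),
                                      reference = g_extra)
  extra_key <- hexeye:::hex_key(
    g_extra$omm$x_hex[nrow(g_extra$omm)], g_extra$omm$y_hex[nrow(g_extra$omm)])
  expect_false(extra_key %in% hexeye:::hex_key(avg4$x_hex, avg4$y_hex))
})
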