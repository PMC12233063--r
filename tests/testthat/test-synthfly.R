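test_that("the generator is deterministic under a fixed seed", {
  spec <- synthetic_eye_spec(n_target = 150, seed = 4)
  gt1 <- generate_lattice(spec)
  gt2 <- generate_lattice(spec)
  expect_identical(gt1, gt2)
  expect_identical(render_image(gt1), render_image(gt2))
})

test_that("flat patches realize centered hexagonal numbers", {
  for (k in c(2, 4, 6))
    expect_equal(nrow(flat_patch_truth(k)$centers), 3 * k * (k + 1) + 1)
  # a sphere too small to hold a full ring of facets is refused
  expect_error(generate_lattice(synthetic_eye_spec(
    n_target = 7, sphere_radius = 10, facet_spacing = 16, cap_angle = 30)),
    "fewer than 7")
})

test_that("orthographic projection foreshortens the rim", {
  gt <- generate_lattice(synthetic_eye_spec(n_target = 400, jitter_sd = 0,
                                            seed = 1))
  nn_dist <- function(i) {
    d <- sqrt((gt$centers[, 1] - gt$centers[i, 1])^2 +
              (gt$centers[, 2] - gt$centers[i, 2])^2)
    min(d[d > 0])
  }
  cx <- (gt$width - 1) / 2
  r <- sqrt((gt$centers[, 1] - cx)^2 + (gt$centers[, 2] - cx)^2)
  apex <- which.min(r)
  rim <- which.max(r)
  expect_lt(nn_dist(rim), nn_dist(apex))
  # altitude: rim facets are the lowest
  expect_lt(gt$z[rim], gt$z[apex])
  expect_equal(min(gt$z), 0)
})

test_that("ideal probability maps separate interiors from boundaries", {
  gt <- flat_patch_truth(3, spacing_px = 14)
  maps <- ideal_probability_maps(gt)
  expect_equal(dim(maps$facet_prob), c(gt$height, gt$width))
  at <- function(m, p) m[round(p[2]) + 1, round(p[1]) + 1]
  # facet probability > 0.9 at every true center
  ctr_vals <- vapply(seq_len(nrow(gt$centers)),
                     function(i) at(maps$facet_prob, gt$centers[i, ]),
                     numeric(1))
  expect_true(all(ctr_vals > 0.9))
  # < 0.3 at Voronoi boundaries (midpoints between adjacent centers)
  dirs <- rbind(c(1, 0), c(0, 1), c(1, -1))
  bvals <- c()
  for (i in seq_len(nrow(gt$hex))) for (k in 1:3) {
    j <- which(gt$hex[, 1] == gt$hex[i, 1] + dirs[k, 1] &
               gt$hex[, 2] == gt$hex[i, 2] + dirs[k, 2])
    if (length(j))
      bvals <- c(bvals, at(maps$facet_prob,
                           (gt$centers[i, ] + gt$centers[j, ]) / 2))
  }
  expect_true(all(bvals < 0.3))
  # the Otsu mask of the ideal eye probability recovers the true mask
  expect_gt(mean(eye_mask_from_prob(maps$eye_prob) == gt$eye_mask), 0.995)
})

test_that("rendered facets are brightest near their centers", {
  spec <- synthetic_eye_spec(n_target = 150, noise_sd = 0,
                             bristle_density = 0, jitter_sd = 0, seed = 6)
  gt <- generate_lattice(spec)
  img <- render_image(gt, spec)
  expect_true(all(img >= 0 & img <= 1))
  geom <- hexeye:::truth_geometry(gt)
  s <- gt$spacing_px
  bad <- 0
  for (i in seq_len(nrow(gt$centers))) {
    cell <- which(geom$label == i & gt$eye_mask)
    if (length(cell) < 10) next
    peak <- cell[which.max(img[cell])]
    py <- (peak - 1) %% nrow(img)
    px <- (peak - 1) %/% nrow(img)
    d <- sqrt((px - gt$centers[i, 1])^2 + (py - gt$centers[i, 2])^2)
    if (d > 0.3 * s) bad <- bad + 1
  }
  expect_lt(bad / nrow(gt$centers), 0.05)
})

test_that("stack rendering focuses each facet at its own plane", {
  spec <- synthetic_eye_spec(n_target = 150, n_planes = 8, noise_sd = 0,
                             bristle_density = 0, jitter_sd = 0, seed = 6)
  gt <- generate_lattice(spec)
  stk <- render_image(gt, spec)
  expect_s3_class(stk, "image_stack")
  expect_length(stk$planes, 8)
  # per-facet focus oracle: the sharpest plane is the plane nearest the
  # facet's altitude (checked on a spread of facets)
  sharp <- lapply(stk$planes, hexeye:::sharpness_map, window = 9)
  idx <- round(seq(1, nrow(gt$centers), length.out = 12))
  hits <- 0
  for (i in idx) {
    px <- round(gt$centers[i, 1]); py <- round(gt$centers[i, 2])
    win_y <- pmax(1, py - 3):pmin(gt$height, py + 5)
    win_x <- pmax(1, px - 3):pmin(gt$width, px + 5)
    sc <- vapply(sharp, function(s) mean(s[win_y, win_x]), numeric(1))
    best <- which.max(sc)
    truth <- which.min(abs((seq_len(8) - 1) * spec$z_step - gt$z[i]))
    if (abs(best - truth) <= 1) hits <- hits + 1
  }
  expect_gte(hits, 10)
})

test_that("reflections add a second intensity mode inside facets", {
  base <- synthetic_eye_spec(n_target = 150, noise_sd = 0,
                             bristle_density = 0, reflection_strength = 0,
                             jitter_sd = 0, seed = 6)
  gt <- generate_lattice(base)
  img0 <- render_image(gt, base)
  specr <- synthetic_eye_spec(n_target = 150, noise_sd = 0,
                              bristle_density = 0, reflection_strength = 0.5,
                              jitter_sd = 0, seed = 6)
  img1 <- render_image(generate_lattice(specr), specr)
  expect_gt(max(img1[gt$eye_mask]), max(img0[gt$eye_mask]))
  expect_gt(mean(img1[gt$eye_mask]), mean(img0[gt$eye_mask]))
})

test_that("truth-derived annotations carry the requested facet sample", {
  gt <- generate_lattice(synthetic_eye_spec(n_target = 300, seed = 2))
  ann <- annotation_from_truth(gt, n_facets = 40, seed = 1)
  expect_s3_class(ann, "training_annotation")
  expect_equal(max(ann$facet_label), 40L)
  expect_true(all(ann$eye_region[ann$facet_label > 0]))
})
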