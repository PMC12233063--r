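test_that("feature stack has the contracted shape and flat-input behavior", {
  rec <- feature_recipe(sigmas = c(1, 2))
  img <- matrix(0.42, 20, 24)
  fs <- extract_features(img, rec)
  expect_equal(dim(fs), c(20, 24, 13))
  expect_equal(dimnames(fs)[[3]], rec$feature_names)
  # constant image: non-derivative features constant, derivative features 0
  expect_true(all(abs(fs[, , "gauss_s1"] - 0.42) < 1e-6))
  for (f in c("gradmag_s1", "laplacian_s2", "hess_hi_s1", "hess_lo_s2",
              "variance_s1"))
    expect_lt(max(abs(fs[, , f])), 1e-6)
})

test_that("Gaussian channels of a bright dot decay with scale as convolution", {
  img <- matrix(0, 41, 41); img[21, 21] <- 1
  fs <- extract_features(img, feature_recipe(sigmas = c(1, 2, 4)))
  peaks <- c(max(fs[, , "gauss_s1"]), max(fs[, , "gauss_s2"]),
             max(fs[, , "gauss_s4"]))
  expect_true(all(diff(peaks) < 0))
  # peak of a unit impulse equals the Gaussian kernel's central weight
  for (s in c(1, 2)) {
    r <- 2 * ceiling(3 * s) + 1
    k <- dnorm(seq(-(r - 1) / 2, (r - 1) / 2), 0, s)
    k2 <- outer(k, k); k2 <- k2 / sum(k2)
    expect_equal(max(fs[, , paste0("gauss_s", s)]), max(k2),
                 tolerance = 1e-6)
  }
})

test_that("otsu threshold maximizes between-class variance", {
  # bimodal sample: threshold strictly between the modes
  x <- c(rep(0.1, 60), rep(0.9, 40))
  thr <- otsu_threshold(x)
  expect_gt(thr, 0.1)
  expect_lt(thr, 0.9)
  expect_error(otsu_threshold(rep(0.5, 10)), "constant")

  # exhaustive oracle on random histograms
  oracle_split <- function(counts, mids) {
    n <- sum(counts)
    best <- -Inf; kb <- NA
    for (k in 1:(length(counts) - 1)) {
      w0 <- sum(counts[1:k]) / n
      w1 <- 1 - w0
      if (w0 == 0 || w1 == 0) next
      mu0 <- sum(counts[1:k] * mids[1:k]) / sum(counts[1:k])
      mu1 <- sum(counts[-(1:k)] * mids[-(1:k)]) / sum(counts[-(1:k)])
      v <- w0 * w1 * (mu0 - mu1)^2
      if (v > best) { best <- v; kb <- k }
    }
    kb
  }
  withr::with_seed(99, {
    for (rep in 1:20) {
      counts <- rpois(256, lambda = runif(1, 0.5, 20))
      if (sum(counts > 0) < 2) next
      mids <- seq(0, 1, length.out = 256)
      expect_identical(otsu_split(counts, mids), oracle_split(counts, mids))
    }
  })
})

test_that("eye mask keeps the largest component and fills holes", {
  n <- 60
  xs <- matrix(rep(1:n, each = n), n); ys <- matrix(rep(1:n, n), n)
  disk <- (xs - 30)^2 + (ys - 30)^2 <= 15^2
  prob <- disk * 0.95 + 0.02
  expect_equal(eye_mask_from_prob(prob), disk)

  speck <- disk; speck[3:4, 3:4] <- TRUE
  m2 <- eye_mask_from_prob(speck * 0.95 + 0.02)
  expect_equal(m2, disk)  # speck removed
  expect_equal(max(EBImage::bwlabel(m2 * 1)), 1)

  holey <- disk & !((xs - 30)^2 + (ys - 30)^2 <= 4^2)
  expect_equal(eye_mask_from_prob(holey * 0.95 + 0.02), disk)  # hole filled
})

make_separable_annotation <- function() {
  n <- 72
  xs <- matrix(rep(1:n, each = n), n); ys <- matrix(rep(1:n, n), n)
  eye <- (xs - 36)^2 + (ys - 36)^2 <= 30^2
  facets <- matrix(0L, n, n)
  cx <- c(24, 48, 36, 24, 48); cy <- c(24, 24, 36, 48, 48)
  for (k in seq_along(cx))
    facets[(xs - cx[k])^2 + (ys - cy[k])^2 <= 5^2] <- k
  img <- 0.2 + 0.3 * eye + 0.4 * (facets > 0)
  list(img = img,
       ann = training_annotation("toy", eye_region = eye,
                                 facet_label = facets))
}

test_that("training on separable intensities is accurate and seed-deterministic", {
  fx <- make_separable_annotation()
  rec <- feature_recipe(sigmas = c(1, 2, 4))
  m1 <- train_models(fx$ann, fx$img, seed = 5, recipe = rec)
  maps1 <- predict_maps(fx$img, m1$eye, m1$facet)
  # separable training data: near-perfect probabilities on the training image
  expect_gt(mean(maps1$eye_prob[fx$ann$eye_region]), 0.9)
  expect_lt(mean(maps1$eye_prob[!fx$ann$eye_region]), 0.1)
  expect_gt(mean(maps1$facet_prob[fx$ann$facet_label > 0]), 0.5)
  expect_true(min(maps1$eye_prob) >= 0 && max(maps1$eye_prob) <= 1)
  expect_true(min(maps1$facet_prob) >= 0 && max(maps1$facet_prob) <= 1)

  m2 <- train_models(fx$ann, fx$img, seed = 5, recipe = rec)
  maps2 <- predict_maps(fx$img, m2$eye, m2$facet)
  expect_identical(maps1$eye_prob, maps2$eye_prob)
  expect_identical(maps1$facet_prob, maps2$facet_prob)

  # feature recipe mismatch is an error
  m3 <- train_models(fx$ann, fx$img, seed = 5,
                     recipe = feature_recipe(sigmas = c(1, 2)))
  expect_error(predict_maps(fx$img, m1$eye, m3$facet), "recipe")
})

test_that("label-image annotations round trip through PNG", {
  eye <- matrix(FALSE, 30, 30); eye[5:26, 5:26] <- TRUE
  fac <- matrix(0L, 30, 30)
  fac[8:11, 8:11] <- 1L; fac[16:19, 16:19] <- 1L
  lab <- matrix(0L, 30, 30)
  lab[eye] <- 1L; lab[fac > 0] <- 2L
  p <- withr::local_tempfile(fileext = ".png")
  png::writePNG(lab / 255, p)
  ann <- read_annotation(p)
  expect_equal(ann$eye_region, eye)
  expect_equal(max(ann$facet_label), 2L)  # two connected facet groups
  expect_equal(ann$facet_label > 0, fac > 0)
})

test_that("annotations reject facets outside the eye and empty classes", {
  eye <- matrix(FALSE, 10, 10); eye[3:8, 3:8] <- TRUE
  fac <- matrix(0L, 10, 10); fac[1, 1] <- 1L
  expect_error(training_annotation("a", eye, fac), "inside")
  expect_error(training_annotation("a", eye, matrix(0L, 10, 10)), "empty")
})
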