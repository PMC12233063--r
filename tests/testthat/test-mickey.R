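test_that("template geometry follows the three-circle construction", {
  tm <- build_mickey_template(40)
  expect_equal(tm$m, 40L)
  # circle centers are an equilateral triangle with side 0.5 * m = 20
  d12 <- sqrt(sum((tm$anchors[1, ] - tm$anchors[2, ])^2))
  d13 <- sqrt(sum((tm$anchors[1, ] - tm$anchors[3, ])^2))
  d23 <- sqrt(sum((tm$anchors[2, ] - tm$anchors[3, ])^2))
  expect_equal(c(d12, d13, d23), c(20, 20, 20), tolerance = 1e-9)
  # smoothing keeps the maximum strictly below 1
  expect_lt(max(tm$image, na.rm = TRUE), 1)
  # high probability at circle centers (radius 0.225 * m = 9)
  for (k in 1:3)
    expect_gt(tm$image[round(tm$anchors[k, 2]) + 1,
                       round(tm$anchors[k, 1]) + 1], 0.95)
  # non-NaN region is symmetric under swapping the two ears (x mirror)
  nn <- !is.na(tm$image)
  mirrored <- nn[, rev(seq_len(ncol(nn)))]
  expect_true(all(nn == mirrored))
  expect_error(build_mickey_template(15), "m >= 20")
})

test_that("anchor affine maps are exact and detect degeneracy", {
  tm <- build_mickey_template(30)
  a <- tm$anchors
  tr_id <- affine_from_anchors(tm, a[1, ], a[2, ], a[3, ])
  expect_equal(tr_id$A, diag(2), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(tr_id$b, c(0, 0), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(tr_id$slant, 0, tolerance = 1e-6)

  tr_2x <- affine_from_anchors(tm, 2 * a[1, ], 2 * a[2, ], 2 * a[3, ])
  expect_equal(tr_2x$A, 2 * diag(2), tolerance = 1e-9, ignore_attr = TRUE)

  withr::with_seed(4, {
    for (rep in 1:10) {
      tgt <- matrix(runif(6, 0, 100), 3)
      if (abs(det(cbind(tgt[2, ] - tgt[1, ], tgt[3, ] - tgt[1, ]))) < 5) next
      tr <- affine_from_anchors(tm, tgt[1, ], tgt[2, ], tgt[3, ])
      got <- apply_affine(tr, a)
      expect_lt(max(abs(got - tgt)), 1e-9)
    }
  })
  expect_error(affine_from_anchors(tm, c(0, 0), c(1, 1), c(2, 2)),
               "collinear")
})

test_that("closed-form brightness parameter minimizes the objective", {
  tm <- build_mickey_template(24)
  prob <- smooth_prob_image(90, sigma = 2, seed = 11)
  withr::with_seed(12, {
    for (rep in 1:5) {
      e1 <- runif(2, 25, 65); e2 <- e1 + c(12, rnorm(1, 0, 2))
      fc <- (e1 + e2) / 2 + c(0, 10)
      ob <- mickey_objective(prob, tm, e1, e2, fc)
      thetas <- seq(0, 2, by = 1e-4)
      deltas <- vapply(thetas,
                       function(th) mickey_objective(prob, tm, e1, e2, fc,
                                                     theta = th)$delta,
                       numeric(1))
      expect_lt(abs(ob$theta - thetas[which.min(deltas)]), 1e-3)
      expect_lte(ob$delta, min(deltas) + 1e-9)
    }
  })
})

test_that("the objective is invariant under swapping the ears", {
  tm <- build_mickey_template(26)
  prob <- smooth_prob_image(80, sigma = 3, seed = 21)
  e1 <- c(30, 35); e2 <- c(43, 36); fc <- c(36, 48)
  o1 <- mickey_objective(prob, tm, e1, e2, fc)
  o2 <- mickey_objective(prob, tm, e2, e1, fc)
  expect_equal(o1$delta, o2$delta, tolerance = 1e-9)
  expect_equal(o1$theta, o2$theta, tolerance = 1e-9)
})

# render the template into an image at an integer offset with brightness th0
render_template_at <- function(tm, off, th0, n = 120) {
  img <- matrix(0, n, n)
  vals <- tm$image
  vals[is.na(vals)] <- 0
  img[cbind(tm$ty + off[2] + 1, tm$tx + off[1] + 1)] <-
    th0 * vals[cbind(tm$ty + 1, tm$tx + 1)]
  img
}

test_that("fit_candidate recovers a rendered facet center", {
  tm <- build_mickey_template(28)
  th0 <- 0.8
  off <- c(41, 38)
  img <- render_template_at(tm, off, th0)
  truth <- sweep(tm$anchors, 2, off, "+")
  L <- 14  # = 0.5 * m, the template's own edge length
  fit <- fit_candidate(img, truth[1, ], truth[2, ],
                       predicted = truth[3, ] + c(2, -1), omtd1 = NULL,
                       L_grid = L, template = tm)
  expect_lt(sqrt(sum((fit$pos - truth[3, ])^2)), 1)
  expect_equal(fit$theta, th0, tolerance = 0.05)
  expect_lt(fit$delta, 1e-3 * length(tm$tvals))
})

test_that("a prediction far from the only plausible facet is rejected", {
  tm <- build_mickey_template(28)
  off <- c(41, 38)
  img <- render_template_at(tm, off, 0.9)
  truth <- sweep(tm$anchors, 2, off, "+")
  L <- 14
  # predicted face displaced by 0.5 * L_grid: the true facet lies outside the
  # 0.3 * L_grid search disk, which contains only dark background
  fit <- fit_candidate(img, truth[1, ] + c(20, 20), truth[2, ] + c(20, 20),
                       predicted = truth[3, ] + c(20 + 0.5 * L, 20),
                       omtd1 = NULL, L_grid = L, template = tm)
  expect_identical(fit$delta, Inf)
})

test_that("steep or inconsistent slants are rejected", {
  tm <- build_mickey_template(28)
  off <- c(41, 38)
  img <- render_template_at(tm, off, 0.9)
  truth <- sweep(tm$anchors, 2, off, "+")
  # squash the ear separation to mimic an extremely foreshortened facet
  e1 <- truth[3, ] + (truth[1, ] - truth[3, ]) * 0.15
  e2 <- truth[3, ] + (truth[2, ] - truth[3, ]) * 0.15
  fit <- fit_candidate(img, e1, e2, predicted = truth[3, ], omtd1 = NULL,
                       L_grid = 14, template = tm)
  expect_identical(fit$delta, Inf)

  fit2 <- fit_candidate(img, truth[1, ], truth[2, ], predicted = truth[3, ],
                        omtd1 = list(slant = 60), L_grid = 14, template = tm)
  expect_identical(fit2$delta, Inf)  # flat fit vs 60 deg reference slant
})
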