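test_that("Otsu binarization matches the exhaustive between-class oracle", {
  set.seed(11)
  img <- matrix(c(rnorm(1500, 0.2, 0.03), rnorm(1500, 0.8, 0.03)), 50, 60)
  thr_oracle <- otsu_exhaustive(img)
  mask <- binarize(img)
  norm <- (img - min(img)) / diff(range(img))
  # same classification as the oracle threshold (up to quantization)
  expect_lt(mean(mask != (norm > thr_oracle)), 0.005)
  # idempotent on binary input
  bin <- matrix(rep(c(0, 1), each = 50), 10)
  expect_identical(binarize(bin), bin == 1)
  expect_warning(empty <- binarize(matrix(0, 5, 5)), "constant")
  expect_false(any(empty))
})

test_that("Canny finds a thin closed contour on an analytic disc", {
  disc <- make_disc() * 1
  edges <- canny_edges(disc, 1.4, 0.1, 0.3)
  g <- grid_xy(dim(disc))
  r <- sqrt((g$x[edges] - 32)^2 + (g$y[edges] - 32)^2)
  expect_gt(sum(edges), 60)
  expect_true(all(abs(r - 20) <= 1))    # within 1 cell of the true circle
  expect_false(any(canny_edges(matrix(1, 20, 20), 1.4, 0.1, 0.3)))
  expect_error(canny_edges(disc, 1.4, 0.5, 0.2), "low < high")
})

test_that("hysteresis keeps weak edges only when connected to strong ones", {
  # a vertical step edge whose height fades smoothly from strong (top) to
  # weak (bottom): hysteresis keeps the weak tail because it is 8-connected
  # to the strong section
  h <- seq(1, 0.2, length.out = 40)
  img <- matrix(0, 40, 40)
  img[, 21:40] <- matrix(rep(h, 20), 40)
  joined <- canny_edges(img, 1, 0.05, 0.5)
  expect_true(any(joined[35:40, 18:23]))
  # the same weak edge with no strong section of its own is dropped, even
  # though an unconnected strong edge elsewhere sets the same threshold
  img2 <- matrix(0, 40, 40)
  img2[, 21:40] <- 0.2                        # uniformly weak edge at col 20
  img2[, 5:8] <- 1                            # distant strong edges
  alone <- canny_edges(img2, 1, 0.05, 0.5)
  expect_false(any(alone[, 15:30]))
  expect_true(any(alone[, 3:10]))
})

test_that("spot geometry: moments, radius definition, equivariance", {
  disc <- make_disc(r = 20)
  geo <- spot_geometry(disc)
  expect_equal(unname(geo$centroid), c(32, 32), tolerance = 1e-6)
  expect_equal(geo$radius, 20, tolerance = 0.5)
  one <- matrix(FALSE, 9, 9); one[5, 5] <- TRUE
  expect_equal(spot_geometry(one)$radius, sqrt(1 / pi))
  shifted <- make_disc(cx = 37, cy = 29, r = 20)
  gs <- spot_geometry(shifted)
  expect_equal(unname(gs$centroid - geo$centroid), c(5, -3), tolerance = 1e-9)
  expect_error(spot_geometry(matrix(FALSE, 4, 4)), "empty")
})

test_that("inscribed ellipse approximates discs and rectangles", {
  disc <- make_disc(r = 20)
  el <- inscribe_ellipse(disc)
  expect_gte(el$area / (pi * 400), 0.95)
  rect <- matrix(FALSE, 40, 60); rect[11:30, 16:45] <- TRUE
  er <- inscribe_ellipse(rect)
  expect_equal(sort(unname(er$axes)), c(10, 15), tolerance = 0.1)
  expect_error(inscribe_ellipse(matrix(c(TRUE, TRUE, FALSE, FALSE), 2)),
               "thin")
})

test_that("compensation refills a notch bitten out of a disc", {
  disc <- make_disc(r = 20)
  notched <- disc & !make_disc(cx = 50, cy = 32, r = 8)
  comp <- compensate_spot(disc * 1, notched)
  hole <- disc & !notched
  expect_gt(sum(comp$mask & hole) / sum(hole), 0.6)
  # compensated radius close to the intact disc radius
  expect_equal(spot_geometry(comp$mask)$radius, 20, tolerance = 1)
})

test_that("gamma transform identities and rank preservation", {
  img <- matrix(seq(0, 1, length.out = 25), 5)
  expect_equal(gamma_transform(img, 1), img)
  expect_equal(gamma_transform(matrix(0.25), 0.5)[1], 0.5)
  set.seed(3)
  r <- matrix(runif(100), 10)
  for (g in c(0.4, 1, 2.2)) {
    expect_identical(order(gamma_transform(r, g)), order(r))
  }
  expect_error(gamma_transform(img, 0), "> 0")
  expect_error(gamma_transform(img - 2, 1), "negative")
})

test_that("Gaussian fit recovers parameters exactly without noise", {
  sp <- generate_synthetic_spot(c(64, 64), amplitude = 0.9, x0 = 30.3,
                                y0 = 33.7, sx = 6, sy = 4.5, offset = 0.05)
  f <- fit_gaussian(sp$image)
  expect_equal(f$x0, 30.3, tolerance = 1e-6)
  expect_equal(f$y0, 33.7, tolerance = 1e-6)
  expect_equal(f$sx, 6, tolerance = 1e-6)
  expect_equal(f$sy, 4.5, tolerance = 1e-6)
  expect_equal(f$amplitude, 0.9, tolerance = 1e-6)
  expect_lt(glance(f)$rmse, 1e-8)
  td <- tidy(f)
  expect_identical(td$term,
                   c("amplitude", "x0", "y0", "sx", "sy", "offset"))
})

test_that("Gaussian fit centre is stable under 1% noise", {
  errs <- vapply(1:10, function(s) {
    sp <- generate_synthetic_spot(c(64, 64), x0 = 31.2, y0 = 32.8,
                                  sx = 6, sy = 6, noise_sd = 0.01, seed = s)
    f <- fit_gaussian(sp$image)
    sqrt((f$x0 - 31.2)^2 + (f$y0 - 32.8)^2)
  }, numeric(1))
  expect_lt(sqrt(mean(errs^2)), 0.1)
  # symmetric input gives equal sigmas
  sp <- generate_synthetic_spot(c(64, 64), x0 = 32, y0 = 32, sx = 5, sy = 5)
  f <- fit_gaussian(sp$image)
  expect_equal(f$sx, f$sy, tolerance = 1e-6)
})

test_that("halo overlay conserves linear energy and handles edge cases", {
  obs <- default_observer()
  hp <- halo_profile(obs, reference_scene(), reference_exposure(),
                     max_radius_cells = 40, deg_per_cell = 0.1)
  expect_true(all(diff(hp$luminance) <= 0))
  sp <- generate_synthetic_spot(c(64, 64), x0 = 32, y0 = 32, sx = 6, sy = 6)
  f <- fit_gaussian(sp$image)
  ov <- overlay_halo(sp$image, f, hp, mode = "additive")
  expect_equal(sum(ov$linear), sum(sp$image) + sum(ov$halo_image))
  expect_true(all(ov$image >= 0 & ov$image <= 1))
  # zero halo: output equals the renormalized spot
  zero <- hp; zero$luminance <- rep(0, nrow(hp))
  ov0 <- overlay_halo(sp$image, f, zero)
  rng <- range(sp$image)
  expect_equal(ov0$image, (sp$image - rng[1]) / diff(rng), tolerance = 1e-9)
  # halo-only image is radially non-increasing from the centre
  flat <- matrix(0, 64, 64)
  ovh <- overlay_halo(flat, f, hp)
  g <- grid_xy(c(64, 64))
  r <- sqrt((g$x - f$x0)^2 + (g$y - f$y0)^2)
  ord <- order(r)
  profile_sorted <- ovh$linear[ord]
  expect_true(all(diff(profile_sorted) <= 1e-9))
  bad <- f; bad$x0 <- 200
  expect_error(overlay_halo(sp$image, bad, hp), "outside")
})

test_that("generator is deterministic and analytic at zero noise", {
  a <- generate_synthetic_spot(c(32, 32), noise_sd = 0.05, seed = 9)
  b <- generate_synthetic_spot(c(32, 32), noise_sd = 0.05, seed = 9)
  expect_identical(a$image, b$image)
  d <- generate_synthetic_spot(c(32, 32), noise_sd = 0.05, seed = 10)
  expect_false(identical(a$image, d$image))
  clean <- generate_synthetic_spot(c(32, 32), amplitude = 2, x0 = 10,
                                   y0 = 12, sx = 3, sy = 4, offset = 0.1)
  g <- grid_xy(c(32, 32))
  expected <- 2 * exp(-((g$x - 10)^2 / 18 + (g$y - 12)^2 / 32)) + 0.1
  expect_equal(clean$image, expected)
})

test_that("pipeline is translation-equivariant", {
  sp1 <- generate_synthetic_spot(c(64, 64), x0 = 28, y0 = 30, sx = 6, sy = 6)
  sp2 <- generate_synthetic_spot(c(64, 64), x0 = 33, y0 = 36, sx = 6, sy = 6)
  p1 <- process_spot(sp1$image)
  p2 <- process_spot(sp2$image)
  expect_equal(p2$summary$fit_x0 - p1$summary$fit_x0, 5, tolerance = 0.1)
  expect_equal(p2$summary$fit_y0 - p1$summary$fit_y0, 6, tolerance = 0.1)
  expect_equal(p2$summary$centroid_x - p1$summary$centroid_x, 5,
               tolerance = 0.1)
})

test_that("pipeline recovers truth on defected noisy spots", {
  res <- vapply(1:20, function(s) {
    sp <- generate_synthetic_spot(
      c(64, 64), x0 = 30 + s / 10, y0 = 33 - s / 10, sx = 7, sy = 7,
      notch = list(x = 36 + s %% 3, y = 30, radius = 5),
      noise_sd = 0.02, seed = s)
    clean <- generate_synthetic_spot(c(64, 64), x0 = 30 + s / 10,
                                     y0 = 33 - s / 10, sx = 7, sy = 7)
    ref_radius <- spot_geometry(binarize(clean$image))$radius
    p <- process_spot(sp$image)
    c(sqrt((p$summary$fit_x0 - sp$truth$x0)^2 +
             (p$summary$fit_y0 - sp$truth$y0)^2),
      abs(p$summary$radius_cells - ref_radius) / ref_radius)
  }, numeric(2))
  expect_lt(median(res[1, ]), 0.5)
  expect_lt(median(res[2, ]), 0.05)
})
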